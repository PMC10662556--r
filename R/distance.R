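#' Empirical conditional profile of one gene for one attribute
#'
#' The profile is the empirical distribution P(category | gene): the
#' fraction of the gene's mutation records carrying each category of the
#' attribute.  Unseen categories get probability 0 implicitly (no
#' smoothing or pseudocounts), which is what makes small worked examples
#' exact rationals.
#'
#' @param tbl A mutation table.
#' @param gene A gene present in the table.
#' @param attribute An attribute column of the table.
#' @return A tibble with columns `gene`, `attribute`, `category`, `prob`
#'   and `support` (the gene's record count); `prob` sums to 1.
#' @examples
#' tab <- mutation_table(data.frame(
#'   gene = c("FAM171B", "FAM171B", "FAM171B", "ABCA6"),
#'   mutation_type = c("Missense", "Nonsense", "Missense", "Missense"),
#'   nucleotide_change = c("AA>AC", "GG>GT", "GG>GA", "GG>GT")
#' ))
#' conditional_profile(tab, "FAM171B", "mutation_type")
#' @export
conditional_profile <- function(tbl, gene, attribute) {
  if (!gene %in% tbl$gene) {
    abort_lookup(paste0("unknown gene: ", gene))
  }
  if (!attribute %in% attribute_names(tbl)) {
    abort_lookup(paste0("unknown attribute: ", attribute))
  }
  vals <- tbl[[attribute]][tbl$gene == gene]
  counts <- table(vals)
  tibble::tibble(
    gene = gene,
    attribute = attribute,
    category = names(counts),
    prob = as.numeric(counts) / length(vals),
    support = length(vals)
  )
}

#' All conditional profiles of a table
#'
#' @param tbl A mutation table.
#' @param attributes Attributes to profile (default: all).
#' @return A long tibble with one row per (gene, attribute, category),
#'   columns as in [conditional_profile()].
#' @export
conditional_profiles <- function(tbl, attributes = attribute_names(tbl)) {
  purrr::map_dfr(attributes, function(a) {
    tbl |>
      dplyr::count(.data$gene, category = .data[[a]]) |>
      dplyr::group_by(.data$gene) |>
      dplyr::mutate(
        attribute = a,
        support = sum(.data$n),
        prob = .data$n / .data$support
      ) |>
      dplyr::ungroup() |>
      dplyr::select("gene", "attribute", "category", "prob", "support")
  })
}

profile_vectors <- function(p, q) {
  pa <- unique(p$attribute)
  qa <- unique(q$attribute)
  if (length(pa) != 1 || length(qa) != 1 || !identical(pa, qa)) {
    abort_domain("profiles must be over the same single attribute")
  }
  cats <- sort(union(p$category, q$category))
  list(
    categories = cats,
    p = stats::setNames(p$prob, p$category)[cats] |>
      tidyr::replace_na(0) |> unname(),
    q = stats::setNames(q$prob, q$category)[cats] |>
      tidyr::replace_na(0) |> unname()
  )
}

#' Co-occurrence distance between two conditional profiles
#'
#' The distance for one attribute is the maximum, over subsets w of the
#' attribute's categories, of `P_x(w) + P_y(~w) - 1`.  This subset
#' maximization has the closed form `sum_v max(p_x(v), p_y(v)) - 1`,
#' which equals half the L1 distance between the profiles (the total
#' variation distance), so no subset enumeration is needed.  The value
#' lies in [0, 1]: 0 iff the profiles are identical, 1 iff their
#' supports are disjoint.
#'
#' @param p,q Conditional profiles from [conditional_profile()] over the
#'   same attribute (typically for two different genes).
#' @return The distance, a double in `[0, 1]`.
#' @seealso [attribute_distance_bruteforce()] for the literal
#'   subset-enumeration computation with the maximizing subset.
#' @export
attribute_distance <- function(p, q) {
  v <- profile_vectors(p, q)
  sum(pmax(v$p, v$q)) - 1
}

#' Co-occurrence distance by explicit subset enumeration
#'
#' Enumerates all 2^K subsets w of the union vocabulary and maximizes
#' `P_x(w) + P_y(~w) - 1` directly.  Exponential in the vocabulary, so
#' it is guarded at K <= 20; it exists as the ground-truth reference for
#' [attribute_distance()] and to report the maximizing subset.
#'
#' @inheritParams attribute_distance
#' @return A list with `value` (the distance) and `omega` (the
#'   maximizing category subset; among ties the smallest subset, then the
#'   lexicographically first, is returned).
#' @export
attribute_distance_bruteforce <- function(p, q) {
  v <- profile_vectors(p, q)
  k <- length(v$categories)
  if (k > 20) {
    abort_domain(sprintf(
      "vocabulary of %d categories is too large for 2^K enumeration; use attribute_distance()", k
    ))
  }
  # rows of `subsets`: membership indicators for all 2^k subsets
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  vals <- as.numeric(subsets %*% v$p + (!subsets) %*% v$q) - 1
  best <- max(vals)
  cand <- which(abs(vals - best) < 1e-15)
  sizes <- rowSums(subsets)[cand]
  cand <- cand[sizes == min(sizes)]
  keys <- vapply(cand, function(i) {
    paste(v$categories[subsets[i, ]], collapse = "\r")
  }, character(1))
  pick <- cand[order(keys)][[1]]
  list(value = best, omega = v$categories[subsets[pick, ]])
}

#' Distance between two genes
#'
#' The mean of the per-attribute co-occurrence distances over the
#' configured attributes (with the two default attributes, half the sum
#' of the mutation-type and nucleotide-change distances).
#'
#' @param tbl A mutation table.
#' @param x,y Gene identifiers present in the table.
#' @param attributes Attributes to average over (default: all).
#' @return The gene distance, a double in `[0, 1]`; 0 iff the two genes
#'   have identical conditional profiles for every attribute.
#' @export
gene_distance <- function(tbl, x, y, attributes = attribute_names(tbl)) {
  ds <- vapply(attributes, function(a) {
    attribute_distance(
      conditional_profile(tbl, x, a),
      conditional_profile(tbl, y, a)
    )
  }, numeric(1))
  mean(ds)
}

#' All-pairs gene distance matrix
#'
#' Precomputes, per attribute, each gene's conditional profile as a row
#' of a gene-by-category probability matrix; the per-attribute distance
#' between two genes is then half the Manhattan distance between their
#' rows, and the gene distance is the mean over attributes.  Each
#' unordered pair is evaluated once and mirrored; the diagonal is
#' exactly zero; genes are sorted lexicographically so the result does
#' not depend on record order.
#'
#' @param tbl A mutation table with at least two genes.
#' @param attributes Attributes to average over (default: all).
#' @return A `ccn_dist` object: the symmetric matrix plus the gene index
#'   and the attributes used.  Supports `as.matrix()`, `tidy()`,
#'   `glance()`, `autoplot()` and `print()`.
#' @examples
#' tab <- mutation_table(data.frame(
#'   gene = c("FAM171B", "FAM171B", "FAM171B", "ABCA6"),
#'   mutation_type = c("Missense", "Nonsense", "Missense", "Missense"),
#'   nucleotide_change = c("AA>AC", "GG>GT", "GG>GA", "GG>GT")
#' ))
#' d <- pairwise_distance_matrix(tab)
#' as.matrix(d)
#' @export
pairwise_distance_matrix <- function(tbl, attributes = attribute_names(tbl)) {
  genes <- gene_index(tbl)
  if (length(genes) < 2) {
    abort_domain("need at least 2 genes to build a distance matrix")
  }
  acc <- matrix(0, length(genes), length(genes),
    dimnames = list(genes, genes)
  )
  for (a in attributes) {
    counts <- table(factor(tbl$gene, levels = genes), tbl[[a]])
    probs <- unclass(counts / rowSums(counts))
    # total variation distance = half the L1 distance between profile rows
    acc <- acc + as.matrix(stats::dist(probs, method = "manhattan")) / 2
  }
  values <- acc / length(attributes)
  diag(values) <- 0
  new_ccn_dist(values, genes, attributes)
}

new_ccn_dist <- function(values, genes, attributes) {
  dimnames(values) <- list(genes, genes)
  structure(
    list(
      genes = genes,
      values = values,
      attributes = attributes,
      n_attributes = length(attributes)
    ),
    class = "ccn_dist"
  )
}

#' @export
print.ccn_dist <- function(x, ...) {
  cat(sprintf(
    "# Gene distance matrix: %d genes, attributes: %s\n",
    length(x$genes), paste(x$attributes, collapse = ", ")
  ))
  off <- x$values[upper.tri(x$values)]
  if (length(off)) {
    cat(sprintf(
      "# off-diagonal distances: min %.4g, median %.4g, max %.4g\n",
      min(off), stats::median(off), max(off)
    ))
  }
  print(utils::head(tidy(x)), ...)
  invisible(x)
}

#' @export
as.matrix.ccn_dist <- function(x, ...) x$values

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a gene distance matrix into a pair table
#'
#' @param x A `ccn_dist` object.
#' @param threshold Optional: keep only pairs with
#'   `distance <= threshold` (within a 1e-9 tolerance).
#' @param ... Unused.
#' @return A tibble with one row per unordered gene pair
#'   (`gene_a < gene_b`): columns `gene_a`, `gene_b`, `distance`,
#'   `similarity` (= 1 - distance), sorted by pair.
#' @export
tidy.ccn_dist <- function(x, threshold = NULL, ...) {
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  out <- tibble::tibble(
    gene_a = x$genes[idx[, 1]],
    gene_b = x$genes[idx[, 2]],
    distance = x$values[idx],
    similarity = 1 - x$values[idx]
  ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  if (!is.null(threshold)) {
    out <- dplyr::filter(out, .data$distance <= threshold + 1e-9)
  }
  out
}

#' One-row summary of a gene distance matrix
#'
#' @param x A `ccn_dist` object.
#' @param ... Unused.
#' @return A one-row tibble: gene count, attribute count, and the
#'   min/mean/max off-diagonal distance plus the number of zero-distance
#'   ("very similar") pairs.
#' @export
glance.ccn_dist <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  tibble::tibble(
    n_genes = length(x$genes),
    n_attributes = x$n_attributes,
    min_distance = min(off),
    mean_distance = mean(off),
    max_distance = max(off),
    n_zero_pairs = sum(off <= 1e-9)
  )
}

#' Heatmap of a gene distance matrix
#'
#' @param object A `ccn_dist` object.
#' @param ... Unused.
#' @return A ggplot: genes on both axes, tiles filled by distance.
#' @export
autoplot.ccn_dist <- function(object, ...) {
  long <- tibble::as_tibble(as.table(object$values), .name_repair = ~ c(
    "gene_a", "gene_b", "distance"
  ))
  ggplot2::ggplot(long, ggplot2::aes(
    .data$gene_a, .data$gene_b,
    fill = .data$distance
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), direction = -1) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "distance",
      title = "Co-occurrence gene distances"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' Write / read a distance matrix as TSV
#'
#' The file has gene names as both header row and first column and the
#' full symmetric matrix printed with 10 significant digits.
#'
#' @param d A `ccn_dist` object.
#' @param path Output (or input) path.
#' @param attributes For the reader: attribute names to record on the
#'   restored object (the file does not carry them).
#' @return `write_distance_matrix()`: `path`, invisibly;
#'   `read_distance_matrix()`: a `ccn_dist` object.
#' @export
write_distance_matrix <- function(d, path) {
  m <- format(d$values, digits = 10, scientific = FALSE, trim = TRUE)
  lines <- c(
    paste(c("gene", d$genes), collapse = "\t"),
    vapply(seq_along(d$genes), function(i) {
      paste(c(d$genes[[i]], m[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path, attributes = character(0)) {
  if (!file.exists(path)) abort_config(paste0("file not found: ", path))
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      gene = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  genes <- df$gene
  values <- as.matrix(df[, -1])
  if (!identical(colnames(values), genes)) {
    abort_config("distance matrix file is not square with matching gene names")
  }
  new_ccn_dist(values, genes, attributes)
}

#' Write a thresholded long-format edge list
#'
#' @param d A `ccn_dist` object.
#' @param path Output path.
#' @param threshold Keep pairs with `distance <= threshold`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(d, path, threshold = 1) {
  readr::write_tsv(tidy(d, threshold = threshold), path, progress = FALSE)
  invisible(path)
}
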