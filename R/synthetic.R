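#' Specify a synthetic mutation dataset with known gene profiles
#'
#' A synthetic spec fixes, for every gene and attribute, the true
#' categorical distribution records are drawn from.  Attributes are
#' sampled independently within a record: the distance only consumes
#' per-attribute marginals conditional on gene, so independence is the
#' simplest structure that exercises it, and the true (population)
#' distance between any two genes is available in closed form via
#' [true_distance()].
#'
#' @param probs A data frame with columns `gene`, `attribute`,
#'   `category`, `prob`.  For each (gene, attribute) the probabilities
#'   must be non-negative and sum to 1 within 1e-9; every gene must have
#'   a distribution for every attribute.
#' @param mutations_per_gene Number of records to draw per gene: a
#'   single integer, or a named integer vector keyed by gene.
#' @param seed Integer seed; generation is fully reproducible from it,
#'   and each gene gets its own substream so adding a gene does not
#'   perturb the others' draws.
#' @return A `ccn_spec` object.
#' @export
synthetic_spec <- function(probs, mutations_per_gene, seed = 1L) {
  probs <- tibble::as_tibble(probs)
  need <- c("gene", "attribute", "category", "prob")
  if (!all(need %in% names(probs))) {
    abort_config(paste0(
      "spec needs columns: ", paste(need, collapse = ", ")
    ))
  }
  genes <- sort(unique(probs$gene))
  attributes <- sort(unique(probs$attribute))
  chk <- probs |>
    dplyr::group_by(.data$gene, .data$attribute) |>
    dplyr::summarise(total = sum(.data$prob), neg = any(.data$prob < 0),
      .groups = "drop"
    )
  bad <- chk |>
    dplyr::filter(abs(.data$total - 1) > 1e-9 | .data$neg)
  if (nrow(bad)) {
    abort_config(sprintf(
      "invalid distribution for gene '%s', attribute '%s' (sum %.12g)",
      bad$gene[[1]], bad$attribute[[1]], bad$total[[1]]
    ))
  }
  if (nrow(chk) != length(genes) * length(attributes)) {
    abort_config("every gene needs a distribution for every attribute")
  }
  n <- mutations_per_gene
  if (is.null(names(n))) {
    n <- stats::setNames(rep(as.integer(n), length(genes)), genes)
  } else {
    missing <- setdiff(genes, names(n))
    if (length(missing)) {
      abort_config(paste0(
        "mutations_per_gene missing for: ", paste(missing, collapse = ", ")
      ))
    }
    n <- stats::setNames(as.integer(n[genes]), genes)
  }
  if (any(n < 1)) abort_config("mutations_per_gene must be >= 1")
  structure(
    list(
      probs = dplyr::arrange(
        probs, .data$gene, .data$attribute, .data$category
      ),
      genes = genes,
      attributes = attributes,
      mutations_per_gene = n,
      seed = as.integer(seed)
    ),
    class = "ccn_spec"
  )
}

#' @export
print.ccn_spec <- function(x, ...) {
  cat(sprintf(
    "# Synthetic spec: %d genes x %d attributes, %s records/gene, seed %d\n",
    length(x$genes), length(x$attributes),
    if (length(unique(x$mutations_per_gene)) == 1) {
      as.character(x$mutations_per_gene[[1]])
    } else {
      sprintf("%d-%d", min(x$mutations_per_gene), max(x$mutations_per_gene))
    },
    x$seed
  ))
  invisible(x)
}

# Deterministic 31-bit substream seed from (seed, gene name): a small
# polynomial hash over the UTF-8 bytes, folded with the global seed.
gene_substream_seed <- function(seed, gene) {
  h <- as.numeric(seed %% 2147483647)
  for (b in as.integer(charToRaw(gene))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

#' Draw a mutation table from a synthetic spec
#'
#' Genes are generated in sorted order, each from its own seeded
#' substream; within a gene, records are drawn sequentially and each
#' attribute is sampled independently from its specified distribution.
#' Two calls with the same spec produce byte-identical tables.
#'
#' @param spec A `ccn_spec` from [synthetic_spec()].
#' @return A `ccn_mut_tbl` mutation table.
#' @export
generate_table <- function(spec) {
  rows <- purrr::map_dfr(spec$genes, function(g) {
    n <- spec$mutations_per_gene[[g]]
    out <- tibble::tibble(gene = rep(g, n))
    set.seed(gene_substream_seed(spec$seed, g))
    for (a in spec$attributes) {
      d <- spec$probs[spec$probs$gene == g & spec$probs$attribute == a, ]
      out[[a]] <- if (nrow(d) == 1) {
        rep(d$category, n)
      } else {
        sample(d$category, n, replace = TRUE, prob = d$prob)
      }
    }
    out
  })
  mutation_table(rows, attributes = spec$attributes)
}

#' Ground-truth distance between two genes of a synthetic spec
#'
#' Applies the co-occurrence distance to the true distributions instead
#' of empirical profiles: the mean over attributes of
#' `sum_v max(p_x(v), p_y(v)) - 1`.  Empirical distances from
#' [generate_table()] converge to this value as `mutations_per_gene`
#' grows.
#'
#' @param spec A `ccn_spec`.
#' @param x,y Gene names in the spec.
#' @return The true distance, a double in `[0, 1]`.
#' @export
true_distance <- function(spec, x, y) {
  for (g in c(x, y)) {
    if (!g %in% spec$genes) abort_lookup(paste0("unknown gene: ", g))
  }
  ds <- vapply(spec$attributes, function(a) {
    sub <- spec$probs[spec$probs$attribute == a, ]
    px <- sub[sub$gene == x, ]
    py <- sub[sub$gene == y, ]
    cats <- union(px$category, py$category)
    p <- stats::setNames(px$prob, px$category)[cats]
    q <- stats::setNames(py$prob, py$category)[cats]
    p[is.na(p)] <- 0
    q[is.na(q)] <- 0
    sum(pmax(p, q)) - 1
  }, numeric(1))
  mean(ds)
}

#' All-pairs ground-truth distance matrix of a spec
#'
#' @param spec A `ccn_spec`.
#' @return A `ccn_dist` over the spec's genes with the closed-form true
#'   distances.
#' @export
true_distance_matrix <- function(spec) {
  genes <- spec$genes
  values <- matrix(0, length(genes), length(genes))
  for (i in seq_along(genes)) {
    for (j in seq_len(i - 1L)) {
      v <- true_distance(spec, genes[[i]], genes[[j]])
      values[i, j] <- v
      values[j, i] <- v
    }
  }
  new_ccn_dist(values, genes, spec$attributes)
}

#' Random synthetic spec over the point-mutation vocabularies
#'
#' Draws, for each gene, Dirichlet-like random distributions (normalized
#' exponentials) over the six mutation types and the twelve nucleotide
#' changes — the structure of real point-mutation tables.
#'
#' @param n_genes Number of genes (named `G001`, `G002`, ...).
#' @param mutations_per_gene Records per gene.
#' @param seed Integer seed (also stored in the spec).
#' @param vocab Named list of category vectors per attribute; defaults
#'   to the six mutation types and twelve `REF>ALT` changes.
#' @param concentration Dirichlet concentration; 1 gives uniform random
#'   distributions over the simplex.
#' @return A `ccn_spec`.
#' @export
random_synthetic_spec <- function(n_genes, mutations_per_gene, seed = 1L,
                                  vocab = default_attribute_vocab(),
                                  concentration = 1) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  set.seed(seed)
  probs <- purrr::map_dfr(genes, function(g) {
    purrr::map_dfr(names(vocab), function(a) {
      w <- stats::rgamma(length(vocab[[a]]), shape = concentration)
      tibble::tibble(
        gene = g, attribute = a,
        category = vocab[[a]], prob = w / sum(w)
      )
    })
  })
  synthetic_spec(probs, mutations_per_gene, seed = seed)
}

#' Default attribute vocabularies for point mutations
#'
#' @return A named list: the six mutation types and the twelve possible
#'   single-nucleotide changes.
#' @export
default_attribute_vocab <- function() {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  list(
    mutation_type = c(
      "Missense", "Nonsense", "Nonstop", "RNA", "Silent", "Splice_Site"
    ),
    nucleotide_change = sort(paste0(pairs$ref, ">", pairs$alt))
  )
}

#' Read / write a synthetic spec as YAML
#'
#' The YAML layout is `seed`, `mutations_per_gene` (scalar or map), and
#' `genes: {gene: {attribute: {category: prob}}}`.
#'
#' @param path File path.
#' @param spec A `ccn_spec` (for the writer).
#' @return `read_synthetic_spec()`: a `ccn_spec`;
#'   `write_synthetic_spec()`: `path`, invisibly.
#' @export
read_synthetic_spec <- function(path) {
  if (!file.exists(path)) abort_config(paste0("file not found: ", path))
  y <- yaml::read_yaml(path)
  probs <- purrr::imap_dfr(y$genes, function(atts, g) {
    purrr::imap_dfr(atts, function(dist, a) {
      tibble::tibble(
        gene = g, attribute = a,
        category = names(dist), prob = as.numeric(unlist(dist))
      )
    })
  })
  n <- y$mutations_per_gene
  if (is.list(n)) n <- unlist(n)
  synthetic_spec(probs, n, seed = y$seed %||% 1L)
}

#' @rdname read_synthetic_spec
#' @export
write_synthetic_spec <- function(spec, path) {
  genes <- split(spec$probs, spec$probs$gene)
  y <- list(
    seed = spec$seed,
    mutations_per_gene = if (length(unique(spec$mutations_per_gene)) == 1) {
      unname(spec$mutations_per_gene[[1]])
    } else {
      as.list(spec$mutations_per_gene)
    },
    genes = lapply(genes, function(gdf) {
      lapply(split(gdf, gdf$attribute), function(adf) {
        stats::setNames(as.list(adf$prob), adf$category)
      })
    })
  )
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}
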