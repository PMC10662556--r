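EDGE_TOL <- 1e-9

new_ccn_network <- function(nodes, edges, threshold, mode,
                            seeds = character(0)) {
  structure(
    list(
      nodes = tibble::tibble(gene = nodes),
      edges = edges |>
        dplyr::arrange(.data$gene_a, .data$gene_b),
      threshold = threshold,
      mode = mode,
      seeds = seeds
    ),
    class = "ccn_network"
  )
}

empty_edges <- function() {
  tibble::tibble(
    gene_a = character(0), gene_b = character(0),
    distance = numeric(0), similarity = numeric(0)
  )
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
    is.na(threshold) || threshold < 0 || threshold > 1) {
    abort_domain("threshold must be a single number in [0, 1]")
  }
}

check_seed_gene <- function(d, seed) {
  if (!seed %in% d$genes) abort_lookup(paste0("unknown gene: ", seed))
}

#' Global gene similarity network from a distance matrix
#'
#' Connects every gene pair whose distance is at most `threshold` (with
#' a 1e-9 tolerance so threshold-0 "very similar" networks are robust to
#' floating-point noise).  Each edge carries both the distance and the
#' similarity `1 - distance`, so the orientation of either number is
#' always explicit.
#'
#' @param d A `ccn_dist` object from [pairwise_distance_matrix()].
#' @param threshold Maximum edge distance, in `[0, 1]`.
#' @param include_isolated Keep genes with no surviving edge as isolated
#'   nodes (default `FALSE`, matching the connected local neighborhoods
#'   one usually visualizes).
#' @return A `ccn_network`: tibbles of nodes and edges plus the
#'   threshold and mode.  Supports `tidy()`, `glance()`, `autoplot()`,
#'   [as_igraph()] and [export_network()].
#' @export
build_network <- function(d, threshold, include_isolated = FALSE) {
  check_threshold(threshold)
  edges <- tidy(d, threshold = threshold)
  nodes <- if (include_isolated) {
    d$genes
  } else {
    sort(unique(c(edges$gene_a, edges$gene_b)))
  }
  new_ccn_network(nodes, edges, threshold, "global")
}

#' Ego (local) network of one seed gene
#'
#' The neighborhood of `seed`: every gene within `threshold` of the seed,
#' with seed-to-neighbor edges always present and neighbor-to-neighbor
#' edges added only when `include_neighbor_edges` is set (and they pass
#' the threshold themselves).
#'
#' @inheritParams build_network
#' @param seed The seed gene.
#' @param include_neighbor_edges Also connect qualifying neighbors to
#'   each other.
#' @return A `ccn_network` with `mode = "ego"`.
#' @export
ego_network <- function(d, seed, threshold,
                        include_neighbor_edges = FALSE) {
  check_threshold(threshold)
  check_seed_gene(d, seed)
  dist_to_seed <- d$values[seed, ]
  neighbors <- setdiff(names(which(dist_to_seed <= threshold + EDGE_TOL)), seed)
  pair <- function(a, b) {
    tibble::tibble(
      gene_a = pmin(a, b), gene_b = pmax(a, b),
      distance = d$values[cbind(a, b)]
    )
  }
  edges <- if (length(neighbors)) pair(seed, neighbors) else empty_edges()
  if (include_neighbor_edges && length(neighbors) > 1) {
    combs <- utils::combn(sort(neighbors), 2)
    nn <- pair(combs[1, ], combs[2, ])
    edges <- dplyr::bind_rows(
      edges, nn[nn$distance <= threshold + EDGE_TOL, ]
    )
  }
  edges$similarity <- 1 - edges$distance
  new_ccn_network(
    sort(c(seed, neighbors)), edges, threshold, "ego",
    seeds = seed
  )
}

#' Intersection network of two seed genes
#'
#' Genes simultaneously within `threshold` of both seeds; each
#' qualifying gene is connected to both seeds.  With identical seeds
#' this degenerates to [ego_network()] (a message is emitted).
#'
#' @inheritParams build_network
#' @param seed_a,seed_b The two seed genes.
#' @return A `ccn_network` with `mode = "intersection"` (or `"ego"` for
#'   identical seeds).
#' @export
intersection_network <- function(d, seed_a, seed_b, threshold) {
  check_threshold(threshold)
  check_seed_gene(d, seed_a)
  check_seed_gene(d, seed_b)
  if (seed_a == seed_b) {
    message("identical seeds; returning the ego network of ", seed_a)
    return(ego_network(d, seed_a, threshold))
  }
  near_a <- d$values[seed_a, ] <= threshold + EDGE_TOL
  near_b <- d$values[seed_b, ] <= threshold + EDGE_TOL
  shared <- setdiff(d$genes[near_a & near_b], c(seed_a, seed_b))
  edges <- if (length(shared)) {
    purrr::map_dfr(c(seed_a, seed_b), function(s) {
      tibble::tibble(
        gene_a = pmin(s, shared), gene_b = pmax(s, shared),
        distance = d$values[cbind(s, shared)]
      )
    })
  } else {
    empty_edges()
  }
  edges$similarity <- 1 - edges$distance
  new_ccn_network(
    sort(c(seed_a, seed_b, shared)), edges, threshold, "intersection",
    seeds = c(seed_a, seed_b)
  )
}

#' @export
print.ccn_network <- function(x, ...) {
  cat(sprintf(
    "# Gene similarity network (%s): %d nodes, %d edges, threshold %g%s\n",
    x$mode, nrow(x$nodes), nrow(x$edges), x$threshold,
    if (length(x$seeds)) paste0(", seeds: ", paste(x$seeds, collapse = ", ")) else ""
  ))
  print(x$edges, ...)
  invisible(x)
}

#' Tidy a network into its edge table
#'
#' @param x A `ccn_network`.
#' @param ... Unused.
#' @return The edge tibble (`gene_a`, `gene_b`, `distance`,
#'   `similarity`), sorted.
#' @export
tidy.ccn_network <- function(x, ...) x$edges

#' One-row summary of a network
#'
#' @param x A `ccn_network`.
#' @param ... Unused.
#' @return A one-row tibble with node/edge counts, threshold, mode and
#'   mean edge distance.
#' @export
glance.ccn_network <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    threshold = x$threshold,
    mean_edge_distance = if (nrow(x$edges)) mean(x$edges$distance) else NA_real_
  )
}

#' Convert a network to an igraph graph
#'
#' @param net A `ccn_network`.
#' @return An undirected igraph object with edge attributes `distance`
#'   and `similarity` and graph attribute `threshold`.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges,
    directed = FALSE, vertices = net$nodes
  )
  igraph::graph_attr(g, "threshold") <- net$threshold
  igraph::graph_attr(g, "mode") <- net$mode
  g
}

#' Plot a gene similarity network
#'
#' @param object A `ccn_network`.
#' @param ... Unused.
#' @return A ggplot of the graph with a deterministic circular layout;
#'   edges shaded by similarity, seed genes highlighted.
#' @export
autoplot.ccn_network <- function(object, ...) {
  genes <- object$nodes$gene
  ang <- seq(0, 2 * pi, length.out = length(genes) + 1)[seq_along(genes)]
  lay <- tibble::tibble(
    gene = genes, x = cos(ang), y = sin(ang),
    seed = genes %in% object$seeds
  )
  ed <- object$edges |>
    dplyr::left_join(dplyr::rename(lay[1:3], xa = "x", ya = "y"),
      by = c(gene_a = "gene")
    ) |>
    dplyr::left_join(dplyr::rename(lay[1:3], xb = "x", yb = "y"),
      by = c(gene_b = "gene")
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(.data$xa, .data$ya,
        xend = .data$xb, yend = .data$yb,
        alpha = .data$similarity
      )
    ) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(.data$x, .data$y, color = .data$seed), size = 3
    ) +
    ggplot2::geom_text(
      data = lay,
      ggplot2::aes(.data$x * 1.12, .data$y * 1.12, label = .data$gene),
      size = 3
    ) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey30"), guide = "none"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(
      alpha = "similarity",
      title = sprintf(
        "%s network, threshold %g", object$mode, object$threshold
      )
    )
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

write_gexf <- function(net, path) {
  nodes <- sort(net$nodes$gene)
  e <- net$edges
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<gexf xmlns=\"http://www.gexf.net/1.2draft\" version=\"1.2\">",
    sprintf(
      "  <graph defaultedgetype=\"undirected\" mode=\"static\" threshold=\"%.10g\">",
      net$threshold
    ),
    "    <attributes class=\"edge\">",
    "      <attribute id=\"0\" title=\"distance\" type=\"double\"/>",
    "      <attribute id=\"1\" title=\"similarity\" type=\"double\"/>",
    "    </attributes>",
    "    <nodes>",
    sprintf(
      "      <node id=\"%s\" label=\"%s\"/>",
      xml_escape(nodes), xml_escape(nodes)
    ),
    "    </nodes>",
    "    <edges>"
  )
  if (nrow(e)) {
    lines <- c(lines, sprintf(
      paste0(
        "      <edge id=\"%d\" source=\"%s\" target=\"%s\" ",
        "weight=\"%.10g\"><attvalues>",
        "<attvalue for=\"0\" value=\"%.10g\"/>",
        "<attvalue for=\"1\" value=\"%.10g\"/>",
        "</attvalues></edge>"
      ),
      seq_len(nrow(e)) - 1L, xml_escape(e$gene_a), xml_escape(e$gene_b),
      e$similarity, e$distance, e$similarity
    ))
  }
  c(lines, "    </edges>", "  </graph>", "</gexf>") |>
    writeLines(path)
  invisible(path)
}

#' Export a network for visualization
#'
#' Writes Gephi-compatible GEXF 1.2 or GraphML, or a plain edge-list
#' TSV with columns `gene_a`, `gene_b`, `distance`, `similarity`.
#' Node and edge ordering is lexicographic, so identical networks
#' export to identical files.
#'
#' @param net A `ccn_network`.
#' @param path Output path.
#' @param format `"tsv"`, `"gexf"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "gexf", "graphml")) {
  format <- match.arg(format)
  switch(format,
    tsv = readr::write_tsv(net$edges, path, progress = FALSE),
    gexf = write_gexf(net, path),
    graphml = igraph::write_graph(as_igraph(net), path, format = "graphml")
  )
  invisible(path)
}

#' Read an edge-list TSV back into an edge table
#'
#' Companion of `export_network(format = "tsv")`; round-trips the edge
#' multiset exactly.
#'
#' @param path Path to the TSV written by [export_network()].
#' @return The edge tibble.
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      gene_a = readr::col_character(),
      gene_b = readr::col_character(),
      distance = readr::col_double(),
      similarity = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
}
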