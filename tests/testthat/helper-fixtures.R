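# Shared fixtures: the four-row worked example and randomized generators.

worked_example_path <- function() {
  system.file("extdata", "worked_example.tsv", package = "cooccurnet")
}

worked_example_table <- function() {
  mutation_table(data.frame(
    gene = c("FAM171B", "FAM171B", "FAM171B", "ABCA6"),
    mutation_type = c("Missense", "Nonsense", "Missense", "Missense"),
    nucleotide_change = c("AA>AC", "GG>GT", "GG>GA", "GG>GT")
  ))
}

# A conditional-profile tibble with random probabilities over k categories.
random_profile <- function(k, gene = "X", attribute = "a",
                           categories = paste0("c", seq_len(k))) {
  w <- stats::rgamma(k, shape = 1)
  # random sparsity so disjoint / partial-overlap supports occur
  keep <- stats::runif(k) < 0.8
  if (!any(keep)) keep[sample.int(k, 1)] <- TRUE
  w[!keep] <- 0
  w <- w / sum(w)
  tibble::tibble(
    gene = gene, attribute = attribute,
    category = categories[w > 0], prob = w[w > 0],
    support = 1L
  )
}

# Small random mutation table: few categories so identical empirical
# profiles occur by chance (exercising the zero-distance case).
random_table <- function(n_genes, max_records = 30, n_cats = 2) {
  genes <- paste0("g", seq_len(n_genes))
  rows <- lapply(genes, function(g) {
    n <- sample.int(max_records, 1)
    data.frame(
      gene = rep(g, n),
      mutation_type = sample(paste0("T", seq_len(n_cats)), n, replace = TRUE),
      nucleotide_change = sample(c("A>G", "C>T", "G>A")[seq_len(n_cats)],
        n,
        replace = TRUE
      )
    )
  })
  mutation_table(do.call(rbind, rows))
}

# TRUE iff two genes have identical empirical profiles on every attribute.
profiles_identical <- function(tbl, x, y) {
  all(vapply(attribute_names(tbl), function(a) {
    p <- conditional_profile(tbl, x, a)
    q <- conditional_profile(tbl, y, a)
    identical(p$category, q$category) &&
      isTRUE(all.equal(p$prob, q$prob, tolerance = 1e-12))
  }, logical(1)))
}

# Distance-matrix fixture whose genes A,B,C share one profile, D and E others.
ego_fixture_table <- function() {
  prof <- function(g, type, change) {
    data.frame(gene = g, mutation_type = type, nucleotide_change = change)
  }
  mutation_table(rbind(
    prof("S", "Missense", "G>T"),
    prof("A", "Missense", "G>T"),
    prof("B", "Missense", "G>T"),
    prof("C", "Missense", "G>T"),
    prof("D", "Silent", "A>G"),
    prof("E", "Nonsense", "C>T")
  ))
}
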