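test_that("conditional profiles reproduce the worked example's fractions", {
  tab <- worked_example_table()
  p <- conditional_profile(tab, "FAM171B", "mutation_type")
  expect_equal(p$category, c("Missense", "Nonsense"))
  expect_equal(p$prob, c(2 / 3, 1 / 3))
  expect_equal(unique(p$support), 3L)
  expect_equal(sum(p$prob), 1, tolerance = 1e-12)

  q <- conditional_profile(tab, "ABCA6", "mutation_type")
  expect_equal(q$category, "Missense")
  expect_equal(q$prob, 1)
  expect_equal(q$support, 1L)

  expect_error(conditional_profile(tab, "NOPE", "mutation_type"),
    "NOPE",
    class = "ccn_lookup_error"
  )
  expect_error(conditional_profile(tab, "ABCA6", "zone"),
    class = "ccn_lookup_error"
  )
})

test_that("conditional_profiles matches per-gene calls over the whole table", {
  set.seed(11)
  tbl <- random_table(6, max_records = 12, n_cats = 3)
  long <- conditional_profiles(tbl)
  for (g in gene_index(tbl)) {
    for (a in attribute_names(tbl)) {
      one <- long[long$gene == g & long$attribute == a, ]
      expect_equal(
        one[order(one$category), names(one)],
        conditional_profile(tbl, g, a)
      )
    }
  }
})

test_that("per-attribute distances reproduce the worked example", {
  tab <- worked_example_table()
  p1 <- conditional_profile(tab, "FAM171B", "mutation_type")
  q1 <- conditional_profile(tab, "ABCA6", "mutation_type")
  expect_equal(attribute_distance(p1, q1), 1 / 3, tolerance = 1e-12)

  p2 <- conditional_profile(tab, "FAM171B", "nucleotide_change")
  q2 <- conditional_profile(tab, "ABCA6", "nucleotide_change")
  expect_equal(p2$prob, rep(1 / 3, 3))
  expect_equal(attribute_distance(p2, q2), 2 / 3, tolerance = 1e-12)

  expect_error(attribute_distance(p1, q2), class = "ccn_domain_error")
})

test_that("identical and disjoint profiles hit the distance extremes", {
  prof <- function(g, cats, probs) {
    tibble::tibble(
      gene = g, attribute = "a", category = cats,
      prob = probs, support = 10L
    )
  }
  p <- prof("x", c("u", "v"), c(0.4, 0.6))
  expect_equal(attribute_distance(p, prof("y", c("u", "v"), c(0.4, 0.6))), 0)
  expect_equal(attribute_distance(prof("x", "u", 1), prof("y", "v", 1)), 1)
})

test_that("brute-force enumeration returns the maximizing subset", {
  tab <- worked_example_table()
  p <- conditional_profile(tab, "ABCA6", "mutation_type")
  q <- conditional_profile(tab, "FAM171B", "mutation_type")
  bf <- attribute_distance_bruteforce(p, q)
  expect_equal(bf$value, 1 / 3, tolerance = 1e-12)
  expect_equal(bf$omega, "Missense")
  # swapped arguments maximize at the complementary subset, same value
  bf2 <- attribute_distance_bruteforce(q, p)
  expect_equal(bf2$value, 1 / 3, tolerance = 1e-12)
  expect_equal(bf2$omega, "Nonsense")

  same <- attribute_distance_bruteforce(p, p)
  expect_equal(same$value, 0)
  expect_equal(same$omega, character(0)) # smallest tying subset

  big_p <- tibble::tibble(
    gene = "x", attribute = "a",
    category = paste0("c", 1:21), prob = rep(1 / 21, 21), support = 21L
  )
  expect_error(attribute_distance_bruteforce(big_p, big_p),
    class = "ccn_domain_error"
  )
})

test_that("the closed form equals subset enumeration on random profiles", {
  set.seed(101)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    p <- random_profile(k, gene = "x")
    q <- random_profile(k, gene = "y")
    fast <- attribute_distance(p, q)
    slow <- attribute_distance_bruteforce(p, q)
    expect_equal(fast, slow$value, tolerance = 1e-12)
    # and both equal half the L1 distance on the union support
    cats <- sort(union(p$category, q$category))
    pv <- setNames(rep(0, length(cats)), cats)
    qv <- pv
    pv[p$category] <- p$prob
    qv[q$category] <- q$prob
    expect_equal(fast, sum(abs(pv - qv)) / 2, tolerance = 1e-12)
  }
})

test_that("gene distance averages the attribute distances (worked example: 1/2)", {
  tab <- worked_example_table()
  expect_equal(gene_distance(tab, "FAM171B", "ABCA6"), 1 / 2, tolerance = 1e-12)
  expect_equal(gene_distance(tab, "ABCA6", "FAM171B"), 1 / 2, tolerance = 1e-12)
  expect_equal(gene_distance(tab, "ABCA6", "ABCA6"), 0)
  expect_error(gene_distance(tab, "ABCA6", "NOPE"), class = "ccn_lookup_error")
  # restricting to one attribute reproduces that attribute's distance
  expect_equal(
    gene_distance(tab, "FAM171B", "ABCA6", attributes = "mutation_type"),
    1 / 3,
    tolerance = 1e-12
  )
})

test_that("the all-pairs matrix matches the worked example and the naive loop", {
  tab <- worked_example_table()
  d <- pairwise_distance_matrix(tab)
  expect_equal(d$genes, c("ABCA6", "FAM171B"))
  expect_equal(
    as.matrix(d),
    matrix(c(0, 0.5, 0.5, 0), 2, 2,
      dimnames = list(d$genes, d$genes)
    ),
    tolerance = 1e-12
  )

  set.seed(7)
  big <- random_table(20, max_records = 25, n_cats = 3)
  dm <- as.matrix(pairwise_distance_matrix(big))
  genes <- gene_index(big)
  for (i in seq_along(genes)) {
    for (j in seq_len(i)) {
      expect_equal(dm[i, j], gene_distance(big, genes[[i]], genes[[j]]),
        tolerance = 1e-12
      )
    }
  }
  expect_error(
    pairwise_distance_matrix(mutation_table(data.frame(
      gene = "solo", mutation_type = "Missense", nucleotide_change = "A>G"
    ))),
    class = "ccn_domain_error"
  )
})

test_that("the matrix is invariant to record order", {
  set.seed(21)
  tbl <- random_table(8, max_records = 15, n_cats = 3)
  shuffled <- mutation_table(
    tibble::as_tibble(tbl)[sample.int(nrow(tbl)), ]
  )
  expect_equal(
    as.matrix(pairwise_distance_matrix(tbl)),
    as.matrix(pairwise_distance_matrix(shuffled))
  )
})

test_that("distances satisfy range, symmetry, identity, and the zero law", {
  set.seed(33)
  for (rep in 1:20) {
    tbl <- random_table(sample(3:8, 1), max_records = 10, n_cats = 2)
    m <- as.matrix(pairwise_distance_matrix(tbl))
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    genes <- gene_index(tbl)
    for (i in seq_along(genes)) {
      for (j in seq_len(i - 1)) {
        same <- profiles_identical(tbl, genes[[i]], genes[[j]])
        expect_equal(m[i, j] <= 1e-12, same)
      }
    }
  }
})

test_that("the triangle inequality holds on random tables", {
  set.seed(55)
  for (rep in 1:10) {
    tbl <- random_table(6, max_records = 12, n_cats = 3)
    m <- as.matrix(pairwise_distance_matrix(tbl))
    n <- nrow(m)
    for (i in 1:n) {
      for (j in 1:n) {
        for (k in 1:n) {
          expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-12)
        }
      }
    }
  }
})

test_that("matrix TSV and thresholded edge lists round-trip", {
  set.seed(5)
  tbl <- random_table(6, max_records = 10, n_cats = 3)
  d <- pairwise_distance_matrix(tbl)

  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, mpath)
  back <- read_distance_matrix(mpath, attributes = d$attributes)
  expect_equal(back$genes, d$genes)
  expect_equal(as.matrix(back), as.matrix(d), tolerance = 1e-9)

  epath <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(d, epath, threshold = 0.5)
  edges <- read_edge_list(epath)
  expect_equal(edges, tidy(d, threshold = 0.5))
  expect_true(all(edges$distance <= 0.5 + 1e-9))
  expect_equal(edges$similarity, 1 - edges$distance)
})

test_that("tidy and glance summarize a distance matrix", {
  d <- pairwise_distance_matrix(worked_example_table())
  td <- tidy(d)
  expect_equal(nrow(td), 1)
  expect_equal(td$gene_a, "ABCA6")
  expect_equal(td$distance, 0.5, tolerance = 1e-12)
  g <- glance(d)
  expect_equal(g$n_genes, 2)
  expect_equal(g$n_zero_pairs, 0)
  expect_s3_class(autoplot(d), "ggplot")
})
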