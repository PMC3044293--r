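test_that("std_within worked examples and invariances hold", {
  m <- tiny_matrix(matrix(c(0, 2, 5, 5), 2, 2))
  # 2 genes x 1 array, values {0, 2}: column mean 1, sqrt((1+1)/2) = 1
  expect_equal(std_within(m, c("g1", "g2"), "a1"), 1)
  # identical profiles -> 0
  m2 <- tiny_matrix(matrix(c(1, 1, -2, -2, 0.5, 0.5), 2, 3))
  expect_equal(std_within(m2, c("g1", "g2"), colnames(m2)), 0)
  # adding a per-array constant to all selected genes changes nothing
  set.seed(14)
  vals <- matrix(rnorm(50), 10, 5)
  shifted <- sweep(vals, 2, c(5, -3, 0.5, 100, -7), "+")
  a <- std_within(tiny_matrix(vals), paste0("g", 1:10), paste0("a", 1:5))
  b <- std_within(tiny_matrix(shifted), paste0("g", 1:10), paste0("a", 1:5))
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(std_within(m, "g1", "a1"), "at least 2")
})

test_that("std_across worked examples and homogeneity hold", {
  m <- tiny_matrix(rbind(c(3, 1, -4, 2), rnorm(4)))
  # single gene, arrays {a1, a3}: sqrt((9 + 16) / 2)
  expect_equal(std_across(m, "g1", c("a1", "a3")), sqrt(12.5))
  zero <- tiny_matrix(matrix(c(1, -1, 2, -2), 2, 2))
  expect_equal(std_across(zero, c("g1", "g2"), c("a1", "a2")), 0)
  set.seed(15)
  vals <- matrix(rnorm(30), 6, 5)
  for (c_scale in c(-3, 0.25, 7)) {
    expect_equal(std_across(tiny_matrix(vals * c_scale),
                            paste0("g", 1:6), paste0("a", 1:5)),
                 abs(c_scale) * std_across(tiny_matrix(vals),
                                           paste0("g", 1:6),
                                           paste0("a", 1:5)),
                 tolerance = 1e-12)
  }
})

test_that("quality statistics match naive double-loop oracles on random data", {
  set.seed(16)
  for (rep in 1:5) {
    vals <- matrix(rnorm(300), 20, 15)
    vals[sample(300, 10)] <- NA
    m <- tiny_matrix(vals)
    genes <- sample(rownames(m), 8)
    arrays <- sample(colnames(m), 6)
    expect_equal(std_within(m, genes, arrays),
                 naive_std_within(m, genes, arrays), tolerance = 1e-10)
    expect_equal(std_across(m, genes, arrays),
                 naive_std_across(m, genes, arrays), tolerance = 1e-10)
  }
})

test_that("categorization covers the caption cases", {
  T2 <- c("t1", "t2")
  N2 <- c("n1", "n2")
  expect_identical(categorize_bicluster(character(0), T2, N2), "empty")
  expect_identical(categorize_bicluster(T2, T2, N2), "only_full_seed_set")
  expect_identical(categorize_bicluster("t1", T2, N2),
                   "only_part_of_seed_set")
  expect_identical(categorize_bicluster("n2", T2, N2), "only_random_seed")
  expect_identical(categorize_bicluster(c(T2, "x"), T2, N2),
                   "full_seed_set_and_additional")
  expect_identical(categorize_bicluster(c("t1", "n1", "x"), T2, N2),
                   "part_of_seed_set_and_additional")
  expect_identical(categorize_bicluster(c("n1", "x"), T2, N2),
                   "random_seed_and_additional")
  expect_identical(categorize_bicluster(c("x", "y"), T2, N2), "drift_away")
  expect_error(categorize_bicluster("t1", T2, c("t1", "n1")), "disjoint")
})

test_that("every membership pattern over a six-gene universe maps to exactly one category", {
  universe <- c("t1", "t2", "n1", "n2", "o1", "o2")
  labels <- bicluster_categories()
  seen <- character(0)
  for (bits in 0:63) {
    members <- universe[bitwAnd(bits, 2^(0:5)) > 0]
    lab <- categorize_bicluster(members, c("t1", "t2"), c("n1", "n2"))
    expect_length(lab, 1)
    expect_true(lab %in% labels)
    seen <- union(seen, lab)
  }
  expect_setequal(seen, labels)  # all eight categories are reachable
})

test_that("hypergeometric mid-P reproduces the worked value and the enumeration oracle", {
  expect_equal(hypergeom_midp(2, 4, 3, 10), 0.5 * 0.3 + 1 / 30,
               tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:50) {
    N <- sample(2:30, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    expect_equal(hypergeom_midp(k, K, n, N), enum_midp(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("mid-P identities hold", {
  # maximal overlap leaves only half of its own mass
  expect_equal(hypergeom_midp(3, 4, 3, 10), 0.5 * dhyper(3, 4, 6, 3),
               tolerance = 1e-14)
  # upper and lower mid-P partition the probability mass
  for (k in 0:3) {
    upper <- hypergeom_midp(k, 4, 3, 10)
    lower <- 0.5 * dhyper(k, 4, 6, 3) + phyper(k - 1, 4, 6, 3)
    expect_equal(upper + lower, 1, tolerance = 1e-12)
    # mid-P is strictly below the classical upper tail when P(X = k) > 0
    if (dhyper(k, 4, 6, 3) > 0)
      expect_lt(upper, dhyper(k, 4, 6, 3) + phyper(k, 4, 6, 3,
                                                   lower.tail = FALSE))
  }
  expect_error(hypergeom_midp(4, 4, 3, 10), "impossible")
  expect_error(hypergeom_midp(1, 12, 3, 10), "universe")
})

test_that("enrichment excludes seeds and matches per-annotation mid-P calls", {
  universe <- paste0("g", 1:20)
  annotations <- list(A = paste0("g", 1:5),
                      B = paste0("g", 6:12),
                      C = paste0("g", 13:16))
  bicluster <- c("g1", "g2", "g6", "g7", "g8", "g9", "g13")
  seeds <- c("g1", "g2")
  res <- enrich_bicluster(bicluster, seeds, annotations, universe)
  expect_identical(res$annotation_id, c("A", "B", "C"))
  expect_identical(res$overlap, c(0L, 4L, 1L))
  # oracle: direct per-call evaluation on the seed-excluded query of size 5
  for (i in 1:3)
    expect_equal(res$midp[i],
                 hypergeom_midp(res$overlap[i],
                                length(annotations[[i]]), 5, 20),
                 tolerance = 1e-14)
  expect_true(res$significant[2])  # B contains 4 of 5 query genes

  # query identical to one annotation minimizes that annotation's mid-P
  res2 <- enrich_bicluster(c(seeds, annotations$C), seeds, annotations,
                           universe)
  expect_identical(res2$annotation_id[which.min(res2$midp)], "C")

  # bicluster equal to the seed set leaves nothing to test
  res3 <- enrich_bicluster(seeds, seeds, annotations, universe)
  expect_identical(nrow(res3), 0L)
  expect_true(attr(res3, "empty_query"))
})

test_that("recall and enrichment are plain set arithmetic", {
  r <- recall_and_enrichment(paste0("g", 1:10), paste0("s", 1:4),
                             c("g1", "g2", "v3", "v4", "v5"))
  expect_equal(r$recall, 0.4)
  expect_equal(r$enrichment, 0.2)
  full <- recall_and_enrichment(c("v1", "v2"), "s1", c("v1", "v2"))
  expect_equal(full$recall, 1)
  expect_equal(full$enrichment, 1)
  empty <- recall_and_enrichment(character(0), "s1", "v1")
  expect_equal(empty$recall, 0)
  expect_equal(empty$enrichment, 0)
  expect_error(recall_and_enrichment("g", "s", character(0)), "empty")
  expect_error(recall_and_enrichment("g", "s", "s"), "disjoint")
})
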