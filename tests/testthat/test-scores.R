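# neutral prior: log_penalty 0, p_gene 0.5, zero biases, explicit
# hyperparameters; background fixed by hand
neutral_setup <- function(vals, seeds, bg_mu, bg_sigma,
                          mu0 = NULL, sigma0 = 1, kappa0 = 1, nu0 = 1) {
  m <- expression_matrix(vals)
  bg <- background_model(setNames(rep(bg_mu, ncol(m)), colnames(m)),
                         setNames(rep(bg_sigma, ncol(m)), colnames(m)))
  pr <- build_prior(m, seeds, bg, log_penalty = 0, p_gene = 0.5,
                    kappa0 = kappa0, nu0 = nu0)
  if (!is.null(mu0)) pr$mu0[] <- mu0
  pr$sigma0[] <- sigma0
  list(m = m, bg = bg, pr = pr)
}

test_that("gene score equals the worked one-array example", {
  vals <- matrix(c(2, 0, 0, 0), 2, 2,
                 dimnames = list(c("g1", "g2"), c("a1", "a2")))
  s <- neutral_setup(vals, "g1", bg_mu = 0, bg_sigma = 1)
  asg <- init_assignments(s$m, "g1")
  asg$array[, 1] <- c(TRUE, FALSE)  # one member array
  params <- map_update_params(s$m, asg, s$pr)
  params$mu["a1", 1] <- 2
  params$sigma["a1", 1] <- 0.5
  score <- gene_log_score("g1", 1, s$m, params, asg, s$bg, s$pr)
  # logN(2; 2, 0.5) - logN(2; 0, 1) = -log(0.5) + 2
  expect_equal(score, -log(0.5) + 2, tolerance = 1e-12)
})

test_that("bicluster identical to background scores zero under neutral priors", {
  set.seed(3)
  vals <- matrix(rnorm(20), 5, 4,
                 dimnames = list(paste0("g", 1:5), paste0("a", 1:4)))
  s <- neutral_setup(vals, c("g1", "g2"), bg_mu = 0.3, bg_sigma = 1.1)
  asg <- init_assignments(s$m, c("g1", "g2"))
  params <- map_update_params(s$m, asg, s$pr)
  params$mu[, 1] <- s$bg$mu
  params$sigma[, 1] <- s$bg$sigma
  for (g in rownames(vals))
    expect_equal(gene_log_score(g, 1, s$m, params, asg, s$bg, s$pr), 0,
                 tolerance = 1e-12)
})

test_that("an array where background fits better strictly lowers the gene score", {
  vals <- matrix(c(2, 0, 5, 0), 2, 2,
                 dimnames = list(c("g1", "g2"), c("a1", "a2")))
  s <- neutral_setup(vals, "g1", bg_mu = 0, bg_sigma = 1)
  asg <- init_assignments(s$m, "g1")
  params <- map_update_params(s$m, asg, s$pr)
  params$mu[, 1] <- 2      # bicluster centred at 2 on both arrays
  params$sigma[, 1] <- 0.5
  asg$array[, 1] <- c(TRUE, FALSE)
  one <- gene_log_score("g1", 1, s$m, params, asg, s$bg, s$pr)
  asg$array[, 1] <- c(TRUE, TRUE)  # a2 value 5 is likelier under neither,
                                   # but far worse under the tight bicluster
  two <- gene_log_score("g1", 1, s$m, params, asg, s$bg, s$pr)
  expect_lt(two, one)
})

test_that("gene score with no member arrays reduces to the prior terms", {
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("a", 1:4)))
  m <- expression_matrix(vals)
  bg <- estimate_background(m, trim_fraction = 0, sigma_floor = 1e-8)
  pr <- build_prior(m, "g1", bg, log_penalty = 7, p_gene = 0.2,
                    gene_bias = c(g1 = 0.25))
  asg <- init_assignments(m, "g1")
  asg$array[, 1] <- FALSE
  params <- map_update_params(m, asg, pr)
  expect_equal(gene_log_score("g1", 1, m, params, asg, bg, pr),
               log(0.2 / 0.8) + 0.25, tolerance = 1e-12)
})

test_that("array score is positive for a tight displaced member-gene profile", {
  set.seed(41)
  n_mem <- 20
  vals <- matrix(rnorm(25 * 3), 25, 3,
                 dimnames = list(paste0("g", sprintf("%02d", 1:25)),
                                 paste0("a", 1:3)))
  vals[1:n_mem, 1] <- rnorm(n_mem, 3, 0.1)  # 3 background sigmas away
  m <- expression_matrix(vals)
  bg <- estimate_background(m, trim_fraction = 0, sigma_floor = 1e-8)
  bg$mu[] <- 0
  bg$sigma[] <- 1
  pr <- build_prior(m, rownames(vals)[1:n_mem], bg, log_penalty = log(2),
                    p_gene = 0.05)
  asg <- init_assignments(m, rownames(vals)[1:n_mem])
  expect_gt(array_log_score("a1", 1, m, asg, bg, pr), 0)
})

test_that("array score cannot beat the background's own maximum-likelihood fit", {
  # member-gene values on a1 have mean and ML sd exactly equal to the
  # background parameters, so no candidate Normal can improve on the
  # background term-sum; the score is bounded by the penalty and bias terms
  z <- c(-1.5, -0.5, 0.5, 1.5)
  z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))  # ML-standardized
  vals <- cbind(z, rnorm(4), rnorm(4))
  dimnames(vals) <- list(paste0("g", 1:4), paste0("a", 1:3))
  m <- expression_matrix(vals)
  bg <- background_model(setNames(rep(0, 3), colnames(m)),
                         setNames(rep(1, 3), colnames(m)))
  for (lp in c(0, log(2), 1)) {
    pr <- build_prior(m, rownames(vals), bg, log_penalty = lp, p_gene = 0.5)
    pr$mu0[] <- 0
    asg <- init_assignments(m, rownames(vals))
    expect_lte(array_log_score("a1", 1, m, asg, bg, pr),
               -4 * lp + 1e-12)
  }
})

test_that("array score is invariant under member-gene order", {
  set.seed(9)
  vals <- matrix(rnorm(30), 10, 3,
                 dimnames = list(paste0("g", sprintf("%02d", 1:10)),
                                 paste0("a", 1:3)))
  m1 <- expression_matrix(vals)
  perm <- sample(10)
  m2 <- expression_matrix(vals[perm, ])
  seeds <- c("g03", "g07", "g09")
  bg1 <- estimate_background(m1, sigma_floor = 1e-6)
  bg2 <- estimate_background(m2, sigma_floor = 1e-6)
  pr1 <- build_prior(m1, seeds, bg1)
  pr2 <- build_prior(m2, seeds, bg2)
  s1 <- array_log_score("a2", 1, m1, init_assignments(m1, seeds), bg1, pr1)
  s2 <- array_log_score("a2", 1, m2, init_assignments(m2, seeds), bg2, pr2)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("array score demands member genes", {
  m <- tiny_matrix(matrix(rnorm(12), 3, 4))
  bg <- estimate_background(m, sigma_floor = 1e-6)
  pr <- build_prior(m, "g1", bg)
  asg <- init_assignments(m, "g1")
  asg$gene[, 1] <- FALSE
  expect_error(array_log_score("a1", 1, m, asg, bg, pr), "no member genes")
})
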