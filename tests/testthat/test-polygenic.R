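test_that("polygenic log-likelihood matches hand-computed densities", {
  # single standard-normal observation: -0.5 * log(2 * pi)
  ped1 <- build_pedigree(data.frame(id = "a", family_id = "f", pair_id = "",
                                    zygosity = "NONE", sex = 0, age = 30))
  d1 <- structure(list(ids = "a", X = cbind(intercept = 1)),
                  class = "covariate_design")
  for (h2 in c(0, 0.3, 0.9)) {
    expect_equal(polygenic_loglik(0, d1, expected_relatedness(ped1),
                                  h2 = h2, sigma_p2 = 1, beta = 0),
                 -0.5 * log(2 * pi), tolerance = 1e-10)
  }

  # MZ pair at the origin with h2 = 0.5: bivariate normal, correlation 0.5
  ped2 <- build_pedigree(data.frame(id = c("a", "b"), family_id = "f",
                                    pair_id = "p", zygosity = "MZ",
                                    sex = 0, age = 30))
  d2 <- structure(list(ids = c("a", "b"), X = cbind(intercept = c(1, 1))),
                  class = "covariate_design")
  expect_equal(polygenic_loglik(c(0, 0), d2, expected_relatedness(ped2),
                                h2 = 0.5, sigma_p2 = 1, beta = 0),
               -log(2 * pi) - 0.5 * log(0.75), tolerance = 1e-10)
  expect_equal(round(-log(2 * pi) - 0.5 * log(0.75), 4), -1.694)

  # h2 = 1 with an MZ pair makes the covariance singular
  expect_error(polygenic_loglik(c(0, 0), d2, expected_relatedness(ped2),
                                h2 = 1, sigma_p2 = 1, beta = 0),
               "singular family block")
})

test_that("blockwise likelihood equals the dense-matrix oracle", {
  for (seed in 1:30) {
    set.seed(seed + 100)
    n <- sample(8:30, 1)
    ped <- random_pedigree(n, seed = seed)
    n <- nrow(ped)
    K <- expected_relatedness(ped)
    des <- test_design(ped$id)
    y <- rnorm(n, sd = 2)
    h2 <- runif(1, 0, 0.95)
    s2 <- runif(1, 0.2, 3)
    beta <- rnorm(ncol(des$X), sd = 0.3)
    ll <- polygenic_loglik(y, des, K, h2 = h2, sigma_p2 = s2, beta = beta)
    oracle <- dense_mvn_loglik(y, drop(des$X %*% beta),
                               s2 * (h2 * unclass(K) + (1 - h2) * diag(n)))
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant under joint relabeling of individuals", {
  ped_df <- as.data.frame(random_pedigree(16, seed = 2))
  set.seed(7)
  y <- rnorm(nrow(ped_df))
  perm <- sample(nrow(ped_df))
  d <- test_design(ped_df$id)
  ll1 <- polygenic_loglik(y, d, expected_relatedness(build_pedigree(ped_df)),
                          h2 = 0.4, sigma_p2 = 1.3, beta = rep(0, 6))
  d2 <- structure(list(ids = ped_df$id[perm], X = d$X[perm, , drop = FALSE]),
                  class = "covariate_design")
  ll2 <- polygenic_loglik(y[perm], d2,
                          expected_relatedness(build_pedigree(ped_df[perm, ])),
                          h2 = 0.4, sigma_p2 = 1.3, beta = rep(0, 6))
  expect_equal(ll2, ll1, tolerance = 1e-10)
})

test_that("boundary LRT p-values follow the 50:50 mixture", {
  expect_equal(lrt_boundary_pvalue(0), 0.5)
  expect_equal(lrt_boundary_pvalue(-1e-8), 0.5)
  expect_equal(lrt_boundary_pvalue(3.84), 0.025, tolerance = 1e-3)
  expect_equal(lrt_boundary_pvalue(3.84),
               0.5 * pchisq(3.84, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(lrt_boundary_pvalue(-0.1), "negative")
})

test_that("perfect within-MZ correlation drives h2 to the boundary", {
  set.seed(31)
  n_pairs <- 50
  vals <- rnorm(n_pairs, sd = 2)
  ped <- build_pedigree(data.frame(
    id = paste0("i", 1:(2 * n_pairs)),
    family_id = rep(paste0("f", 1:n_pairs), each = 2),
    pair_id = rep(paste0("p", 1:n_pairs), each = 2),
    zygosity = "MZ", sex = rep_len(c(0, 1), 2 * n_pairs),
    age = rep(runif(n_pairs, 20, 40), each = 2)))
  y <- rep(vals, each = 2)
  fit <- fit_univariate(y, intercept_design(ped$id), expected_relatedness(ped))
  expect_gte(fit$h2, 0.99)
  expect_true(is.na(fit$se_h2))   # curvature unreliable at the boundary
})

test_that("null cohorts give near-zero heritability estimates", {
  ests <- vapply(1:20, function(s) {
    sim_fit_h2(0, seed = 9000 + s, n_mz = 100, n_dz = 100, n_single = 100)$h2
  }, numeric(1))
  expect_lt(median(ests), 0.05)
})

test_that("maximum-likelihood fit matches the dense grid-search oracle", {
  for (seed in 1:8) {
    ped <- random_pedigree(12, seed = 300 + seed)
    n <- nrow(ped)
    K <- expected_relatedness(ped)
    set.seed(seed)
    d <- intercept_design(ped$id)
    g <- drop(msqrt_test(unclass(K)) %*% rnorm(n))
    y <- sqrt(0.6) * g + sqrt(0.4) * rnorm(n)
    if (inherits(try(fit_univariate(y, d, K), silent = TRUE), "try-error")) next
    fit <- fit_univariate(y, d, K)
    oracle <- grid_fit_h2(y, d$X, unclass(K))
    expect_lt(abs(fit$h2 - oracle$h2), 0.005)
  }
})

test_that("estimates are invariant to affine rescaling of the trait", {
  co <- simulate_cohort(cohort_spec(
    n_mz_pairs = 60, n_dz_pairs = 40, n_singletons = 30,
    traits = list(y = list(h2 = 0.5, mean = 0, var = 1))), seed = 12)
  d <- covariate_design(co$pedigree$id, co$pedigree$age, co$pedigree$sex)
  K <- expected_relatedness(co$pedigree)
  f1 <- fit_univariate(co$phenotypes$y, d, K)
  f2 <- fit_univariate(7 * co$phenotypes$y - 3, d, K)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-6)
  expect_equal(f2$sigma_p2, 49 * f1$sigma_p2, tolerance = 1e-4)
  expect_equal(f2$p_boundary, f1$p_boundary, tolerance = 1e-6)
})

test_that("all-singleton cohorts are rejected as unidentifiable", {
  ped <- build_pedigree(data.frame(
    id = paste0("i", 1:40), family_id = paste0("f", 1:40), pair_id = "",
    zygosity = "NONE", sex = rep_len(c(0, 1), 40), age = 30 + (1:40) %% 7))
  set.seed(2)
  expect_error(fit_univariate(rnorm(40), intercept_design(ped$id),
                              expected_relatedness(ped)),
               "unidentifiable")
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- sim_fit_h2(0.5, seed = 77, n_mz = 60, n_dz = 40, n_single = 20)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  expect_equal(td$estimate[td$term == "h2"], fit$h2)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_used, fit$n_used)
})

test_that("implied phenotypic correlation evaluates the decomposition formula", {
  expect_equal(implied_phenotypic_correlation(1, 1, 0.5, -0.8), 0.5)
  expect_equal(implied_phenotypic_correlation(0.3, 0.3, 0.7, 0.7), 0.7,
               tolerance = 1e-12)
  # frozen hand evaluation: 0.42 * sqrt(0.1584) + 0.19 * sqrt(0.2584)
  expect_equal(implied_phenotypic_correlation(0.24, 0.66, 0.42, 0.19),
               0.2637407, tolerance = 1e-7)
  expect_error(implied_phenotypic_correlation(1.2, 0.5, 0, 0), "0, 1")
})
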