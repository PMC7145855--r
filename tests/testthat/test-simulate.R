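within_pair_cor <- function(co, zyg, trait = 1) {
  ped <- co$pedigree
  v <- co$phenotypes[[trait + 1]]
  idx <- which(ped$zygosity == zyg)
  first <- idx[seq(1, length(idx), by = 2)]
  cor(v[first], v[first + 1])
}

test_that("within-pair correlations converge to h2 (MZ) and h2/2 (DZ)", {
  # average the empirical within-pair correlation over 3 independent draws
  # of 2000 pairs, tightening the Monte-Carlo error well below the band
  for (h2 in c(0.2, 0.5, 0.8)) {
    spec <- cohort_spec(n_mz_pairs = 2000, n_dz_pairs = 2000, n_singletons = 0,
                        traits = list(y = list(h2 = h2, mean = 0, var = 1)),
                        covariate_effects = list())
    draws <- lapply(1:3, function(s) simulate_cohort(spec, seed = round(1000 * h2) + s))
    expect_lt(abs(mean(vapply(draws, within_pair_cor, numeric(1), zyg = "MZ")) - h2),
              0.03)
    expect_lt(abs(mean(vapply(draws, within_pair_cor, numeric(1), zyg = "DZ")) - h2 / 2),
              0.03)
  }
})

test_that("a non-heritable trait shows no familial signal", {
  spec <- cohort_spec(n_mz_pairs = 2000, n_dz_pairs = 0, n_singletons = 0,
                      traits = list(y = list(h2 = 0, mean = 0, var = 1)),
                      covariate_effects = list())
  co <- simulate_cohort(spec, seed = 3)
  expect_lt(abs(within_pair_cor(co, "MZ")), 0.05)
})

test_that("cross-trait phenotypic correlation matches the decomposition formula", {
  cases <- list(c(0.24, 0.66, 0.42, 0.19), c(0.12, 0.24, 0.32, 0.38),
                c(0.5, 0.5, -0.4, 0.1))
  for (cs in cases) {
    spec <- cohort_spec(n_mz_pairs = 1000, n_dz_pairs = 1000, n_singletons = 0,
                        traits = list(a = list(h2 = cs[1], mean = 0, var = 1),
                                      b = list(h2 = cs[2], mean = 0, var = 1)),
                        rho_g = corr2(cs[3]), rho_e = corr2(cs[4]),
                        covariate_effects = list())
    draws <- vapply(1:3, function(s) {
      co <- simulate_cohort(spec, seed = round(sum(abs(cs)) * 997) + s)
      cor(co$phenotypes$a, co$phenotypes$b)
    }, numeric(1))
    expected <- implied_phenotypic_correlation(cs[1], cs[2], cs[3], cs[4])
    expect_lt(abs(mean(draws) - expected), 0.03)
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  spec <- cohort_spec(n_mz_pairs = 30, n_dz_pairs = 20, n_singletons = 10)
  co1 <- simulate_cohort(spec, seed = 99)
  co2 <- simulate_cohort(spec, seed = 99)
  expect_identical(co1, co2)
  p1 <- simulate_parcel_data(spec, co1, seed = 100)
  expect_identical(p1, simulate_parcel_data(spec, co2, seed = 100))
})

test_that("pedigree composition and trait panel match the spec", {
  spec <- cohort_spec()
  expect_equal(spec$n_mz_pairs, 143)
  expect_equal(spec$n_dz_pairs, 85)
  expect_equal(spec$n_singletons, 650)
  co <- simulate_cohort(spec, seed = 1)
  expect_equal(nrow(co$pedigree), 1106)
  expect_equal(sum(co$pedigree$zygosity == "MZ"), 286)
  expect_true(all(co$pedigree$age >= 22 & co$pedigree$age <= 37))
  expect_named(co$phenotypes, c("id", "sleep_duration", "psqi_total", "bmi",
                                "iq", "depression"))
  # twins share age; MZ co-twins share sex
  mz <- which(co$pedigree$zygosity == "MZ")
  first <- mz[seq(1, length(mz), 2)]
  expect_equal(co$pedigree$age[first], co$pedigree$age[first + 1])
  expect_equal(co$pedigree$sex[first], co$pedigree$sex[first + 1])
})

test_that("invalid generative correlation matrices are rejected", {
  bad <- matrix(c(1, 1.5, 1.5, 1), 2)
  expect_error(cohort_spec(traits = list(a = list(h2 = 0.5, mean = 0, var = 1),
                                         b = list(h2 = 0.5, mean = 0, var = 1)),
                           rho_g = bad),
               "positive semi-definite")
  expect_error(cohort_spec(traits = list(a = list(h2 = 1.4, mean = 0, var = 1))),
               "h2")
})

test_that("planted parcel components behave as specified", {
  base_traits <- list(t1 = list(h2 = 0, mean = 0, var = 1),
                      t2 = list(h2 = 0, mean = 0, var = 1),
                      t3 = list(h2 = 0, mean = 0, var = 1))
  # strength 0: pure noise, first component not significant in most seeds
  null_spec <- cohort_spec(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 300,
                           traits = base_traits, n_parcels = 50,
                           planted_components = list(list(
                             brain = rep(1 / sqrt(50), 50),
                             behavior = c(1, 0, 0), strength = 0)))
  ok <- vapply(1:10, function(s) {
    co <- simulate_cohort(null_spec, seed = 500 + s)
    parcels <- simulate_parcel_data(null_spec, co, seed = 600 + s)
    prep <- prepare_matrices(parcels, co$phenotypes)
    permutation_pvalues(prep$X, prep$Y, n_perm = 100, seed = s)[1] > 0.05
  }, logical(1))
  expect_gte(sum(ok), 8)

  # strength 2: loading recovered with high cosine
  v <- rep(0, 200); v[10:49] <- 1 / sqrt(40)
  spec2 <- cohort_spec(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 500,
                       traits = base_traits, n_parcels = 200,
                       parcel_noise_sd = 0.1,
                       planted_components = list(list(
                         brain = v, behavior = c(1, 1, 0) / sqrt(2),
                         strength = 2)))
  co <- simulate_cohort(spec2, seed = 7)
  parcels <- simulate_parcel_data(spec2, co, seed = 8)
  prep <- prepare_matrices(parcels, co$phenotypes)
  fit <- fit_pls(prep$X, prep$Y)
  cosine <- abs(sum(fit$brain_saliences[, 1] * v))
  expect_gte(cosine, 0.95)

  # two orthogonal components with strengths 3 and 1.5 come out ordered
  v1 <- c(rep(1 / sqrt(25), 25), rep(0, 75))
  v2 <- c(rep(0, 25), rep(1 / sqrt(25), 25), rep(0, 50))
  spec3 <- cohort_spec(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 400,
                       traits = base_traits, n_parcels = 100,
                       parcel_noise_sd = 0.5,
                       planted_components = list(
                         list(brain = v1, behavior = c(1, 0, 0), strength = 3),
                         list(brain = v2, behavior = c(0, 1, 0), strength = 1.5)))
  ordered <- vapply(1:20, function(s) {
    co <- simulate_cohort(spec3, seed = 1500 + s)
    parcels <- simulate_parcel_data(spec3, co, seed = 1600 + s)
    prep <- prepare_matrices(parcels, co$phenotypes)
    fit <- fit_pls(prep$X, prep$Y)
    abs(sum(fit$brain_saliences[, 1] * v1)) > abs(sum(fit$brain_saliences[, 1] * v2))
  }, logical(1))
  expect_gte(sum(ordered), 18)
})

test_that("cohorts round-trip through the plain-text writers", {
  spec <- cohort_spec(n_mz_pairs = 5, n_dz_pairs = 5, n_singletons = 5,
                      n_parcels = 10)
  co <- simulate_cohort(spec, seed = 42)
  parcels <- simulate_parcel_data(spec, co, seed = 43)
  dir <- withr::local_tempdir()
  write_cohort(co, dir, spec = spec, seed = 42, parcels = parcels,
               networks = network_labels(10))
  expect_true(all(file.exists(file.path(
    dir, c("pedigree.csv", "phenotypes.csv", "parcels.tsv", "networks.csv",
           "spec.yaml")))))
  ped2 <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_equal(ped2$id, co$pedigree$id)
  expect_equal(expected_relatedness(ped2), expected_relatedness(co$pedigree))
  meta <- yaml::read_yaml(file.path(dir, "spec.yaml"))
  expect_equal(meta$seed, 42)
  expect_equal(meta$n_mz_pairs, 5)
})
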