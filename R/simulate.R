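## Synthetic twin-cohort generator: the generative inverse of the polygenic
## model. Traits are mean + covariate effects + g + e, where the genetic
## vector g has cross-individual covariance h2 * var * K (K = expected
## relatedness) and cross-trait correlation rho_g, and e is family-
## independent with variance (1 - h2) * var and cross-trait correlation
## rho_e. No shared-household component is simulated: a genes+environment
## model is the chosen structure for extended-twin cohorts of this kind.

msqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) < -1e-8) abort("correlation matrix is not positive semi-definite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Default trait panel for the synthetic cohort
#'
#' Five phenotypes -- sleep duration, global sleep quality (PSQI total),
#' BMI, IQ, depression -- with heritabilities, means, and variances typical
#' of a young-adult twin cohort.
#'
#' @return Named list of per-trait generative parameters (`h2`, `mean`,
#'   `var`).
#' @export
default_traits <- function() {
  list(
    sleep_duration = list(h2 = 0.24, mean = 6.8, var = 1.1^2),
    psqi_total     = list(h2 = 0.12, mean = 4.8, var = 2.8^2),
    bmi            = list(h2 = 0.68, mean = 26.5, var = 5.2^2),
    iq             = list(h2 = 0.66, mean = 121.8, var = 14.6^2),
    depression     = list(h2 = 0.24, mean = 53.9, var = 5.7^2)
  )
}

#' Specify a synthetic twin cohort
#'
#' Collects and validates every generative parameter: pedigree composition,
#' per-trait heritabilities/means/variances, cross-trait genetic and
#' environmental correlation matrices, covariate effect sizes, the age
#' range, and the parcel-level structure (number of parcels, noise SD,
#' planted low-rank brain-behavior components).
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons Pedigree composition. Defaults
#'   mirror an HCP-scale extended-twin cohort (n = 1106). Counts are pairs,
#'   not individuals.
#' @param traits Named list of `list(h2, mean, var)` per trait.
#' @param rho_g,rho_e Cross-trait genetic / environmental correlation
#'   matrices (symmetric PSD, unit diagonal); identity when `NULL`.
#' @param covariate_effects Named list of fixed-effect sizes in residual-SD
#'   units: `age` (per SD of age), `sex`, `age_sex`.
#' @param age_range Uniform age range in years (twins share an age).
#' @param n_parcels Number of cortical parcels for [simulate_parcel_data()].
#' @param parcel_noise_sd SD of the iid parcel noise.
#' @param planted_components List of planted brain-behavior components,
#'   each `list(brain =, behavior =, strength =, score_h2 = NULL)`.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_mz_pairs = 143, n_dz_pairs = 85, n_singletons = 650,
                        traits = default_traits(), rho_g = NULL, rho_e = NULL,
                        covariate_effects = list(age = 0.1, sex = 0.1, age_sex = 0.05),
                        age_range = c(22, 37), n_parcels = 200,
                        parcel_noise_sd = 1, planted_components = list()) {
  t_names <- names(traits)
  if (is.null(t_names) || any(t_names == "")) abort("traits must be named")
  nt <- length(traits)
  for (nm in t_names) {
    tr <- traits[[nm]]
    if (tr$h2 < 0 || tr$h2 > 1) abort(paste0("trait '", nm, "': h2 must lie in [0, 1]"))
    if (tr$var <= 0) abort(paste0("trait '", nm, "': var must be positive"))
  }
  fix_corr <- function(R, label) {
    if (is.null(R)) R <- diag(nt)
    R <- as.matrix(R)
    if (!isTRUE(all.equal(unname(R), unname(t(R)))) || any(abs(diag(R) - 1) > 1e-12)) {
      abort(paste0(label, " must be symmetric with unit diagonal"))
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort(paste0(label, " is not positive semi-definite"))
    }
    dimnames(R) <- list(t_names, t_names)
    R
  }
  structure(list(
    n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs, n_singletons = n_singletons,
    traits = traits, rho_g = fix_corr(rho_g, "rho_g"), rho_e = fix_corr(rho_e, "rho_e"),
    covariate_effects = covariate_effects, age_range = age_range,
    n_parcels = n_parcels, parcel_noise_sd = parcel_noise_sd,
    planted_components = planted_components
  ), class = "cohort_spec")
}

# standardized genetic scores with the twin-design covariance:
# MZ co-twins share their score, DZ co-twins correlate 0.5
draw_genetic <- function(n_mz, n_dz, n_single, n_traits) {
  g_mz <- matrix(rnorm(n_mz * n_traits), nrow = n_mz, ncol = n_traits)
  z_sh <- matrix(rnorm(n_dz * n_traits), nrow = n_dz, ncol = n_traits)
  g_dz <- matrix(0, nrow = 2 * n_dz, ncol = n_traits)
  odd <- seq(1, by = 2, length.out = n_dz)
  g_dz[odd, ] <- (z_sh + matrix(rnorm(n_dz * n_traits), n_dz, n_traits)) / sqrt(2)
  g_dz[odd + 1, ] <- (z_sh + matrix(rnorm(n_dz * n_traits), n_dz, n_traits)) / sqrt(2)
  rbind(
    g_mz[rep(seq_len(n_mz), each = 2), , drop = FALSE],
    g_dz,
    matrix(rnorm(n_single * n_traits), nrow = n_single, ncol = n_traits)
  )
}

#' Simulate a twin cohort with known generative parameters
#'
#' Draws an extended-twin pedigree and multi-trait phenotypes under a
#' [cohort_spec()]. Twins share their age; MZ co-twins share sex. The
#' genetic draw uses the exact twin-design construction (MZ co-twins share
#' their genetic score, DZ co-twins get a shared plus an individual part in
#' equal variance), crossed with the square root of the cross-trait genetic
#' correlation matrix, so the target covariance `h2 * var * (K x rho_g)`
#' holds exactly in distribution. Fixing the seed reproduces identical
#' output.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List with `pedigree` (a [build_pedigree()] object) and
#'   `phenotypes` (tibble: `id` plus one column per trait).
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n_mz <- spec$n_mz_pairs; n_dz <- spec$n_dz_pairs; n_s <- spec$n_singletons
    n <- 2 * (n_mz + n_dz) + n_s
    fam <- c(rep(sprintf("MZF%04d", seq_len(n_mz)), each = 2),
             rep(sprintf("DZF%04d", seq_len(n_dz)), each = 2),
             sprintf("SGF%04d", seq_len(max(0, n_s))))
    pair <- c(rep(sprintf("MZP%04d", seq_len(n_mz)), each = 2),
              rep(sprintf("DZP%04d", seq_len(n_dz)), each = 2),
              rep("", n_s))
    zyg <- c(rep("MZ", 2 * n_mz), rep("DZ", 2 * n_dz), rep("NONE", n_s))
    age_pair <- runif(n_mz + n_dz, spec$age_range[1], spec$age_range[2])
    age <- c(rep(age_pair, each = 2), runif(n_s, spec$age_range[1], spec$age_range[2]))
    sex_mz <- rbinom(n_mz, 1, 0.5)
    sex <- c(rep(sex_mz, each = 2), rbinom(2 * n_dz, 1, 0.5), rbinom(n_s, 1, 0.5))
    ped <- build_pedigree(tibble(
      id = sprintf("I%05d", seq_len(n)), family_id = fam, pair_id = pair,
      zygosity = zyg, sex = sex, age = age))

    t_names <- names(spec$traits)
    nt <- length(t_names)
    h2 <- vapply(spec$traits, `[[`, numeric(1), "h2")
    vv <- vapply(spec$traits, `[[`, numeric(1), "var")
    mm <- vapply(spec$traits, `[[`, numeric(1), "mean")
    Lg <- msqrt(spec$rho_g)
    Le <- msqrt(spec$rho_e)
    g <- draw_genetic(n_mz, n_dz, n_s, nt) %*% t(Lg)
    e <- matrix(rnorm(n * nt), n) %*% t(Le)
    values <- sweep(g, 2, sqrt(h2 * vv), "*") + sweep(e, 2, sqrt((1 - h2) * vv), "*")

    ce <- spec$covariate_effects
    za <- (age - mean(spec$age_range)) / (diff(spec$age_range) / sqrt(12))
    fx <- rep(0, n) +
          (if (is.null(ce$age)) 0 else ce$age * za) +
          (if (is.null(ce$sex)) 0 else ce$sex * (sex - 0.5)) +
          (if (is.null(ce$age_sex)) 0 else ce$age_sex * za * (sex - 0.5))
    values <- values + outer(fx, sqrt(vv))
    values <- sweep(values, 2, mm, "+")
    colnames(values) <- t_names
    list(pedigree = ped,
         phenotypes = dplyr::bind_cols(tibble(id = ped$id), as_tibble(values)))
  })
}

unit <- function(v) v / sqrt(sum(v^2))

#' Simulate parcel-wise thickness data with planted low-rank structure
#'
#' Builds an individuals x parcels matrix as iid Gaussian noise plus the
#' planted components of the spec: each component contributes
#' `strength * score %*% t(unit brain loading)`, where the score is the
#' standardized projection of the (z-scored) behavior matrix onto the
#' component's behavior loading. When `score_h2` is given, a fully
#' heritable standardized genetic score is mixed in with weight
#' `sqrt(score_h2)` (and the behavioral part with `sqrt(1 - score_h2)`),
#' planting heritability in the latent brain score itself.
#'
#' @param spec A [cohort_spec()] (supplies `n_parcels`, `parcel_noise_sd`,
#'   `planted_components`).
#' @param cohort Output of [simulate_cohort()].
#' @param seed Integer seed.
#' @return Tibble: `id` plus `parcel_001 ...` columns.
#' @export
simulate_parcel_data <- function(spec, cohort, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  ped <- cohort$pedigree
  n <- nrow(ped)
  P <- spec$n_parcels
  Y <- as.matrix(cohort$phenotypes[, setdiff(names(cohort$phenotypes), "id")])
  with_seed(seed, {
    M <- matrix(rnorm(n * P, sd = spec$parcel_noise_sd), n, P)
    for (comp in spec$planted_components) {
      bl <- comp$brain
      if (length(bl) > P) abort("planted brain loading longer than n_parcels")
      if (length(bl) < P) bl <- c(bl, rep(0, P - length(bl)))
      if (length(comp$behavior) != ncol(Y)) {
        abort("planted behavior loading length must match trait count")
      }
      s <- drop(scale(Y) %*% comp$behavior)
      s <- drop(scale(s))
      if (!is.null(comp$score_h2)) {
        w <- comp$score_h2
        if (w < 0 || w > 1) abort("score_h2 must lie in [0, 1]")
        gsc <- drop(draw_genetic(spec$n_mz_pairs, spec$n_dz_pairs,
                                 spec$n_singletons, 1))
        s <- sqrt(1 - w) * s + sqrt(w) * gsc
      }
      M <- M + comp$strength * tcrossprod(s, unit(bl))
    }
    colnames(M) <- sprintf("parcel_%03d", seq_len(P))
    dplyr::bind_cols(tibble(id = ped$id), as_tibble(M))
  })
}

#' Canonical 7-network parcel labels
#'
#' Assigns each parcel to one of the seven canonical functional networks
#' (visual, sensorimotor, dorsal-attention, ventral-attention, limbic,
#' frontoparietal, default) in contiguous blocks -- a synthetic stand-in
#' label map for network summaries.
#'
#' @param n_parcels Number of parcels.
#' @return Tibble: `parcel`, `network`.
#' @export
network_labels <- function(n_parcels = 200) {
  nets <- c("visual", "sensorimotor", "dorsal-attention", "ventral-attention",
            "limbic", "frontoparietal", "default")
  tibble(parcel = sprintf("parcel_%03d", seq_len(n_parcels)),
         network = nets[ceiling(seq_len(n_parcels) / n_parcels * 7)])
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `pedigree.csv`, `phenotypes.csv`, optionally `parcels.tsv` and
#' `networks.csv`, plus `spec.yaml` recording every generative parameter
#' and the seed.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param spec The [cohort_spec()] used (recorded in `spec.yaml`).
#' @param seed The seed used (recorded in `spec.yaml`).
#' @param parcels Optional parcel tibble from [simulate_parcel_data()].
#' @param networks Optional label tibble from [network_labels()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL, seed = NULL,
                         parcels = NULL, networks = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(as_tibble(cohort$pedigree), file.path(dir, "pedigree.csv"))
  readr::write_csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  if (!is.null(parcels)) readr::write_tsv(parcels, file.path(dir, "parcels.tsv"))
  if (!is.null(networks)) readr::write_csv(networks, file.path(dir, "networks.csv"))
  if (!is.null(spec)) {
    rec <- unclass(spec)
    rec$rho_g <- as.vector(rec$rho_g); rec$rho_e <- as.vector(rec$rho_e)
    rec$seed <- seed
    yaml::write_yaml(rec, file.path(dir, "spec.yaml"))
  }
  invisible(dir)
}
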