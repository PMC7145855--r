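## Pipeline wrappers: the analysis sequence as composable tibble-in,
## tibble-out steps with a single config object carrying the covariate
## scheme, FDR level, resampling sizes, and the master seed.

#' Analysis configuration
#'
#' One place for the knobs shared across pipeline stages. All randomness
#' flows from `seed`: each stochastic stage derives its own stream from it.
#'
#' @param fdr_q FDR level, in (0, 1).
#' @param n_perm Permutations for PLS significance (>= 1).
#' @param n_boot Bootstrap resamples (PLS stability and association CIs).
#' @param seed Master seed.
#' @param inverse_normal Inverse-normal transform thickness parcels before
#'   polygenic fits? (Behavioral traits are left untransformed by default;
#'   pass trait columns through [inverse_normal_transform()] yourself to
#'   transform them too.)
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(fdr_q = 0.05, n_perm = 1000, n_boot = 500,
                            seed = 1L, inverse_normal = TRUE) {
  if (fdr_q <= 0 || fdr_q >= 1) abort("fdr_q must lie in (0, 1)")
  if (n_perm < 1) abort("n_perm must be >= 1")
  structure(list(fdr_q = fdr_q, n_perm = n_perm, n_boot = n_boot,
                 seed = as.integer(seed), inverse_normal = inverse_normal),
            class = "analysis_config")
}

check_ids <- function(data_ids, ped) {
  missing <- setdiff(data_ids, ped$id)
  if (length(missing) > 0) {
    abort(paste0("ids absent from pedigree: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) " ..."))
  }
}

ped_design <- function(ped, extras = list()) {
  covariate_design(ped$id, ped$age, ped$sex, extras = extras)
}

#' Per-parcel (or per-trait) heritability scan
#'
#' Fits the univariate polygenic model to every non-id column of `traits`
#' over the pedigree, with the standard covariate design (age, sex,
#' age x sex, age^2, age^2 x sex, plus `extras`), and BH-adjusts the
#' boundary-LRT p-values across the scanned family.
#'
#' @param traits Tibble with an `id` column and one column per trait or
#'   parcel, rows matching the pedigree ids.
#' @param pedigree A [build_pedigree()] pedigree.
#' @param config An [analysis_config()].
#' @param extras Named list of extra covariate columns (pedigree order),
#'   e.g. global thickness.
#' @return Tibble: `trait`, `h2`, `se_h2`, `sigma_p2`, `loglik_full`,
#'   `loglik_null`, `p`, `q`, `n`, `significant`.
#' @export
run_heritability <- function(traits, pedigree, config = analysis_config(),
                             extras = list()) {
  stopifnot(inherits(pedigree, "pedigree"))
  check_ids(traits$id, pedigree)
  traits <- traits[match(pedigree$id, traits$id), ]
  K <- expected_relatedness(pedigree)
  design <- ped_design(pedigree, extras)
  cols <- setdiff(names(traits), "id")
  out <- purrr::map_dfr(cols, function(nm) {
    v <- traits[[nm]]
    if (isTRUE(config$inverse_normal)) v <- inverse_normal_transform(v)
    fit <- fit_univariate(v, design, K)
    tibble(trait = nm, h2 = fit$h2, se_h2 = fit$se_h2, sigma_p2 = fit$sigma_p2,
           loglik_full = fit$loglik_full, loglik_null = fit$loglik_null,
           p = fit$p_boundary, n = fit$n_used)
  })
  adj <- fdr_bh(out$p, q = config$fdr_q)
  out$q <- adj$q_value
  out$significant <- adj$reject
  out
}

#' Bivariate genetic-correlation scan
#'
#' Fits the bivariate polygenic model for each requested trait pair and
#' BH-adjusts the rho_g and rho_e LRT p-values (each correlation family
#' separately) across the scanned pairs.
#'
#' @param traits Tibble with `id` plus trait columns (pedigree order not
#'   required; rows are matched by id).
#' @param pairs Two-column data frame (or list of 2-vectors) naming the
#'   trait pairs to fit; `NULL` fits all unordered pairs.
#' @param pedigree A pedigree.
#' @param config An [analysis_config()].
#' @param extras Extra covariate columns.
#' @return Tibble: `trait_a`, `trait_b`, `rho_g`, `se_rho_g`, `p_rho_g`,
#'   `q_rho_g`, `rho_e`, `se_rho_e`, `p_rho_e`, `q_rho_e`, `rho_p_model`,
#'   `h2_a`, `h2_b`, `n`.
#' @export
run_genetic_correlation <- function(traits, pedigree, pairs = NULL,
                                    config = analysis_config(), extras = list()) {
  stopifnot(inherits(pedigree, "pedigree"))
  check_ids(traits$id, pedigree)
  traits <- traits[match(pedigree$id, traits$id), ]
  cols <- setdiff(names(traits), "id")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(cols, 2))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  K <- expected_relatedness(pedigree)
  design <- ped_design(pedigree, extras)
  out <- purrr::pmap_dfr(list(pairs[[1]], pairs[[2]], seq_len(nrow(pairs))),
    function(a, b, i) {
      fit <- fit_bivariate(traits[[a]], traits[[b]], design, K,
                           seed = config$seed + i)
      tibble(trait_a = a, trait_b = b,
             rho_g = fit$rho_g, se_rho_g = fit$se_rho_g, p_rho_g = fit$p_rho_g,
             rho_e = fit$rho_e, se_rho_e = fit$se_rho_e, p_rho_e = fit$p_rho_e,
             rho_p_model = fit$rho_p_model, h2_a = fit$h2_a, h2_b = fit$h2_b,
             n = fit$n_used)
    })
  out$q_rho_g <- fdr_bh(out$p_rho_g, q = config$fdr_q)$q_value
  out$q_rho_e <- fdr_bh(out$p_rho_e, q = config$fdr_q)$q_value
  dplyr::relocate(out, "q_rho_g", .after = "p_rho_g") |>
    dplyr::relocate("q_rho_e", .after = "p_rho_e")
}

#' Full PLS brain-behavior analysis
#'
#' Prepares the matrices (residualize on age/sex covariates plus optional
#' global thickness, then z-score), fits the PLS correlation model, runs
#' the permutation test and bootstrap-ratio stability analysis, summarizes
#' BSRs by functional network, and optionally projects a second sample
#' onto the fitted saliences.
#'
#' @param brain Tibble: `id` + parcel columns.
#' @param behavior Tibble: `id` + behavior columns.
#' @param data Tibble with `id`, `age`, `sex` (e.g. a pedigree) for the
#'   covariate design.
#' @param config An [analysis_config()].
#' @param networks Optional label tibble (see [network_labels()]).
#' @param extras Extra covariate columns (aligned with `data` rows), e.g.
#'   global thickness.
#' @param new_sample Optional list with `brain`, `behavior`, `data`,
#'   `extras` for cross-sample projection.
#' @return List: `model` (`pls_fit`), `inference` tibble (component,
#'   singular_value, explained_cov, perm_p, latent_corr), `bsr` matrix,
#'   `network_summary` (per component, `NULL` without labels), and
#'   `projection` (`NULL` without a second sample).
#' @export
run_pls <- function(brain, behavior, data, config = analysis_config(),
                    networks = NULL, extras = list(), new_sample = NULL) {
  if (ncol(behavior) < 3) abort("need at least 2 behavior traits")
  ids <- as.character(data$id)
  stopifnot(identical(as.character(brain$id), ids),
            identical(as.character(behavior$id), ids))
  design <- covariate_design(ids, data$age, data$sex, extras = extras)
  prep <- prepare_matrices(brain, behavior, design)
  model <- fit_pls(prep$X, prep$Y)
  perm_p <- permutation_pvalues(prep$X, prep$Y, n_perm = config$n_perm,
                                seed = config$seed)
  bsr <- bootstrap_ratios(prep$X, prep$Y, model, n_boot = max(50, config$n_boot),
                          seed = config$seed + 1L)
  inference <- tibble(
    component = seq_along(model$singular_values),
    singular_value = model$singular_values,
    explained_cov = model$explained_cov,
    perm_p = perm_p,
    latent_corr = model$latent_corr)
  net <- NULL
  if (!is.null(networks)) {
    net <- purrr::map_dfr(seq_len(ncol(bsr)), function(i) {
      dplyr::mutate(network_summary(bsr[, i], networks), component = i,
                    .before = 1)
    })
  }
  projection <- NULL
  if (!is.null(new_sample)) {
    nd <- new_sample$data
    ndesign <- covariate_design(nd$id, nd$age, nd$sex,
                                extras = new_sample$extras %||% list())
    nprep <- prepare_matrices(new_sample$brain, new_sample$behavior, ndesign)
    projection <- project_pls(model, nprep$X, nprep$Y)
  }
  list(model = model, inference = inference, bsr = bsr,
       network_summary = net, projection = projection, prepared = prep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
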