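## Covariate-adjusted rank correlation with bootstrap confidence intervals,
## BH false-discovery control over parcel maps, and cross-sample map overlap.

rank_cor <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Covariate-adjusted Spearman correlation
#'
#' "Partial Spearman" implemented as residualize-then-rank: both variables
#' are residualized on the covariate design, ranked (average ranks for
#' ties), and the Pearson correlation of the ranks is returned. Rank-based
#' correlation keeps outliers from dominating. The p-value uses the
#' t-approximation on the rank correlation; the confidence interval is a
#' seeded percentile bootstrap over individuals of the adjusted variables.
#'
#' @param x,y Numeric vectors, aligned.
#' @param design A [covariate_design()] or `NULL` for no adjustment
#'   (centering only, which leaves ranks untouched).
#' @param n_boot Bootstrap resamples for the 95% CI (0 skips the CI).
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `r`, `ci_low`, `ci_high`, `p`, `n_used`.
#' @export
spearman_partial <- function(x, y, design = NULL, n_boot = 1000, seed = NULL) {
  if (length(x) != length(y)) abort("x and y must align")
  if (is.null(design)) design <- intercept_design(seq_along(x))
  ok <- !is.na(x) & !is.na(y) & complete.cases(design$X)
  n <- sum(ok)
  if (n < 10) abort("spearman_partial needs >= 10 complete observations")
  qrX <- qr(design$X[ok, , drop = FALSE])
  if (qrX$rank < ncol(design$X)) abort("rank-deficient design")
  xr <- qr.resid(qrX, x[ok])
  yr <- qr.resid(qrX, y[ok])
  if (sd(rank(xr)) == 0 || sd(rank(yr)) == 0) {
    abort("near-zero rank variance after residualization")
  }
  r <- rank_cor(xr, yr)
  tstat <- r * sqrt((n - 2) / max(1e-12, 1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p <- min(1, max(p, .Machine$double.xmin))
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        rank_cor(xr[idx], yr[idx])
      }, numeric(1))
    })
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  }
  tibble(r = r, ci_low = ci[1], ci_high = ci[2], p = p, n_used = n)
}

#' Benjamini-Hochberg false-discovery control
#'
#' Step-up procedure at level `q`: sort the p-values, reject all hypotheses
#' up to the largest `i` with `p_(i) <= i * q / m`. Adjusted q-values come
#' from `stats::p.adjust(method = "BH")`; the rejection mask
#' `q_value <= q` is exactly the step-up rule.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @return List with `reject` (logical mask), `q_value` (BH-adjusted
#'   values), and `p_threshold` (largest rejected p, `NA` if none).
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) abort("fdr_bh: empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("fdr_bh: p-values must lie in [0, 1]")
  }
  if (q <= 0 || q >= 1) abort("fdr_bh: q must lie in (0, 1)")
  qv <- stats::p.adjust(pvalues, method = "BH")
  reject <- qv <= q
  list(reject = reject,
       q_value = qv,
       p_threshold = if (any(reject)) max(pvalues[reject]) else NA_real_)
}

#' Parcel-wise covariate-adjusted association map
#'
#' Runs [spearman_partial()] of every parcel column against `y` and
#' applies BH false-discovery control across exactly this parcel family
#' (never pooled across analyses or samples).
#'
#' @param brain Data frame or matrix of parcel columns (an `id` column, if
#'   present, is carried through and excluded from testing).
#' @param y Outcome vector aligned with the rows of `brain`.
#' @param design A [covariate_design()] or `NULL`.
#' @param q FDR level.
#' @param n_boot Bootstrap resamples per parcel (0 skips CIs).
#' @param seed Seed; each parcel's bootstrap is derived from it.
#' @return Tibble with one row per parcel: `parcel`, `r`, `ci_low`,
#'   `ci_high`, `p`, `q`, `n`, `significant`.
#' @export
parcelwise_association <- function(brain, y, design = NULL, q = 0.05,
                                   n_boot = 1000, seed = NULL) {
  brain <- tibble::as_tibble(as.data.frame(brain))
  parcel_cols <- setdiff(names(brain), "id")
  if (length(parcel_cols) == 0) abort("no parcel columns")
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  rows <- purrr::imap(brain[parcel_cols], function(v, nm) {
    s <- if (is.null(base_seed)) NULL else base_seed + match(nm, parcel_cols)
    spearman_partial(v, y, design = design, n_boot = n_boot, seed = s)
  })
  out <- dplyr::bind_rows(rows, .id = "parcel")
  adj <- fdr_bh(out$p, q = q)
  out$q <- adj$q_value
  out$significant <- adj$reject
  dplyr::rename(out, n = "n_used")
}

#' Spatial similarity of two parcel maps
#'
#' Spearman correlation of two per-parcel statistic maps (e.g. association
#' maps from two samples), quantifying cross-sample overlap of the spatial
#' pattern irrespective of effect magnitude.
#'
#' @param map_a,map_b Numeric vectors over the same parcels in the same
#'   order, length >= 10.
#' @return Scalar Spearman correlation.
#' @export
map_similarity <- function(map_a, map_b) {
  if (length(map_a) != length(map_b)) abort("map_similarity: length mismatch")
  if (length(map_a) < 10) abort("map_similarity needs >= 10 parcels")
  rank_cor(map_a, map_b)
}
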