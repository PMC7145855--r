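#' Rank-based inverse normal transformation
#'
#' Maps a variable onto normal quantiles of rank-based plotting positions,
#' the standard device for making skewed phenotypes (here, parcel-wise
#' cortical thickness) conform to the normality assumption of the polygenic
#' likelihood. Uses the Blom offset (r - 3/8) / (n + 1/4) with average ranks
#' for ties; missing values are preserved.
#'
#' @param x Numeric vector with at least 3 non-missing, non-constant values.
#' @param offset Plotting-position offset; 3/8 (Blom) by default.
#' @return Numeric vector of the same length; `NA`s stay `NA`.
#' @export
inverse_normal_transform <- function(x, offset = 3 / 8) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) abort("inverse_normal_transform needs >= 3 non-missing values")
  v <- x[ok]
  if (max(v) == min(v)) abort("inverse_normal_transform: constant vector (ranks undefined)")
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Trimmed mean
#'
#' Mean after discarding `floor(trim * n)` smallest and as many largest
#' values; with `trim = 0.1` this is the 10 percent trimmed mean used to
#' summarize cortical thickness within a parcel robustly.
#'
#' @param x Non-empty numeric vector.
#' @param trim Fraction trimmed from each tail, in `[0, 0.5)`.
#' @param na.rm Drop missing values first?
#' @return Scalar trimmed mean.
#' @export
trimmed_mean <- function(x, trim = 0.1, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) abort("trimmed_mean: empty vector")
  if (!is.numeric(trim) || trim < 0 || trim >= 0.5) {
    abort("trimmed_mean: trim must be in [0, 0.5)")
  }
  k <- floor(trim * n)
  v <- sort(x)
  mean(v[(k + 1):(n - k)])
}

#' Body-mass index
#'
#' `weight / height^2` in metric units (kg, m) or `703 * weight / height^2`
#' in imperial units (lb, in).
#'
#' @param weight Positive weight (kg or lb).
#' @param height Positive height (m or in).
#' @param units `"metric"` or `"imperial"`.
#' @return BMI (kg/m^2 scale).
#' @export
compute_bmi <- function(weight, height, units = c("metric", "imperial")) {
  units <- match.arg(units)
  if (any(weight <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE)) {
    abort("compute_bmi: weight and height must be positive")
  }
  scale <- if (units == "imperial") 703 else 1
  scale * weight / height^2
}

#' Fixed-effects covariate design
#'
#' Builds the covariate design used throughout: intercept, age, sex,
#' age x sex, age^2, age^2 x sex, plus optional extra columns (global
#' thickness, depression, BMI, IQ for sensitivity analyses). Age is not
#' pre-centered; results are invariant to affine re-coding of age because
#' the polynomial span is unchanged.
#'
#' @param ids Character vector of individual ids.
#' @param age Numeric vector of ages (years), aligned with `ids`.
#' @param sex 0/1 vector aligned with `ids`.
#' @param extras Named list of extra numeric columns.
#' @return A `covariate_design`: list with `ids` and the model matrix `X`
#'   (columns `intercept, age, sex, age_sex, age2, age2_sex`, then extras).
#' @export
covariate_design <- function(ids, age, sex, extras = list()) {
  ids <- as.character(ids)
  n <- length(ids)
  if (length(age) != n || length(sex) != n) {
    abort("covariate_design: age and sex must align with ids")
  }
  if (!all(sex %in% c(0, 1) | is.na(sex))) abort("covariate_design: sex must be coded 0/1")
  X <- cbind(intercept = rep(1, n), age = age, sex = sex,
             age_sex = age * sex, age2 = age^2, age2_sex = age^2 * sex)
  if (length(extras) > 0) {
    if (is.null(names(extras)) || any(names(extras) == "")) {
      abort("covariate_design: extras must be named")
    }
    for (nm in names(extras)) {
      v <- extras[[nm]]
      if (length(v) != n) abort(paste0("covariate_design: extra '", nm, "' length mismatch"))
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- nm
    }
  }
  const <- apply(X[, -1, drop = FALSE], 2, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && max(v) == min(v)
  })
  if (any(const)) {
    warn(paste0("dropping constant covariate column(s): ",
                paste(colnames(X)[-1][const], collapse = ", ")))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  structure(list(ids = ids, X = X), class = "covariate_design")
}

#' Intercept-only design
#'
#' Convenience for analyses without covariate adjustment (centering only).
#'
#' @param ids Character vector of individual ids.
#' @return A `covariate_design` with a single intercept column.
#' @export
intercept_design <- function(ids) {
  ids <- as.character(ids)
  structure(list(ids = ids, X = cbind(intercept = rep(1, length(ids)))),
            class = "covariate_design")
}

#' Residualize a variable on a covariate design
#'
#' Ordinary least-squares residuals of `values` on the design columns;
#' missing rows (in `values` or the design) stay missing. Idempotent, and
#' residuals are numerically orthogonal to every design column.
#'
#' @param values Numeric vector aligned with `design$ids`.
#' @param design A `covariate_design`.
#' @return Residual vector of the same length.
#' @export
residualize <- function(values, design) {
  stopifnot(inherits(design, "covariate_design"))
  X <- design$X
  if (length(values) != nrow(X)) abort("residualize: values do not align with design")
  ok <- !is.na(values) & complete.cases(X)
  if (sum(ok) <= ncol(X)) abort("residualize: fewer complete rows than design columns")
  qrX <- qr(X[ok, , drop = FALSE])
  if (qrX$rank < ncol(X)) abort("residualize: rank-deficient design")
  out <- rep(NA_real_, length(values))
  out[ok] <- qr.resid(qrX, values[ok])
  out
}
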