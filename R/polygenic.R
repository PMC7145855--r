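## Polygenic variance decomposition on family blocks.
##
## The model for one trait y is
##   y ~ N(X beta, sigma_p2 * (h2 * K + (1 - h2) * I))
## with K the expected relatedness (2*Phi) matrix. K is block diagonal by
## family, so everything is evaluated in the eigenbasis of each family
## block: one eigendecomposition per block pattern up front, after which
## every likelihood evaluation is O(n).

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# eigendecompose each family block of K, caching by block pattern
# (MZ / DZ / SIB blocks repeat thousands of times in a twin cohort)
eigen_blocks <- function(K, blocks) {
  n <- nrow(K)
  lambda <- numeric(n)
  U <- vector("list", length(blocks))
  cache <- new.env(parent = emptyenv())
  for (j in seq_along(blocks)) {
    b <- blocks[[j]]
    if (length(b) == 1) {
      lambda[b] <- K[b, b]
      U[[j]] <- NULL
      next
    }
    Kb <- K[b, b, drop = FALSE]
    key <- paste(c(length(b), round(Kb * 2)), collapse = "")
    e <- cache[[key]]
    if (is.null(e)) {
      e <- eigen(Kb, symmetric = TRUE)
      cache[[key]] <- e
    }
    lambda[b] <- e$values
    U[[j]] <- e$vectors
  }
  list(lambda = lambda, U = U, blocks = blocks)
}

# rotate columns of M into the blockwise eigenbasis
block_rotate <- function(eb, M) {
  M <- as.matrix(M)
  out <- M
  for (j in seq_along(eb$blocks)) {
    b <- eb$blocks[[j]]
    if (length(b) > 1) out[b, ] <- crossprod(eb$U[[j]], M[b, , drop = FALSE])
  }
  out
}

# listwise-delete and align trait(s)/design/relatedness; returns the
# rotated pieces every fit works with
prepare_polygenic <- function(traits, design, relatedness) {
  stopifnot(inherits(design, "covariate_design"))
  if (!is.matrix(relatedness)) abort("relatedness must be a matrix")
  traits <- as.matrix(traits)
  n <- nrow(relatedness)
  if (nrow(traits) != n || nrow(design$X) != n) {
    abort("trait, design, and relatedness must align (same individuals, same order)")
  }
  if (!is.null(rownames(relatedness)) &&
      !identical(as.character(design$ids), rownames(relatedness))) {
    abort("design ids do not match relatedness ids")
  }
  ok <- complete.cases(traits) & complete.cases(design$X)
  idx <- which(ok)
  K <- unclass(relatedness)[idx, idx, drop = FALSE]
  X <- design$X[idx, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) abort("rank-deficient covariate design after listwise deletion")
  blocks <- blocks_from_matrix(K)
  eb <- eigen_blocks(K, blocks)
  informative <- any(vapply(blocks, function(b) {
    length(b) > 1 && any(K[b, b][upper.tri(K[b, b])] != 0)
  }, logical(1)))
  list(idx = idx, n = length(idx), K = K, eb = eb,
       Xt = block_rotate(eb, X), Yt = block_rotate(eb, traits),
       X = X, Y = traits[idx, , drop = FALSE], informative = informative)
}

# profile log-likelihood pieces at a given h2 (beta, sigma_p2 solved by GLS)
uni_profile <- function(h2, lambda, Xt, yt) {
  n <- length(yt)
  w <- h2 * lambda + (1 - h2)
  sw <- sqrt(w)
  qrw <- qr(Xt / sw)
  beta <- qr.coef(qrw, yt / sw)
  r <- qr.resid(qrw, yt / sw)
  s2 <- sum(r^2) / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + sum(log(w)) + n)
  list(ll = ll, beta = beta, sigma_p2 = s2)
}

#' Polygenic multivariate-normal log-likelihood
#'
#' Log-density of a trait under the polygenic model with mean
#' `design %*% beta` and covariance `sigma_p2 * (h2 * K + (1 - h2) * I)`,
#' evaluated block-wise by family. Exposed mainly for verification; the
#' fitters profile this internally.
#'
#' @param trait Numeric vector (no missing values).
#' @param design A [covariate_design()].
#' @param relatedness Matrix from [expected_relatedness()].
#' @param h2 Heritability in `[0, 1]`.
#' @param sigma_p2 Positive phenotypic variance.
#' @param beta Fixed-effect coefficients (length = design columns).
#' @return Scalar log-likelihood.
#' @export
polygenic_loglik <- function(trait, design, relatedness, h2, sigma_p2, beta) {
  if (h2 < 0 || h2 > 1) abort("h2 must lie in [0, 1]")
  if (sigma_p2 <= 0) abort("sigma_p2 must be positive")
  pp <- prepare_polygenic(trait, design, relatedness)
  if (pp$n < length(trait)) abort("polygenic_loglik expects complete data")
  w <- h2 * pp$eb$lambda + (1 - h2)
  if (any(w < 1e-12)) {
    bad <- which(w < 1e-12)[1]
    blk <- which(vapply(pp$eb$blocks, function(b) bad %in% b, logical(1)))
    abort(paste0("singular family block ", blk, " at h2 = ", h2))
  }
  r <- block_rotate(pp$eb, pp$Y[, 1] - drop(pp$X %*% beta))
  n <- pp$n
  -0.5 * (n * log(2 * pi * sigma_p2) + sum(log(w)) + sum(r^2 / w) / sigma_p2)
}

#' Boundary likelihood-ratio p-value for a variance parameter
#'
#' The null value h2 = 0 sits on the boundary of the parameter space, so
#' the LRT statistic is referred to a 50:50 mixture of a point mass at zero
#' and chi-square with 1 df: `p = 0.5 * P(chisq_1 >= T)` for `T > 0` and
#' `p = 0.5` at `T = 0`.
#'
#' @param lrt_stat `2 * (loglik_full - loglik_null)`; small negative values
#'   (>= -1e-6) are clipped to zero.
#' @return p-value in (0, 1].
#' @export
lrt_boundary_pvalue <- function(lrt_stat) {
  if (lrt_stat < -1e-6) abort("negative LRT statistic: full model fit worse than null (fit inconsistency)")
  t_stat <- max(0, lrt_stat)
  if (t_stat == 0) return(0.5)
  0.5 * pchisq(t_stat, df = 1, lower.tail = FALSE)
}

#' Univariate heritability by maximum likelihood
#'
#' Profile-likelihood fit of the polygenic model: at each h2 the fixed
#' effects and phenotypic variance have closed-form (GLS) solutions in the
#' blockwise eigenbasis, and h2 is found by bounded scalar optimization
#' over `[0, 1)` (a coarse grid bracket followed by golden-section/parabolic
#' refinement, robust to boundary solutions). The standard error comes from
#' the curvature of the profile log-likelihood and is reported `NA` within
#' 0.01 of a boundary, where curvature is unreliable; the significance test
#' is the boundary LRT against h2 = 0.
#'
#' @param trait Numeric vector aligned with the design/relatedness rows;
#'   missing values trigger listwise deletion.
#' @param design A [covariate_design()].
#' @param relatedness Matrix from [expected_relatedness()].
#' @return A `herit_fit` with elements `h2`, `se_h2`, `sigma_p2`, `beta`,
#'   `loglik_full`, `loglik_null`, `p_boundary`, `n_used`.
#' @examples
#' spec <- cohort_spec(n_mz_pairs = 60, n_dz_pairs = 40, n_singletons = 0,
#'                     traits = list(y = list(h2 = 0.5, mean = 0, var = 1)))
#' cohort <- simulate_cohort(spec, seed = 1)
#' des <- covariate_design(cohort$pedigree$id, cohort$pedigree$age,
#'                         cohort$pedigree$sex)
#' fit <- fit_univariate(cohort$phenotypes$y, des,
#'                       expected_relatedness(cohort$pedigree))
#' fit$h2
#' @export
fit_univariate <- function(trait, design, relatedness) {
  pp <- prepare_polygenic(trait, design, relatedness)
  if (!pp$informative) abort("h2 unidentifiable: no informative relative pairs (all singletons)")
  if (pp$n <= ncol(pp$X) + 2) abort("too few complete observations for the design")
  lambda <- pp$eb$lambda
  Xt <- pp$Xt
  yt <- pp$Yt[, 1]
  upper <- 1 - 1e-6
  negll <- function(h2) -uni_profile(h2, lambda, Xt, yt)$ll

  # coarse bracket first (the profile can be flat or multimodal), then
  # refine around the grid optimum and inside both boundary intervals,
  # where narrow optima can hide from a coarse scan
  grid <- seq(0, upper, length.out = 26)
  vals <- vapply(grid, negll, numeric(1))
  i <- which.min(vals)
  brackets <- unique(list(
    c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
    c(0, grid[2]),
    c(grid[25], upper)))
  cand <- do.call(rbind, lapply(brackets, function(b) {
    opt <- optimize(negll, b, tol = 1e-9)
    c(opt$minimum, opt$objective)
  }))
  cand <- rbind(cand, c(0, vals[1]), c(upper, vals[length(vals)]))
  best <- cand[which.min(cand[, 2]), ]
  h2_hat <- best[1]
  at_opt <- uni_profile(h2_hat, lambda, Xt, yt)
  ll_null <- uni_profile(0, lambda, Xt, yt)$ll
  lrt <- 2 * (at_opt$ll - ll_null)
  p_boundary <- lrt_boundary_pvalue(max(lrt, 0))

  se_h2 <- NA_real_
  if (h2_hat > 0.01 && h2_hat < 0.99) {
    d <- min(1e-3, (1 - h2_hat) / 2, h2_hat / 2)
    d2 <- (negll(h2_hat + d) - 2 * negll(h2_hat) + negll(h2_hat - d)) / d^2
    if (is.finite(d2) && d2 > 0) se_h2 <- 1 / sqrt(d2)
  }

  structure(list(
    h2 = h2_hat, se_h2 = se_h2, sigma_p2 = at_opt$sigma_p2,
    beta = setNames(drop(at_opt$beta), colnames(pp$X)),
    loglik_full = at_opt$ll, loglik_null = ll_null,
    p_boundary = p_boundary, n_used = pp$n
  ), class = "herit_fit")
}

#' @export
print.herit_fit <- function(x, ...) {
  cat(sprintf("<herit_fit> h2 = %.3f (SE %s), sigma_p2 = %.3f, n = %d\n",
              x$h2, ifelse(is.na(x$se_h2), "NA", sprintf("%.3f", x$se_h2)),
              x$sigma_p2, x$n_used))
  cat(sprintf("  boundary LRT p = %.4g (logLik full %.2f, null %.2f)\n",
              x$p_boundary, x$loglik_full, x$loglik_null))
  invisible(x)
}

#' @rdname fit_univariate
#' @param x,object A `herit_fit`.
#' @param ... Unused.
#' @export
tidy.herit_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "h2", estimate = x$h2, std.error = x$se_h2,
           p.value = x$p_boundary),
    tibble(term = names(x$beta), estimate = unname(x$beta),
           std.error = NA_real_, p.value = NA_real_)
  )
}

#' @rdname fit_univariate
#' @export
glance.herit_fit <- function(x, ...) {
  tibble(h2 = x$h2, se_h2 = x$se_h2, sigma_p2 = x$sigma_p2,
         logLik = x$loglik_full, logLik_null = x$loglik_null,
         p_boundary = x$p_boundary, n_used = x$n_used)
}

#' Model-implied phenotypic correlation from a bivariate decomposition
#'
#' Evaluates `rho_p = rho_g * sqrt(h2_a * h2_b) +
#' rho_e * sqrt((1 - h2_a) * (1 - h2_b))`: the phenotypic correlation
#' implied by the genetic and environmental correlations of two traits,
#' weighted by their heritabilities.
#'
#' @param h2_a,h2_b Heritabilities in `[0, 1]`.
#' @param rho_g,rho_e Genetic and environmental correlations in `[-1, 1]`.
#' @return Scalar implied phenotypic correlation.
#' @export
implied_phenotypic_correlation <- function(h2_a, h2_b, rho_g, rho_e) {
  if (any(c(h2_a, h2_b) < 0 | c(h2_a, h2_b) > 1)) abort("h2 values must lie in [0, 1]")
  if (any(abs(c(rho_g, rho_e)) > 1)) abort("correlations must lie in [-1, 1]")
  rho_g * sqrt(h2_a * h2_b) + rho_e * sqrt((1 - h2_a) * (1 - h2_b))
}
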