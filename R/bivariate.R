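## Bivariate polygenic model.
##
## For traits (y_a, y_b) the joint covariance is G (x) K + E (x) I with
## 2x2 genetic and environmental covariance matrices G and E. In the
## blockwise eigenbasis of K the 2n-dimensional problem decouples into n
## independent 2x2 normals with covariance lambda_i * G + E, so every
## likelihood evaluation is O(n). G and E are parameterized as
## (log-variance, log-variance, atanh-correlation), which keeps both
## positive semi-definite and makes the restricted models (rho_g = 0 or
## rho_e = 0) a single fixed coordinate.

Z_BOUND <- atanh(1 - 1e-6)
LV_BOUND <- 15

bi_unpack <- function(theta, fix_zg, fix_ze) {
  i <- 1
  take <- function() { v <- theta[i]; i <<- i + 1; v }
  lv_g1 <- take(); lv_g2 <- take()
  zg <- if (fix_zg) 0 else take()
  lv_e1 <- take(); lv_e2 <- take()
  ze <- if (fix_ze) 0 else take()
  g1 <- exp(lv_g1); g2 <- exp(lv_g2); rg <- tanh(zg)
  e1 <- exp(lv_e1); e2 <- exp(lv_e2); re <- tanh(ze)
  list(G = matrix(c(g1, rg * sqrt(g1 * g2), rg * sqrt(g1 * g2), g2), 2),
       E = matrix(c(e1, re * sqrt(e1 * e2), re * sqrt(e1 * e2), e2), 2))
}

# negative log-likelihood with the two fixed-effect vectors profiled out
bi_negll <- function(theta, lambda, Xt, ya, yb, fix_zg = FALSE, fix_ze = FALSE,
                     want_fit = FALSE) {
  par <- bi_unpack(theta, fix_zg, fix_ze)
  G <- par$G; E <- par$E
  a <- lambda * G[1, 1] + E[1, 1]
  b <- lambda * G[1, 2] + E[1, 2]
  cc <- lambda * G[2, 2] + E[2, 2]
  det <- a * cc - b^2
  if (any(det <= 0) || any(a <= 0)) return(if (want_fit) NULL else 1e10)
  ia <- cc / det; ib <- -b / det; ic <- a / det
  p <- ncol(Xt); n <- length(ya)
  A <- matrix(0, 2 * p, 2 * p)
  A[1:p, 1:p] <- crossprod(Xt, Xt * ia)
  A[1:p, (p + 1):(2 * p)] <- crossprod(Xt, Xt * ib)
  A[(p + 1):(2 * p), 1:p] <- A[1:p, (p + 1):(2 * p)]
  A[(p + 1):(2 * p), (p + 1):(2 * p)] <- crossprod(Xt, Xt * ic)
  rhs <- c(crossprod(Xt, ia * ya + ib * yb), crossprod(Xt, ib * ya + ic * yb))
  beta <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(beta)) return(if (want_fit) NULL else 1e10)
  ra <- ya - drop(Xt %*% beta[1:p])
  rb <- yb - drop(Xt %*% beta[(p + 1):(2 * p)])
  Q <- sum(ia * ra^2 + 2 * ib * ra * rb + ic * rb^2)
  nll <- 0.5 * (2 * n * log(2 * pi) + sum(log(det)) + Q)
  if (!is.finite(nll)) return(if (want_fit) NULL else 1e10)
  if (want_fit) list(nll = nll, beta_a = beta[1:p], beta_b = beta[(p + 1):(2 * p)],
                     G = G, E = E) else nll
}

bi_optim <- function(start, lambda, Xt, ya, yb, fix_zg = FALSE, fix_ze = FALSE) {
  k <- length(start)
  is_z <- if (fix_zg && fix_ze) rep(FALSE, k) else {
    flags <- c(FALSE, FALSE, if (!fix_zg) TRUE, FALSE, FALSE, if (!fix_ze) TRUE)
    flags
  }
  lower <- ifelse(is_z, -Z_BOUND, -LV_BOUND)
  upper <- ifelse(is_z, Z_BOUND, LV_BOUND)
  tryCatch(
    optim(start, bi_negll, lambda = lambda, Xt = Xt, ya = ya, yb = yb,
          fix_zg = fix_zg, fix_ze = fix_ze,
          method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 300)),
    error = function(e) NULL)
}

num_hessian <- function(f, x, d = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k); ei[i] <- d; ej[j] <- d
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / d^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) / (4 * d^2)
      }
    }
  }
  H
}

#' Bivariate polygenic fit: genetic and environmental correlation
#'
#' Joint maximum-likelihood fit of two traits under the polygenic model,
#' decomposing their phenotypic correlation into a genetic correlation
#' `rho_g` (shared additive-genetic influences, i.e. pleiotropy) and an
#' environmental correlation `rho_e` (shared residual influences --
#' including measurement error, so `rho_e` should not be over-interpreted).
#' The optimizer is quasi-Newton (L-BFGS-B) over the component variances
#' and correlations with the fixed effects profiled out; one informed start
#' (from univariate fits and the residual phenotypic correlation) plus
#' seeded random restarts guard against local optima. Each correlation's
#' p-value is an LRT against the model with that correlation fixed at 0,
#' referred to chi-square with 1 df (interior parameter, no boundary
#' mixture). Standard errors are delta-method values from the numerical
#' Hessian and are `NA` when the correlation sits within 0.01 of +/-1.
#'
#' @param trait_a,trait_b Numeric vectors aligned with the design rows.
#' @param design A [covariate_design()].
#' @param relatedness Matrix from [expected_relatedness()].
#' @param n_restarts Total optimizer starts (informed + random), >= 1.
#' @param seed Seed for the random restarts.
#' @return An `rg_fit` with `rho_g`, `rho_e`, `rho_p_model` (the implied
#'   phenotypic correlation, satisfying the decomposition identity by
#'   construction), `h2_a`, `h2_b`, `se_rho_g`, `se_rho_e`, `p_rho_g`,
#'   `p_rho_e`, `loglik_full`, `n_used`, and the fitted `G`, `E` matrices.
#' @export
fit_bivariate <- function(trait_a, trait_b, design, relatedness,
                          n_restarts = 5, seed = NULL) {
  pp <- prepare_polygenic(cbind(trait_a, trait_b), design, relatedness)
  if (!pp$informative) abort("unidentifiable: no informative relative pairs")
  if (pp$n <= ncol(pp$X) + 2) abort("too few complete observations for the design")
  lambda <- pp$eb$lambda
  Xt <- pp$Xt

  # standardize internally: conditioning + exact affine invariance
  qrX <- qr(pp$X)
  res_a <- qr.resid(qrX, pp$Y[, 1])
  res_b <- qr.resid(qrX, pp$Y[, 2])
  sd_a <- sd(res_a); sd_b <- sd(res_b)
  if (sd_a == 0 || sd_b == 0) abort("trait constant after covariate adjustment")
  ya <- pp$Yt[, 1] / sd_a
  yb <- pp$Yt[, 2] / sd_b
  rp <- cor(res_a, res_b)

  ua <- fit_uni_on_prepared(lambda, Xt, ya)
  ub <- fit_uni_on_prepared(lambda, Xt, yb)
  start0 <- c(log(pmax(ua$h2 * ua$sigma_p2, 1e-3)),
              log(pmax(ub$h2 * ub$sigma_p2, 1e-3)),
              atanh(max(-0.9, min(0.9, rp))),
              log(pmax((1 - ua$h2) * ua$sigma_p2, 1e-3)),
              log(pmax((1 - ub$h2) * ub$sigma_p2, 1e-3)),
              atanh(max(-0.9, min(0.9, rp))))

  starts <- list(start0)
  if (n_restarts > 1) {
    with_seed(if (is.null(seed)) 42L else seed, {
      for (r in seq_len(n_restarts - 1)) {
        starts[[r + 1]] <- start0 + rnorm(6, sd = c(0.6, 0.6, 0.8, 0.6, 0.6, 0.8))
      }
    })
  }
  fits <- lapply(starts, bi_optim, lambda = lambda, Xt = Xt, ya = ya, yb = yb)
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (length(fits) == 0) {
    abort("fit_bivariate did not converge from any start (non-convergence after multi-start)")
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  full <- bi_negll(best$par, lambda, Xt, ya, yb, want_fit = TRUE)
  ll_full <- -full$nll

  # restricted models for the correlation LRTs
  restrict <- function(fix_zg, fix_ze) {
    keep <- c(TRUE, TRUE, !fix_zg, TRUE, TRUE, !fix_ze)
    st <- list(best$par[keep], start0[keep])
    rf <- lapply(st, bi_optim, lambda = lambda, Xt = Xt, ya = ya, yb = yb,
                 fix_zg = fix_zg, fix_ze = fix_ze)
    rf <- Filter(function(f) !is.null(f) && is.finite(f$value), rf)
    if (length(rf) == 0) return(NA_real_)
    -min(vapply(rf, `[[`, numeric(1), "value"))
  }
  ll_r_g <- restrict(TRUE, FALSE)
  ll_r_e <- restrict(FALSE, TRUE)
  p_rho_g <- if (is.na(ll_r_g)) NA_real_ else
    pchisq(max(0, 2 * (ll_full - ll_r_g)), df = 1, lower.tail = FALSE)
  p_rho_e <- if (is.na(ll_r_e)) NA_real_ else
    pchisq(max(0, 2 * (ll_full - ll_r_e)), df = 1, lower.tail = FALSE)

  G <- full$G; E <- full$E
  rho_g <- tanh(best$par[3])
  rho_e <- tanh(best$par[6])
  h2_a <- G[1, 1] / (G[1, 1] + E[1, 1])
  h2_b <- G[2, 2] / (G[2, 2] + E[2, 2])

  se_rho_g <- se_rho_e <- NA_real_
  H <- tryCatch(num_hessian(function(th) bi_negll(th, lambda, Xt, ya, yb), best$par),
                error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      if (abs(rho_g) < 0.99 && V[3, 3] > 0) se_rho_g <- (1 - rho_g^2) * sqrt(V[3, 3])
      if (abs(rho_e) < 0.99 && V[6, 6] > 0) se_rho_e <- (1 - rho_e^2) * sqrt(V[6, 6])
    }
  }

  # back to the original trait scale
  S <- diag(c(sd_a, sd_b))
  structure(list(
    rho_g = rho_g, rho_e = rho_e,
    rho_p_model = implied_phenotypic_correlation(h2_a, h2_b, rho_g, rho_e),
    h2_a = h2_a, h2_b = h2_b,
    se_rho_g = se_rho_g, se_rho_e = se_rho_e,
    p_rho_g = p_rho_g, p_rho_e = p_rho_e,
    loglik_full = ll_full - pp$n * log(sd_a * sd_b),
    n_used = pp$n,
    G = S %*% G %*% S, E = S %*% E %*% S,
    note = "environmental component includes measurement error"
  ), class = "rg_fit")
}

# univariate profile fit reusing an existing blockwise transform
fit_uni_on_prepared <- function(lambda, Xt, yt) {
  negll <- function(h2) -uni_profile(h2, lambda, Xt, yt)$ll
  grid <- seq(0, 1 - 1e-6, length.out = 26)
  vals <- vapply(grid, negll, numeric(1))
  i <- which.min(vals)
  opt <- optimize(negll, c(grid[max(1, i - 1)], grid[min(26, i + 1)]), tol = 1e-8)
  h2 <- if (vals[1] <= opt$objective) 0 else opt$minimum
  c(uni_profile(h2, lambda, Xt, yt)[c("sigma_p2")], h2 = h2)
}

#' @export
print.rg_fit <- function(x, ...) {
  cat(sprintf("<rg_fit> rho_g = %.3f (p = %.3g), rho_e = %.3f (p = %.3g), n = %d\n",
              x$rho_g, x$p_rho_g, x$rho_e, x$p_rho_e, x$n_used))
  cat(sprintf("  h2_a = %.3f, h2_b = %.3f, implied rho_p = %.3f\n",
              x$h2_a, x$h2_b, x$rho_p_model))
  cat(sprintf("  note: %s\n", x$note))
  invisible(x)
}

#' @rdname fit_bivariate
#' @param x,object An `rg_fit`.
#' @param ... Unused.
#' @export
tidy.rg_fit <- function(x, ...) {
  tibble(term = c("rho_g", "rho_e"),
         estimate = c(x$rho_g, x$rho_e),
         std.error = c(x$se_rho_g, x$se_rho_e),
         p.value = c(x$p_rho_g, x$p_rho_e))
}

#' @rdname fit_bivariate
#' @export
glance.rg_fit <- function(x, ...) {
  tibble(rho_g = x$rho_g, rho_e = x$rho_e, rho_p_model = x$rho_p_model,
         h2_a = x$h2_a, h2_b = x$h2_b, logLik = x$loglik_full, n_used = x$n_used)
}
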