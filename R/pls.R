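## Partial least squares correlation between a parcel-thickness matrix and
## a behavior matrix: SVD of the cross-covariance, permutation significance
## per latent component, bootstrap-ratio stability of the brain saliences,
## functional-network summaries, and out-of-sample projection.

as_id_matrix <- function(x) {
  x <- as.data.frame(x)
  ids <- if ("id" %in% names(x)) as.character(x$id) else as.character(seq_len(nrow(x)))
  m <- as.matrix(x[setdiff(names(x), "id")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Prepare matrices for PLS
#'
#' Listwise-deletes incomplete rows, residualizes every column on the
#' covariate design, and z-scores each residualized column. All PLS
#' normalization happens here; [fit_pls()] assumes prepared input.
#'
#' @param brain Data frame/matrix of parcel columns (optional `id` column).
#' @param behavior Data frame/matrix of behavior columns (optional `id`).
#' @param design A [covariate_design()] or `NULL` (plain z-scoring).
#' @return List with `X` (individuals x parcels), `Y` (individuals x
#'   traits), and `ids`.
#' @export
prepare_matrices <- function(brain, behavior, design = NULL) {
  Xm <- as_id_matrix(brain)
  Ym <- as_id_matrix(behavior)
  if (nrow(Xm) != nrow(Ym)) abort("brain and behavior must have aligned rows")
  if (is.null(design)) design <- intercept_design(rownames(Xm))
  ok <- complete.cases(Xm) & complete.cases(Ym) & complete.cases(design$X)
  if (sum(ok) <= ncol(design$X) + 2) abort("too few complete rows")
  D <- design$X[ok, , drop = FALSE]
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) abort("rank-deficient design")
  normalize <- function(M, label) {
    R <- qr.resid(qrD, M[ok, , drop = FALSE])
    sds <- apply(R, 2, sd)
    if (any(sds < 1e-12)) {
      abort(paste0("constant ", label, " column(s) after residualization: ",
                   paste(colnames(M)[sds < 1e-12], collapse = ", ")))
    }
    scale(R, center = TRUE, scale = sds)
  }
  list(X = normalize(Xm, "brain"), Y = normalize(Ym, "behavior"),
       ids = rownames(Xm)[ok])
}

svd_cross <- function(X, Y) {
  n <- nrow(X)
  R <- crossprod(Y, X) / (n - 1)          # traits x parcels
  k <- min(dim(R))
  s <- svd(R, nu = k, nv = k)
  # deterministic sign: largest-magnitude behavior loading positive
  for (i in seq_len(k)) {
    j <- which.max(abs(s$u[, i]))
    if (s$u[j, i] < 0) {
      s$u[, i] <- -s$u[, i]
      s$v[, i] <- -s$v[, i]
    }
  }
  s
}

#' Fit a PLS correlation model
#'
#' Singular value decomposition of the brain-behavior cross-covariance
#' `t(Y) %*% X / (n - 1)` of prepared matrices. Each latent component
#' pairs a brain salience (parcel pattern) with a behavior salience
#' (trait profile); projecting individuals onto the saliences gives
#' composite scores whose Spearman correlation is the component's latent
#' brain-behavior association. The number of components equals the number
#' of behavior traits. Sign convention: the largest-magnitude entry of each
#' behavior salience is positive, the paired brain salience flips with it.
#'
#' @param X,Y Prepared matrices from [prepare_matrices()] (individuals in
#'   rows; `nrow >= ncol(Y)`).
#' @return A `pls_fit` with `brain_saliences` (parcel x k),
#'   `behavior_saliences` (trait x k), `singular_values`, `explained_cov`
#'   (squared singular values over their sum), `brain_scores`,
#'   `behavior_scores`, `latent_corr`.
#' @export
fit_pls <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("X and Y must have the same rows")
  if (nrow(X) < ncol(Y)) abort("need at least as many individuals as behavior traits")
  s <- svd_cross(X, Y)
  k <- length(s$d)
  total <- sum(s$d^2)
  if (total < 1e-24) {
    warn("degenerate cross-covariance: all singular values are zero")
    expl <- rep(0, k)
  } else {
    expl <- s$d^2 / total
  }
  dimnames(s$v) <- list(colnames(X), paste0("LC", seq_len(k)))
  dimnames(s$u) <- list(colnames(Y), paste0("LC", seq_len(k)))
  brain_scores <- X %*% s$v
  behavior_scores <- Y %*% s$u
  latent_corr <- vapply(seq_len(k), function(i) {
    rank_cor(brain_scores[, i], behavior_scores[, i])
  }, numeric(1))
  structure(list(
    brain_saliences = s$v, behavior_saliences = s$u,
    singular_values = s$d, explained_cov = expl,
    brain_scores = brain_scores, behavior_scores = behavior_scores,
    latent_corr = latent_corr, n = nrow(X)
  ), class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  k <- length(x$singular_values)
  cat(sprintf("<pls_fit> %d latent components (n = %d, %d parcels, %d traits)\n",
              k, x$n, nrow(x$brain_saliences), nrow(x$behavior_saliences)))
  print(tibble(component = seq_len(k),
               singular_value = x$singular_values,
               explained_cov = x$explained_cov,
               latent_corr = x$latent_corr))
  invisible(x)
}

#' @rdname fit_pls
#' @param x,object A `pls_fit`.
#' @param ... Unused.
#' @export
tidy.pls_fit <- function(x, ...) {
  tibble(component = seq_along(x$singular_values),
         singular_value = x$singular_values,
         explained_cov = x$explained_cov,
         latent_corr = x$latent_corr)
}

#' @rdname fit_pls
#' @export
glance.pls_fit <- function(x, ...) {
  tibble(n = x$n, n_parcels = nrow(x$brain_saliences),
         n_traits = nrow(x$behavior_saliences),
         total_cov = sum(x$singular_values^2))
}

#' Permutation p-values for PLS components
#'
#' Shuffles individual labels of `Y` (breaking the brain-behavior pairing
#' while preserving each matrix's internal structure) and compares the i-th
#' permuted singular value with the i-th observed one:
#' `p_i = (1 + #{s_perm_i >= s_i}) / (n_perm + 1)`.
#'
#' @param X,Y Prepared matrices.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Seed.
#' @return Numeric vector of per-component p-values.
#' @export
permutation_pvalues <- function(X, Y, n_perm = 1000, seed = NULL) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  X <- as.matrix(X); Y <- as.matrix(Y)
  obs <- svd_cross(X, Y)$d
  n <- nrow(X)
  exceed <- numeric(length(obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      d_perm <- svd(crossprod(Y[sample.int(n), , drop = FALSE], X) / (n - 1),
                    nu = 0, nv = 0)$d
      exceed <- exceed + (d_perm >= obs)
    }
  })
  (1 + exceed) / (n_perm + 1)
}

#' Bootstrap ratios for brain saliences
#'
#' Resamples individuals with replacement, refits the cross-covariance
#' SVD, aligns each resample's saliences to the original by orthogonal
#' Procrustes rotation of the behavior saliences (with a per-component
#' sign fix so aligned columns have nonnegative inner product with the
#' original), and returns BSR = original salience / bootstrap standard
#' error per parcel and component. |BSR| > 2 is the conventional
#' stability threshold (roughly p < 0.05).
#'
#' @param X,Y Prepared matrices.
#' @param model The `pls_fit` for the original sample.
#' @param n_boot Number of resamples (minimum 50; below that the SE is too
#'   unstable to interpret).
#' @param seed Seed.
#' @return Matrix (parcel x component) of bootstrap ratios; parcels whose
#'   bootstrap SE is zero get `Inf`/`-Inf` and should be excluded from
#'   thresholded summaries (as [network_summary()] does).
#' @export
bootstrap_ratios <- function(X, Y, model, n_boot = 500, seed = NULL) {
  if (n_boot < 50) abort("n_boot must be >= 50 for stable bootstrap SEs")
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  k <- ncol(model$behavior_saliences)
  u0 <- model$behavior_saliences
  acc <- matrix(0, ncol(X), k)
  acc2 <- matrix(0, ncol(X), k)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      s <- svd(crossprod(Y[idx, , drop = FALSE], X[idx, , drop = FALSE]) / (n - 1),
               nu = k, nv = k)
      # Procrustes: rotation Q minimizing || u0 - u_b Q ||_F
      m <- svd(crossprod(s$u, u0))
      Q <- m$u %*% t(m$v)
      vb <- s$v %*% Q
      ub <- s$u %*% Q
      flip <- ifelse(colSums(ub * u0) < 0, -1, 1)
      vb <- sweep(vb, 2, flip, "*")
      acc <- acc + vb
      acc2 <- acc2 + vb^2
    }
  })
  se <- sqrt(pmax(0, acc2 / n_boot - (acc / n_boot)^2) * n_boot / (n_boot - 1))
  bsr <- model$brain_saliences / se
  bsr[se == 0] <- sign(model$brain_saliences[se == 0]) * Inf
  dimnames(bsr) <- dimnames(model$brain_saliences)
  bsr
}

#' Functional-network summary of a bootstrap-ratio map
#'
#' Summarizes a per-parcel BSR vector at the level of functional networks:
#' the mean BSR per network, and the relative contribution of each network
#' to positive (`BSR > threshold`) and negative (`BSR < -threshold`)
#' relations. Contributions are counts of suprathreshold parcels divided
#' by network size (controlling for network size), renormalized to sum to
#' 1 across networks. Non-finite BSR values are excluded from the
#' thresholded counts.
#'
#' @param bsr Numeric vector of bootstrap ratios, one per parcel.
#' @param labels Character vector of network labels aligned with `bsr`, or
#'   a two-column data frame `parcel,network` in parcel order.
#' @param threshold BSR cutoff (default 2).
#' @return Tibble: `network`, `size`, `mean_bsr`, `positive_contribution`,
#'   `negative_contribution`.
#' @export
network_summary <- function(bsr, labels, threshold = 2) {
  if (is.data.frame(labels)) labels <- labels$network
  if (length(labels) != length(bsr)) abort("labels must cover all parcels")
  if (any(is.na(labels))) abort("unknown (missing) network label")
  d <- tibble(network = as.character(labels), bsr = as.numeric(bsr))
  out <- d |>
    dplyr::group_by(.data$network) |>
    dplyr::summarise(
      size = dplyr::n(),
      mean_bsr = mean(.data$bsr[is.finite(.data$bsr)]),
      pos_rate = sum(is.finite(.data$bsr) & .data$bsr > threshold) / dplyr::n(),
      neg_rate = sum(is.finite(.data$bsr) & .data$bsr < -threshold) / dplyr::n(),
      .groups = "drop")
  norm <- function(v) if (sum(v) > 0) v / sum(v) else rep(0, length(v))
  out$positive_contribution <- norm(out$pos_rate)
  out$negative_contribution <- norm(out$neg_rate)
  dplyr::select(out, "network", "size", "mean_bsr",
                "positive_contribution", "negative_contribution")
}

#' Project a new sample onto fitted PLS saliences
#'
#' Computes composite scores of an independent sample by linear projection
#' onto the training saliences (`X_new %*% brain_saliences`,
#' `Y_new %*% behavior_saliences`) and the per-component Spearman
#' correlation of the paired scores -- the cross-sample replication check.
#' `X_new`/`Y_new` must be prepared with the new sample's own design.
#'
#' @param model A `pls_fit`.
#' @param X_new,Y_new Prepared matrices with the same columns as the
#'   training matrices.
#' @return List with `brain_scores`, `behavior_scores`, and `latent_corr`
#'   (per-component Spearman correlations).
#' @export
project_pls <- function(model, X_new, Y_new) {
  X_new <- as.matrix(X_new); Y_new <- as.matrix(Y_new)
  if (ncol(X_new) != nrow(model$brain_saliences) ||
      ncol(Y_new) != nrow(model$behavior_saliences)) {
    abort("column mismatch between new sample and model saliences")
  }
  bs <- X_new %*% model$brain_saliences
  hs <- Y_new %*% model$behavior_saliences
  k <- ncol(bs)
  list(brain_scores = bs, behavior_scores = hs,
       latent_corr = vapply(seq_len(k), function(i) rank_cor(bs[, i], hs[, i]),
                            numeric(1)))
}
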