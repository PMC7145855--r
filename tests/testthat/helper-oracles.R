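# Independent oracle implementations and small fixture builders.
# These deliberately take the naive dense / brute-force route so they share
# no code path with the package internals they check.

# dense multivariate-normal log-density via Cholesky
dense_mvn_loglik <- function(y, mu, Sigma) {
  L <- chol(Sigma)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# exhaustive grid search over h2 with dense-matrix profiled nuisance params
grid_fit_h2 <- function(y, X, K, step = 0.001) {
  n <- length(y)
  grid <- seq(0, 1 - 1e-6, by = step)
  ll <- vapply(grid, function(h2) {
    Omega <- h2 * K + (1 - h2) * diag(n)
    Oi <- solve(Omega)
    beta <- solve(t(X) %*% Oi %*% X, t(X) %*% Oi %*% y)
    r <- y - X %*% beta
    s2 <- drop(t(r) %*% Oi %*% r) / n
    -0.5 * (n * log(2 * pi) + n * log(s2) + determinant(Omega)$modulus + n)
  }, numeric(1))
  list(h2 = grid[which.max(ll)], loglik = max(ll))
}

# rank with average ties, built from scratch (no rank())
naive_rank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# residualize-then-rank Spearman, sums-based Pearson
naive_spearman_partial <- function(x, y, X = NULL) {
  if (!is.null(X)) {
    bx <- solve(t(X) %*% X, t(X) %*% x)
    by <- solve(t(X) %*% X, t(X) %*% y)
    x <- x - drop(X %*% bx)
    y <- y - drop(X %*% by)
  }
  rx <- naive_rank(x); ry <- naive_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# literal step-up rule: reject all i <= max{i : p_(i) <= i q / m}
brute_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ok) > 0) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# random small pedigree mixing MZ/DZ/SIB families and singletons
random_pedigree <- function(n_target, seed) {
  set.seed(seed)
  rows <- list()
  fam <- 0
  n <- 0
  while (n < n_target) {
    fam <- fam + 1
    kind <- sample(c("MZ", "DZ", "SIB", "NONE"), 1)
    size <- if (kind == "NONE") 1 else if (kind == "SIB") sample(2:4, 1) else 2
    size <- min(size, n_target - n)
    if (size == 1) kind <- "NONE"
    rows[[fam]] <- data.frame(
      id = paste0("f", fam, "i", seq_len(size)),
      family_id = paste0("f", fam),
      pair_id = if (kind == "NONE") "" else paste0("f", fam, "p"),
      zygosity = kind,
      sex = rep_len(c(0, 1), size),
      age = round(runif(1, 20, 60)) + seq_len(size) * 0,
      stringsAsFactors = FALSE)
    n <- n + size
  }
  build_pedigree(do.call(rbind, rows))
}

# a design guaranteed full-rank at small n (manual construction is fine in
# tests: the covariate_design() validators are exercised elsewhere)
test_design <- function(ids, age = NULL, sex = NULL) {
  n <- length(ids)
  if (is.null(age)) age <- seq(20, 40, length.out = n)
  if (is.null(sex)) sex <- rep_len(c(0, 1), n)
  covariate_design(ids, age, sex)
}

# symmetric PSD matrix square root, for fixture construction
msqrt_test <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# two-trait correlation matrix shorthand
corr2 <- function(r) matrix(c(1, r, r, 1), 2)

# planted one-component brain-behavior data: Y carries a latent score that
# loads on X through a fixed unit parcel pattern
planted_pls <- function(n = 500, p = 200, q = 5, strength = 2,
                        noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  nl <- min(40, floor(p / 2))
  v <- rep(0, p); v[seq_len(nl)] <- 1 / sqrt(nl)   # brain loading
  u <- c(0.6, -0.5, 0.4, -0.3, 0.35)[1:q]
  u <- u / sqrt(sum(u^2))                      # behavior loading
  s <- rnorm(n)
  Y <- tcrossprod(s, u) + matrix(rnorm(n * q, sd = 0.5), n)
  X <- strength * tcrossprod(drop(Y %*% u), v) + matrix(rnorm(n * p, sd = noise_sd), n)
  colnames(X) <- sprintf("parcel_%03d", 1:p)
  colnames(Y) <- paste0("t", 1:q)
  list(X = scale(X), Y = scale(Y), v = v, u = u)
}

cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# one-trait cohort simulation + univariate fit, returning the h2 estimate
sim_fit_h2 <- function(h2, seed, n_mz = 143, n_dz = 85, n_single = 650) {
  spec <- cohort_spec(n_mz_pairs = n_mz, n_dz_pairs = n_dz,
                      n_singletons = n_single,
                      traits = list(y = list(h2 = h2, mean = 0, var = 1)))
  co <- simulate_cohort(spec, seed = seed)
  des <- covariate_design(co$pedigree$id, co$pedigree$age, co$pedigree$sex)
  fit_univariate(co$phenotypes$y, des, expected_relatedness(co$pedigree))
}
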