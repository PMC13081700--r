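# Independent reference implementations used as oracles. These are written
# deliberately naively (explicit loops, textbook formulas) and share no code
# with the package internals.

# pairwise-indicator dominance estimate: P(X <= Y) - 1/2
brute_d0 <- function(tin, tout) {
  cnt <- 0
  for (y in tin) for (x in tout) if (x <= y) cnt <- cnt + 1
  cnt / (length(tin) * length(tout)) - 0.5
}

# Riemann-sum evaluation of int_gamma^1 (ODC(t) - t) dt on the plug-in curve
riemann_d_gamma <- function(tin, tout, gamma, npts = 2e6) {
  m <- length(tin)
  yin <- sort(tin)
  tt <- seq(gamma, 1, length.out = npts + 1)
  tt <- (tt[-1] + tt[-length(tt)]) / 2          # midpoints
  gi <- yin[pmin(m, ceiling(tt * m))]           # left-continuous G_m^{-1}
  odc <- stats::ecdf(tout)(gi)                  # right-continuous F_n
  sum(odc - tt) * (1 - gamma) / npts
}

# leave-one-out minimum-p null, O(K^2 * G) double loop
brute_null_q <- function(D_null, side = "right") {
  K <- nrow(D_null)
  q <- numeric(K)
  for (k in seq_len(K)) {
    pg <- numeric(ncol(D_null))
    for (g in seq_len(ncol(D_null))) {
      cnt <- 0
      for (k1 in seq_len(K)) {
        if (k1 == k) next
        hit <- if (side == "right") D_null[k1, g] >= D_null[k, g]
               else D_null[k1, g] <= D_null[k, g]
        if (hit) cnt <- cnt + 1
      }
      pg[g] <- (1 + cnt) / K
    }
    q[k] <- min(pg)
  }
  q
}

# textbook Benjamini-Hochberg step-up
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# direct summation of the hypergeometric upper tail (Eq-style)
hyper_tail <- function(s, S, m, V) {
  tot <- 0
  for (x in s:S) {
    if (x > m || S - x > V - m) next
    tot <- tot + choose(S, x) * choose(V - S, m - x) / choose(V, m)
  }
  tot
}

# per-location t maps by literal lm() fits
naive_tmap <- function(Y, df_covs, target, nuisance) {
  fml <- stats::as.formula(paste("y ~", paste(c(nuisance, target), collapse = "+")))
  vapply(seq_len(ncol(Y)), function(v) {
    d <- cbind(data.frame(y = Y[, v]), df_covs)
    summary(stats::lm(fml, data = d))$coefficients[target, "t value"]
  }, numeric(1))
}

# straight-line reimplementation of the whole enrichment procedure:
# observed t map, Freedman-Lane null maps by explicit lm() refits, shifted
# truncated ODC integrals by brute-force step sums, per-gamma p-values,
# leave-one-out q null, and the intersection-union maximum.
naive_netdom <- function(Y, covs, target, nuisance, in_idx, perms, gammas,
                         side = "right") {
  N <- nrow(Y)
  fml_red <- stats::as.formula(
    paste("y ~", if (length(nuisance)) paste(nuisance, collapse = "+") else "1"))
  tmap_of <- function(Ymat) naive_tmap(Ymat, covs, target, nuisance)
  d_of <- function(tvec, gamma) {
    tin <- sort(tvec[in_idx]); tout <- tvec[-in_idx]
    m <- length(tin)
    tot <- 0
    for (i in seq_len(m)) {
      lo <- max(gamma, (i - 1) / m); hi <- i / m
      if (hi > lo) tot <- tot + mean(tout <= tin[i]) * (hi - lo)
    }
    tot - (1 - gamma^2) / 2
  }
  t_obs <- tmap_of(Y)
  K <- nrow(perms)
  # Freedman-Lane: permute reduced-model residuals, add back fits, refit
  Rres <- Fhat <- matrix(0, N, ncol(Y))
  for (v in seq_len(ncol(Y))) {
    d <- cbind(data.frame(y = Y[, v]), covs)
    fit <- stats::lm(fml_red, data = d)
    Fhat[, v] <- stats::fitted(fit)
    Rres[, v] <- stats::resid(fit)
  }
  D_null <- matrix(0, K, length(gammas))
  mean_null <- numeric(K)
  for (k in seq_len(K)) {
    Ystar <- Fhat + Rres[perms[k, ], ]
    tk <- tmap_of(Ystar)
    mean_null[k] <- mean(tk[in_idx])
    for (g in seq_along(gammas)) D_null[k, g] <- d_of(tk, gammas[g])
  }
  D_obs <- vapply(gammas, function(g) d_of(t_obs, g), numeric(1))
  cmp <- function(a, b) if (side == "right") a >= b else a <= b
  p_gamma <- vapply(seq_along(gammas), function(g)
    (1 + sum(cmp(D_null[, g], D_obs[g]))) / (K + 1), numeric(1))
  q_obs <- min(p_gamma)
  q_null <- brute_null_q(D_null, side)
  p_diff <- (1 + sum(q_null <= q_obs)) / (K + 1)
  mo <- mean(t_obs[in_idx])
  p_zero <- if (side == "right") (1 + sum(mean_null >= mo)) / (K + 1)
            else (1 + sum(mean_null <= mo)) / (K + 1)
  list(p = max(p_diff, p_zero), p_diff = p_diff, p_zero = p_zero,
       q_obs = q_obs, p_gamma = p_gamma, D_obs = D_obs)
}

# small synthetic dataset shared by several tests
tiny_dataset <- function(N = 24, V = 40, seed = 7, beta3 = NULL) {
  set.seed(seed)
  covs <- data.frame(x1 = stats::rbinom(N, 1, 0.5), x2 = stats::rnorm(N),
                     x3 = stats::rnorm(N))
  if (is.null(beta3)) beta3 <- rep(0, V)
  Y <- 1 + 0.05 * covs$x1 - 0.05 * covs$x2 + outer(covs$x3, beta3) +
    matrix(stats::rnorm(N * V, sd = 0.4), N, V)
  list(imaging = imaging_matrix(Y),
       design = phenotype_design(covs, "x3", c("x1", "x2")),
       covs = covs, Y = Y, beta3 = beta3)
}
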