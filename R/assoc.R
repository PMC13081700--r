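# Mass-univariate association mapping.
#
# Every location is fit with the same ordinary least squares design
# [1 | nuisance | target], so the whole map reduces to a handful of matrix
# products: with Q the orthonormal basis of the reduced design and z the
# residual of the target on that basis, the target t-statistic at location v
# is  t_v = (z'Y_v) * sqrt(df) / sqrt(SSR_v * z'z),  SSR_v the full-model
# residual sum of squares. Permutation null maps reuse the same
# decomposition, which is what makes K = 1000 feasible.

# shared precomputation for one (imaging, design) pair
.assoc_prep <- function(imaging, design) {
  stopifnot(inherits(imaging, "imaging_matrix"),
            inherits(design, "phenotype_design"))
  N <- nrow(imaging$data)
  if (N != nrow(design$values))
    stop("imaging and phenotype tables have different numbers of subjects")
  X <- design_matrix(design)
  p_full <- ncol(X)
  if (N < p_full + 1L)
    stop("need at least ", p_full + 1L, " subjects for ", p_full,
         " regression coefficients")
  Y <- imaging$data[, imaging$mask, drop = FALSE]
  Xred <- X[, -p_full, drop = FALSE]
  qr_red <- qr(Xred)
  Qred <- qr.Q(qr_red)
  z <- qr.resid(qr_red, X[, p_full])
  zz <- sum(z * z)
  if (zz <= 0) stop("target is collinear with the nuisance covariates")
  zn <- z / sqrt(zz)
  Fhat <- Qred %*% crossprod(Qred, Y)
  Rres <- Y - Fhat
  cR2 <- colSums(Rres * Rres)
  df <- N - p_full
  # degenerate locations: no variation across subjects
  ctr <- sweep(Y, 2L, colMeans(Y))
  totSS <- colSums(ctr * ctr)
  valid <- totSS > 1e-12 * N * (1 + colMeans(Y)^2)
  if (!any(valid)) stop("all analyzable locations are degenerate (constant)")
  # floor for residual sums of squares: saturated fits get a huge but finite
  # statistic, and roundoff-only numerators stay at ~0
  ssr_floor <- 1e-12 * pmax(totSS, .Machine$double.xmin)
  list(Y = Y, N = N, df = df, Qred = Qred, qr_red = qr_red, zn = zn,
       Fhat = Fhat, Rres = Rres, cR2 = cR2, valid = valid,
       ssr_floor = ssr_floor, p_red = ncol(Xred))
}

.t_from_parts <- function(num, ssr, df, floor) {
  num * sqrt(df) / sqrt(pmax(ssr, floor))
}

# one Freedman-Lane t-map for a given row ordering; the observed map is the
# identity ordering, so both share this path bit-for-bit
.fl_tmap <- function(prep, perm) {
  W0 <- cbind(prep$zn, prep$Qred)
  Wp <- W0
  Wp[perm, ] <- W0
  G <- crossprod(Wp, prep$Rres)
  zrow <- G[1L, ]
  gq2 <- if (nrow(G) > 1L) colSums(G[-1L, , drop = FALSE]^2) else 0
  ssr <- prep$cR2 - gq2 - zrow^2
  .t_from_parts(zrow, ssr, prep$df, prep$ssr_floor)
}

.convert_stat <- function(tval, df, stat_kind) {
  switch(stat_kind,
         t = tval,
         pearson_r = tval / sqrt(tval^2 + df),
         F = tval^2,
         stop("unknown stat_kind '", stat_kind, "'"))
}

#' Fit a mass-univariate association map
#'
#' Fits, at every analyzable location, an ordinary least squares model of
#' the imaging measure on an intercept, the nuisance covariates, and the
#' target predictor, and returns the per-location statistic for the target:
#' its t-statistic, the partial Pearson correlation of the residualized
#' pair, or the (unsigned) F-statistic for the target coefficient.
#' Locations with no variation across subjects are flagged invalid rather
#' than assigned a value.
#'
#' @param imaging An [imaging_matrix()].
#' @param design A [phenotype_design()]; the design must be full rank.
#' @param stat_kind `"t"` (default), `"pearson_r"`, or `"F"`.
#' @return An [association_map()] over the analyzable locations, with
#'   `origin = "observed"`.
#' @export
fit_association_map <- function(imaging, design, stat_kind = "t") {
  prep <- .assoc_prep(imaging, design)
  tval <- .fl_tmap(prep, seq_len(prep$N))
  vals <- .convert_stat(tval, prep$df, stat_kind)
  vals[!prep$valid] <- NA_real_
  association_map(vals, stat_kind, origin = "observed", valid = prep$valid)
}

#' Permutation null association maps
#'
#' Generates `K` null maps under the scheme recorded in the plan. For
#' `freedman_lane`, every location's measure is regressed on the reduced
#' model (intercept + nuisance), the residual rows are permuted by the
#' plan's k-th ordering (the same ordering at every location, preserving
#' spatial autocorrelation), reduced-model fits are added back, and the full
#' model is refit. For `simple`/`stratified`, the target column itself is
#' permuted and the full model refit. With no nuisance covariates the
#' Freedman-Lane scheme reduces to permuting residuals about the intercept.
#'
#' @param imaging An [imaging_matrix()].
#' @param design A [phenotype_design()].
#' @param plan A [permutation_plan()].
#' @param stat_kind Statistic kind as in [fit_association_map()].
#' @return A [surrogate_map_set()] with `K` rows, mechanism
#'   `"phenotype_permutation"`, covering the same analyzable locations as
#'   the observed map (invalid locations NA in every row).
#' @export
null_association_maps <- function(imaging, design, plan, stat_kind = "t") {
  stopifnot(inherits(plan, "permutation_plan"))
  prep <- .assoc_prep(imaging, design)
  if (plan$n_subjects != prep$N)
    stop("permutation plan was built for ", plan$n_subjects,
         " subjects, data have ", prep$N)
  K <- plan$K
  Va <- ncol(prep$Y)
  maps <- matrix(NA_real_, K, Va)
  if (plan$scheme == "freedman_lane") {
    for (k in seq_len(K)) {
      maps[k, ] <- .fl_tmap(prep, plan$permutations[k, ])
    }
  } else {
    x_target <- design_matrix(design)[, prep$p_red + 1L]
    for (k in seq_len(K)) {
      xk <- x_target[plan$permutations[k, ]]
      zk <- qr.resid(prep$qr_red, xk)
      zzk <- sum(zk * zk)
      if (zzk <= 0) stop("permuted target collinear with nuisance covariates")
      znk <- zk / sqrt(zzk)
      num <- as.vector(crossprod(znk, prep$Y))
      ssr <- prep$cR2 - num^2
      maps[k, ] <- .t_from_parts(num, ssr, prep$df, prep$ssr_floor)
    }
  }
  maps <- .convert_stat(maps, prep$df, stat_kind)
  maps[, !prep$valid] <- NA_real_
  out <- surrogate_map_set(maps, "phenotype_permutation", stat_kind)
  out$valid <- prep$valid
  out$df <- prep$df
  out
}

#' Freedman-Lane null maps
#'
#' Convenience wrapper around [null_association_maps()] that insists on the
#' Freedman-Lane scheme (permutation of reduced-model residuals).
#'
#' @inheritParams null_association_maps
#' @return A [surrogate_map_set()]; see [null_association_maps()].
#' @export
freedman_lane_null_maps <- function(imaging, design, plan, stat_kind = "t") {
  if (plan$scheme != "freedman_lane")
    stop("plan scheme is '", plan$scheme, "'; expected 'freedman_lane'")
  null_association_maps(imaging, design, plan, stat_kind)
}

#' Permuted copies of a phenotype design
#'
#' Returns `K` designs in which only the target column has been reordered
#' according to the plan. Under the stratified scheme subjects trade target
#' values only within strata.
#'
#' @inheritParams null_association_maps
#' @return A list of `K` [phenotype_design()] objects.
#' @export
permute_phenotype <- function(design, plan) {
  stopifnot(inherits(design, "phenotype_design"),
            inherits(plan, "permutation_plan"))
  if (plan$n_subjects != nrow(design$values))
    stop("plan and design disagree on the number of subjects")
  x <- design$values[[design$target]]
  lapply(seq_len(plan$K), function(k) {
    d <- design
    d$values[[design$target]] <- x[plan$permutations[k, ]]
    d
  })
}
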