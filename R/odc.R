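# Ordinal dominance curves.
#
# For in-network statistics with CDF G (m samples) and out-of-network
# statistics with CDF F (n samples), the ODC is F(G^{-1}(t)); its integral
# over (0, 1] is P(X <= Y), the probability that a random out-of-network
# statistic falls at or below a random in-network one. The plug-in
# estimator uses the two ECDFs: G_m^{-1} is the left-continuous generalized
# inverse (smallest order statistic y_(i) with i/m >= t) and F_n is the
# right-continuous ECDF with ties counted as <=. The estimated curve is a
# step function, constant on ((i-1)/m, i/m] at height c_i = F_n(y_(i)),
# so all integrals below are exact piecewise sums, never quadrature.

#' Plug-in ordinal dominance curve
#'
#' Computes the plug-in ODC of in-network versus out-of-network association
#' statistics: the sorted samples and the step heights
#' `c_i = F_n(y_(i)) = #\{x in out : x <= y_(i)\} / n`.
#'
#' @param assoc An [association_map()] (or bare numeric vector) of
#'   per-location statistics.
#' @param partition A [network_partition()] aligned to `assoc`.
#' @return An object of class `odc_curve` with `in_sorted`, `out_sorted`,
#'   `step_heights`, `m`, `n`.
#' @export
odc_plugin <- function(assoc, partition) {
  vals <- if (inherits(assoc, "association_map")) assoc$values else as.numeric(assoc)
  stopifnot(inherits(partition, "network_partition"))
  if (length(vals) != partition$V)
    stop("association map and partition cover different numbers of locations")
  tin <- vals[partition$in_idx]
  tout <- vals[-partition$in_idx]
  tin <- tin[!is.na(tin)]
  tout <- tout[!is.na(tout)]
  if (length(tin) == 0L || length(tout) == 0L)
    stop("in-network and out-of-network sets must both be non-empty")
  .odc_from_samples(tin, tout)
}

.odc_from_samples <- function(tin, tout) {
  yin <- sort.int(tin, method = "quick")
  xout <- sort.int(tout, method = "quick")
  # findInterval on sorted xout counts #{x <= y} (right-continuous, <= ties)
  ci <- findInterval(yin, xout) / length(xout)
  structure(list(in_sorted = yin, out_sorted = xout, step_heights = ci,
                 m = length(yin), n = length(xout)),
            class = "odc_curve")
}

#' Truncated shifted-ODC statistic
#'
#' Exact integral of the shifted ODC above the truncation quantile:
#' `D_gamma = int_gamma^1 (ODC(t) - t) dt`, computed from the
#' piecewise-constant plug-in curve. `gamma` is the lowest in-network
#' quantile contributing to the comparison; `gamma = 0` integrates the whole
#' curve, in which case `D_0` equals the pairwise dominance proportion
#' `#\{(x, y) : x <= y\} / (n m) - 1/2`. A step straddling `gamma` is
#' split exactly.
#'
#' @param curve An `odc_curve` from [odc_plugin()].
#' @param gamma Truncation quantile in `[0, 1)`.
#' @return The scalar statistic.
#' @export
d_gamma <- function(curve, gamma) {
  stopifnot(inherits(curve, "odc_curve"))
  if (length(gamma) != 1L || is.na(gamma) || gamma < 0 || gamma >= 1)
    stop("gamma must lie in [0, 1)")
  .d_gamma_sum(curve$step_heights, curve$m, gamma)
}

.d_gamma_sum <- function(ci, m, gamma) {
  i <- seq_len(m)
  len <- pmax(0, i / m - pmax(gamma, (i - 1) / m))
  sum(ci * len) - (1 - gamma^2) / 2
}

#' Gamma grid
#'
#' The finite set of truncation quantiles swept by the adaptive test. The
#' identical grid must be used for the observed and every permuted map.
#'
#' @param gammas Ascending values in `[0, 1)`; default
#'   `seq(0, 0.95, by = 0.05)`.
#' @return Numeric vector of class `gamma_grid`.
#' @export
gamma_grid <- function(gammas = seq(0, 0.95, by = 0.05)) {
  gammas <- as.numeric(gammas)
  if (length(gammas) == 0L || anyNA(gammas) || any(gammas < 0 | gammas >= 1))
    stop("gamma values must lie in [0, 1)")
  if (is.unsorted(gammas, strictly = TRUE)) stop("gamma grid must be strictly ascending")
  structure(gammas, class = "gamma_grid")
}

# D_gamma for every row of a K x V matrix of maps, plus in-network means.
# Valid locations only; the same split is used for every map.
.d_matrix <- function(maps, in_idx, valid, gammas) {
  use_in <- intersect(in_idx, which(valid))
  use_out <- setdiff(which(valid), in_idx)
  K <- nrow(maps)
  G <- length(gammas)
  D <- matrix(NA_real_, K, G)
  mean_in <- numeric(K)
  m <- length(use_in)
  i <- seq_len(m)
  upper <- i / m
  lower <- (i - 1) / m
  nout <- length(use_out)
  # interval lengths |((i-1)/m, i/m] \cap (gamma, 1]| depend only on the grid
  lens <- vapply(gammas, function(g) pmax(0, upper - pmax(g, lower)),
                 numeric(m))                      # m x G
  shift <- (1 - gammas^2) / 2
  for (k in seq_len(K)) {
    row <- maps[k, ]
    tin <- row[use_in]
    tout <- row[use_out]
    mean_in[k] <- sum(tin) / m
    ci <- findInterval(sort.int(tin, method = "quick"),
                       sort.int(tout, method = "quick")) / nout
    D[k, ] <- as.vector(crossprod(lens, ci)) - shift
  }
  list(D = D, mean_in = mean_in, m = m, n = nout)
}
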