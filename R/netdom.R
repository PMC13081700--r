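# The NETDOM intersection-union test.
#
# The composite null for a right-sided test is the union of (a) in-network
# statistics not stochastically greater than out-of-network statistics and
# (b) in-network mean association <= 0. The test rejects only when both
# components reject: p = max(p_diff, p_zero). p_diff comes from the
# truncated shifted-ODC statistic D_gamma, with gamma chosen adaptively by
# minimizing the per-gamma permutation p-value; the minimum q is then
# calibrated against a leave-one-out null so that adaptivity does not
# inflate the type I error. p_zero compares the observed in-network mean
# against its permutation distribution (the null reference value is 0, as
# for t-statistics and correlations).

#' Per-gamma intermediate permutation p-values
#'
#' For each truncation quantile, compares the observed statistic to its
#' permutation distribution with the conservative `(1 + count) / (K + 1)`
#' form and inclusive ties. Right side counts null statistics `>=` the
#' observed; left side flips the inequality so that lower (more negative)
#' observed statistics give lower p-values.
#'
#' @param D_obs Numeric vector of observed `D_gamma`, one per grid value.
#' @param D_null `K x length(D_obs)` matrix of null `D_gamma`.
#' @param side `"right"` or `"left"`.
#' @return Numeric vector of p-values, one per gamma.
#' @export
gamma_p_values <- function(D_obs, D_null, side = c("right", "left")) {
  side <- match.arg(side)
  D_null <- as.matrix(D_null)
  K <- nrow(D_null)
  if (K < 1L) stop("at least one permutation is required")
  if (ncol(D_null) != length(D_obs))
    stop("observed and null statistics use different gamma grids")
  cnt <- if (side == "right") {
    colSums(D_null >= rep(D_obs, each = K))
  } else {
    colSums(D_null <= rep(D_obs, each = K))
  }
  (1 + cnt) / (K + 1)
}

#' Adaptive minimum p-value
#'
#' `q = min(p_gamma)`; ties are broken toward the smallest gamma, which is
#' also the value reported as the selected truncation quantile.
#'
#' @param p_gamma Per-gamma p-values.
#' @param gammas Matching grid (optional, for reporting).
#' @return List with `q` and `gamma_index` (and `gamma` when supplied).
#' @export
select_q <- function(p_gamma, gammas = NULL) {
  if (length(p_gamma) == 0L) stop("p_gamma is empty")
  idx <- which.min(p_gamma)   # first minimum = smallest gamma
  out <- list(q = p_gamma[idx], gamma_index = idx)
  if (!is.null(gammas)) out$gamma <- gammas[idx]
  out
}

#' Leave-one-out null distribution of the minimum p-value
#'
#' Treats each permuted map in turn as "observed" against the remaining
#' `K - 1` maps: `p_gamma^(k) = (1 + #\{k1 != k : D^(k1) >= D^(k)\}) / K`
#' (inequality flipped for a left-sided test), and `q^(k)` is the minimum
#' over the grid. Computed by per-gamma ranking in O(K log K) per gamma;
#' with ties counted inclusively this reduces to
#' `#\{k1 : D^(k1) >= D^(k)\} / K`.
#'
#' @param D_null `K x G` matrix of null statistics.
#' @param side `"right"` or `"left"`.
#' @return Numeric vector of `K` leave-one-out minima `q^(k)`.
#' @export
null_q_distribution <- function(D_null, side = c("right", "left")) {
  side <- match.arg(side)
  D_null <- as.matrix(D_null)
  K <- nrow(D_null)
  if (K < 2L) stop("leave-one-out null requires K >= 2")
  P <- matrix(NA_real_, K, ncol(D_null))
  for (g in seq_len(ncol(D_null))) {
    d <- D_null[, g]
    cnt_ge <- if (side == "right") {
      K - rank(d, ties.method = "min") + 1   # #{k1 : d[k1] >= d[k]}
    } else {
      rank(d, ties.method = "max")           # #{k1 : d[k1] <= d[k]}
    }
    P[, g] <- cnt_ge / K
  }
  apply(P, 1L, min)
}

#' Self-containment p-value for the in-network mean
#'
#' Compares the observed in-network mean statistic against its permutation
#' distribution: right side `(1 + #\{k : mean^(k) >= mean_obs\}) / (K + 1)`,
#' left side with the inequality flipped so that strong negative
#' associations give low p-values. A left-sided test on an unsigned
#' statistic is refused: unsigned statistics only capture association
#' strength, so only right-sided testing is meaningful for them.
#'
#' @param mean_in_obs Observed in-network mean statistic.
#' @param mean_in_null Numeric vector of `K` permutation means.
#' @param side `"right"` or `"left"`.
#' @param signed Is the statistic signed? (`FALSE` for F.)
#' @return Scalar p-value.
#' @export
p_zero <- function(mean_in_obs, mean_in_null, side = c("right", "left"),
                   signed = TRUE) {
  side <- match.arg(side)
  if (side == "left" && !signed)
    stop("left-sided test is undefined for an unsigned statistic; ",
         "use side = 'right' with a strictly positive statistic")
  K <- length(mean_in_null)
  if (K < 1L) stop("at least one permutation is required")
  cnt <- if (side == "right") sum(mean_in_null >= mean_in_obs)
         else sum(mean_in_null <= mean_in_obs)
  (1 + cnt) / (K + 1)
}

#' Network enrichment test with ordinal dominance curves
#'
#' Runs the full intersection-union enrichment test for one network:
#' fits the observed association map, generates permutation null maps,
#' sweeps the truncated shifted-ODC statistic over the gamma grid on the
#' observed and every permuted map, calibrates the adaptive minimum p-value
#' against its leave-one-out null, computes the self-containment p-value
#' for the in-network mean, and returns `p = max(p_diff, p_zero)` together
#' with every intermediate quantity for audit.
#'
#' @param imaging An [imaging_matrix()].
#' @param design A [phenotype_design()].
#' @param partition A [network_partition()] over the analyzable locations.
#' @param plan A [permutation_plan()].
#' @param grid A [gamma_grid()] (default `seq(0, 0.95, by = 0.05)`).
#' @param side `"right"` or `"left"`.
#' @param stat_kind `"t"`, `"pearson_r"`, or `"F"`.
#' @param small_network_warn Warn when fewer than this many in-network
#'   locations are available (default 100; small networks make the plug-in
#'   ODC noisy).
#' @return An object of class `netdom_result`; see Details.
#' @details The result records `D_obs` (per gamma), `p_gamma`, `q_obs`,
#'   `q_null`, `mean_in_obs`, `mean_in_null`, `p_diff`, `p_zero`, the final
#'   `p`, the selected gamma (smallest gamma attaining `q_obs`), the
#'   partition sizes actually used after dropping degenerate locations, and
#'   `K`. All permutation p-values lie in `[1/(K+1), 1]`. A left-sided test
#'   is carried out as the right-sided test on the negated map (so the
#'   truncation acts on the strongest negative associations); the recorded
#'   `D` values then refer to the negated map, while the in-network means
#'   keep their original sign.
#' @export
netdom_test <- function(imaging, design, partition, plan,
                        grid = gamma_grid(), side = c("right", "left"),
                        stat_kind = "t", small_network_warn = 100L) {
  side <- match.arg(side)
  if (!inherits(grid, "gamma_grid")) grid <- gamma_grid(grid)
  obs <- fit_association_map(imaging, design, stat_kind)
  nulls <- null_association_maps(imaging, design, plan, stat_kind)
  netdom_from_maps(obs, nulls, partition, grid = grid, side = side,
                   small_network_warn = small_network_warn,
                   seed = plan$seed)
}

#' NETDOM from precomputed maps
#'
#' Same inference as [netdom_test()], starting from an observed map and a
#' phenotype-permutation surrogate set. Useful when several networks are
#' tested against one common null ensemble.
#'
#' @param obs An [association_map()] (origin observed).
#' @param nulls A [surrogate_map_set()] with mechanism
#'   `"phenotype_permutation"` aligned to `obs`.
#' @inheritParams netdom_test
#' @param seed Seed recorded in the result (for reporting only).
#' @return A `netdom_result`.
#' @export
netdom_from_maps <- function(obs, nulls, partition, grid = gamma_grid(),
                             side = c("right", "left"),
                             small_network_warn = 100L, seed = NA_integer_) {
  side <- match.arg(side)
  if (!inherits(grid, "gamma_grid")) grid <- gamma_grid(grid)
  stopifnot(inherits(obs, "association_map"),
            inherits(nulls, "surrogate_map_set"),
            inherits(partition, "network_partition"))
  if (side == "left" && !obs$signed)
    stop("left-sided test is undefined for an unsigned statistic")
  if (length(obs$values) != partition$V)
    stop("association map and partition cover different numbers of locations")
  K <- nulls$K
  valid <- obs$valid
  m_used <- sum(valid[partition$in_idx])
  if (m_used < 2L || sum(valid) - m_used < 2L)
    stop("fewer than two valid in- or out-of-network locations")
  if (m_used < small_network_warn)
    warning("only ", m_used, " in-network locations; ",
            "enrichment tests on small networks have limited power")
  gammas <- as.numeric(grid)
  # A left-sided test is the right-sided test on the negated map: this makes
  # the truncation parameter act on the strongest *negative* in-network
  # associations and gives exact left/right symmetry under sign flip.
  flip <- side == "left"
  all_maps <- rbind(obs$values, nulls$maps)
  if (flip) all_maps <- -all_maps
  dm <- .d_matrix(all_maps, partition$in_idx, valid, gammas)
  D_obs <- dm$D[1L, ]
  D_null <- dm$D[-1L, , drop = FALSE]
  sgn <- if (flip) -1 else 1
  mean_in_obs <- sgn * dm$mean_in[1L]
  mean_in_null <- sgn * dm$mean_in[-1L]
  p_gamma <- gamma_p_values(D_obs, D_null, "right")
  sel <- select_q(p_gamma, gammas)
  q_null <- null_q_distribution(D_null, "right")
  p_diff <- (1 + sum(q_null <= sel$q)) / (K + 1)
  pz <- p_zero(mean_in_obs, mean_in_null, side, signed = obs$signed)
  mean_out_obs <- {
    use_out <- setdiff(which(valid), partition$in_idx)
    mean(obs$values[use_out])
  }
  structure(list(network_id = partition$network_id, side = side,
                 stat_kind = obs$stat_kind,
                 m = dm$m, n = dm$n,
                 gammas = gammas, D_obs = D_obs, D_null = D_null,
                 p_gamma = p_gamma, q_obs = sel$q, q_null = q_null,
                 gamma_selected = sel$gamma, gamma_index = sel$gamma_index,
                 mean_in_obs = mean_in_obs, mean_in_null = mean_in_null,
                 mean_out_obs = mean_out_obs,
                 p_diff = p_diff, p_zero = pz, p = max(p_diff, pz),
                 K = K, seed = seed),
            class = "netdom_result")
}

#' @export
print.netdom_result <- function(x, ...) {
  cat("NETDOM enrichment test (", x$side, "-sided, ", x$stat_kind,
      " statistic)\n", sep = "")
  cat("  network ", x$network_id, ": m = ", x$m, ", n = ", x$n, "\n", sep = "")
  cat(sprintf("  mean in-network statistic: %.4g (out: %.4g)\n",
              x$mean_in_obs, x$mean_out_obs))
  cat(sprintf("  selected gamma = %.2f, q = %.4g\n",
              x$gamma_selected, x$q_obs))
  cat(sprintf("  p_diff = %.4g, p_zero = %.4g, p = %.4g  (K = %d)\n",
              x$p_diff, x$p_zero, x$p, x$K))
  invisible(x)
}

#' Benjamini-Hochberg adjustment across networks
#'
#' Step-up false discovery rate adjustment of the per-network p-values;
#' adjusted values are monotone and capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) stop("no p-values supplied")
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
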