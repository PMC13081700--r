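# Monte Carlo rejection-rate studies: type I error under the two null
# effect configurations, power under the two alternatives.

.study_methods <- c("netdom", "rigea", "nest", "meandiff_perm",
                    "brainsmash", "spin")

#' Monte Carlo rejection-rate study
#'
#' Repeatedly simulates a dataset under the given setting, runs the chosen
#' enrichment test for one network, and reports the proportion of
#' replicates with `p < alpha` together with its binomial Monte Carlo
#' standard error. Per-replicate seeds are derived deterministically from
#' the master seed, so reruns reproduce the same replicates and adding
#' replicates never changes earlier ones.
#'
#' Methods: `"netdom"` (the ODC intersection-union test, Freedman-Lane
#' permutation), `"rigea"` (thresholded Fisher's exact; no permutations),
#' `"nest"` (weighted-KS score against Freedman-Lane null maps),
#' `"meandiff_perm"` (difference in means against Freedman-Lane null maps),
#' `"brainsmash"` (difference in means against variogram surrogates),
#' `"spin"` (difference in means against spin surrogates; sphere layouts
#' only).
#'
#' @param method One of the method names above.
#' @param setting A [simulation_setting()] (its `seed` is ignored; the
#'   study's `seed` governs everything).
#' @param geometry A [make_geometry()] object.
#' @param network_id Network label to test.
#' @param reps Number of simulation replicates (>= 50 recommended for a
#'   usable standard error).
#' @param K Permutations/surrogates per replicate.
#' @param alpha Significance level (default 0.05).
#' @param side `"right"` or `"left"`.
#' @param seed Master seed.
#' @param grid Gamma grid for `"netdom"`.
#' @param stat_kind Association statistic (default `"t"`).
#' @param vario_config Configuration list for `"brainsmash"`.
#' @return Object of class `rejection_study`: `rate`, `se`, `n_reject`,
#'   `reps`, `p_values`, and the study parameters.
#' @export
run_rejection_study <- function(method, setting, geometry, network_id,
                                reps, K, alpha = 0.05,
                                side = c("right", "left"), seed = 1L,
                                grid = gamma_grid(), stat_kind = "t",
                                vario_config = list(nmax = 300L)) {
  side <- match.arg(side)
  if (!method %in% .study_methods)
    stop("unknown method '", method, "'; choose one of: ",
         paste(.study_methods, collapse = ", "))
  if (method == "spin" && geometry$layout != "sphere")
    stop("the spin method requires a sphere layout")
  if (reps < 1) stop("reps must be positive")
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, reps))
  labels_an <- geometry$labels[geometry$analyzable]
  partition <- network_partition(labels_an, network_id)
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- setting
    st$seed <- rep_seeds[r]
    st$network_id <- network_id
    ds <- simulate_dataset(st, geometry)
    pvals[r] <- switch(method,
      netdom = {
        plan <- permutation_plan(st$N, K, "freedman_lane", seed = rep_seeds[r])
        suppressWarnings(
          netdom_test(ds$imaging, ds$design, partition, plan,
                      grid = grid, side = side, stat_kind = stat_kind))$p
      },
      rigea = {
        obs <- fit_association_map(ds$imaging, ds$design, stat_kind)
        rigea_test(obs, partition, side)
      },
      nest = , meandiff_perm = {
        obs <- fit_association_map(ds$imaging, ds$design, stat_kind)
        plan <- permutation_plan(st$N, K, "freedman_lane", seed = rep_seeds[r])
        nulls <- null_association_maps(ds$imaging, ds$design, plan, stat_kind)
        if (method == "nest")
          as.numeric(weighted_ks_enrichment(obs, partition, nulls, side))
        else
          as.numeric(surrogate_test(obs, partition, nulls, side))
      },
      brainsmash = {
        obs <- fit_association_map(ds$imaging, ds$design, stat_kind)
        coords_an <- geometry$coords[geometry$analyzable, , drop = FALSE]
        surr <- variogram_surrogates(obs, coords_an, K, seed = rep_seeds[r],
                                     config = vario_config)
        as.numeric(surrogate_test(obs, partition, surr, side))
      },
      spin = {
        obs <- fit_association_map(ds$imaging, ds$design, stat_kind)
        surr <- spin_surrogates(obs, geometry$sphere, K, seed = rep_seeds[r])
        as.numeric(suppressWarnings(
          surrogate_test(obs, partition, surr, side)))
      })
  }
  n_reject <- sum(pvals < alpha)
  rate <- n_reject / reps
  structure(list(method = method, rate = rate,
                 se = sqrt(rate * (1 - rate) / reps),
                 n_reject = n_reject, reps = reps, K = K, alpha = alpha,
                 side = side, network_id = network_id,
                 setting = setting, seed = seed, p_values = pvals),
            class = "rejection_study")
}

#' @export
print.rejection_study <- function(x, ...) {
  cat(sprintf(
    "Rejection study: %s, network %s, %d reps (K = %d, alpha = %.3g)\n",
    x$method, x$network_id, x$reps, x$K, x$alpha))
  cat(sprintf("  rejection rate = %.3f (MC SE %.3f)\n", x$rate, x$se))
  invisible(x)
}
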