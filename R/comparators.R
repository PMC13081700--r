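# Comparator enrichment tests: thresholded Fisher's-exact enrichment
# (RIGEA-style), difference-in-means against surrogate maps (spin or
# variogram mechanisms), and a GSEA-style weighted Kolmogorov-Smirnov
# permutation test.

#' Thresholded Fisher's-exact enrichment test
#'
#' Dichotomizes the association map at a threshold (right side:
#' `T_v >= threshold`; left side: `T_v <= -threshold`), cross-tabulates
#' significance against network membership, and returns the upper-tail
#' hypergeometric probability
#' `p = sum_{s <= x <= S} C(S, x) C(V - S, m - x) / C(V, m)`
#' computed in log space. Infeasible terms (`x > m` or `S - x > n`)
#' contribute zero mass. An empty set of significant locations gives the
#' vacuous p-value 1, with a warning.
#'
#' @param assoc An [association_map()] or numeric vector.
#' @param partition A [network_partition()].
#' @param side `"right"` or `"left"`.
#' @param threshold Positive significance cutoff (default 1.96).
#' @return Scalar p-value.
#' @export
rigea_test <- function(assoc, partition, side = c("right", "left"),
                       threshold = 1.96) {
  side <- match.arg(side)
  vals <- if (inherits(assoc, "association_map")) assoc$values else as.numeric(assoc)
  stopifnot(inherits(partition, "network_partition"))
  keep <- !is.na(vals)
  sig <- if (side == "right") vals >= threshold else vals <= -threshold
  in_net <- seq_along(vals) %in% partition$in_idx
  s <- sum(sig & in_net & keep)
  S <- sum(sig & keep)
  m <- sum(in_net & keep)
  V <- sum(keep)
  n <- V - m
  if (S == 0L) {
    warning("no significant locations at the chosen threshold; p = 1")
    return(1)
  }
  x <- s:S
  feas <- x <= m & (S - x) <= n
  if (!any(feas)) return(0)
  x <- x[feas]
  logp <- lchoose(S, x) + lchoose(V - S, m - x) - lchoose(V, m)
  mx <- max(logp)
  min(1, exp(mx) * sum(exp(logp - mx)))
}

#' Difference-in-means enrichment score
#'
#' `ES = mean(in-network) - mean(out-of-network)` over valid locations.
#'
#' @inheritParams rigea_test
#' @return Scalar enrichment score.
#' @export
enrichment_score <- function(assoc, partition) {
  vals <- if (inherits(assoc, "association_map")) assoc$values else as.numeric(assoc)
  stopifnot(inherits(partition, "network_partition"))
  tin <- vals[partition$in_idx]
  tout <- vals[-partition$in_idx]
  tin <- tin[!is.na(tin)]
  tout <- tout[!is.na(tout)]
  if (length(tin) == 0L || length(tout) == 0L)
    stop("in-network and out-of-network sets must both be non-empty")
  mean(tin) - mean(tout)
}

#' Surrogate-map mean-difference test
#'
#' Compares the observed difference-in-means enrichment score against the
#' scores of `K` surrogate maps:
#' right side `p = (1 + #\{k : ES^(k) >= ES_obs\}) / (K + 1)`, left side
#' with the inequality reversed. Surrogate maps may carry their own invalid
#' locations (spin surrogates discard rotated-in medial wall); means are
#' taken over each map's valid locations. A surrogate whose valid locations
#' leave the network (or its complement) empty is dropped with a warning
#' and `K` decremented.
#'
#' @param assoc Observed [association_map()] or numeric vector.
#' @param partition A [network_partition()].
#' @param surrogates A [surrogate_map_set()].
#' @param side `"right"` or `"left"`.
#' @return Scalar p-value; the effective `K` is attached as attribute `"K"`.
#' @export
surrogate_test <- function(assoc, partition, surrogates,
                           side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(inherits(surrogates, "surrogate_map_set"))
  es_obs <- enrichment_score(assoc, partition)
  in_net <- seq_len(partition$V) %in% partition$in_idx
  es_null <- apply(surrogates$maps, 1L, function(row) {
    tin <- row[in_net]
    tout <- row[!in_net]
    tin <- tin[!is.na(tin)]
    tout <- tout[!is.na(tout)]
    if (length(tin) == 0L || length(tout) == 0L) return(NA_real_)
    mean(tin) - mean(tout)
  })
  if (anyNA(es_null)) {
    warning(sum(is.na(es_null)),
            " surrogate map(s) left the network empty and were excluded")
    es_null <- es_null[!is.na(es_null)]
  }
  K <- length(es_null)
  if (K < 1L) stop("no usable surrogate maps")
  cnt <- if (side == "right") sum(es_null >= es_obs) else sum(es_null <= es_obs)
  structure((1 + cnt) / (K + 1), K = K)
}

# GSEA-style running-sum score; side determines the ranking direction
.wks_score <- function(vals, in_net, side) {
  ok <- !is.na(vals)
  v <- vals[ok]
  memb <- in_net[ok]
  ord <- order(v, decreasing = (side == "right"))
  memb <- memb[ord]
  w <- abs(v[ord])
  denom <- sum(w[memb])
  if (denom == 0) stop("all in-network statistics are zero; weights undefined")
  n_out <- sum(!memb)
  step <- ifelse(memb, w / denom, -1 / n_out)
  running <- cumsum(step)
  running[which.max(abs(running))]
}

#' Weighted Kolmogorov-Smirnov enrichment test
#'
#' GSEA-style enrichment: locations are ranked by statistic (descending for
#' a right-sided test, ascending for left), a running sum takes steps
#' `+|T_v| / sum_N |T_v|` at in-network locations and `-1/n` at
#' out-of-network locations, and the enrichment score is the running sum's
#' signed maximum deviation from zero. The p-value compares the observed
#' score with scores computed identically on each surrogate map (intended
#' for phenotype-permutation surrogates).
#'
#' @inheritParams surrogate_test
#' @return Scalar p-value with attributes `"score"` (observed) and `"K"`.
#' @export
weighted_ks_enrichment <- function(assoc, partition, surrogates,
                                   side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(inherits(surrogates, "surrogate_map_set"))
  vals <- if (inherits(assoc, "association_map")) assoc$values else as.numeric(assoc)
  in_net <- seq_len(partition$V) %in% partition$in_idx
  s_obs <- .wks_score(vals, in_net, side)
  s_null <- apply(surrogates$maps, 1L, .wks_score, in_net = in_net, side = side)
  K <- length(s_null)
  p <- (1 + sum(s_null >= s_obs)) / (K + 1)
  structure(p, score = s_obs, K = K)
}
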