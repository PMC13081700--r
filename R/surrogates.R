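# Spatial-autocorrelation-preserving surrogate association maps:
# spherical rotations of the map (spin) and variogram-matched smoothed
# permutations.

#' Spherical geometry for spin surrogates
#'
#' Unit-sphere vertex coordinates with hemisphere labels and a medial-wall
#' mask. Coordinates are normalized to radius 1; both hemispheres must be
#' present so rotations can be mirrored contralaterally.
#'
#' @param coords `V x 3` matrix of vertex coordinates (normalized here).
#' @param hemisphere Character vector (`"L"`/`"R"`), one per vertex.
#' @param medial_wall Logical; `TRUE` marks medial-wall vertices excluded
#'   from analysis. Default none.
#' @return Object of class `sphere_geometry`.
#' @export
sphere_geometry <- function(coords, hemisphere, medial_wall = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be a V x 3 matrix")
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != nrow(coords))
    stop("hemisphere labels must cover every vertex")
  if (!all(hemisphere %in% c("L", "R")))
    stop("hemisphere labels must be 'L' or 'R'")
  if (!all(c("L", "R") %in% hemisphere))
    stop("both hemispheres are required for contralateral mirroring")
  if (is.null(medial_wall)) medial_wall <- rep(FALSE, nrow(coords))
  nrm <- sqrt(rowSums(coords^2))
  if (any(nrm == 0)) stop("zero-length vertex coordinate")
  coords <- coords / nrm
  structure(list(coords = coords, hemisphere = hemisphere,
                 medial_wall = as.logical(medial_wall)),
            class = "sphere_geometry")
}

.rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
.rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
.rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Spin-rotation surrogate maps
#'
#' Generates `K` surrogate maps by rotating the spherical projection of the
#' association map. For each surrogate, rotation angles about the x, y, and
#' z axes are drawn uniformly on `[0, 2*pi)`; the left hemisphere receives
#' the rotation `Rz Ry Rx`, and the right hemisphere the same x-rotation
#' with negated y- and z-rotations, preserving contralateral symmetry. Each
#' vertex is then reassigned the value of the nearest rotated vertex within
#' its hemisphere (ties broken toward the lowest vertex index). Vertices
#' that receive a rotated-in medial-wall value are marked invalid and
#' excluded from downstream statistics.
#'
#' @param assoc [association_map()] or numeric vector over the analyzable
#'   (non-medial-wall) vertices, in vertex order.
#' @param geometry A [sphere_geometry()] covering every vertex.
#' @param K Number of surrogates.
#' @param seed Integer seed.
#' @return A [surrogate_map_set()] with mechanism `"spin"`; rows contain NA
#'   at invalidated locations.
#' @export
spin_surrogates <- function(assoc, geometry, K, seed = 1L) {
  stopifnot(inherits(geometry, "sphere_geometry"))
  vals <- if (inherits(assoc, "association_map")) assoc$values else as.numeric(assoc)
  analyzable <- !geometry$medial_wall
  if (length(vals) != sum(analyzable))
    stop("association map must cover the ", sum(analyzable),
         " non-medial-wall vertices")
  Vfull <- nrow(geometry$coords)
  full <- rep(NA_real_, Vfull)
  full[analyzable] <- vals
  hemi_idx <- list(L = which(geometry$hemisphere == "L"),
                   R = which(geometry$hemisphere == "R"))
  maps <- matrix(NA_real_, K, sum(analyzable))
  with_seed(seed, {
    for (k in seq_len(K)) {
      ang <- stats::runif(3, 0, 2 * pi)
      maps[k, ] <- .spin_one(full, geometry, hemi_idx, ang)[analyzable]
    }
  })
  surrogate_map_set(maps, "spin",
                    if (inherits(assoc, "association_map")) assoc$stat_kind else "t")
}

# one spin: rotate each hemisphere, reassign each vertex the value of the
# nearest rotated vertex (max inner product on the unit sphere; ties to the
# lowest vertex index); right hemisphere gets the mirrored rotation
.spin_one <- function(full, geometry, hemi_idx, ang) {
  rot <- list(L = .rot_z(ang[3]) %*% .rot_y(ang[2]) %*% .rot_x(ang[1]),
              R = .rot_z(-ang[3]) %*% .rot_y(-ang[2]) %*% .rot_x(ang[1]))
  surr <- rep(NA_real_, length(full))
  for (h in c("L", "R")) {
    idx <- hemi_idx[[h]]
    ch <- geometry$coords[idx, , drop = FALSE]
    crot <- ch %*% t(rot[[h]])
    sim <- tcrossprod(ch, crot)
    src <- idx[max.col(sim, ties.method = "first")]
    surr[idx] <- full[src]   # NA where the medial wall rotated in
  }
  surr
}

# binned empirical variogram over a fixed set of pairs
.vario_binned <- function(x, pi1, pi2, bin) {
  sq <- 0.5 * (x[pi1] - x[pi2])^2
  as.vector(tapply(sq, bin, mean))
}

#' Variogram-matched surrogate maps
#'
#' Generates `K` surrogate maps that preserve the spatial autocorrelation
#' of the observed map, in the style of variogram-matching surrogate
#' generators. Per surrogate: (1) the map values are permuted across
#' locations, destroying the autocorrelation; (2) the permuted map is
#' smoothed with a Gaussian kernel over each candidate width; (3) binned
#' empirical variograms (equal-count distance bins, optionally on a random
#' subsample of locations) of the smoothed-permuted and observed maps are
#' computed; (4) the observed variogram is regressed on the
#' smoothed-permuted one by ordinary least squares; (5) the width
#' minimizing the regression sum of squared errors is kept; (6) the fitted
#' linear transform is applied: the smoothed map is scaled by the square
#' root of the slope and the intercept is injected as white-noise variance.
#'
#' @param assoc [association_map()] or numeric vector over the locations.
#' @param coordinates Numeric matrix of location coordinates (Euclidean
#'   distances), or supply a precomputed distance matrix via
#'   `config$dist`.
#' @param K Number of surrogates.
#' @param seed Integer seed.
#' @param config List of options: `nbins` (default 25 equal-count distance
#'   bins; fewer than 3 is an error), `widths` (candidate Gaussian kernel
#'   widths; default a 5-point geometric grid spanning the 10th-90th
#'   distance percentiles), `nmax` (cap on locations entering the variogram,
#'   default 500), `transform` (set `FALSE` to skip step 6, making each
#'   surrogate a pure permutation when `widths = 0`).
#' @return A [surrogate_map_set()] with mechanism `"variogram"` and an
#'   element `widths` recording the kernel width chosen per surrogate.
#' @export
variogram_surrogates <- function(assoc, coordinates, K, seed = 1L,
                                 config = list()) {
  vals <- if (inherits(assoc, "association_map")) assoc$values else as.numeric(assoc)
  V <- length(vals)
  nbins <- config$nbins %||% 25L
  if (nbins < 3L) stop("at least 3 distance bins are required")
  nmax <- config$nmax %||% 500L
  transform <- config$transform %||% TRUE
  D <- config$dist %||% as.matrix(stats::dist(as.matrix(coordinates)))
  if (!all(dim(D) == c(V, V)))
    stop("distance matrix does not match the number of locations")
  dpos <- D[upper.tri(D)]
  widths <- config$widths %||%
    exp(seq(log(stats::quantile(dpos, 0.10)),
            log(stats::quantile(dpos, 0.90)), length.out = 5L))
  # smoothing operators, row-normalized Gaussian kernels (width 0 = identity)
  smooth_ops <- lapply(widths, function(w) {
    if (w <= 0) return(NULL)
    Wt <- exp(-D^2 / (2 * w^2))
    Wt / rowSums(Wt)
  })
  out <- with_seed(seed, {
    sub <- if (V > nmax) sort(sample.int(V, nmax)) else seq_len(V)
    pr <- which(upper.tri(D[sub, sub, drop = FALSE]), arr.ind = TRUE)
    pi1 <- sub[pr[, 1L]]
    pi2 <- sub[pr[, 2L]]
    pd <- D[cbind(pi1, pi2)]
    breaks <- unique(stats::quantile(pd, probs = seq(0, 1, length.out = nbins + 1L)))
    if (length(breaks) < 4L) stop("at least 3 distance bins are required")
    bin <- cut(pd, breaks, include.lowest = TRUE)
    v_target <- .vario_binned(vals, pi1, pi2, bin)
    keep_bin <- !is.na(v_target)   # equal-count breaks; guard empty bins
    v_target <- v_target[keep_bin]
    maps <- matrix(NA_real_, K, V)
    chosen <- numeric(K)
    for (k in seq_len(K)) {
      xp <- vals[sample.int(V)]
      best <- NULL
      for (j in seq_along(widths)) {
        xs <- if (is.null(smooth_ops[[j]])) xp else as.vector(smooth_ops[[j]] %*% xp)
        v_sm <- .vario_binned(xs, pi1, pi2, bin)[keep_bin]
        fit <- stats::lm.fit(cbind(1, v_sm), v_target)
        sse <- sum(fit$residuals^2)
        if (is.null(best) || sse < best$sse)
          best <- list(sse = sse, xs = xs, coef = fit$coefficients, w = widths[j])
      }
      chosen[k] <- best$w
      maps[k, ] <- if (!transform) best$xs else {
        slope <- max(best$coef[2L], 0)
        icpt <- max(best$coef[1L], 0)
        mean(vals) + sqrt(slope) * (best$xs - mean(best$xs)) +
          sqrt(icpt) * stats::rnorm(V)
      }
    }
    list(maps = maps, chosen = chosen)
  })
  res <- surrogate_map_set(out$maps, "variogram",
                           if (inherits(assoc, "association_map")) assoc$stat_kind else "t")
  res$widths <- out$chosen
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
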