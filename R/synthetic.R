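# Synthetic imaging data with controllable spatial autocorrelation.
#
# Stands in for plasmode resampling of real cortical data: subject-level
# noise fields are white Gaussian noise smoothed with a Gaussian kernel and
# rescaled to a target marginal variance, on either a 2D toroidal grid or a
# two-hemisphere triangulated sphere. Imaging values follow
#   Y_iv = beta0 + 0.05 * x1_i - 0.05 * x2_i + beta3_v * x3_i + noise_iv
# with x1 ~ Bernoulli(0.5) and x2, x3 ~ N(0, 1); the matched analysis
# model is the linear regression of Y_v on [1, x1, x2, x3].

#' Synthetic geometry with contiguous network patches
#'
#' Builds a location layout and a partition into networks of differing
#' size. On the (toroidal) grid, locations are cells with 4-neighbor
#' adjacency; on the sphere, two mirror-image hemispheres of near-uniform
#' vertices with k-nearest-neighbor adjacency and a medial-wall band
#' excluded from analysis. Each requested network is grown as one
#' connected patch from a random seed location; remaining locations are
#' labeled 0 (background, out-of-network for every test).
#'
#' @param layout `"grid"` or `"sphere"`.
#' @param size Grid: edge length (square) or `c(nr, nc)`. Sphere: total
#'   vertex count across both hemispheres (rounded up to even).
#' @param network_sizes Integer vector of patch sizes; labels are
#'   `1, 2, ...` in the given order. Their sum must be below the number of
#'   analyzable locations.
#' @param seed Integer seed for patch placement.
#' @param knn Sphere only: neighbors per vertex for adjacency (default 6).
#' @param medial_frac Sphere only: vertices with |x| below this are the
#'   medial wall (default 0.12).
#' @return Object of class `synthetic_geometry`: `layout`, `coords`,
#'   `labels` (per location, 0 = background), `analyzable` (logical),
#'   `neighbors` (adjacency list), and for spheres a [sphere_geometry()].
#' @export
make_geometry <- function(layout = c("grid", "sphere"), size, network_sizes,
                          seed = 1L, knn = 6L, medial_frac = 0.12) {
  layout <- match.arg(layout)
  if (layout == "grid") {
    dims <- as.integer(if (length(size) == 1L) c(size, size) else size[1:2])
    nr <- dims[1L]; nc <- dims[2L]
    V <- nr * nc
    idx <- seq_len(V)
    row <- (idx - 1L) %% nr + 1L
    col <- (idx - 1L) %/% nr + 1L
    coords <- cbind(row, col)
    wrap <- function(i, n) (i - 1L) %% n + 1L
    at <- function(r, co) (wrap(co, nc) - 1L) * nr + wrap(r, nr)
    neighbors <- lapply(idx, function(i)
      c(at(row[i] - 1L, col[i]), at(row[i] + 1L, col[i]),
        at(row[i], col[i] - 1L), at(row[i], col[i] + 1L)))
    analyzable <- rep(TRUE, V)
    sphere <- NULL
  } else {
    half <- ceiling(size / 2)
    # Fibonacci lattice, folded onto the left hemisphere (x < 0)
    i <- seq_len(half) - 0.5
    phi <- acos(1 - 2 * i / half)
    theta <- pi * (1 + sqrt(5)) * i
    pts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
    pts[, 1L] <- -abs(pts[, 1L])
    coords <- rbind(pts, cbind(-pts[, 1L], pts[, 2:3]))
    hemisphere <- rep(c("L", "R"), each = half)
    medial <- abs(coords[, 1L]) < medial_frac
    V <- nrow(coords)
    analyzable <- !medial
    # kNN adjacency within hemisphere
    neighbors <- vector("list", V)
    for (h in c("L", "R")) {
      hid <- which(hemisphere == h)
      sim <- tcrossprod(coords[hid, , drop = FALSE])
      diag(sim) <- -Inf
      for (j in seq_along(hid)) {
        nb <- hid[order(sim[j, ], decreasing = TRUE)[seq_len(knn)]]
        neighbors[[hid[j]]] <- nb
      }
    }
    sphere <- sphere_geometry(coords, hemisphere, medial)
  }
  n_an <- sum(analyzable)
  if (sum(network_sizes) >= n_an)
    stop("requested network sizes (", sum(network_sizes),
         ") must sum to fewer than the ", n_an, " analyzable locations")
  labels <- rep(0L, V)
  with_seed(seed, {
    for (net in seq_along(network_sizes)) {
      want <- network_sizes[net]
      grown <- FALSE
      for (attempt in 1:25) {
        free <- which(labels == 0L & analyzable)
        start <- free[sample.int(length(free), 1L)]
        patch <- start
        frontier <- setdiff(intersect(neighbors[[start]], free), patch)
        while (length(patch) < want && length(frontier) > 0L) {
          nxt <- frontier[sample.int(length(frontier), 1L)]
          patch <- c(patch, nxt)
          frontier <- setdiff(
            union(frontier, intersect(neighbors[[nxt]],
                                      which(labels == 0L & analyzable))),
            patch)
          frontier <- frontier[!frontier %in% nxt]
        }
        if (length(patch) == want) { labels[patch] <- net; grown <- TRUE; break }
      }
      if (!grown)
        stop("could not grow a contiguous patch of size ", want,
             "; requested sizes infeasible for this layout")
    }
    labels
  }) -> labels
  structure(list(layout = layout, coords = coords, labels = labels,
                 analyzable = analyzable, neighbors = neighbors,
                 dims = if (layout == "grid") c(nr, nc) else NULL,
                 sphere = sphere),
            class = "synthetic_geometry")
}

# noise core: uses the current RNG stream
.noise_core <- function(geometry, N, sigma2, kernel_width) {
  V <- length(geometry$labels)
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (kernel_width < 0) stop("kernel_width must be non-negative")
  if (kernel_width == 0)
    return(matrix(stats::rnorm(N * V, sd = sqrt(sigma2)), N, V))
  if (geometry$layout == "grid") {
    nr <- geometry$dims[1L]; nc <- geometry$dims[2L]
    dr <- pmin(0:(nr - 1L), nr - 0:(nr - 1L))
    dc <- pmin(0:(nc - 1L), nc - 0:(nc - 1L))
    d2 <- outer(dr^2, dc^2, `+`)
    kern <- exp(-d2 / (2 * kernel_width^2))
    kern <- kern / sum(kern)
    scale <- sqrt(sigma2 / sum(kern^2))   # exact stationary variance on the torus
    kf <- stats::fft(kern)
    out <- matrix(0, N, V)
    for (i in seq_len(N)) {
      e <- matrix(stats::rnorm(V), nr, nc)
      sm <- Re(stats::fft(stats::fft(e) * kf, inverse = TRUE)) / V
      out[i, ] <- as.vector(sm) * scale
    }
    out
  } else {
    ang <- acos(pmin(1, pmax(-1, tcrossprod(geometry$coords))))
    Wt <- exp(-ang^2 / (2 * kernel_width^2))
    Wt <- Wt / rowSums(Wt)
    loc_scale <- sqrt(sigma2 / rowSums(Wt^2))
    E <- matrix(stats::rnorm(N * V), V, N)
    t(Wt %*% E) * rep(loc_scale, each = N)
  }
}

#' Spatially autocorrelated Gaussian noise fields
#'
#' Per subject, white Gaussian noise is smoothed with a Gaussian kernel of
#' the given width (grid: circular convolution on the torus via FFT;
#' sphere: kernel weights on great-circle angle) and rescaled so that every
#' location's marginal variance equals `sigma2` exactly in expectation.
#' `kernel_width = 0` gives i.i.d. noise.
#'
#' @param geometry A [make_geometry()] object.
#' @param N Number of subjects (rows).
#' @param sigma2 Marginal variance at every location (> 0).
#' @param kernel_width Gaussian kernel standard deviation, in grid cells
#'   (grid) or radians (sphere).
#' @param seed Integer seed.
#' @return `N x V` matrix of noise values.
#' @export
sample_autocorrelated_noise <- function(geometry, N, sigma2, kernel_width,
                                        seed = 1L) {
  with_seed(seed, .noise_core(geometry, N, sigma2, kernel_width))
}

.beta3_core <- function(config, geometry, network_id) {
  in_net <- geometry$labels == network_id
  V <- length(in_net)
  switch(config,
    null_directional = ifelse(in_net, 0, -0.03),
    null_equal = rep(0.04, V),
    shifted = ifelse(in_net, 0.06, 0.04),
    gamma_variance = ifelse(in_net,
                            stats::rgamma(V, shape = 2, rate = 40),
                            stats::rgamma(V, shape = 20, rate = 400)),
    stop("unknown beta3 config '", config, "'"))
}

#' Per-location true effect field
#'
#' The four effect configurations of the simulation study, as a per-location
#' field for the target predictor's coefficient:
#' \describe{
#'   \item{`null_directional`}{0 in-network, -0.03 out-of-network (null for
#'     a right-sided test: in-network effects are zero, yet they exceed the
#'     out-of-network effects).}
#'   \item{`null_equal`}{0.04 everywhere (null: identical nonzero effects).}
#'   \item{`shifted`}{0.06 in-network, 0.04 out-of-network (alternative).}
#'   \item{`gamma_variance`}{in-network effects drawn Gamma(shape 2, rate
#'     40), out-of-network Gamma(shape 20, rate 400): equal means 0.05 but
#'     tenfold higher in-network variance (alternative).}
#' }
#' Gamma draws are independent across locations and redrawn per call.
#'
#' @param config One of the four configuration names.
#' @param geometry A [make_geometry()] object.
#' @param network_id Label of the in-network region (default 1).
#' @param seed Integer seed (used only by `gamma_variance`).
#' @return Numeric vector of per-location effects.
#' @export
sample_beta3 <- function(config, geometry, network_id = 1L, seed = 1L) {
  with_seed(seed, .beta3_core(config, geometry, network_id))
}

#' Simulation setting
#'
#' Bundles the knobs of one simulated condition. The spatial-autocorrelation
#' level fixes the marginal noise variance, the smoothing kernel width, and
#' the imaging intercept: `"low"` emulates a cortical-thickness-like
#' modality (`sigma2 = 0.09`, `beta0 = 3`, kernel width 1) and `"high"` a
#' task-activation-like modality (`sigma2 = 0.36`, `beta0 = 0`, kernel
#' width 3). Any of the three may be overridden for custom conditions.
#'
#' @param N Number of subjects (>= 10).
#' @param sa_level `"low"` or `"high"`.
#' @param beta3_config Effect configuration; see [sample_beta3()].
#' @param network_id In-network label (default 1).
#' @param sigma2,beta0,kernel_width Optional overrides.
#' @param seed Integer seed for the dataset draw.
#' @return Object of class `simulation_setting`.
#' @export
simulation_setting <- function(N, sa_level = c("low", "high"),
                               beta3_config = "null_equal", network_id = 1L,
                               sigma2 = NULL, beta0 = NULL,
                               kernel_width = NULL, seed = 1L) {
  sa_level <- match.arg(sa_level)
  defaults <- if (sa_level == "low") list(sigma2 = 0.09, beta0 = 3, kw = 1)
              else list(sigma2 = 0.36, beta0 = 0, kw = 3)
  if (N < 10) stop("N must be at least 10")
  structure(list(N = as.integer(N), sa_level = sa_level,
                 beta3_config = beta3_config, network_id = network_id,
                 sigma2 = sigma2 %||% defaults$sigma2,
                 beta0 = beta0 %||% defaults$beta0,
                 kernel_width = kernel_width %||% defaults$kw,
                 seed = as.integer(seed)),
            class = "simulation_setting")
}

#' Simulate a dataset
#'
#' Draws covariates (`x1 ~ Bernoulli(0.5)`, `x2, x3 ~ N(0, 1)`), the true
#' per-location effect field, and the autocorrelated noise, and assembles
#' `Y_iv = beta0 + 0.05 x1 - 0.05 x2 + beta3_v x3 + noise_iv`. The matched
#' analysis design (target `x3`, nuisance `x1`, `x2`) is returned alongside.
#'
#' @param setting A [simulation_setting()].
#' @param geometry A [make_geometry()] object.
#' @return Object of class `synthetic_dataset`: `imaging`
#'   ([imaging_matrix()], medial wall masked out on spheres), `design`
#'   ([phenotype_design()]), `true_beta3` (per location), `setting`.
#' @export
simulate_dataset <- function(setting, geometry) {
  stopifnot(inherits(setting, "simulation_setting"),
            inherits(geometry, "synthetic_geometry"))
  N <- setting$N
  out <- with_seed(setting$seed, {
    x1 <- stats::rbinom(N, 1L, 0.5)
    x2 <- stats::rnorm(N)
    x3 <- stats::rnorm(N)
    beta3 <- .beta3_core(setting$beta3_config, geometry, setting$network_id)
    noise <- .noise_core(geometry, N, setting$sigma2, setting$kernel_width)
    Y <- setting$beta0 + 0.05 * x1 - 0.05 * x2 + outer(x3, beta3) + noise
    list(x1 = x1, x2 = x2, x3 = x3, beta3 = beta3, Y = Y)
  })
  img <- imaging_matrix(out$Y, mask = geometry$analyzable)
  des <- phenotype_design(data.frame(x1 = out$x1, x2 = out$x2, x3 = out$x3),
                          target = "x3", nuisance = c("x1", "x2"))
  structure(list(imaging = img, design = des, true_beta3 = out$beta3,
                 setting = setting),
            class = "synthetic_dataset")
}
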