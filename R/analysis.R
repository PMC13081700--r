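# End-to-end analysis: load aligned inputs, compute one common permutation
# null ensemble, test every requested network, adjust across networks.

#' Analysis configuration
#'
#' Paths and options for a file-based enrichment analysis. Imaging may be a
#' single CSV or a pair of GIFTI metric files (left then right hemisphere);
#' labels and mask are one-integer-per-line text or GIFTI files; sphere
#' coordinates (needed only for the spin method) come from a CSV with
#' columns `x, y, z, hemisphere` or a pair of GIFTI surface files.
#'
#' @param imaging Path(s) to the imaging data.
#' @param phenotype Path to the phenotype CSV.
#' @param labels Path to the network-label file (one label per location).
#' @param target Predictor of interest (column of the phenotype table).
#' @param nuisance Nuisance covariate names.
#' @param mask Optional path to a 0/1 mask file (nonzero = analyzable).
#' @param coords Optional path(s) to sphere coordinates.
#' @param subject_col Subject-ID column name (default `"subject"`).
#' @param strata_col Optional stratification column.
#' @param side `"right"` or `"left"`.
#' @param stat_kind `"t"`, `"pearson_r"`, or `"F"` (no left-sided F).
#' @param K Number of permutations/surrogates (default 1000).
#' @param seed Integer seed.
#' @param gammas Gamma grid (default `seq(0, 0.95, by = 0.05)`).
#' @param networks Integer labels to test; default all nonzero labels.
#' @param method One of `"netdom"`, `"rigea"`, `"nest"`, `"meandiff_perm"`,
#'   `"brainsmash"`, `"spin"`.
#' @param threshold Significance threshold for `"rigea"` (default 1.96).
#' @param output_dir Where [run_analysis()] writes its outputs.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(imaging, phenotype, labels, target,
                            nuisance = character(), mask = NULL,
                            coords = NULL, subject_col = "subject",
                            strata_col = NULL,
                            side = c("right", "left"), stat_kind = "t",
                            K = 1000L, seed = 1L,
                            gammas = seq(0, 0.95, by = 0.05),
                            networks = NULL, method = "netdom",
                            threshold = 1.96, output_dir = ".") {
  side <- match.arg(side)
  if (side == "left" && stat_kind == "F")
    stop("left-sided tests are incompatible with the unsigned F statistic")
  if (!method %in% .study_methods)
    stop("unknown method '", method, "'")
  structure(list(imaging = imaging, phenotype = phenotype, labels = labels,
                 mask = mask, coords = coords, subject_col = subject_col,
                 strata_col = strata_col, target = target,
                 nuisance = nuisance, side = side, stat_kind = stat_kind,
                 K = as.integer(K), seed = as.integer(seed),
                 gammas = gammas, networks = networks, method = method,
                 threshold = threshold, output_dir = output_dir),
            class = "analysis_config")
}

.is_gifti <- function(path) grepl("\\.gii$", path, ignore.case = TRUE)

#' Load and align analysis inputs
#'
#' Reads the imaging matrix, phenotype table, labels, optional mask, and
#' optional sphere coordinates, reconciles subject order by ID join (the
#' phenotype rows are reordered to the imaging row order; unmatched
#' subjects are an error naming the offenders), and applies the mask.
#'
#' @param config An [analysis_config()].
#' @return List with `imaging` ([imaging_matrix()], mask applied),
#'   `design` ([phenotype_design()], subject-aligned), `labels` (per
#'   analyzable location), `sphere` ([sphere_geometry()] or `NULL`),
#'   `coords` (per analyzable location or `NULL`).
#' @export
load_inputs <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  mask <- if (!is.null(config$mask)) {
    if (.is_gifti(config$mask))
      read_gifti_data(config$mask)[[1L]]$values != 0
    else read_mask(config$mask)
  }
  if (all(.is_gifti(config$imaging))) {
    dat <- read_gifti_metric(config$imaging)   # V x subjects
    img_data <- t(as.matrix(dat))
    img <- imaging_matrix(img_data,
                          mask = mask %||% rep(TRUE, ncol(img_data)))
    has_ids <- FALSE
  } else if (grepl("\\.npy$", config$imaging[1L], ignore.case = TRUE)) {
    img_data <- read_npy_matrix(config$imaging[1L])
    img <- imaging_matrix(img_data,
                          mask = mask %||% rep(TRUE, ncol(img_data)))
    has_ids <- FALSE
  } else {
    img <- read_imaging_csv(config$imaging, subject_col = config$subject_col,
                            mask = mask)
    has_ids <- !is.null(rownames(img$data))
  }
  design <- read_phenotype_csv(config$phenotype, config$subject_col,
                               config$target, config$nuisance,
                               config$strata_col)
  if (has_ids) {
    ids_img <- rownames(img$data)
    missing_ph <- setdiff(ids_img, design$subjects)
    missing_im <- setdiff(design$subjects, ids_img)
    if (length(missing_ph) || length(missing_im))
      stop("subject mismatch between imaging and phenotype; ",
           "imaging-only: [", paste(missing_ph, collapse = ", "),
           "], phenotype-only: [", paste(missing_im, collapse = ", "), "]")
    ord <- match(ids_img, design$subjects)
    design$values <- design$values[ord, , drop = FALSE]
    design$subjects <- design$subjects[ord]
    if (!is.null(design$strata)) design$strata <- design$strata[ord]
  } else if (nrow(img$data) != nrow(design$values)) {
    stop("imaging has ", nrow(img$data), " subjects but phenotype has ",
         nrow(design$values), " and no IDs are available to join on")
  }
  labels <- if (.is_gifti(config$labels))
    as.integer(read_gifti_data(config$labels)[[1L]]$values)
  else read_labels(config$labels)
  if (length(labels) != length(img$mask))
    stop("label file covers ", length(labels), " locations but imaging has ",
         length(img$mask))
  sphere <- NULL
  coords_an <- NULL
  if (!is.null(config$coords)) {
    if (all(.is_gifti(config$coords))) {
      parts <- lapply(config$coords, read_gifti_surface)
      coords <- do.call(rbind, parts)
      hemi <- rep(c("L", "R")[seq_along(parts)],
                  vapply(parts, nrow, integer(1)))
    } else {
      cdf <- utils::read.csv(config$coords)
      coords <- as.matrix(cdf[, c("x", "y", "z")])
      hemi <- if ("hemisphere" %in% names(cdf)) as.character(cdf$hemisphere)
    }
    if (!is.null(hemi) && all(c("L", "R") %in% hemi))
      sphere <- sphere_geometry(coords, hemi, medial_wall = !img$mask)
    coords_an <- coords[img$mask, , drop = FALSE]
  }
  list(imaging = img, design = design, labels = labels[img$mask],
       sphere = sphere, coords = coords_an)
}

#' Test several networks against one null ensemble
#'
#' Runs the selected enrichment test once per requested network. For
#' permutation-based methods the null maps are computed once and reused
#' across networks, so the across-network FDR adjustment rests on a common
#' null ensemble. Networks with fewer than two valid in-network locations
#' are skipped with a warning.
#'
#' @param imaging An [imaging_matrix()].
#' @param design A [phenotype_design()].
#' @param labels Integer network label per analyzable location.
#' @param networks Labels to test (default all nonzero labels).
#' @param method,side,stat_kind,K,seed,gammas,threshold See
#'   [analysis_config()].
#' @param sphere Optional [sphere_geometry()] (spin method).
#' @param coords Optional coordinates per analyzable location (brainsmash
#'   method).
#' @param vario_config Variogram surrogate options.
#' @return Data frame with one row per tested network (columns
#'   `network_id, method, side, m, n, mean_in, mean_out, gamma_selected,
#'   p_diff, p_zero, p, p_fdr, K, seed`) with per-network diagnostics in
#'   `attr(, "diagnostics")`.
#' @export
analyze_networks <- function(imaging, design, labels, networks = NULL,
                             method = "netdom", side = "right",
                             stat_kind = "t", K = 1000L, seed = 1L,
                             gammas = seq(0, 0.95, by = 0.05),
                             sphere = NULL, coords = NULL,
                             threshold = 1.96, vario_config = list()) {
  labels <- as.integer(labels)
  Va <- sum(imaging$mask)
  if (length(labels) != Va)
    stop("need one label per analyzable location (", Va, ")")
  if (is.null(networks)) networks <- sort(setdiff(unique(labels), 0L))
  grid <- gamma_grid(gammas)
  obs <- fit_association_map(imaging, design, stat_kind)
  scheme <- if (is.null(design$strata)) "freedman_lane" else "stratified"
  nulls <- NULL
  if (method %in% c("netdom", "nest", "meandiff_perm")) {
    plan <- permutation_plan(nrow(design$values), K, scheme,
                             seed = seed, strata = design$strata)
    nulls <- null_association_maps(imaging, design, plan, stat_kind)
  } else if (method == "spin") {
    if (is.null(sphere)) stop("the spin method requires sphere coordinates")
    nulls <- spin_surrogates(obs, sphere, K, seed = seed)
  } else if (method == "brainsmash") {
    if (is.null(coords)) stop("the brainsmash method requires coordinates")
    nulls <- variogram_surrogates(obs, coords, K, seed = seed,
                                  config = vario_config)
  }
  rows <- list()
  diagnostics <- list()
  for (net in networks) {
    m <- sum(labels == net)
    if (m < 2L || Va - m < 2L) {
      warning("network ", net, " has m = ", m, "; skipped")
      next
    }
    part <- network_partition(labels, net)
    tin <- obs$values[part$in_idx]
    tout <- obs$values[-part$in_idx]
    row <- data.frame(network_id = net, method = method, side = side,
                      m = sum(!is.na(tin)), n = sum(!is.na(tout)),
                      mean_in = mean(tin, na.rm = TRUE),
                      mean_out = mean(tout, na.rm = TRUE),
                      gamma_selected = NA_real_, p_diff = NA_real_,
                      p_zero = NA_real_, p = NA_real_, K = K, seed = seed)
    if (method == "netdom") {
      res <- suppressWarnings(
        netdom_from_maps(obs, nulls, part, grid = grid, side = side,
                         seed = seed))
      row$gamma_selected <- res$gamma_selected
      row$p_diff <- res$p_diff
      row$p_zero <- res$p_zero
      row$p <- res$p
      diagnostics[[as.character(net)]] <-
        list(gammas = res$gammas, D_obs = res$D_obs, p_gamma = res$p_gamma,
             q_obs = res$q_obs, gamma_selected = res$gamma_selected,
             p_diff = res$p_diff, p_zero = res$p_zero, p = res$p)
    } else {
      row$p <- switch(method,
        rigea = rigea_test(obs, part, side, threshold),
        nest = as.numeric(weighted_ks_enrichment(obs, part, nulls, side)),
        as.numeric(suppressWarnings(surrogate_test(obs, part, nulls, side))))
      diagnostics[[as.character(net)]] <- list(p = row$p)
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) stop("no testable networks")
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p)
  out <- out[, c("network_id", "method", "side", "m", "n", "mean_in",
                 "mean_out", "gamma_selected", "p_diff", "p_zero", "p",
                 "p_fdr", "K", "seed")]
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Run a file-based enrichment analysis
#'
#' Loads the configured inputs, tests every requested network with a
#' common permutation null ensemble, adjusts across networks by
#' Benjamini-Hochberg, and writes `results.tsv`, `diagnostics.json`, and
#' `netdom.log` (seed, K, gamma grid, versions) to the output directory.
#' Outputs are byte-for-byte reproducible given the same configuration and
#' seed.
#'
#' @param config An [analysis_config()].
#' @return The results data frame, invisibly.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  inputs <- load_inputs(config)
  res <- analyze_networks(inputs$imaging, inputs$design, inputs$labels,
                          networks = config$networks, method = config$method,
                          side = config$side, stat_kind = config$stat_kind,
                          K = config$K, seed = config$seed,
                          gammas = config$gammas, sphere = inputs$sphere,
                          coords = inputs$coords,
                          threshold = config$threshold)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_results_tsv(res, file.path(config$output_dir, "results.tsv"))
  jsonlite::write_json(
    list(seed = config$seed, K = config$K, gammas = config$gammas,
         method = config$method, side = config$side,
         stat_kind = config$stat_kind,
         networks = attr(res, "diagnostics")),
    file.path(config$output_dir, "diagnostics.json"),
    auto_unbox = TRUE, digits = NA)
  writeLines(c(paste0("netdom ", as.character(utils::packageVersion("netdom"))),
               paste0("R ", R.version$major, ".", R.version$minor),
               paste0("seed: ", config$seed),
               paste0("K: ", config$K),
               paste0("gamma grid: ", paste(config$gammas, collapse = " ")),
               paste0("method: ", config$method),
               paste0("side: ", config$side),
               paste0("stat: ", config$stat_kind)),
             file.path(config$output_dir, "netdom.log"))
  invisible(res)
}

#' Run a simulation grid
#'
#' Expands a study configuration (as read from YAML/JSON) into the product
#' of methods, effect configurations, spatial-autocorrelation levels,
#' sample sizes, and networks, runs [run_rejection_study()] for each cell,
#' and returns a tidy data frame (one row per condition).
#'
#' @param spec List with components `geometry` (arguments to
#'   [make_geometry()]) and `grid` (`methods`, `beta3_configs`,
#'   `sa_levels`, `sample_sizes`, `networks`, `reps`, `K`, `alpha`, `side`,
#'   `seed`). Note the key is `sample_sizes`, not `N`: a bare `N` is parsed
#'   as a boolean by YAML 1.1 readers (`N` is still accepted from JSON).
#' @return Data frame of rejection rates.
#' @export
run_simulation_grid <- function(spec) {
  g <- spec$geometry
  geom <- make_geometry(layout = g$layout %||% "grid", size = g$size,
                        network_sizes = unlist(g$network_sizes),
                        seed = g$seed %||% 1L)
  gr <- spec$grid
  sizes <- unlist(gr$sample_sizes %||% gr$N)
  if (is.null(sizes)) stop("the study grid needs 'sample_sizes'")
  cells <- expand.grid(method = unlist(gr$methods),
                       beta3_config = unlist(gr$beta3_configs),
                       sa_level = unlist(gr$sa_levels %||% "low"),
                       N = sizes,
                       network = unlist(gr$networks %||% 1L),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    st <- simulation_setting(cell$N, cell$sa_level, cell$beta3_config,
                             network_id = cell$network)
    study <- run_rejection_study(cell$method, st, geom, cell$network,
                                 reps = gr$reps %||% 100L,
                                 K = gr$K %||% 100L,
                                 alpha = gr$alpha %||% 0.05,
                                 side = gr$side %||% "right",
                                 seed = gr$seed %||% 1L)
    data.frame(cell, reps = study$reps, K = study$K, alpha = study$alpha,
               rate = study$rate, se = study$se)
  })
  do.call(rbind, rows)
}
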