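#' Imaging data matrix
#'
#' Container for a subjects-by-locations matrix of imaging measurements
#' (e.g., vertexwise cortical thickness or task activation), together with
#' location identifiers and an analyzability mask. Masked-out locations
#' (such as the medial wall on surface meshes) carry no statistics
#' downstream: they are excluded before any model fitting.
#'
#' @param data Numeric matrix, one row per subject, one column per location.
#' @param location_ids Optional character/integer vector of location
#'   identifiers; defaults to column names or `1:V`.
#' @param mask Optional logical vector of length `ncol(data)`; `TRUE` marks
#'   a location as analyzable. Defaults to all `TRUE`.
#' @return An object of class `imaging_matrix` with elements `data`,
#'   `location_ids`, `mask`.
#' @export
imaging_matrix <- function(data, location_ids = NULL, mask = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("imaging data must be numeric")
  if (anyNA(data)) stop("imaging data contains missing values")
  V <- ncol(data)
  if (is.null(location_ids)) {
    location_ids <- if (!is.null(colnames(data))) colnames(data) else seq_len(V)
  }
  if (length(location_ids) != V) stop("location_ids length must equal ncol(data)")
  if (is.null(mask)) mask <- rep(TRUE, V)
  mask <- as.logical(mask)
  if (length(mask) != V || anyNA(mask)) stop("mask must be logical of length ncol(data)")
  structure(list(data = data, location_ids = location_ids, mask = mask),
            class = "imaging_matrix")
}

#' Phenotype and covariate design
#'
#' Holds the subject-level phenotype table, naming the predictor of interest
#' (the "target", e.g. a cognitive score) and the nuisance covariates. An
#' intercept is implicit in every fitted model. Optional strata labels
#' support stratified permutation when observations are exchangeable only
#' within groups (e.g., family membership).
#'
#' @param values Data frame or matrix of covariates, one row per subject.
#' @param target Name of the predictor of interest (must be a column of
#'   `values`).
#' @param nuisance Character vector of nuisance covariate names (default
#'   none; the intercept is always included and never listed here).
#' @param subjects Optional subject identifiers; defaults to row names or
#'   `1:N`.
#' @param strata Optional grouping labels (length `N`) for stratified
#'   permutation.
#' @return An object of class `phenotype_design`.
#' @export
phenotype_design <- function(values, target, nuisance = character(),
                             subjects = NULL, strata = NULL) {
  values <- as.data.frame(values)
  if (anyNA(values[, c(target, nuisance), drop = FALSE]))
    stop("phenotype values contain missing entries")
  if (!target %in% names(values)) stop("target '", target, "' not found")
  if (!all(nuisance %in% names(values)))
    stop("nuisance column(s) not found: ",
         paste(setdiff(nuisance, names(values)), collapse = ", "))
  if (target %in% nuisance) stop("target must not appear among nuisance covariates")
  N <- nrow(values)
  if (is.null(subjects)) {
    subjects <- if (!is.null(rownames(values)) &&
                    !identical(rownames(values), as.character(seq_len(N))))
      rownames(values) else as.character(seq_len(N))
  }
  if (length(subjects) != N) stop("subjects length must equal nrow(values)")
  if (!is.null(strata)) {
    if (length(strata) != N) stop("strata length must equal nrow(values)")
    strata <- as.factor(strata)
  }
  des <- structure(list(values = values, target = target, nuisance = nuisance,
                        subjects = as.character(subjects), strata = strata),
                   class = "phenotype_design")
  X <- design_matrix(des)
  if (qr(X)$rank < ncol(X)) {
    # name the offending columns for the user
    drop <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  des
}

# full design matrix: intercept + nuisance + target (target last)
design_matrix <- function(design) {
  vals <- design$values
  X <- cbind(`(Intercept)` = 1,
             as.matrix(vals[, design$nuisance, drop = FALSE]),
             as.matrix(vals[, design$target, drop = FALSE]))
  colnames(X) <- c("(Intercept)", design$nuisance, design$target)
  storage.mode(X) <- "double"
  X
}

#' Per-location association map
#'
#' One association statistic per analyzable location: the observed map
#' `T_obs(v)` or one permutation null map `T^(k)(v)`. Degenerate locations
#' (zero residual variance) are recorded as invalid rather than assigned a
#' value.
#'
#' @param values Numeric vector of statistics (NA at invalid locations).
#' @param stat_kind One of `"t"`, `"pearson_r"`, `"F"`.
#' @param origin `"observed"` or the permutation index `k`.
#' @param valid Logical vector marking valid locations.
#' @return An object of class `association_map`.
#' @export
association_map <- function(values, stat_kind = c("t", "pearson_r", "F"),
                            origin = "observed", valid = NULL) {
  stat_kind <- match.arg(stat_kind)
  values <- as.numeric(values)
  if (is.null(valid)) valid <- !is.na(values)
  signed <- stat_kind != "F"
  if (!signed && any(values[valid] < 0))
    stop("unsigned association map contains negative values")
  structure(list(values = values, stat_kind = stat_kind, signed = signed,
                 origin = origin, valid = as.logical(valid)),
            class = "association_map")
}

#' Permutation plan
#'
#' Pre-generates `K` row-orderings of the subjects. The same permutation is
#' applied at every location within one `k`, which preserves the spatial
#' autocorrelation of the image. Under the stratified scheme subjects move
#' only within strata.
#'
#' @param n_subjects Number of subjects.
#' @param K Number of permutations.
#' @param scheme `"freedman_lane"`, `"simple"`, or `"stratified"`.
#' @param seed Integer seed; the plan is fully reproducible from it.
#' @param strata Required for the stratified scheme: one label per subject.
#' @return An object of class `permutation_plan` with a `K x n_subjects`
#'   integer matrix `permutations`, each row a bijection of `1:n_subjects`.
#' @export
permutation_plan <- function(n_subjects, K,
                             scheme = c("freedman_lane", "simple", "stratified"),
                             seed = 1L, strata = NULL) {
  scheme <- match.arg(scheme)
  K <- as.integer(K)
  if (is.na(K) || K < 1) stop("K must be a positive integer")
  N <- as.integer(n_subjects)
  if (scheme == "stratified") {
    if (is.null(strata)) stop("stratified scheme requires strata labels")
    strata <- as.factor(strata)
    if (length(strata) != N) stop("strata length must equal n_subjects")
    sizes <- table(strata)
    if (any(sizes == 1L))
      warning("stratum/strata of size 1: ",
              paste(names(sizes)[sizes == 1L], collapse = ", "),
              " (those subjects are fixed under permutation)")
  }
  perms <- matrix(0L, K, N)
  with_seed(seed, {
    for (k in seq_len(K)) {
      if (scheme == "stratified") {
        p <- seq_len(N)
        for (lev in levels(strata)) {
          idx <- which(strata == lev)
          if (length(idx) > 1L) p[idx] <- idx[sample.int(length(idx))]
        }
        perms[k, ] <- p
      } else {
        perms[k, ] <- sample.int(N)
      }
    }
  })
  structure(list(K = K, scheme = scheme, seed = as.integer(seed),
                 strata = if (scheme == "stratified") strata else NULL,
                 n_subjects = N, permutations = perms),
            class = "permutation_plan")
}

#' Network partition
#'
#' Splits the analyzable locations into the network of interest `N` (size
#' `m`) and its complement (size `n`), given an integer label per location.
#'
#' @param labels Integer vector, one network label per analyzable location.
#' @param network_id The label defining the network of interest.
#' @return An object of class `network_partition` with elements `labels`,
#'   `network_id`, `in_idx`, `m`, `n`, `V`.
#' @export
network_partition <- function(labels, network_id) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels contain missing values")
  in_idx <- which(labels == network_id)
  m <- length(in_idx)
  V <- length(labels)
  n <- V - m
  if (m < 2L || n < 2L)
    stop("network partition requires m >= 2 and n >= 2 (got m = ", m,
         ", n = ", n, ")")
  structure(list(labels = labels, network_id = network_id, in_idx = in_idx,
                 m = m, n = n, V = V),
            class = "network_partition")
}

#' Set of surrogate (null) association maps
#'
#' `K` null maps from any null-generating mechanism: phenotype permutation,
#' spherical rotation ("spin"), or variogram-matched surrogates. Spin
#' surrogates may invalidate locations (medial wall rotated into cortex);
#' per-map validity is carried alongside.
#'
#' @param maps Numeric `K x V` matrix of null statistics (NA where invalid).
#' @param mechanism One of `"phenotype_permutation"`, `"spin"`, `"variogram"`.
#' @param stat_kind Statistic kind shared with the observed map.
#' @return An object of class `surrogate_map_set`.
#' @export
surrogate_map_set <- function(maps,
                              mechanism = c("phenotype_permutation", "spin",
                                            "variogram"),
                              stat_kind = "t") {
  mechanism <- match.arg(mechanism)
  maps <- as.matrix(maps)
  if (nrow(maps) < 1L) stop("surrogate map set requires K >= 1")
  structure(list(maps = maps, mechanism = mechanism, stat_kind = stat_kind,
                 K = nrow(maps)),
            class = "surrogate_map_set")
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
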