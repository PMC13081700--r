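# File readers and writers. Imaging matrices travel as CSV (subjects x
# locations, optional subject-ID column) or paired GIFTI metric files;
# labels and masks as one-integer-per-line text or GIFTI label files;
# sphere coordinates as CSV (x, y, z, optional hemisphere) or GIFTI
# surface files. Locations are kept in file order; for GIFTI pairs the
# order is left hemisphere then right.

#' Read an imaging matrix from CSV
#'
#' One row per subject, one column per location; an optional subject-ID
#' column is moved to row names.
#'
#' @param path CSV file path.
#' @param subject_col Name of the subject-ID column, or `NULL` if absent.
#' @param mask Optional logical mask applied to the locations.
#' @return An [imaging_matrix()].
#' @export
read_imaging_csv <- function(path, subject_col = NULL, mask = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  subjects <- NULL
  if (!is.null(subject_col)) {
    if (!subject_col %in% names(df))
      stop("subject column '", subject_col, "' not found in ", path)
    subjects <- as.character(df[[subject_col]])
    df <- df[, setdiff(names(df), subject_col), drop = FALSE]
  }
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric imaging values in column(s): ",
         paste(utils::head(names(df)[bad], 5L), collapse = ", "))
  mat <- as.matrix(df)
  if (!is.null(subjects)) rownames(mat) <- subjects
  imaging_matrix(mat, location_ids = colnames(mat), mask = mask)
}

#' Write an imaging matrix to CSV
#'
#' @param imaging An [imaging_matrix()].
#' @param path Output path.
#' @param subject_col Column name for subject IDs (default `"subject"`).
#' @export
write_imaging_csv <- function(imaging, path, subject_col = "subject") {
  df <- as.data.frame(imaging$data)
  colnames(df) <- imaging$location_ids
  subj <- rownames(imaging$data)
  if (is.null(subj)) subj <- as.character(seq_len(nrow(df)))
  df <- cbind(stats::setNames(data.frame(subj), subject_col), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table from CSV
#'
#' @param path CSV with a header row, one subject per row.
#' @param subject_col Name of the subject-ID column.
#' @param target,nuisance Covariate names; see [phenotype_design()].
#' @param strata_col Optional stratification column.
#' @return A [phenotype_design()].
#' @export
read_phenotype_csv <- function(path, subject_col, target,
                               nuisance = character(), strata_col = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!subject_col %in% names(df))
    stop("subject column '", subject_col, "' not found in ", path)
  phenotype_design(df, target = target, nuisance = nuisance,
                   subjects = as.character(df[[subject_col]]),
                   strata = if (!is.null(strata_col)) df[[strata_col]])
}

#' Read integer labels (one per line)
#'
#' @param path Text file with one integer per location, in location order.
#' @return Integer vector.
#' @export
read_labels <- function(path) {
  as.integer(scan(path, what = integer(), quiet = TRUE))
}

#' Read a 0/1 mask (one per line)
#'
#' @param path Text file; nonzero = analyzable.
#' @return Logical vector.
#' @export
read_mask <- function(path) {
  scan(path, what = integer(), quiet = TRUE) != 0L
}

#' Read a 2D matrix from an NPY file
#'
#' Minimal reader for the NPY binary format, version 1.0/2.0, little-endian
#' float64/float32/int32/int64 arrays of one or two dimensions. Fortran
#' order is honored.
#'
#' @param path .npy file.
#' @param subjects Optional subject IDs to attach as row names.
#' @return Numeric matrix (a 1-D array becomes a 1-row matrix). 64-bit
#'   integer arrays are not supported (R has no native int64).
#' @export
read_npy_matrix <- function(path, subjects = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop(path, " is not an NPY file")
  ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  hlen <- if (ver[1L] >= 2L) readBin(con, "integer", 1L, size = 4L,
                                     endian = "little")
          else readBin(con, "integer", 1L, size = 2L, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("[[:space:]]", "", shape_s), ",")[[1L]])
  if (length(shape) > 2L) stop("only 1-D and 2-D NPY arrays are supported")
  n <- prod(shape)
  endian <- if (startsWith(descr, ">")) "big" else "little"
  vals <- switch(substring(descr, 2L),
                 f8 = readBin(con, "double", n, size = 8L, endian = endian),
                 f4 = readBin(con, "double", n, size = 4L, endian = endian),
                 i4 = readBin(con, "integer", n, size = 4L, endian = endian),
                 stop("unsupported NPY dtype '", descr, "'"))
  out <- if (length(shape) == 1L) matrix(vals, nrow = 1L)
         else if (fortran) matrix(vals, shape[1L], shape[2L])
         else matrix(vals, shape[1L], shape[2L], byrow = TRUE)
  if (!is.null(subjects)) rownames(out) <- subjects
  out
}

# ---- minimal GIFTI (XML) support ---------------------------------------

.gifti_read_array <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  dims <- as.integer(xml2::xml_attrs(node)[grepl("^Dim[0-9]+$",
                                                 names(xml2::xml_attrs(node)))])
  ntot <- prod(dims)
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(data_node)
  vals <- if (identical(enc, "ASCII")) {
    as.numeric(strsplit(trimws(txt), "[[:space:]]+")[[1L]])
  } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
    raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
    if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
    endian <- if (identical(xml2::xml_attr(node, "Endian"), "BigEndian"))
      "big" else "little"
    switch(dtype,
           NIFTI_TYPE_FLOAT32 = readBin(raw, "double", ntot, size = 4L,
                                        endian = endian),
           NIFTI_TYPE_FLOAT64 = readBin(raw, "double", ntot, size = 8L,
                                        endian = endian),
           NIFTI_TYPE_INT32 = readBin(raw, "integer", ntot, size = 4L,
                                      endian = endian),
           stop("unsupported GIFTI data type '", dtype, "'"))
  } else {
    stop("unsupported GIFTI encoding '", enc, "'")
  }
  if (length(vals) != ntot)
    stop("GIFTI data array length ", length(vals), " does not match dims ",
         paste(dims, collapse = "x"))
  list(values = vals, dims = dims,
       intent = xml2::xml_attr(node, "Intent"))
}

#' Read the data arrays of a GIFTI file
#'
#' Minimal GIFTI reader covering ASCII, Base64Binary, and GZipBase64Binary
#' encodings of float32/float64/int32 arrays (metric, label, and surface
#' files). External binary files are not supported.
#'
#' @param path GIFTI (.gii) file.
#' @return List of arrays, each with `values`, `dims`, `intent`.
#' @export
read_gifti_data <- function(path) {
  doc <- xml2::xml_ns_strip(xml2::read_xml(path))
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) == 0L) stop("no DataArray elements in ", path)
  lapply(arrays, .gifti_read_array)
}

#' Read a pair of GIFTI metric files
#'
#' Concatenates per-vertex values in file order (conventionally left then
#' right hemisphere). Every data array in each file contributes one column;
#' with a single array per file the result is a vector.
#'
#' @param paths Character vector of .gii paths, in hemisphere order.
#' @return Numeric vector (single array per file) or matrix.
#' @export
read_gifti_metric <- function(paths) {
  per_file <- lapply(paths, function(p) {
    arr <- read_gifti_data(p)
    do.call(cbind, lapply(arr, `[[`, "values"))
  })
  out <- do.call(rbind, per_file)
  if (ncol(out) == 1L) as.vector(out) else out
}

#' Read a GIFTI surface's vertex coordinates
#'
#' @param path Surface .gii containing a POINTSET data array.
#' @return `V x 3` coordinate matrix.
#' @export
read_gifti_surface <- function(path) {
  arr <- read_gifti_data(path)
  ps <- Filter(function(a) identical(a$intent, "NIFTI_INTENT_POINTSET") ||
                 (length(a$dims) == 2L && a$dims[2L] == 3L), arr)
  if (length(ps) == 0L) stop("no pointset array found in ", path)
  matrix(ps[[1L]]$values, ncol = 3L, byrow = TRUE)
}

#' Write per-vertex values as an ASCII GIFTI metric file
#'
#' @param values Numeric vector (or matrix, one array per column).
#' @param path Output .gii path.
#' @param intent NIFTI intent string (default `"NIFTI_INTENT_NONE"`).
#' @export
write_gifti_metric <- function(values, path, intent = "NIFTI_INTENT_NONE") {
  values <- as.matrix(values)
  arrays <- vapply(seq_len(ncol(values)), function(j) {
    paste0('  <DataArray Intent="', intent,
           '" DataType="NIFTI_TYPE_FLOAT32" ArrayIndexingOrder="RowMajorOrder"',
           ' Dimensionality="1" Dim0="', nrow(values),
           '" Encoding="ASCII" Endian="LittleEndian">\n   <Data>',
           paste(format(values[, j], digits = 9, trim = TRUE,
                        scientific = FALSE),
                 collapse = " "),
           "</Data>\n  </DataArray>")
  }, character(1))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               paste0('<GIFTI Version="1.0" NumberOfDataArrays="',
                      ncol(values), '">'),
               arrays, "</GIFTI>"), path)
  invisible(path)
}

# 6 significant digits for all floating-point output
.fmt6 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) signif(x, 6L) else x
}

#' Write an enrichment results table as TSV
#'
#' Columns: `network_id, side, m, n, mean_in, mean_out, gamma_selected,
#' p_diff, p_zero, p, p_fdr, K, seed` (plus `method` when present).
#' Floating-point values are printed at 6 significant digits; permutation
#' p-values are bounded away from zero by construction.
#'
#' @param results Data frame as produced by [run_analysis()].
#' @param path Output TSV path.
#' @export
write_results_tsv <- function(results, path) {
  out <- as.data.frame(lapply(results, .fmt6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
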