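# The Scan container: a 4-D intensity grid plus the acquisition metadata the
# pipeline needs (TR, voxel size, subject/session identity).

#' Construct a Scan
#'
#' @param data 4-D numeric array (x, y, z, volume), all values finite.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id subject identifier string.
#' @param session `"baseline"` or `"followup"`.
#' @param voxel_size_mm numeric length-3 voxel size in mm.
#' @return an object of class `icn_scan`.
#' @export
new_scan <- function(data, tr_seconds = 2, subject_id = "S000",
                     session = c("baseline", "followup"),
                     voxel_size_mm = c(3, 3, 3)) {
  session <- match.arg(session)
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("scan data must be a 4-D array (x, y, z, volume)", call. = FALSE)
  if (any(!is.finite(data)))
    stop("scan data must be finite everywhere", call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("`tr_seconds` must be a positive scalar", call. = FALSE)
  structure(
    list(data = data, tr_seconds = as.numeric(tr_seconds),
         subject_id = as.character(subject_id), session = session,
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "icn_scan")
}

#' @export
print.icn_scan <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<icn_scan> %s [%s]  grid %dx%dx%d, %d volumes, TR %.3g s, voxel %s mm\n",
              x$subject_id, x$session, d[1], d[2], d[3], d[4], x$tr_seconds,
              paste(signif(x$voxel_size_mm, 3), collapse = "x")))
  invisible(x)
}

#' @export
dim.icn_scan <- function(x) dim(x$data)

n_volumes <- function(scan) dim(scan$data)[4L]

# Flatten a scan to a voxel x volume matrix (the layout most stages use).
scan_matrix <- function(scan) {
  d <- dim(scan$data)
  matrix(scan$data, nrow = prod(d[1:3]), ncol = d[4])
}

# Rebuild a Scan from a voxel x volume matrix, reusing metadata from `like`.
matrix_to_scan <- function(m, like) {
  d <- dim(like$data)
  stopifnot(nrow(m) == prod(d[1:3]))
  out <- like
  out$data <- array(m, dim = c(d[1:3], ncol(m)))
  out
}

#' Read a 4-D scan from a NIfTI-1 file
#'
#' @param path path to an uncompressed `.nii` file with a 4-D grid.
#' @param subject_id,session identity metadata to attach (NIfTI carries
#'   neither); defaults parse nothing from the filename.
#' @return an [new_scan()] object.
#' @export
read_scan <- function(path, subject_id = NULL, session = "baseline") {
  nii <- read_nifti(path)
  if (length(nii$dim) != 4L)
    stop(sprintf("dimension error in %s: expected a 4-D scan, got %d-D",
                 path, length(nii$dim)), call. = FALSE)
  tr <- nii$tr_seconds
  if (!is.finite(tr) || tr <= 0) tr <- 2
  if (is.null(subject_id))
    subject_id <- sub("\\.nii$", "", basename(path))
  new_scan(nii$data, tr_seconds = tr, subject_id = subject_id,
           session = session, voxel_size_mm = nii$voxel_size_mm)
}

#' Write a scan to a NIfTI-1 file
#'
#' Defaults to float64 so the round-trip through [read_scan()] is lossless;
#' pass `datatype = "float32"` for half-size files at ~1e-5 relative
#' precision.
#'
#' @param scan an `icn_scan`.
#' @param path output path.
#' @param datatype `"float64"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, datatype = "float64") {
  stopifnot(inherits(scan, "icn_scan"))
  write_nifti(scan$data, path, voxel_size_mm = scan$voxel_size_mm,
              tr_seconds = scan$tr_seconds, datatype = datatype)
}

.pheno_columns <- c("subject_id", "group", "arm", "session", "age", "sex",
                    "education_years", "illness_years",
                    "panss_total", "panss_pos", "panss_neg", "panss_gen")

#' Read a phenotype table
#'
#' Validates the schema used throughout the pipeline: one row per subject per
#' session with group (`patient`/`control`), treatment arm (`ECT`/`MED`/
#' `none`) and PANSS scores.  Controls and baseline-only patients carry
#' `arm = "none"`; PANSS columns are `NA` for controls.
#'
#' @param path CSV file path.
#' @return a `data.frame` of typed subject records, with an attribute
#'   `validation` listing per-column missing-value counts.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.pheno_columns, names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("phenotype schema error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  bad_group <- which(!df$group %in% c("patient", "control"))
  if (length(bad_group) > 0L)
    stop(sprintf("phenotype schema error: invalid group value(s) '%s' in row(s) %s",
                 paste(unique(df$group[bad_group]), collapse = "', '"),
                 paste(bad_group, collapse = ", ")), call. = FALSE)
  bad_arm <- which(!df$arm %in% c("ECT", "MED", "none"))
  if (length(bad_arm) > 0L)
    stop(sprintf("phenotype schema error: invalid arm value(s) '%s' in row(s) %s",
                 paste(unique(df$arm[bad_arm]), collapse = "', '"),
                 paste(bad_arm, collapse = ", ")), call. = FALSE)
  bad_sess <- which(!df$session %in% c("baseline", "followup"))
  if (length(bad_sess) > 0L)
    stop(sprintf("phenotype schema error: invalid session value(s) in row(s) %s",
                 paste(bad_sess, collapse = ", ")), call. = FALSE)
  key <- paste(df$subject_id, df$session, sep = ":")
  if (anyDuplicated(key))
    stop(sprintf("phenotype uniqueness error: duplicated subject_id+session: %s",
                 paste(unique(key[duplicated(key)]), collapse = ", ")), call. = FALSE)
  for (col in c("age", "education_years", "illness_years",
                "panss_total", "panss_pos", "panss_neg", "panss_gen"))
    df[[col]] <- as.numeric(df[[col]])
  attr(df, "validation") <- vapply(df, function(x) sum(is.na(x)), integer(1))
  df
}
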