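#' Write an image series or 3-D map to NIfTI with a YAML sidecar
#'
#' The array goes to `<path>.nii.gz`; the acquisition schedule and any
#' extra metadata go to `<path>.yaml`.
#'
#' @param x An [image_series()], [parametric_map()] or bare array.
#' @param path Output path without extension.
#' @param extra Named list merged into the sidecar.
#' @return Invisibly, the NIfTI path.
#' @export
write_nifti_sidecar <- function(x, path, extra = list()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "image_series")) {
    arr <- x$data
    meta <- c(list(modality = x$modality,
                   pixel_spacing = x$pixel_spacing,
                   slice_thickness = x$slice_thickness,
                   schedule = x$schedule[!vapply(x$schedule, is.null, TRUE)]),
              extra)
  } else if (inherits(x, "parametric_map")) {
    arr <- x$values
    meta <- c(list(parameter = x$parameter, units = x$units), extra)
  } else {
    arr <- x
    meta <- extra
  }
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(arr, nii)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(nii)
}

#' Read an image series written by [write_nifti_sidecar()]
#'
#' @param path Path without extension.
#' @return An [image_series()] when the sidecar holds a schedule, otherwise
#'   the bare array.
#' @export
read_nifti_sidecar <- function(path) {
  arr <- as.array(RNifti::readNifti(paste0(path, ".nii.gz")))
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) return(arr)
  meta <- yaml::read_yaml(side)
  if (is.null(meta$schedule)) return(arr)
  sch <- do.call(acquisition_schedule, meta$schedule)
  image_series(arr, sch, meta$modality,
               pixel_spacing = unlist(meta$pixel_spacing),
               slice_thickness = meta$slice_thickness)
}

#' Append per-subject biomarker summaries to a cohort table
#'
#' @param table Existing cohort data frame (or `NULL`).
#' @param subject,treatment,timepoint,biomarker Identifiers.
#' @param median Summary value (the per-subject median; mean for volumes).
#' @param n_pixels,n_converged Pixel accounting.
#' @return The grown cohort data frame.
#' @export
cohort_append <- function(table, subject, treatment, timepoint, biomarker,
                          median, n_pixels = NA, n_converged = NA) {
  row <- data.frame(subject = subject, treatment = treatment,
                    timepoint = timepoint, biomarker = biomarker,
                    value = median, n_pixels = n_pixels,
                    n_converged = n_converged)
  if (is.null(table)) row else rbind(table, row)
}

#' Write/read tab-separated tables
#'
#' Plain TSV writers used for cohort tables, count matrices, alignment
#' summaries and DE results. Row names are kept for matrices (gene ids).
#'
#' @param x Data frame or matrix.
#' @param path Output file.
#' @return `write_tsv()` returns `path` invisibly; `read_tsv()` the table.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = is.matrix(x), col.names = NA_not_matrix(x))
  invisible(path)
}

NA_not_matrix <- function(x) if (is.matrix(x)) NA else TRUE

#' @param header Does the file carry a header line?
#' @rdname write_tsv
#' @export
read_tsv <- function(path, header = TRUE) {
  x <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE, check.names = FALSE)
  # matrices are written with an unnamed leading row-name column
  if (header && ncol(x) > 1 && identical(names(x)[1], "")) {
    rownames(x) <- x[[1]]
    x <- x[, -1, drop = FALSE]
  }
  x
}

#' Write a run manifest with file checksums
#'
#' @param dir Output directory whose files are listed.
#' @param info Named list of run metadata (seeds, config, versions).
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(dir, info = list()) {
  files <- setdiff(list.files(dir, recursive = TRUE),
                   "manifest.json")
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- c(info, list(files = lapply(seq_along(files), function(i)
    list(path = files[i], md5 = unname(sums[i])))))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
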