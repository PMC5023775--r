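#' 4-D MRI image series
#'
#' A spatial volume (slice, row, col) acquired repeatedly along a sample
#' axis whose meaning depends on the modality: b-values for DWI, echo times
#' for MGRE, and the concatenated baseline-inversion block plus
#' (frame x inversion-time) dynamic block for the IR true-FISP DCE readout.
#'
#' @param data 4-D numeric array `(slice, row, col, sample)`.
#' @param schedule An [acquisition_schedule()].
#' @param modality One of `"dwi"`, `"mgre"`, `"ir_truefisp_dce"`.
#' @param pixel_spacing In-plane pixel spacing, mm (length 2).
#' @param slice_thickness Slice thickness, mm.
#' @return Object of class `image_series`.
#' @export
image_series <- function(data, schedule, modality = c("dwi", "mgre",
                                                      "ir_truefisp_dce"),
                         pixel_spacing = c(30 / 128, 30 / 128),
                         slice_thickness = 1) {
  modality <- match.arg(modality)
  stopifnot(is.array(data), length(dim(data)) == 4,
            inherits(schedule, "acquisition_schedule"))
  if (any(pixel_spacing <= 0) || slice_thickness <= 0)
    stop("pixel spacing and slice thickness must be positive", call. = FALSE)
  n_expected <- switch(modality,
    dwi = length(schedule$b_values),
    mgre = length(schedule$echo_times),
    ir_truefisp_dce = length(schedule$baseline_inversion_times) +
      length(schedule$frame_times) * length(schedule$inversion_times))
  if (n_expected == 0)
    stop(sprintf("schedule carries no timing lists for modality '%s'",
                 modality), call. = FALSE)
  if (dim(data)[4] != n_expected)
    stop(sprintf("sample dimension (%d) does not match the schedule (%d)",
                 dim(data)[4], n_expected), call. = FALSE)
  structure(list(data = data, schedule = schedule, modality = modality,
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_thickness = slice_thickness),
            class = "image_series")
}

#' Region-of-interest mask
#'
#' @param mask Logical 3-D array `(slice, row, col)`; tumour ROI drawn on
#'   anatomical images.
#' @param label Free-text label.
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "tumour") {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  mask <- array(as.logical(mask), dim(mask))
  if (anyNA(mask)) stop("mask contains NA", call. = FALSE)
  structure(list(mask = mask, label = label), class = "roi_mask")
}

#' Parametric biomarker map
#'
#' Per-pixel parameter estimates over a fitted ROI; out-of-mask pixels are
#' `NA`. Carries per-pixel convergence flags from the fitting stage.
#'
#' @param values 3-D numeric array, `NA` outside the fitted mask.
#' @param parameter Parameter name (e.g. `"ADC"`).
#' @param units Unit string (e.g. `"10^-6 mm^2/s"`).
#' @param converged Logical 3-D array (or NULL): per-pixel convergence.
#' @param provenance List describing the fit configuration.
#' @return Object of class `parametric_map`.
#' @export
parametric_map <- function(values, parameter, units, converged = NULL,
                           provenance = list()) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!is.null(converged))
    stopifnot(identical(dim(converged), dim(values)))
  structure(list(values = values, parameter = parameter, units = units,
                 converged = converged, provenance = provenance),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<parametric_map> %s [%s]: %d fitted pixels, median %.4g\n",
              x$parameter, x$units, length(v),
              if (length(v)) stats::median(v) else NA_real_))
  invisible(x)
}

check_geometry <- function(series, mask) {
  if (!identical(dim(series$data)[1:3], dim(mask$mask)))
    stop("series and mask geometries differ", call. = FALSE)
  if (!any(mask$mask)) stop("mask is empty", call. = FALSE)
  invisible(TRUE)
}

# Extract in-mask pixel signals as a (samples x pixels) matrix.
mask_signal_matrix <- function(series, mask) {
  d <- dim(series$data)
  flat <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  t(flat[as.vector(mask$mask), , drop = FALSE])
}

# Scatter a per-pixel vector back into a 3-D array over the mask.
unmask <- function(values, mask) {
  out <- array(NA_real_, dim(mask$mask))
  out[mask$mask] <- values
  out
}
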