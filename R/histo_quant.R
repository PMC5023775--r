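#' Unit-norm stain vector matrix
#'
#' Rows are optical-density directions of up to three stains; rows are
#' normalised to unit length and the matrix must be invertible for
#' deconvolution. The default pairs haematoxylin and DAB (standard
#' brightfield IHC values) with a neutral residual channel.
#'
#' @param m 3x3 numeric matrix (rows = stains).
#' @return Object of class `stain_vectors`.
#' @export
stain_vectors <- function(m = rbind(c(0.650, 0.704, 0.286),
                                    c(0.268, 0.570, 0.776),
                                    c(0.711, -0.423, 0.561))) {
  m <- as.matrix(m)
  stopifnot(identical(dim(m), c(3L, 3L)))
  m <- m / sqrt(rowSums(m^2))
  if (abs(det(m)) < 1e-8)
    stop("stain matrix is singular", call. = FALSE)
  structure(m, class = c("stain_vectors", "matrix"))
}

#' Simulate a stained microscopy field with known truth
#'
#' Places non-overlapping (or warned-overlapping) discs or squares of a
#' given stain into a background field and composes the RGB image by
#' Beer-Lambert optical-density mixing: `I = I0 * 10^(-OD)` with
#' `OD = conc %*% stain_vector`.
#'
#' @param field_size `c(rows, cols)` pixels.
#' @param n_objects Number of stained objects.
#' @param radius_range Object radius range, pixels.
#' @param shape `"disc"` or `"square"`.
#' @param stain Row index of [stain_vectors()] used for the objects.
#' @param intensity Optical density of object pixels.
#' @param vectors A [stain_vectors()].
#' @param background Background intensity I0 (per channel, 0-1 scale).
#' @param seed RNG seed.
#' @return List: `image` (rows x cols x 3 RGB in (0, 1]), `truth` (logical
#'   object mask), `n_objects`, `area_fraction` (%, of the whole field),
#'   `pixel_size`.
#' @export
simulate_histology_field <- function(field_size = c(128, 128), n_objects = 5,
                                     radius_range = c(4, 8), shape = "disc",
                                     stain = 2, intensity = 1,
                                     vectors = stain_vectors(),
                                     background = c(0.95, 0.95, 0.95),
                                     seed = 1L) {
  stopifnot(length(field_size) == 2, all(field_size > 0))
  if (max(radius_range) * 2 + 2 > min(field_size))
    stop("objects do not fit in the field", call. = FALSE)
  truth <- matrix(FALSE, field_size[1], field_size[2])
  rows <- row(truth); cols <- col(truth)
  overlap <- FALSE
  if (n_objects > 0) with_seed(seed, {
    for (i in seq_len(n_objects)) {
      r <- stats::runif(1, radius_range[1], radius_range[2])
      placed <- FALSE
      for (try in 1:50) {
        cy <- stats::runif(1, r + 1, field_size[1] - r)
        cx <- stats::runif(1, r + 1, field_size[2] - r)
        obj <- if (shape == "disc")
          (rows - cy)^2 + (cols - cx)^2 <= r^2
        else abs(rows - cy) <= r & abs(cols - cx) <= r
        if (!any(obj & truth)) { truth <- truth | obj; placed <- TRUE; break }
      }
      if (!placed) {
        warning("could not place all objects without overlap", call. = FALSE)
        overlap <- TRUE
        truth <- truth | obj
      }
    }
  })
  od <- array(0, c(field_size, 3))
  for (ch in 1:3)
    od[, , ch] <- truth * intensity * vectors[stain, ch]
  img <- array(0, c(field_size, 3))
  for (ch in 1:3)
    img[, , ch] <- background[ch] * 10^(-od[, , ch])
  list(image = img, truth = truth, n_objects = n_objects,
       area_fraction = 100 * mean(truth), pixel_size = 1,
       overlap = overlap)
}

#' Colour deconvolution of an RGB field into stain channels
#'
#' Converts intensities to optical densities `OD = -log10(I / I0)` and
#' unmixes them with the inverse of the stain-vector matrix; a pure-stain
#' pixel loads onto a single channel, and remixing the channels
#' reconstructs the OD image exactly (linear inverse).
#'
#' @param image rows x cols x 3 RGB array, intensities in (0, 1].
#' @param vectors A [stain_vectors()].
#' @param I0 Incident intensity per channel.
#' @return rows x cols x 3 array of per-stain OD channels.
#' @export
colour_deconvolve <- function(image, vectors = stain_vectors(),
                              I0 = c(1, 1, 1)) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  d <- dim(image)
  flat <- matrix(image, ncol = 3)
  od <- -log10(sweep(pmax(flat, 1e-6), 2, I0, "/"))
  conc <- od %*% solve(unclass(vectors))
  array(conc, d)
}

#' Positive-area fraction within an ROI
#'
#' `100 * (positive & roi) / roi` pixels. Positivity is decided by a fixed
#' absolute threshold or by Otsu's method on the in-ROI intensities.
#'
#' @param channel 2-D intensity (or stain OD) image.
#' @param roi Logical mask; defaults to the whole field.
#' @param threshold Numeric threshold, or `"otsu"`.
#' @return Area fraction, percent.
#' @export
area_fraction <- function(channel, roi = NULL, threshold = 0.5) {
  channel <- as.matrix(channel)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(channel), ncol(channel))
  stopifnot(identical(dim(roi), dim(channel)))
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  thr <- if (identical(threshold, "otsu")) {
    v <- channel[roi]
    rng <- range(v)
    if (diff(rng) == 0) Inf else
      EBImage::otsu(matrix((v - rng[1]) / diff(rng), ncol = 1)) *
        diff(rng) + rng[1]
  } else threshold
  100 * sum(channel > thr & roi) / sum(roi)
}

#' Microvessel density across fields
#'
#' Counts connected components (4-connectivity) of positive pixels of at
#' least `min_size` pixels in each field and returns the mean count per
#' field, the convention for CD31 vessel counting in high-power fields.
#'
#' @param fields List of 2-D positive-signal images (or logical masks).
#' @param threshold Positivity threshold for numeric fields.
#' @param min_size Minimum object size, pixels.
#' @return List: `mvd` (mean vessels/field), `per_field` counts.
#' @export
microvessel_density <- function(fields, threshold = 0.5, min_size = 10) {
  if (!is.list(fields)) fields <- list(fields)
  if (length(fields) < 5)
    warning("fewer than 5 fields; vessel counting is usually done on >5",
            call. = FALSE)
  per_field <- vapply(fields, function(f) {
    bw <- if (is.logical(f)) f else f > threshold
    if (!any(bw)) return(0)
    lab <- EBImage::bwlabel(matrix(as.numeric(bw), nrow(bw), ncol(bw)))
    sizes <- tabulate(lab[lab > 0])
    sum(sizes >= min_size)
  }, numeric(1))
  list(mvd = mean(per_field), per_field = per_field)
}

#' Summarise histology endpoints for one tumour
#'
#' @param hoechst_pct,pimonidazole_pct,sma_pct,necrosis_pct Area fractions,
#'   percent.
#' @param mvd Mean vessel count per field.
#' @param n_fields Number of fields analysed.
#' @return A one-row data frame (`histo_summary`).
#' @export
histo_summary <- function(hoechst_pct = NA, pimonidazole_pct = NA,
                          sma_pct = NA, necrosis_pct = NA, mvd = NA,
                          n_fields = NA) {
  for (v in c(hoechst_pct, pimonidazole_pct, sma_pct, necrosis_pct))
    if (!is.na(v) && (v < 0 || v > 100))
      stop("percentages must lie in [0, 100]", call. = FALSE)
  if (!is.na(mvd) && mvd < 0) stop("mvd must be >= 0", call. = FALSE)
  data.frame(hoechst_pct = hoechst_pct, pimonidazole_pct = pimonidazole_pct,
             sma_pct = sma_pct, necrosis_pct = necrosis_pct, mvd = mvd,
             n_fields = n_fields)
}
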