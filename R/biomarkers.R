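#' ADC map and median from a diffusion-weighted series
#'
#' Fits the mono-exponential diffusion model pixel by pixel over the ROI
#' (see [fit_map()]) and reports the ADC map together with the median over
#' converged in-mask pixels, in the conventional reporting units of
#' 1e-6 mm^2 s^-1.
#'
#' @param series A DWI [image_series()] with at least 3 b-values.
#' @param mask An [roi_mask()].
#' @param priors Optional [prior_spec()] (parameters `S0`, `ADC`).
#' @param iters Refinement iterations, see [fit_map()].
#' @return List: `adc` ([parametric_map()], 1e-6 mm^2/s), `s0`, `median`
#'   (1e-6 mm^2/s), `n_pixels`, `n_converged`.
#' @export
compute_adc_map <- function(series, mask, priors = NULL, iters = 64L) {
  if (length(series$schedule$b_values) < 3)
    stop("ADC mapping needs at least 3 b-values", call. = FALSE)
  maps <- fit_map("dwi", series, mask, priors = priors, iters = iters)
  adc <- maps$ADC
  adc$values <- adc$values * 1e6
  adc$units <- "10^-6 mm^2/s"
  conv <- adc$converged & !is.na(adc$values)
  vals <- adc$values[which(conv)]
  list(adc = adc, s0 = maps$S0,
       median = stats::median(vals),
       n_pixels = sum(mask$mask), n_converged = length(vals))
}

#' Per-pixel contrast-agent concentration dynamics from an IR true-FISP series
#'
#' Recovers the tissue gadolinium concentration time course of every
#' in-mask pixel from the inversion-recovery true-FISP experiment. The
#' multi-inversion baseline block is fitted per pixel for the recovery
#' amplitudes (A, B) and apparent rate; each dynamic frame is then fitted
#' for its apparent rate with the amplitudes held at their baseline values.
#' Apparent rates are converted to true R1 with the selected correction and
#' to concentration by the linear fast-exchange relation, referencing each
#' pixel to its own baseline R1 so that pre-injection frames average to
#' zero up to noise.
#'
#' @param series An `ir_truefisp_dce` [image_series()].
#' @param mask An [roi_mask()].
#' @param cfg A [concentration_config()] (relaxivity; the per-pixel
#'   baseline R1 is estimated from the baseline block).
#' @param correction `"look_locker"` or `"none"`, see [r1_from_ir_fit()].
#' @param iters Golden-section refinement iterations (baseline block).
#' @param dyn_iters Refinement iterations for the per-frame rate fits;
#'   defaults to `iters`.
#' @return Object of class `concentration_series`: `conc` (pixels x frames,
#'   mM), `frame_times` and `injection_time` (s), `baseline_r1` (s^-1),
#'   `converged`, and the `mask`.
#' @export
compute_concentration_series <- function(series, mask,
                                         cfg = concentration_config(),
                                         correction = c("look_locker", "none"),
                                         iters = 64L, dyn_iters = iters) {
  correction <- match.arg(correction)
  stopifnot(inherits(series, "image_series"))
  if (series$modality != "ir_truefisp_dce")
    stop("concentration extraction needs an IR true-FISP DCE series",
         call. = FALSE)
  sch <- series$schedule
  if (length(sch$baseline_inversion_times) == 0)
    stop("missing baseline inversion-time block", call. = FALSE)
  check_geometry(series, mask)
  Y <- mask_signal_matrix(series, mask)          # samples x pixels
  n_base <- length(sch$baseline_inversion_times)
  nti <- length(sch$inversion_times)
  n_fr <- length(sch$frame_times)
  n_px <- ncol(Y)

  base_fit <- fit_ir_cols(Y[seq_len(n_base), , drop = FALSE],
                          sch$baseline_inversion_times, iters = iters)
  ok <- is.finite(base_fit$A) & base_fit$A > 0 & base_fit$B > 0
  ratio <- base_fit$B / base_fit$A
  if (correction == "look_locker") ok <- ok & ratio > 1

  dyn <- Y[-seq_len(n_base), , drop = FALSE]     # (frames*nti) x pixels
  dyn <- array(dyn, c(nti, n_fr, n_px))
  dyn <- matrix(dyn, nrow = nti)                 # columns: (frame, pixel)
  rate <- fit_ir_rate_cols(dyn, sch$inversion_times,
                           A = rep(base_fit$A, each = n_fr),
                           B = rep(base_fit$B, each = n_fr),
                           grid_n = 12L, iters = dyn_iters)
  r1_app <- matrix(rate$R1_app, n_fr, n_px)      # frames x pixels
  r1 <- if (correction == "look_locker")
    sweep(r1_app, 2, pmax(ratio - 1, 1e-12), "/")
  else r1_app
  base_r1 <- if (correction == "look_locker")
    base_fit$R1_app / pmax(ratio - 1, 1e-12)
  else base_fit$R1_app
  conc <- sweep(r1, 2, base_r1, "-") / cfg$r1
  structure(list(conc = t(conc), frame_times = sch$frame_times,
                 injection_time = sch$injection_time,
                 baseline_r1 = base_r1, converged = ok, mask = mask,
                 cfg = cfg, correction = correction),
            class = "concentration_series")
}

#' Ktrans and ve maps from concentration dynamics
#'
#' Pixelwise MAP fit of the Tofts-Kermode model to the post-injection
#' concentration course. With the default uniform priors the vectorised
#' separable least-squares solver is used; informative priors trigger a
#' per-pixel [map_estimate()] fit. Pixels whose concentration is entirely
#' zero (or whose baseline fit failed) are flagged non-converged and
#' excluded from the medians.
#'
#' @param conc A `concentration_series` from
#'   [compute_concentration_series()].
#' @param aif An [aif_params()].
#' @param priors Optional [prior_spec()] (parameters `Ktrans`, `ve`).
#' @param iters Refinement iterations.
#' @param grid_n Size of the kep bracketing grid.
#' @return List: `ktrans` and `ve` ([parametric_map()]s), `median_ktrans`
#'   (min^-1), `median_ve`, `n_converged`.
#' @export
compute_ktrans_ve_maps <- function(conc, aif = aif_params(), priors = NULL,
                                   iters = 64L, grid_n = 32L) {
  stopifnot(inherits(conc, "concentration_series"))
  post <- conc$frame_times >= conc$injection_time
  if (sum(post) < 10)
    stop("need at least 10 post-injection frames", call. = FALSE)
  t_min <- (conc$frame_times[post] - conc$injection_time) / 60
  C <- t(conc$conc[, post, drop = FALSE])        # frames x pixels
  zero <- colSums(abs(C)) == 0
  if (is.null(priors)) {
    fit <- fit_tofts_cols(C, t_min, aif = aif, grid_n = grid_n,
                          iters = iters)
    kt <- fit$Ktrans
    ve <- pmin(fit$ve, 0.999)
  } else {
    kt <- ve <- rep(NA_real_, ncol(C))
    for (i in which(!zero)) {
      fr <- map_estimate("tofts", t_min, C[, i], priors = priors, aif = aif)
      kt[i] <- fr$estimates["Ktrans"]; ve[i] <- fr$estimates["ve"]
    }
  }
  convd <- conc$converged & !zero & is.finite(kt)
  kt[!convd & !is.finite(kt)] <- NA_real_
  mask <- conc$mask
  conv_arr <- unmask_logical(convd, mask)
  prov <- list(model = "tofts", aif = aif)
  sel <- which(convd & is.finite(ve) & !is.na(ve))
  list(ktrans = parametric_map(unmask(kt, mask), "Ktrans", "1/min",
                               converged = conv_arr, provenance = prov),
       ve = parametric_map(unmask(ve, mask), "ve", "fraction",
                           converged = conv_arr, provenance = prov),
       median_ktrans = stats::median(kt[convd]),
       median_ve = stats::median(ve[sel]),
       n_converged = sum(convd))
}

#' Initial area under the gadolinium uptake curve (IAUGC60)
#'
#' Trapezoidal integral of the per-pixel concentration course over the
#' first 60 s after injection, in mM min. The window is anchored at the
#' injection frame (the first post-injection frame when none coincides)
#' and the 60-s endpoint is obtained by linear interpolation when no frame
#' lands on it.
#'
#' @param conc A `concentration_series`.
#' @param window Integration window length, s.
#' @param time_unit Unit of the stored frame times; the integral is the
#'   same mM min quantity either way.
#' @return List: `iaugc` ([parametric_map()], mM min), `median`,
#'   `n_pixels`.
#' @export
compute_iaugc60 <- function(conc, window = 60, time_unit = c("s", "min")) {
  stopifnot(inherits(conc, "concentration_series"))
  time_unit <- match.arg(time_unit)
  scale <- if (time_unit == "min") 60 else 1
  conc$frame_times <- conc$frame_times * scale
  conc$injection_time <- conc$injection_time * scale
  t_rel <- conc$frame_times - conc$injection_time
  t0 <- min(t_rel[t_rel >= 0])
  t_end <- t0 + window
  if (max(t_rel) < t_end)
    stop("dynamic frames do not cover the 60-s window after injection",
         call. = FALSE)
  sel <- t_rel >= t0 & t_rel <= t_end
  tt <- t_rel[sel]
  Cw <- conc$conc[, sel, drop = FALSE]
  if (max(tt) < t_end) {                          # interpolate the endpoint
    i_hi <- which(t_rel > t_end)[1]
    i_lo <- i_hi - 1L
    w <- (t_end - t_rel[i_lo]) / (t_rel[i_hi] - t_rel[i_lo])
    c_end <- (1 - w) * conc$conc[, i_lo] + w * conc$conc[, i_hi]
    tt <- c(tt, t_end)
    Cw <- cbind(Cw, c_end)
  }
  dt <- diff(tt)
  auc_s <- as.numeric((Cw[, -ncol(Cw), drop = FALSE] +
                       Cw[, -1, drop = FALSE]) %*% (dt / 2))
  auc <- auc_s / 60                               # mM s -> mM min
  ok <- conc$converged
  vals <- ifelse(ok, auc, NA_real_)
  list(iaugc = parametric_map(unmask(vals, conc$mask), "IAUGC60", "mM min",
                              converged = unmask_logical(ok, conc$mask)),
       median = stats::median(auc[ok]), n_pixels = length(auc))
}

#' Delta-R2* and fractional blood volume maps from pre/post-USPIO MGRE series
#'
#' Fits R2* pixelwise before and after USPIO injection, forms the
#' susceptibility-induced rate change `dR2* = R2*_post - R2*_pre` and
#' converts it to fractional blood volume `fBV(%) = 100 dR2* / kappa`.
#' Negative dR2* pixels are retained (and counted) rather than clipped, so
#' cohort medians stay unbiased.
#'
#' @param pre_series,post_series MGRE [image_series()] acquired before and
#'   after USPIO injection, with identical echo schedules.
#' @param mask An [roi_mask()].
#' @param consts An [fbv_constants()].
#' @param priors Optional [prior_spec()] for the R2* fits.
#' @param iters Refinement iterations.
#' @return List: `dr2star` and `fbv` ([parametric_map()]s), `median_dr2star`
#'   (s^-1), `median_fbv` (%), `n_negative`, `n_converged`.
#' @export
compute_fbv_map <- function(pre_series, post_series, mask,
                            consts = fbv_constants(), priors = NULL,
                            iters = 64L) {
  if (!isTRUE(all.equal(pre_series$schedule$echo_times,
                        post_series$schedule$echo_times)))
    stop("pre and post series must share the echo schedule", call. = FALSE)
  pre <- fit_map("mgre", pre_series, mask, priors = priors, iters = iters)
  post <- fit_map("mgre", post_series, mask, priors = priors, iters = iters)
  dr2 <- post$R2star$values - pre$R2star$values
  conv <- pre$R2star$converged & post$R2star$converged
  fbv <- 100 * dr2 / consts$kappa
  sel <- which(conv & !is.na(dr2))
  list(dr2star = parametric_map(dr2, "deltaR2star", "1/s", converged = conv),
       fbv = parametric_map(fbv, "fBV", "%", converged = conv),
       median_dr2star = stats::median(dr2[sel]),
       median_fbv = stats::median(fbv[sel]),
       n_negative = sum(dr2[sel] < 0), n_converged = length(sel))
}

#' Tumour volume from calliper measurements or ROI masks
#'
#' Calliper volumes use the ellipsoid formula `L W^2 / 2` with `L >= W` the
#' two largest dimensions; ROI volumes sum the in-mask pixel area over
#' slices times the slice thickness.
#'
#' @param calliper Numeric `c(L, W)` in mm, or `NULL`.
#' @param roi An [roi_mask()] (or list of them), or `NULL`.
#' @param slice_thickness Slice thickness, mm (ROI mode).
#' @param pixel_spacing In-plane spacing, mm (ROI mode).
#' @return Volume in mm^3.
#' @examples
#' tumour_volume(calliper = c(10, 5))  # 125
#' @export
tumour_volume <- function(calliper = NULL, roi = NULL, slice_thickness = 1,
                          pixel_spacing = c(30 / 128, 30 / 128)) {
  if (!is.null(calliper)) {
    L <- calliper[[1]]; W <- calliper[[2]]
    if (W > L) stop("calliper W exceeds L", call. = FALSE)
    if (W <= 0) stop("calliper dimensions must be positive", call. = FALSE)
    return(L * W^2 / 2)
  }
  if (is.null(roi)) stop("supply 'calliper' or 'roi'", call. = FALSE)
  masks <- if (inherits(roi, "roi_mask")) list(roi) else roi
  n_px <- sum(vapply(masks, function(m) sum(m$mask), numeric(1)))
  if (n_px == 0) stop("empty ROI", call. = FALSE)
  n_px * prod(pixel_spacing) * slice_thickness
}
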