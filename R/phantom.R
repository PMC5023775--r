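#' Treatment effect specification for phantom studies
#'
#' Encodes how a post-treatment phantom differs from its pre-treatment
#' counterpart: a bare volume multiplier, multiplicative changes to Ktrans
#' and ADC, an additive change to fractional blood volume, and optionally
#' the periphery-restricted enhancement pattern in which post-treatment
#' contrast uptake is confined to the tumour rim.
#'
#' @param label Treatment arm label.
#' @param volume_growth_factor Pre-to-post tumour volume multiplier (> 0).
#' @param ktrans_multiplier Multiplier applied to the Ktrans map (> 0).
#' @param fbv_delta Additive change to fBV, percentage points.
#' @param adc_multiplier Multiplier applied to the ADC map (> 0).
#' @param rim_restriction If `TRUE`, post-treatment Ktrans is retained (and
#'   scaled) only in the rim shell and set to zero in the tumour core.
#' @param seed Seed for drawing map values on newly grown mask pixels.
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(label = "treatment", volume_growth_factor = 1,
                        ktrans_multiplier = 1, fbv_delta = 0,
                        adc_multiplier = 1, rim_restriction = FALSE,
                        seed = 1L) {
  for (nm in c("volume_growth_factor", "ktrans_multiplier", "adc_multiplier"))
    stop_if_not_scalar(get(nm), nm, lower = 0, strict_lower = TRUE)
  stop_if_not_scalar(fbv_delta, "fbv_delta")
  structure(list(label = label, volume_growth_factor = volume_growth_factor,
                 ktrans_multiplier = ktrans_multiplier, fbv_delta = fbv_delta,
                 adc_multiplier = adc_multiplier,
                 rim_restriction = isTRUE(rim_restriction),
                 seed = as.integer(seed)),
            class = "effect_spec")
}

# In-plane binary erosion by `px` pixels (4-neighbourhood, per slice).
erode_inplane <- function(mask, px = 2L) {
  out <- mask
  for (i in seq_len(px)) {
    d <- dim(out)
    sh <- function(dr, dc) {
      m <- array(FALSE, d)
      rs <- seq_len(d[2]); cs <- seq_len(d[3])
      rsrc <- rs - dr; csrc <- cs - dc
      keep_r <- rsrc >= 1 & rsrc <= d[2]
      keep_c <- csrc >= 1 & csrc <= d[3]
      m[, rs[keep_r], cs[keep_c]] <- out[, rsrc[keep_r], csrc[keep_c]]
      m
    }
    out <- out & sh(1, 0) & sh(-1, 0) & sh(0, 1) & sh(0, -1)
  }
  out
}

ellipsoid_mask <- function(shape, semi_axes, center = (shape + 1) / 2) {
  sl <- slice.index(array(0, shape), 1)
  ro <- slice.index(array(0, shape), 2)
  co <- slice.index(array(0, shape), 3)
  ((sl - center[1]) / semi_axes[1])^2 + ((ro - center[2]) / semi_axes[2])^2 +
    ((co - center[3]) / semi_axes[3])^2 <= 1
}

default_baseline_params <- function() {
  list(adc = c(mean = 729e-6, sd = 40e-6),    # mm^2/s
       ktrans = c(mean = 0.2, sd = 0.02),     # 1/min
       ve = c(mean = 0.3, sd = 0.03),         # fraction
       r2star = c(mean = 60, sd = 5),         # 1/s, pre-USPIO
       fbv = c(mean = 6.1, sd = 0.5),         # %
       s0 = c(mean = 1000, sd = 0),           # a.u.
       r1 = c(mean = 0.55, sd = 0.02))        # 1/s, pre-contrast
}

.baseline_bounds <- list(
  adc = c(100e-6, 3000e-6), ktrans = c(1e-4, 5), ve = c(0.01, 0.95),
  r2star = c(1, 500), fbv = c(0, 60), s0 = c(1, Inf), r1 = c(0.05, 20))

draw_map <- function(n, mean, sd, bounds) {
  v <- stats::rnorm(n, mean, sd)
  pmin(pmax(v, bounds[1]), bounds[2])
}

#' Ground-truth digital tumour phantom
#'
#' Assembles a `phantom_truth` from its component maps and validates the
#' type invariants: maps finite and non-negative in-mask, `0 < ve < 1`, rim
#' contained in the mask, and exact consistency of the fBV map with the
#' pre/post-USPIO R2* maps through the susceptibility constant kappa.
#'
#' @param mask,rim_mask Logical 3-D arrays.
#' @param maps Named list of 3-D arrays: `adc` (mm^2/s), `ktrans` (1/min),
#'   `ve`, `r1` (1/s), `r2star_pre`, `r2star_post` (1/s), `s0` (a.u.),
#'   `fbv` (%).
#' @param consts An [fbv_constants()].
#' @return Object of class `phantom_truth`.
#' @export
phantom_truth <- function(mask, rim_mask, maps, consts = fbv_constants()) {
  shape <- dim(mask)
  need <- c("adc", "ktrans", "ve", "r1", "r2star_pre", "r2star_post",
            "s0", "fbv")
  if (!all(need %in% names(maps)))
    stop("missing maps: ", paste(setdiff(need, names(maps)), collapse = ", "),
         call. = FALSE)
  for (nm in need)
    if (!identical(dim(maps[[nm]]), shape))
      stop(sprintf("map '%s' has the wrong shape", nm), call. = FALSE)
  if (any(rim_mask & !mask))
    stop("rim_mask must be contained in mask", call. = FALSE)
  inm <- which(mask)
  for (nm in need) {
    v <- maps[[nm]][inm]
    if (any(!is.finite(v)) || any(v < 0))
      stop(sprintf("map '%s' must be finite and non-negative in-mask", nm),
           call. = FALSE)
  }
  ve <- maps$ve[inm]
  if (any(ve <= 0 | ve >= 1))
    stop("'ve' must lie strictly in (0, 1) in-mask", call. = FALSE)
  dr2 <- maps$r2star_post[inm] - maps$r2star_pre[inm]
  if (max(abs(dr2 - consts$kappa * maps$fbv[inm] / 100)) >
      1e-9 * (1 + max(abs(dr2))))
    stop("fbv map inconsistent with (r2star_post - r2star_pre) / kappa",
         call. = FALSE)
  structure(c(list(shape = shape, mask = mask, rim_mask = rim_mask,
                   consts = consts), maps),
            class = "phantom_truth")
}

#' Generate a paired pre/post-treatment phantom study
#'
#' Builds an ellipsoidal tumour phantom with a 2-pixel peripheral rim
#' shell, draws per-pixel baseline parameter maps from truncated normal
#' distributions, and applies an [effect_spec()] to obtain the
#' post-treatment truth: the tumour volume is scaled by the growth factor
#' (new mask pixels receive freshly drawn baseline values), Ktrans and ADC
#' are scaled by their multipliers (optionally restricting post-treatment
#' Ktrans to the rim), and fBV is shifted additively with the post-USPIO
#' R2* map rebuilt to stay exactly consistent.
#'
#' @param geometry Integer triple `(slices, rows, cols)`.
#' @param baseline_params Named list of `c(mean, sd)` pairs for `adc`
#'   (mm^2/s), `ktrans` (1/min), `ve`, `r2star` (1/s), `fbv` (%), `s0`,
#'   `r1` (1/s). Missing entries fall back to defaults.
#' @param effect An [effect_spec()].
#' @param consts An [fbv_constants()].
#' @param seed Seed for the baseline draws.
#' @return List with elements `pre` and `post` (both `phantom_truth`).
#' @examples
#' st <- make_phantom_study(c(3, 32, 32), effect = effect_spec(), seed = 1)
#' sum(st$pre$mask)
#' @export
make_phantom_study <- function(geometry = c(3, 32, 32),
                               baseline_params = list(),
                               effect = effect_spec(),
                               consts = fbv_constants(), seed = 1L) {
  geometry <- as.integer(geometry)
  if (length(geometry) != 3 || any(geometry < 1))
    stop("'geometry' must be a positive integer triple", call. = FALSE)
  bp <- utils::modifyList(default_baseline_params(), baseline_params)
  for (nm in names(.baseline_bounds)) {
    b <- .baseline_bounds[[nm]]
    if (bp[[nm]][1] < b[1] || bp[[nm]][1] > b[2])
      stop(sprintf("non-physical baseline for '%s': mean %g outside [%g, %g]",
                   nm, bp[[nm]][1], b[1], b[2]), call. = FALSE)
  }
  stopifnot(inherits(effect, "effect_spec"))

  ax_inplane <- pmax(0.40 * geometry[2:3], 3)
  ax_slice <- if (geometry[1] == 1) 1 else geometry[1] / 2 - 0.1
  semi <- c(ax_slice, ax_inplane)
  mask <- ellipsoid_mask(geometry, semi)
  if (!any(mask)) stop("geometry too small for a phantom", call. = FALSE)
  rim <- mask & !erode_inplane(mask, 2L)

  draw_all <- function(idx) {
    maps <- list()
    for (nm in names(.baseline_bounds)) {
      m <- array(0, geometry)
      m[idx] <- draw_map(length(idx), bp[[nm]][1], bp[[nm]][2],
                         .baseline_bounds[[nm]])
      maps[[nm]] <- m
    }
    maps
  }
  pre_maps <- with_seed(seed, draw_all(which(mask)))
  pre_maps$r2star_pre <- pre_maps$r2star
  pre_maps$r2star_post <- pre_maps$r2star_pre +
    consts$kappa * pre_maps$fbv / 100
  pre_maps$r2star <- NULL
  pre <- phantom_truth(mask, rim, pre_maps, consts)

  # post-treatment mask: growth rendered in-plane (the slice coverage is
  # fixed by the acquisition), so the in-plane semi-axes scale by sqrt(g)
  g <- sqrt(effect$volume_growth_factor)
  semi_post <- c(semi[1], pmin(semi[2:3] * g, (geometry[2:3] - 0.5) / 2))
  post_mask <- if (effect$volume_growth_factor == 1) mask else
    ellipsoid_mask(geometry, semi_post)
  post_rim <- post_mask & !erode_inplane(post_mask, 2L)

  post_maps <- pre_maps
  new_px <- which(post_mask & !mask)
  if (length(new_px)) {
    # grown-region draws depend on both the study seed and the effect seed,
    # so arms differ deterministically but subjects stay independent
    fresh <- with_seed(seed + effect$seed, draw_all(new_px))
    for (nm in setdiff(names(fresh), "r2star")) {
      if (nm %in% names(post_maps))
        post_maps[[nm]][new_px] <- fresh[[nm]][new_px]
    }
    post_maps$r2star_pre[new_px] <- fresh$r2star[new_px]
  }
  gone_px <- which(mask & !post_mask)
  if (length(gone_px))
    for (nm in names(post_maps)) post_maps[[nm]][gone_px] <- 0

  post_maps$adc <- post_maps$adc * effect$adc_multiplier
  post_maps$ktrans <- post_maps$ktrans * effect$ktrans_multiplier
  if (effect$rim_restriction)
    post_maps$ktrans[post_mask & !post_rim] <- 0
  post_maps$fbv <- pmax(post_maps$fbv + effect$fbv_delta, 0) * post_mask
  post_maps$r2star_post <- post_maps$r2star_pre +
    consts$kappa * post_maps$fbv / 100
  post_maps$adc[post_mask] <-
    pmin(pmax(post_maps$adc[post_mask], .baseline_bounds$adc[1]),
         .baseline_bounds$adc[2])
  post <- phantom_truth(post_mask, post_rim, post_maps, consts)
  list(pre = pre, post = post, effect = effect)
}

#' Simulate an MRI series from a ground-truth phantom
#'
#' Evaluates the matching closed-form forward model at every pixel of the
#' phantom and optionally adds zero-mean Gaussian noise scaled so that the
#' in-mask mean signal divided by the noise standard deviation equals
#' `snr`. The DCE modality renders the full inversion-recovery true-FISP
#' experiment: a multi-inversion baseline block at the pre-contrast R1
#' followed by dynamic frames whose R1 follows the Tofts-Kermode tissue
#' concentration through the configured relaxivity. The apparent recovery
#' rate is `R1 (B/A - 1)` so that the Look-Locker-type correction is exact,
#' with the recovery amplitude ratio `B/A` fixed by `sim_options$ba_ratio`.
#'
#' @param truth A `phantom_truth`.
#' @param modality `"dwi"`, `"mgre"` or `"ir_truefisp_dce"`.
#' @param schedule An [acquisition_schedule()] consistent with the
#'   modality.
#' @param aif [aif_params()]; required for (and only for) DCE.
#' @param snr In-mask mean signal to noise sd ratio; `NULL` for noise-free.
#' @param uspio For MGRE: simulate the pre- (`"pre"`) or post-USPIO
#'   (`"post"`) R2* map.
#' @param sim_options List: `ba_ratio` (recovery amplitude ratio B/A > 1),
#'   `relaxivity` (s^-1 mM^-1).
#' @param seed RNG seed for the noise draw.
#' @return An [image_series()].
#' @export
simulate_mri_series <- function(truth, modality = c("dwi", "mgre",
                                                    "ir_truefisp_dce"),
                                schedule = NULL, aif = NULL, snr = NULL,
                                uspio = c("pre", "post"),
                                sim_options = list(), seed = NULL) {
  modality <- match.arg(modality)
  uspio <- match.arg(uspio)
  stopifnot(inherits(truth, "phantom_truth"))
  if (is.null(schedule))
    schedule <- default_schedule(switch(modality, ir_truefisp_dce = "dce",
                                        modality))
  opts <- utils::modifyList(list(ba_ratio = 2, relaxivity = 3.8), sim_options)
  if (!is.null(snr)) stop_if_not_scalar(snr, "snr", lower = 0,
                                        strict_lower = TRUE)
  if (modality == "ir_truefisp_dce" && is.null(aif))
    stop("DCE simulation requires an 'aif'", call. = FALSE)
  if (modality != "ir_truefisp_dce" && !is.null(aif))
    stop("'aif' is only meaningful for the DCE modality", call. = FALSE)

  shape <- truth$shape
  n_px <- prod(shape)
  sig <- switch(modality,
    dwi = {
      if (length(schedule$b_values) == 0)
        stop("schedule lacks b_values for DWI", call. = FALSE)
      outer(as.vector(truth$s0), rep(1, length(schedule$b_values))) *
        exp(-outer(as.vector(truth$adc), schedule$b_values))
    },
    mgre = {
      if (length(schedule$echo_times) == 0)
        stop("schedule lacks echo_times for MGRE", call. = FALSE)
      r2 <- if (uspio == "pre") truth$r2star_pre else truth$r2star_post
      outer(as.vector(truth$s0), rep(1, length(schedule$echo_times))) *
        exp(-outer(as.vector(r2), schedule$echo_times))
    },
    ir_truefisp_dce = {
      if (length(schedule$baseline_inversion_times) == 0 ||
          length(schedule$inversion_times) == 0 ||
          length(schedule$frame_times) == 0)
        stop("DCE schedule needs baseline_inversion_times, inversion_times ",
             "and frame_times", call. = FALSE)
      ba <- opts$ba_ratio
      if (ba <= 1) stop("ba_ratio must exceed 1", call. = FALSE)
      inm <- which(truth$mask)               # render in-mask pixels only;
      A <- truth$s0[inm]                     # s0 = 0 elsewhere
      r1_0 <- truth$r1[inm]
      t_post_min <- pmax(schedule$frame_times - schedule$injection_time, 0) / 60
      n_fr <- length(schedule$frame_times)
      ct <- matrix(0, length(inm), n_fr)
      kt <- truth$ktrans[inm]; ve <- truth$ve[inm]
      for (i in which(kt > 0))
        ct[i, ] <- tofts_concentration(t_post_min,
                                       list(Ktrans = kt[i], ve = ve[i]), aif)
      ct[, schedule$frame_times < schedule$injection_time] <- 0
      r1_t <- r1_0 + opts$relaxivity * ct            # in-mask x n_frames
      n_ba <- length(schedule$baseline_inversion_times)
      base <- abs(matrix(A, length(inm), n_ba) -
                  matrix(ba * A, length(inm), n_ba) *
                  exp(-outer(r1_0 * (ba - 1),
                             schedule$baseline_inversion_times)))
      nti <- length(schedule$inversion_times)
      dyn <- matrix(0, length(inm), n_fr * nti)
      for (fr in seq_len(n_fr)) {
        e <- exp(-outer(r1_t[, fr] * (ba - 1), schedule$inversion_times))
        dyn[, (fr - 1) * nti + seq_len(nti)] <- abs(A - ba * A * e)
      }
      full <- matrix(0, n_px, n_ba + n_fr * nti)
      full[inm, ] <- cbind(base, dyn)
      full
    })

  if (!is.null(snr)) {
    # snr refers to a single average; acquisitions with multiple averages
    # carry correspondingly less noise
    noise_sd <- mean(sig[as.vector(truth$mask), ]) / snr
    sd_col <- rep(noise_sd / sqrt(schedule$averages %||% 1), ncol(sig))
    if (modality == "ir_truefisp_dce") {
      n_ba <- length(schedule$baseline_inversion_times)
      sd_col[seq_len(n_ba)] <-
        noise_sd / sqrt(schedule$baseline_averages %||% 1)
    }
    sig <- with_seed(seed, sig + stats::rnorm(length(sig), 0,
                                              rep(sd_col, each = nrow(sig))))
  }
  image_series(array(sig, c(shape, ncol(sig))), schedule, modality)
}
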