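#' MRI acquisition schedule
#'
#' Bundles the acquisition timing of a multiparametric tumour MRI session:
#' diffusion weightings for DW-EPI, echo times for multi-gradient-echo (MGRE)
#' R2* mapping, and inversion times plus dynamic frame times for the
#' inversion-recovery true-FISP DCE readout.
#'
#' @param b_values Diffusion b-values, s mm^-2 (DWI).
#' @param echo_times Echo times, s (MGRE).
#' @param inversion_times Inversion times of each dynamic frame, s (DCE).
#' @param baseline_inversion_times Inversion times of the pre-contrast
#'   baseline T1 block, s (DCE).
#' @param frame_times Dynamic frame times relative to the start of the
#'   series, s (DCE).
#' @param injection_time Contrast injection time on the `frame_times` axis, s.
#' @param flip_angle Excitation flip angle, degrees.
#' @param B0 Static field strength, tesla.
#' @param averages Signal averages of the acquisition (noise falls with
#'   the square root of this).
#' @param baseline_averages Signal averages of the DCE baseline block
#'   (the dynamic frames use `averages`).
#'
#' @return An object of class `acquisition_schedule`.
#' @examples
#' sch <- acquisition_schedule(b_values = c(40, 200, 400, 550, 700))
#' sch$b_values
#' @export
acquisition_schedule <- function(b_values = NULL, echo_times = NULL,
                                 inversion_times = NULL,
                                 baseline_inversion_times = NULL,
                                 frame_times = NULL, injection_time = NULL,
                                 flip_angle = 60, B0 = 7, averages = 1,
                                 baseline_averages = averages) {
  chk_sorted <- function(x, name, lower = 0) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (any(!is.finite(x)) || any(x < lower))
      stop(sprintf("'%s' must be finite and >= %g", name, lower), call. = FALSE)
    if (is.unsorted(x, strictly = FALSE))
      stop(sprintf("'%s' must be sorted ascending", name), call. = FALSE)
    x
  }
  b_values <- chk_sorted(b_values, "b_values")
  echo_times <- chk_sorted(echo_times, "echo_times")
  inversion_times <- chk_sorted(inversion_times, "inversion_times")
  baseline_inversion_times <- chk_sorted(baseline_inversion_times,
                                         "baseline_inversion_times")
  frame_times <- chk_sorted(frame_times, "frame_times", lower = -Inf)
  stop_if_not_scalar(B0, "B0", lower = 0, strict_lower = TRUE)
  stop_if_not_scalar(flip_angle, "flip_angle", lower = 0, upper = 180)
  stop_if_not_scalar(averages, "averages", lower = 1)
  stop_if_not_scalar(baseline_averages, "baseline_averages", lower = 1)
  if (!is.null(frame_times)) {
    if (is.null(injection_time))
      stop("a dynamic schedule needs 'injection_time'", call. = FALSE)
    stop_if_not_scalar(injection_time, "injection_time",
                       lower = min(frame_times), upper = max(frame_times))
  }
  structure(list(b_values = b_values, echo_times = echo_times,
                 inversion_times = inversion_times,
                 baseline_inversion_times = baseline_inversion_times,
                 frame_times = frame_times, injection_time = injection_time,
                 flip_angle = flip_angle, B0 = B0, averages = averages,
                 baseline_averages = baseline_averages),
            class = "acquisition_schedule")
}

#' Default acquisition schedules
#'
#' Schedules matching the study protocol the package targets: DW-EPI with 5
#' b-values from 40 to 700 s mm^-2 at 4 averages; MGRE with a first echo at
#' 6 ms and 16 echoes spaced 4 ms apart at 16 averages; IR true-FISP DCE
#' with a 50-point baseline inversion block (25-1451 ms, 8 averages),
#' 8 inversion times per dynamic frame (109-924 ms, single average) and
#' 60 frames at 20 s resolution spanning 3 min before to 17 min after
#' injection.
#'
#' @param modality One of `"dwi"`, `"mgre"`, `"dce"`.
#' @return An [acquisition_schedule()].
#' @export
default_schedule <- function(modality = c("dwi", "mgre", "dce")) {
  modality <- match.arg(modality)
  switch(modality,
    dwi = acquisition_schedule(b_values = c(40, 200, 400, 550, 700),
                               averages = 4),
    mgre = acquisition_schedule(echo_times = (6 + 4 * (0:15)) / 1000,
                                averages = 16),
    dce = acquisition_schedule(
      baseline_inversion_times = seq(0.025, 1.451, length.out = 50),
      inversion_times = seq(0.109, 0.924, length.out = 8),
      frame_times = seq(0, by = 20, length.out = 60),
      injection_time = 180, averages = 1, baseline_averages = 8)
  )
}

#' Population arterial input function parameters
#'
#' Biexponential plasma clearance model `Cp(t) = D (a1 e^{-m1 t} + a2
#' e^{-m2 t})`. Defaults are the classic population values for a standard
#' 0.1 mmol/kg Gd-DTPA bolus (a1 = 3.99, a2 = 4.78 kg/l; m1 = 0.144,
#' m2 = 0.0111 min^-1); all fields are configurable because the plasma
#' kinetics of a given host strain are rarely measured directly.
#'
#' @param D Injected dose, mmol kg^-1.
#' @param a1,a2 Compartment amplitudes, kg l^-1.
#' @param m1,m2 Compartment clearance rates, min^-1; `m1 > m2`.
#' @return An object of class `aif_params`.
#' @export
aif_params <- function(D = 0.1, a1 = 3.99, a2 = 4.78, m1 = 0.144, m2 = 0.0111) {
  for (nm in c("D", "a1", "a2", "m1", "m2"))
    stop_if_not_scalar(get(nm), nm, lower = 0, strict_lower = TRUE)
  if (m1 <= m2)
    stop("'m1' must exceed 'm2' (fast then slow compartment)", call. = FALSE)
  structure(list(D = D, a1 = a1, a2 = a2, m1 = m1, m2 = m2),
            class = "aif_params")
}

#' Tracer kinetic parameters of the Tofts-Kermode model
#'
#' @param Ktrans Volume transfer constant, min^-1.
#' @param ve Extravascular extracellular volume fraction, in (0, 1).
#' @return Object of class `pk_params` with derived efflux rate
#'   `kep = Ktrans / ve` (min^-1).
#' @export
pk_params <- function(Ktrans, ve) {
  stop_if_not_scalar(Ktrans, "Ktrans", lower = 0)
  stop_if_not_scalar(ve, "ve", lower = 0, upper = 1, strict_lower = TRUE)
  if (ve >= 1) stop("'ve' must be < 1", call. = FALSE)
  structure(list(Ktrans = Ktrans, ve = ve, kep = Ktrans / ve),
            class = "pk_params")
}

#' Signal-to-concentration conversion configuration
#'
#' Linear fast-exchange conversion `C(t) = (R1(t) - baseline_R1) / r1`.
#' The default longitudinal relaxivity is a literature 7 T value for
#' Gd-DTPA.
#'
#' @param r1 Longitudinal relaxivity, s^-1 mM^-1.
#' @param baseline_R1 Pre-contrast tissue R1, s^-1.
#' @return Object of class `concentration_config`.
#' @export
concentration_config <- function(r1 = 3.8, baseline_R1 = 0.55) {
  stop_if_not_scalar(r1, "r1", lower = 0, strict_lower = TRUE)
  stop_if_not_scalar(baseline_R1, "baseline_R1", lower = 0)
  structure(list(r1 = r1, baseline_R1 = baseline_R1),
            class = "concentration_config")
}

#' Susceptibility constants converting USPIO-induced delta-R2* to fBV
#'
#' Fractional blood volume is obtained from the steady-state USPIO-induced
#' change in R2* as `fBV(%) = 100 * dR2* / kappa` with
#' `kappa = (4 pi / 3) gamma dchi B0`.
#'
#' @param gamma Proton gyromagnetic ratio, rad s^-1 T^-1.
#' @param delta_chi Susceptibility difference between fully USPIO-loaded
#'   blood and tissue, dimensionless (SI).
#' @param B0 Field strength, T.
#' @return Object of class `fbv_constants` with derived `kappa` (s^-1).
#' @export
fbv_constants <- function(gamma = 2.675e8, delta_chi = 2e-7, B0 = 7) {
  stop_if_not_scalar(gamma, "gamma", lower = 0, strict_lower = TRUE)
  stop_if_not_scalar(delta_chi, "delta_chi", lower = 0, strict_lower = TRUE)
  stop_if_not_scalar(B0, "B0", lower = 0, strict_lower = TRUE)
  structure(list(gamma = gamma, delta_chi = delta_chi, B0 = B0,
                 kappa = (4 * pi / 3) * gamma * delta_chi * B0),
            class = "fbv_constants")
}
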