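#' Mono-exponential diffusion-weighted signal
#'
#' `S(b) = S0 exp(-b ADC)`. ADC is expressed in mm^2 s^-1 here (the
#' reporting convention elsewhere in the package is 1e-6 mm^2 s^-1).
#'
#' @param S0 Unweighted signal, arbitrary units; `S0 >= 0`.
#' @param ADC Apparent diffusion coefficient, mm^2 s^-1; `ADC >= 0`.
#' @param b Diffusion weighting(s), s mm^-2; `b >= 0`.
#' @return Signal, same length as `b`.
#' @examples
#' dwi_signal(1000, 750e-6, 700)  # 591.55
#' @export
dwi_signal <- function(S0, ADC, b) {
  stop_if_not_scalar(S0, "S0", lower = 0)
  stop_if_not_scalar(ADC, "ADC", lower = 0)
  if (any(b < 0)) stop("negative b-value", call. = FALSE)
  S0 * exp(-b * ADC)
}

#' Multi-gradient-echo R2* decay signal
#'
#' `S(TE) = S0 exp(-TE R2*)`.
#'
#' @param S0 Signal at zero echo time, arbitrary units.
#' @param R2star Effective transverse relaxation rate, s^-1.
#' @param te Echo time(s), s.
#' @return Signal, same length as `te`.
#' @examples
#' mgre_signal(100, 50, 0.006)  # 74.08
#' @export
mgre_signal <- function(S0, R2star, te) {
  stop_if_not_scalar(S0, "S0", lower = 0)
  stop_if_not_scalar(R2star, "R2star", lower = 0)
  if (any(te < 0)) stop("negative echo time", call. = FALSE)
  S0 * exp(-te * R2star)
}

#' Three-parameter magnitude inversion-recovery signal
#'
#' `S(TI) = |A - B exp(-TI R1_app)|`, the magnitude recovery of an
#' inversion-recovery true-FISP readout. `A` is the asymptotic (driven
#' equilibrium) signal, `B` the recovery amplitude (`B >= A` for a full
#' inversion) and `R1_app` the apparent longitudinal rate, which mixes T1
#' and T2 contributions of the balanced readout.
#'
#' @param A Asymptotic signal, > 0.
#' @param B Recovery amplitude, `B >= A`.
#' @param R1_app Apparent relaxation rate, s^-1, > 0.
#' @param ti Inversion time(s), s.
#' @return Magnitude signal, same length as `ti`.
#' @export
ir_recovery_signal <- function(A, B, R1_app, ti) {
  stop_if_not_scalar(A, "A", lower = 0, strict_lower = TRUE)
  stop_if_not_scalar(B, "B", lower = A)
  stop_if_not_scalar(R1_app, "R1_app", lower = 0, strict_lower = TRUE)
  if (any(ti < 0)) stop("negative inversion time", call. = FALSE)
  abs(A - B * exp(-ti * R1_app))
}

#' Apparent-to-true longitudinal rate conversion
#'
#' The rapid repeated sampling of an inversion-recovery true-FISP train
#' drives recovery at an apparent rate faster than the true R1. With the
#' Look-Locker-type correction the true rate is recovered from the fitted
#' recovery amplitude ratio as `R1 = R1_app / (B/A - 1)`; with
#' `correction = "none"` the apparent rate is returned unchanged.
#'
#' @param A,B,R1_app Fitted recovery parameters (see
#'   [ir_recovery_signal()]).
#' @param correction `"look_locker"` or `"none"`.
#' @return True longitudinal rate R1, s^-1.
#' @export
r1_from_ir_fit <- function(A, B, R1_app,
                           correction = c("look_locker", "none")) {
  correction <- match.arg(correction)
  stop_if_not_scalar(R1_app, "R1_app", lower = 0, strict_lower = TRUE)
  if (correction == "none") return(R1_app)
  stop_if_not_scalar(A, "A", lower = 0, strict_lower = TRUE)
  stop_if_not_scalar(B, "B", lower = 0, strict_lower = TRUE)
  ratio <- B / A
  if (ratio <= 1)
    stop("non-physical inversion-recovery fit: B/A <= 1 under the ",
         "Look-Locker correction; reject this pixel", call. = FALSE)
  R1_app / (ratio - 1)
}

#' Population arterial input function
#'
#' Biexponential plasma concentration after a bolus:
#' `Cp(t) = D (a1 e^{-m1 t} + a2 e^{-m2 t})` for `t >= 0` (mM), and 0 for
#' `t < 0`. With dose in mmol kg^-1 and amplitudes in kg l^-1 the product
#' is mmol l^-1 = mM.
#'
#' @param t Time since injection, minutes; may be a vector.
#' @param aif An [aif_params()] object.
#' @return Plasma concentration, mM.
#' @examples
#' population_aif(0, aif_params())  # 0.877 mM
#' @export
population_aif <- function(t, aif = aif_params()) {
  stopifnot(inherits(aif, "aif_params"))
  cp <- aif$D * (aif$a1 * exp(-aif$m1 * t) + aif$a2 * exp(-aif$m2 * t))
  cp[t < 0] <- 0
  cp
}

# (e^{-m t} - e^{-kep t}) / (kep - m), stable as kep -> m.
.decay_diff <- function(t, kep, m) {
  d <- kep - m
  x <- d * t
  # exp(-kep t) * t * (expm1(x)/x); expm1(x)/x -> 1 as x -> 0
  f <- expm1(x) / x
  small <- abs(x) < 1e-8
  if (any(small)) f[small] <- 1 + x[small] / 2
  exp(-kep * t) * t * f
}

#' Tofts-Kermode tissue concentration
#'
#' Closed-form solution of the single-compartment leakage model
#' `Ct(t) = Ktrans \int_0^t Cp(u) e^{-kep (t - u)} du` for the
#' biexponential population input function:
#' `Ct(t) = D Ktrans sum_i a_i (e^{-m_i t} - e^{-kep t}) / (kep - m_i)`.
#'
#' @param t Time since injection, minutes; vectorised.
#' @param pk A [pk_params()] object (or list with `Ktrans`, `ve`).
#' @param aif An [aif_params()] object.
#' @return Tissue concentration, mM.
#' @export
tofts_concentration <- function(t, pk, aif = aif_params()) {
  stopifnot(inherits(aif, "aif_params"))
  if (any(t < 0)) stop("negative time since injection", call. = FALSE)
  Ktrans <- pk$Ktrans
  if (Ktrans == 0) return(rep(0, length(t)))
  kep <- pk$kep %||% (pk$Ktrans / pk$ve)
  aif$D * Ktrans * (aif$a1 * .decay_diff(t, kep, aif$m1) +
                    aif$a2 * .decay_diff(t, kep, aif$m2))
}

#' Convert a longitudinal relaxation rate series to concentration
#'
#' Linear fast-exchange conversion `C(t) = (R1(t) - baseline_R1) / r1`.
#'
#' @param r1_t Series of R1 values, s^-1.
#' @param cfg A [concentration_config()].
#' @return Concentration series, mM.
#' @export
concentration_from_r1 <- function(r1_t, cfg = concentration_config()) {
  stopifnot(inherits(cfg, "concentration_config"))
  if (length(r1_t) == 0) stop("empty R1 series", call. = FALSE)
  (r1_t - cfg$baseline_R1) / cfg$r1
}
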