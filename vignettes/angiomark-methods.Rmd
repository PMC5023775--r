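---
title: "Quantifying acute tumour vascular response: models, fitting and study simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying acute tumour vascular response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiomark)
```

# Scope

`angiomark` implements the quantitative analysis chain used to measure the
acute response of xenograft tumours to antiangiogenic antibodies with
multiparametric MRI, together with the companion cohort statistics, a
dual-species RNA-seq differential-expression stage, and histology
quantitation. Because no animal data ship with the package, every stage is
exercised end to end on synthetic inputs with known ground truth: digital
tumour phantoms rendered through the same closed-form signal models the
fitting stage inverts, negative-binomial count simulations, and
stain-mixture microscopy fields.

# Signal models

All forward models are closed-form and vectorised.

* **Diffusion**: `S(b) = S0 exp(-b ADC)`. ADC is carried internally in
  mm^2/s and reported in the conventional 1e-6 mm^2/s units.
* **Multi-gradient echo**: `S(TE) = S0 exp(-TE R2*)`.
* **IR true-FISP**: magnitude recovery `|A - B exp(-TI R1_app)|`. The
  balanced readout drives recovery at an apparent rate; the package models
  the dual-relaxation character of the sequence through the recovery
  amplitude ratio `B/A` and recovers the true longitudinal rate with a
  Look-Locker-type correction `R1 = R1_app / (B/A - 1)`. The exact T1/T2
  separation used by scanner-side in-house software is not published, so
  the correction is a selectable strategy (`look_locker` or `none`), not
  hard-coded physics.
* **Plasma input**: a population biexponential
  `Cp(t) = D (a1 e^{-m1 t} + a2 e^{-m2 t})` with the classic Gd-DTPA
  population constants (a1 = 3.99, a2 = 4.78 kg/l; m1 = 0.144,
  m2 = 0.0111 min^-1; D = 0.1 mmol/kg) as defaults. A murine AIF was never
  reported for this protocol; every constant is configurable.
* **Tissue leakage**: the original two-parameter Tofts–Kermode model
  without a plasma-volume term,
  `Ct(t) = Ktrans \int_0^t Cp(u) e^{-kep (t-u)} du`, evaluated by the exact
  biexponential solution (with a series-protected limit as `kep`
  approaches an AIF rate). Tests pin this closed form against adaptive
  quadrature of the convolution to below 1e-6 mM.
* **Concentration conversion**: linear fast exchange,
  `C = (R1 - R1_baseline)/r1`, with r1 = 3.8 s^-1 mM^-1 as a literature
  7 T Gd-DTPA value (configurable; also unpublished for the source
  protocol).
* **fBV**: `fBV(%) = 100 dR2*/kappa` with
  `kappa = (4 pi/3) gamma dchi B0 ≈ 1568.7 s^-1` at 7 T for fully
  USPIO-loaded blood (`gamma = 2.675e8 rad/s/T`, `dchi = 2e-7` SI). The
  calibration constant is configurable because published fBV work delegates
  it to instrument-specific values.

# MAP fitting

Maps are produced by pixel-wise maximum a posteriori estimation under a
Gaussian likelihood. Priors default to uniform over broad physical ranges
(`ADC` up to 4000e-6 mm^2/s, `R2*` up to 1000 s^-1, `Ktrans` up to
5 min^-1, `ve` in (0.01, 0.999)); with uniform priors the MAP estimate *is*
the nonlinear least-squares solution, which keeps the estimator auditable
against an independent grid-search oracle. Log-uniform and normal priors
are available where shrinkage is wanted; the noise standard deviation is
estimated from the residuals of a model-based initial fit unless fixed.

The reference engine (`map_estimate`) runs bounded L-BFGS-B from five
deterministic starts spread over the prior box plus a model-specific
closed-form initial value (log-linear regression for the exponential
decays), breaks ties by objective and then lexicographically, and finishes
with a damped Gauss-Newton polish. The polish matters: quasi-Newton
termination tests are objective-based and leave roughly 1e-6 relative
parameter error in flat directions, while the package asserts agreement
with an independent least-squares oracle at 1e-8.

Because all fitted models are linear in their amplitude, whole-ROI fitting
(`fit_map`, and the DCE chain) uses a separable ("variable projection")
formulation: the amplitude is profiled out analytically and the single
nonlinear parameter is located by a coarse grid bracket followed by a
golden-section refinement evaluated for *all pixels simultaneously*. This
is the same optimum as the per-pixel engine (tests assert equality) at a
small fraction of the cost, which is what makes the 100-replicate power
simulation tractable on one CPU. The `iters` argument controls the
golden-section depth; the default 64 iterations converge to numerical
precision, while the study runner uses 20 (and 12 for the per-frame
dynamic fits), which resolves rates far below the SNR-20 noise floor.

The IR true-FISP chain fits the 50-point baseline inversion block per pixel
for `(A, B, R1_app)` — restoring signal polarity around the magnitude
minimum, trying the three candidate crossing positions — and then fits each
dynamic frame only for its apparent rate with the amplitudes pinned at
their baseline values. Each pixel's own baseline R1 anchors the
concentration conversion, so pre-injection frames average to zero by
construction up to noise.

# Biomarkers

* **ADC**: median over converged in-mask pixels, 1e-6 mm^2/s.
* **Ktrans, ve**: Tofts fit of the per-pixel concentration course over the
  post-injection frames; medians over converged pixels. Pixels with
  all-zero concentration (or failed baseline fits) are flagged and
  excluded from medians — the handling of failed fits is a package
  convention, stated rather than inherited.
* **IAUGC60**: trapezoidal integral of `C(t)` over the first 60 s after
  injection in mM min, anchored at the first post-injection frame with
  linear interpolation at the window edge.
* **fBV**: R2* fitted before and after USPIO injection on identical echo
  schedules; `dR2*` converted by `kappa`. Negative `dR2*` pixels are
  retained and counted rather than clipped so cohort medians stay
  unbiased.
* **Volume**: ellipsoid calliper formula `L W^2 / 2` or ROI pixel
  summation; the study runner uses ROI volumes.

# The synthetic study

`make_phantom_study()` builds an ellipsoidal tumour with a 2-pixel
in-plane rim shell and draws per-pixel parameter maps from truncated
normals. Defaults are anchored to the cohort values the pipeline is meant
to reproduce: ADC 729e-6 mm^2/s, fBV 6.1%, Ktrans 0.2 min^-1 (a mid-range
choice — no baseline Ktrans is printed anywhere for this model), ve 0.3,
R2* 60 s^-1, R1 0.55 s^-1 (7 T tumour T1 near 1.8 s), S0 1000 a.u.
Treatment arms are `effect_spec()` objects: the bispecific-antibody arm
multiplies Ktrans by 0.6 with post-treatment enhancement confined to the
rim and shifts fBV by -2.7 percentage points; the isotype control arm only
grows (x2.66 over five days). Growth is a bare volume multiplier applied
to the in-plane semi-axes (the imaged slab is fixed by the protocol);
no kinetic growth model is implied. Newly grown pixels draw fresh baseline
values under a seed combining the subject and effect seeds, keeping arms
deterministic but subjects independent.

`simulate_mri_series()` renders the protocol: DW-EPI with 5 b-values
40–700 s/mm^2 at 4 averages; MGRE with 16 echoes from 6 ms at 4 ms spacing
and 16 averages, before and 2 min after USPIO; IR true-FISP with a
50-inversion baseline block (25–1451 ms, 8 averages) and 60 dynamic frames
(8 inversions 109–924 ms each) at 20 s resolution spanning 3 min before to
17 min after injection. Noise is zero-mean Gaussian with the in-mask mean
signal divided by `snr` as the single-average standard deviation, scaled
down by the square root of the schedule's averages; a noise-free series is
the exact forward model, which is what makes the generator → fit → truth
round-trip testable at 0.1%. Rician magnitude noise is deliberately not
the default: the Gaussian choice keeps the MAP ↔ least-squares equivalence
exactly testable, and at SNR 20 and above the difference is second order.

What the phantom does *not* emulate: k-space sampling, motion and
partial-volume effects, B1 inhomogeneity, water exchange, realistic tissue
texture, or inter-session registration error. Passing recovery tests
therefore demonstrate correctness of the estimators under their own
generative model, not robustness to scanner physics beyond it.

The default study geometry is deliberately desk-scale: one 14x14 slice
(~100 in-mask pixels) per subject for the replicated power simulation, a
32x32x3 phantom (~1000 pixels) for the exact-recovery checks, and a
28x28 slice (~390 pixels) for the noisy-recovery checks. Medians over
~100 pixels are already extremely stable, so the power study loses nothing
by not simulating 128x128 frames.

# Cohort statistics

Quantitative MRI biomarkers are summarised per subject as medians
("mean of medians" at the cohort level); volumes as means. The paired
pre/post comparison is an exact two-sided Wilcoxon signed-rank test: zero
differences are dropped (and counted), tied magnitudes get mid-ranks, and
for n ≤ 25 the null distribution is enumerated exactly by convolution over
the (doubled) rank weights — identical to enumerating all 2^n sign
patterns. Across arms, a between-subject two-way ANOVA
(treatment x timepoint) with per-timepoint treatment-vs-control contrasts
on the pooled residual variance, Bonferroni-multiplied by the number of
contrasts; the source legends do not state a repeated-measures structure,
so the factorial form is the default. Histology endpoints use one-way
ANOVA with Dunnett's many-to-one comparisons; the Dunnett adjustment is a
seeded 50 000-draw Monte Carlo sample of the balanced max-|t| null
(cached per design), which agrees with multivariate-t implementations to
about 0.01 and is auditable without numerical quadrature.

A note on calibration at small n: with n = 6 pairs the smallest attainable
two-sided exact Wilcoxon p is 1/32 ≈ 0.031, so the realised type-I error
at the 0.05 level is 0.031; with n = 7 it is 6/128 ≈ 0.047. The
calibration simulations therefore run at n = 7, the size of the control
cohort in the susceptibility-contrast experiment.

# RNA-seq stage

Reads from a tumour xenograft contain a human (tumour) and a murine
(stroma) component. The simulator draws, per sample, a multinomial split
of the library into human-only, mouse-only, both-species and unmapped
reads (defaults 0.504/0.126/0.07/0.30 of the library, i.e. 80/20 of the
uniquely mapped reads are human and 70% of all reads map to either
transcriptome), then distributes unambiguous reads over genes with
probabilities proportional to log-normal baseline weights times a
per-gene-and-sample gamma multiplier (negative-binomial marginals,
dispersion a design field) times `2^(log2 effect)` for spiked genes.
`disambiguate_reads()` discards both-species reads and counts the rest;
the returned truth count matrices equal what perfect disambiguation
recovers, which the tests assert exactly.

RPKM uses the composite gene length — the summed width of the union of a
gene's exons (merging overlapping and bookended intervals, via
`IRanges::reduce`) — and per-species mapped totals:
`RPKM = 1e9 count/(total x length)`. Zeros are handled by a +1 offset
before the log2 transform (configurable). Differential expression is a
per-gene one-way ANOVA on log2 RPKM via `aov()`, with treatment-vs-control
contrasts on the pooled variance; "correction across contrast pairs" is
implemented as Bonferroni over the three contrasts per gene (no
across-gene FDR, matching the raw-p criterion of the source analysis), and
the log2 ratio is the difference of group means of log2 values (not the
log2 of the ratio of means — the alternative is a documented switch of
interpretation, not of code). A gene-contrast is significant when the
corrected p < 0.05 and |log2 ratio| > 0.5. Exclusivity of significant
genes across antibodies is an exact set partition
(`classify_de_sets()`).

# Histology stage

Stained fields are quantified by: optical-density colour deconvolution
(`OD = -log10(I/I0)` unmixed by the inverse of a unit-norm stain matrix —
an exact linear inverse, round-tripping to numerical precision); positive
area fractions within hand-drawn ROIs under a fixed absolute threshold
(default) or Otsu's method; and microvessel density as the mean count of
4-connected components of at least 10 pixels across ≥5 fields (EBImage's
labelling is 4-connected, which matches the package convention). The
synthetic field generator composes discs or squares of a chosen stain by
Beer–Lambert mixing and returns exact truth masks. Necrosis quantitation
is an `area_fraction()` call on a user-supplied likelihood channel;
automated H&E necrosis classification is out of scope.

# Numerical conventions

* Time is seconds at the acquisition interface and minutes inside the
  tracer-kinetic model; `Ktrans`/`kep` are reported in min^-1.
* Golden-section refinement uses deterministic grid bracketing; grid-tie
  breaks take the first (lowest) candidate, so reruns are bit-identical.
* All generators accept a seed and restore the caller's RNG state; study
  runs derive per-subject seeds from the study seed, so an identical
  configuration reproduces outputs byte for byte.
* Degenerate inputs: all-zero pixels are flagged non-converged, never an
  error; empty ROIs, mismatched geometries or schedules, non-physical
  baselines and invalid exon intervals raise immediately with the offending
  field named.

# Known limitations

* The phantom's generative model and the fitting model coincide; recovery
  tests validate the inverse problem, not robustness to model
  misspecification (vp ≠ 0, water exchange, non-Gaussian noise).
* The IR dynamic fit pins the recovery amplitudes at baseline values;
  strong T2* changes after USPIO within the DCE session would violate
  this, but the two agents are simulated in separate sessions, as in the
  source protocol.
* The Dunnett Monte-Carlo adjustment has ~0.5% simulation noise on
  adjusted p-values near 0.05.
* Growth beyond what the phantom grid can hold is clipped at the grid
  boundary; size the geometry generously when volume is the endpoint.
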