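Package: angiomark
Title: Multiparametric MRI, Expression and Histology Biomarkers of Tumour
    Vascular Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying acute tumour vascular response to
    antiangiogenic therapy in xenograft studies. Implements closed-form MRI
    signal models (mono-exponential diffusion decay, multi-gradient-echo R2*
    decay, inversion-recovery true-FISP R1 dynamics, and the Tofts-Kermode
    pharmacokinetic model with a population arterial input function),
    pixel-wise Bayesian maximum a posteriori map fitting, and derived
    biomarkers: apparent diffusion coefficient (ADC), volume transfer
    constant (Ktrans), initial area under the gadolinium uptake curve
    (IAUGC60), and USPIO susceptibility-contrast fractional blood volume
    (fBV). Companion stages cover cohort statistics (exact paired Wilcoxon
    signed-rank, two-way ANOVA with Bonferroni post-tests, one-way ANOVA with
    Dunnett's test), dual-species xenograft RNA-seq read disambiguation with
    RPKM quantification and per-gene ANOVA differential expression, and
    immunohistochemistry quantitation via colour deconvolution, area
    fractions and microvessel density. Synthetic digital phantoms, simulated
    count data and simulated stain fields with known ground truth exercise
    the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite,
    IRanges,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    rtracklayer
Config/testthat/edition: 3
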