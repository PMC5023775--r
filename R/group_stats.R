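#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided exact signed-rank test for paired pre/post measurements.
#' Zero differences are dropped (their count is reported) and tied absolute
#' differences receive mid-ranks. For n <= 25 retained pairs the null
#' distribution of the positive-rank sum is enumerated exactly over all
#' 2^n sign assignments (computed by convolution over the rank weights,
#' which is the same enumeration organised efficiently); larger n falls
#' back to the normal approximation with continuity correction.
#'
#' @param pre,post Paired measurement vectors (equal length >= 3).
#' @return A `test_result` list: `statistic` (V, positive-rank sum),
#'   `p_value`, `adjusted_p` (= `p_value`), `method`, `n` (retained pairs),
#'   `n_zero` (dropped zero differences).
#' @export
paired_wilcoxon <- function(pre, post) {
  if (length(pre) != length(post))
    stop("'pre' and 'post' must be paired (equal length)", call. = FALSE)
  if (length(pre) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- post - pre
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0)
    stop("all paired differences are zero", call. = FALSE)
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25) {
    # exact null: convolve the +/- contribution of each rank; mid-ranks can
    # be half-integers, so work on doubled ranks
    w <- as.integer(round(2 * r))
    tot <- sum(w)
    f <- numeric(tot + 1)           # counts over doubled statistic 0..tot
    f[1] <- 1
    for (wi in w) {
      g <- numeric(tot + 1)
      g[(wi + 1):(tot + 1)] <- f[1:(tot + 1 - wi)]
      f <- f + g
    }
    probs <- f / 2^n
    v2 <- as.integer(round(2 * V))
    p_lo <- sum(probs[seq_len(v2 + 1)])
    p_hi <- sum(probs[(v2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (abs(V - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-z))
  }
  structure(list(statistic = V, p_value = p, adjusted_p = p,
                 method = "exact Wilcoxon matched-pairs signed-rank",
                 n = n, n_zero = n_zero),
            class = "test_result")
}

#' Two-way ANOVA with Bonferroni-corrected treatment-vs-control post-tests
#'
#' Between-subject factorial ANOVA of a biomarker on treatment and
#' timepoint, followed by per-timepoint contrasts of each treatment against
#' the control using the pooled residual variance; contrast p-values are
#' Bonferroni-multiplied by the number of contrasts performed.
#'
#' @param table Cohort data frame with columns `subject`, `treatment`,
#'   `timepoint`, `value` (see [cohort_summary()]).
#' @param control Control treatment label.
#' @return List: `anova` (data frame of F tests for treatment, timepoint
#'   and their interaction) and `contrasts` (data frame with one
#'   `test_result`-style row per treatment x timepoint contrast).
#' @export
two_way_anova_bonferroni <- function(table, control = "omalizumab") {
  table <- as.data.frame(table)
  stopifnot(all(c("treatment", "timepoint", "value") %in% names(table)))
  table$treatment <- factor(table$treatment)
  table$timepoint <- factor(table$timepoint)
  if (!control %in% levels(table$treatment))
    stop("control treatment absent from the table", call. = FALSE)
  cells <- table(table$treatment, table$timepoint)
  if (any(cells == 0)) stop("empty treatment x timepoint cell", call. = FALSE)
  if (nlevels(table$treatment) < 2 || nlevels(table$timepoint) < 2)
    stop("need >= 2 treatments and >= 2 timepoints", call. = FALSE)

  fit <- stats::aov(value ~ treatment * timepoint, data = table)
  an <- as.data.frame(summary(fit)[[1]])
  an$term <- trimws(rownames(an))
  names(an) <- c("df", "sum_sq", "mean_sq", "F", "p_value", "term")
  mse <- an$mean_sq[an$term == "Residuals"]
  df_res <- an$df[an$term == "Residuals"]

  trts <- setdiff(levels(table$treatment), control)
  tps <- levels(table$timepoint)
  k <- length(trts) * length(tps)
  rows <- list()
  for (tp in tps) for (tr in trts) {
    a <- table$value[table$treatment == tr & table$timepoint == tp]
    b <- table$value[table$treatment == control & table$timepoint == tp]
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    tstat <- (mean(a) - mean(b)) / se
    p <- 2 * stats::pt(-abs(tstat), df_res)
    rows[[length(rows) + 1]] <- data.frame(
      treatment = tr, timepoint = tp, diff = mean(a) - mean(b),
      statistic = tstat, df = df_res, p_value = p,
      adjusted_p = min(1, k * p), n = length(a) + length(b))
  }
  contrasts <- do.call(rbind, rows)
  contrasts$method <- "two-way ANOVA + Bonferroni contrast"
  contrasts$stars <- significance_stars(contrasts$adjusted_p)
  list(anova = an[, c("term", "df", "sum_sq", "mean_sq", "F", "p_value")],
       contrasts = contrasts)
}

# Cached max-|t| null samples for the Dunnett adjustment, keyed by
# (k treatments, per-group n, df). 50 000 draws under a fixed internal seed
# make the adjustment reproducible across sessions.
.dunnett_cache <- new.env(parent = emptyenv())

dunnett_null_sample <- function(k, n, df, draws = 50000L) {
  key <- paste(k, n, df, draws, sep = "_")
  if (!is.null(.dunnett_cache[[key]])) return(.dunnett_cache[[key]])
  s <- with_seed(191919L + k, {
    m_t <- matrix(stats::rnorm(draws * k, sd = 1 / sqrt(n)), draws, k)
    m_c <- stats::rnorm(draws, sd = 1 / sqrt(n))
    sp <- sqrt(stats::rchisq(draws, df) / df)
    tmax <- apply(abs(m_t - m_c) / (sp * sqrt(2 / n)), 1, max)
    sort(tmax)
  })
  .dunnett_cache[[key]] <- s
  s
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Omnibus one-way ANOVA across treatment groups followed by Dunnett-type
#' comparisons of every treatment against the control. Adjusted p-values
#' are the probability, under a seeded 50 000-draw Monte Carlo sample of
#' the balanced max-|t| null distribution, of a maximum statistic at least
#' as large as the observed one; with a single treatment the adjustment
#' reduces to the ordinary two-sample pooled t-test.
#'
#' @param groups Named list of numeric vectors, one per treatment group
#'   (including the control).
#' @param control Name of the control group.
#' @return List: `anova` (omnibus F and p), `comparisons` (data frame with
#'   statistic, raw and adjusted p per treatment).
#' @export
one_way_anova_dunnett <- function(groups, control = "omalizumab") {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (!control %in% names(groups))
    stop("control group missing", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs >= 2 values", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  mse <- an[["Mean Sq"]][2]
  df_res <- an[["Df"]][2]

  trts <- setdiff(names(groups), control)
  k <- length(trts)
  n_bal <- round(mean(lengths(groups)))
  ctrl <- groups[[control]]
  tstat <- vapply(trts, function(tr) {
    a <- groups[[tr]]
    (mean(a) - mean(ctrl)) /
      sqrt(mse * (1 / length(a) + 1 / length(ctrl)))
  }, numeric(1))
  p_raw <- 2 * stats::pt(-abs(tstat), df_res)
  adj <- if (k == 1) p_raw else {
    null_s <- dunnett_null_sample(k, n_bal, df_res)
    vapply(abs(tstat), function(tv)
      (length(null_s) - findInterval(tv, null_s)) / length(null_s),
      numeric(1))
  }
  comparisons <- data.frame(
    treatment = trts, statistic = tstat, df = df_res,
    p_value = p_raw, adjusted_p = pmax(pmin(adj, 1), 0),
    method = "one-way ANOVA + Dunnett (Monte Carlo)",
    stars = significance_stars(pmax(pmin(adj, 1), 0)))
  # Dunnett adjustment is never below the raw p
  comparisons$adjusted_p <- pmax(comparisons$adjusted_p, comparisons$p_value)
  list(anova = data.frame(F = an[["F value"]][1], df1 = an[["Df"]][1],
                          df2 = df_res, p_value = an[["Pr(>F)"]][1]),
       comparisons = comparisons)
}

#' Cohort summary statistics and per-subject percent change
#'
#' Mean, standard error and n of per-subject biomarker summaries for each
#' treatment x timepoint cell, plus the per-subject percent change
#' `100 (post - pre) / pre` for subjects with both timepoints.
#'
#' @param table Data frame with columns `subject`, `treatment`,
#'   `timepoint` (`"pre"`/`"post"`), `value`.
#' @return List: `cells` (mean, sem, n per treatment x timepoint) and
#'   `percent_change` (per subject; unpaired subjects are excluded and
#'   counted in `n_unpaired`).
#' @export
cohort_summary <- function(table) {
  table <- as.data.frame(table)
  stopifnot(nrow(table) > 0,
            all(c("subject", "treatment", "timepoint", "value") %in%
                  names(table)))
  agg <- stats::aggregate(value ~ treatment + timepoint, table, function(v)
    c(mean = mean(v), sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                            else NA_real_, n = length(v)))
  cells <- cbind(agg[c("treatment", "timepoint")], as.data.frame(agg$value))

  wide <- merge(table[table$timepoint == "pre",
                      c("subject", "treatment", "value")],
                table[table$timepoint == "post", c("subject", "value")],
                by = "subject", suffixes = c("_pre", "_post"))
  n_unpaired <- length(unique(table$subject)) - nrow(wide)
  pc <- data.frame(subject = wide$subject, treatment = wide$treatment,
                   percent_change = 100 * (wide$value_post - wide$value_pre) /
                     wide$value_pre)
  list(cells = cells, percent_change = pc, n_unpaired = n_unpaired)
}

#' Figure-legend significance stars
#'
#' `*` for p < 0.05, `**` for p < 0.01, `***` for p < 0.001.
#'
#' @param p Vector of p-values.
#' @return Character vector of stars (`""` when not significant).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) "" else if (pp < 0.001) "***" else if (pp < 0.01) "**"
    else if (pp < 0.05) "*" else ""
  }, character(1))
}
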