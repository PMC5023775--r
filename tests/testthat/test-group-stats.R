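test_that("exact Wilcoxon p equals literal sign-pattern enumeration", {
  set.seed(101)
  for (n in 3:10) {
    for (rep in 1:3) {
      pre <- rnorm(n, 10)
      post <- pre + rnorm(n)
      # occasionally force rank ties through duplicated magnitudes
      if (rep == 3) post[2] <- pre[2] + (post[1] - pre[1])
      expect_equal(paired_wilcoxon(pre, post)$p_value,
                   enumerate_wilcoxon_p(pre, post), tolerance = 1e-12)
    }
  }
})

test_that("Wilcoxon handles one-sided patterns, zeros and symmetry", {
  pre <- c(10, 12, 14, 16, 18, 20)
  post <- pre - c(1, 2, 3, 4, 5, 6)
  r <- paired_wilcoxon(pre, post)
  expect_equal(r$p_value, 2 / 2^6)
  # swapping pre and post leaves the two-sided p unchanged
  expect_equal(paired_wilcoxon(post, pre)$p_value, r$p_value)
  # zero differences are dropped and counted
  r0 <- paired_wilcoxon(c(1, 2, 3, 4, 5), c(1, 3, 2, 6, 7))
  expect_equal(r0$n_zero, 1)
  expect_equal(r0$n, 4)
  expect_error(paired_wilcoxon(1:5, 1:5), "zero")
  # balanced signs sit at the p = 1 boundary
  pre_b <- c(0, 0, 0, 0)
  post_b <- c(1, -1, 2, -2)
  expect_equal(paired_wilcoxon(pre_b, post_b)$p_value,
               enumerate_wilcoxon_p(pre_b, post_b))
})

test_that("two-way ANOVA F values match hand-computed sums of squares", {
  # balanced 2x2 with n = 2 per cell, integers chosen for exact arithmetic
  tab <- data.frame(
    subject = paste0("s", 1:8),
    treatment = rep(c("a", "omalizumab"), each = 4),
    timepoint = rep(rep(c("pre", "post"), each = 2), 2),
    value = c(10, 12, 20, 22, 30, 32, 40, 42))
  res <- two_way_anova_bonferroni(tab, control = "omalizumab")
  # hand sums of squares: grand mean 26; treatment SS = 8*10^2 ... computed
  cell_means <- with(tab, tapply(value, list(treatment, timepoint), mean))
  gm <- mean(tab$value)
  ss_trt <- 4 * sum((rowMeans(cell_means) - gm)^2)
  ss_tp <- 4 * sum((colMeans(cell_means) - gm)^2)
  ss_res <- sum((tab$value - ave(tab$value,
                                 tab$treatment, tab$timepoint))^2)
  ms_res <- ss_res / 4
  an <- res$anova
  expect_equal(an$F[an$term == "treatment"], (ss_trt / 1) / ms_res)
  expect_equal(an$F[an$term == "timepoint"], (ss_tp / 1) / ms_res)
  # Bonferroni multiplies by the number of contrasts, capped at 1
  expect_equal(res$contrasts$adjusted_p,
               pmin(1, nrow(res$contrasts) * res$contrasts$p_value))
})

test_that("two-way ANOVA null configuration yields no significance", {
  set.seed(7)
  tab <- expand.grid(subject = 1:6,
                     treatment = c("a", "b", "omalizumab"),
                     timepoint = c("pre", "post"))
  tab$value <- 100 + rnorm(nrow(tab))
  res <- two_way_anova_bonferroni(tab, control = "omalizumab")
  expect_true(all(res$anova$p_value[1:3] > 0.05))
  expect_true(all(res$contrasts$adjusted_p > 0.05))
  expect_error(two_way_anova_bonferroni(tab[tab$treatment != "omalizumab", ],
                                        control = "omalizumab"), "control")
})

test_that("Dunnett reduces to the pooled t-test for one treatment", {
  set.seed(3)
  g <- list(omalizumab = rnorm(6), trt = rnorm(6) + 1)
  r <- one_way_anova_dunnett(g)
  tt <- t.test(g$trt, g$omalizumab, var.equal = TRUE)
  expect_equal(r$comparisons$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(r$comparisons$adjusted_p, r$comparisons$p_value)
})

test_that("Dunnett Monte-Carlo adjustment matches the multivariate-t answer", {
  set.seed(5)
  g <- list(omalizumab = rnorm(6), a = rnorm(6) + 2.5, b = rnorm(6),
            c = rnorm(6) - 0.8)
  r <- one_way_anova_dunnett(g)
  expect_true(all(r$comparisons$adjusted_p >= r$comparisons$p_value))
  df <- data.frame(v = unlist(g),
                   g = factor(rep(names(g), each = 6), levels = names(g)))
  mc <- summary(multcomp::glht(aov(v ~ g, df),
                               linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(r$comparisons$adjusted_p, as.numeric(mc$test$pvalues),
               tolerance = 0.01)
  # jittered identical groups: nothing flagged
  g0 <- lapply(1:4, function(i) 5 + rnorm(6, sd = 1e-3))
  names(g0) <- c("omalizumab", "a", "b", "c")
  expect_true(all(one_way_anova_dunnett(g0)$comparisons$adjusted_p > 0.05))
})

test_that("cohort summaries report mean, sem and percent change", {
  tab <- data.frame(subject = c("s1", "s2", "s3", "s1", "s2", "s3"),
                    treatment = "vanucizumab",
                    timepoint = rep(c("pre", "post"), each = 3),
                    value = c(2, 4, 6, 3, 6, 9))
  cs <- cohort_summary(tab)
  pre_row <- cs$cells[cs$cells$timepoint == "pre", ]
  expect_equal(pre_row$mean, 4)
  expect_equal(pre_row$sem, 2 / sqrt(3), tolerance = 1e-6)
  expect_equal(sort(cs$percent_change$percent_change), c(50, 50, 50))
  # percent-change convention: 100 -> 152 is +52%
  tab2 <- data.frame(subject = "s1", treatment = "a",
                     timepoint = c("pre", "post"), value = c(100, 152))
  expect_equal(cohort_summary(tab2)$percent_change$percent_change, 52)
  # single subject: sem reported missing
  expect_true(is.na(cohort_summary(tab2)$cells$sem[1]))
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009)),
               c("", "*", "**", "***"))
})
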