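# Independent oracles used across the suite. Each reimplements the quantity
# under test by a different route (literal enumeration, quadrature, grid
# search, per-base tabulation) and must stay independent of the package's
# own code paths.

# Two-sided exact signed-rank p by literal enumeration of all 2^n sign
# assignments (n small).
enumerate_wilcoxon_p <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Tofts tissue concentration by adaptive quadrature of the convolution
# integral (no closed form).
quadrature_tofts <- function(t_min, Ktrans, ve, aif) {
  kep <- Ktrans / ve
  vapply(t_min, function(tt) {
    if (tt == 0) return(0)
    Ktrans * stats::integrate(function(u)
      aif$D * (aif$a1 * exp(-aif$m1 * u) + aif$a2 * exp(-aif$m2 * u)) *
        exp(-kep * (tt - u)),
      0, tt, rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, numeric(1))
}

# Grid-refined least-squares oracle for the 2-parameter exponential decay
# c * exp(-x * theta): dense grid then Gauss-Newton to numerical precision.
ls_grid_polish_oracle <- function(x, y, lo, hi, n_grid = 80) {
  g1 <- seq(max(lo[1], 1e-3), hi[1], length.out = n_grid)
  g2 <- seq(lo[2], hi[2], length.out = n_grid)
  gg <- as.matrix(expand.grid(g1, g2))
  rss <- vapply(seq_len(nrow(gg)), function(i)
    sum((y - gg[i, 1] * exp(-x * gg[i, 2]))^2), numeric(1))
  th <- gg[which.min(rss), ]
  for (it in 1:100) {
    e <- exp(-x * th[2]); r <- y - th[1] * e
    J <- cbind(e, -th[1] * x * e)
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    f0 <- sum(r^2)
    ftol <- 4 * .Machine$double.eps * f0
    repeat {
      cand <- pmin(pmax(th + lam * as.numeric(step), lo), hi)
      f1 <- sum((y - cand[1] * exp(-x * cand[2]))^2)
      if (f1 <= f0 + ftol || lam < 1e-10) break
      lam <- lam / 2
    }
    if (f1 > f0 + ftol) break
    done <- max(abs(cand - th) / pmax(abs(th), 1e-12)) < 1e-15
    th <- cand
    if (done) break
  }
  th
}

# Union length of integer intervals by per-base occupancy.
per_base_union_length <- function(exons) {
  hi <- max(exons[, 2])
  covered <- logical(hi)
  for (i in seq_len(nrow(exons)))
    covered[(exons[i, 1] + 1):exons[i, 2]] <- TRUE
  sum(covered)
}

# One-way ANOVA F statistic from hand-computed sums of squares.
hand_anova_F <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- mean(values)
  ss_b <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ss_w <- sum(unlist(tapply(values, groups, function(v) (v - mean(v))^2)))
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  (ss_b / df_b) / (ss_w / df_w)
}

# Small noise-free phantom shared by several tests.
tiny_phantom <- function(geometry = c(1, 16, 16), sd0 = TRUE, seed = 5) {
  bp <- if (sd0) list(adc = c(729e-6, 0), ktrans = c(0.2, 0), ve = c(0.3, 0),
                      r2star = c(60, 0), fbv = c(6.1, 0), s0 = c(1000, 0),
                      r1 = c(0.55, 0))
        else list()
  make_phantom_study(geometry, baseline_params = bp, effect = effect_spec(),
                     seed = seed)
}
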