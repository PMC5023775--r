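#' Parameter prior specifications for MAP fitting
#'
#' Builders for the per-parameter priors consumed by [map_estimate()] and
#' [fit_map()]. Every prior carries hard bounds that double as the
#' optimisation box. The package default is a uniform prior over a broad
#' physical range, which makes the maximum a posteriori estimate coincide
#' with the nonlinear least-squares solution and therefore auditable.
#'
#' @param lo,hi Hard bounds (lo < hi).
#' @param mean,sd Location and scale of the normal prior.
#' @return A `prior` object.
#' @name priors
NULL

#' @rdname priors
#' @export
prior_uniform <- function(lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("uniform prior needs finite lo < hi", call. = FALSE)
  structure(list(dist = "uniform", lo = lo, hi = hi), class = "prior")
}

#' @rdname priors
#' @export
prior_log_uniform <- function(lo, hi) {
  if (lo <= 0 || lo >= hi || !is.finite(hi))
    stop("log-uniform prior needs 0 < lo < hi < Inf", call. = FALSE)
  structure(list(dist = "log_uniform", lo = lo, hi = hi), class = "prior")
}

#' @rdname priors
#' @export
prior_normal <- function(mean, sd, lo = mean - 6 * sd, hi = mean + 6 * sd) {
  if (sd <= 0) stop("normal prior needs sd > 0", call. = FALSE)
  if (lo >= hi) stop("normal prior needs lo < hi", call. = FALSE)
  structure(list(dist = "normal", lo = lo, hi = hi, mean = mean, sd = sd),
            class = "prior")
}

#' @param ... Named `prior` objects, one per model parameter.
#' @rdname priors
#' @export
prior_spec <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !inherits(ps[[1]], "prior"))
    ps <- ps[[1]]
  if (is.null(names(ps)) || any(names(ps) == ""))
    stop("priors must be named after model parameters", call. = FALSE)
  if (!all(vapply(ps, inherits, TRUE, "prior")))
    stop("every element must be a 'prior'", call. = FALSE)
  structure(ps, class = "prior_spec")
}

neg_log_prior <- function(theta, priors) {
  s <- 0
  for (j in seq_along(theta)) {
    p <- priors[[j]]
    s <- s + switch(p$dist,
      uniform = 0,
      log_uniform = log(max(theta[j], 1e-300)),
      normal = 0.5 * ((theta[j] - p$mean) / p$sd)^2)
  }
  s
}

neg_log_prior_grad <- function(theta, priors) {
  vapply(seq_along(theta), function(j) {
    p <- priors[[j]]
    switch(p$dist,
      uniform = 0,
      log_uniform = 1 / max(theta[j], 1e-300),
      normal = (theta[j] - p$mean) / p$sd^2)
  }, numeric(1))
}

prior_hess <- function(theta, priors) {
  vapply(seq_along(theta), function(j) {
    p <- priors[[j]]
    switch(p$dist,
      uniform = 0,
      log_uniform = -1 / max(theta[j], 1e-300)^2,
      normal = 1 / p$sd^2)
  }, numeric(1))
}

all_uniform <- function(priors)
  all(vapply(priors, function(p) p$dist == "uniform", TRUE))

# ---- model registry -------------------------------------------------------

# d/dkep of (e^{-m t} - e^{-kep t})/(kep - m), stable as kep -> m
.decay_diff_dkep <- function(t, kep, m) {
  d <- kep - m
  x <- d * t
  ek <- exp(-kep * t)
  psi <- .decay_diff(t, kep, m)
  ifelse(abs(x) < 1e-6,
         -t^2 * ek * (0.5 + x / 6),
         (t * ek - psi) / d)
}

model_spec <- function(model, aif = NULL) {
  switch(model,
    dwi = list(
      params = c("S0", "ADC"),
      forward = function(theta, x) theta[1] * exp(-x * theta[2]),
      jac = function(theta, x) {
        e <- exp(-x * theta[2])
        cbind(e, -theta[1] * x * e)
      },
      default_priors = function(x, y) prior_spec(
        S0 = prior_uniform(0, max(10 * max(abs(y)), 1)),
        ADC = prior_uniform(0, 4e-3)),
      smart_init = function(x, y) {
        ok <- y > 0
        if (sum(ok) >= 2) {
          fit <- stats::lm.wfit(cbind(1, x[ok]), log(y[ok]), w = y[ok]^2)
          c(exp(fit$coefficients[1]), max(-fit$coefficients[2], 0))
        } else c(max(y), 1e-3)
      }),
    mgre = list(
      params = c("S0", "R2star"),
      forward = function(theta, x) theta[1] * exp(-x * theta[2]),
      jac = function(theta, x) {
        e <- exp(-x * theta[2])
        cbind(e, -theta[1] * x * e)
      },
      default_priors = function(x, y) prior_spec(
        S0 = prior_uniform(0, max(10 * max(abs(y)), 1)),
        R2star = prior_uniform(0, 1000)),
      smart_init = function(x, y) {
        ok <- y > 0
        if (sum(ok) >= 2) {
          fit <- stats::lm.wfit(cbind(1, x[ok]), log(y[ok]), w = y[ok]^2)
          c(exp(fit$coefficients[1]), max(-fit$coefficients[2], 0))
        } else c(max(y), 50)
      }),
    ir = list(
      params = c("A", "B", "R1_app"),
      forward = function(theta, x)
        abs(theta[1] - theta[2] * exp(-x * theta[3])),
      jac = function(theta, x) {
        e <- exp(-x * theta[3])
        s <- sign(theta[1] - theta[2] * e)
        cbind(s, -s * e, s * theta[2] * x * e)
      },
      default_priors = function(x, y) prior_spec(
        A = prior_uniform(1e-9, max(10 * max(abs(y)), 1)),
        B = prior_uniform(1e-9, max(20 * max(abs(y)), 1)),
        R1_app = prior_uniform(0.02, 50)),
      smart_init = function(x, y) {
        A0 <- max(mean(y[x >= stats::median(x)]), 1e-6)
        c(A0, 2 * A0, 1 / max(x[which.min(y)], 1e-3))
      }),
    tofts = list(
      params = c("Ktrans", "ve"),
      forward = function(theta, x)
        tofts_concentration(x, list(Ktrans = theta[1], ve = theta[2]), aif),
      jac = function(theta, x) {
        kep <- theta[1] / theta[2]
        h <- aif$D * (aif$a1 * .decay_diff(x, kep, aif$m1) +
                      aif$a2 * .decay_diff(x, kep, aif$m2))
        hp <- aif$D * (aif$a1 * .decay_diff_dkep(x, kep, aif$m1) +
                       aif$a2 * .decay_diff_dkep(x, kep, aif$m2))
        cbind(h + theta[1] * hp / theta[2],
              -theta[1]^2 * hp / theta[2]^2)
      },
      default_priors = function(x, y) prior_spec(
        Ktrans = prior_uniform(0, 5),
        ve = prior_uniform(0.01, 0.999)),
      smart_init = function(x, y) c(0.2, 0.3)),
    stop(sprintf("unknown model '%s'", model), call. = FALSE))
}

#' Result of a single-pixel MAP fit
#'
#' @param estimates Named parameter vector.
#' @param objective Negative log posterior at the optimum (additive
#'   constants dropped).
#' @param converged Logical.
#' @param n_iter Objective evaluations used.
#' @param noise_sd Noise standard deviation used in the likelihood.
#' @return Object of class `fit_result`.
#' @keywords internal
fit_result <- function(estimates, objective, converged, n_iter, noise_sd) {
  structure(list(estimates = estimates, objective = objective,
                 converged = converged, n_iter = n_iter,
                 noise_sd = noise_sd),
            class = "fit_result")
}

#' Pixelwise Bayesian maximum a posteriori estimate
#'
#' Maximises the Gaussian log-likelihood plus log prior for one pixel by
#' bounded quasi-Newton (`L-BFGS-B`) optimisation with analytic gradients,
#' started from five deterministic points spread over the prior box plus a
#' model-specific closed-form initial value. Ties between starts are broken
#' by lowest objective, then lexicographically smallest parameter vector.
#' With uniform priors the estimate equals the nonlinear least-squares
#' solution.
#'
#' @param model `"dwi"`, `"mgre"`, `"ir"` or `"tofts"`.
#' @param x Sample coordinates (b-values s mm^-2, echo times s, inversion
#'   times s, or minutes post injection for `"tofts"`).
#' @param y Signal (or concentration, for `"tofts"`) at each coordinate.
#' @param priors A [prior_spec()]; broad uniform defaults when `NULL`.
#' @param noise_sd Gaussian noise standard deviation, or `"estimate"` to
#'   estimate it from the residuals of the model-based initial fit.
#' @param aif An [aif_params()], used by the `"tofts"` model.
#' @param maxit Maximum iterations per start.
#' @return A `fit_result` (estimates, objective, converged, n_iter,
#'   noise_sd). All-zero signals are flagged non-converged rather than
#'   raising an error.
#' @export
map_estimate <- function(model, x, y, priors = NULL, noise_sd = "estimate",
                         aif = aif_params(), maxit = 500L) {
  spec <- model_spec(model, aif)
  p <- length(spec$params)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("'x' and 'y' lengths differ", call. = FALSE)
  if (length(y) < p)
    stop(sprintf("need at least %d samples for model '%s'", p, model),
         call. = FALSE)
  if (all(y == 0))
    return(fit_result(stats::setNames(rep(NA_real_, p), spec$params),
                      NA_real_, FALSE, 0L, NA_real_))
  if (is.null(priors)) priors <- spec$default_priors(x, y)
  if (!identical(sort(names(priors)), sort(spec$params)))
    stop("priors must be named exactly after the model parameters: ",
         paste(spec$params, collapse = ", "), call. = FALSE)
  priors <- priors[spec$params]
  lo <- vapply(priors, `[[`, numeric(1), "lo")
  hi <- vapply(priors, `[[`, numeric(1), "hi")

  init <- pmin(pmax(spec$smart_init(x, y), lo), hi)
  sigma <- if (identical(noise_sd, "estimate")) {
    r <- y - spec$forward(init, x)
    max(sqrt(sum(r^2) / max(length(y) - p, 1)), 1e-9 * mean(abs(y)), 1e-12)
  } else {
    stopifnot(is.numeric(noise_sd), noise_sd > 0)
    noise_sd
  }

  inv_var <- if (is.finite(sigma)) 1 / sigma^2 else 0
  fn <- function(theta) {
    r <- y - spec$forward(theta, x)
    0.5 * sum(r^2) * inv_var + neg_log_prior(theta, priors)
  }
  gr <- function(theta) {
    r <- y - spec$forward(theta, x)
    J <- spec$jac(theta, x)
    -as.numeric(crossprod(J, r)) * inv_var + neg_log_prior_grad(theta, priors)
  }

  # 5 deterministic starts over the prior box (staggered quantiles) + init
  q <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  starts <- lapply(seq_along(q), function(i) {
    frac <- q[((i + seq_len(p) - 2L) %% length(q)) + 1L]
    lo + frac * (hi - lo)
  })
  starts <- c(starts, list(init))

  scale <- pmax(abs(hi - lo) / 10, 1e-10)
  best <- NULL
  n_eval <- 0L
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, fn, gr, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = maxit, factr = 10, pgtol = 0,
                                  parscale = scale)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_eval <- n_eval + res$counts[1]
    if (is.null(best) || res$value < best$value - 1e-12 * abs(best$value) ||
        (abs(res$value - best$value) <= 1e-12 * abs(best$value) &&
         .lex_less(res$par, best$par)))
      best <- res
  }
  if (is.null(best))
    return(fit_result(stats::setNames(rep(NA_real_, p), spec$params),
                      NA_real_, FALSE, n_eval, sigma))

  # Gauss-Newton polish to numerical precision (quasi-Newton termination is
  # objective-based and leaves ~1e-6 relative parameter error behind)
  theta <- best$par
  f_cur <- best$value
  interior <- function(th) all(th > lo + 1e-12 * (hi - lo) &
                               th < hi - 1e-12 * (hi - lo))
  if (interior(theta)) {
    for (it in seq_len(30L)) {
      r <- y - spec$forward(theta, x)
      J <- spec$jac(theta, x)
      H <- crossprod(J) * inv_var + diag(prior_hess(theta, priors), p)
      g <- -as.numeric(crossprod(J, r)) * inv_var +
        neg_log_prior_grad(theta, priors)
      step <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      improved <- FALSE
      ftol <- 4 * .Machine$double.eps * (abs(f_cur) + 1e-300)
      for (h in 1:10) {
        cand <- pmin(pmax(theta + lam * step, lo), hi)
        f_new <- fn(cand)
        if (is.finite(f_new) && f_new <= f_cur + ftol) {
          improved <- any(cand != theta)
          theta <- cand; f_cur <- min(f_new, f_cur)
          break
        }
        lam <- lam / 2
      }
      n_eval <- n_eval + h
      if (!improved || max(abs(lam * step) / pmax(abs(theta), 1e-12)) < 1e-14)
        break
    }
  }
  fit_result(stats::setNames(theta, spec$params), f_cur,
             best$convergence == 0, as.integer(n_eval), sigma)
}

.lex_less <- function(a, b) {
  for (j in seq_along(a)) {
    if (a[j] < b[j]) return(TRUE)
    if (a[j] > b[j]) return(FALSE)
  }
  FALSE
}

# ---- vectorised separable least squares -----------------------------------
#
# The decay models fitted here are linear in their amplitude: S = c * g(theta).
# Profiling out c reduces the pixelwise least-squares problem to a 1-D search
# over theta, which is carried out for all pixels simultaneously (grid
# bracketing + golden-section refinement). Under uniform priors this equals
# the MAP estimate and is what fit_map uses for whole maps.

# Vectorised golden-section minimisation: f maps a vector of candidate
# positions (one per column/problem) to a vector of objective values.
golden_min_vec <- function(f, lo, hi, iters = 64L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(iters)) {
    upd <- f1 < f2
    b[upd] <- x2[upd]; x2[upd] <- x1[upd]; f2[upd] <- f1[upd]
    a[!upd] <- x1[!upd]; x1[!upd] <- x2[!upd]; f1[!upd] <- f2[!upd]
    x1[upd] <- b[upd] - gr * (b[upd] - a[upd])
    x2[!upd] <- a[!upd] + gr * (b[!upd] - a[!upd])
    xnew <- ifelse(upd, x1, x2)
    fnew <- f(xnew)
    f1[upd] <- fnew[upd]; f2[!upd] <- fnew[!upd]
  }
  ifelse(f1 < f2, x1, x2)
}

# Exponential decay c*exp(-x theta) fitted to all columns of Y (length(x)
# rows). Returns amplitude, rate and RSS per column.
fit_exp_decay_cols <- function(Y, x, lo, hi, grid_n = 24L, iters = 64L) {
  Y <- as.matrix(Y)
  yy <- colSums(Y^2)
  rss_at <- function(theta) {
    G <- exp(-outer(x, theta))
    gy <- pmax(colSums(G * Y), 0)
    yy - gy^2 / colSums(G^2)
  }
  grid <- seq(lo, hi, length.out = grid_n)
  R <- matrix(vapply(grid, function(th) rss_at(rep(th, ncol(Y))),
                     numeric(ncol(Y))), nrow = ncol(Y))
  k <- max.col(-R, ties.method = "first")   # per-column best grid index
  a <- grid[pmax(k - 1L, 1L)]
  b <- grid[pmin(k + 1L, grid_n)]
  theta <- golden_min_vec(rss_at, a, b, iters = iters)
  G <- exp(-outer(x, theta))
  cc <- pmax(colSums(G * Y), 0) / colSums(G^2)
  rss <- colSums((Y - G * rep(cc, each = length(x)))^2)
  list(amplitude = cc, rate = theta, rss = rss)
}

# Tofts model Ct = Ktrans * h(kep; t) fitted to all columns of C (length(t)
# rows, minutes post injection). Profile over kep; Ktrans is the nonnegative
# linear coefficient.
fit_tofts_cols <- function(C, t_min, aif = aif_params(),
                           kep_lo = 0.01, kep_hi = 20, grid_n = 32L,
                           iters = 64L) {
  C <- as.matrix(C)
  yy <- colSums(C^2)
  basis <- function(kep) {                # length(t) x length(kep)
    Tm <- matrix(t_min, length(t_min), length(kep))
    Km <- matrix(kep, length(t_min), length(kep), byrow = TRUE)
    ek <- exp(-Km * Tm)                   # shared between both AIF terms
    term <- function(m, a) {
      x <- (Km - m) * Tm
      f <- expm1(x) / x
      small <- abs(x) < 1e-8
      if (any(small)) f[small] <- 1 + x[small] / 2
      a * Tm * ek * f
    }
    aif$D * (term(aif$m1, aif$a1) + term(aif$m2, aif$a2))
  }
  rss_at <- function(kep) {
    G <- basis(kep)
    gy <- pmax(colSums(G * C), 0)
    yy - gy^2 / colSums(G^2)
  }
  grid <- exp(seq(log(kep_lo), log(kep_hi), length.out = grid_n))
  R <- matrix(vapply(grid, function(th) rss_at(rep(th, ncol(C))),
                     numeric(ncol(C))), nrow = ncol(C))
  k <- max.col(-R, ties.method = "first")
  a <- grid[pmax(k - 1L, 1L)]
  b <- grid[pmin(k + 1L, grid_n)]
  kep <- golden_min_vec(rss_at, a, b, iters = iters)
  G <- basis(kep)
  Ktrans <- pmax(colSums(G * C), 0) / colSums(G^2)
  rss <- colSums((C - G * rep(Ktrans, each = length(t_min)))^2)
  list(Ktrans = Ktrans, kep = kep, ve = ifelse(Ktrans > 0, Ktrans / kep, NA),
       rss = rss)
}

#' Fit a signal model over every in-mask pixel of a series
#'
#' Runs the MAP estimator pixel by pixel over the ROI and assembles one
#' [parametric_map()] per model parameter. With uniform priors (the
#' default) the estimator reduces to nonlinear least squares and a
#' vectorised separable solver is used; with informative priors each pixel
#' goes through [map_estimate()] individually.
#'
#' @param model `"dwi"` or `"mgre"`.
#' @param series An [image_series()] of the matching modality.
#' @param mask An [roi_mask()] with the same geometry.
#' @param priors A [prior_spec()]; defaults to broad uniform priors.
#' @param noise_sd Passed to [map_estimate()] (pixelwise path only).
#' @param iters Golden-section refinement iterations of the vectorised
#'   solver (64 gives convergence to numerical precision).
#' @return Named list of [parametric_map()]s, one per parameter.
#' @export
fit_map <- function(model = c("dwi", "mgre"), series, mask, priors = NULL,
                    noise_sd = "estimate", iters = 64L) {
  model <- match.arg(model)
  stopifnot(inherits(series, "image_series"), inherits(mask, "roi_mask"))
  check_geometry(series, mask)
  if (series$modality != model)
    stop(sprintf("series modality '%s' does not match model '%s'",
                 series$modality, model), call. = FALSE)
  x <- switch(model, dwi = series$schedule$b_values,
              mgre = series$schedule$echo_times)
  Y <- mask_signal_matrix(series, mask)
  spec <- model_spec(model)
  if (is.null(priors)) priors <- spec$default_priors(x, as.numeric(Y))
  priors <- priors[spec$params]
  lo <- vapply(priors, `[[`, numeric(1), "lo")
  hi <- vapply(priors, `[[`, numeric(1), "hi")

  zero <- colSums(Y != 0) == 0
  if (all_uniform(priors)) {
    fit <- fit_exp_decay_cols(Y, x, lo = lo[2], hi = hi[2], iters = iters)
    amp <- pmin(fit$amplitude, hi[1])
    est <- rbind(amp, fit$rate)
    conv <- !zero & is.finite(fit$rss)
  } else {
    est <- matrix(NA_real_, 2, ncol(Y))
    conv <- logical(ncol(Y))
    for (i in seq_len(ncol(Y))) {
      fr <- map_estimate(model, x, Y[, i], priors = priors,
                         noise_sd = noise_sd)
      est[, i] <- fr$estimates
      conv[i] <- fr$converged
    }
  }
  est[, zero] <- NA_real_
  conv[zero] <- FALSE
  prov <- list(model = model, priors = priors, n_samples = length(x))
  units <- switch(model, dwi = c("a.u.", "mm^2/s"),
                  mgre = c("a.u.", "1/s"))
  out <- lapply(seq_along(spec$params), function(j)
    parametric_map(unmask(est[j, ], mask), spec$params[j], units[j],
                   converged = unmask_logical(conv, mask),
                   provenance = prov))
  names(out) <- spec$params
  out
}

unmask_logical <- function(flags, mask) {
  out <- array(NA, dim(mask$mask))
  out[mask$mask] <- flags
  out
}
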