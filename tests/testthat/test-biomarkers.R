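test_that("ADC median of a uniform phantom equals the common value", {
  st <- tiny_phantom(c(1, 14, 14))
  m <- roi_mask(st$pre$mask)
  ser <- simulate_mri_series(st$pre, "dwi")
  res <- compute_adc_map(ser, m)
  expect_equal(res$median, 729, tolerance = 1e-5)
  expect_equal(res$n_converged, sum(m$mask))
  expect_error(compute_adc_map(
    simulate_mri_series(st$pre, "dwi",
                        acquisition_schedule(b_values = c(100, 700))), m),
    "3 b-values")
})

test_that("concentration extraction returns zero without contrast change", {
  st <- make_phantom_study(c(1, 12, 12),
                           baseline_params = list(ktrans = c(1e-4, 0)),
                           effect = effect_spec(), seed = 2)
  st$pre$ktrans[] <- 0
  m <- roi_mask(st$pre$mask)
  ser <- simulate_mri_series(st$pre, "ir_truefisp_dce", aif = aif_params())
  cs <- compute_concentration_series(ser, m)
  expect_lt(max(abs(cs$conc)), 1e-6)
})

test_that("full DCE round trip recovers the generating concentrations", {
  st <- tiny_phantom(c(1, 12, 12))
  m <- roi_mask(st$pre$mask)
  ser <- simulate_mri_series(st$pre, "ir_truefisp_dce", aif = aif_params())
  cs <- compute_concentration_series(ser, m)
  sch <- ser$schedule
  t_min <- pmax(sch$frame_times - sch$injection_time, 0) / 60
  truth_ct <- tofts_concentration(t_min, pk_params(0.2, 0.3), aif_params())
  truth_ct[sch$frame_times < sch$injection_time] <- 0
  for (i in c(1, ncol(cs$conc) %/% 2))
    expect_equal(unname(cs$conc[i, ]), truth_ct, tolerance = 1e-3)
  # pre-injection frames average to zero
  expect_lt(max(abs(cs$conc[, sch$frame_times < sch$injection_time])), 1e-6)
})

test_that("Ktrans and ve maps recover a parameter grid noise-free", {
  st <- tiny_phantom(c(1, 16, 16))
  grid_kt <- seq(0.05, 0.5, length.out = 4)
  grid_ve <- seq(0.1, 0.5, length.out = 4)
  idx <- which(st$pre$mask)
  combos <- expand.grid(kt = grid_kt, ve = grid_ve)
  for (i in seq_len(nrow(combos))) {
    st$pre$ktrans[idx[i]] <- combos$kt[i]
    st$pre$ve[idx[i]] <- combos$ve[i]
  }
  m <- roi_mask(st$pre$mask)
  ser <- simulate_mri_series(st$pre, "ir_truefisp_dce", aif = aif_params())
  kv <- compute_ktrans_ve_maps(compute_concentration_series(ser, m))
  got_kt <- kv$ktrans$values[idx[seq_len(nrow(combos))]]
  got_ve <- kv$ve$values[idx[seq_len(nrow(combos))]]
  expect_equal(got_kt, combos$kt, tolerance = 5e-3, ignore_attr = TRUE)
  expect_equal(got_ve, combos$ve, tolerance = 5e-3, ignore_attr = TRUE)
})

test_that("null-Ktrans pixels fit to (near) zero and are excluded", {
  st <- tiny_phantom(c(1, 12, 12))
  idx <- which(st$pre$mask)
  st$pre$ktrans[idx[1:3]] <- 0
  m <- roi_mask(st$pre$mask)
  ser <- simulate_mri_series(st$pre, "ir_truefisp_dce", aif = aif_params())
  kv <- compute_ktrans_ve_maps(compute_concentration_series(ser, m))
  expect_true(all(kv$ktrans$values[idx[1:3]] <= 1e-4))
})

test_that("IAUGC60 integrates constants, ramps and zeros exactly", {
  mk_conc <- function(C, times, inj) {
    mask <- roi_mask(array(TRUE, c(1, 1, nrow(C))))
    structure(list(conc = C, frame_times = times, injection_time = inj,
                   converged = rep(TRUE, nrow(C)), mask = mask),
              class = "concentration_series")
  }
  times <- seq(0, 300, by = 20)
  inj <- 100
  zeroC <- matrix(0, 1, length(times))
  expect_equal(compute_iaugc60(mk_conc(zeroC, times, inj))$median, 0)
  constC <- matrix(1.2 * (times >= inj), 1, byrow = TRUE,
                   ncol = length(times))
  expect_equal(compute_iaugc60(mk_conc(constC, times, inj))$median, 1.2,
               tolerance = 1e-12)
  # linear ramp 0 -> 1 mM over the 60 s window: integral 0.5 mM min
  ramp <- pmin(pmax((times - inj) / 60, 0), 1)
  expect_equal(compute_iaugc60(mk_conc(matrix(ramp, 1), times, inj))$median,
               0.5, tolerance = 1e-12)
  # dense-grid quadrature oracle for the ramp
  tq <- seq(0, 60, by = 0.01)
  expect_equal(0.5, sum(diff(tq) * (head(tq, -1) + tail(tq, -1)) / 2) /
                 60 / 60, tolerance = 1e-4)
  # frame-time unit invariance (seconds vs minutes)
  cs_min <- mk_conc(matrix(ramp, 1), times / 60, inj / 60)
  expect_equal(compute_iaugc60(cs_min, time_unit = "min")$median, 0.5,
               tolerance = 1e-12)
  expect_error(compute_iaugc60(mk_conc(zeroC, times[times < 140], inj)),
               "window")
})

test_that("delta-R2* to fBV conversion is exact, linear and sign-preserving", {
  consts <- fbv_constants()
  expect_equal(consts$kappa, (4 * pi / 3) * 2.675e8 * 2e-7 * 7)
  expect_equal(100 * 78.4 / 1568.7, 4.998, tolerance = 1e-3)
  st <- tiny_phantom(c(1, 12, 12))
  m <- roi_mask(st$pre$mask)
  pre <- simulate_mri_series(st$pre, "mgre", uspio = "pre")
  post <- simulate_mri_series(st$pre, "mgre", uspio = "post")
  fb <- compute_fbv_map(pre, post, m, consts = st$pre$consts)
  expect_equal(fb$median_fbv, 6.1, tolerance = 1e-4)
  expect_equal(fb$n_negative, 0)
  # identical series give identically zero change
  fb0 <- compute_fbv_map(pre, pre, m, consts = st$pre$consts)
  expect_equal(fb0$median_fbv, 0, tolerance = 1e-8)
  # linearity in delta-R2*
  expect_equal(100 * (2 * 78.4) / consts$kappa,
               2 * 100 * 78.4 / consts$kappa)
  expect_error(compute_fbv_map(pre, simulate_mri_series(
    st$pre, "mgre", acquisition_schedule(echo_times = (1:16) / 100)), m),
    "echo")
})

test_that("tumour volumes from callipers and ROIs match hand arithmetic", {
  expect_equal(tumour_volume(calliper = c(10, 5)), 125)
  expect_error(tumour_volume(calliper = c(5, 10)), "W exceeds L")
  mk <- array(FALSE, c(3, 20, 20)); mk[, 3:12, 4:13] <- TRUE
  expect_equal(tumour_volume(roi = roi_mask(mk), slice_thickness = 1,
                             pixel_spacing = c(0.25, 0.2)),
               3 * 100 * 0.05 * 1)
  # voxelised sphere volume vs analytic 4 pi r^3 / 3 at r = 10
  r <- 10
  n <- 25
  ax <- seq_len(2 * n + 1) - (n + 1)
  sphere <- outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= r^2
  vol <- tumour_volume(roi = roi_mask(sphere), slice_thickness = 1,
                       pixel_spacing = c(1, 1))
  expect_equal(vol, 4 * pi * r^3 / 3, tolerance = 0.05)
})
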