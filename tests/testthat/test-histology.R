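test_that("area fractions follow exact pixel arithmetic", {
  ch <- matrix(0, 100, 100)
  expect_equal(area_fraction(ch, threshold = 0.5), 0)
  ch[1:25, 1:25] <- 1
  expect_equal(area_fraction(ch, threshold = 0.5), 6.25)
  roi <- matrix(FALSE, 100, 100); roi[1:50, 1:50] <- TRUE
  expect_equal(area_fraction(ch, roi, threshold = 0.5), 25)
  expect_error(area_fraction(ch, roi & FALSE), "empty ROI")
  # monotone non-decreasing as the threshold is lowered
  set.seed(2)
  noisy <- matrix(runif(1e4), 100, 100)
  fr <- vapply(seq(0.9, 0.1, by = -0.2), function(th)
    area_fraction(noisy, threshold = th), numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 100))
})

test_that("synthetic fields are recovered within 1% absolute", {
  f <- simulate_histology_field(c(128, 128), n_objects = 6,
                                radius_range = c(5, 9), seed = 21)
  dec <- colour_deconvolve(f$image, I0 = c(0.95, 0.95, 0.95))
  got <- area_fraction(dec[, , 2], threshold = 0.5)
  expect_lt(abs(got - f$area_fraction), 1)
  # otsu policy lands close to the fixed threshold on a bimodal field
  got_otsu <- area_fraction(dec[, , 2], threshold = "otsu")
  expect_lt(abs(got_otsu - f$area_fraction), 1)
})

test_that("colour deconvolution is the exact linear inverse", {
  # identity stain matrix returns the raw OD channels
  f <- simulate_histology_field(c(64, 64), n_objects = 3, seed = 4)
  od_direct <- -log10(pmax(f$image, 1e-6))
  dec_id <- colour_deconvolve(f$image, stain_vectors(diag(3)))
  expect_equal(dec_id, od_direct, tolerance = 1e-12)
  # two-stain mixture: unmix then remix reproduces the OD image
  v <- stain_vectors()
  conc1 <- matrix(runif(400), 20, 20)
  conc2 <- matrix(runif(400), 20, 20)
  od <- array(0, c(20, 20, 3))
  for (ch in 1:3)
    od[, , ch] <- conc1 * v[1, ch] + conc2 * v[2, ch]
  img <- 10^(-od)
  dec <- colour_deconvolve(img, v)
  remix <- array(0, c(20, 20, 3))
  for (ch in 1:3)
    remix[, , ch] <- dec[, , 1] * v[1, ch] + dec[, , 2] * v[2, ch] +
      dec[, , 3] * v[3, ch]
  expect_equal(remix, od, tolerance = 1e-6)
  expect_lt(max(abs(dec[, , 1] - conc1)), 1e-6)
  expect_lt(max(abs(dec[, , 3])), 1e-6)
  expect_error(stain_vectors(matrix(1, 3, 3)), "singular")
})

test_that("microvessel density counts disjoint objects exactly", {
  counts <- c(3, 4, 5, 4, 4)
  fields <- lapply(seq_along(counts), function(i)
    simulate_histology_field(c(128, 128), counts[i], c(4, 7),
                             seed = 30 + i)$truth)
  res <- microvessel_density(fields, min_size = 10)
  expect_equal(res$per_field, counts)
  expect_equal(res$mvd, 4)
  # invariant to field order
  expect_equal(microvessel_density(rev(fields), min_size = 10)$mvd, 4)
  # empty fields count zero
  empty <- replicate(5, matrix(FALSE, 32, 32), simplify = FALSE)
  expect_equal(microvessel_density(empty)$mvd, 0)
  expect_warning(microvessel_density(fields[1:2], min_size = 10), "fewer")
  # min size filter removes small specks
  speck <- matrix(FALSE, 64, 64); speck[10, 10] <- TRUE
  speck[30:40, 30:40] <- TRUE
  expect_equal(suppressWarnings(
    microvessel_density(list(speck), min_size = 10)$mvd), 1)
})

test_that("histology summaries validate their ranges", {
  h <- histo_summary(hoechst_pct = 17, mvd = 15, n_fields = 6)
  expect_equal(h$hoechst_pct, 17)
  expect_error(histo_summary(hoechst_pct = 130), "0, 100")
  expect_error(histo_summary(mvd = -2), "mvd")
})
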