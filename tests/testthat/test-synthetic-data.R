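test_that("identity effect returns the pre-treatment truth map-for-map", {
  st <- make_phantom_study(c(3, 20, 20), effect = effect_spec(), seed = 3)
  for (nm in c("adc", "ktrans", "ve", "r1", "r2star_pre", "r2star_post",
               "s0", "fbv"))
    expect_identical(st$post[[nm]], st$pre[[nm]])
  expect_identical(st$post$mask, st$pre$mask)
})

test_that("zero-sd baselines give constant maps at the requested mean", {
  st <- make_phantom_study(c(1, 16, 16),
                           baseline_params = list(adc = c(729e-6, 0)),
                           effect = effect_spec(), seed = 2)
  expect_true(all(st$pre$adc[st$pre$mask] == 729e-6))
})

test_that("phantom truth invariants hold and violations are rejected", {
  st <- make_phantom_study(c(3, 24, 24), effect = effect_spec(
    volume_growth_factor = 1.5, fbv_delta = -2.7), seed = 4)
  for (ph in st[c("pre", "post")]) {
    v <- ph$ve[ph$mask]
    expect_true(all(v > 0 & v < 1))
    expect_true(all(ph$rim_mask <= ph$mask))
    dr2 <- (ph$r2star_post - ph$r2star_pre)[ph$mask]
    expect_equal(dr2, ph$consts$kappa * ph$fbv[ph$mask] / 100,
                 tolerance = 1e-12)
  }
  expect_error(make_phantom_study(c(1, 16, 16),
                                  baseline_params = list(adc = c(5e-3, 0))),
               "adc")
  expect_error(make_phantom_study(c(1, 16, 16),
                                  baseline_params = list(ve = c(0.99, 0))),
               "ve")
})

test_that("rim-restricted Ktrans effect matches direct map arithmetic", {
  eff <- effect_spec(ktrans_multiplier = 0.6, rim_restriction = TRUE)
  st <- make_phantom_study(c(1, 20, 20), effect = eff, seed = 6)
  rim <- st$post$rim_mask
  core <- st$post$mask & !rim
  expect_equal(st$post$ktrans[rim], 0.6 * st$pre$ktrans[rim],
               tolerance = 1e-12)
  expect_true(all(st$post$ktrans[core] == 0))
  # independent recomputation of the masked means
  expect_equal(mean(st$post$ktrans[rim]), 0.6 * mean(st$pre$ktrans[rim]),
               tolerance = 1e-12)
})

test_that("volume growth scales the ROI volume by the requested factor", {
  st <- make_phantom_study(c(3, 32, 32),
                           effect = effect_spec(volume_growth_factor = 1.66),
                           seed = 8)
  v_pre <- sum(st$pre$mask)
  v_post <- sum(st$post$mask)
  expect_equal(v_post / v_pre, 1.66, tolerance = 0.15)  # voxelisation error
})

test_that("simulated series match the forward models and are reproducible", {
  st <- tiny_phantom(c(1, 12, 12))
  px <- which(st$pre$mask)[1]
  dwi <- simulate_mri_series(st$pre, "dwi")
  expect_equal(dwi$data[, , , 5][px], dwi_signal(1000, 729e-6, 700),
               tolerance = 1e-12)
  mg <- simulate_mri_series(st$pre, "mgre")
  expect_equal(mg$data[, , , 1][px], mgre_signal(1000, 60, 0.006),
               tolerance = 1e-12)
  expect_true(all(dwi$data >= 0) && all(mg$data >= 0))
  # determinism of the noise draw
  aif <- aif_params()
  s1 <- simulate_mri_series(st$pre, "ir_truefisp_dce", aif = aif, snr = 20,
                            seed = 42)
  s2 <- simulate_mri_series(st$pre, "ir_truefisp_dce", aif = aif, snr = 20,
                            seed = 42)
  s3 <- simulate_mri_series(st$pre, "ir_truefisp_dce", aif = aif, snr = 20,
                            seed = 43)
  expect_identical(s1$data, s2$data)
  expect_false(identical(s1$data, s3$data))
  expect_error(simulate_mri_series(st$pre, "dwi", aif = aif), "aif")
  expect_error(simulate_mri_series(st$pre, "ir_truefisp_dce", aif = aif,
                                   snr = -2), "snr")
  expect_error(simulate_mri_series(st$pre, "dwi",
                                   default_schedule("mgre")), "b_values")
})

test_that("xenograft read categories conserve the library size exactly", {
  gm <- simulate_gene_models(100, 40, seed = 1)
  des <- rna_sim_design(n_genes = 100, groups = c(a = 2, omalizumab = 2),
                        library_size = 50000, seed = 2)
  sim <- simulate_xenograft_counts(des, gm)
  expect_true(all(colSums(sim$category_counts) == 50000))
  expect_true(all(colSums(sim$counts_human) == sim$category_counts["human", ]))
  # degenerate ambiguous fraction
  des0 <- rna_sim_design(n_genes = 100, groups = c(a = 1, omalizumab = 1),
                         ambiguous_fraction = 0, library_size = 20000,
                         seed = 3)
  sim0 <- simulate_xenograft_counts(des0, gm, read_level = TRUE)
  expect_true(all(sim0$category_counts["both", ] == 0))
  expect_false(any(sim0$summaries[[1]]$maps_human &
                     sim0$summaries[[1]]$maps_mouse))
})

test_that("empirical read fractions sit within 3 sd of the design", {
  gm <- simulate_gene_models(200, 50, seed = 4)
  des <- rna_sim_design(n_genes = 200, groups = c(omalizumab = 1),
                        human_fraction = 0.8, ambiguous_fraction = 0.07,
                        unmapped_fraction = 0.30, library_size = 1e6,
                        seed = 5)
  sim <- simulate_xenograft_counts(des, gm)
  L <- 1e6
  probs <- c(human = 0.8 * 0.63, mouse = 0.2 * 0.63, both = 0.07)
  for (nm in names(probs)) {
    expect_lt(abs(sim$category_counts[nm, 1] / L - probs[nm]),
              3 * sqrt(probs[nm] * (1 - probs[nm]) / L))
  }
})

test_that("spiked log2 effects appear in the group mean counts", {
  gm <- simulate_gene_models(60, 20, seed = 6)
  des <- rna_sim_design(
    n_genes = 60, groups = c(vanucizumab = 8, omalizumab = 8),
    dispersion = 1e-4, library_size = 2e6,
    de_spec = data.frame(gene = 5, treatments = "vanucizumab",
                         log2_effect = 1), seed = 7)
  sim <- simulate_xenograft_counts(des, gm)
  tr <- sim$samples$treatment
  ratio <- mean(sim$counts_human[5, tr == "vanucizumab"]) /
    mean(sim$counts_human[5, tr == "omalizumab"])
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("histology generator produces exact truth masks", {
  f0 <- simulate_histology_field(c(100, 100), n_objects = 0)
  expect_equal(f0$area_fraction, 0)
  expect_true(all(abs(f0$image[, , 1] - 0.95) < 1e-12))
  f5 <- simulate_histology_field(c(128, 128), n_objects = 5,
                                 radius_range = c(4, 7), seed = 11)
  lab <- EBImage::bwlabel(matrix(as.numeric(f5$truth), 128, 128))
  expect_equal(max(lab), 5)
  expect_equal(f5$area_fraction, 100 * mean(f5$truth))
})
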