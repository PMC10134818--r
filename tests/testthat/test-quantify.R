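test_that("isotope-ratio estimator follows the ratio times standard", {
  expect_equal(isotope_ratio_concentration(1e6, 1e6, 5e-5), 5e-5)
  expect_equal(isotope_ratio_concentration(2e6, 1e6, 50e-6), 100e-6)
  expect_identical(isotope_ratio_concentration(0, 1e6, 1e-4), 0)
  # zero standard channel: below LOD, not a crash
  expect_true(is.na(isotope_ratio_concentration(1e6, 0, 1e-4)))
  expect_error(isotope_ratio_concentration(-1, 1e6, 1e-4), "non-negative")
  # invariance under common rescaling of both channels
  for (k in c(1e-3, 0.5, 7, 1e4)) {
    expect_equal(isotope_ratio_concentration(k * 3e6, k * 2e6, 1e-5),
                 isotope_ratio_concentration(3e6, 2e6, 1e-5))
  }
})

test_that("extract-to-intracellular conversion is the volume ratio", {
  g <- extraction_geometry(culture_volume_mL = 10, solvent_volume_mL = 1.5,
                           biovolume_uL_per_OD_mL = 3.0)
  expect_equal(extract_to_intracellular(1e-6, g, od600 = 0.5), 1e-4)
  # inverse composition is the identity
  expect_equal(extract_to_intracellular(
    mepscope:::intracellular_to_extract(6.35e-3, g, 0.5), g, 0.5), 6.35e-3)
  expect_error(extraction_geometry(solvent_volume_mL = 0))
})

test_that("extracellular correction subtracts carryover and clamps at zero", {
  g0 <- extraction_geometry(carryover_uL = 0)
  expect_identical(extracellular_correction(1e-9, 1e-5, g0), 1e-9)
  g50 <- extraction_geometry(carryover_uL = 50)
  expect_equal(extracellular_correction(1e-9, 1e-5, g50), 0.5e-9)
  expect_warning(out <- extracellular_correction(1e-10, 1e-4, g50), "clamped")
  expect_identical(out, 0)
})

test_that("zero-noise quantification reproduces the configured truths", {
  cfg <- sim_config("GFP", "single_timepoint", seed = 3, n_replicates = 6,
                    noise_cv = 0)
  sim <- simulate_single_timepoint(cfg)
  standards <- tibble::tibble(metabolite_id = names(cfg$std_conc),
                              conc_M = unname(cfg$std_conc))
  ct <- quantify_samples(sim$peaks, standards, cfg$geometry)
  gfp <- dplyr::filter(ct, strain == "GFP")
  expect_equal(gfp$molarity_M[gfp$metabolite_id == "PYR"], 6.35e-3,
               tolerance = 1e-9)
  expect_equal(gfp$molarity_M[gfp$metabolite_id == "DXP"], 1.68e-4,
               tolerance = 1e-9)
  # every configured truth round-trips
  truth <- cfg$true_conc[names(cfg$std_conc)]
  got <- gfp$molarity_M[match(names(truth), gfp$metabolite_id)]
  expect_equal(got, unname(truth), tolerance = 1e-9)
  # CDP-MEP has no standard
  expect_identical(gfp$flag[gfp$metabolite_id == "CDP-MEP"], "no_standard")
})

test_that("single replicate yields a point estimate without a CI", {
  cfg <- sim_config("GFP", "single_timepoint", seed = 5, n_replicates = 1,
                    noise_cv = 0)
  sim <- simulate_single_timepoint(cfg)
  standards <- tibble::tibble(metabolite_id = names(cfg$std_conc),
                              conc_M = unname(cfg$std_conc))
  ct <- quantify_samples(sim$peaks, standards, cfg$geometry)
  row <- dplyr::filter(ct, strain == "GFP", metabolite_id == "DXP")
  expect_equal(row$molarity_M, 1.68e-4, tolerance = 1e-9)
  expect_true(is.na(row$ci_lo))
})

test_that("replicate CI covers the truth at roughly the nominal rate", {
  # coverage simulation for one metabolite, n = 6 replicates, cv = 0.1
  n_seeds <- 300
  covered <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config("GFP", "single_timepoint", seed = s, n_replicates = 6,
                      noise_cv = 0.1, true_conc = c(DXP = 1.68e-4))
    sim <- simulate_single_timepoint(cfg)
    standards <- tibble::tibble(metabolite_id = "DXP",
                                conc_M = unname(cfg$std_conc["DXP"]))
    peaks <- dplyr::filter(sim$peaks, strain == "GFP")
    ct <- quantify_samples(peaks, standards, cfg$geometry)
    covered[s] <- ct$ci_lo <= 1.68e-4 && 1.68e-4 <= ct$ci_hi
  }
  # binomial noise at 300 draws: 95% +- ~4 points
  expect_gt(mean(covered), 0.90)
  expect_lte(mean(covered), 1.0)
})

test_that("quantified molarities are never negative", {
  cfg <- sim_config("DXS2", "single_timepoint", seed = 11, noise_cv = 0.3)
  sim <- simulate_single_timepoint(cfg)
  standards <- tibble::tibble(metabolite_id = names(cfg$std_conc),
                              conc_M = unname(cfg$std_conc))
  ct <- quantify_samples(sim$peaks, standards, cfg$geometry)
  expect_true(all(ct$molarity_M[ct$flag == "ok"] >= 0))
})
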