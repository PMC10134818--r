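test_that("growth-rate fits recover exact exponentials to machine precision", {
  gs <- tibble::tibble(time_h = 0:6, od600 = 0.05 * 2^(0:6))
  expect_equal(fit_growth_rate(gs)$mu_per_h, log(2), tolerance = 1e-12)
  flat <- tibble::tibble(time_h = 0:5, od600 = rep(0.4, 6))
  expect_equal(fit_growth_rate(flat)$mu_per_h, 0, tolerance = 1e-12)
  expect_error(fit_growth_rate(tibble::tibble(time_h = 0:1, od600 = c(1, 2))),
               "at least")
})

test_that("growth-rate recovery under noise is accurate on average", {
  mu_hat <- vapply(1:60, function(s) {
    od <- withr::with_seed(s, {
      0.05 * exp(0.30 * (0:8)) * exp(rnorm(9, 0, 0.02))
    })
    fit_growth_rate(tibble::tibble(time_h = 0:8, od600 = od),
                    window = c(0, 8))$mu_per_h
  }, numeric(1))
  expect_equal(mean(mu_hat), 0.30, tolerance = 0.05)
})

test_that("the exponential window excludes stationary phase", {
  tt <- 0:10
  od <- pmin(0.05 * exp(0.4 * tt), 1.0)
  fit <- fit_growth_rate(tibble::tibble(time_h = tt, od600 = od))
  expect_equal(fit$mu_per_h, 0.4, tolerance = 0.05)
})

test_that("glucose assay algebra is self-inverse", {
  expect_equal(glucose_concentration(0), 0)
  # 1 mM spike, 50:50 mix, 1/50 dilution: the mix cancels, S = ratio * 50
  expect_equal(glucose_concentration(0.20), 10)
  expect_equal(glucose_concentration(1), 50)
  expect_equal(glucose_concentration(0.4, spike_mM = 2, dilution = 10), 8)
  expect_error(glucose_concentration(0.1, spike_mM = 0))
  # generator round trip at zero noise
  cfg <- sim_config("GFP", seed = 4, noise_cv = 0)
  ph <- simulate_physiology(cfg)
  gl <- dplyr::filter(ph$glucose, strain == "ZM4_GFP", replicate == 1)
  expect_equal(glucose_concentration(gl$ratio_12c_13c), gl$glucose_mM,
               tolerance = 1e-12)
})

test_that("specific consumption rate is mu dS over dX", {
  growth <- tibble::tibble(time_h = 0:4, od600 = 0.1 * exp(0.3 * (0:4)))
  no_change <- tibble::tibble(time_h = 0:4, glucose_mM = rep(50, 5))
  expect_equal(consumption_rate(no_change, growth,
                                window = c(0, 4))$q_mmol_gdcw_h, 0)
  # plug-in check against the hand formula q = mu * dS / dX
  gdcw <- 0.33
  growth2 <- tibble::tibble(time_h = c(0, 0.5, 1),
                            od600 = 0.2 * exp(0.3 * c(0, 0.5, 1)))
  glc <- tibble::tibble(time_h = c(0, 0.5, 1), glucose_mM = c(50, 45, 40))
  res <- consumption_rate(glc, growth2, gdcw_per_od = gdcw, window = c(0, 1))
  dX <- (growth2$od600[3] - growth2$od600[1]) * gdcw
  expect_equal(res$q_mmol_gdcw_h, 0.3 * 10 / dX, tolerance = 1e-9)
})

test_that("generator physiology rates are recovered", {
  cfg <- sim_config("GFP", seed = 2, noise_cv = 0,
                    od_curve = list(od0 = 0.05, mu_per_h = 0.30, od_cap = 10))
  ph <- simulate_physiology(cfg, hours = 8)
  g <- dplyr::filter(ph$growth, strain == "ZM4_GFP", replicate == 1)
  gl <- dplyr::filter(ph$glucose, strain == "ZM4_GFP", replicate == 1)
  fit <- fit_growth_rate(dplyr::select(g, time_h, od600))
  expect_equal(fit$mu_per_h, 0.30, tolerance = 1e-9)
  res <- consumption_rate(dplyr::select(gl, time_h, glucose_mM),
                          dplyr::select(g, time_h, od600),
                          gdcw_per_od = cfg$gdcw_per_od)
  # dS/dt = -q X integrates to q * dX over any window: exact recovery
  expect_equal(res$q_mmol_gdcw_h, 30, tolerance = 1e-6)
})

test_that("isoprene yield converts headspace readings and scales linearly", {
  assay <- tibble::tibble(strain = "X", glucose_consumed_mmol = 0.002,
                          headspace_volume_mL = 1.8, sampled_volume_mL = 1,
                          isoprene_nmol_sampled = 0)
  expect_equal(isoprene_yield(assay)$yield_nmol_per_mmol, 0)
  assay$isoprene_nmol_sampled <- 0.01
  y1 <- isoprene_yield(assay)$yield_nmol_per_mmol
  assay2 <- dplyr::mutate(assay, isoprene_nmol_sampled = 0.02)
  expect_equal(isoprene_yield(assay2)$yield_nmol_per_mmol, 2 * y1)
  # ppbv route: ideal-gas conversion, scaled to the full headspace
  assay3 <- dplyr::mutate(assay, isoprene_nmol_sampled = NULL, fis_ppbv = 500)
  n_gas <- 1 * 1e-3 / (0.08206 * 303.15)
  expect_equal(isoprene_yield(assay3)$yield_nmol_per_mmol,
               500 * 1e-9 * n_gas * 1e9 * 1.8 / 0.002, tolerance = 1e-9)
  # invariance to culture-volume rescaling with proportional readings
  big <- dplyr::mutate(assay, glucose_consumed_mmol = 5 * glucose_consumed_mmol,
                       isoprene_nmol_sampled = 5 * isoprene_nmol_sampled)
  expect_equal(isoprene_yield(big)$yield_nmol_per_mmol, y1)
})

test_that("yield folds reproduce the strain comparisons", {
  expect_equal(as.numeric(yield_fold(33.3, 5.6)), 5.9)
  expect_equal(as.numeric(yield_fold(16.3, 5.6)), 2.9)
  expect_equal(as.numeric(yield_fold(5.6, 5.6)), 1.0)
  expect_error(yield_fold(10, 0))
})

test_that("yield difference between producer and control is detectable", {
  # two-sample t on replicate yields from the generator's production table
  # truths: the DXS2_IspS vs GFP contrast should be significant essentially
  # always at these effect sizes
  hits <- vapply(1:40, function(s) {
    cfg <- sim_config("all", seed = s, noise_cv = 0.2, n_replicates = 4)
    ph <- simulate_physiology(cfg)
    ys <- isoprene_yield(ph$assay)
    a <- log2(ys$yield_nmol_per_mmol[ys$strain == "ZM4_DXS2_IspS"])
    b <- log2(ys$yield_nmol_per_mmol[ys$strain == "ZM4_GFP"])
    two_sample_t_equal_var(a, b)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
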