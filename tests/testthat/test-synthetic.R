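test_that("the generator is deterministic for a fixed seed and config", {
  cfg <- sim_config("DXS2", "single_timepoint", seed = 9, noise_cv = 0.2)
  expect_identical(simulate_single_timepoint(cfg)$peaks,
                   simulate_single_timepoint(cfg)$peaks)
  cfg2 <- sim_config("DXS2_IspG", "timecourse", seed = 9, noise_cv = 0.2)
  expect_identical(simulate_timecourse(cfg2)$peaks,
                   simulate_timecourse(cfg2)$peaks)
  # a different seed changes the noise
  cfg3 <- sim_config("DXS2", "single_timepoint", seed = 10, noise_cv = 0.2)
  expect_false(identical(simulate_single_timepoint(cfg)$peaks,
                         simulate_single_timepoint(cfg3)$peaks))
})

test_that("zero noise gives the exact channel-ratio identity", {
  cfg <- sim_config("DXS2", "single_timepoint", seed = 1, noise_cv = 0)
  sim <- simulate_single_timepoint(cfg)
  wide <- tidyr::pivot_wider(sim$peaks, names_from = channel,
                             values_from = intensity)
  wide <- dplyr::filter(wide, !is.na(U12C))
  c_extract <- mepscope:::intracellular_to_extract(
    cfg$true_conc[wide$metabolite_id] *
      ifelse(wide$strain == "GFP", 1, sim$truth$true_fold[wide$metabolite_id]),
    cfg$geometry, cfg$od_single)
  expect_equal(wide$U13C / wide$U12C,
               unname(c_extract / cfg$std_conc[wide$metabolite_id]),
               tolerance = 1e-12)
})

test_that("multiplicative noise has mean one and the configured CV", {
  x <- withr::with_seed(4, mepscope:::ln_noise(2e5, 0.2))
  expect_equal(mean(x), 1, tolerance = 0.01)
  expect_equal(sd(x) / mean(x), 0.2, tolerance = 0.02)
  expect_identical(mepscope:::ln_noise(5, 0), rep(1, 5))
})

test_that("constant trajectories propagate to unit fold changes", {
  cfg <- sim_config("GFP", "timecourse", seed = 2, noise_cv = 0)
  sim <- simulate_timecourse(cfg)
  fct <- fold_change_vs_t0(sim$peaks)
  expect_true(all(abs(fct$fold_change - 1) < 1e-12))
})

test_that("trajectories must start at fold one at time zero", {
  traj <- list(DXP = tibble::tibble(time = c(7.5, 60), fold = c(2, 4)))
  expect_error(mepscope:::trajectory_fold(traj, "DXP", 30), "must start")
})

test_that("single-time-point recovery is exact without noise and unbiased with it", {
  run_one <- function(seed, cv) {
    cfg <- sim_config("DXS2", "single_timepoint", seed = seed, noise_cv = cv)
    sim <- simulate_single_timepoint(cfg)
    standards <- tibble::tibble(metabolite_id = names(cfg$std_conc),
                                conc_M = unname(cfg$std_conc))
    reps <- quantify_replicates(sim$peaks, standards, cfg$geometry)
    fct <- fold_change_vs_control(reps)
    fct$fold_change[fct$metabolite_id == "MEcDP"]
  }
  expect_equal(run_one(1, 0), 102, tolerance = 1e-9)
  folds <- vapply(1:25, run_one, numeric(1), cv = 0.2)
  expect_equal(mean(folds), 102, tolerance = 0.3)
})

test_that("fold-change bias shrinks as noise shrinks and replicates grow", {
  mean_fold <- function(cv, n, seeds = 12) {
    mean(vapply(seq_len(seeds), function(s) {
      cfg <- sim_config("DXS2", "single_timepoint", seed = s, noise_cv = cv,
                        n_replicates = n,
                        true_conc = c(MEcDP = 1.25e-4))
      sim <- simulate_single_timepoint(cfg)
      standards <- tibble::tibble(metabolite_id = names(cfg$std_conc),
                                  conc_M = unname(cfg$std_conc))
      reps <- quantify_replicates(sim$peaks, standards, cfg$geometry)
      fold_change_vs_control(reps)$fold_change
    }, numeric(1)))
  }
  err <- function(x) abs(x / 102 - 1)
  expect_equal(mean_fold(0, 3), 102, tolerance = 1e-9)
  # more replicates at the same noise bring the estimate closer to truth
  expect_lt(err(mean_fold(0.2, 30)), err(mean_fold(0.2, 3)) + 0.02)
  expect_lt(err(mean_fold(0.1, 30)), 0.1)
})

test_that("physiology generator recovers configured yields without noise", {
  cfg <- sim_config("all", seed = 1, noise_cv = 0)
  ph <- simulate_physiology(cfg)
  ys <- summarise_yields(isoprene_yield(ph$assay))
  expect_equal(ys$yield_nmol_per_mmol[ys$strain == "ZM4_GFP"], 5.6,
               tolerance = 1e-9)
  expect_equal(ys$yield_nmol_per_mmol[ys$strain == "ZM4_DXS2_IspS"], 33.3,
               tolerance = 1e-9)
  fold <- yield_fold(ys$yield_nmol_per_mmol[ys$strain == "ZM4_DXS2_IspS"],
                     ys$yield_nmol_per_mmol[ys$strain == "ZM4_GFP"])
  expect_equal(attr(fold, "exact"), 33.3 / 5.6, tolerance = 1e-9)
})

test_that("growth curves double per hour when mu is ln 2", {
  cfg <- sim_config("GFP", seed = 1, noise_cv = 0,
                    od_curve = list(od0 = 0.01, mu_per_h = log(2), od_cap = 50))
  ph <- simulate_physiology(cfg, hours = 5)
  g <- dplyr::filter(ph$growth, strain == "ZM4_GFP", replicate == 1)
  expect_equal(g$od600[-1] / g$od600[-nrow(g)], rep(2, nrow(g) - 1),
               tolerance = 1e-12)
})
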