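#' Generator configuration
#'
#' Assembles everything the synthetic LC-MS generator needs: the scenario
#' (which strain responses to emulate), the experimental design, replicate
#' structure, noise level, true wild-type concentrations, response factors
#' and spiked-standard concentrations, growth parameters and extraction
#' geometry. Defaults reproduce the study conditions: three biological
#' replicates, sampling at OD600 0.5 (single time point) or induction at
#' OD600 0.35 with sampling at 0, 7.5, 15, 30, 45, 60 and 120 min (time
#' course), wild-type truth equal to the reference concentration table, and
#' multiplicative lognormal intensity noise (mean 1) with coefficient of
#' variation `noise_cv` applied independently per channel.
#'
#' @param scenario Scenario name (see [mep_scenarios()]), default `"GFP"`.
#' @param design `"single_timepoint"` or `"timecourse"`.
#' @param seed Integer seed fixing all randomness.
#' @param n_replicates Biological replicates per group, default 3.
#' @param noise_cv Lognormal noise CV per channel, default 0.2;
#'   `0` disables noise entirely.
#' @param timepoints Minutes, default `c(0, 7.5, 15, 30, 45, 60, 120)`.
#' @param true_conc Named molarity vector of wild-type truths; defaults to
#'   the reference table plus an assumed 2e-5 M for CDP-MEP (relative-only:
#'   it is generated but carries no standard).
#' @param response_factor Named vector of intensities per M in the extract
#'   (a.u./M); defaults to 1e10 for every metabolite.
#' @param std_conc Named vector of spiked-standard extract concentrations
#'   (M); defaults to the extract-equivalent of the wild-type truth, with
#'   CDP-MEP absent.
#' @param od_single OD600 at single-time-point sampling, default 0.5.
#' @param od_curve List `od0`, `mu_per_h`, `od_cap` for the time-course and
#'   physiology growth model.
#' @param glucose List `initial_mM`, `q_mmol_gdcw_h`.
#' @param gdcw_per_od Dry weight per OD (g/L/OD), default 0.33.
#' @param geometry An [extraction_geometry()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(scenario = "GFP",
                       design = c("single_timepoint", "timecourse"),
                       seed = 1, n_replicates = 3, noise_cv = 0.2,
                       timepoints = c(0, 7.5, 15, 30, 45, 60, 120),
                       true_conc = NULL, response_factor = NULL,
                       std_conc = NULL, od_single = 0.5,
                       od_curve = list(od0 = 0.35, mu_per_h = 0.30, od_cap = 2.0),
                       glucose = list(initial_mM = 111, q_mmol_gdcw_h = 30),
                       gdcw_per_od = 0.33,
                       geometry = extraction_geometry()) {
  design <- match.arg(design)
  stopifnot(n_replicates >= 1, noise_cv >= 0,
            timepoints[1] == 0, !is.unsorted(timepoints, strictly = TRUE))
  if (is.null(true_conc)) {
    true_conc <- c(concentration_vector(zm4_concentrations()),
                   "CDP-MEP" = 2e-5)
  }
  stopifnot(all(true_conc > 0))
  if (is.null(response_factor)) {
    response_factor <- stats::setNames(rep(1e10, length(true_conc)),
                                       names(true_conc))
  }
  stopifnot(all(response_factor > 0))
  if (is.null(std_conc)) {
    std_conc <- intracellular_to_extract(true_conc, geometry, od_single)
    std_conc <- std_conc[names(std_conc) != "CDP-MEP"]
  }
  stopifnot(all(std_conc > 0))
  structure(list(scenario = scenario, design = design, seed = as.integer(seed),
                 n_replicates = n_replicates, noise_cv = noise_cv,
                 timepoints = timepoints, true_conc = true_conc,
                 response_factor = response_factor, std_conc = std_conc,
                 od_single = od_single, od_curve = od_curve,
                 glucose = glucose, gdcw_per_od = gdcw_per_od,
                 geometry = geometry),
            class = "sim_config")
}

#' Bundled generator scenarios
#'
#' Scenario definitions encode the study's printed strain responses as
#' generator ground truth: single-time-point fold changes versus the GFP
#' control (e.g. DXS2: DXP 9.3, CDP-ME 9.1, MEcDP 102) and time-course fold
#' trajectories versus pre-induction (e.g. DXS2_IspG: HMBDP reaching
#' 140-fold at 60 min), plus isoprene yields per strain.
#'
#' @return Nested list with elements `single_timepoint`, `timecourse`,
#'   `physiology`.
#' @export
mep_scenarios <- function() {
  yaml::read_yaml(system.file("extdata", "scenarios.yaml",
                              package = "mepscope", mustWork = TRUE))
}

# fold map (single tp) or trajectory list (timecourse) for a scenario
scenario_truth <- function(cfg) {
  sc <- mep_scenarios()
  if (cfg$design == "single_timepoint") {
    entry <- sc$single_timepoint[[cfg$scenario]]
    if (is.null(entry)) stop("unknown single-time-point scenario: ", cfg$scenario)
    folds <- unlist(entry$fold) %||% numeric(0)
    full <- stats::setNames(rep(1, length(cfg$true_conc)), names(cfg$true_conc))
    full[names(folds)] <- folds
    full
  } else {
    entry <- sc$timecourse[[cfg$scenario]]
    if (is.null(entry)) stop("unknown time-course scenario: ", cfg$scenario)
    purrr::map(entry$trajectory, function(knots) {
      k <- matrix(as.numeric(unlist(knots)), ncol = 2, byrow = TRUE)
      tibble::tibble(time = k[, 1], fold = k[, 2])
    })
  }
}

# piecewise-linear interpolation on the log(fold) scale; fold 1 outside knots
trajectory_fold <- function(traj, metabolite, t) {
  tr <- traj[[metabolite]]
  if (is.null(tr)) return(rep(1, length(t)))
  if (tr$time[1] != 0 || tr$fold[1] != 1) {
    stop("trajectory for ", metabolite, " must start at (0, 1)")
  }
  exp(stats::approx(tr$time, log(tr$fold), xout = t, rule = 2)$y)
}

# multiplicative lognormal noise with mean exactly 1 (cv = 0 -> exactly 1)
ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a single-time-point isotope-dilution experiment
#'
#' Emulates the absolute-quantification design: cells grown on \[U-13C\]
#' glucose (analyte in the 13C channel) extracted into solvent containing
#' unlabeled standards (12C channel). Two groups are generated: the GFP
#' control at the wild-type truth and the scenario strain at
#' `truth x fold`. Intensities are
#' `I13 = RF x c_extract x eps` and `I12 = RF x c_std x eps'` with
#' independent lognormal noise per channel; `c_extract` follows from the
#' intracellular truth via the extraction geometry at the sampling OD.
#'
#' @param cfg A [sim_config()] with `design = "single_timepoint"`.
#' @return List with `peaks` (peak-table tibble) and `truth` (list:
#'   `true_conc` per strain, `true_fold`, `strain`, `control`).
#' @export
simulate_single_timepoint <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$design == "single_timepoint")
  folds <- scenario_truth(cfg)
  strain <- if (cfg$scenario == "GFP") "GFP_null" else cfg$scenario
  mets <- names(cfg$true_conc)
  missing_rf <- setdiff(mets, names(cfg$response_factor))
  if (length(missing_rf)) {
    stop("missing response factor for: ", paste(missing_rf, collapse = ", "))
  }
  withr::with_seed(cfg$seed, {
    grid <- tidyr::expand_grid(
      strain = c("GFP", strain),
      replicate = seq_len(cfg$n_replicates),
      metabolite_id = mets
    ) |>
      dplyr::mutate(
        fold = dplyr::if_else(.data$strain == "GFP", 1,
                              unname(folds[.data$metabolite_id])),
        c_intra = unname(cfg$true_conc[.data$metabolite_id]) * .data$fold,
        c_extract = intracellular_to_extract(.data$c_intra, cfg$geometry,
                                             cfg$od_single),
        rf = unname(cfg$response_factor[.data$metabolite_id]),
        U13C = .data$rf * .data$c_extract * ln_noise(dplyr::n(), cfg$noise_cv),
        U12C = .data$rf *
          unname(cfg$std_conc[.data$metabolite_id]) *
          ln_noise(dplyr::n(), cfg$noise_cv),
        od600_at_sampling = cfg$od_single,
        timepoint_min = 0,
        sample_id = paste(.data$strain, .data$replicate, sep = "_")
      )
  })
  # metabolites without a spiked standard get NA in the standard channel
  grid$U12C[!grid$metabolite_id %in% names(cfg$std_conc)] <- NA_real_
  peaks <- grid |>
    tidyr::pivot_longer(c("U12C", "U13C"), names_to = "channel",
                        values_to = "intensity") |>
    dplyr::select("sample_id", "strain", "replicate", "timepoint_min",
                  "metabolite_id", "channel", "intensity", "od600_at_sampling")
  truth <- list(
    control = "GFP", strain = strain, true_fold = folds,
    true_conc = list(GFP = cfg$true_conc,
                     strain = cfg$true_conc * folds),
    config = cfg
  )
  list(peaks = peaks, truth = truth)
}

od_at_minutes <- function(cfg, t_min) {
  oc <- cfg$od_curve
  pmin(oc$od0 * exp(oc$mu_per_h * t_min / 60), oc$od_cap)
}

#' Simulate a time-course experiment with a 13C reference spike
#'
#' Emulates the dynamic design: unlabeled experimental samples (12C channel)
#' combined with a fixed, fully labeled reference extract (13C channel,
#' identical for every sample of the experiment). The 12C intensity is
#' proportional to the true concentration trajectory times the biomass at
#' sampling (`I12 = RF x c_true(t) x OD(t) x eps`); the reference channel is
#' `I13 = RF x c_ref x eps'`. The OD series follows exponential growth from
#' the induction OD, capped at stationary phase.
#'
#' @param cfg A [sim_config()] with `design = "timecourse"`.
#' @return List with `peaks`, `od` (tibble `strain`, `timepoint_min`,
#'   `od600`) and `truth` (list incl. the fold-trajectory function table).
#' @export
simulate_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$design == "timecourse")
  traj <- scenario_truth(cfg)
  strain <- if (cfg$scenario == "GFP") "GFP_null" else cfg$scenario
  mets <- names(cfg$true_conc)
  c_ref <- cfg$true_conc  # reference extract at wild-type levels
  withr::with_seed(cfg$seed, {
    grid <- tidyr::expand_grid(
      strain = strain,
      replicate = seq_len(cfg$n_replicates),
      timepoint_min = cfg$timepoints,
      metabolite_id = mets
    ) |>
      dplyr::mutate(
        fold = purrr::map2_dbl(.data$metabolite_id, .data$timepoint_min,
                               ~ trajectory_fold(traj, .x, .y)),
        c_true = unname(cfg$true_conc[.data$metabolite_id]) * .data$fold,
        od600_at_sampling = od_at_minutes(cfg, .data$timepoint_min),
        rf = unname(cfg$response_factor[.data$metabolite_id]),
        U12C = .data$rf * .data$c_true * .data$od600_at_sampling *
          ln_noise(dplyr::n(), cfg$noise_cv),
        U13C = .data$rf * unname(c_ref[.data$metabolite_id]) *
          ln_noise(dplyr::n(), cfg$noise_cv),
        sample_id = paste(.data$strain, .data$replicate, .data$timepoint_min,
                          sep = "_")
      )
  })
  peaks <- grid |>
    tidyr::pivot_longer(c("U12C", "U13C"), names_to = "channel",
                        values_to = "intensity") |>
    dplyr::select("sample_id", "strain", "replicate", "timepoint_min",
                  "metabolite_id", "channel", "intensity", "od600_at_sampling")
  od <- grid |>
    dplyr::distinct(.data$strain, .data$timepoint_min, .data$od600_at_sampling) |>
    dplyr::rename(od600 = "od600_at_sampling")
  truth <- list(strain = strain, trajectory = traj,
                true_fold_at = function(metabolite, t) {
                  trajectory_fold(traj, metabolite, t)
                },
                config = cfg)
  list(peaks = peaks, od = od, truth = truth)
}

#' Simulate growth, glucose depletion and headspace isoprene
#'
#' Generates, per strain of the physiology scenario table: an hourly OD600
#' series (exponential growth to a stationary cap), the matching supernatant
#' glucose series expressed both in mM and as the 12C/13C assay peak ratio,
#' and a sealed-vial isoprene assay whose readings are proportional to the
#' strain's true yield times the glucose consumed during the sealed window.
#'
#' @param cfg A [sim_config()]; `scenario` selects strains: `"all"` (every
#'   strain in the yield table) or one strain name.
#' @param hours Simulated duration (h), default 10.
#' @return List with `growth` (tibble `strain, replicate, time_h, od600`),
#'   `glucose` (`strain, replicate, time_h, glucose_mM, ratio_12c_13c`),
#'   `assay` (per-replicate sealed-vial tibble ready for
#'   [isoprene_yield()]) and `truth`.
#' @export
simulate_physiology <- function(cfg, hours = 10) {
  stopifnot(inherits(cfg, "sim_config"))
  phys <- mep_scenarios()$physiology
  yields <- phys$yields
  strains <- if (identical(cfg$scenario, "all") || cfg$scenario == "GFP") {
    names(yields)
  } else {
    sn <- cfg$scenario
    if (!sn %in% names(yields)) stop("unknown physiology strain: ", sn)
    sn
  }
  oc <- cfg$od_curve
  mu <- oc$mu_per_h
  gl <- cfg$glucose
  tt <- seq(0, hours, by = 1)
  od_true <- pmin(oc$od0 * exp(mu * tt), oc$od_cap)
  # substrate: dS/dt = -q * X(t), X = gdcw_per_od * OD
  s_true <- pmax(0, gl$initial_mM -
                   gl$q_mmol_gdcw_h * cfg$gdcw_per_od * oc$od0 *
                   (exp(mu * tt) - 1) / mu)
  withr::with_seed(cfg$seed, {
    frames <- purrr::map(strains, function(sn) {
      reps <- purrr::map(seq_len(cfg$n_replicates), function(r) {
        eps_od <- ln_noise(length(tt), cfg$noise_cv)
        eps_s <- ln_noise(length(tt), cfg$noise_cv)
        growth <- tibble::tibble(strain = sn, replicate = r, time_h = tt,
                                 od600 = od_true * eps_od)
        gmM <- s_true * eps_s
        glucose <- tibble::tibble(
          strain = sn, replicate = r, time_h = tt, glucose_mM = gmM,
          ratio_12c_13c = gmM / 50  # assay: 1/50 dilution, 50:50 mix, 1 mM spike
        )
        # sealed vial at 3 h post "induction" (OD 0.35), 10-min window
        t_ind <- log(0.35 / oc$od0) / mu
        t1 <- t_ind + 3
        t2 <- t1 + 10 / 60
        s_at <- function(t) {
          pmax(0, gl$initial_mM - gl$q_mmol_gdcw_h * cfg$gdcw_per_od *
                 oc$od0 * (exp(mu * t) - 1) / mu)
        }
        consumed_mM <- s_at(t1) - s_at(t2)
        aliquot_mL <- 0.2
        consumed_mmol <- consumed_mM * aliquot_mL / 1000
        y_true <- yields[[sn]]$yield
        total_nmol <- y_true * consumed_mmol * ln_noise(1, cfg$noise_cv)
        headspace_mL <- 1.8
        sampled_mL <- 1.0
        assay <- tibble::tibble(
          strain = sn, replicate = r,
          glucose_consumed_mmol = consumed_mmol,
          headspace_volume_mL = headspace_mL,
          sampled_volume_mL = sampled_mL,
          isoprene_nmol_sampled = total_nmol * sampled_mL / headspace_mL
        )
        list(growth = growth, glucose = glucose, assay = assay)
      })
      list(growth = purrr::map_dfr(reps, "growth"),
           glucose = purrr::map_dfr(reps, "glucose"),
           assay = purrr::map_dfr(reps, "assay"))
    })
  })
  truth <- list(
    mu_per_h = mu,
    q_mmol_gdcw_h = gl$q_mmol_gdcw_h,
    yields = purrr::map_dbl(yields[strains], "yield"),
    config = cfg
  )
  list(growth = purrr::map_dfr(frames, "growth"),
       glucose = purrr::map_dfr(frames, "glucose"),
       assay = purrr::map_dfr(frames, "assay"),
       truth = truth)
}
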