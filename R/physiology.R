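#' Fit an exponential growth rate
#'
#' Least-squares slope of `ln(OD600)` versus time over the exponential
#' window. If no window is given, the largest contiguous run of at least
#' `min_points` points whose log-linear fit has R^2 >= `r2_min` is chosen
#' (deterministic: the earliest longest run wins; R^2 breaks length ties).
#'
#' @param growth Tibble with columns `time_h` and `od600` (> 0, times
#'   increasing).
#' @param window Optional numeric length-2 `c(t_min, t_max)` in hours.
#' @param r2_min Window-selection R^2 threshold, default 0.99.
#' @param min_points Minimum points in the window, default 3.
#' @return A `growth_fit` object wrapping the `lm`; `mu_per_h` is the slope.
#'   Use [generics::tidy()] / [generics::glance()] for coefficient and fit
#'   summaries.
#' @examples
#' gs <- tibble::tibble(time_h = 0:6, od600 = 0.05 * 2^(0:6))
#' fit_growth_rate(gs)$mu_per_h  # ln 2
#' @export
fit_growth_rate <- function(growth, window = NULL, r2_min = 0.99,
                            min_points = 3) {
  stopifnot(all(c("time_h", "od600") %in% names(growth)),
            all(growth$od600 > 0), !is.unsorted(growth$time_h))
  if (nrow(growth) < min_points) stop("need at least ", min_points, " points")
  if (!is.null(window)) {
    keep <- growth$time_h >= window[1] & growth$time_h <= window[2]
    growth <- growth[keep, ]
    if (nrow(growth) < min_points) stop("too few points in window")
    fit <- stats::lm(log(od600) ~ time_h, data = growth)
  } else {
    fit <- best_exponential_window(growth, r2_min, min_points)
  }
  structure(list(fit = fit, mu_per_h = unname(stats::coef(fit)[2]),
                 window_h = range(fit$model$time_h),
                 n = nrow(fit$model)),
            class = "growth_fit")
}

# Largest contiguous run with log-linear R^2 >= r2_min; flat series (R^2
# undefined because ln OD has zero variance) count as perfectly log-linear.
best_exponential_window <- function(growth, r2_min, min_points) {
  n <- nrow(growth)
  best <- NULL
  best_len <- 0
  best_r2 <- -Inf
  for (i in seq_len(n - min_points + 1)) {
    for (j in seq(i + min_points - 1, n)) {
      d <- growth[i:j, ]
      f <- stats::lm(log(od600) ~ time_h, data = d)
      # noiseless series fit exactly; summary() warns about perfect fits
      r2 <- suppressWarnings(summary(f)$r.squared)
      if (is.nan(r2)) r2 <- 1  # zero-variance response: exactly flat
      len <- j - i + 1
      if (r2 >= r2_min && (len > best_len || (len == best_len && r2 > best_r2))) {
        best <- f; best_len <- len; best_r2 <- r2
      }
    }
  }
  if (is.null(best)) stop("no log-linear window with R^2 >= ", r2_min)
  best
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> mu = ", format(x$mu_per_h, digits = 4), " /h over [",
      x$window_h[1], ", ", x$window_h[2], "] h (", x$n, " points)\n", sep = "")
  invisible(x)
}

#' Supernatant glucose from a 12C/13C peak ratio
#'
#' Glucose is assayed by diluting supernatant `1/dilution`, mixing
#' `mix_sample : mix_13c` with a `spike_mM` fully labeled glucose spike, and
#' taking the 12C:13C peak-intensity ratio. Because the mix dilutes both
#' channels equally, only the spike concentration, the mixing proportion and
#' the pre-dilution factor enter:
#' `S = ratio * spike_mM * (mix_13c / mix_sample) * dilution`.
#' At the defaults (1 mM spike, 50:50 mix, 1/50 dilution) this is
#' `ratio * 50` mM.
#'
#' @param ratio_12c_13c 12C/13C intensity ratio (>= 0).
#' @param spike_mM Labeled-spike concentration (mM), default 1.
#' @param mix_sample,mix_13c Mixing proportions, default 0.5 and 0.5.
#' @param dilution Pre-mix dilution factor of the supernatant, default 50.
#' @return Supernatant glucose (mM).
#' @export
glucose_concentration <- function(ratio_12c_13c, spike_mM = 1,
                                  mix_sample = 0.5, mix_13c = 0.5,
                                  dilution = 50) {
  stopifnot(all(ratio_12c_13c >= 0, na.rm = TRUE), spike_mM > 0,
            mix_sample > 0, mix_13c > 0, dilution > 0)
  ratio_12c_13c * spike_mM * (mix_13c / mix_sample) * dilution
}

#' Specific glucose consumption rate
#'
#' `q = mu * dS / dX` over the exponential window, with `dS` the substrate
#' consumed (mmol/L) and `dX` the biomass formed (gDCW/L). Biomass is
#' OD600 times a dry-cell-weight conversion; the default 0.33 g/L per OD is
#' a documented assumption (the conversion is not published for this
#' system).
#'
#' @param glucose Tibble `time_h`, `glucose_mM` (supernatant).
#' @param growth Tibble `time_h`, `od600`.
#' @param gdcw_per_od Dry cell weight per OD600 (g/L/OD), default 0.33.
#' @param window Optional exponential window (hours); defaults to the
#'   window selected by [fit_growth_rate()].
#' @return List: `q_mmol_gdcw_h`, `mu_per_h`, `window_h`, `dS_mM`,
#'   `dX_g_per_L`.
#' @export
consumption_rate <- function(glucose, growth, gdcw_per_od = 0.33,
                             window = NULL) {
  stopifnot(all(c("time_h", "glucose_mM") %in% names(glucose)),
            gdcw_per_od > 0)
  gf <- fit_growth_rate(growth, window = window)
  w <- gf$window_h
  gl <- glucose[glucose$time_h >= w[1] & glucose$time_h <= w[2], ]
  gr <- growth[growth$time_h >= w[1] & growth$time_h <= w[2], ]
  if (nrow(gl) < 2) stop("need at least 2 glucose points in the window")
  dS <- gl$glucose_mM[1] - gl$glucose_mM[nrow(gl)]
  dX <- (gr$od600[nrow(gr)] - gr$od600[1]) * gdcw_per_od
  if (dX <= 0) stop("no biomass increase over the window")
  list(q_mmol_gdcw_h = gf$mu_per_h * dS / dX, mu_per_h = gf$mu_per_h,
       window_h = w, dS_mM = dS, dX_g_per_L = dX)
}

#' Isoprene yield per glucose
#'
#' Converts a headspace reading from a sealed-vial assay into total nmol of
#' isoprene in the vial and divides by the mmol of glucose consumed by the
#' culture aliquot over the assay window. Readings can be supplied either
#' already calibrated (`isoprene_nmol_sampled`, nmol in the sampled gas
#' volume) or as an amount fraction (`fis_ppbv`), which is converted via the
#' ideal gas law at the assay temperature. The sampled amount is scaled by
#' `headspace_volume / sampled_volume` to the whole headspace.
#'
#' @param assay Tibble (one row per replicate) with columns
#'   `glucose_consumed_mmol` (> 0), `headspace_volume_mL`,
#'   `sampled_volume_mL`, and either `isoprene_nmol_sampled` or `fis_ppbv`.
#' @param temperature_K Assay temperature (K), default 303.15.
#' @param pressure_atm Headspace pressure (atm), default 1.
#' @return Tibble `yield_nmol_per_mmol` per replicate, plus summary
#'   attributes via [summarise_yields()].
#' @export
isoprene_yield <- function(assay, temperature_K = 303.15, pressure_atm = 1) {
  stopifnot(all(c("glucose_consumed_mmol", "headspace_volume_mL",
                  "sampled_volume_mL") %in% names(assay)),
            all(assay$glucose_consumed_mmol > 0),
            all(assay$headspace_volume_mL > 0),
            all(assay$sampled_volume_mL > 0))
  if ("isoprene_nmol_sampled" %in% names(assay)) {
    sampled_nmol <- assay$isoprene_nmol_sampled
  } else if ("fis_ppbv" %in% names(assay)) {
    # n = p V / (R T); 0.08206 L atm / mol K
    n_gas_mol <- pressure_atm * (assay$sampled_volume_mL / 1000) /
      (0.08206 * temperature_K)
    sampled_nmol <- assay$fis_ppbv * 1e-9 * n_gas_mol * 1e9
  } else {
    stop("assay needs isoprene_nmol_sampled or fis_ppbv")
  }
  total_nmol <- sampled_nmol * assay$headspace_volume_mL / assay$sampled_volume_mL
  dplyr::mutate(assay,
                yield_nmol_per_mmol = total_nmol / assay$glucose_consumed_mmol)
}

#' Summarise per-replicate yields into a production table
#'
#' @param yields Tibble with `strain` and `yield_nmol_per_mmol` columns
#'   (e.g. from [isoprene_yield()]).
#' @return Tibble `strain`, `yield_nmol_per_mmol` (mean), `se`, `n`.
#' @export
summarise_yields <- function(yields) {
  yields |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(n = dplyr::n(),
                     se = stats::sd(.data$yield_nmol_per_mmol) / sqrt(dplyr::n()),
                     yield_nmol_per_mmol = mean(.data$yield_nmol_per_mmol),
                     .groups = "drop") |>
    dplyr::select("strain", "yield_nmol_per_mmol", "se", "n")
}

#' Fold change in isoprene yield versus a control
#'
#' @param strain_yield,control_yield Yields (nmol/mmol); control > 0.
#' @return Ratio rounded to 1 decimal (half away from zero) for reporting;
#'   the unrounded value is returned as attribute `"exact"`.
#' @examples
#' yield_fold(33.3, 5.6)  # 5.9
#' @export
yield_fold <- function(strain_yield, control_yield) {
  stopifnot(all(control_yield > 0))
  fold <- strain_yield / control_yield
  out <- round_half_away(fold, 1)
  attr(out, "exact") <- fold
  out
}
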