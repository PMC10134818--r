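#' 12C/13C reference normalization
#'
#' For time-course samples, the 12C parent signal (from the experimental
#' sample) is divided by the fully labeled 13C signal (from the spiked-in
#' 13C-labeled reference extract, shared by all samples of an experiment) to
#' normalize away injection-to-injection LC-MS variation.
#'
#' @param i12_sample 12C-channel intensity of the experimental sample.
#' @param i13_reference 13C-channel intensity of the reference spike.
#' @return `i12 / i13`; a zero 13C signal yields `NA` (flagged missing).
#' @export
reference_ratio <- function(i12_sample, i13_reference) {
  if (any(i12_sample < 0, na.rm = TRUE) || any(i13_reference < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  out <- i12_sample / i13_reference
  out[!is.na(i13_reference) & i13_reference == 0] <- NA_real_
  out
}

#' OD600 normalization
#'
#' Divides a reference-normalized ratio by the OD600 at which metabolites
#' were extracted, so that signals are per unit biomass and growth during the
#' time course does not masquerade as concentration change.
#'
#' @param ratio Reference-normalized ratio.
#' @param od600 OD600 at sampling (> 0).
#' @return `ratio / od600`.
#' @export
od_normalize <- function(ratio, od600) {
  stopifnot(all(od600 > 0, na.rm = TRUE))
  ratio / od600
}

#' Fold changes versus the pre-induction state
#'
#' Runs the full time-course relative quantification on a paired-channel peak
#' table: per sample, the 12C/13C reference ratio; OD normalization; then per
#' replicate the fold change of every metabolite at each time point against
#' that replicate's own pre-induction (t = 0) value. The reported fold is the
#' geometric mean over replicates (the test statistics operate in the log2
#' domain, and the geometric mean is the matching location estimate).
#'
#' Replicates without a t = 0 observation are dropped with a warning.
#'
#' @param peaks Time-course peak table: columns `sample_id`, `strain`,
#'   `replicate`, `timepoint_min`, `metabolite_id`, `channel`
#'   (`"U12C"` = sample, `"U13C"` = reference spike), `intensity`,
#'   `od600_at_sampling`.
#' @return A `fold_change_table` tibble: `strain`, `metabolite_id`,
#'   `timepoint_min`, `fold_change` (geometric mean), `log2_fc`, `n`, plus a
#'   `log2_fc_reps` list-column of per-replicate log2 fold changes for
#'   downstream testing.
#' @export
fold_change_vs_t0 <- function(peaks) {
  validate_peak_table(peaks, timecourse = TRUE)
  norm <- peaks |>
    tidyr::pivot_wider(
      id_cols = c("sample_id", "strain", "replicate", "timepoint_min",
                  "metabolite_id", "od600_at_sampling"),
      names_from = "channel", values_from = "intensity"
    ) |>
    dplyr::mutate(
      x = od_normalize(reference_ratio(.data$U12C, .data$U13C),
                       .data$od600_at_sampling)
    )
  # per-replicate fold vs that replicate's t = 0
  norm <- norm |>
    dplyr::group_by(.data$strain, .data$replicate, .data$metabolite_id) |>
    dplyr::mutate(x0 = .data$x[match(0, .data$timepoint_min)]) |>
    dplyr::ungroup()
  dropped <- norm |>
    dplyr::filter(is.na(.data$x0)) |>
    dplyr::distinct(.data$strain, .data$replicate, .data$metabolite_id)
  if (nrow(dropped)) {
    warning(nrow(dropped), " replicate series dropped: no t = 0 observation")
    norm <- dplyr::filter(norm, !is.na(.data$x0))
  }
  out <- norm |>
    dplyr::mutate(fc = .data$x / .data$x0) |>
    dplyr::group_by(.data$strain, .data$metabolite_id, .data$timepoint_min) |>
    dplyr::summarise(
      n = sum(!is.na(.data$fc)),
      log2_fc = mean(log2(.data$fc), na.rm = TRUE),
      log2_fc_reps = list(log2(.data$fc[!is.na(.data$fc)])),
      .groups = "drop"
    ) |>
    dplyr::mutate(fold_change = 2^.data$log2_fc) |>
    dplyr::select("strain", "metabolite_id", "timepoint_min", "fold_change",
                  "log2_fc", "n", "log2_fc_reps")
  new_tbl(out, "fold_change_table")
}

#' Fold changes of overexpression strains versus a control strain
#'
#' Single-time-point design: every strain is sampled once (at the same OD),
#' quantified absolutely, and compared against the control strain
#' (GFP-overexpressing). The reported fold is the ratio of group mean
#' concentrations; per-replicate log2 concentrations are carried along for
#' the equal-variance two-sample t test.
#'
#' @param conc_reps Per-replicate value tibble with columns `strain`,
#'   `replicate`, `metabolite_id` and the value column (e.g. from
#'   [quantify_replicates()]).
#' @param control Control strain name, default `"GFP"`.
#' @param values_from Value column name, default `"molarity_M"`; pass an
#'   intensity column to fold on raw signals (how relative-only metabolites
#'   such as CDP-MEP are handled).
#' @return A `fold_change_table` tibble: `strain`, `metabolite_id`,
#'   `fold_change` (ratio of group means vs control), `log2_fc`, `n`, with
#'   list-columns `log2_reps` and `log2_reps_control` for testing.
#' @export
fold_change_vs_control <- function(conc_reps, control = "GFP",
                                   values_from = "molarity_M") {
  stopifnot(all(c("strain", "replicate", "metabolite_id", values_from) %in%
                  names(conc_reps)))
  if (!control %in% conc_reps$strain) {
    stop("control strain not present: ", control)
  }
  conc_reps$.value <- conc_reps[[values_from]]
  ctrl <- conc_reps |>
    dplyr::filter(.data$strain == control) |>
    dplyr::group_by(.data$metabolite_id) |>
    dplyr::summarise(
      mean_control = mean(.data$.value, na.rm = TRUE),
      log2_reps_control = list(log2(.data$.value[!is.na(.data$.value)])),
      .groups = "drop"
    )
  out <- conc_reps |>
    dplyr::filter(.data$strain != control) |>
    dplyr::group_by(.data$strain, .data$metabolite_id) |>
    dplyr::summarise(
      n = sum(!is.na(.data$.value)),
      mean_strain = mean(.data$.value, na.rm = TRUE),
      log2_reps = list(log2(.data$.value[!is.na(.data$.value)])),
      .groups = "drop"
    ) |>
    dplyr::inner_join(ctrl, by = "metabolite_id") |>
    dplyr::mutate(
      fold_change = .data$mean_strain / .data$mean_control,
      log2_fc = log2(.data$fold_change)
    ) |>
    dplyr::select("strain", "metabolite_id", "fold_change", "log2_fc", "n",
                  "log2_reps", "log2_reps_control")
  new_tbl(out, "fold_change_table")
}

#' Per-replicate absolute concentrations
#'
#' Like [quantify_samples()] but without replicate aggregation: one row per
#' (sample, metabolite) with its intracellular molarity. Used by the
#' single-time-point differential pipeline, which tests on per-replicate
#' log2 concentrations.
#'
#' @inheritParams quantify_samples
#' @return Tibble `sample_id`, `strain`, `replicate`, `metabolite_id`,
#'   `molarity_M`, `flag`.
#' @export
quantify_replicates <- function(peaks, standards,
                                geometry = extraction_geometry()) {
  validate_peak_table(peaks)
  stopifnot(all(c("metabolite_id", "conc_M") %in% names(standards)))
  peaks |>
    tidyr::pivot_wider(
      id_cols = c("sample_id", "strain", "replicate", "metabolite_id",
                  "od600_at_sampling"),
      names_from = "channel", values_from = "intensity"
    ) |>
    dplyr::left_join(standards, by = "metabolite_id") |>
    dplyr::mutate(
      flag = dplyr::case_when(
        is.na(.data$conc_M) ~ "no_standard",
        is.na(.data$U12C) | .data$U12C == 0 ~ "below_LOD",
        TRUE ~ "ok"
      ),
      c_extract = dplyr::if_else(
        .data$flag == "ok",
        isotope_ratio_concentration(.data$U13C, .data$U12C,
                                    dplyr::coalesce(.data$conc_M, 1)),
        NA_real_),
      molarity_M = extract_to_intracellular(.data$c_extract, geometry,
                                            .data$od600_at_sampling)
    ) |>
    dplyr::select("sample_id", "strain", "replicate", "metabolite_id",
                  "molarity_M", "flag")
}
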