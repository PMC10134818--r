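#' Extraction geometry for filter-based metabolite extraction
#'
#' Volumes describing the fast-filtration extraction: culture volume passed
#' through the filter, cold-solvent volume the filter is immersed in, the
#' cytoplasmic aqueous volume per OD600 unit per mL of culture (used to
#' convert extract molarity to intracellular molarity), and any residual
#' medium carried over on the filter (used by the extracellular correction).
#'
#' The biovolume constant is not published for this system; the default of
#' 3.0 uL per OD.mL is a documented assumption and should be set explicitly
#' when absolute accuracy matters.
#'
#' @param culture_volume_mL Culture volume filtered (mL), default 10.
#' @param solvent_volume_mL Extraction solvent volume (mL), default 1.5.
#' @param biovolume_uL_per_OD_mL Cytoplasmic aqueous volume per OD600 per mL
#'   culture (uL), default 3.0.
#' @param carryover_uL Residual medium on the filter (uL), default 0.
#' @return An `extraction_geometry` list.
#' @export
extraction_geometry <- function(culture_volume_mL = 10,
                                solvent_volume_mL = 1.5,
                                biovolume_uL_per_OD_mL = 3.0,
                                carryover_uL = 0) {
  stopifnot(culture_volume_mL > 0, solvent_volume_mL > 0,
            biovolume_uL_per_OD_mL > 0, carryover_uL >= 0)
  structure(list(culture_volume_mL = culture_volume_mL,
                 solvent_volume_mL = solvent_volume_mL,
                 biovolume_uL_per_OD_mL = biovolume_uL_per_OD_mL,
                 carryover_uL = carryover_uL),
            class = "extraction_geometry")
}

#' Isotope-ratio concentration estimate
#'
#' Absolute quantification by isotope dilution: cells grown on \[U-13C\]
#' glucose are extracted into solvent containing unlabeled standards of known
#' concentration, and the analyte concentration in the extract is the
#' labeled:unlabeled intensity ratio times the standard concentration.
#' The estimate is invariant to any common rescaling of both channels.
#'
#' @param i13 13C-channel intensity (the analyte; arbitrary units, >= 0).
#' @param i12 12C-channel intensity (the spiked standard; >= 0).
#' @param c_std Standard concentration in the extract (M, > 0).
#' @return Extract molarity `(i13 / i12) * c_std`. A zero 12C intensity
#'   yields `NA` (below the limit of detection), not an error; negative
#'   inputs are errors.
#' @examples
#' isotope_ratio_concentration(2e6, 1e6, 50e-6)  # 100 uM
#' @export
isotope_ratio_concentration <- function(i13, i12, c_std) {
  if (any(i13 < 0, na.rm = TRUE) || any(i12 < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  stopifnot(all(c_std > 0, na.rm = TRUE))
  out <- (i13 / i12) * c_std
  out[!is.na(i12) & i12 == 0] <- NA_real_
  out
}

#' Convert extract molarity to intracellular molarity
#'
#' Moles in the extract (`c_extract * solvent_volume`) divided by the total
#' cytoplasmic volume collected on the filter
#' (`od600 * culture_volume * biovolume`).
#'
#' @param c_extract Molarity in the extraction solvent (M).
#' @param geometry An [extraction_geometry()].
#' @param od600 Culture OD600 at sampling (> 0).
#' @return Intracellular molarity (M).
#' @export
extract_to_intracellular <- function(c_extract, geometry = extraction_geometry(),
                                     od600) {
  stopifnot(inherits(geometry, "extraction_geometry"), all(od600 > 0))
  cyto_mL <- od600 * geometry$culture_volume_mL *
    geometry$biovolume_uL_per_OD_mL * 1e-3
  c_extract * geometry$solvent_volume_mL / cyto_mL
}

# inverse mapping used by the generator
intracellular_to_extract <- function(c_intra, geometry, od600) {
  cyto_mL <- od600 * geometry$culture_volume_mL *
    geometry$biovolume_uL_per_OD_mL * 1e-3
  c_intra * cyto_mL / geometry$solvent_volume_mL
}

#' Correct filter totals for carried-over extracellular metabolite
#'
#' Pyruvate and MEcDP are partly excreted; medium retained on the filter
#' contributes extracellular moles that are subtracted from the filter total.
#' The result is clamped at zero (with a warning) if the correction exceeds
#' the total.
#'
#' @param total_on_filter Total moles measured on the filter.
#' @param c_extracellular Extracellular (supernatant) molarity (M).
#' @param geometry An [extraction_geometry()]; only `carryover_uL` is used.
#' @return Corrected moles, never negative.
#' @export
extracellular_correction <- function(total_on_filter, c_extracellular,
                                     geometry = extraction_geometry()) {
  stopifnot(inherits(geometry, "extraction_geometry"))
  corrected <- total_on_filter - c_extracellular * geometry$carryover_uL * 1e-6
  if (any(corrected < 0, na.rm = TRUE)) {
    warning("extracellular correction exceeded filter total; clamped to 0")
    corrected <- pmax(corrected, 0)
  }
  corrected
}

#' Absolute quantification of a paired-channel peak table
#'
#' Runs the isotope-ratio estimator on every (sample, metabolite) pair of a
#' peak table from the isotope-dilution design (13C-labeled cells, unlabeled
#' standards), converts extract molarity to intracellular molarity via the
#' extraction geometry and the sampling OD600, and summarises replicates into
#' a concentration table with a normal-theory (t-interval) 95% CI.
#'
#' Metabolites with no spiked standard (CDP-MEP has no purified standard) are
#' flagged `no_standard`; samples with a missing or zero 12C channel are
#' flagged `below_LOD`; a zero 13C channel gives 0 M with a `below_LOD` flag.
#'
#' @param peaks A peak table tibble with columns `sample_id`, `strain`,
#'   `replicate`, `metabolite_id`, `channel` (`"U12C"`/`"U13C"`),
#'   `intensity`, `od600_at_sampling` (see [read_peak_table()]).
#' @param standards Tibble with columns `metabolite_id`, `conc_M`: standard
#'   concentrations in the extraction solvent.
#' @param geometry An [extraction_geometry()].
#' @param conf_level Confidence level for the CI, default 0.95.
#' @return A `conc_table` tibble: `metabolite_id`, `molarity_M`, `ci_lo`,
#'   `ci_hi`, `n`, `flag` in `{ok, below_LOD, no_standard}`, grouped by
#'   `strain` when more than one strain is present.
#' @export
quantify_samples <- function(peaks, standards, geometry = extraction_geometry(),
                             conf_level = 0.95) {
  validate_peak_table(peaks)
  stopifnot(all(c("metabolite_id", "conc_M") %in% names(standards)))
  wide <- peaks |>
    tidyr::pivot_wider(
      id_cols = c("sample_id", "strain", "replicate", "metabolite_id",
                  "od600_at_sampling"),
      names_from = "channel", values_from = "intensity"
    )
  if (!"U12C" %in% names(wide)) wide$U12C <- NA_real_
  if (!"U13C" %in% names(wide)) wide$U13C <- NA_real_
  wide <- wide |>
    dplyr::left_join(standards, by = "metabolite_id") |>
    dplyr::mutate(
      no_standard = is.na(.data$conc_M),
      c_extract = dplyr::if_else(
        .data$no_standard, NA_real_,
        isotope_ratio_concentration(
          .data$U13C, .data$U12C,
          dplyr::if_else(.data$no_standard, 1, .data$conc_M))
      ),
      molarity = extract_to_intracellular(.data$c_extract, geometry,
                                          .data$od600_at_sampling)
    )
  out <- wide |>
    dplyr::group_by(.data$strain, .data$metabolite_id) |>
    dplyr::summarise(
      n = sum(!is.na(.data$molarity)),
      molarity_M = mean(.data$molarity[!is.na(.data$molarity)]),
      sd = stats::sd(.data$molarity[!is.na(.data$molarity)]),
      flag = dplyr::case_when(
        any(.data$no_standard) ~ "no_standard",
        any(is.na(.data$U12C) | .data$U12C == 0) ~ "below_LOD",
        all(.data$U13C == 0, na.rm = TRUE) ~ "below_LOD",
        TRUE ~ "ok"
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      molarity_M = dplyr::if_else(.data$flag == "no_standard", NA_real_,
                                  .data$molarity_M),
      se = .data$sd / sqrt(.data$n),
      tcrit = stats::qt(1 - (1 - conf_level) / 2, pmax(.data$n - 1, 1)),
      ci_lo = dplyr::if_else(.data$n >= 2,
                             .data$molarity_M - .data$tcrit * .data$se,
                             NA_real_),
      ci_hi = dplyr::if_else(.data$n >= 2,
                             .data$molarity_M + .data$tcrit * .data$se,
                             NA_real_)
    ) |>
    dplyr::select("strain", "metabolite_id", "molarity_M", "ci_lo", "ci_hi",
                  "n", "flag")
  new_tbl(out, "conc_table")
}

new_tbl <- function(x, cls) {
  class(x) <- unique(c(cls, class(tibble::tibble())))
  x
}
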