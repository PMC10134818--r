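#' Read and validate a peak table
#'
#' Peak tables are UTF-8 tab-separated text with one row per (sample,
#' metabolite, channel): columns `sample_id`, `strain`, `replicate`,
#' `timepoint_min`, `metabolite_id`, `channel` (`U12C`/`U13C`),
#' `intensity`, `od600_at_sampling`. Scientific notation is accepted on
#' read. Metabolite ids are normalized to the pathway map's canonical ids
#' (case-insensitive, punctuation variants of the combined IDP/DMADP pool
#' accepted); unknown ids are an error naming the offenders.
#'
#' @param path TSV file path.
#' @param pathway A `pathway_map` for id normalization; `NULL` skips it.
#' @return A validated peak-table tibble.
#' @export
read_peak_table <- function(path, pathway = mep_pathway()) {
  pt <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "strain", "replicate", "timepoint_min",
                "metabolite_id", "channel", "intensity", "od600_at_sampling")
  miss <- setdiff(required, names(pt))
  if (length(miss)) {
    stop("peak table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.null(pathway)) {
    pt$metabolite_id <- canonical_metabolite_ids(pt$metabolite_id, pathway)
  }
  validate_peak_table(pt)
  pt
}

#' Write a peak table as TSV
#'
#' @param peaks Peak-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  validate_peak_table(peaks)
  readr::write_tsv(peaks, path, progress = FALSE)
  invisible(path)
}

validate_peak_table <- function(peaks, timecourse = FALSE) {
  required <- c("sample_id", "strain", "replicate", "metabolite_id",
                "channel", "intensity", "od600_at_sampling")
  if (timecourse) required <- c(required, "timepoint_min")
  miss <- setdiff(required, names(peaks))
  if (length(miss)) {
    stop("peak table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(peaks$intensity < 0, na.rm = TRUE)) stop("negative intensities")
  if (any(peaks$od600_at_sampling <= 0, na.rm = TRUE)) stop("OD600 must be > 0")
  bad <- setdiff(unique(peaks$channel), c("U12C", "U13C"))
  if (length(bad)) stop("unknown channel value(s): ", paste(bad, collapse = ", "))
  dup <- peaks |>
    dplyr::count(.data$sample_id, .data$metabolite_id, .data$channel) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate (sample, metabolite, channel) rows, e.g. ",
         dup$sample_id[1], " / ", dup$metabolite_id[1])
  }
  invisible(peaks)
}

#' Write a concentration table as CSV
#'
#' Molarity columns are rendered in `%.4E` scientific notation, mirroring
#' the reference-table style; values are stored internally in molar.
#'
#' @param ct A `conc_table` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_conc_table <- function(ct, path) {
  out <- ct |>
    dplyr::mutate(dplyr::across(dplyr::any_of(c("molarity_M", "ci_lo", "ci_hi")),
                                ~ ifelse(is.na(.x), "", sprintf("%.4E", .x))))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a fold-change table as CSV
#'
#' List-columns of per-replicate log2 values are dropped; everything else is
#' written as-is.
#'
#' @param fct A `fold_change_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fold_change_table <- function(fct, path) {
  out <- dplyr::select(fct, -dplyr::where(is.list))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
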