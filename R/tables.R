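#' Reference intracellular concentrations for wild-type Z. mobilis ZM4
#'
#' The published steady-state intracellular metabolite concentrations of
#' anaerobically grown wild-type *Z. mobilis* ZM4 (ED glycolysis, MEP pathway,
#' nucleotides, cofactors), shipped as a plain CSV. These molarities are used
#' as the generator's default ground truth and as the concentration input for
#' pool accounting and thermodynamics.
#'
#' @return A tibble with columns `metabolite` (full name), `abbreviation`
#'   (the id used throughout the package), `molarity_M`, `source`.
#' @examples
#' zm4_concentrations()
#' @export
zm4_concentrations <- function() {
  path <- system.file("extdata", "zm4_metabolite_concentrations.csv",
                      package = "mepscope", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Reference isoprene production per glucose by engineered strains
#'
#' Headspace isoprene yields (nmol isoprene per mmol glucose consumed) of
#' *Z. mobilis* strains overexpressing isoprene synthase alone or with MEP
#' pathway enzymes, with standard errors and replicate counts. Used as the
#' physiology generator's ground truth.
#'
#' @return A tibble with columns `strain`, `genes`, `yield_nmol_per_mmol`,
#'   `se`, `n`, `significant_vs_gfp`.
#' @export
isoprene_production_table <- function() {
  path <- system.file("extdata", "isoprene_production.csv",
                      package = "mepscope", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Concentration vector keyed by metabolite id
#'
#' Convenience: named numeric vector of molarities from a concentration
#' table (either the reference table or a [quantify_samples()] result).
#'
#' @param ct A tibble with an id column (`abbreviation` or `metabolite_id`)
#'   and a molarity column (`molarity_M`).
#' @return Named numeric vector (M).
#' @export
concentration_vector <- function(ct) {
  idcol <- intersect(c("metabolite_id", "abbreviation"), names(ct))[1]
  if (is.na(idcol)) stop("no metabolite id column found")
  stopifnot("molarity_M" %in% names(ct))
  keep <- !is.na(ct$molarity_M)
  stats::setNames(ct$molarity_M[keep], ct[[idcol]][keep])
}

# Canonical-id lookup: case-insensitive, with common punctuation variants
# ("IDP_DMADP", "idp-dmadp" -> "IDP/DMADP").
canonical_metabolite_ids <- function(ids, pathway = mep_pathway()) {
  canon <- pathway$metabolites$id
  norm <- function(x) gsub("[^a-z0-9]+", "", tolower(x))
  lut <- stats::setNames(canon, norm(canon))
  # the combined pool id collapses to "idpdmadp" either way
  out <- unname(lut[norm(ids)])
  unknown <- unique(ids[is.na(out)])
  if (length(unknown)) {
    stop("unknown metabolite id(s): ", paste(unknown, collapse = ", "))
  }
  out
}
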