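#' Sum a metabolite pool from a concentration table
#'
#' A category pool (e.g. "MEP pathway", "ED glycolysis") is the sum of the
#' absolute intracellular concentrations of its member metabolites. Members
#' whose concentration is flagged (`no_standard`, `below_LOD`) or absent are
#' excluded from the sum and reported explicitly rather than silently
#' imputed as zero.
#'
#' @param ct Concentration table: tibble with `metabolite_id` (or
#'   `abbreviation`) and `molarity_M` columns, optionally `flag`.
#' @param members Character vector of member metabolite ids.
#' @param pool Name for the pool (used in output), default
#'   deparsed from `members`.
#' @return A `pool_summary` list: `pool`, `members`, `included`, `excluded`
#'   (tibble of id + reason), `total_M`, `n_included`.
#' @examples
#' ct <- zm4_concentrations()
#' pool_sum(ct, mep_pathway()$pools$MEP, pool = "MEP")
#' @export
pool_sum <- function(ct, members, pool = "pool") {
  idcol <- intersect(c("metabolite_id", "abbreviation"), names(ct))[1]
  if (is.na(idcol)) stop("no metabolite id column found")
  stopifnot("molarity_M" %in% names(ct), length(members) > 0)
  idx <- match(members, ct[[idcol]])
  reason <- rep(NA_character_, length(members))
  reason[is.na(idx)] <- "not measured"
  flags <- if ("flag" %in% names(ct)) ct$flag[idx] else rep("ok", length(idx))
  reason[!is.na(idx) & !is.na(flags) & flags != "ok"] <- flags[!is.na(idx) & !is.na(flags) & flags != "ok"]
  vals <- ct$molarity_M[idx]
  reason[!is.na(idx) & is.na(vals) & is.na(reason)] <- "missing value"
  include <- is.na(reason)
  if (!any(include)) stop("pool ", pool, ": no usable members")
  structure(list(
    pool = pool,
    members = members,
    included = members[include],
    excluded = tibble::tibble(metabolite_id = members[!include],
                              reason = reason[!include]),
    total_M = sum(vals[include]),
    n_included = sum(include)
  ), class = "pool_summary")
}

#' @export
print.pool_summary <- function(x, ...) {
  cat("<pool_summary> ", x$pool, ": ", format(x$total_M, digits = 5), " M over ",
      x$n_included, " metabolites\n", sep = "")
  if (nrow(x$excluded)) {
    cat("excluded: ",
        paste(x$excluded$metabolite_id, " (", x$excluded$reason, ")",
              sep = "", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Ratio of two pool sums
#'
#' @param a,b `pool_summary` objects (numerator, denominator).
#' @return `a$total_M / b$total_M`; errors on a zero denominator.
#' @export
pool_ratio <- function(a, b) {
  stopifnot(inherits(a, "pool_summary"), inherits(b, "pool_summary"))
  if (b$total_M == 0) stop("zero denominator pool: ", b$pool)
  a$total_M / b$total_M
}

#' Summarise all pathway pools of a concentration table
#'
#' @param ct Concentration table (see [pool_sum()]).
#' @param pathway A `pathway_map`; its `pools` define memberships.
#' @return Tibble: `pool`, `total_M`, `n_included`, `n_excluded`.
#' @export
pool_summary_table <- function(ct, pathway = mep_pathway()) {
  purrr::map_dfr(names(pathway$pools), function(p) {
    ps <- pool_sum(ct, pathway$pools[[p]], pool = p)
    tibble::tibble(pool = p, total_M = ps$total_M,
                   n_included = ps$n_included,
                   n_excluded = nrow(ps$excluded))
  })
}

#' Round half away from zero
#'
#' Integer-fold claims (e.g. "38-fold higher") use commercial rounding, not
#' banker's rounding: halves round away from zero.
#'
#' @param x Numeric vector.
#' @param digits Decimal places, default 0.
#' @return Rounded values.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
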