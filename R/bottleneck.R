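#' Reaction-level accumulation scores
#'
#' Formalizes the bottleneck reasoning as a score per reaction:
#' `score = log2(FC of main substrate) - log2(FC of main product)` (bits).
#' A reaction whose substrate accumulates much faster than its product is a
#' candidate bottleneck; the default call requires at least 1 bit (2-fold
#' differential accumulation) and a significant substrate fold change.
#' A score at or below `-threshold` is classified `mitigated` (carbon
#' mobilized through the step); anything else is `none`. The score is
#' exactly antisymmetric under substrate/product swap. The study makes these
#' calls qualitatively; the numeric criterion is this package's explicit
#' formalization.
#'
#' @param fct A `fold_change_table` (single-time-point, or time-course
#'   filtered via `timepoint`).
#' @param pathway A `pathway_map`.
#' @param timepoint For time-course tables, the time point (min) to score.
#' @param threshold Bottleneck call threshold in bits, default 1.
#' @param strain Strain to score; defaults to the only non-control strain
#'   present.
#' @return A `bottleneck_scores` tibble: `reaction`, `substrate`, `product`,
#'   `substrate_fc`, `product_fc`, `score_bits`, `substrate_significant`,
#'   `classification`, ranked by decreasing score. Reactions with either
#'   fold change missing are skipped with a message.
#' @export
accumulation_scores <- function(fct, pathway = mep_pathway(),
                                timepoint = NULL, threshold = 1,
                                strain = NULL) {
  stopifnot(inherits(fct, "fold_change_table") || is.data.frame(fct))
  d <- fct
  if (!is.null(timepoint)) {
    stopifnot("timepoint_min" %in% names(d))
    d <- dplyr::filter(d, .data$timepoint_min == timepoint)
  }
  if (!is.null(strain)) d <- dplyr::filter(d, .data$strain == strain)
  if (dplyr::n_distinct(d$strain) > 1) {
    stop("fold changes from multiple strains; pick one with `strain`")
  }
  fc <- stats::setNames(d$fold_change, d$metabolite_id)
  sig <- if ("significant" %in% names(d)) {
    stats::setNames(d$significant, d$metabolite_id)
  } else {
    stats::setNames(rep(NA, nrow(d)), d$metabolite_id)
  }
  rxns <- pathway$reactions
  out <- purrr::map_dfr(seq_len(nrow(rxns)), function(i) {
    s <- rxns$main_substrate[i]
    p <- rxns$main_product[i]
    if (is.na(fc[s]) || is.na(fc[p]) || !s %in% names(fc) || !p %in% names(fc)) {
      return(tibble::tibble())
    }
    score <- log2(fc[[s]]) - log2(fc[[p]])
    ssig <- sig[[s]]
    cls <- if (score >= threshold && isTRUE(ssig)) "bottleneck"
           else if (score >= threshold && is.na(ssig)) "bottleneck"
           else if (score <= -threshold) "mitigated"
           else "none"
    tibble::tibble(reaction = rxns$id[i], substrate = s, product = p,
                   substrate_fc = fc[[s]], product_fc = fc[[p]],
                   score_bits = score,
                   substrate_significant = ssig,
                   classification = cls)
  })
  if (!nrow(out)) {
    out <- tibble::tibble(reaction = character(), substrate = character(),
                          product = character(), substrate_fc = numeric(),
                          product_fc = numeric(), score_bits = numeric(),
                          substrate_significant = logical(),
                          classification = character())
  }
  skipped <- setdiff(rxns$id, out$reaction)
  if (length(skipped)) {
    message("skipped (missing fold changes): ", paste(skipped, collapse = ", "))
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$score_bits))
  new_tbl(out, "bottleneck_scores")
}

#' Write the bottleneck report
#'
#' Renders the combined analysis - ranked bottleneck scores, pool totals,
#' the in vivo free-energy table and significance flags - as a Markdown
#' summary plus a machine-readable JSON file that re-parses to the same
#' structures.
#'
#' @param scores A `bottleneck_scores` tibble (may be empty).
#' @param pools Pool summary tibble from [pool_summary_table()] (optional).
#' @param dg_table A `dg_table` from [pathway_dg_table()] (optional).
#' @param out Output directory (created if needed).
#' @param name Base filename, default `"bottleneck_report"`.
#' @return Invisibly, the paths of the two files written.
#' @export
render_report <- function(scores, pools = NULL, dg_table = NULL,
                          out = ".", name = "bottleneck_report") {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  md <- file.path(out, paste0(name, ".md"))
  js <- file.path(out, paste0(name, ".json"))
  lines <- c("# MEP pathway bottleneck report", "")
  if (nrow(scores)) {
    called <- dplyr::filter(scores, .data$classification == "bottleneck")
    lines <- c(lines, "## Ranked accumulation scores",
               "(score = log2 substrate fold - log2 product fold; the numeric",
               "bottleneck call is this package's formalization of a",
               "qualitative judgement)", "",
               paste0("- ", scores$reaction, ": ",
                      sprintf("%.2f", scores$score_bits), " bits [",
                      scores$classification, "]"),
               "",
               if (nrow(called)) {
                 paste0("Top-ranked bottleneck: **", called$reaction[1], "**")
               } else "No reaction meets the bottleneck criterion.", "")
  } else {
    lines <- c(lines, "No scorable reactions (empty input).", "")
  }
  if (!is.null(pools) && nrow(pools)) {
    lines <- c(lines, "## Pool totals (M)",
               paste0("- ", pools$pool, ": ",
                      sprintf("%.4E", pools$total_M), " (",
                      pools$n_included, " metabolites)"), "")
  }
  if (!is.null(dg_table) && nrow(dg_table)) {
    dd <- dg_table
    lines <- c(lines, "## In vivo reaction energies (kJ/mol)",
               paste0("- ", dd$reaction, ": ",
                      ifelse(is.na(dd$dg_in_vivo), paste0("[", dd$flag, "]"),
                             sprintf("%.1f", dd$dg_in_vivo))), "")
  }
  writeLines(lines, md)
  payload <- list(
    scores = if (nrow(scores)) scores else list(),
    pools = pools,
    dg_table = if (!is.null(dg_table)) {
      dplyr::mutate(dg_table, missing = purrr::map(.data$missing, as.list))
    },
    top_bottleneck = if (nrow(scores) &&
                         any(scores$classification == "bottleneck")) {
      scores$reaction[scores$classification == "bottleneck"][1]
    }
  )
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(markdown = md, json = js))
}

#' Run the full synthetic-data pipeline
#'
#' Composes every stage for one scenario: generate synthetic data, quantify
#' or normalize, test with BH-FDR, aggregate pools, evaluate thermodynamics
#' and score bottlenecks. Deterministic for a fixed config and seed.
#'
#' @param cfg A [sim_config()].
#' @param timepoint Time point (min) scored for bottlenecks in time-course
#'   designs, default 60.
#' @param alpha FDR level, default 0.05.
#' @param out Optional output directory; when given, the report files are
#'   written there.
#' @return List: `fold_changes` (tested table), `conc` (concentration table
#'   where applicable), `scores`, `pools`, `dg_table`, `truth`.
#' @export
run_pipeline <- function(cfg, timepoint = 60, alpha = 0.05, out = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$design == "single_timepoint") {
    sim <- simulate_single_timepoint(cfg)
    standards <- tibble::tibble(metabolite_id = names(cfg$std_conc),
                                conc_M = unname(cfg$std_conc))
    # fold on the analyte-channel intensities so relative-only metabolites
    # (CDP-MEP) participate; identical to concentration folds when response
    # factors are strain-independent
    ireps <- sim$peaks |>
      dplyr::filter(.data$channel == "U13C") |>
      dplyr::select("strain", "replicate", "metabolite_id", "intensity")
    fct <- fold_change_vs_control(ireps, control = "GFP",
                                  values_from = "intensity") |>
      test_fold_changes(alpha = alpha)
    ct <- quantify_samples(sim$peaks, standards, cfg$geometry) |>
      dplyr::filter(.data$strain != "GFP")
    scores <- accumulation_scores(fct)
  } else {
    sim <- simulate_timecourse(cfg)
    fct <- fold_change_vs_t0(sim$peaks) |>
      test_fold_changes(alpha = alpha)
    ct <- NULL
    scores <- accumulation_scores(fct, timepoint = timepoint)
  }
  conc_for_pools <- if (!is.null(ct)) ct else zm4_concentrations()
  pools <- pool_summary_table(conc_for_pools)
  dg <- pathway_dg_table(zm4_concentrations())
  if (!is.null(out)) render_report(scores, pools, dg, out = out)
  list(fold_changes = fct, conc = ct, scores = scores, pools = pools,
       dg_table = dg, truth = sim$truth)
}
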