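#' Equal-variance two-sample t test on log2 values
#'
#' The single-time-point design tests log2-transformed signals of an
#' overexpression strain against the GFP control with a two-tailed pooled
#' variance t test (`df = n_a + n_b - 2`).
#'
#' @param log2_a,log2_b Numeric vectors of log2 values, each of length >= 2.
#' @return One-row tibble: `t_statistic`, `df`, `p_value`, `mean_diff`.
#'   Identical groups with zero pooled variance give `t = 0`, `p = 1`.
#' @examples
#' two_sample_t_equal_var(c(1, 2, 3), c(4, 5, 6))
#' @export
two_sample_t_equal_var <- function(log2_a, log2_b) {
  log2_a <- log2_a[!is.na(log2_a)]
  log2_b <- log2_b[!is.na(log2_b)]
  if (length(log2_a) < 2 || length(log2_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  df <- length(log2_a) + length(log2_b) - 2
  md <- mean(log2_a) - mean(log2_b)
  if (stats::sd(log2_a) == 0 && stats::sd(log2_b) == 0) {
    # degenerate: no within-group variance
    if (md == 0) {
      return(tibble::tibble(t_statistic = 0, df = df, p_value = 1, mean_diff = 0))
    }
    return(tibble::tibble(t_statistic = sign(md) * Inf, df = df, p_value = 0,
                          mean_diff = md))
  }
  ht <- stats::t.test(log2_a, log2_b, var.equal = TRUE)
  tibble::tibble(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_diff = md)
}

#' Paired t test of per-replicate log2 fold changes against baseline
#'
#' The time-course design pairs each post-induction sample with its own
#' replicate's pre-induction value; the paired two-tailed t test is
#' algebraically a one-sample t of the per-replicate log2 fold changes
#' against 0 (`df = n - 1`).
#'
#' @param log2_fc_reps Per-replicate log2 fold changes, length >= 2.
#' @return One-row tibble: `t_statistic`, `df`, `p_value`, `mean_log2_fc`,
#'   `degenerate` (TRUE when the replicate variance is exactly zero with a
#'   nonzero mean, where p underflows to 0).
#' @examples
#' paired_t_vs_baseline(c(1.0, 1.2, 0.8))
#' @export
paired_t_vs_baseline <- function(log2_fc_reps) {
  x <- log2_fc_reps[!is.na(log2_fc_reps)]
  if (length(x) < 2) stop("need at least 2 replicates")
  df <- length(x) - 1
  if (stats::sd(x) == 0) {
    if (mean(x) == 0) {
      return(tibble::tibble(t_statistic = 0, df = df, p_value = 1,
                            mean_log2_fc = 0, degenerate = FALSE))
    }
    return(tibble::tibble(t_statistic = sign(mean(x)) * Inf, df = df,
                          p_value = 0, mean_log2_fc = mean(x),
                          degenerate = TRUE))
  }
  ht <- stats::t.test(x, mu = 0)
  tibble::tibble(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_log2_fc = mean(x),
                 degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment with the usual cumulative-minimum
#' monotonicity enforcement; input order is preserved and ties are handled
#' deterministically.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return q values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Attach q values and significance flags to a results table
#'
#' Applies [bh_adjust()] over a chosen family of tests and flags results at
#' `q < alpha`. For time-course tables the family defaults to all
#' metabolite-by-timepoint tests within one experiment (strain); a
#' per-metabolite "significant at any time point" flag is added, matching
#' how time-course significance is marked per metabolite.
#'
#' @param results Tibble with a `p_value` column, and `strain` /
#'   `timepoint_min` columns as applicable.
#' @param alpha FDR level, default 0.05.
#' @param scope BH family: `"per_experiment"` (default; within strain),
#'   `"per_timepoint"` (within strain and time point) or `"global"`.
#' @return `results` with `q_value`, `significant`, and (when
#'   `timepoint_min` is present) `significant_any_timepoint` columns.
#' @export
flag_significance <- function(results, alpha = 0.05,
                              scope = c("per_experiment", "per_timepoint",
                                        "global")) {
  scope <- match.arg(scope)
  stopifnot("p_value" %in% names(results), alpha > 0, alpha < 1)
  grp <- switch(scope,
    global = character(0),
    per_experiment = intersect("strain", names(results)),
    per_timepoint = intersect(c("strain", "timepoint_min"), names(results))
  )
  out <- results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(q_value = bh_adjust(.data$p_value),
                  significant = !is.na(.data$q_value) & .data$q_value < alpha) |>
    dplyr::ungroup()
  if ("timepoint_min" %in% names(out)) {
    by <- intersect(c("strain", "metabolite_id"), names(out))
    out <- out |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::mutate(significant_any_timepoint = any(.data$significant)) |>
      dplyr::ungroup()
  }
  out
}

#' Run the design-appropriate tests on a fold-change table
#'
#' For time-course tables (with `log2_fc_reps`), a paired t of per-replicate
#' log2 fold changes against baseline at each (strain, metabolite, time
#' point), with t = 0 rows exempted (fold is identically 1 there). For
#' single-time-point tables (with `log2_reps` / `log2_reps_control`), an
#' equal-variance two-sample t against the control strain.
#'
#' @param fct A `fold_change_table`.
#' @param alpha,scope Passed to [flag_significance()].
#' @return The table extended with `t_statistic`, `df`, `p_value`,
#'   `q_value`, `significant` (and the any-timepoint flag for time courses).
#' @export
test_fold_changes <- function(fct, alpha = 0.05, scope = "per_experiment") {
  if ("log2_fc_reps" %in% names(fct)) {
    tested <- fct |>
      dplyr::mutate(res = purrr::map2(.data$log2_fc_reps, .data$timepoint_min,
        function(reps, tp) {
          if (tp == 0) {
            return(tibble::tibble(t_statistic = NA_real_, df = NA_real_,
                                  p_value = NA_real_))
          }
          paired_t_vs_baseline(reps)[, c("t_statistic", "df", "p_value")]
        })) |>
      tidyr::unnest("res")
    tested |>
      dplyr::filter(.data$timepoint_min > 0) |>
      flag_significance(alpha = alpha, scope = scope) |>
      dplyr::bind_rows(dplyr::filter(tested, .data$timepoint_min == 0)) |>
      dplyr::arrange(.data$strain, .data$metabolite_id, .data$timepoint_min) |>
      new_tbl("fold_change_table")
  } else if ("log2_reps" %in% names(fct)) {
    fct |>
      dplyr::mutate(res = purrr::map2(.data$log2_reps, .data$log2_reps_control,
        function(a, b) {
          # untestable (e.g. no standard -> no concentrations): NA stats
          if (length(a[is.finite(a)]) < 2 || length(b[is.finite(b)]) < 2) {
            return(tibble::tibble(t_statistic = NA_real_, df = NA_real_,
                                  p_value = NA_real_))
          }
          two_sample_t_equal_var(a, b)[, c("t_statistic", "df", "p_value")]
        })) |>
      tidyr::unnest("res") |>
      flag_significance(alpha = alpha, scope = scope) |>
      new_tbl("fold_change_table")
  } else {
    stop("fold-change table carries no per-replicate log2 values")
  }
}
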