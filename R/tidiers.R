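#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a growth fit
#'
#' @param x A `growth_fit` from [fit_growth_rate()].
#' @param ... Unused.
#' @return Tibble with one row per coefficient of the log-linear fit
#'   (`term`, `estimate`, `std.error`, `statistic`, `p.value`).
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' Glance at a growth fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return One-row tibble: `mu_per_h`, `r.squared`, `n`, `window_start_h`,
#'   `window_end_h`.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(mu_per_h = x$mu_per_h,
                 r.squared = suppressWarnings(summary(x$fit))$r.squared,
                 n = x$n,
                 window_start_h = x$window_h[1],
                 window_end_h = x$window_h[2])
}

#' Tidy a pool summary
#'
#' @param x A `pool_summary` from [pool_sum()].
#' @param ... Unused.
#' @return One row per member metabolite with its inclusion status.
#' @method tidy pool_summary
#' @export
tidy.pool_summary <- function(x, ...) {
  tibble::tibble(
    pool = x$pool,
    metabolite_id = x$members,
    included = x$members %in% x$included,
    reason = ifelse(x$members %in% x$included, NA_character_,
                    x$excluded$reason[match(x$members, x$excluded$metabolite_id)])
  )
}

#' Glance at a pool summary
#'
#' @param x A `pool_summary`.
#' @param ... Unused.
#' @return One-row tibble: `pool`, `total_M`, `n_included`, `n_excluded`.
#' @method glance pool_summary
#' @export
glance.pool_summary <- function(x, ...) {
  tibble::tibble(pool = x$pool, total_M = x$total_M,
                 n_included = x$n_included, n_excluded = nrow(x$excluded))
}
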