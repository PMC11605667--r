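# tidy()/glance()/autoplot() methods for run and comparison objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a run: one row per query
#'
#' @param x a `segsuggest_run`.
#' @param ... unused.
#' @return the query-log tibble (`t, section, class, cost,
#'   cumulative_cost, mean_dice`).
#' @method tidy segsuggest_run
#' @export
tidy.segsuggest_run <- function(x, ...) x$log

#' One-row summary of a run
#'
#' @param x a `segsuggest_run`.
#' @param ... unused.
#' @return tibble with strategy, iterations, bootstrap and final effort
#'   fractions, final mean Dice and the exhaustion flag.
#' @method glance segsuggest_run
#' @export
glance.segsuggest_run <- function(x, ...) {
  tibble::tibble(
    strategy = x$config$strategy,
    n_queries = nrow(x$log),
    bootstrap_cost = x$bootstrap_cost,
    total_cost = x$total_cost,
    cum_cost_frac = x$curve$cum_cost_frac[nrow(x$curve)],
    mean_dice = x$curve$mean_dice[nrow(x$curve)],
    exhausted = x$exhausted)
}

#' Tidy a comparison: the per-run summary table
#' @param x a `segsuggest_comparison`.
#' @param ... unused.
#' @return tibble with one row per (strategy, seed) run.
#' @method tidy segsuggest_comparison
#' @export
tidy.segsuggest_comparison <- function(x, ...) x$per_run

#' Per-strategy summary of a comparison
#' @param x a `segsuggest_comparison`.
#' @param ... unused.
#' @return tibble of per-strategy medians.
#' @method glance segsuggest_comparison
#' @export
glance.segsuggest_comparison <- function(x, ...) x$summary

#' Dice-versus-effort curve of one run
#'
#' @param object a `segsuggest_run`.
#' @param ... unused.
#' @return a ggplot: mean Dice against the fraction of the total boundary
#'   length manually traced (bootstrap point included).
#' @method autoplot segsuggest_run
#' @export
autoplot.segsuggest_run <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 100 * .data$cum_cost_frac, y = .data$mean_dice)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "boundary length manually traced (%)",
                  y = "mean Dice",
                  title = sprintf("strategy %s", object$config$strategy)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Dice-versus-effort curves of a strategy comparison
#'
#' @param object a `segsuggest_comparison`.
#' @param ... unused.
#' @return a ggplot with one curve per (strategy, seed), coloured by
#'   strategy.
#' @method autoplot segsuggest_comparison
#' @export
autoplot.segsuggest_comparison <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = 100 * .data$cum_cost_frac, y = .data$mean_dice,
                               colour = .data$strategy,
                               group = interaction(.data$strategy, .data$seed))) +
    ggplot2::geom_step(alpha = 0.7) +
    ggplot2::labs(x = "boundary length manually traced (%)",
                  y = "mean Dice", colour = "strategy") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
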