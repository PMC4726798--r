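# broom-style accessors for experiment objects.

#' Tidy an experiment: one row per condition
#'
#' @param x A `load_experiment`.
#' @param ... Unused.
#' @return The condition-summary tibble.
#' @export
tidy.load_experiment <- function(x, ...) {
  x$summaries
}

#' One-row summary of an experiment
#'
#' @param x A `load_experiment`.
#' @param ... Unused.
#' @return A one-row tibble with experiment-level counts and rates.
#' @export
glance.load_experiment <- function(x, ...) {
  tibble::tibble(
    experiment = x$name,
    n_conditions = nrow(x$summaries),
    n_trials = nrow(x$trials),
    accuracy = mean(x$trials$correct),
    omission_rate = mean(!x$trials$responded),
    median_latency = stats::median(
      x$trials$latency[x$trials$responded & x$trials$correct]),
    master_seed = x$master_seed)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
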