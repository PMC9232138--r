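#' Tidiers for benchmark and ensemble results
#'
#' `tidy()` on a `yc_benchmark` returns the per-class sensitivity/specificity
#' table; `glance()` returns a one-row summary (accuracy, counts). `tidy()`
#' on a `yc_ensemble` returns one row per outcome label with counts and
#' proportions; `glance()` returns the one-row report.
#'
#' @param x A `yc_benchmark` or `yc_ensemble`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.yc_benchmark <- function(x, ...) {
  attr(x, "by_class")
}

#' @rdname tidiers
#' @export
glance.yc_benchmark <- function(x, ...) {
  scored <- x[!x$skipped, ]
  tibble::tibble(
    n_mutants = nrow(scored),
    n_skipped = sum(x$skipped),
    n_correct = sum(scored$correct),
    accuracy = attr(x, "accuracy")
  )
}

#' @rdname tidiers
#' @export
tidy.yc_ensemble <- function(x, ...) {
  tab <- table(factor(x$labels))
  tibble::tibble(
    outcome = names(tab),
    n = as.integer(tab),
    proportion = as.integer(tab) / x$n_runs
  )
}

#' @rdname tidiers
#' @export
glance.yc_ensemble <- function(x, ...) {
  tibble::tibble(
    n_runs = x$n_runs,
    seed = x$seed,
    functional_fraction = x$functional_fraction,
    largest_functional_grouping = as.integer(x$basin_note)
  )
}
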