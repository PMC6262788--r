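#' Tidy and glance methods for test results
#'
#' `tidy()` returns the test as a one-row tibble; `glance()` adds the
#' group means and sizes.
#'
#' @param x an `fs_test` from [welch_t()] or [anova_with_batch()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy fs_test
#' @export
tidy.fs_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 df = if (length(x$df) == 1) x$df else x$df[1],
                 df_error = if (length(x$df) == 2) x$df[2] else NA_real_,
                 p_value = x$p_value,
                 stars = significance_stars(x$p_value))
}

#' @rdname tidy.fs_test
#' @method glance fs_test
#' @export
glance.fs_test <- function(x, ...) {
  out <- tidy.fs_test(x)
  out$n_groups <- length(x$ns)
  out$n_total <- sum(x$ns)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
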