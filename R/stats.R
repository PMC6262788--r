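#' Group comparison statistics
#'
#' The statistical layer of the pipeline: Welch's t-test for two-group
#' comparisons; one-way ANOVA with experimental batch as an additive fixed
#' effect (Type-II sums of squares) for multi-group designs; Tukey's
#' Honest Significant Difference post-hoc test gated on the ANOVA p-value;
#' and the significance star convention p < 0.05 (*), < 0.01 (**),
#' < 0.005 (***). The unit of analysis is the embryo: cell- or side-level
#' replicates should be averaged per embryo first (see
#' [aggregate_embryos()]).
#'
#' `welch_t()` computes t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param a,b numeric vectors of per-embryo values.
#' @return an object of class `fs_test` (see [tidy.fs_test()]).
#' @examples
#' welch_t(c(0.52, 0.48, 0.55, 0.50), c(0.61, 0.66, 0.63, 0.68))
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stopf("each group needs at least 2 values")
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 == 0 && v2 == 0) stopf("zero variance in both groups")
  n1 <- length(a); n2 <- length(b)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  new_fs_test(statistic = t, df = df, p_value = p, method = "welch_t",
              means = c(mean(a), mean(b)), ns = c(n1, n2))
}

#' One-way ANOVA with batch as an additive fixed effect
#'
#' Fits `value ~ group + batch` by least squares and tests the group
#' factor with Type-II sums of squares (equal to Type-I under balance,
#' robust to mild imbalance). A design in which group is aliased with
#' batch is an error.
#'
#' @param data data frame of per-embryo values.
#' @param value,group,batch column names (strings) of the response, the
#'   treatment group and the experimental batch.
#' @return an `fs_test` whose `error_ms` and `error_df` feed [tukey_hsd()].
#' @export
anova_with_batch <- function(data, value = "value", group = "group",
                             batch = "batch") {
  stopifnot(is.data.frame(data),
            all(c(value, group, batch) %in% names(data)))
  df <- data.frame(value = as.numeric(data[[value]]),
                   group = factor(data[[group]]),
                   batch = factor(data[[batch]]))
  if (nlevels(df$group) < 2) stopf("need at least 2 groups")
  if (!all(is.finite(df$value))) stopf("values must be finite")
  if (nlevels(df$batch) > 1) {
    fit <- stats::lm(value ~ group + batch, data = df)
    if (any(is.na(stats::coef(fit))))
      stopf("confounded design: 'group' is aliased with 'batch'")
  } else {
    fit <- stats::lm(value ~ group, data = df)
  }
  tab <- car::Anova(fit, type = 2)
  i <- match("group", rownames(tab))
  res <- match("Residuals", rownames(tab))
  new_fs_test(
    statistic = tab$`F value`[i], df = c(tab$Df[i], tab$Df[res]),
    p_value = tab$`Pr(>F)`[i], method = "anova_batch",
    means = tapply(df$value, df$group, mean),
    ns = as.integer(table(df$group)),
    error_ms = tab$`Sum Sq`[res] / tab$Df[res],
    error_df = tab$Df[res])
}

#' Tukey HSD pairwise comparisons
#'
#' For each pair of groups the studentized-range statistic
#' `q = |m_i - m_j| / sqrt(error_ms / 2 * (1/n_i + 1/n_j))` (Tukey-Kramer
#' for unequal n) is referred to the studentized-range distribution with
#' k groups and `error_df` degrees of freedom. The error variance comes
#' from the batch-adjusted ANOVA, which by convention must reject at
#' `gate` before the post-hoc test is run.
#'
#' @param data data frame of per-embryo values.
#' @param value,group column names of the response and the group factor.
#' @param error_ms,error_df residual mean square and degrees of freedom
#'   from [anova_with_batch()]; if `NULL` they are computed from a one-way
#'   fit without batch.
#' @param gate ANOVA p-value gate (default 0.05); set `NULL` to skip the
#'   gate check.
#' @param anova_p the gating ANOVA p-value; required when `gate` is set
#'   and `error_ms` was supplied.
#' @return tibble with one row per pair: `group1`, `group2`, `diff`, `q`,
#'   `p_adj`, `stars`.
#' @export
tukey_hsd <- function(data, value = "value", group = "group",
                      error_ms = NULL, error_df = NULL,
                      gate = 0.05, anova_p = NULL) {
  stopifnot(is.data.frame(data), all(c(value, group) %in% names(data)))
  v <- as.numeric(data[[value]])
  g <- factor(data[[group]])
  k <- nlevels(g)
  if (k < 2) stopf("Tukey HSD needs at least 2 groups")
  if (is.null(error_ms) || is.null(error_df)) {
    fit <- stats::lm(v ~ g)
    error_df <- fit$df.residual
    error_ms <- sum(stats::residuals(fit)^2) / error_df
    if (is.null(anova_p))
      anova_p <- stats::anova(fit)$`Pr(>F)`[1]
  }
  if (!is.null(gate) && !is.null(anova_p) && anova_p >= gate)
    warning(sprintf("ANOVA p = %.3g is above the %.3g gate; post-hoc test is exploratory",
                    anova_p, gate), call. = FALSE)
  m <- tapply(v, g, mean)
  n <- tapply(v, g, length)
  pairs <- utils::combn(levels(g), 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(error_ms / 2 * (1 / n[[i]] + 1 / n[[j]]))
    q <- abs(m[[i]] - m[[j]]) / se
    p <- stats::ptukey(q, nmeans = k, df = error_df, lower.tail = FALSE)
    tibble::tibble(group1 = i, group2 = j, diff = m[[j]] - m[[i]],
                   q = q, p_adj = p, stars = significance_stars(p))
  })
  fs_table(dplyr::bind_rows(rows), "tukey")
}

#' Significance stars
#'
#' `"***"` for p < 0.005, `"**"` for p < 0.01, `"*"` for p < 0.05,
#' `""` otherwise.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of star labels.
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("p must be in [0, 1]")
  ifelse(p < 0.005, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Average replicate measurements to one value per embryo
#'
#' Figure-legend n's count embryos, so cell-level or left/right replicate
#' rows are averaged within embryo before testing.
#'
#' @param data measurement table.
#' @param value value column name.
#' @param embryo,group,batch grouping column names (`batch` optional).
#' @return tibble with one row per embryo.
#' @export
aggregate_embryos <- function(data, value = "value", embryo = "embryo_id",
                              group = "group", batch = NULL) {
  stopifnot(is.data.frame(data))
  keys <- c(embryo, group, batch)
  stopifnot(all(c(keys, value) %in% names(data)))
  out <- dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(keys))),
    value = mean(.data[[value]]), .groups = "drop")
  names(out)[names(out) == "value"] <- value
  out
}

# --- fs_test object --------------------------------------------------------

new_fs_test <- function(statistic, df, p_value, method, means, ns,
                        error_ms = NULL, error_df = NULL) {
  if (!is.finite(p_value) || p_value < 0 || p_value > 1)
    stopf("computed p-value is not in [0, 1]")
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, means = means, ns = ns,
                 error_ms = error_ms, error_df = error_df),
            class = "fs_test")
}

#' @export
print.fs_test <- function(x, ...) {
  lab <- switch(x$method, welch_t = "Welch's t-test",
                anova_batch = "one-way ANOVA with batch effect", x$method)
  stat <- if (x$method == "welch_t")
    sprintf("t = %.4g, df = %.3g", x$statistic, x$df)
  else
    sprintf("F(%g, %g) = %.4g", x$df[1], x$df[2], x$statistic)
  cat(sprintf("<fs_test> %s: %s, p = %.4g %s\n", lab, stat, x$p_value,
              significance_stars(x$p_value)))
  invisible(x)
}
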