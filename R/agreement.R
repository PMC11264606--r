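#' Build a complete-case paired sample
#'
#' Aligns two score vectors, drops incomplete pairs, and validates that at
#' least two complete pairs remain.
#'
#' @param x,y aligned numeric score vectors.
#' @return An object of class `paired_sample`: list with `x`, `y`, `n` and
#'   the logical `complete` mask on the original rows.
#' @export
paired_sample <- function(x, y) {
  .check_numeric(x, "x"); .check_numeric(y, "y")
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2)
    stop("insufficient data: fewer than 2 complete pairs", call. = FALSE)
  structure(list(x = x[ok], y = y[ok], n = sum(ok), complete = ok),
            class = "paired_sample")
}

#' Two-way person-by-measure ANOVA decomposition of a paired sample
#'
#' Decomposes the n-by-2 score table into the between-person, between-measure
#' and person-by-measure interaction mean squares via closed-form sums of
#' squares (equivalent to `anova(lm(score ~ person + measure))`, but linear
#' in n). These are the mean squares the two intraclass correlation forms
#' are built from.
#'
#' @param x a [paired_sample], or the first score vector.
#' @param y second score vector when `x` is a vector.
#' @return An object of class `anova_decomposition` with fields
#'   `ms_between`, `ms_within` (interaction), `ms_time` (measure main
#'   effect), the matching sums of squares and degrees of freedom, `n`, and
#'   `k = 2`.
#' @export
anova_decompose <- function(x, y = NULL) {
  p <- if (inherits(x, "paired_sample")) x else paired_sample(x, y)
  n <- p$n
  rowm <- (p$x + p$y) / 2
  colm <- c(mean(p$x), mean(p$y))
  grand <- mean(colm)
  ss_between <- 2 * sum((rowm - grand)^2)
  ss_time <- n * sum((colm - grand)^2)
  ss_total <- sum((p$x - grand)^2) + sum((p$y - grand)^2)
  ss_within <- ss_total - ss_between - ss_time
  structure(list(ms_between = ss_between / (n - 1),
                 ms_within = ss_within / (n - 1),
                 ms_time = ss_time / 1,
                 ss_between = ss_between, ss_within = ss_within,
                 ss_time = ss_time, ss_total = ss_total,
                 df_between = n - 1, df_within = n - 1, df_time = 1,
                 n = n, k = 2L),
            class = "anova_decomposition")
}

#' @export
print.anova_decomposition <- function(x, ...) {
  cat(sprintf("<anova_decomposition> n = %d persons x %d measures\n", x$n, x$k))
  cat(sprintf("  MS between = %.6g  MS within = %.6g  MS time = %.6g\n",
              x$ms_between, x$ms_within, x$ms_time))
  invisible(x)
}

.as_decomp <- function(x, y) {
  if (inherits(x, "anova_decomposition")) x else anova_decompose(x, y)
}

#' Two-way mixed-effects (consistency) intraclass correlation
#'
#' The single-measure consistency ICC from the two-way mean squares,
#' `(MS_between - MS_within) / (MS_between + (k - 1) MS_within)` with
#' `k = 2` measures. Mean differences between the measures do not reduce
#' this form.
#'
#' @param x an [anova_decompose()] result, or the first score vector.
#' @param y second score vector when `x` is a vector.
#' @return The ICC (a scalar, at most 1).
#' @export
icc_two_way_mixed <- function(x, y = NULL) {
  d <- .as_decomp(x, y)
  den <- d$ms_between + (d$k - 1) * d$ms_within
  if (!is.finite(den) || den <= 0 || d$ms_between <= 0)
    stop("undefined statistic: zero between-person variability", call. = FALSE)
  (d$ms_between - d$ms_within) / den
}

#' Two-way random-effects (absolute agreement) intraclass correlation
#'
#' The single-measure absolute-agreement ICC,
#' `(MS_between - MS_within) / (MS_between + (k - 1) MS_within +
#' (k / n)(MS_time - MS_within))`. The measure main effect (a mean
#' difference between the two scores) enters the denominator, so this form
#' is penalized by systematic mean differences; it equals the
#' mixed-effects form when the column means coincide. It is also the
#' ANOVA estimate of the concordance between the two measures: for large n
#' it converges to `2 r s1 s2 / (s1^2 + s2^2 + (m1 - m2)^2)`.
#'
#' @inheritParams icc_two_way_mixed
#' @return The ICC (a scalar, at most 1).
#' @export
icc_two_way_random <- function(x, y = NULL) {
  d <- .as_decomp(x, y)
  den <- d$ms_between + (d$k - 1) * d$ms_within +
    (d$k / d$n) * (d$ms_time - d$ms_within)
  if (!is.finite(den) || den <= 0)
    stop("undefined statistic: degenerate denominator", call. = FALSE)
  (d$ms_between - d$ms_within) / den
}

#' Normalized mean absolute error
#'
#' Mean absolute deviation between observed and predicted scores divided by
#' the standard deviation (n - 1 denominator) of the observed scores. Lower
#' values indicate better prediction; 1 corresponds to an average error of
#' one observed SD.
#'
#' @param observed,predicted aligned numeric vectors.
#' @return NMAE scalar.
#' @export
nmae <- function(observed, predicted) {
  p <- paired_sample(observed, predicted)
  s <- sd(p$x)
  if (!is.finite(s) || s == 0)
    stop("undefined statistic: observed scores have zero SD", call. = FALSE)
  mean(abs(p$x - p$y)) / s
}

#' Convert a Cohen d effect size to a correlation
#'
#' `r = d / sqrt(d^2 + 4)`, the equal-group-size conversion: d of 0.2, 0.5
#' and 0.8 (small, medium, large) correspond to r of 0.100, 0.243 and
#' 0.371.
#'
#' @param d numeric effect size(s).
#' @return Correlation value(s) in (-1, 1).
#' @export
cohen_d_to_r <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)))
    stop("`d` must be finite numeric", call. = FALSE)
  d / sqrt(d^2 + 4)
}

#' Pairwise product-moment correlation matrix with p-values
#'
#' Pairwise complete-case Pearson correlations over the requested columns,
#' with two-sided p-values from the t distribution. Pairs with a constant
#' column (or fewer than 3 complete cases) are flagged `NA`.
#'
#' @param data data frame.
#' @param vars character vector of column names (default: all numeric
#'   columns).
#' @return A list of class `correlation_matrix` with matrices `r`, `p`,
#'   `n`, and a logical matrix `undefined` flagging degenerate pairs.
#' @export
correlation_matrix <- function(data, vars = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  if (is.null(vars)) vars <- names(data)[vapply(data, is.numeric, logical(1))]
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop(sprintf("columns not found: %s", paste(missing_vars, collapse = ", ")),
         call. = FALSE)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  nm <- matrix(NA_integer_, k, k, dimnames = list(vars, vars))
  undef <- matrix(FALSE, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) for (j in i:k) {
    xi <- as.numeric(data[[vars[i]]]); xj <- as.numeric(data[[vars[j]]])
    ok <- is.finite(xi) & is.finite(xj)
    nm[i, j] <- nm[j, i] <- sum(ok)
    if (sum(ok) < 3 || sd(xi[ok]) == 0 || sd(xj[ok]) == 0) {
      undef[i, j] <- undef[j, i] <- TRUE
      next
    }
    rij <- cor(xi[ok], xj[ok])
    r[i, j] <- r[j, i] <- rij
    if (i == j) { p[i, j] <- NA_real_; next }
    df <- sum(ok) - 2
    tt <- rij * sqrt(df / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- p[j, i] <- 2 * pt(-abs(tt), df)
  }
  structure(list(r = r, p = p, n = nm, undefined = undef),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("<correlation_matrix>\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Full agreement report for two measures
#'
#' Product-moment correlation, both two-way ICC forms, the mean difference
#' and per-measure means/SDs for a complete-case paired sample.
#'
#' @param x,y aligned score vectors (x is the first measure).
#' @param labels length-2 character vector naming the measures.
#' @return A list of class `agreement_report`.
#' @export
agreement_report <- function(x, y, labels = c("measure_1", "measure_2")) {
  p <- paired_sample(x, y)
  d <- anova_decompose(p)
  structure(list(labels = labels,
                 pearson_r = cor(p$x, p$y),
                 icc_mixed = icc_two_way_mixed(d),
                 icc_random = icc_two_way_random(d),
                 mean_difference = mean(p$x) - mean(p$y),
                 means = c(mean(p$x), mean(p$y)),
                 sds = c(sd(p$x), sd(p$y)),
                 n = p$n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s vs %s (n = %d)\n", x$labels[1], x$labels[2], x$n))
  cat(sprintf("  means %.3f / %.3f (difference %.3f), SDs %.3f / %.3f\n",
              x$means[1], x$means[2], x$mean_difference, x$sds[1], x$sds[2]))
  cat(sprintf("  r = %.3f, ICC mixed = %.3f, ICC random = %.3f\n",
              x$pearson_r, x$icc_mixed, x$icc_random))
  invisible(x)
}
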