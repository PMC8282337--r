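#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples, the nonparametric test
#' used for retraction-velocity and linescan comparisons. The U statistic is
#' computed from midranks. For tie-free data with combined n <= 14 the
#' two-sided p-value is exact (distribution of U under the permutation null,
#' doubled one-sided tail capped at 1); otherwise a normal approximation with
#' tie correction and continuity correction is used. If every value in both
#' samples is identical the comparison is degenerate and p = 1 is returned
#' with a flag.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param exact_max_n Combined sample size up to which the exact distribution
#'   is used (default 14; applies only without ties).
#' @return A list of class `group_test`: `statistic` (U, for the first
#'   sample), `p_value`, `test_name`, `exact`, `degenerate`, `n`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p_value  # exact, 1/3
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 14L) {
  x <- check_sample(x, "x"); y <- check_sample(y, "y")
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))
  U <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (length(unique(c(x, y))) == 1L) {
    return(structure(list(statistic = U, p_value = 1, test_name = "Mann-Whitney U",
                          exact = FALSE, degenerate = TRUE, n = c(n1, n2)),
                     class = "group_test"))
  }
  if (!ties && n1 + n2 <= exact_max_n) {
    # exact null distribution of U; doubled smaller tail, capped at 1
    p_lo <- stats::pwilcox(U, n1, n2)
    p_hi <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    exact <- TRUE
  } else {
    mu <- n1 * n2 / 2
    nt <- table(c(x, y))
    N <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  structure(list(statistic = U, p_value = p, test_name = "Mann-Whitney U",
                 exact = exact, degenerate = FALSE, n = c(n1, n2)),
            class = "group_test")
}

#' Student's t-test (two-sided, pooled variance)
#'
#' Two-sample t with pooled variance and n1 + n2 - 2 degrees of freedom, the
#' test used for fluorescence-intensity ratios. Degenerate inputs (zero
#' pooled variance) give p = 1 when the means agree, or a flagged p = 0
#' when they differ.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return A `group_test` list: `statistic` (t), `p_value`, `df`,
#'   `test_name`, `degenerate`, `n`.
#' @export
students_t <- function(x, y) {
  x <- check_sample(x, "x"); y <- check_sample(y, "y")
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  dm <- mean(x) - mean(y)
  if (sp2 <= 0) {
    degen <- dm != 0
    return(structure(list(statistic = if (degen) Inf * sign(dm) else 0,
                          p_value = if (degen) 0 else 1, df = df,
                          test_name = "Student's t", degenerate = degen,
                          n = c(n1, n2)),
                     class = "group_test"))
  }
  t <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(list(statistic = t, p_value = 2 * stats::pt(-abs(t), df), df = df,
                 test_name = "Student's t", degenerate = FALSE, n = c(n1, n2)),
            class = "group_test")
}

#' One-way ANOVA
#'
#' Standard between/within sum-of-squares decomposition across k groups;
#' p-value from the F distribution with (k - 1, N - k) degrees of freedom.
#' Used for multi-condition apical-width ratio comparisons.
#'
#' @param groups A list of numeric samples (>= 2 groups, each n >= 2).
#' @return A `group_test` list: `statistic` (F), `p_value`, `df`
#'   (c(between, within)), `test_name`, `degenerate`, `n`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least 2 groups", call. = FALSE)
  }
  groups <- lapply(seq_along(groups), function(i) {
    check_sample(groups[[i]], sprintf("group %d", i))
  })
  k <- length(groups)
  ns <- lengths(groups)
  all_v <- unlist(groups)
  gm <- mean(all_v)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1L
  dfw <- sum(ns) - k
  if (ssw <= 0) {
    degen <- ssb > 0
    return(structure(list(statistic = if (degen) Inf else 0,
                          p_value = if (degen) 0 else 1, df = c(dfb, dfw),
                          test_name = "one-way ANOVA", degenerate = degen, n = ns),
                     class = "group_test"))
  }
  f <- (ssb / dfb) / (ssw / dfw)
  structure(list(statistic = f, p_value = stats::pf(f, dfb, dfw, lower.tail = FALSE),
                 df = c(dfb, dfw), test_name = "one-way ANOVA",
                 degenerate = FALSE, n = ns),
            class = "group_test")
}

#' @export
print.group_test <- function(x, digits = 4, ...) {
  cat(sprintf("%s: statistic = %.*g, p = %.*g %s\n", x$test_name, digits,
              x$statistic, digits, x$p_value, significance_stars(x$p_value)))
  if (isTRUE(x$degenerate)) cat("  (degenerate input)\n")
  invisible(x)
}

#' Percent change of a treated group relative to control
#'
#' `100 * (mean(treated) - mean(control)) / mean(control)`, the convention in
#' which condition-level effects are reported (e.g. a knockdown decreasing
#' retraction velocity by 49% gives -49).
#'
#' @param treated,control Numeric samples; `control` must have nonzero mean.
#' @return Percent change (scalar).
#' @export
percent_change <- function(treated, control) {
  treated <- as.numeric(treated); control <- as.numeric(control)
  if (any(!is.finite(treated)) || any(!is.finite(control))) {
    stop("samples must be finite", call. = FALSE)
  }
  mc <- mean(control)
  if (mc == 0) stop("control mean is zero; percent change undefined", call. = FALSE)
  100 * (mean(treated) - mc) / mc
}

#' Mean, sample standard deviation and n
#'
#' Summary in the mean +/- s.d. convention of the figure legends. The s.d.
#' uses the n - 1 denominator and is NA (flagged) for n = 1.
#'
#' @param values Numeric sample (n >= 1).
#' @return List with `mean`, `sd`, `n`.
#' @export
summarize_sample <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values))) {
    stop("need at least one finite value", call. = FALSE)
  }
  list(mean = mean(values), sd = sample_sd(values), n = length(values))
}

#' Two-condition comparison report
#'
#' Bundles per-group summaries, the percent change of the second condition
#' relative to the first, and the requested test into one comparison record,
#' ready for tabular export. No multiple-testing correction is applied.
#'
#' @param control,treated Numeric samples (control first: percent change is
#'   relative to it).
#' @param labels Character vector of length 2 with condition names.
#' @param test `"mann-whitney"` (default) or `"t"`.
#' @return A list of class `group_comparison` with `labels`, `means`, `sds`,
#'   `ns`, `percent_change`, `statistic`, `p_value`, `test_name`, `stars`.
#' @export
compare_groups <- function(control, treated,
                           labels = c("control", "treated"),
                           test = c("mann-whitney", "t")) {
  test <- match.arg(test)
  ts <- if (test == "mann-whitney") mann_whitney_u(treated, control)
        else students_t(treated, control)
  s1 <- summarize_sample(control); s2 <- summarize_sample(treated)
  structure(list(labels = labels,
                 means = c(s1$mean, s2$mean), sds = c(s1$sd, s2$sd),
                 ns = c(s1$n, s2$n),
                 percent_change = percent_change(treated, control),
                 statistic = ts$statistic, p_value = ts$p_value,
                 test_name = ts$test_name,
                 stars = significance_stars(ts$p_value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Comparison: %s vs %s (%s)\n", x$labels[1], x$labels[2], x$test_name))
  for (i in 1:2) {
    cat(sprintf("  %-12s mean %.*g +/- %.*g s.d. (n = %d)\n", x$labels[i],
                digits, x$means[i], digits, x$sds[i], x$ns[i]))
  }
  cat(sprintf("  change: %+.1f%%, statistic = %.*g, p = %.*g %s\n",
              x$percent_change, digits, x$statistic, digits, x$p_value, x$stars))
  invisible(x)
}

check_sample <- function(v, name) {
  v <- as.numeric(v)
  if (length(v) < 2L) stop(sprintf("'%s' needs n >= 2", name), call. = FALSE)
  if (any(!is.finite(v))) stop(sprintf("'%s' must be finite", name), call. = FALSE)
  v
}
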