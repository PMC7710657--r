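#' Mean and standard error of the mean
#'
#' @param values Numeric vector, `n >= 2`, NAs removed with a message if
#'   `na.rm = TRUE`.
#' @param na.rm Drop NAs before computing (default TRUE).
#' @return A list with `mean`, `sem` (sd with n-1 denominator over sqrt(n))
#'   and `n`.
#' @export
mean_sem <- function(values, na.rm = TRUE) {
  if (na.rm) values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a SEM")
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

#' One-way ANOVA with Tukey's multiple comparisons
#'
#' Classical fixed-effects one-way ANOVA (between df = k - 1, within
#' df = N - k) followed by Tukey HSD pairwise comparisons using the
#' studentized-range distribution with the Tukey-Kramer correction for
#' unequal group sizes.
#'
#' @param groups Named list of >= 2 numeric vectors, each with `n >= 2`.
#' @return Object of class `group_comparison`: per-group `n`, `mean`, `sem`;
#'   `statistic` (F), `df` (c(between, within)), `p_value`, and `pairwise`
#'   (data.frame of pair labels, difference and Tukey-adjusted p).
#' @examples
#' one_way_anova_tukey(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
one_way_anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs n >= 2")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pair <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"], row.names = NULL)
  desc <- lapply(groups, mean_sem)
  structure(
    list(group_labels = names(groups),
         n = vapply(desc, `[[`, 1L, "n"),
         mean = vapply(desc, `[[`, 1, "mean"),
         sem = vapply(desc, `[[`, 1, "sem"),
         test = "anova_tukey",
         statistic = tab["group", "F value"],
         df = c(between = tab["group", "Df"],
                within = tab["Residuals", "Df"]),
         p_value = tab["group", "Pr(>F)"],
         pairwise = pair),
    class = "group_comparison")
}

#' Two-sample t test
#'
#' Student's pooled-variance t test by default (df = n_a + n_b - 2, matching
#' printed two-group dfs in monitor studies); Welch's unequal-variance test
#' via `welch = TRUE`. Two-sided.
#'
#' @param a,b Numeric vectors, each `n >= 2`.
#' @param welch Use Welch's correction (default FALSE).
#' @param labels Length-2 character vector naming the groups.
#' @return A `group_comparison` with `statistic` (t), `df`, `p_value`.
#' @export
two_sample_t <- function(a, b, welch = FALSE, labels = c("a", "b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  ht <- stats::t.test(a, b, var.equal = !welch)
  desc <- lapply(list(a, b), mean_sem)
  structure(
    list(group_labels = labels,
         n = vapply(desc, `[[`, 1L, "n"),
         mean = vapply(desc, `[[`, 1, "mean"),
         sem = vapply(desc, `[[`, 1, "sem"),
         test = if (welch) "welch_t" else "student_t",
         statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = ht$p.value,
         pairwise = NULL),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\n", x$test))
  for (i in seq_along(x$group_labels))
    cat(sprintf("  %-16s n = %3d  mean = %8.3f  sem = %.3f\n",
                x$group_labels[i], x$n[i], x$mean[i], x$sem[i]))
  if (x$test == "anova_tukey") {
    cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n",
                x$df[1], x$df[2], x$statistic, x$p_value))
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("    %-24s diff = %8.3f  p_adj = %.4g\n",
                  x$pairwise$pair[i], x$pairwise$diff[i], x$pairwise$p_adj[i]))
  } else {
    cat(sprintf("  t(%.1f) = %.3f, p = %.4g\n", x$df, x$statistic, x$p_value))
  }
  invisible(x)
}
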