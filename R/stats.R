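#' Pooled-variance independent-samples t-test
#'
#' Two-sided t-test with the pooled variance estimate and
#' `df = n1 + n2 - 2`, implemented from the sums directly. Used for the
#' pre-treatment group comparisons (age, hearing thresholds, baseline
#' outcomes).
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return A tibble with columns `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
independent_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 observations", call. = FALSE)
  s2p <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (s2p == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(t = 0, df = n1 + n2 - 2L, p = 1,
                            mean_x = mean(x), mean_y = mean(y)))
    }
    stop("zero pooled variance with unequal means: degenerate samples", call. = FALSE)
  }
  tval <- (mean(x) - mean(y)) / sqrt(s2p * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2L
  tibble::tibble(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
                 mean_x = mean(x), mean_y = mean(y))
}

#' Effect size r from an F ratio
#'
#' Computes r as `sqrt(F / (F + df2))`, the correlation-metric effect size for a
#' 1-numerator-df contrast, applied here to every reported F.
#'
#' @param F F ratio (>= 0), vectorized.
#' @param df2 Denominator degrees of freedom.
#' @return Effect size(s) in `[0, 1)`.
#' @export
effect_size_r <- function(F, df2) {
  if (any(F < 0)) stop("F must be nonnegative", call. = FALSE)
  sqrt(F / (F + df2))
}

# Fast sums-of-squares core for the two-way mixed (split-plot) design:
# one between-subjects factor (group), one within-subjects factor (time),
# every subject observed at every timepoint. Plain-vector interface so
# simulation studies can call it thousands of times cheaply.
mixed_anova_core <- function(value, subject, group, time) {
  subject <- as.character(subject)
  group <- as.character(group)
  time <- as.character(time)
  tlev <- unique(time)
  t_n <- length(tlev)
  subj <- unique(subject)
  N <- length(subj)
  tab <- table(subject)
  if (length(unique(as.vector(tab))) != 1 || tab[1] != t_n) {
    stop("unbalanced design: every subject needs all ", t_n, " timepoints",
         call. = FALSE)
  }
  grand <- mean(value)
  ss_total <- sum((value - grand)^2)

  subj_mean <- tapply(value, subject, mean)
  subj_group <- tapply(group, subject, function(g) g[1])
  ss_subjects <- t_n * sum((subj_mean - grand)^2)

  g_mean <- tapply(value, group, mean)
  n_g <- table(subj_group)                       # subjects per group
  ss_group <- t_n * sum(n_g[names(g_mean)] * (g_mean - grand)^2)
  ss_subj_within <- ss_subjects - ss_group

  t_mean <- tapply(value, time, mean)
  ss_time <- N * sum((t_mean - grand)^2)

  cell_mean <- tapply(value, list(group, time), mean)
  gm <- g_mean[rownames(cell_mean)]
  tm <- t_mean[colnames(cell_mean)]
  dev <- sweep(sweep(cell_mean, 1, gm), 2, tm) + grand
  ss_inter <- sum(as.vector(n_g[rownames(cell_mean)]) * dev^2)

  ss_within_err <- ss_total - ss_subjects - ss_time - ss_inter

  k <- length(unique(subj_group))
  df_group <- k - 1L
  df_subj_within <- N - k
  df_time <- t_n - 1L
  df_inter <- df_group * df_time
  df_within_err <- df_time * df_subj_within

  list(
    ss = c(group = ss_group, subj_within = ss_subj_within, time = ss_time,
           interaction = ss_inter, within_error = ss_within_err, total = ss_total),
    df = c(group = df_group, subj_within = df_subj_within, time = df_time,
           interaction = df_inter, within_error = df_within_err),
    F_group = (ss_group / df_group) / (ss_subj_within / df_subj_within),
    F_time = (ss_time / df_time) / (ss_within_err / df_within_err),
    F_inter = (ss_inter / df_inter) / (ss_within_err / df_within_err)
  )
}

#' Two-way mixed (split-plot) ANOVA
#'
#' Sum-of-squares decomposition for one between-subjects factor (group) and
#' one within-subjects factor (time), balanced within subject. The
#' between-subjects effect is tested against subject-within-group variation
#' on `(k - 1, N - k)` df; the time and group-by-time effects against the
#' within-subject residual on `(t - 1, (t - 1)(N - k))` df. With two groups
#' of 38 and 29 subjects over four timepoints this gives F(1, 65) for the
#' group effect and F(3, 195) for the within-subject effects.
#'
#' @param data Tidy tibble with one row per subject x timepoint (for one
#'   outcome), e.g. a filtered [simulate_cohort()] result.
#' @param value,subject,group,time Column names (tidy-select, defaults match
#'   [simulate_cohort()] output).
#' @return A tibble of class `mixed_anova` with one row per effect
#'   (`between_group`, `time`, `interaction`): `effect`, `ss`, `F`, `df1`,
#'   `df2`, `p`, `r`.
#' @export
mixed_anova <- function(data, value = "value", subject = "subject_id",
                        group = "group", time = "time") {
  res <- mixed_anova_core(data[[value]], data[[subject]],
                          data[[group]], data[[time]])
  out <- tibble::tibble(
    effect = c("between_group", "time", "interaction"),
    ss = unname(res$ss[c("group", "time", "interaction")]),
    F = c(res$F_group, res$F_time, res$F_inter),
    df1 = unname(res$df[c("group", "time", "interaction")]),
    df2 = unname(res$df[c("subj_within", "within_error", "within_error")])
  )
  out$p <- stats::pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  out$r <- effect_size_r(out$F, out$df2)
  attr(out, "ss_table") <- res$ss
  attr(out, "df_table") <- res$df
  class(out) <- c("mixed_anova", class(out))
  out
}

#' Pooled one-way time ANOVA (the study's within-group convention)
#'
#' One-way ANOVA with timepoint as the factor, pooling all observations and
#' ignoring the subject pairing, giving `df = (t - 1, t n - t)` — with four
#' timepoints and n subjects, `(3, 4n - 4)`: the degrees-of-freedom pattern
#' the study prints for its within-group tests (F(3, 148) for n = 38,
#' F(3, 112) for n = 29). The statistically stricter repeated-measures
#' alternative is available via [mixed_anova()] on a single group.
#'
#' @param data Tidy tibble, one row per subject x timepoint, single group and
#'   outcome.
#' @param value,time Column names.
#' @return A one-row tibble of class `mixed_anova`: `effect = "time"`, `ss`,
#'   `F`, `df1`, `df2`, `p`, `r`.
#' @export
pooled_time_anova <- function(data, value = "value", time = "time") {
  y <- data[[value]]
  tfac <- as.character(data[[time]])
  n_per <- table(tfac)
  if (any(n_per < 2)) stop("need at least 2 subjects per timepoint", call. = FALSE)
  grand <- mean(y)
  tmeans <- tapply(y, tfac, mean)
  ss_between <- sum(n_per[names(tmeans)] * (tmeans - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_within <- ss_total - ss_between
  df1 <- length(tmeans) - 1L
  df2 <- length(y) - length(tmeans)
  Fv <- (ss_between / df1) / (ss_within / df2)
  out <- tibble::tibble(effect = "time", ss = ss_between, F = Fv,
                        df1 = df1, df2 = df2,
                        p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
                        r = effect_size_r(Fv, df2))
  attr(out, "mse") <- ss_within / df2
  attr(out, "n_per_cell") <- as.vector(n_per[1])
  class(out) <- c("mixed_anova", class(out))
  out
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise comparisons of level means using the studentized range
#' statistic `q = |m_i - m_j| / sqrt(MSE / n)` with adjusted p-values from
#' the studentized range distribution.
#'
#' @param means Named numeric vector of level means (e.g. timepoint means).
#' @param mse Error mean square from the corresponding ANOVA.
#' @param df_error Error degrees of freedom (>= 1).
#' @param n_per_cell Observations per level (balanced).
#' @return A tibble of class `tukey_hsd`, one row per pair: `level1`,
#'   `level2`, `diff`, `q`, `p_tukey`.
#' @export
tukey_hsd <- function(means, mse, df_error, n_per_cell) {
  if (length(means) < 2) stop("need at least 2 level means", call. = FALSE)
  if (df_error < 1) stop("df_error must be at least 1", call. = FALSE)
  k <- length(means)
  lv <- names(means) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  se <- sqrt(mse / n_per_cell)
  means <- unname(as.vector(means))
  out <- tibble::tibble(
    level1 = lv[pairs[1, ]],
    level2 = lv[pairs[2, ]],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    q = abs(means[pairs[2, ]] - means[pairs[1, ]]) / se
  )
  out$p_tukey <- ifelse(out$q == 0, 1,
                        stats::ptukey(out$q, nmeans = k, df = df_error,
                                      lower.tail = FALSE))
  class(out) <- c("tukey_hsd", class(out))
  out
}

#' Tukey HSD across timepoints for one group and outcome
#'
#' Convenience wrapper: runs [pooled_time_anova()] on the supplied single
#' group/outcome slice and feeds its timepoint means and error term into
#' [tukey_hsd()].
#'
#' @param data Tidy tibble, one row per subject x timepoint.
#' @param value,time Column names.
#' @return A `tukey_hsd` tibble.
#' @export
tukey_time_posthoc <- function(data, value = "value", time = "time") {
  an <- pooled_time_anova(data, value = value, time = time)
  tfac <- as.character(data[[time]])
  tlev <- if (is.factor(data[[time]])) levels(data[[time]]) else unique(tfac)
  means <- tapply(data[[value]], factor(tfac, levels = tlev), mean)
  tukey_hsd(means, attr(an, "mse"), an$df2, attr(an, "n_per_cell"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed ANOVA result
#'
#' @param x A `mixed_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per effect (`term`, `ss`, `statistic`,
#'   `df1`, `df2`, `p.value`, `r`).
#' @method tidy mixed_anova
#' @export
tidy.mixed_anova <- function(x, ...) {
  tibble::tibble(term = x$effect, ss = x$ss, statistic = x$F,
                 df1 = x$df1, df2 = x$df2, p.value = x$p, r = x$r)
}

#' One-line summary of a mixed ANOVA result
#'
#' @param x A `mixed_anova` object.
#' @param ... Unused.
#' @return A one-row tibble with the headline (first) effect.
#' @method glance mixed_anova
#' @export
glance.mixed_anova <- function(x, ...) {
  tibble::tibble(statistic = x$F[1], df1 = x$df1[1], df2 = x$df2[1],
                 p.value = x$p[1], r = x$r[1], n_effects = nrow(x))
}

#' @method tidy tukey_hsd
#' @export
tidy.tukey_hsd <- function(x, ...) {
  tibble::tibble(contrast = paste(x$level2, "-", x$level1),
                 estimate = x$diff, statistic = x$q, adj.p.value = x$p_tukey)
}
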