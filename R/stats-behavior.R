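# Behavioral summary formulas and the assumption-gated statistical
# layer: Shapiro-Wilk normality gate (with optional log transform for
# peak calcium data), Levene homogeneity check, then Student t /
# Mann-Whitney for two groups; one-way ANOVA; and a mixed-design
# (between group x within time) repeated-measures ANOVA with an
# explicit sums-of-squares partition.

#' Block-1 freezing mean
#'
#' Fear expression and extinction sessions are summarized as the mean
#' percent freezing of block 1, i.e. tones 1 and 2 of the session
#' (extinction may already occur within a session, so later tones are
#' not averaged in).
#'
#' @param per_tone_freezing percent freezing per tone (0-100), tone 1
#'   first.
#' @return mean of tones 1 and 2, percent.
#' @export
block1_mean <- function(per_tone_freezing) {
  if (length(per_tone_freezing) < 2 || anyNA(per_tone_freezing[1:2])) {
    stop("block1_mean: tones 1 and 2 required")
  }
  if (any(per_tone_freezing < 0 | per_tone_freezing > 100)) {
    stop("block1_mean: freezing must be within 0-100%")
  }
  mean(per_tone_freezing[1:2])
}

#' Novel-object recognition index
#'
#' `t_novel / (t_novel + t_familiar)`: 0.5 = no preference, 1 = only
#' the novel object explored.
#'
#' @param t_novel,t_familiar exploration times, s (non-negative, not
#'   both zero).
#' @return fraction in \[0, 1\].
#' @export
recognition_index <- function(t_novel, t_familiar) {
  stopifnot(t_novel >= 0, t_familiar >= 0)
  if (t_novel + t_familiar <= 0) {
    stop("recognition_index: no exploration time recorded")
  }
  t_novel / (t_novel + t_familiar)
}

#' Percent open-arm time (elevated plus maze)
#'
#' `100 * t_open / (t_open + t_closed)`.
#'
#' @param t_open,t_closed arm times, s (non-negative, not both zero).
#' @return percent in \[0, 100\].
#' @export
percent_open_arm <- function(t_open, t_closed) {
  stopifnot(t_open >= 0, t_closed >= 0)
  if (t_open + t_closed <= 0) stop("percent_open_arm: zero total arm time")
  100 * t_open / (t_open + t_closed)
}

levene_p <- function(x, y) {
  dat <- data.frame(v = c(x, y),
                    g = factor(rep(c("x", "y"), c(length(x), length(y)))))
  tab <- car::leveneTest(v ~ g, data = dat)
  tab[["Pr(>F)"]][1]
}

#' Assumption-gated two-group comparison
#'
#' Decision procedure: (1) Shapiro-Wilk normality per group at alpha =
#' 0.05; (2) if normality is rejected and `log_gate` is set, natural-log
#' transform (requires strictly positive data, as for peak calcium
#' responses) and retest; (3) Levene's test for homogeneity of variance
#' on the (possibly transformed) data; (4) if normality and homogeneity
#' hold, a two-sided unpaired Student t-test; otherwise a Mann-Whitney
#' (Wilcoxon rank-sum) test — exact when n1 + n2 <= 12 without ties,
#' else the normal approximation with tie and continuity correction.
#' The full decision trail (normality p, Levene p, transform) is kept
#' in the result.
#'
#' @param x,y numeric samples, n >= 3 each.
#' @param log_gate offer the log transform when normality fails.
#' @param alpha gate level for the assumption checks.
#' @return a [group_comparison()].
#' @export
gated_two_group_test <- function(x, y, log_gate = FALSE, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) {
    stop("gated_two_group_test: n >= 3 per group required")
  }
  transform <- "none"
  norm_p <- min(stats::shapiro.test(x)$p.value,
                stats::shapiro.test(y)$p.value)
  if (norm_p < alpha && log_gate) {
    if (any(x <= 0) || any(y <= 0)) {
      stop("gated_two_group_test: log transform requires positive values")
    }
    x <- log(x); y <- log(y)
    transform <- "log"
    norm_p <- min(stats::shapiro.test(x)$p.value,
                  stats::shapiro.test(y)$p.value)
  }
  lev_p <- levene_p(x, y)

  if (norm_p >= alpha && lev_p >= alpha) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    return(group_comparison("unpaired t-test", unname(tt$statistic),
                            unname(tt$parameter), tt$p.value, transform,
                            norm_p, lev_p))
  }
  m <- length(x); n <- length(y)
  exact <- (m + n) <= 12 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  group_comparison("Mann-Whitney", unname(wt$statistic), NA_real_,
                   wt$p.value, transform, norm_p, lev_p)
}

#' One-way ANOVA
#'
#' Standard between/within partition via `stats::oneway.test` with
#' equal variances assumed; for two groups the F statistic equals the
#' squared unpaired-t statistic exactly.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return a [group_comparison()] with `df = (df1, df2)`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("one_way_anova: >= 2 groups with n >= 2 each required")
  }
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(v) == 0) {
    return(group_comparison("one-way ANOVA", 0,
                            c(nlevels(g) - 1, length(v) - nlevels(g)), 1))
  }
  ft <- stats::oneway.test(v ~ g, var.equal = TRUE)
  group_comparison("one-way ANOVA", unname(ft$statistic),
                   unname(ft$parameter), ft$p.value)
}

#' Two-way repeated-measures (mixed design) ANOVA
#'
#' Between-subject factor `group`, within-subject factor `time`, each
#' subject measured at every time (complete balanced-within design; no
#' imputation — missing cells are an error). The sums of squares are
#' partitioned explicitly:
#' between-subjects SS into group and subjects-within-group (the group
#' error term), within-subjects SS into time, time x group and the
#' within error; F tests use the conventional mixed-design error terms
#' with df `(g-1, N-g)` for group, `(t-1, (N-g)(t-1))` for time and
#' `((g-1)(t-1), (N-g)(t-1))` for the interaction. No sphericity
#' correction is applied by default (uncorrected df are reported);
#' Greenhouse-Geisser correction of the within-term p-values is
#' available via `gg_correction`.
#'
#' @param data data.frame with columns `subject`, `group`, `time`,
#'   `value`.
#' @param gg_correction apply Greenhouse-Geisser epsilon to the
#'   within-subject tests.
#' @return data.frame with one row per effect (`group`, `time`,
#'   `time:group`): `SS`, `df1`, `df2`, `F`, `p`; attribute `"SS_parts"`
#'   carries the full partition (including error terms and the total).
#' @export
two_way_rm_anova <- function(data, gg_correction = FALSE) {
  need <- c("subject", "group", "time", "value")
  if (!all(need %in% names(data))) {
    stop("two_way_rm_anova: need columns subject, group, time, value")
  }
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$time <- factor(data$time)
  tab <- table(data$subject, data$time)
  if (any(tab != 1)) {
    stop("two_way_rm_anova: incomplete design ",
         "(every subject must be measured exactly once at every time)")
  }
  sub_group <- tapply(as.character(data$group), data$subject, unique)
  if (any(lengths(sub_group) != 1)) {
    stop("two_way_rm_anova: subject assigned to more than one group")
  }

  y <- data$value
  grand <- mean(y)
  n_t <- nlevels(data$time)
  n_g <- nlevels(data$group)
  N <- nlevels(data$subject)
  n_per_g <- table(factor(unlist(sub_group), levels = levels(data$group)))

  ss_total <- sum((y - grand)^2)
  subj_mean <- tapply(y, data$subject, mean)
  ss_between_subj <- n_t * sum((subj_mean - grand)^2)
  grp_mean <- tapply(y, data$group, mean)
  ss_group <- n_t * sum(n_per_g * (grp_mean - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group

  time_mean <- tapply(y, data$time, mean)
  ss_time <- N * sum((time_mean - grand)^2)
  cell_mean <- tapply(y, list(data$group, data$time), mean)
  ss_cells <- sum(rep(n_per_g, n_t) *
                  (cell_mean - outer(grp_mean, time_mean, "+") + grand)^2)
  ss_inter <- ss_cells
  ss_error <- ss_total - ss_between_subj - ss_time - ss_inter

  df_group <- n_g - 1; df_subj <- N - n_g
  df_time <- n_t - 1; df_inter <- (n_g - 1) * (n_t - 1)
  df_error <- (N - n_g) * (n_t - 1)

  f_group <- (ss_group / df_group) / (ss_subj_within / df_subj)
  f_time <- (ss_time / df_time) / (ss_error / df_error)
  f_inter <- (ss_inter / df_inter) / (ss_error / df_error)

  eps <- 1
  if (gg_correction && n_t > 2) {
    # Greenhouse-Geisser epsilon from the pooled within-group covariance
    # of the subject x time matrix
    wide <- matrix(NA_real_, N, n_t,
                   dimnames = list(levels(data$subject), levels(data$time)))
    wide[cbind(as.integer(data$subject), as.integer(data$time))] <- y
    grp_of <- factor(unlist(sub_group), levels = levels(data$group))
    S <- Reduce(`+`, lapply(levels(grp_of), function(g) {
      w <- wide[grp_of == g, , drop = FALSE]
      stats::cov(w) * (nrow(w) - 1)
    })) / (N - n_g)
    dbar <- mean(diag(S)); sbar <- mean(S)
    eps <- (n_t * (dbar - sbar))^2 /
      ((n_t - 1) * (sum(S^2) - 2 * n_t * sum(rowMeans(S)^2) +
                    n_t^2 * sbar^2))
    eps <- min(1, max(eps, 1 / (n_t - 1)))
  }

  p_group <- stats::pf(f_group, df_group, df_subj, lower.tail = FALSE)
  p_time <- stats::pf(f_time, eps * df_time, eps * df_error,
                      lower.tail = FALSE)
  p_inter <- stats::pf(f_inter, eps * df_inter, eps * df_error,
                       lower.tail = FALSE)

  out <- data.frame(
    effect = c("group", "time", "time:group"),
    SS = c(ss_group, ss_time, ss_inter),
    df1 = c(df_group, df_time, df_inter),
    df2 = c(df_subj, df_error, df_error),
    F = c(f_group, f_time, f_inter),
    p = c(p_group, p_time, p_inter))
  attr(out, "SS_parts") <- c(
    group = ss_group, subjects_within_group = ss_subj_within,
    time = ss_time, interaction = ss_inter, error = ss_error,
    total = ss_total)
  attr(out, "gg_epsilon") <- eps
  out
}
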