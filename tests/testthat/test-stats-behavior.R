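test_that("behavioral summary formulas match their definitions", {
  expect_equal(block1_mean(c(40, 60, 70, 80, 90, 95)), 50)
  expect_equal(block1_mean(c(33, 33, 10, 10, 10, 10)), 33)
  tones <- c(48.2, 61.8, 70, 75, 80, 85)
  expect_equal(block1_mean(tones), mean(tones[c(1, 2)]))
  expect_error(block1_mean(55), "tones 1 and 2")
  expect_error(block1_mean(c(120, 30)), "0-100")

  expect_equal(recognition_index(30, 30), 0.5)
  expect_equal(recognition_index(45, 15), 0.75)
  expect_equal(recognition_index(12.3, 45.6), 12.3 / (12.3 + 45.6))
  expect_error(recognition_index(0, 0), "exploration")

  expect_equal(percent_open_arm(60, 240), 20)
  expect_equal(percent_open_arm(0, 100), 0)
  expect_equal(percent_open_arm(33, 77), 100 * 33 / 110)
  expect_error(percent_open_arm(0, 0), "zero total")
})

test_that("gated comparison falls through t-test with a full decision trail", {
  set.seed(5)
  x <- rnorm(12)
  res <- gated_two_group_test(x, x)
  expect_equal(res$test_name, "unpaired t-test")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_equal(res$transform, "none")
  expect_true(res$normality_p >= 0.05 && res$levene_p >= 0.05)
  expect_error(gated_two_group_test(1:2, 1:5), "n >= 3")
})

test_that("lognormal data trip the gate, get log-transformed, then t-tested", {
  set.seed(8)
  x <- exp(rnorm(30, 0, 1.2))
  y <- exp(rnorm(30, 0.3, 1.2))
  res <- gated_two_group_test(x, y, log_gate = TRUE)
  expect_equal(res$transform, "log")
  expect_equal(res$test_name, "unpaired t-test")
  # equals the t-test on the logs
  tt <- t.test(log(x), log(y), var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)

  # without the gate the same data fall to Mann-Whitney
  res2 <- gated_two_group_test(x, y, log_gate = FALSE)
  expect_equal(res2$test_name, "Mann-Whitney")

  expect_error(gated_two_group_test(c(x, -1), y, log_gate = TRUE),
               "positive")
})

test_that("Mann-Whitney p equals exhaustive rank enumeration at n = 4 vs 4", {
  # brute-force oracle: enumerate all C(8,4) group assignments of the
  # pooled sample and count rank-sum statistics at least as extreme
  exact_mw_p <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    m <- length(x)
    u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    combos <- utils::combn(length(pooled), m)
    u_all <- apply(combos, 2, function(idx) {
      sum(r[idx]) - m * (m + 1) / 2
    })
    mu <- m * (length(y)) / 2
    mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  }
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(4); y <- rnorm(4, 1)
    res <- gated_two_group_test(exp(3 * x), exp(3 * y))  # force MW branch
    if (res$test_name != "Mann-Whitney") next
    expect_equal(res$p_value, exact_mw_p(exp(3 * x), exp(3 * y)),
                 tolerance = 1e-12)
  }
  # and once with data guaranteed to take the MW branch
  x <- exp(c(0.1, 5, 5.1, 5.2)); y <- exp(c(0.2, 0.3, 5.3, 10))
  res <- gated_two_group_test(x, y)
  expect_equal(res$test_name, "Mann-Whitney")
  expect_equal(res$p_value, exact_mw_p(x, y), tolerance = 1e-12)
})

test_that("one-way ANOVA: F = t^2, hand SS oracle, degenerate input", {
  set.seed(3)
  g1 <- rnorm(10, 5); g2 <- rnorm(12, 6)
  a <- one_way_anova(list(g1, g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(a$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)

  # brute-force sums of squares on a hand-checkable 3-group dataset
  groups <- list(c(1, 2, 3), c(2, 4, 6), c(5, 5, 8))
  y <- unlist(groups); gm <- mean(y)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                     numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f_oracle <- (ss_b / 2) / (ss_w / 6)
  a3 <- one_way_anova(groups)
  expect_equal(a3$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(a3$df, c(2, 6))

  expect_equal(one_way_anova(list(rep(4, 5), rep(4, 6)))$statistic, 0)
  expect_error(one_way_anova(list(1:5)), ">= 2 groups")
})

test_that("mixed-design RM-ANOVA partitions SS like aov and keeps df shape", {
  set.seed(21)
  n_per <- c(18, 19); n_t <- 3      # 37 subjects, 3 sessions
  dat <- do.call(rbind, lapply(1:2, function(g) {
    do.call(rbind, lapply(seq_len(n_per[g]), function(s) {
      subj <- paste0("g", g, "s", s)
      base <- rnorm(1, 60 - 10 * g, 8)
      data.frame(subject = subj, group = paste0("grp", g), time = 1:n_t,
                 value = base - 12 * (0:(n_t - 1)) + rnorm(n_t, 0, 5))
    }))
  }))
  res <- two_way_rm_anova(dat)
  expect_equal(res$df1, c(1, 2, 2))
  expect_equal(res$df2, c(35, 70, 70))   # (N-g) and (N-g)(t-1)

  # dual route: stats::aov with an Error(subject) stratum
  fit <- stats::aov(value ~ group * factor(time) +
                      Error(subject / factor(time)), data = dat)
  s <- summary(fit)
  aov_group <- s[["Error: subject"]][[1]]
  aov_within <- s[[length(s)]][[1]]
  f_of <- function(tab, name) tab[trimws(rownames(tab)) == name, "F value"]
  expect_equal(res$F[res$effect == "group"], f_of(aov_group, "group"),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "time"],
               f_of(aov_within, "factor(time)"), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "time:group"],
               f_of(aov_within, "group:factor(time)"), tolerance = 1e-8)

  # the partition is exhaustive
  parts <- attr(res, "SS_parts")
  expect_equal(parts[["total"]],
               sum(parts[c("group", "subjects_within_group", "time",
                           "interaction", "error")]),
               tolerance = 1e-9)

  # identical group means at every time -> interaction F ~ 0
  flat <- dat
  flat$value <- ave(flat$value, flat$time) +
    rep(rnorm(37, 0, 1e-8), each = n_t)
  res_flat <- two_way_rm_anova(flat)
  expect_lt(res_flat$F[res_flat$effect == "time:group"], 1e-6)

  # missing cells are an error, never imputed
  expect_error(two_way_rm_anova(dat[-1, ]), "incomplete")
})
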