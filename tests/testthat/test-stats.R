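test_that("pooled t-test matches t.test(var.equal) and hand computation", {
  withr::with_seed(1, {
    x <- rnorm(12, 5, 2); y <- rnorm(9, 4, 2)
  })
  res <- independent_t_test(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)

  # hand-computed 3-vs-3: x = 1,2,3; y = 2,4,6 -> sp2 = (2+8)/4 = 2.5,
  # t = (2-4)/sqrt(2.5*(2/3)) = -1.549193
  h <- independent_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(h$t, -2 / sqrt(2.5 * (2 / 3)), tolerance = 1e-12)
  expect_equal(h$df, 4L)

  same <- independent_t_test(c(1, 1), c(1, 1))
  expect_equal(c(same$t, same$p), c(0, 1))
  expect_equal(independent_t_test(rnorm(38), rnorm(29))$df, 65L)
})

test_that("mixed ANOVA reproduces aov's split-plot decomposition", {
  d <- toy_mixed_data(n_a = 5, n_b = 3, seed = 42)
  res <- mixed_anova(d)
  fit <- summary(stats::aov(value ~ group * time + Error(subject_id),
                            data = as.data.frame(d)))
  between <- fit[["Error: subject_id"]][[1]]
  within <- fit[["Error: Within"]][[1]]
  expect_equal(res$F[res$effect == "between_group"], between["group", "F value"],
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "time"], within["time", "F value"],
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "interaction"], within["group:time", "F value"],
               tolerance = 1e-10)
  expect_equal(res$ss[res$effect == "time"], within["time", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(res$df2, c(6L, 18L, 18L))
})

test_that("mixed ANOVA df match the study design and degenerate cases", {
  co <- dplyr::filter(simulate_cohort(cohort_config(seed = 1)), outcome == "tll")
  res <- mixed_anova(co)
  expect_equal(res$df1, c(1L, 3L, 3L))
  expect_equal(res$df2, c(65L, 195L, 195L))

  # identical groups: between-group F = 0
  d <- toy_mixed_data(4, 4, seed = 9)
  half <- dplyr::filter(d, group == "A")
  mirror <- dplyr::mutate(half, group = "B",
                          subject_id = paste0(subject_id, "b"))
  res0 <- mixed_anova(dplyr::bind_rows(half, mirror))
  expect_equal(res0$F[res0$effect == "between_group"], 0, tolerance = 1e-12)

  unb <- d[-1, ]
  expect_error(mixed_anova(unb), "unbalanced")
})

test_that("sum-of-squares decomposition conserves total variance", {
  withr::with_seed(3, {
    for (i in 1:20) {
      d <- toy_mixed_data(n_a = sample(3:10, 1), n_b = sample(3:10, 1), seed = i)
      res <- mixed_anova(d)
      ss <- attr(res, "ss_table")
      parts <- ss[["group"]] + ss[["subj_within"]] + ss[["time"]] +
        ss[["interaction"]] + ss[["within_error"]]
      expect_lt(abs(parts - ss[["total"]]) / ss[["total"]], 1e-9)
    }
  })
})

test_that("mixed ANOVA is invariant to subject order", {
  d <- toy_mixed_data(5, 4, seed = 13)
  shuffled <- withr::with_seed(1, d[sample(nrow(d)), ])
  expect_equal(tidy(mixed_anova(d)), tidy(mixed_anova(shuffled)), tolerance = 1e-12)
})

test_that("pooled time ANOVA matches one-way aov and the study's df pattern", {
  d <- dplyr::filter(toy_mixed_data(6, 3, seed = 21), group == "A")
  res <- pooled_time_anova(d)
  ref <- summary(stats::aov(value ~ time, data = as.data.frame(d)))[[1]]
  expect_equal(res$F, ref["time", "F value"], tolerance = 1e-10)
  expect_equal(res$p, ref["time", "Pr(>F)"], tolerance = 1e-10)

  n38 <- dplyr::filter(simulate_cohort(single_outcome_config(seed = 2)), group == "RI+")
  expect_equal(pooled_time_anova(n38)$df2, 148L)
  n29 <- dplyr::filter(simulate_cohort(single_outcome_config(seed = 2)), group == "RI-")
  expect_equal(pooled_time_anova(n29)$df2, 112L)

  # all timepoints identical -> F = 0
  flat <- d; flat$value <- 5 + as.integer(factor(flat$subject_id)) * 0.1
  expect_equal(pooled_time_anova(flat)$F, 0, tolerance = 1e-12)
})

test_that("Tukey HSD matches TukeyHSD and the published critical value", {
  d <- dplyr::filter(toy_mixed_data(6, 3, seed = 5), group == "A")
  ours <- tukey_time_posthoc(d)
  ref <- stats::TukeyHSD(stats::aov(value ~ time, data = as.data.frame(d)))$time
  # orientation-free pair keys (TukeyHSD orders levels alphabetically)
  canon <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ours_key <- canon(ours$level1, ours$level2)
  ref_pairs <- do.call(rbind, strsplit(rownames(ref), "-"))
  ref_key <- canon(ref_pairs[, 1], ref_pairs[, 2])
  expect_equal(ours$p_tukey[match(ref_key, ours_key)],
               unname(ref[, "p adj"]), tolerance = 1e-8)

  # studentized range critical value q(k = 4, df = 60, alpha = .05) = 3.74
  expect_equal(stats::qtukey(0.95, 4, 60), 3.74, tolerance = 0.01)
  expect_equal(tukey_hsd(c(a = 1, b = 1), mse = 2, df_error = 10,
                         n_per_cell = 5)$p_tukey, 1)
  expect_error(tukey_hsd(c(a = 1, b = 2), 1, df_error = 0.5, n_per_cell = 3), "df_error")
})

test_that("pre vs month-6 is the strongest contrast for simulated RI+ TLL", {
  # Monte-Carlo: under the RI+ TLL trajectory the pre/m6 pair should carry
  # the smallest adjusted p in nearly every replicate
  hits <- vapply(1:40, function(s) {
    co <- dplyr::filter(simulate_cohort(single_outcome_config("tll", seed = s)),
                        group == "RI+")
    tk <- tukey_time_posthoc(co)
    pair <- paste(tk$level1, tk$level2)[which.min(tk$p_tukey)]
    pair == "pre m6"
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("effect size r follows sqrt(F / (F + df2))", {
  expect_equal(effect_size_r(0, 65), 0)
  expect_equal(effect_size_r(15.45, 65), sqrt(15.45 / (15.45 + 65)))
  expect_equal(round(effect_size_r(15.45, 65), 3), 0.438)
  Fs <- seq(0, 50, 0.5)
  expect_true(all(diff(effect_size_r(Fs, 65)) > 0))
  expect_error(effect_size_r(-1, 65), "nonnegative")
})

test_that("tidy and glance expose broom-style summaries", {
  res <- mixed_anova(toy_mixed_data(4, 3, seed = 2))
  td <- tidy(res)
  expect_named(td, c("term", "ss", "statistic", "df1", "df2", "p.value", "r"))
  expect_equal(nrow(td), 3)
  gl <- glance(res)
  expect_equal(gl$statistic, res$F[1])
  tk <- tidy(tukey_time_posthoc(dplyr::filter(toy_mixed_data(4, 3, seed = 2),
                                              group == "A")))
  expect_true(all(c("contrast", "estimate", "adj.p.value") %in% names(tk)))
})
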