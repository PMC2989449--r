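# builds a minimal trial log with given outcomes
mk_trials <- function(correct, is_correction = rep(FALSE, length(correct)),
                      subject_id = "s1", session_id = 1L) {
  n <- length(correct)
  data.frame(subject_id = subject_id, session_id = session_id,
             trial_index = seq_len(n), is_correction = is_correction,
             correct = correct,
             separation_euclid = rep(6, n), intervening_windows = rep(5L, n),
             delay_s = rep(6, n))
}

test_that("percent correct excludes correction trials", {
  base <- mk_trials(rep(c(TRUE, FALSE), c(32, 8)))
  expect_equal(percent_correct(base)$percent_correct, 80)
  expect_equal(percent_correct(base)$n_trials, 40L)
  # appending correction trials with any outcomes changes nothing
  extra <- mk_trials(rep(c(TRUE, FALSE), 5), is_correction = rep(TRUE, 10))
  extra$trial_index <- extra$trial_index + 40L
  expect_equal(percent_correct(rbind(base, extra))$percent_correct, 80)
  expect_error(percent_correct(extra), "undefined")
})

test_that("block summaries average session-level percentages", {
  # two subjects x 4 sessions; sessions differ in trial counts so a pooled
  # trial mean would differ from the mean of session percentages
  logs <- list()
  outcomes <- list(c(rep(TRUE, 6), rep(FALSE, 4)),   # 60%, 10 trials
                   c(rep(TRUE, 16), rep(FALSE, 4)),  # 80%, 20 trials
                   c(rep(TRUE, 5), rep(FALSE, 5)),   # 50%
                   c(rep(TRUE, 9), rep(FALSE, 1)))   # 90%
  for (s in 1:2) for (k in 1:4)
    logs[[length(logs) + 1]] <- mk_trials(outcomes[[k]],
                                          subject_id = paste0("s", s),
                                          session_id = k)
  df <- do.call(rbind, logs)
  out <- accuracy_by_condition(df, "block", block_size = 2)
  expect_identical(nrow(out), 4L)  # 2 subjects x 2 blocks
  expect_equal(out$percent_correct[out$subject_id == "s1" & out$block == 1],
               70)  # mean(60, 80), not pooled 22/30
  expect_equal(out$percent_correct[out$subject_id == "s1" & out$block == 2],
               70)  # mean(50, 90)
})

test_that("twenty sessions in blocks of five give four summaries", {
  logs <- lapply(1:20, function(k)
    mk_trials(rep(c(TRUE, FALSE), c(7, 3)), session_id = k))
  out <- accuracy_by_condition(do.call(rbind, logs), "block", block_size = 5)
  expect_identical(nrow(out), 4L)
  expect_true(all(out$percent_correct == 70))
  expect_true(all(out$n_trials == 50))
})

test_that("bin and level groupings classify trials by separation", {
  df <- rbind(
    within(mk_trials(rep(TRUE, 10)), separation_euclid <- 2),
    within(mk_trials(rep(c(TRUE, FALSE), 5)), separation_euclid <- 4),
    within(mk_trials(rep(FALSE, 10)), separation_euclid <- 6))
  df$trial_index <- seq_len(nrow(df))
  out <- accuracy_by_condition(df, "bin")
  expect_identical(out$bin[order(out$bin)], c("maximum", "medium", "minimum"))
  expect_equal(out$percent_correct[out$bin == "minimum"], 100)
  expect_equal(out$percent_correct[out$bin == "medium"], 50)
  expect_equal(out$percent_correct[out$bin == "maximum"], 0)

  lv <- mk_trials(rep(TRUE, 6))
  lv$intervening_windows <- c(1L, 1L, 3L, 3L, NA, NA)
  expect_message(out2 <- accuracy_by_condition(lv, "level"), "cross-row")
  expect_identical(sort(unique(out2$level)), c(1L, 3L))
})

test_that("benefit score reproduces the hand-worked contingency example", {
  # one rat: e = 48, behavior present on c = 10 with a = 9 correct;
  # absent on d = 38 with b = 19 correct -> (9 - (19/38)*10)/48 = 1/12
  correct <- c(rep(TRUE, 9), FALSE, rep(TRUE, 19), rep(FALSE, 19))
  present <- c(rep(1L, 10), rep(0L, 38))
  tr <- mk_trials(correct)
  ann <- data.frame(subject_id = "s1", trial_index = seq_len(48))
  for (bl in behavior_labels()) ann[[bl]] <- 0L
  ann$waiting_left <- present
  bt <- benefit_scores(tr, ann, behaviors = "waiting_left")
  expect_equal(bt$mean_benefit, 1 / 12, tolerance = 1e-12)
  expect_identical(bt$n_rats, 1L)
})

test_that("behavior-independent accuracy gives a zero contribution", {
  # a/c == b/d == 0.5 exactly
  correct <- rep(c(TRUE, FALSE), 24)
  present <- rep(c(1L, 1L, 0L, 0L), 12)
  tr <- mk_trials(correct)
  ann <- data.frame(subject_id = "s1", trial_index = seq_len(48),
                    waiting_left = present)
  bt <- benefit_scores(tr, ann, behaviors = "waiting_left")
  expect_equal(bt$mean_benefit, 0)
})

test_that("degenerate emission margins follow the stated conventions", {
  tr <- mk_trials(rep(c(TRUE, FALSE), 10))
  never <- data.frame(subject_id = "s1", trial_index = 1:20, waiting_left = 0L)
  bt <- benefit_scores(tr, never, behaviors = "waiting_left")
  expect_equal(bt$mean_benefit, 0)   # c = 0: contribution 0, rat retained
  expect_equal(bt$sem, 0)
  expect_identical(bt$n_rats, 1L)

  tr2 <- rbind(tr, within(tr, subject_id <- "s2"))
  always <- rbind(never,
                  data.frame(subject_id = "s2", trial_index = 1:20,
                             waiting_left = 1L))
  expect_message(
    bt2 <- benefit_scores(tr2, always, behaviors = "waiting_left"),
    "every trial")
  expect_identical(bt2$n_rats, 1L)   # d = 0 rat dropped for that behavior
})

test_that("benefit scores equal the brute-force contingency oracle", {
  agents <- replicate(6, default_agents()$sham, simplify = FALSE)
  cohort <- simulate_probe_cohort(agents, seeds = 301:306)
  bt <- benefit_scores(cohort$trials, cohort$annotations)
  for (bh in behavior_labels()) {
    want <- brute_benefit(cohort$trials, cohort$annotations, bh)
    expect_equal(bt$mean_benefit[bt$behavior == bh], mean(want),
                 tolerance = 1e-12)
    got <- attr(bt, "contributions")[, bh]
    expect_equal(sort(unname(got[!is.na(got)])), sort(want),
                 tolerance = 1e-12)
  }
})

test_that("benefit t-tests match the hand formula and Bonferroni rule", {
  agents <- replicate(5, default_agents()$sham, simplify = FALSE)
  cohort <- simulate_probe_cohort(agents, seeds = 401:405)
  bt <- test_benefits(benefit_scores(cohort$trials, cohort$annotations))
  contrib <- attr(bt, "contributions")
  for (bh in c("body_turn_right", "screen_touch_sample")) {
    x <- contrib[, bh][!is.na(contrib[, bh])]
    t_hand <- mean(x) / (stats::sd(x) / sqrt(length(x)))
    row <- bt[bt$behavior == bh, ]
    expect_equal(row$t, t_hand, tolerance = 1e-10)
    expect_equal(row$p_uncorrected,
                 2 * stats::pt(-abs(t_hand), length(x) - 1),
                 tolerance = 1e-10)
  }
  expect_equal(bt$p_bonferroni, pmin(1, 18 * bt$p_uncorrected))
  # the correction scale itself: p = 0.008 with 18 comparisons stays 0.144
  expect_equal(min(1, 18 * 0.008), 0.144)
})

test_that("identically-zero contributions give t = 0, p = 1", {
  tr <- rbind(mk_trials(rep(c(TRUE, FALSE), 10)),
              within(mk_trials(rep(c(TRUE, FALSE), 10)), subject_id <- "s2"))
  ann <- data.frame(subject_id = rep(c("s1", "s2"), each = 20),
                    trial_index = rep(1:20, 2))
  for (bl in behavior_labels()) ann[[bl]] <- 0L
  bt <- test_benefits(benefit_scores(tr, ann))
  expect_true(all(bt$t == 0))
  expect_true(all(bt$p_uncorrected == 1))
  expect_true(all(bt$p_bonferroni == 1))
})

test_that("chance test matches the closed form and handles constants", {
  expect_identical(chance_test(c(50, 50, 50))$t, 0)
  expect_identical(chance_test(c(50, 50, 50))$p, 1)
  res <- chance_test(c(60, 55, 65, 58))
  expect_equal(res$t, 4.520394039, tolerance = 1e-8)  # hand (mean-50)/(sd/sqrt(4))
  ht <- stats::t.test(c(60, 55, 65, 58), mu = 50)      # independent route
  expect_equal(res$t, unname(ht$statistic), tolerance = 1e-12)
  expect_equal(res$p, ht$p.value, tolerance = 1e-12)
  expect_identical(chance_test(c(70, 70))$p, 0)
  expect_error(chance_test(55), "at least 2")
})

test_that("null accuracy values rarely reject chance", {
  set.seed(61)
  rejections <- vapply(1:40, function(i) {
    vals <- 100 * stats::rbinom(8, 200, 0.5) / 200
    chance_test(vals)$p < 0.05
  }, TRUE)
  expect_lte(mean(rejections), 0.10)
})
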