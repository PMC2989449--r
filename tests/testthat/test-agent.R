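test_that("choice probability matches the closed-form model", {
  sham <- default_agents()$sham
  lesion <- default_agents()$lesion
  # frozen hand evaluations of 0.5 + (p_max-0.5)(1-exp(-(sep-floor)/scale))exp(-d/tau)
  expect_equal(choice_probability(sham, 6, 6), 0.8199471527, tolerance = 1e-9)
  expect_equal(choice_probability(lesion, 6, 6), 0.5676707639, tolerance = 1e-9)
  expect_equal(choice_probability(sham, 1, 6), 0.8477518560, tolerance = 1e-9)
  expect_equal(choice_probability(lesion, 1, 6), 0.7361941744, tolerance = 1e-9)
  # separation at or below the floor gives chance
  expect_equal(choice_probability(sham, 1, 2), 0.5)
  expect_equal(choice_probability(lesion, 1, 0.5), 0.5)
  # very long delays give chance in the limit
  expect_equal(choice_probability(sham, 1e6, 6), 0.5, tolerance = 1e-8)
  expect_error(choice_probability(sham, -1, 6), "non-negative")
  expect_error(choice_probability(sham, 6, 0), "positive")
})

test_that("choice probability is bounded and monotone in each argument", {
  agents <- default_agents()
  delays <- c(0, 0.5, 1, 2, 4, 6, 10, 30, 120)
  seps <- c(0.5, 1, sqrt(2), 2, 3, 4.5, 6, 6.4)
  for (a in agents) {
    p <- outer(delays, seps, function(d, s) choice_probability(a, d, s))
    expect_true(all(p >= 0.5 & p <= a$p_max))
    expect_true(all(apply(p, 2, diff) <= 1e-12))   # non-increasing in delay
    expect_true(all(apply(p, 1, diff) >= -1e-12))  # non-decreasing in separation
  }
})

test_that("default agents reproduce the qualitative lesion pattern", {
  a <- default_agents()
  expect_true(a$lesion$lesion && !a$sham$lesion)
  # lesion near 60% at the demanding condition (6 s delay, max separation)
  expect_gt(choice_probability(a$lesion, 6, 6), 0.55)
  expect_lt(choice_probability(a$lesion, 6, 6), 0.65)
  # both groups at chance at the separation floor
  expect_equal(choice_probability(a$sham, 1, 2), 0.5)
  expect_equal(choice_probability(a$lesion, 1, 2), 0.5)
  # the lesion deficit collapses at a short delay: the 1 s gap is a
  # fraction of the 6 s gap
  gap6 <- choice_probability(a$sham, 6, 6) - choice_probability(a$lesion, 6, 6)
  gap1 <- choice_probability(a$sham, 1, 6) - choice_probability(a$lesion, 1, 6)
  expect_lt(gap1, gap6 / 2)
})

test_that("a p_max 0.5 agent is a fair coin regardless of conditions", {
  set.seed(11)
  ag <- random_agent()
  hits <- vapply(1:4000, function(i)
    tunlsim:::agent_act(ag, delay_s = sample(c(0, 6), 1),
                        separation = sample(c(1, 6), 1))$correct, TRUE)
  se <- sqrt(0.25 / length(hits))
  expect_lt(abs(mean(hits) - 0.5), 3 * se)
})

test_that("an injected strategy shifts accuracy only on emitting trials", {
  # baseline 0.6 agent: p_max 0.6 reached at delay 0 and huge separation
  set.seed(21)
  ag <- agent_params(p_max = 0.6, tau_s = 1e9, sep_floor = 0,
                     sep_scale = 1e-9,
                     strategy = strategy_spec("screen_touch_sample", 0.5, 0.15))
  acts <- lapply(1:10000, function(i)
    tunlsim:::agent_act(ag, delay_s = 0, separation = 50))
  hit <- vapply(acts, `[[`, TRUE, "correct")
  emitted <- vapply(acts, function(a) a$behaviors[["screen_touch_sample"]], TRUE)
  se <- function(p, n) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(hit[emitted]) - 0.75), 3 * se(0.75, sum(emitted)))
  expect_lt(abs(mean(hit[!emitted]) - 0.60), 3 * se(0.60, sum(!emitted)))
  expect_lt(abs(mean(emitted) - 0.5), 3 * se(0.5, length(emitted)))
})

test_that("a zero-benefit strategy leaves outcomes independent of emission", {
  set.seed(31)
  ag <- agent_params(p_max = 0.75, tau_s = 1e9, sep_floor = 0, sep_scale = 1e-9,
                     strategy = strategy_spec("waiting_left", 0.5, 0))
  acts <- lapply(1:10000, function(i)
    tunlsim:::agent_act(ag, delay_s = 0, separation = 50))
  hit <- vapply(acts, `[[`, TRUE, "correct")
  emitted <- vapply(acts, function(a) a$behaviors[["waiting_left"]], TRUE)
  diff <- mean(hit[emitted]) - mean(hit[!emitted])
  se <- sqrt(0.25 / sum(emitted) + 0.25 / sum(!emitted))
  expect_lt(abs(diff), 3 * se)
})

test_that("strategy emission with probability one marks every trial", {
  set.seed(41)
  ag <- agent_params(strategy = strategy_spec("orient_side_left", 1, 0),
                     behavior_base_rate = 0)
  acts <- lapply(1:50, function(i) tunlsim:::agent_act(ag, 6, 6))
  expect_true(all(vapply(acts, function(a)
    a$behaviors[["orient_side_left"]], TRUE)))
  others <- vapply(acts, function(a)
    sum(a$behaviors[setdiff(behavior_labels(), "orient_side_left")]), 0)
  expect_true(all(others == 0))
})

test_that("memory time constant is recoverable by maximum likelihood", {
  gen <- agent_params(p_max = 0.88, tau_s = 4, sep_floor = 2, sep_scale = 2.5,
                      latency_min = 0, latency_max = 0,
                      behavior_base_rate = 0)
  # 50 standard-length sessions at maximum separation, delays bracketing
  # tau: the identification experiment for the decay constant
  delays <- rep(c(1, 2, 4, 6, 10), each = 10)
  logs <- lapply(seq_along(delays), function(i) {
    spec <- session_spec("B", delay_s = delays[i], condition = "same_row",
                         windows = 5, n_trials_cap = 64)
    cfg <- task_config(delay_s = delays[i], iti_s = 0, timeout_s = 0,
                       max_trials = 64)
    session_trials(run_session(cfg, gen, spec, rng_seed = 5000 + i), i)
  })
  trials <- do.call(rbind, logs)
  tau_hat <- fit_memory_decay(trials, gen)
  expect_lt(abs(tau_hat - 4) / 4, 0.20)
})

test_that("invalid agent parameters are rejected", {
  expect_error(agent_params(p_max = 0.4), "p_max")
  expect_error(agent_params(tau_s = 0), "tau_s")
  expect_error(agent_params(sep_scale = -1), "sep_scale")
  expect_error(strategy_spec("not_a_behavior", 0.5, 0), "unknown behavior")
  expect_error(strategy_spec("waiting_left", 1.5, 0))
})
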