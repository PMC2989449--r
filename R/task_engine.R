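#' Session-level task configuration
#'
#' Defaults reproduce the standard testing regime: 6 s sample-choice delay,
#' 10 s inter-trial interval, a 5 s house-light-off timeout after errors,
#' sample touches rewarded on 1/3 of trials, correction trials enabled, and
#' a session ending at 64 completed (non-correction) trials or one hour,
#' whichever comes first.
#'
#' @param delay_s Sample-choice delay in seconds.
#' @param iti_s Inter-trial interval in seconds.
#' @param timeout_s Post-error timeout in seconds.
#' @param max_trials Cap on completed non-correction trials.
#' @param max_session_s Session time cap in seconds.
#' @param sample_reward_prob Probability that a sample touch is rewarded.
#' @param corrections_enabled Run a correction trial after each error?
#' @param max_corrections Cap on consecutive correction trials after one
#'   error (`Inf` = repeat until correct; the time cap still bounds the
#'   session).
#' @return An object of class `task_config`.
#' @export
task_config <- function(delay_s = 6, iti_s = 10, timeout_s = 5,
                        max_trials = 64, max_session_s = 3600,
                        sample_reward_prob = 1 / 3,
                        corrections_enabled = TRUE,
                        max_corrections = Inf) {
  stopifnot(delay_s >= 0, iti_s >= 0, timeout_s >= 0,
            max_trials >= 1, max_session_s > 0,
            sample_reward_prob >= 0, sample_reward_prob <= 1,
            max_corrections >= 0)
  structure(list(delay_s = delay_s, iti_s = iti_s, timeout_s = timeout_s,
                 max_trials = as.integer(max_trials),
                 max_session_s = max_session_s,
                 sample_reward_prob = sample_reward_prob,
                 corrections_enabled = isTRUE(corrections_enabled),
                 max_corrections = max_corrections),
            class = "task_config")
}

#' Read a task configuration from YAML or JSON
#'
#' @param path Path to the config file; fields mirror [task_config()]
#'   arguments, unknown fields are an error.
#' @return A `task_config`.
#' @export
task_config_from_file <- function(path) {
  cfg <- read_config_file(path)
  known <- names(formals(task_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown task_config fields: ", paste(bad, collapse = ", "))
  do.call(task_config, cfg)
}

#' Draw sample-phase reward flags
#'
#' Each sample touch is rewarded with a pellet with probability
#' `sample_reward_prob`, independently per trial.
#'
#' @param config A [task_config()].
#' @param n Number of independent draws.
#' @return Logical vector of length `n`.
#' @export
sample_reward_draw <- function(config, n = 1) {
  stopifnot(inherits(config, "task_config"))
  stats::runif(n) < config$sample_reward_prob
}

# normalises the trial source into a zero-argument draw function
make_pair_sampler <- function(trial_source) {
  if (inherits(trial_source, "session_spec"))
    trial_source <- eligible_pairs(trial_source)
  if (is.data.frame(trial_source)) {
    pairs <- trial_source
    if (nrow(pairs) == 0) stop("trial source contains no eligible pairs")
    need <- c("sminus_row", "sminus_col", "splus_row", "splus_col")
    if (!all(need %in% names(pairs)))
      stop("pair data frame must have columns ", paste(need, collapse = ", "))
    return(function() as.numeric(pairs[sample.int(nrow(pairs), 1L),
                                       need]))
  }
  if (is.function(trial_source)) {
    return(function() {
      p <- trial_source()
      if (is.data.frame(p))
        p <- as.numeric(p[1, c("sminus_row", "sminus_col",
                               "splus_row", "splus_col")])
      if (length(p) != 4) stop("trial source must yield an ordered pair")
      as.numeric(p)
    })
  }
  stop("trial_source must be a session_spec, a pair data frame, or a function")
}

#' Run one TUNL session against an agent
#'
#' A discrete-event simulation of the trial state machine: initiation poke,
#' sample touch (rewarded with a pellet on a fraction of trials), delay,
#' magazine poke, choice between the repeated sample location (S-) and the
#' novel location (S+), then reward collection on correct choices or a
#' house-light-off timeout on errors, followed by the inter-trial interval.
#' Every error is followed by a correction trial with identical placements
#' (when enabled); correction trials do not count toward the trial cap and
#' are excluded from accuracy downstream. The session ends at the trial cap
#' or the time cap, whichever is reached first. A trial that would end past
#' the time cap is discarded, matching a session cut off by the clock.
#'
#' @param config A [task_config()].
#' @param agent An [agent_params()].
#' @param trial_source Where S-/S+ placements come from: a
#'   [session_spec()], a pair data frame from [enumerate_pairs()], or a
#'   function returning `(sminus_row, sminus_col, splus_row, splus_col)`.
#' @param rng_seed Integer seed; the full session (placements, latencies,
#'   rewards, behaviors, choices) is reproducible from it.
#' @return An object of class `tunl_session`: list with `trials` (data
#'   frame, one row per trial including corrections), `annotations` (data
#'   frame of per-trial 0/1 marks for the 18 candidate behaviors),
#'   `config`, `agent_label`, `termination` (`"trial_cap"` or
#'   `"time_cap"`), `rng_seed`, and `pellets` delivered.
#' @examples
#' s <- run_session(task_config(), default_agents()$sham,
#'                  session_spec(tunl_mask("B"), 6, "same_row", windows = 5),
#'                  rng_seed = 1)
#' percent_correct(s)
#' @export
run_session <- function(config, agent, trial_source, rng_seed) {
  stopifnot(inherits(config, "task_config"), inherits(agent, "agent_params"))
  draw_pair <- make_pair_sampler(trial_source)
  set.seed(as.integer(rng_seed))

  cap_n <- config$max_trials
  alloc <- max(16L, cap_n * 4L)
  idx <- is_corr <- s_row <- s_col <- p_row <- p_col <- numeric(alloc)
  r_row <- r_col <- correct <- s_rew <- t0 <- t1 <- numeric(alloc)
  behav <- matrix(0L, nrow = alloc, ncol = 18L)

  lat <- function() stats::runif(1, agent$latency_min, agent$latency_max)

  t <- 0; k <- 0L; n_main <- 0L; n_corr_run <- 0
  pellets <- 0L
  pending <- NULL
  termination <- "trial_cap"

  repeat {
    if (n_main >= cap_n) { termination <- "trial_cap"; break }
    if (t >= config$max_session_s) { termination <- "time_cap"; break }
    correction <- !is.null(pending)
    pair <- if (correction) pending else draw_pair()
    t_start <- t
    tt <- t
    tt <- tt + lat()                      # initiation poke
    tt <- tt + lat()                      # sample touch
    rewarded <- stats::runif(1) < config$sample_reward_prob
    tt <- tt + config$delay_s             # delay
    tt <- tt + lat()                      # magazine poke opens choice
    tt <- tt + lat()                      # choice touch
    sep <- sep_euclid(pair[1], pair[2], pair[3], pair[4])
    act <- agent_act(agent, config$delay_s, sep)
    ok <- act$correct
    if (ok) tt <- tt + lat()              # collect reward pellet
    else tt <- tt + config$timeout_s      # house light off
    tt <- tt + config$iti_s
    if (tt > config$max_session_s) { termination <- "time_cap"; break }
    t <- tt

    k <- k + 1L
    if (k > alloc) {                      # grow storage (heavy-correction runs)
      grow <- function(v) c(v, numeric(alloc))
      idx <- grow(idx); is_corr <- grow(is_corr)
      s_row <- grow(s_row); s_col <- grow(s_col)
      p_row <- grow(p_row); p_col <- grow(p_col)
      r_row <- grow(r_row); r_col <- grow(r_col)
      correct <- grow(correct); s_rew <- grow(s_rew)
      t0 <- grow(t0); t1 <- grow(t1)
      behav <- rbind(behav, matrix(0L, alloc, 18L))
      alloc <- alloc * 2L
    }
    idx[k] <- k; is_corr[k] <- correction
    s_row[k] <- pair[1]; s_col[k] <- pair[2]
    p_row[k] <- pair[3]; p_col[k] <- pair[4]
    if (ok) { r_row[k] <- pair[3]; r_col[k] <- pair[4] }
    else    { r_row[k] <- pair[1]; r_col[k] <- pair[2] }
    correct[k] <- ok; s_rew[k] <- rewarded
    t0[k] <- t_start; t1[k] <- t
    behav[k, ] <- as.integer(act$behaviors)
    pellets <- pellets + as.integer(ok) + as.integer(rewarded)

    if (!correction) n_main <- n_main + 1L
    if (!ok && config$corrections_enabled &&
        (if (correction) n_corr_run else 0) < config$max_corrections) {
      n_corr_run <- if (correction) n_corr_run + 1 else 1
      pending <- pair
    } else {
      n_corr_run <- 0
      pending <- NULL
    }
  }

  keep <- seq_len(k)
  trials <- data.frame(
    trial = as.integer(idx[keep]),
    is_correction = as.logical(is_corr[keep]),
    sample_row = as.integer(s_row[keep]), sample_col = as.integer(s_col[keep]),
    splus_row = as.integer(p_row[keep]), splus_col = as.integer(p_col[keep]),
    response_row = as.integer(r_row[keep]), response_col = as.integer(r_col[keep]),
    correct = as.logical(correct[keep]),
    sample_rewarded = as.logical(s_rew[keep]),
    t_start = t0[keep], t_end = t1[keep]
  )
  trials$separation_euclid <- sep_euclid(trials$sample_row, trials$sample_col,
                                         trials$splus_row, trials$splus_col)
  trials$intervening_windows <- ifelse(
    trials$sample_row == trials$splus_row,
    abs(trials$sample_col - trials$splus_col) - 1L, NA_integer_)

  ann <- as.data.frame(behav[keep, , drop = FALSE])
  names(ann) <- behavior_labels()
  ann <- cbind(trial = trials$trial, ann)

  structure(list(trials = trials, annotations = ann, config = config,
                 agent_label = agent$label, termination = termination,
                 rng_seed = as.integer(rng_seed), pellets = pellets),
            class = "tunl_session")
}

#' @export
print.tunl_session <- function(x, ...) {
  nm <- sum(!x$trials$is_correction)
  nc <- sum(x$trials$is_correction)
  cat(sprintf(
    "TUNL session (agent '%s', seed %d): %d trials + %d corrections, %s after %.0f s\n",
    x$agent_label, x$rng_seed, nm, nc, x$termination,
    if (nrow(x$trials)) max(x$trials$t_end) else 0))
  if (nm > 0)
    cat(sprintf("  %.1f%% correct (correction trials excluded), %d pellets\n",
                percent_correct(x)$percent_correct, x$pellets))
  invisible(x)
}

#' Run the pre-training stages against an agent
#'
#' The four stages run in fixed order. *Habituation*: 20 min of free
#' exploration (always passes). *Tone-food*: one 100-trial session pairing a
#' tone with a pellet; a non-responding subject still receives the pellet
#' after 30 s, so the stage always completes. *Touch-any*: the subject must
#' touch the active screen; criterion is 100 trials within 30 min (up to
#' `max_stage_sessions` attempts). *Single-location*: one randomly lit
#' window must be poked; pokes elsewhere are neither rewarded nor punished
#' and only cost time; criterion is 100 trials within 1 h.
#'
#' @param agent An [agent_params()]; its `responsiveness` is the per-attempt
#'   probability of responding within a stage's response window.
#' @param rng_seed Integer seed.
#' @param max_stage_sessions Attempts allowed for criterion stages.
#' @return A data frame with one row per stage: `stage`, `passed`,
#'   `trials_completed`, `sessions_used`, `time_s` (time of the last
#'   session).
#' @export
run_pretraining <- function(agent, rng_seed, max_stage_sessions = 5) {
  stopifnot(inherits(agent, "agent_params"))
  set.seed(as.integer(rng_seed))
  q <- agent$responsiveness
  lat <- function() stats::runif(1, agent$latency_min, agent$latency_max)

  res <- list()
  res[[1]] <- data.frame(stage = "habituation", passed = TRUE,
                         trials_completed = 0L, sessions_used = 1L,
                         time_s = 20 * 60)

  # tone_food: tone + pellet every 30 s; a touch earns 3 pellets immediately.
  t <- 0; done <- 0L
  while (done < 100L) {
    if (stats::runif(1) < q) t <- t + lat() else t <- t + 30
    done <- done + 1L
  }
  res[[2]] <- data.frame(stage = "tone_food", passed = TRUE,
                         trials_completed = done, sessions_used = 1L,
                         time_s = t)

  run_criterion_stage <- function(stage, window_s, slack_per_trial,
                                  p_respond) {
    sessions <- 0L; best <- 0L; t_last <- 0
    passed <- FALSE
    while (sessions < max_stage_sessions && !passed) {
      sessions <- sessions + 1L
      t <- 0; done <- 0L
      while (t < window_s && done < 100L) {
        if (stats::runif(1) < p_respond) {
          t <- t + lat() + slack_per_trial
          done <- done + 1L
        } else {
          t <- t + 30          # response window elapses with no touch
        }
      }
      best <- max(best, done); t_last <- t
      passed <- done >= 100L && t <= window_s
    }
    data.frame(stage = stage, passed = passed, trials_completed = best,
               sessions_used = sessions, time_s = t_last)
  }

  res[[3]] <- run_criterion_stage("touch_any", 30 * 60, 5, q)
  # single_location: off-target pokes are ignored; modelled as extra dead
  # time via the 5 s post-collection ITI plus the magazine poke to start.
  res[[4]] <- run_criterion_stage("single_location", 60 * 60, 5 + 2, q)
  do.call(rbind, res)
}
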