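# Shared fixtures and independent oracles. The oracles deliberately use
# naive double loops / raw contingency arithmetic so they stay independent
# of the package's code paths.

# brute-force ordered pair enumeration over a mask's locations
brute_pairs <- function(mask) {
  locs <- grid_locations(mask)
  out <- list()
  for (i in seq_len(nrow(locs))) for (j in seq_len(nrow(locs))) {
    if (i == j) next
    out[[length(out) + 1L]] <- data.frame(
      sminus_row = locs$row[i], sminus_col = locs$col[i],
      splus_row = locs$row[j], splus_col = locs$col[j])
  }
  do.call(rbind, out)
}

# brute-force benefit score: partition each subject's non-correction trials
# by behavior presence and recompute the contingency arithmetic from raw
# counts, one subject and one behavior at a time
brute_benefit <- function(trials, annotations, behavior) {
  tr <- trials[!as.logical(trials$is_correction), ]
  m <- merge(tr[, c("subject_id", "trial_index", "correct")],
             annotations[, c("subject_id", "trial_index", behavior)],
             by = c("subject_id", "trial_index"))
  xs <- c()
  for (s in sort(unique(m$subject_id))) {
    rows <- m[m$subject_id == s, ]
    pres <- as.logical(rows[[behavior]])
    a <- sum(rows$correct & pres);  cc <- sum(pres)
    b <- sum(rows$correct & !pres); d <- sum(!pres)
    e <- nrow(rows)
    if (cc == 0) xs <- c(xs, 0)
    else if (d == 0) next
    else xs <- c(xs, (a - (b / d) * cc) / e)
  }
  xs
}

# agent whose choice is deterministic-correct when the session delay is 0
perfect_agent <- function(...) {
  agent_params(p_max = 1, tau_s = 1e9, sep_floor = 0, sep_scale = 1e-9,
               latency_min = 0, latency_max = 0, behavior_base_rate = 0,
               label = "perfect", ...)
}

# fair-coin chooser: separation and delay have no effect
random_agent <- function(...) {
  agent_params(p_max = 0.5, latency_min = 0, latency_max = 0,
               behavior_base_rate = 0.2, label = "random", ...)
}

# zero-latency config for fast long sessions
fast_config <- function(...) {
  task_config(delay_s = 0, iti_s = 0, timeout_s = 0, ...)
}

# a small annotated cohort at the largest separations (behavior-probe
# regime: 48-trial cap, 6 s delay, 20 s ITI)
simulate_probe_cohort <- function(agents, seeds) {
  spec <- session_spec("B", delay_s = 6, condition = "same_row",
                       windows = c(4, 5), iti_s = 20, n_trials_cap = 48)
  trials <- list(); anns <- list()
  for (i in seq_along(agents)) {
    ses <- run_session(task_config(delay_s = 6, iti_s = 20, max_trials = 48),
                       agents[[i]], spec, rng_seed = seeds[i])
    sid <- sprintf("s%02d", i)
    trials[[i]] <- session_trials(ses, 1L, sid)
    ann <- ses$annotations
    names(ann)[names(ann) == "trial"] <- "trial_index"
    anns[[i]] <- cbind(subject_id = sid, ann)
  }
  list(trials = do.call(rbind, trials), annotations = do.call(rbind, anns))
}
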