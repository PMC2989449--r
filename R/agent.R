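#' The 18 candidate mediating behaviors
#'
#' Hand-scoreable behaviors emitted during the delay that might bridge it
#' and reduce the memory demand of the task: whole-body and head turns,
#' orienting (forwards, backwards, sideways, in the magazine), back-and-forth
#' shuttling, waiting at the screen, and screen touches at the sample or at
#' another window. Left/right are relative to the box, not the rat.
#'
#' @return Character vector of the 18 behavior labels, in canonical order
#'   (the column order of annotation tables).
#' @export
behavior_labels <- function() {
  c("body_turn_right", "body_turn_left",
    "head_turn_right", "head_turn_left",
    "orient_fwd_right", "orient_fwd_left",
    "orient_back_right", "orient_back_left",
    "orient_side_right", "orient_side_left",
    "orient_mag_right", "orient_mag_left",
    "back_forth_right", "back_forth_left",
    "waiting_right", "waiting_left",
    "screen_touch_sample", "screen_touch_other")
}

#' Specify a candidate mediating strategy for a simulated subject
#'
#' A strategy is one of the 18 candidate behaviors emitted with a fixed
#' per-trial probability; on trials where it is emitted the agent's
#' probability of choosing the novel location shifts by `benefit_beta`
#' (positive = benefit, negative = cost). All other behaviors are emitted
#' at the agent's background rate with no performance effect, so a strategy
#' with `benefit_beta = 0` is behaviorally indistinguishable from background.
#'
#' @param behavior_label One of [behavior_labels()].
#' @param emission_prob Per-trial emission probability in `[0, 1]`.
#' @param benefit_beta Additive change to P(correct) on emitting trials;
#'   the resulting probability is clipped to `[0.02, 0.98]`.
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(behavior_label, emission_prob, benefit_beta) {
  if (!behavior_label %in% behavior_labels())
    stop("unknown behavior label: ", behavior_label)
  stopifnot(emission_prob >= 0, emission_prob <= 1, is.numeric(benefit_beta))
  structure(list(behavior_label = behavior_label,
                 emission_prob = emission_prob,
                 benefit_beta = benefit_beta),
            class = "strategy_spec")
}

#' Parametric simulated TUNL subject
#'
#' The agent's probability of choosing the novel location (S+) is
#' \deqn{P = 0.5 + (p_{max} - 0.5)\, S(sep)\, e^{-delay/\tau}}{
#'       P = 0.5 + (p_max - 0.5) * S(sep) * exp(-delay/tau)}
#' with a saturating separation discriminability
#' \deqn{S(sep) = 1 - e^{-\max(0, sep - floor)/scale}.}{
#'       S(sep) = 1 - exp(-max(0, sep - floor)/scale).}
#' Accuracy therefore decays exponentially with the sample-choice delay
#' (time constant `tau_s`), is at chance for separations at or below
#' `sep_floor`, and saturates toward `p_max` at large separations.
#' Hippocampal lesion status is expressed through the parameters (a short
#' memory time constant and a shallower separation sensitivity), not as a
#' separate mechanism: under short delays and large separations a lesioned
#' agent performs like an intact one.
#'
#' @param p_max Asymptotic accuracy, in `[0.5, 1]`.
#' @param tau_s Memory-decay time constant in seconds (> 0).
#' @param sep_floor Separation (grid units) at or below which discrimination
#'   is nil (>= 0).
#' @param sep_scale Separation sensitivity scale in grid units (> 0).
#' @param lesion Logical flag recording lesion status (bookkeeping only; the
#'   behavioral consequences live in the parameters).
#' @param latency_min,latency_max Bounds of the uniform latency draw (s)
#'   used for each response phase (initiation poke, sample touch, magazine
#'   poke, choice, reward collection).
#' @param strategy Optional [strategy_spec()].
#' @param behavior_base_rate Background per-trial emission probability for
#'   each non-strategy behavior (default 0.2).
#' @param responsiveness Probability of responding within a pre-training
#'   stage's response window (default 1).
#' @param label Optional profile name used in logs.
#' @return An object of class `agent_params`.
#' @seealso [default_agents()], [choice_probability()]
#' @export
agent_params <- function(p_max = 0.88, tau_s = 60, sep_floor = 2,
                         sep_scale = 1.5, lesion = FALSE,
                         latency_min = 1, latency_max = 3,
                         strategy = NULL, behavior_base_rate = 0.2,
                         responsiveness = 1, label = NULL) {
  if (p_max < 0.5 || p_max > 1) stop("p_max must lie in [0.5, 1]")
  if (tau_s <= 0) stop("tau_s must be positive")
  if (sep_scale <= 0) stop("sep_scale must be positive")
  if (sep_floor < 0) stop("sep_floor must be non-negative")
  if (latency_min < 0 || latency_max < latency_min)
    stop("latency bounds must satisfy 0 <= latency_min <= latency_max")
  if (behavior_base_rate < 0 || behavior_base_rate > 1)
    stop("behavior_base_rate must be a probability")
  if (responsiveness < 0 || responsiveness > 1)
    stop("responsiveness must be a probability")
  if (!is.null(strategy) && !inherits(strategy, "strategy_spec"))
    stop("strategy must be a strategy_spec or NULL")
  structure(
    list(p_max = p_max, tau_s = tau_s, sep_floor = sep_floor,
         sep_scale = sep_scale, lesion = isTRUE(lesion),
         latency_min = latency_min, latency_max = latency_max,
         strategy = strategy, behavior_base_rate = behavior_base_rate,
         responsiveness = responsiveness,
         label = label %||% if (isTRUE(lesion)) "lesion" else "sham"),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "TUNL agent '%s'%s: p_max %.2f, tau %.3g s, sep floor %.2g, sep scale %.2g\n",
    x$label, if (x$lesion) " (hippocampal lesion)" else "",
    x$p_max, x$tau_s, x$sep_floor, x$sep_scale))
  if (!is.null(x$strategy))
    cat(sprintf("  strategy: %s (emission %.2f, benefit %+.3f)\n",
                x$strategy$behavior_label, x$strategy$emission_prob,
                x$strategy$benefit_beta))
  invisible(x)
}

#' Calibrated default intact and lesioned agents
#'
#' Parameter sets calibrated so that at a 6 s delay and maximum separation
#' the intact (sham-operated) agent performs near 80% correct and the
#' hippocampal-lesion agent near 60%, while at a 1 s delay and maximum
#' separation both perform well, and at separations at the floor both sit
#' at chance. The lesion is a shorter memory time constant (4 s vs 60 s)
#' and a shallower separation sensitivity (scale 2.5 vs 1.5), with the same
#' asymptote: under undemanding conditions the groups are indistinguishable.
#'
#' @param ... Overrides passed to both [agent_params()] calls.
#' @return A list with elements `sham` and `lesion`.
#' @examples
#' a <- default_agents()
#' choice_probability(a$sham, delay_s = 6, separation = 6)
#' @export
default_agents <- function(...) {
  list(
    sham = agent_params(p_max = 0.88, tau_s = 60, sep_floor = 2,
                        sep_scale = 1.5, lesion = FALSE, label = "sham", ...),
    lesion = agent_params(p_max = 0.88, tau_s = 4, sep_floor = 2,
                          sep_scale = 2.5, lesion = TRUE, label = "lesion", ...)
  )
}

#' Probability of choosing the novel location
#'
#' Evaluates the agent's accuracy model (see [agent_params()]) at a given
#' sample-choice delay and S+/S- separation. Bounded in `[0.5, p_max]`,
#' non-increasing in delay and non-decreasing in separation.
#'
#' @param params An `agent_params` object.
#' @param delay_s Delay in seconds (>= 0); vectorised.
#' @param separation S+/S- separation in Euclidean grid units (> 0);
#'   vectorised.
#' @return Probability (or vector of probabilities) of a correct choice.
#' @export
choice_probability <- function(params, delay_s, separation) {
  stopifnot(inherits(params, "agent_params"))
  if (any(delay_s < 0)) stop("delay_s must be non-negative")
  if (any(separation <= 0)) stop("separation must be positive")
  disc <- 1 - exp(-pmax(0, separation - params$sep_floor) / params$sep_scale)
  0.5 + (params$p_max - 0.5) * disc * exp(-delay_s / params$tau_s)
}

# One choice + behavior emission. Fixed RNG draw order (strategy emission,
# background emissions, choice) keeps sessions bit-reproducible from a seed.
agent_act <- function(params, delay_s, separation) {
  p <- choice_probability(params, delay_s, separation)
  labs <- behavior_labels()
  present <- stats::runif(length(labs)) < params$behavior_base_rate
  names(present) <- labs
  if (!is.null(params$strategy)) {
    st <- params$strategy
    emitted <- stats::runif(1) < st$emission_prob
    present[st$behavior_label] <- emitted
    if (emitted) p <- min(0.98, max(0.02, p + st$benefit_beta))
  }
  list(correct = stats::runif(1) < p, behaviors = present)
}

#' Estimate the memory-decay time constant from trial logs
#'
#' Maximum-likelihood estimate of `tau_s` from a trial log containing
#' per-trial delays, separations and outcomes, holding the remaining
#' accuracy-model parameters at the supplied values. Correction trials are
#' excluded. The delay range must bracket the time constant for it to be
#' identifiable; a 60 s constant cannot be recovered from delays of a few
#' seconds.
#'
#' @param trials A trial-log data frame with columns `delay_s`,
#'   `separation_euclid`, `correct` and `is_correction` (as written by
#'   [write_trial_log()] / returned by [session_trials()]).
#' @param params `agent_params` supplying `p_max`, `sep_floor`, `sep_scale`.
#' @param interval Search interval for `tau_s` in seconds.
#' @return The ML estimate of `tau_s` (scalar).
#' @export
fit_memory_decay <- function(trials, params, interval = c(0.1, 500)) {
  tr <- trials[!as.logical(trials$is_correction), , drop = FALSE]
  if (nrow(tr) == 0) stop("no non-correction trials to fit")
  y <- as.logical(tr$correct)
  d <- tr$delay_s
  s <- tr$separation_euclid
  nll <- function(tau) {
    pars <- params; pars$tau_s <- tau
    p <- choice_probability(pars, d, s)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(ifelse(y, log(p), log(1 - p)))
  }
  stats::optimise(nll, interval = interval)$minimum
}

#' Read agent parameters from a YAML or JSON config file
#'
#' Fields mirror the arguments of [agent_params()]; a nested `strategy`
#' block with `behavior_label`, `emission_prob` and `benefit_beta` becomes
#' a [strategy_spec()].
#'
#' @param path Path to the config file.
#' @return An `agent_params` object.
#' @export
agent_from_config <- function(path) {
  cfg <- read_config_file(path)
  agent_from_list(cfg)
}

agent_from_list <- function(cfg) {
  strat <- NULL
  if (!is.null(cfg$strategy))
    strat <- strategy_spec(cfg$strategy$behavior_label,
                           cfg$strategy$emission_prob,
                           cfg$strategy$benefit_beta)
  agent_params(
    p_max = cfg$p_max %||% 0.88, tau_s = cfg$tau_s %||% 60,
    sep_floor = cfg$sep_floor %||% 2, sep_scale = cfg$sep_scale %||% 1.5,
    lesion = cfg$lesion %||% FALSE,
    latency_min = cfg$latency_min %||% 1, latency_max = cfg$latency_max %||% 3,
    strategy = strat, behavior_base_rate = cfg$behavior_base_rate %||% 0.2,
    responsiveness = cfg$responsiveness %||% 1, label = cfg$label
  )
}
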