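#' Specify one session of an experiment plan
#'
#' Binds a mask, a delay, an inter-trial interval, a trial cap and a
#' separation condition (which pairs are eligible). Construction fails if
#' the condition is unsatisfiable on the mask.
#'
#' @param mask A [tunl_mask()] or mask name (`"A"`/`"B"`).
#' @param delay_s Sample-choice delay in seconds.
#' @param condition Pair constraint: `"all"`, `"same_row"` (with
#'   `windows`), `"bin"` (with `bin`), or `"nonadjacent"` — see
#'   [enumerate_pairs()].
#' @param windows,bin Passed to [enumerate_pairs()].
#' @param iti_s Inter-trial interval in seconds.
#' @param n_trials_cap Cap on completed non-correction trials.
#' @param label Optional condition label carried into plans and logs.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(mask, delay_s, condition = "all", windows = NULL,
                         bin = NULL, iti_s = 10, n_trials_cap = 64,
                         label = NULL) {
  if (is.character(mask)) mask <- tunl_mask(mask)
  stopifnot(inherits(mask, "tunl_mask"), delay_s >= 0, iti_s >= 0,
            n_trials_cap >= 1)
  spec <- structure(
    list(mask = mask, delay_s = delay_s, condition = condition,
         windows = windows, bin = bin, iti_s = iti_s,
         n_trials_cap = as.integer(n_trials_cap),
         label = label %||% condition),
    class = "session_spec")
  if (nrow(eligible_pairs(spec)) == 0)
    stop("separation condition is unsatisfiable on mask ", mask$name)
  spec
}

#' Eligible ordered pairs for a session specification
#'
#' @param spec A [session_spec()].
#' @return The pair data frame from [enumerate_pairs()] under the spec's
#'   condition.
#' @export
eligible_pairs <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  enumerate_pairs(spec$mask, spec$condition, windows = spec$windows,
                  bin = spec$bin)
}

#' Draw one trial's placements under a session specification
#'
#' Uniform over the eligible ordered pairs, independent across calls
#' (consumes the current RNG stream).
#'
#' @param spec A [session_spec()].
#' @return A one-row pair data frame (`sminus_row`, `sminus_col`,
#'   `splus_row`, `splus_col`, `separation`, `windows`).
#' @export
draw_trial <- function(spec) {
  pairs <- eligible_pairs(spec)
  pairs[sample.int(nrow(pairs), 1L), , drop = FALSE]
}

# Williams row-balanced Latin square for k conditions; row i gives one
# subject's condition order within a cycle.
williams_square <- function(k) {
  k <- as.integer(k)
  base <- integer(k)
  base[1] <- 1L
  lo <- 2L; hi <- k
  for (j in 2:k) {
    if (j %% 2 == 0) { base[j] <- hi; hi <- hi - 1L }
    else             { base[j] <- lo; lo <- lo + 1L }
  }
  sq <- t(vapply(0:(k - 1), function(r) ((base - 1L + r) %% k) + 1L,
                 integer(k)))
  sq
}

#' Build the session plan for one of the five experiments
#'
#' * `exp1` — acquisition: 20 sessions on mask A, 6 s delay, all pairs
#'   (separations binned post hoc by intervening-window count).
#' * `exp2` — delay x separation: 16 sessions on mask B in the fixed order
#'   6 s/maximum, 6 s/minimum, 1 s/maximum, 1 s/minimum (4 sessions = 2
#'   blocks of 2 per condition); maximum = 5 intervening windows,
#'   minimum = 1.
#' * `exp3` — counterbalanced delays with mixed separations: 8 sessions on
#'   mask B, delays 1 s and 6 s alternated in counterbalanced cycles,
#'   adjacent (touching-neighbour) pairs excluded, separations mixed within
#'   session and binned post hoc (minimum/medium/maximum).
#' * `exp4` — separation x lesion: 15 sessions on mask B at a 1 s delay,
#'   5 separation levels (1-5 intervening windows) each 3 times, one level
#'   per session, order counterbalanced by Williams Latin-square rows.
#' * `exp5` — mediating-behavior probe: a single 48-trial session on mask B
#'   at the largest separations (4-5 intervening windows), 6 s delay, 20 s
#'   inter-trial interval.
#'
#' Counterbalancing assigns subjects Latin-square rows cyclically: given
#' the same seed and subject the same plan is produced, conditions appear
#' equally often, and within each cycle no condition repeats before all
#' others have occurred.
#'
#' @param experiment `"exp1"` ... `"exp5"`.
#' @param rng_seed Integer seed (used only where the plan itself is
#'   randomised; the session draws are seeded separately at run time).
#' @param subject Subject index (1-based) selecting the Latin-square row
#'   for counterbalanced plans.
#' @return An object of class `tunl_plan`: list with `name`, `sessions`
#'   (list of [session_spec()]), and `block_size` used for reporting.
#' @examples
#' make_plan("exp4", rng_seed = 1, subject = 2)
#' @export
make_plan <- function(experiment, rng_seed = 1, subject = 1) {
  if (!experiment %in% paste0("exp", 1:5))
    stop("unknown experiment: ", experiment)
  set.seed(as.integer(rng_seed))
  subject <- as.integer(subject)

  sessions <- switch(experiment,
    exp1 = replicate(20, session_spec("A", delay_s = 6, condition = "all",
                                      label = "all"),
                     simplify = FALSE),
    exp2 = {
      conds <- list(
        list(delay = 6, windows = 5, label = "6s_max"),
        list(delay = 6, windows = 1, label = "6s_min"),
        list(delay = 1, windows = 5, label = "1s_max"),
        list(delay = 1, windows = 1, label = "1s_min"))
      unlist(lapply(conds, function(cd)
        replicate(4, session_spec("B", delay_s = cd$delay,
                                  condition = "same_row",
                                  windows = cd$windows, label = cd$label),
                  simplify = FALSE)),
        recursive = FALSE)
    },
    exp3 = {
      delays <- c(1, 6)
      sq <- williams_square(2)
      order_idx <- unlist(lapply(seq_len(4), function(cycle)
        sq[((subject - 1 + cycle - 1) %% 2) + 1, ]))
      lapply(delays[order_idx], function(d)
        session_spec("B", delay_s = d, condition = "nonadjacent",
                     label = sprintf("%gs_mixed", d)))
    },
    exp4 = {
      levels <- 1:5
      sq <- williams_square(5)
      order_idx <- unlist(lapply(seq_len(3), function(cycle)
        sq[((subject - 1 + cycle - 1) %% 5) + 1, ]))
      lapply(levels[order_idx], function(w)
        session_spec("B", delay_s = 1, condition = "same_row", windows = w,
                     label = sprintf("level%d", w)))
    },
    exp5 = list(session_spec("B", delay_s = 6, condition = "same_row",
                             windows = c(4, 5), iti_s = 20,
                             n_trials_cap = 48, label = "largest_sep"))
  )
  block_size <- switch(experiment, exp1 = 5L, exp2 = 2L, exp3 = 2L,
                       exp4 = 5L, exp5 = 1L)
  structure(list(name = experiment, sessions = sessions,
                 block_size = block_size, subject = subject,
                 rng_seed = as.integer(rng_seed)),
            class = "tunl_plan")
}

#' @export
print.tunl_plan <- function(x, ...) {
  cat(sprintf("TUNL plan %s (subject %d): %d sessions, block size %d\n",
              x$name, x$subject, length(x$sessions), x$block_size))
  labs <- vapply(x$sessions, `[[`, "", "label")
  delays <- vapply(x$sessions, `[[`, 0, "delay_s")
  cat(sprintf("  %2d. %-12s delay %g s\n", seq_along(labs), labs, delays),
      sep = "")
  invisible(x)
}

#' Serialise a plan to a YAML file
#'
#' @param plan A `tunl_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "tunl_plan"))
  out <- list(
    name = plan$name, subject = plan$subject, rng_seed = plan$rng_seed,
    block_size = plan$block_size,
    sessions = lapply(plan$sessions, function(s) list(
      mask = s$mask$name, delay_s = s$delay_s, condition = s$condition,
      windows = s$windows, bin = s$bin, iti_s = s$iti_s,
      n_trials_cap = s$n_trials_cap, label = s$label)))
  yaml::write_yaml(out, path)
  invisible(path)
}
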