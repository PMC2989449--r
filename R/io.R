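#' Flatten a session into tidy trial-log rows
#'
#' @param session A `tunl_session` from [run_session()].
#' @param session_id Session identifier.
#' @param subject_id Subject identifier.
#' @return A data frame in the trial-log column layout used by
#'   [write_trial_log()]: `session_id`, `trial_index`, `is_correction`,
#'   `sample_row`, `sample_col`, `splus_row`, `splus_col`,
#'   `separation_euclid`, `intervening_windows`, `response_row`,
#'   `response_col`, `correct`, `sample_rewarded`, `delay_s`, `iti_s`,
#'   `t_start_s`, `t_end_s`, `seed`, plus a leading `subject_id`.
#' @export
session_trials <- function(session, session_id = 1L, subject_id = "s1") {
  stopifnot(inherits(session, "tunl_session"))
  tr <- session$trials
  data.frame(
    subject_id = subject_id,
    session_id = session_id,
    trial_index = tr$trial,
    is_correction = tr$is_correction,
    sample_row = tr$sample_row, sample_col = tr$sample_col,
    splus_row = tr$splus_row, splus_col = tr$splus_col,
    separation_euclid = tr$separation_euclid,
    intervening_windows = tr$intervening_windows,
    response_row = tr$response_row, response_col = tr$response_col,
    correct = tr$correct, sample_rewarded = tr$sample_rewarded,
    delay_s = session$config$delay_s, iti_s = session$config$iti_s,
    t_start_s = tr$t_start, t_end_s = tr$t_end,
    seed = session$rng_seed
  )
}

log_columns <- c("subject_id", "session_id", "trial_index", "is_correction",
                 "sample_row", "sample_col", "splus_row", "splus_col",
                 "separation_euclid", "intervening_windows",
                 "response_row", "response_col", "correct",
                 "sample_rewarded", "delay_s", "iti_s",
                 "t_start_s", "t_end_s", "seed")

#' Write / read a trial-log CSV
#'
#' One row per trial (corrections included); booleans are stored as 0/1,
#' times in seconds. The round trip preserves every field.
#'
#' @param trials A trial-log data frame ([session_trials()] rows, possibly
#'   from several sessions/subjects).
#' @param path CSV path.
#' @return `write_trial_log()`: `path` invisibly. `read_trial_log()`: the
#'   trial-log data frame with logical columns restored.
#' @export
write_trial_log <- function(trials, path) {
  df <- as_trials_df(trials)
  miss <- setdiff(log_columns, names(df))
  if (length(miss)) stop("trial log lacks column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, log_columns]
  for (cl in c("is_correction", "correct", "sample_rewarded"))
    df[[cl]] <- as.integer(df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(log_columns, names(df))
  if (length(miss))
    stop("malformed trial log ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  for (cl in c("is_correction", "correct", "sample_rewarded"))
    df[[cl]] <- as.logical(df[[cl]])
  df
}

#' Write / read a trial-by-behavior annotation CSV
#'
#' Columns: `subject_id`, `trial_index`, then one 0/1 column per candidate
#' behavior, named exactly as in [behavior_labels()].
#'
#' @param annotations Annotation data frame.
#' @param path CSV path.
#' @return `write_annotations()`: `path` invisibly. `read_annotations()`:
#'   the annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  ann <- as.data.frame(annotations)
  if (is.null(ann$trial_index)) ann$trial_index <- ann$trial
  if (is.null(ann$subject_id)) ann$subject_id <- "s1"
  cols <- c("subject_id", "trial_index", behavior_labels())
  miss <- setdiff(cols, names(ann))
  if (length(miss)) stop("annotation table lacks column(s): ",
                         paste(miss, collapse = ", "))
  ann <- ann[, cols]
  for (bl in behavior_labels()) ann[[bl]] <- as.integer(as.logical(ann[[bl]]))
  utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "trial_index", behavior_labels()),
                  names(ann))
  if (length(miss))
    stop("malformed annotation table ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  ann
}

#' Assemble a run configuration
#'
#' @param experiment `"exp1"` ... `"exp5"`.
#' @param profiles Named list of [agent_params()] (or plain lists of
#'   parameter fields, converted on the fly).
#' @param subjects Character vector of profile names, one per subject
#'   (subject ids become `s1`, `s2`, ...), or a named character vector
#'   mapping subject id to profile name.
#' @param seed Master integer seed; per-subject-session seeds are derived
#'   from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(experiment, profiles, subjects, seed = 1) {
  profiles <- lapply(profiles, function(p)
    if (inherits(p, "agent_params")) p else agent_from_list(p))
  if (is.null(names(subjects)))
    names(subjects) <- paste0("s", seq_along(subjects))
  bad <- setdiff(unique(subjects), names(profiles))
  if (length(bad))
    stop("subjects reference undefined agent profile(s): ",
         paste(bad, collapse = ", "))
  if (!experiment %in% paste0("exp", 1:5))
    stop("unknown experiment: ", experiment)
  structure(list(experiment = experiment, profiles = profiles,
                 subjects = subjects, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Expected fields: `experiment`; `profiles` (named blocks of agent
#' parameters); `subjects` (list/vector of profile names); `seed`.
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- read_config_file(path)
  run_config(cfg$experiment,
             lapply(cfg$profiles, agent_from_list),
             unlist(cfg$subjects), cfg$seed %||% 1)
}

#' Simulate a full experiment for a cohort of agents
#'
#' Builds each subject's session plan with [make_plan()] (counterbalanced
#' plans differ by subject), runs every session through [run_session()],
#' and collects tidy trial logs and behavior annotations. Bit-identical
#' given the same configuration.
#'
#' @param config A [run_config()] (or path to one).
#' @param out_dir Optional directory; when given, writes `trials.csv`,
#'   `annotations.csv` and `manifest.yaml` there.
#' @return A list with `trials` (trial-log data frame over all subjects),
#'   `annotations` (per-trial behavior marks with `subject_id`,
#'   `trial_index` cumulative within subject), `sessions` (list of
#'   `tunl_session` keyed `subject.session`), and `manifest`.
#' @examples
#' cfg <- run_config("exp5", default_agents(), rep("sham", 2), seed = 7)
#' sim <- simulate_experiment(cfg)
#' head(sim$trials)
#' @export
simulate_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  subjects <- config$subjects
  set.seed(config$seed)
  n_sessions <- length(make_plan(config$experiment, config$seed, 1)$sessions)
  seed_tab <- matrix(
    sample.int(.Machine$integer.max - 1L, length(subjects) * n_sessions),
    nrow = length(subjects))

  all_trials <- list(); all_ann <- list(); sessions <- list()
  for (i in seq_along(subjects)) {
    sid <- names(subjects)[i]
    agent <- config$profiles[[subjects[[i]]]]
    plan <- make_plan(config$experiment, config$seed, subject = i)
    offset <- 0L
    for (j in seq_along(plan$sessions)) {
      spec <- plan$sessions[[j]]
      tc <- task_config(delay_s = spec$delay_s, iti_s = spec$iti_s,
                        max_trials = spec$n_trials_cap)
      ses <- run_session(tc, agent, spec, rng_seed = seed_tab[i, j])
      sessions[[paste(sid, j, sep = ".")]] <- ses
      all_trials[[length(all_trials) + 1L]] <- session_trials(ses, j, sid)
      ann <- ses$annotations
      ann$trial_index <- ann$trial + offset   # cumulative within subject
      ann$trial <- NULL
      ann <- cbind(subject_id = sid, ann[, c("trial_index",
                                             behavior_labels())])
      all_ann[[length(all_ann) + 1L]] <- ann
      offset <- offset + nrow(ses$trials)
    }
  }
  trials <- do.call(rbind, all_trials)
  annotations <- do.call(rbind, all_ann)
  rownames(trials) <- rownames(annotations) <- NULL
  manifest <- list(
    package = "tunlsim",
    version = as.character(utils::packageVersion("tunlsim")),
    experiment = config$experiment, seed = config$seed,
    subjects = as.list(subjects),
    session_seeds = lapply(seq_along(subjects), function(i)
      as.integer(seed_tab[i, ]))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_log(trials, file.path(out_dir, "trials.csv"))
    write_annotations(annotations, file.path(out_dir, "annotations.csv"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(trials = trials, annotations = annotations, sessions = sessions,
       manifest = manifest)
}

#' Run a named analysis on trial logs
#'
#' A thin dispatcher over the analysis functions, convenient for scripted
#' use: `"accuracy"` gives per-subject-per-session percent correct,
#' `"blocks"` block means, `"bins"` Euclidean-bin summaries, and
#' `"benefit"` the 18-behavior benefit-score table with t-tests
#' (annotations required).
#'
#' @param trials Trial-log data frame or CSV path.
#' @param mode `"accuracy"`, `"blocks"`, `"bins"` or `"benefit"`.
#' @param annotations Annotation data frame or CSV path (benefit mode).
#' @param block_size Sessions per block (blocks mode).
#' @return The corresponding summary data frame / `benefit_table`.
#' @export
analyze_trials <- function(trials,
                           mode = c("accuracy", "blocks", "bins", "benefit"),
                           annotations = NULL, block_size = 5) {
  mode <- match.arg(mode)
  if (is.character(trials)) trials <- read_trial_log(trials)
  if (mode == "benefit") {
    if (is.null(annotations))
      stop("benefit mode requires an annotation table")
    if (is.character(annotations)) annotations <- read_annotations(annotations)
    # trial_index in annotations is cumulative within subject
    tr <- trials
    ord <- order(tr$subject_id, tr$session_id, tr$trial_index)
    tr <- tr[ord, ]
    tr$trial_index <- stats::ave(rep(1L, nrow(tr)), tr$subject_id,
                                 FUN = cumsum)
    return(test_benefits(benefit_scores(tr, annotations)))
  }
  tr <- trials[!as.logical(trials$is_correction), , drop = FALSE]
  switch(mode,
    accuracy = session_percent(tr),
    blocks = accuracy_by_condition(trials, "block", block_size = block_size),
    bins = accuracy_by_condition(trials, "bin"))
}
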