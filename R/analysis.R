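as_trials_df <- function(trials) {
  if (inherits(trials, "tunl_session")) trials$trials else as.data.frame(trials)
}

#' Percent correct, excluding correction trials
#'
#' The task's dependent variable: correct trials / total completed trials
#' x 100, computed over non-correction trials only. Appending correction
#' trials to a log never changes it.
#'
#' @param trials A `tunl_session` or a trial-log data frame with logical
#'   (or 0/1) columns `correct` and `is_correction`.
#' @return A list with `percent_correct` and `n_trials` (the non-correction
#'   denominator).
#' @examples
#' percent_correct(data.frame(correct = c(TRUE, TRUE, FALSE, TRUE),
#'                            is_correction = c(FALSE, FALSE, FALSE, TRUE)))
#' @export
percent_correct <- function(trials) {
  tr <- as_trials_df(trials)
  keep <- !as.logical(tr$is_correction)
  n <- sum(keep)
  if (n == 0) stop("no non-correction trials: percent correct is undefined")
  list(percent_correct = 100 * mean(as.logical(tr$correct[keep])),
       n_trials = n)
}

session_percent <- function(df) {
  # per (subject, session) percentages; df must carry subject_id, session_id
  agg <- stats::aggregate(
    cbind(correct = as.numeric(df$correct)) ~ subject_id + session_id,
    data = df, FUN = mean)
  n <- stats::aggregate(
    cbind(n_trials = rep(1, nrow(df))) ~ subject_id + session_id,
    data = df, FUN = sum)
  out <- merge(agg, n, by = c("subject_id", "session_id"))
  out$percent_correct <- 100 * out$correct
  out$correct <- NULL
  out[order(out$subject_id, out$session_id), ]
}

#' Accuracy summaries by experimental condition
#'
#' Aggregates a tidy multi-session trial log (as written by
#' [write_trial_log()]) into per-subject accuracy summaries, always
#' excluding correction trials.
#'
#' Groupings:
#' * `"block"` — sessions are blocked in order per subject (`block_size`
#'   sessions per block); block means average the session-level
#'   percentages.
#' * `"bin"` — Euclidean separation bins (minimum/medium/maximum).
#' * `"level"` — intervening-window separation level (same-row trials
#'   only; cross-row trials are dropped with a message).
#' * `"delay_by_separation"` — delay crossed with Euclidean bin.
#'
#' @param trials Trial-log data frame with columns `subject_id`,
#'   `session_id`, `is_correction`, `correct`, `separation_euclid`,
#'   `intervening_windows`, `delay_s`.
#' @param grouping One of `"block"`, `"bin"`, `"level"`,
#'   `"delay_by_separation"`.
#' @param block_size Sessions per block for `grouping = "block"`.
#' @return A data frame of summaries, one row per subject x group, with
#'   `percent_correct` and `n_trials`.
#' @export
accuracy_by_condition <- function(trials,
                                  grouping = c("block", "bin", "level",
                                               "delay_by_separation"),
                                  block_size = 5) {
  grouping <- match.arg(grouping)
  df <- as_trials_df(trials)
  df <- df[!as.logical(df$is_correction), , drop = FALSE]
  if (nrow(df) == 0) stop("no non-correction trials to summarise")
  if (is.null(df$subject_id)) df$subject_id <- "s1"
  if (is.null(df$session_id)) df$session_id <- 1L

  if (grouping == "block") {
    sp <- session_percent(df)
    sp$block <- stats::ave(as.numeric(sp$session_id), sp$subject_id,
                           FUN = function(s) ceiling(rank(s, ties.method = "first") /
                                                       block_size))
    out <- stats::aggregate(percent_correct ~ subject_id + block, data = sp,
                            FUN = mean)
    ntr <- stats::aggregate(n_trials ~ subject_id + block, data = sp, FUN = sum)
    out <- merge(out, ntr, by = c("subject_id", "block"))
    return(out[order(out$subject_id, out$block), ])
  }

  group_var <- switch(grouping,
    bin = bin_separation(df$separation_euclid, "exp3_euclidean"),
    level = {
      drop <- is.na(df$intervening_windows)
      if (any(drop)) {
        message(sum(drop), " cross-row trial(s) dropped from level grouping")
        df <- df[!drop, , drop = FALSE]
      }
      as.integer(df$intervening_windows)
    },
    delay_by_separation = paste0(df$delay_s, "s_",
                                 bin_separation(df$separation_euclid,
                                                "exp3_euclidean")))
  if (grouping == "level") group_var <- group_var
  df$group <- if (grouping == "level") group_var else group_var
  agg <- stats::aggregate(cbind(correct = as.numeric(df$correct)) ~
                            subject_id + group, data = df, FUN = mean)
  n <- stats::aggregate(cbind(n_trials = rep(1, nrow(df))) ~
                          subject_id + group, data = df, FUN = sum)
  out <- merge(agg, n, by = c("subject_id", "group"))
  out$percent_correct <- 100 * out$correct
  out$correct <- NULL
  if (grouping %in% c("bin")) {
    missing_bins <- setdiff(c("minimum", "medium", "maximum"),
                            unique(out$group))
    if (length(missing_bins))
      message("no trials in bin(s): ", paste(missing_bins, collapse = ", "))
  }
  names(out)[names(out) == "group"] <- grouping
  out[order(out$subject_id, out[[grouping]]), ]
}

#' Per-behavior benefit/cost scores from annotated trial logs
#'
#' For each candidate behavior and each subject, trials (corrections
#' excluded) are split by whether the behavior was present. With
#' `a` = correct trials with the behavior, `b` = correct without,
#' `c` = total with, `d` = total without and `e = c + d`, the subject's
#' contribution is `(a - (b/d) c) / e`: the observed correct count on
#' behavior trials minus the count expected from that subject's accuracy
#' without the behavior, as a proportion of all completed trials. The
#' behavior's score is the mean contribution across subjects; positive
#' values indicate a benefit, negative a cost.
#'
#' Conventions for degenerate margins: a subject that never emits the
#' behavior (`c = 0`) contributes 0 and is retained; a subject that emits
#' it on every trial (`d = 0`) is dropped for that behavior (the score is
#' undefined) with a message.
#'
#' @param trials Trial-log data frame with `subject_id`, `trial_index` (or
#'   `trial`), `is_correction`, `correct`; one session per subject.
#' @param annotations Annotation data frame with `subject_id`,
#'   `trial_index` and one 0/1 column per behavior in [behavior_labels()].
#' @param behaviors Behavior columns to score (default all 18).
#' @return An object of class `benefit_table`: a data frame with one row
#'   per behavior (`behavior`, `mean_benefit`, `sem`, `n_rats`), carrying
#'   the per-subject contribution matrix in attribute `"contributions"`
#'   and the per-subject count tables in attribute `"counts"`.
#' @seealso [test_benefits()]
#' @export
benefit_scores <- function(trials, annotations,
                           behaviors = behavior_labels()) {
  tr <- as_trials_df(trials)
  if (is.null(tr$trial_index)) tr$trial_index <- tr$trial
  if (is.null(tr$subject_id)) tr$subject_id <- "s1"
  ann <- as.data.frame(annotations)
  if (is.null(ann$subject_id)) ann$subject_id <- "s1"
  if (is.null(ann$trial_index)) ann$trial_index <- ann$trial
  missing_b <- setdiff(behaviors, names(ann))
  if (length(missing_b))
    stop("annotation table lacks behavior column(s): ",
         paste(missing_b, collapse = ", "))

  tr <- tr[!as.logical(tr$is_correction), , drop = FALSE]
  m <- merge(tr[, c("subject_id", "trial_index", "correct")],
             ann[, c("subject_id", "trial_index", behaviors)],
             by = c("subject_id", "trial_index"))
  if (nrow(m) < nrow(tr))
    stop("annotations missing for ", nrow(tr) - nrow(m),
         " non-correction trial(s)")
  subjects <- sort(unique(m$subject_id))

  contrib <- matrix(NA_real_, nrow = length(subjects),
                    ncol = length(behaviors),
                    dimnames = list(subjects, behaviors))
  counts <- vector("list", length(behaviors))
  names(counts) <- behaviors
  for (bh in behaviors) {
    tab <- lapply(subjects, function(s) {
      rows <- m$subject_id == s
      pres <- as.logical(m[[bh]][rows])
      corr <- as.logical(m$correct[rows])
      c(a = sum(corr & pres), b = sum(corr & !pres),
        c = sum(pres), d = sum(!pres), e = sum(rows))
    })
    tab <- do.call(rbind, tab)
    rownames(tab) <- subjects
    counts[[bh]] <- tab
    x <- rep(NA_real_, length(subjects))
    for (i in seq_along(subjects)) {
      a <- tab[i, "a"]; b <- tab[i, "b"]; cc <- tab[i, "c"]
      d <- tab[i, "d"]; e <- tab[i, "e"]
      if (cc == 0) x[i] <- 0
      else if (d == 0) {
        message("subject ", subjects[i], " emitted '", bh,
                "' on every trial; dropped for that behavior")
        x[i] <- NA_real_
      } else x[i] <- (a - (b / d) * cc) / e
    }
    contrib[, bh] <- x
  }

  stats_tab <- data.frame(
    behavior = behaviors,
    mean_benefit = unname(vapply(behaviors, function(bh)
      mean(contrib[, bh], na.rm = TRUE), 0)),
    sem = unname(vapply(behaviors, function(bh) {
      x <- contrib[, bh][!is.na(contrib[, bh])]
      if (length(x) < 2) 0 else stats::sd(x) / sqrt(length(x))
    }, 0)),
    n_rats = unname(vapply(behaviors, function(bh)
      sum(!is.na(contrib[, bh])), 0L)),
    row.names = NULL
  )
  structure(stats_tab, contributions = contrib, counts = counts,
            class = c("benefit_table", "data.frame"))
}

#' @export
print.benefit_table <- function(x, ...) {
  cat("Mediating-behavior benefit scores (proportion of total trials)\n")
  df <- as.data.frame(x)
  df$mean_benefit <- sprintf("%+.4f", df$mean_benefit)
  df$sem <- sprintf("%.4f", df$sem)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' One-sample t-tests on benefit scores, Bonferroni-corrected
#'
#' Tests each behavior's per-subject contributions against 0 with a
#' one-sample t-test and reports uncorrected and Bonferroni-corrected
#' p-values, `p_bonferroni = min(1, m * p)` with `m` the full family of
#' 18 candidate behaviors regardless of how many are testable. Behaviors
#' with fewer than two contributing subjects, or with zero variance at
#' zero, get `t = 0`, `p = 1` (constant-at-zero) or `NA` (untestable).
#'
#' @param table A `benefit_table` from [benefit_scores()].
#' @param m Family size for the correction (default 18).
#' @return The table with columns `t`, `df`, `p_uncorrected`,
#'   `p_bonferroni` appended.
#' @export
test_benefits <- function(table, m = 18) {
  stopifnot(inherits(table, "benefit_table"))
  contrib <- attr(table, "contributions")
  res <- lapply(table$behavior, function(bh) {
    x <- contrib[, bh][!is.na(contrib[, bh])]
    if (length(x) < 2)
      return(data.frame(t = NA_real_, df = NA_real_,
                        p_uncorrected = NA_real_))
    if (stats::sd(x) == 0) {
      tv <- if (mean(x) == 0) 0 else sign(mean(x)) * Inf
      return(data.frame(t = tv, df = length(x) - 1,
                        p_uncorrected = if (tv == 0) 1 else 0))
    }
    ht <- stats::t.test(x, mu = 0)
    data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
               p_uncorrected = ht$p.value)
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- pmin(1, m * res$p_uncorrected)
  out <- cbind(as.data.frame(table), res)
  structure(out, contributions = contrib, counts = attr(table, "counts"),
            class = c("benefit_table", "data.frame"))
}

#' One-sample t-test of accuracy against chance (50%)
#'
#' @param values Accuracy percentages, one per subject (or session).
#' @return A list with `t`, `df`, `p`, `mean` and `n`. Constant input at
#'   exactly 50 returns `t = 0`, `p = 1`; constant input elsewhere returns
#'   an infinite `t` with `p = 0`.
#' @export
chance_test <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("chance_test needs at least 2 values")
  mu <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    t <- if (mu == 50) 0 else sign(mu - 50) * Inf
    p <- if (t == 0) 1 else 0
  } else {
    t <- (mu - 50) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  list(t = t, df = n - 1, p = p, mean = mu, n = n)
}
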