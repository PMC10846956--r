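#' Screen ADT responses for machine-derivable error labels
#'
#' Adds the two error labels that can be derived mechanically from the
#' response stream: repetitions (a normalized response string recurring
#' within the same participant x form x block) and strategy errors (three
#' or more successive DA responses sharing the same initial letter, a
#' signature of deliberate cueing). Responses are normalized by
#' case-folding and whitespace trimming only; diacritics are preserved.
#' Rater-supplied labels already present in `error_label` take precedence
#' and are never overwritten. Rule-violation errors are semantic judgements
#' and must come from raters.
#'
#' @param records Trial records in the canonical schema (see
#'   [simulate_trials()]); must contain the ordering columns
#'   `participant_id`, `form`, `block`, `position`.
#' @param schedule Optional schedule to validate conditions against; a
#'   mismatch between a record's condition and the schedule is an error.
#' @return `records` with `error_label` updated.
#' @examples
#' rec <- tibble::tibble(participant_id = "P1", form = "A", block = 1,
#'   position = 1:3, stimulus_id = c("s1", "s2", "s3"), condition = "DA",
#'   rt_sec = c(4, 5, 6), response = c("rope", "rain", "rice"),
#'   error_label = "none")
#' auto_screen(rec)$error_label  # all flagged "strategy"
#' @export
auto_screen <- function(records, schedule = NULL) {
  assert_cols(records, c("participant_id", "form", "block", "position",
                         "condition", "response", "error_label"),
              "trial records")
  if (!is.null(schedule)) {
    key <- c("form", "block", "stimulus_id")
    chk <- dplyr::inner_join(
      records[, c(key, "condition")],
      schedule[, c(key, "condition")],
      by = key, suffix = c("", ".sched"))
    bad <- chk$condition != chk$condition.sched
    if (any(bad)) {
      stop(sprintf("%d record(s) disagree with the schedule's condition",
                   sum(bad)), call. = FALSE)
    }
  }
  ord <- order(records$participant_id, records$form, records$block,
               records$position)
  rec <- records[ord, ]
  norm <- trimws(tolower(rec$response))

  # repetitions: scope is participant x form x block (rows are ordered,
  # so duplicated() flags every recurrence after the first)
  blk <- paste(rec$participant_id, rec$form, rec$block, sep = "\r")
  is_rep <- duplicated(paste(blk, norm, sep = "\r"))

  # strategy: runs of >= 3 successive DA responses with the same initial
  # letter, scanned over the DA trials of each participant x form
  is_strat <- rep(FALSE, nrow(rec))
  da_idx <- which(rec$condition == "DA")
  if (length(da_idx) > 0) {
    grp <- paste(rec$participant_id[da_idx], rec$form[da_idx], sep = "\r")
    for (idx in split(da_idx, grp)) {
      ini <- substr(norm[idx], 1, 1)
      r <- rle(ini)
      ends <- cumsum(r$lengths)
      for (j in which(r$lengths >= 3)) {
        run <- idx[(ends[j] - r$lengths[j] + 1):ends[j]]
        is_strat[run] <- TRUE
      }
    }
  }

  keep_rater <- rec$error_label != "none"
  lab <- rec$error_label
  lab[!keep_rater & is_rep] <- "repetition"
  lab[!keep_rater & !is_rep & is_strat] <- "strategy"
  rec$error_label <- lab
  rec[order(ord), ]  # restore input row order
}

#' Filter ADT trials before scoring
#'
#' Removes trials in a fixed order: repetitions first, then errors (rule
#' violations and strategy errors), and finally extreme latencies
#' exceeding mean + `sd_cut` x SD, where mean and SD are computed per
#' participant x form x condition on the trials surviving the error
#' removals. The latency screen is one-sided (upper tail only). Removal
#' proportions are reported relative to the input trial count.
#'
#' @param records Labelled trial records (after [auto_screen()] or with
#'   rater labels).
#' @param sd_cut Latency cutoff in standard deviations (default 3).
#' @return A list with `records` (the retained trials) and `summary`, a
#'   one-row tibble of removal proportions (`repetitions`, `errors`,
#'   `extreme`, `retained`).
#' @export
filter_trials <- function(records, sd_cut = 3) {
  assert_cols(records, c("participant_id", "form", "condition", "rt_sec",
                         "error_label"), "trial records")
  n0 <- nrow(records)
  empty_summary <- tibble::tibble(repetitions = 0, errors = 0, extreme = 0,
                                  retained = 0)
  if (n0 == 0) {
    warning("no trials to filter", call. = FALSE)
    return(list(records = records, summary = empty_summary))
  }
  is_rep <- records$error_label == "repetition"
  is_err <- records$error_label %in% c("rule", "strategy")
  kept <- records[!is_rep & !is_err, ]

  grp <- paste(kept$participant_id, kept$form, kept$condition, sep = "\r")
  mu <- stats::ave(kept$rt_sec, grp, FUN = mean)
  sg <- stats::ave(kept$rt_sec, grp, FUN = function(x) {
    if (length(x) < 2) Inf else sd(x)
  })
  extreme <- kept$rt_sec > mu + sd_cut * sg
  retained <- kept[!extreme, ]

  list(records = retained,
       summary = tibble::tibble(
         repetitions = sum(is_rep) / n0,
         errors = sum(is_err) / n0,
         extreme = sum(extreme) / n0,
         retained = nrow(retained) / n0))
}

#' Two-sided winsorization by order statistics
#'
#' Replaces the lowest `k = floor(trim * n)` values with the (k+1)-th
#' order statistic and the highest `k` values with the (n-k)-th order
#' statistic. Positions are preserved: only the values change.
#'
#' @param x Non-empty numeric vector (no missing values).
#' @param trim Per-tail trimming proportion in \[0, 0.5).
#' @return A vector of the same length as `x`.
#' @examples
#' winsorize(1:10, trim = 0.10)  # c(2, 2, 3:8, 9, 9)
#' @export
winsorize <- function(x, trim = 0.10) {
  if (length(x) == 0) stop("x must be non-empty", call. = FALSE)
  if (anyNA(x)) stop("x must not contain missing values", call. = FALSE)
  if (trim < 0 || trim >= 0.5) {
    stop("trim must lie in [0, 0.5)", call. = FALSE)
  }
  n <- length(x)
  k <- floor(trim * n)
  if (k == 0) return(x)
  s <- sort(x)
  pmin(pmax(x, s[k + 1]), s[n - k])
}

#' Aggregate filtered trials into participant-level ADT scores
#'
#' For each participant x form x condition, latencies are winsorized
#' ([winsorize()]) and averaged; the inhibition cost is the exact
#' difference `ic = da_mean - fa_mean`. Error rates are computed on the
#' pre-filter records: `error_rate` pools all of a participant's trials
#' across forms (the exclusion denominator), `form_error_rate` is per
#' form. Participants whose overall error rate exceeds
#' `exclude_threshold` are flagged `excluded`. A condition with no
#' surviving trials yields a missing (NA) score, never zero.
#'
#' @param filtered Retained records from [filter_trials()].
#' @param screened The full pre-filter records (with error labels), used
#'   for the error-rate denominator. Defaults to `filtered` (in which case
#'   error rates are zero, since filtering removed all flagged trials).
#' @param trim Winsorizing proportion per tail (default 0.10).
#' @param exclude_threshold Error-rate above which a participant is
#'   excluded (default 0.30).
#' @return A tibble with one row per participant x form: `fa_mean`,
#'   `da_mean`, `ic`, trial counts, `form_error_rate`, `error_rate`,
#'   `excluded`.
#' @export
aggregate_trials <- function(filtered, screened = filtered, trim = 0.10,
                             exclude_threshold = 0.30) {
  assert_cols(filtered, c("participant_id", "form", "condition", "rt_sec"),
              "filtered records")
  assert_cols(screened, c("participant_id", "form", "error_label"),
              "screened records")

  wmean <- function(x) mean(winsorize(x, trim))
  scores <- filtered |>
    dplyr::group_by(.data$participant_id, .data$form, .data$condition) |>
    dplyr::summarise(score = wmean(.data$rt_sec), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("score", "n"),
                       names_glue = "{.value}_{tolower(condition)}")
  for (col in c("score_fa", "score_da", "n_fa", "n_da")) {
    if (!col %in% names(scores)) scores[[col]] <- NA_real_
  }
  scores$n_fa[is.na(scores$n_fa)] <- 0
  scores$n_da[is.na(scores$n_da)] <- 0

  err_form <- screened |>
    dplyr::group_by(.data$participant_id, .data$form) |>
    dplyr::summarise(
      form_error_rate = mean(.data$error_label != "none"),
      n_trials = dplyr::n(), .groups = "drop")
  err_all <- screened |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(error_rate = mean(.data$error_label != "none"),
                     .groups = "drop")

  out <- scores |>
    dplyr::rename(fa_mean = "score_fa", da_mean = "score_da") |>
    dplyr::mutate(ic = .data$da_mean - .data$fa_mean) |>
    dplyr::left_join(err_form, by = c("participant_id", "form")) |>
    dplyr::left_join(err_all, by = "participant_id") |>
    dplyr::mutate(excluded = .data$error_rate > exclude_threshold)
  out[, c("participant_id", "form", "fa_mean", "da_mean", "ic",
          "n_fa", "n_da", "form_error_rate", "error_rate", "excluded")]
}
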