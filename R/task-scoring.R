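#' Score a processing-speed task
#'
#' Inverse-efficiency score in seconds: the winsorized mean latency of the
#' correct trials divided by the overall accuracy (proportion correct over
#' all trials). For the letter-matching variant, pass `match_required` to
#' restrict the latency pool to correct trials that contained a match; the
#' accuracy denominator still covers all trials.
#'
#' @param rt_sec Trial latencies in seconds.
#' @param correct Logical vector, same length as `rt_sec`.
#' @param match_required Optional logical vector; when given, only trials
#'   with `match_required & correct` contribute latencies.
#' @param trim Winsorizing proportion per tail (default 0.10).
#' @return Score in seconds (larger = slower / less efficient).
#' @export
score_speed <- function(rt_sec, correct, match_required = NULL,
                        trim = 0.10) {
  stopifnot(length(rt_sec) == length(correct))
  if (!is.null(match_required)) {
    stopifnot(length(match_required) == length(rt_sec))
  }
  accuracy <- mean(correct)
  if (accuracy == 0) {
    stop("accuracy is zero: the speed score is undefined", call. = FALSE)
  }
  use <- correct
  if (!is.null(match_required)) use <- use & match_required
  if (!any(use)) {
    stop("no scoreable trials (need at least one correct trial",
         if (!is.null(match_required)) " containing a match" else "", ")",
         call. = FALSE)
  }
  mean(winsorize(rt_sec[use], trim)) / accuracy
}

#' Score a working-memory span task
#'
#' The adaptive span staircase ends after five incorrect recalls; capacity
#' is the mean span of those five incorrect trials minus 1.
#'
#' @param incorrect_spans Integer vector of exactly 5 span lengths, each
#'   in 2..9.
#' @return Capacity in items (range 1 to 8).
#' @examples
#' score_span(c(4, 5, 5, 6, 5))  # 4
#' @export
score_span <- function(incorrect_spans) {
  if (length(incorrect_spans) != 5) {
    stop("exactly 5 incorrect spans are required (the task ends after ",
         "five errors)", call. = FALSE)
  }
  if (any(incorrect_spans < 2 | incorrect_spans > 9)) {
    stop("span lengths must lie in 2..9", call. = FALSE)
  }
  mean(incorrect_spans) - 1
}

#' Score a semantic verbal-fluency sequence
#'
#' Counts valid category exemplars. A sequence in which more than 30% of
#' responses are errors (out-of-category or repetition) is omitted from
#' analysis: the score is returned as `NA` with attribute
#' `omitted = TRUE`.
#'
#' @param error_labels Character vector with one label per response, each
#'   one of `"valid"`, `"out_of_category"`, `"repetition"`.
#' @param omit_threshold Error proportion above which the sequence is
#'   omitted (default 0.30).
#' @return Integer count of valid responses (or `NA` if omitted), with
#'   attribute `omitted`.
#' @export
score_fluency <- function(error_labels, omit_threshold = 0.30) {
  ok <- c("valid", "out_of_category", "repetition")
  if (!all(error_labels %in% ok)) {
    stop("error_labels must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  if (length(error_labels) == 0) {
    return(structure(0L, omitted = FALSE))
  }
  err_rate <- mean(error_labels != "valid")
  if (err_rate > omit_threshold) {
    return(structure(NA_integer_, omitted = TRUE))
  }
  structure(sum(error_labels == "valid"), omitted = FALSE)
}

#' Score an associative-combination task
#'
#' Responses slower than the time limit count as errors regardless of
#' content. Invalid responses and latencies beyond mean + `sd_cut` x SD of
#' the valid trials are removed, and the winsorized mean of the remainder
#' is the score.
#'
#' @param rt_sec Trial latencies in seconds.
#' @param valid Logical vector of rater validity judgements.
#' @param trim Winsorizing proportion per tail (default 0.10).
#' @param limit Response time limit in seconds (default 15).
#' @param sd_cut Latency cutoff in standard deviations (default 3).
#' @return Score in seconds, or `NA` when no valid trials survive.
#' @export
score_combination <- function(rt_sec, valid, trim = 0.10, limit = 15,
                              sd_cut = 3) {
  stopifnot(length(rt_sec) == length(valid))
  valid <- valid & rt_sec <= limit
  rts <- rt_sec[valid]
  if (length(rts) == 0) return(NA_real_)
  if (length(rts) >= 2) {
    rts <- rts[rts <= mean(rts) + sd_cut * sd(rts)]
  }
  if (length(rts) == 0) return(NA_real_)
  mean(winsorize(rts, trim))
}
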