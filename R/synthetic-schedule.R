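#' Generate a counterbalanced ADT trial schedule
#'
#' Builds the trial schedule for one or more parallel task forms. Each form
#' presents the same set of stimuli in two consecutive blocks; within a
#' block exactly half of the stimuli are cued free-associatively (FA) and
#' half dissociatively (DA), and every stimulus switches condition between
#' the blocks. Which condition a stimulus meets first (FA then DA, or DA
#' then FA) is counterbalanced over stimuli, half each. Stimulus order is
#' randomized independently per block under the seed.
#'
#' @param n_forms Number of parallel forms (labelled A, B, C, ...).
#' @param n_stimuli Stimuli per form; must be even so that each block can
#'   hold an equal number of FA and DA trials.
#' @param seed Integer seed; the schedule is a deterministic function of it.
#'
#' @return A tibble with columns `form`, `block` (1 or 2), `position`
#'   (1-based within block), `stimulus_id`, `condition` ("FA"/"DA") and
#'   `first_condition` (the condition the stimulus meets in block 1).
#' @examples
#' sched <- generate_schedule(n_forms = 3, n_stimuli = 40, seed = 1)
#' table(sched$form, sched$condition)
#' @export
generate_schedule <- function(n_forms = 3, n_stimuli = 40, seed = 1) {
  if (n_forms < 1) stop("n_forms must be >= 1", call. = FALSE)
  if (n_stimuli < 2 || n_stimuli %% 2 != 0) {
    stop("n_stimuli must be an even count >= 2: each block needs equal FA ",
         "and DA trial numbers and every stimulus must swap condition ",
         "across the two blocks (counterbalance constraint)", call. = FALSE)
  }
  forms <- LETTERS[seq_len(n_forms)]
  out <- vector("list", n_forms)
  for (fi in seq_along(forms)) {
    set.seed(seed_stream(seed, fi))
    stim <- sprintf("%s_s%03d", forms[fi], seq_len(n_stimuli))
    # exactly half the stimuli see FA first
    fa_first <- sample(stim, n_stimuli / 2)
    first_cond <- ifelse(stim %in% fa_first, "FA", "DA")
    names(first_cond) <- stim
    blocks <- lapply(1:2, function(b) {
      order_b <- sample(stim)
      cond <- ifelse(first_cond[order_b] == "FA",
                     c("FA", "DA")[b], c("DA", "FA")[b])
      tibble::tibble(form = forms[fi], block = b,
                     position = seq_len(n_stimuli),
                     stimulus_id = order_b,
                     condition = unname(cond),
                     first_condition = unname(first_cond[order_b]))
    })
    out[[fi]] <- dplyr::bind_rows(blocks)
  }
  dplyr::bind_rows(out)
}
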