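#' Simulate trial-level ADT latencies and error labels
#'
#' Generates lognormal response latencies for every participant x schedule
#' trial under the additive log-scale model described in [adt_params()],
#' together with rater-style error labels drawn at the configured
#' per-category rates. Error categories are mutually exclusive per trial
#' and drawn in priority order rule > repetition > strategy (strategy
#' errors occur only on DA trials). All latent draws are returned in a
#' ground-truth table so recovery can be tested.
#'
#' @param schedule A schedule from [generate_schedule()].
#' @param params An [adt_params()] object.
#' @param n_participants Number of simulated participants (>= 2); every
#'   participant completes every form in the schedule.
#' @param seed Integer seed.
#'
#' @return A list with
#'   \describe{
#'     \item{trials}{tibble in the canonical trial schema: `participant_id`,
#'       `form`, `block`, `position`, `stimulus_id`, `condition`, `rt_sec`,
#'       `response`, `error_label`.}
#'     \item{participants}{tibble of latent person effects `a_p` (speed)
#'       and `d_p` (inhibition), in log-seconds.}
#'     \item{stimuli}{tibble of latent stimulus effects `b_s` and
#'       typicality z-scores `typicality`.}
#'     \item{params}{the generating parameters.}
#'   }
#' @examples
#' sched <- generate_schedule(1, 6, seed = 1)
#' sim <- simulate_trials(sched, adt_params(), n_participants = 4, seed = 1)
#' nrow(sim$trials)  # 4 participants x 12 trials
#' @export
simulate_trials <- function(schedule, params = adt_params(),
                            n_participants, seed = 1) {
  stopifnot(inherits(params, "adt_params"))
  assert_cols(schedule, c("form", "block", "position", "stimulus_id",
                          "condition"), "schedule")
  if (n_participants < 2) {
    stop("n_participants must be >= 2", call. = FALSE)
  }

  stim_ids <- sort(unique(schedule$stimulus_id))
  set.seed(seed_stream(seed, 101))
  stimuli <- tibble::tibble(
    stimulus_id = stim_ids,
    b_s = rnorm(length(stim_ids), 0, params$sigma_stim),
    typicality = rnorm(length(stim_ids)))

  set.seed(seed_stream(seed, 102))
  participants <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n_participants)),
    a_p = rnorm(n_participants, 0, params$sigma_person),
    d_p = rnorm(n_participants, 0, params$sigma_inhib))

  trials <- tidyr::crossing(participant_id = participants$participant_id,
                            schedule)
  trials <- dplyr::left_join(trials, participants, by = "participant_id")
  trials <- dplyr::left_join(trials, stimuli, by = "stimulus_id")

  n <- nrow(trials)
  is_da <- trials$condition == "DA"
  set.seed(seed_stream(seed, 103))
  eps <- rnorm(n, 0, params$sigma_noise)
  log_rt <- params$mu_FA + trials$a_p + trials$b_s +
    ifelse(is_da,
           params$gamma_DA + trials$d_p + params$beta_typ_IC * trials$typicality,
           params$beta_typ_FA * trials$typicality) +
    eps

  set.seed(seed_stream(seed, 104))
  er <- params$error_rates
  u_rule <- runif(n)
  u_rep <- runif(n)
  u_str <- runif(n)
  rule_rate <- ifelse(is_da, er[["rule_DA"]], er[["rule_FA"]])
  label <- rep("none", n)
  label[is_da & u_str < er[["strategy_DA"]]] <- "strategy"
  label[u_rep < er[["repetition"]]] <- "repetition"
  label[u_rule < rule_rate] <- "rule"

  trials$rt_sec <- exp(log_rt)
  # cycle initial letters so the tokens never mimic an initial-letter
  # cueing strategy run
  trials$response <- sprintf("%s_resp%06d",
                             letters[(seq_len(n) - 1) %% 26 + 1],
                             seq_len(n))
  trials$error_label <- label
  trials <- trials[, c("participant_id", "form", "block", "position",
                       "stimulus_id", "condition", "rt_sec", "response",
                       "error_label")]

  list(trials = tibble::as_tibble(trials),
       participants = participants,
       stimuli = stimuli,
       params = params)
}
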