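# Canonical on-disk schemas. All tabular files are UTF-8 with headers,
# latencies in decimal seconds, condition labels literal "FA"/"DA".

trial_cols <- c("participant_id", "form", "block", "position",
                "stimulus_id", "condition", "rt_sec", "response",
                "error_label")
norms_cols <- c("respondent_id", "stimulus_id", "slot", "response")

#' Read / write trial records (canonical CSV schema)
#'
#' The trial CSV has columns `participant_id`, `form`, `block`,
#' `position`, `stimulus_id`, `condition` ("FA"/"DA"), `rt_sec` (decimal
#' seconds), `response`, `error_label`. Reading validates types and keys:
#' malformed latencies are reported with their row numbers, and
#' duplicated (participant, form, block, position) keys are rejected.
#'
#' @param path File path.
#' @return `read_trials()` returns a validated tibble.
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  assert_cols(df, trial_cols, basename(path))
  rt <- suppressWarnings(as.numeric(df$rt_sec))
  bad <- which(is.na(rt) | rt <= 0)
  if (length(bad) > 0) {
    stop(sprintf("%s: malformed rt_sec in row(s) %s", basename(path),
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  df$rt_sec <- rt
  df$block <- as.integer(df$block)
  df$position <- as.integer(df$position)
  if (!all(df$condition %in% c("FA", "DA"))) {
    stop(basename(path), ": condition must be 'FA' or 'DA'", call. = FALSE)
  }
  key <- paste(df$participant_id, df$form, df$block, df$position)
  if (anyDuplicated(key)) {
    stop(basename(path), ": duplicated (participant, form, block, ",
         "position) key(s)", call. = FALSE)
  }
  tibble::as_tibble(df)[, trial_cols]
}

#' @rdname read_trials
#' @param records Trial records to write.
#' @export
write_trials <- function(records, path) {
  assert_cols(records, trial_cols, "trial records")
  write.csv(records[, trial_cols], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write association norms (canonical TSV schema)
#'
#' The norms TSV has columns `respondent_id`, `stimulus_id`, `slot`
#' (1-4) and `response`; each respondent contributes an ordered 4-tuple
#' of responses per stimulus.
#'
#' @param path File path.
#' @return `read_norms()` returns a validated tibble.
#' @export
read_norms <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  assert_cols(df, norms_cols, basename(path))
  df$slot <- as.integer(df$slot)
  if (any(is.na(df$slot) | df$slot < 1 | df$slot > 4)) {
    stop(basename(path), ": slot must be an integer in 1..4",
         call. = FALSE)
  }
  tibble::as_tibble(df)[, norms_cols]
}

#' @rdname read_norms
#' @param norms Norms to write.
#' @export
write_norms <- function(norms, path) {
  assert_cols(norms, norms_cols, "norms")
  write.table(norms[, norms_cols], path, sep = "\t", row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write psycholinguistic rating tables
#'
#' CSV with a `stimulus_id` column and one numeric column per rating
#' scale.
#'
#' @param path File path.
#' @return `read_ratings()` returns a tibble.
#' @export
read_ratings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  assert_cols(df, "stimulus_id", basename(path))
  for (cn in setdiff(names(df), "stimulus_id")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad) > 0) {
      stop(sprintf("%s: malformed value in column %s, row(s) %s",
                   basename(path), cn, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    df[[cn]] <- v
  }
  tibble::as_tibble(df)
}

#' @rdname read_ratings
#' @param ratings Ratings to write.
#' @export
write_ratings <- function(ratings, path) {
  assert_cols(ratings, "stimulus_id", "ratings")
  write.csv(ratings, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end pipeline with its
#' default: winsorizing proportion 0.10 per tail, 3 SD latency cutoff,
#' 0.30 exclusion error-rate, 200 trial-sampling repetitions, 500
#' parallel-analysis simulations at the 95th percentile. Configurations
#' round-trip losslessly through YAML ([write_config()] /
#' [read_config()]).
#'
#' @param seed Master integer seed for every random step.
#' @param n_participants,n_forms,n_stimuli,n_respondents Synthetic study
#'   dimensions.
#' @param trim,sd_cut,exclude_threshold Preprocessing parameters.
#' @param reps,max_n Trial-sampling repetitions and largest set size
#'   (`NULL` = all trials).
#' @param n_sim,quantile Parallel-analysis settings.
#' @param distance,logdice_marginals,clustering Documented alternatives
#'   for the network stage.
#' @param per_form_exclusion Also flag exclusion per form.
#' @param out_dir Output directory for [run_pipeline()].
#' @param overwrite Allow writing into a non-empty `out_dir`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_participants = 100, n_forms = 3,
                            n_stimuli = 40, n_respondents = 90,
                            trim = 0.10, sd_cut = 3.0,
                            exclude_threshold = 0.30, reps = 200,
                            max_n = NULL, n_sim = 500, quantile = 0.95,
                            distance = "inverse",
                            logdice_marginals = "per_stimulus",
                            clustering = "onnela",
                            per_form_exclusion = FALSE,
                            out_dir = "adt_pipeline_output",
                            overwrite = FALSE) {
  stopifnot(trim >= 0, trim < 0.5, sd_cut > 0,
            exclude_threshold > 0, exclude_threshold <= 1,
            reps >= 1, n_sim >= 1, quantile > 0, quantile < 1)
  structure(list(seed = seed, n_participants = n_participants,
                 n_forms = n_forms, n_stimuli = n_stimuli,
                 n_respondents = n_respondents, trim = trim,
                 sd_cut = sd_cut, exclude_threshold = exclude_threshold,
                 reps = reps, max_n = max_n, n_sim = n_sim,
                 quantile = quantile, distance = distance,
                 logdice_marginals = logdice_marginals,
                 clustering = clustering,
                 per_form_exclusion = per_form_exclusion,
                 out_dir = out_dir, overwrite = overwrite),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}
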