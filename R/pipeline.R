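#' Build participant x item (stimulus) latency matrices per form
#'
#' One row per participant, one column per stimulus; cells hold the
#' filtered trial latency of that participant x stimulus in the given
#' condition (`NA` when the trial was removed). For `measure = "IC"` the
#' cell is the per-stimulus DA - FA difference.
#'
#' @param records Filtered trial records.
#' @param form Form identifier.
#' @param measure `"FA"`, `"DA"` or `"IC"`.
#' @param participants Optional participant ids fixing the row order.
#' @return A numeric matrix with participant row names.
#' @export
item_matrix <- function(records, form, measure = c("FA", "DA", "IC"),
                        participants = NULL) {
  measure <- match.arg(measure)
  d <- records[records$form == form, , drop = FALSE]
  if (is.null(participants)) participants <- sort(unique(records$participant_id))
  stims <- sort(unique(d$stimulus_id))
  one <- function(cond) {
    dd <- d[d$condition == cond, c("participant_id", "stimulus_id",
                                   "rt_sec")]
    m <- matrix(NA_real_, length(participants), length(stims),
                dimnames = list(participants, stims))
    m[cbind(match(dd$participant_id, participants),
            match(dd$stimulus_id, stims))] <- dd$rt_sec
    m
  }
  switch(measure,
         FA = one("FA"),
         DA = one("DA"),
         IC = one("DA") - one("FA"))
}

#' Run the full ADT analysis pipeline
#'
#' Drives every stage end to end: simulate (or accept) trial records,
#' norms, ratings and auxiliary scores; screen, filter and aggregate the
#' trials; compute reliability (omega, retest, trial-sampling curves);
#' clean the norms and profile every stimulus's hierarchy and network;
#' build composites and the validity statistics; and write all artifacts
#' to `config$out_dir`. Outputs are a deterministic function of the
#' configuration (including its seed): the same configuration produces
#' byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @param trials,norms,ratings,aux Optional pre-loaded inputs (tibbles in
#'   the canonical schemas); anything left `NULL` is simulated under the
#'   configured seed.
#' @return Invisibly, a list with every intermediate result (`scores`,
#'   `reliability`, `profiles`, `validity`, ...) and the written file
#'   paths.
#' @export
run_pipeline <- function(config = pipeline_config(), trials = NULL,
                         norms = NULL, ratings = NULL, aux = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 &&
      !isTRUE(config$overwrite)) {
    stop("output directory '", out_dir, "' is not empty; set ",
         "overwrite = TRUE to replace its contents", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  ## -- simulate / load ----------------------------------------------------
  schedule <- generate_schedule(config$n_forms, config$n_stimuli,
                                seed = seed_stream(seed, 1))
  truth <- NULL
  if (is.null(trials)) {
    sim <- simulate_trials(schedule, adt_params(), config$n_participants,
                           seed = seed_stream(seed, 2))
    trials <- sim$trials
    truth <- sim[c("participants", "stimuli")]
  }
  stim_ids <- sort(unique(schedule$stimulus_id))
  if (is.null(norms)) {
    norms <- simulate_norms(stim_ids, config$n_respondents,
                            seed = seed_stream(seed, 3))
  }
  if (is.null(ratings)) {
    ratings <- simulate_ratings(stim_ids, seed = seed_stream(seed, 4))
  }
  if (is.null(aux)) {
    aux <- simulate_auxiliary_scores(length(unique(trials$participant_id)),
                                     seed = seed_stream(seed, 5))
  }

  ## -- preprocess ---------------------------------------------------------
  screened <- auto_screen(trials, schedule)
  filt <- filter_trials(screened, sd_cut = config$sd_cut)
  scores <- aggregate_trials(filt$records, screened, trim = config$trim,
                             exclude_threshold = config$exclude_threshold)
  note("screened %d trials; removed %.2f%% repetitions, %.2f%% errors, %.2f%% extreme",
       nrow(screened), 100 * filt$summary$repetitions,
       100 * filt$summary$errors, 100 * filt$summary$extreme)
  excluded_ids <- unique(scores$participant_id[scores$excluded])
  note("excluded %d participant(s) above the %.0f%% error-rate threshold",
       length(excluded_ids), 100 * config$exclude_threshold)
  kept_records <- filt$records[!filt$records$participant_id %in%
                                 excluded_ids, ]
  kept_scores <- scores[!scores$excluded, ]
  participants <- sort(unique(kept_records$participant_id))
  forms <- sort(unique(schedule$form))

  ## -- reliability --------------------------------------------------------
  measures <- c("FA", "DA", "IC")
  matrices <- lapply(setNames(measures, measures), function(m) {
    lapply(setNames(forms, forms), function(f) {
      item_matrix(kept_records, f, m, participants = participants)
    })
  })
  rel_rows <- list()
  for (m in measures) {
    for (f in forms) {
      om <- tryCatch(
        as.numeric(suppressWarnings(mcdonald_omega(matrices[[m]][[f]]))),
        error = function(e) NA_real_)
      rel_rows[[length(rel_rows) + 1]] <- tibble::tibble(
        measure = m, unit = f, statistic = "omega", estimate = om)
    }
    col <- c(FA = "fa_mean", DA = "da_mean", IC = "ic")[[m]]
    wide <- tidyr::pivot_wider(kept_scores[, c("participant_id", "form",
                                               col)],
                               names_from = "form", values_from = dplyr::all_of(col))
    for (pr in combn(forms, 2, simplify = FALSE)) {
      r <- tryCatch(test_retest(wide[[pr[1]]], wide[[pr[2]]]),
                    error = function(e) NA_real_)
      rel_rows[[length(rel_rows) + 1]] <- tibble::tibble(
        measure = m, unit = paste(pr, collapse = "-"),
        statistic = "retest", estimate = r)
    }
  }
  rel_summary <- dplyr::bind_rows(rel_rows)

  curves <- list()
  for (m in measures) {
    for (est in c("omega", "retest")) {
      cv <- sampling_curve(matrices[[m]], estimator = est,
                           max_n = config$max_n, reps = config$reps,
                           seed = seed_stream(seed, 10 + match(m, measures) *
                                                10 + (est == "retest")))
      cv$means$measure <- m
      cv$estimates$measure <- m
      curves[[paste(m, est, sep = "_")]] <- cv
    }
  }
  curve_means <- dplyr::bind_rows(lapply(curves, function(cv) cv$means))
  curve_estimates <- dplyr::bind_rows(lapply(curves,
                                             function(cv) cv$estimates))

  ## -- norms & networks ---------------------------------------------------
  cleaned <- clean_norms(norms)
  profiles <- stimulus_profiles(cleaned, seed = seed_stream(seed, 6),
                                distance = config$distance,
                                clustering = config$clustering)

  ## -- composites ---------------------------------------------------------
  rating_cols <- setdiff(names(ratings), "stimulus_id")
  pa_ratings <- parallel_analysis(ratings[rating_cols],
                                  n_sim = config$n_sim,
                                  quantile = config$quantile,
                                  seed = seed_stream(seed, 7))
  rating_pca <- pca_composites(ratings[rating_cols],
                               max(1, pa_ratings$n_retained))
  assoc_cols <- c("prop_dominant", "slope_beta", "intercept",
                  "modularity", "aspl", "clustering", "efficiency")
  assoc_data <- profiles[assoc_cols]
  ok_assoc <- complete.cases(assoc_data)
  pa_assoc <- parallel_analysis(assoc_data[ok_assoc, ],
                                n_sim = config$n_sim,
                                quantile = config$quantile,
                                seed = seed_stream(seed, 8))
  assoc_pca <- pca_composites(assoc_data[ok_assoc, ],
                              max(1, pa_assoc$n_retained))

  stim_props <- tibble::tibble(stimulus_id = profiles$stimulus_id[ok_assoc])
  for (j in seq_len(ncol(assoc_pca$scores))) {
    stim_props[[paste0("assoc_", colnames(assoc_pca$scores)[j])]] <-
      assoc_pca$scores[[j]]
  }
  if (!is.null(truth)) {
    stim_props <- dplyr::left_join(stim_props,
                                   truth$stimuli[, c("stimulus_id",
                                                     "typicality")],
                                   by = "stimulus_id")
  }
  rating_scores <- tibble::tibble(stimulus_id = ratings$stimulus_id)
  for (j in seq_len(ncol(rating_pca$scores))) {
    rating_scores[[paste0("rating_", colnames(rating_pca$scores)[j])]] <-
      rating_pca$scores[[j]]
  }
  stim_props <- dplyr::left_join(stim_props, rating_scores,
                                 by = "stimulus_id")
  stim_level <- stimulus_level_table(kept_records, stim_props)

  ## -- participant-level validity ----------------------------------------
  comp_scores <- tibble::tibble(participant_id = participants)
  for (m in measures) {
    col <- c(FA = "fa_mean", DA = "da_mean", IC = "ic")[[m]]
    wide <- tidyr::pivot_wider(kept_scores[, c("participant_id", "form",
                                               col)],
                               names_from = "form", values_from = dplyr::all_of(col))
    wide <- wide[match(participants, wide$participant_id), ]
    pca <- pca_composites(wide[forms], 1)
    comp_scores[[m]] <- pca$scores[[1]]
  }
  aux_use <- aux[match(participants, aux$participant_id), ]
  for (cn in c("speed", "working_memory", "fluency", "combination")) {
    cols <- grep(paste0("^", cn, "_"), names(aux_use), value = TRUE)
    if (length(cols) >= 2) {
      pca <- pca_composites(aux_use[cols], 1)
      comp_scores[[cn]] <- pca$scores[[1]]
    }
  }
  cors <- correlation_table(comp_scores[setdiff(names(comp_scores),
                                                "participant_id")])

  contrast_rows <- lapply(forms, function(f) {
    s <- kept_scores[kept_scores$form == f, ]
    dplyr::bind_cols(tibble::tibble(form = f),
                     paired_contrast(s$fa_mean, s$da_mean))
  })
  contrasts <- dplyr::bind_rows(contrast_rows)
  contrasts$p_holm <- holm_adjust(contrasts$p)

  comparison <- compare_correlations(
    r1 = cors$r["FA", "fluency"], r2 = cors$r["DA", "fluency"],
    n = length(participants), method = "dependent_overlapping",
    r12 = cors$r["FA", "DA"])

  ## -- artifacts ----------------------------------------------------------
  paths <- list()
  wr <- function(obj, file, writer = write.csv) {
    p <- file.path(out_dir, file)
    if (identical(writer, write.csv)) {
      write.csv(obj, p, row.names = FALSE, fileEncoding = "UTF-8")
    } else {
      writer(obj, p)
    }
    paths[[file]] <<- p
    p
  }
  wr(config, "config.yaml", writer = write_config)
  wr(trials, "trials.csv", writer = write_trials)
  wr(scores, "scores.csv")
  wr(rel_summary, "reliability_summary.csv")
  wr(curve_means, "reliability_curve_means.csv")
  wr(curve_estimates, "reliability_curve_estimates.csv")
  wr(profiles, "stimulus_profiles.csv")
  wr(stim_level$stimulus_table, "stimulus_table.csv")
  wr(stim_level$correlations, "stimulus_correlations.csv")
  wr(contrasts, "contrasts.csv")
  wr(comparison, "correlation_comparison.csv")
  wr(as.data.frame(cors$r), "correlation_matrix.csv")
  jsonlite::write_json(filt$summary, file.path(out_dir,
                                               "removal_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  paths[["removal_summary.json"]] <- file.path(out_dir,
                                               "removal_summary.json")

  # hash only the analysis-relevant configuration (not output paths)
  cfg_core <- unclass(config)
  cfg_core$out_dir <- NULL
  cfg_core$overwrite <- NULL
  hash_file <- tempfile()
  writeLines(jsonlite::toJSON(cfg_core, auto_unbox = TRUE, null = "null"),
             hash_file)
  cfg_md5 <- unname(tools::md5sum(hash_file))
  unlink(hash_file)
  manifest <- list(
    package = "adtkit",
    version = as.character(utils::packageVersion("adtkit")),
    config_md5 = cfg_md5,
    n_trials = nrow(trials),
    n_participants_retained = length(participants),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths[["manifest.json"]] <- file.path(out_dir, "manifest.json")

  report <- c(
    "# ADT pipeline report", "",
    "## Retrieval latency by form (seconds)", "",
    "| form | FA mean | DA mean | IC | t | df | p (Holm) | d |",
    "|------|---------|---------|----|---|----|----------|---|",
    vapply(seq_len(nrow(contrasts)), function(i) {
      f <- contrasts$form[i]
      s <- kept_scores[kept_scores$form == f, ]
      sprintf("| %s | %.2f | %.2f | %.2f | %.2f | %d | %.3g | %.3f |",
              f, mean(s$fa_mean, na.rm = TRUE),
              mean(s$da_mean, na.rm = TRUE), mean(s$ic, na.rm = TRUE),
              contrasts$t[i], contrasts$df[i], contrasts$p_holm[i],
              contrasts$d[i])
    }, character(1)),
    "", "## Reliability (full-length forms)", "",
    utils::capture.output(as.data.frame(rel_summary)),
    "", "## Construct correlations (component scores)", "",
    utils::capture.output(round(cors$r, 3)),
    "", sprintf("FA-fluency vs DA-fluency: delta r = %.3f, z = %.3f, p = %.4f",
                comparison$delta_r, comparison$z, comparison$p))
  writeLines(report, file.path(out_dir, "report.md"))
  paths[["report.md"]] <- file.path(out_dir, "report.md")

  invisible(list(schedule = schedule, trials = trials, truth = truth,
                 screened = screened, filter_summary = filt$summary,
                 scores = scores, reliability = rel_summary,
                 curves = list(means = curve_means,
                               estimates = curve_estimates),
                 norms = norms, cleaned_norms = cleaned,
                 profiles = profiles, stimulus_level = stim_level,
                 composites = comp_scores, correlations = cors,
                 contrasts = contrasts, comparison = comparison,
                 paths = paths))
}
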