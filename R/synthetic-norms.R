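#' Simulate free-association norms
#'
#' Emulates a norming study in which every respondent supplies four
#' distinct associations to each stimulus. Each stimulus has its own
#' opaque vocabulary whose marginal pick probabilities follow a Zipf
#' profile (rank^-zipf_exponent) and which is partitioned into
#' `n_clusters` semantic clusters; after the first pick, each subsequent
#' association is drawn from the cluster of the previous one with
#' probability `within_cluster_mix` (otherwise from the whole remaining
#' vocabulary). This produces the two structural features the analysis
#' targets: a dominance hierarchy with a steep frequency decay, and
#' clustered co-occurrence structure in the response networks.
#'
#' @param stimulus_ids Character vector of stimulus identifiers.
#' @param n_respondents Number of respondents (>= 2). The default 90
#'   yields about 360 association tokens per stimulus, the scale of the
#'   reference norming samples.
#' @param params An [adt_params()] object (vocabulary, Zipf and cluster
#'   settings are used).
#' @param seed Integer seed.
#'
#' @return A tibble in the canonical norms schema: `respondent_id`,
#'   `stimulus_id`, `slot` (1-4), `response`. Response tokens are opaque
#'   identifiers of the form `<stimulus>_w<rank>`; the token's cluster is
#'   `((rank - 1) %% n_clusters) + 1`.
#' @examples
#' norms <- simulate_norms("cue1", n_respondents = 5, seed = 1)
#' nrow(norms)  # 5 x 4
#' @export
simulate_norms <- function(stimulus_ids, n_respondents = 90,
                           params = adt_params(), seed = 1) {
  stopifnot(inherits(params, "adt_params"))
  if (n_respondents < 2) stop("n_respondents must be >= 2", call. = FALSE)
  V <- params$vocabulary_size
  if (V < 4) stop("vocabulary must hold at least 4 words", call. = FALSE)
  mix <- params$within_cluster_mix
  cluster <- ((seq_len(V) - 1L) %% params$n_clusters) + 1L
  w <- seq_len(V)^(-params$zipf_exponent)
  resp_ids <- sprintf("R%03d", seq_len(n_respondents))

  out <- vector("list", length(stimulus_ids))
  for (si in seq_along(stimulus_ids)) {
    stim <- stimulus_ids[si]
    vocab <- sprintf("%s_w%02d", stim, seq_len(V))
    set.seed(seed_stream(seed, 1000 + si))
    picks <- matrix(0L, nrow = n_respondents, ncol = 4)
    for (r in seq_len(n_respondents)) {
      chosen <- integer(0)
      prev_cl <- NA_integer_
      for (slot in 1:4) {
        stay <- slot > 1 && runif(1) < mix
        cand <- setdiff(seq_len(V), chosen)
        if (stay) {
          in_cl <- cand[cluster[cand] == prev_cl]
          if (length(in_cl) > 0) cand <- in_cl
        }
        pick <- cand[sample.int(length(cand), 1, prob = w[cand])]
        chosen <- c(chosen, pick)
        prev_cl <- cluster[pick]
        picks[r, slot] <- pick
      }
    }
    out[[si]] <- tibble::tibble(
      respondent_id = rep(resp_ids, each = 4),
      stimulus_id = stim,
      slot = rep(1:4, times = n_respondents),
      response = vocab[as.integer(t(picks))])
  }
  dplyr::bind_rows(out)
}

#' Simulate psycholinguistic stimulus ratings
#'
#' Generates per-stimulus mean ratings of concreteness, imageability,
#' context availability, valence and arousal on a 1-7 scale, built from
#' two latent stimulus dimensions: a "vividness" factor loading on the
#' first three scales, and an "affective tone" factor loading positively
#' on valence and negatively on arousal. Used to exercise the composite
#' construction (two oblique components from five ratings).
#'
#' @param stimulus_ids Character vector of stimulus identifiers.
#' @param seed Integer seed.
#' @param loading_vividness,loading_affect Factor loadings in (0, 1).
#' @return A tibble with `stimulus_id` and the five rating columns.
#' @export
simulate_ratings <- function(stimulus_ids, seed = 1,
                             loading_vividness = 0.85,
                             loading_affect = 0.8) {
  if (loading_vividness <= 0 || loading_vividness >= 1 ||
      loading_affect <= 0 || loading_affect >= 1) {
    stop("loadings must lie in (0, 1)", call. = FALSE)
  }
  n <- length(stimulus_ids)
  set.seed(seed_stream(seed, 2001))
  vivid <- rnorm(n)
  affect <- rnorm(n)
  lv <- loading_vividness
  la <- loading_affect
  mk <- function(lat, l, sign = 1) {
    z <- sign * l * lat + sqrt(1 - l^2) * rnorm(n)
    pmin(pmax(4 + z, 1), 7)  # clip to the 1-7 rating scale
  }
  tibble::tibble(
    stimulus_id = stimulus_ids,
    concreteness = mk(vivid, lv),
    imageability = mk(vivid, lv),
    context_availability = mk(vivid, lv),
    valence = mk(affect, la),
    arousal = mk(affect, la, sign = -1))
}

#' Simulate auxiliary cognitive task scores
#'
#' Generates three indicator scores per construct (by default: processing
#' speed, working memory, verbal fluency and associative combination) from
#' a one-factor-per-construct model: indicator = loading x latent +
#' sqrt(1 - loading^2) x noise, with configurable correlations between the
#' construct latents.
#'
#' @param n_participants Number of participants.
#' @param loading_spec Named list giving the three indicator loadings per
#'   construct; all loadings must have absolute value < 1.
#' @param latent_cor Correlation matrix between the construct latents
#'   (order = `names(loading_spec)`); defaults to identity.
#' @param seed Integer seed.
#' @return A tibble with `participant_id`, one column per indicator
#'   (`<construct>_1` ... `<construct>_3`), and the latent scores as
#'   attribute `"latents"`.
#' @export
simulate_auxiliary_scores <- function(n_participants,
                                      loading_spec = list(
                                        speed = c(0.8, 0.8, 0.8),
                                        working_memory = c(0.8, 0.8, 0.8),
                                        fluency = c(0.8, 0.8, 0.8),
                                        combination = c(0.8, 0.8, 0.8)),
                                      latent_cor = NULL, seed = 1) {
  if (n_participants < 2) stop("n_participants must be >= 2", call. = FALSE)
  loads <- unlist(loading_spec)
  if (any(abs(loads) >= 1)) {
    stop("all loadings must satisfy |loading| < 1", call. = FALSE)
  }
  k <- length(loading_spec)
  if (is.null(latent_cor)) latent_cor <- diag(k)
  stopifnot(nrow(latent_cor) == k, ncol(latent_cor) == k)

  set.seed(seed_stream(seed, 3001))
  Z <- matrix(rnorm(n_participants * k), n_participants, k)
  latents <- Z %*% chol(latent_cor)
  colnames(latents) <- names(loading_spec)

  cols <- list(participant_id = sprintf("P%03d", seq_len(n_participants)))
  for (cn in names(loading_spec)) {
    ls <- loading_spec[[cn]]
    for (j in seq_along(ls)) {
      l <- ls[j]
      cols[[sprintf("%s_%d", cn, j)]] <-
        as.numeric(l * latents[, cn] + sqrt(1 - l^2) * rnorm(n_participants))
    }
  }
  out <- tibble::as_tibble(cols)
  attr(out, "latents") <- latents
  out
}
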