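#' Generative parameters for synthetic ADT data
#'
#' Bundles the parameters of the latency, error and association-norm
#' generators. Latencies are lognormal: on the log-seconds scale a trial is
#'
#' \deqn{\log RT = \mu_{FA} + a_p + b_s + \beta_{typFA} T_s 1[FA] +
#'   (\gamma_{DA} + d_p + \beta_{typIC} T_s) 1[DA] + \epsilon}
#'
#' where \eqn{a_p} (person speed), \eqn{d_p} (person inhibition),
#' \eqn{b_s} (stimulus) and \eqn{\epsilon} (residual) are independent
#' zero-mean normals with the stated standard deviations, and \eqn{T_s} is
#' the stimulus associative-typicality z-score. The defaults give grand
#' mean latencies of about 3.35 s (FA) and 5.90 s (DA), the scale reported
#' for young-adult samples on this task.
#'
#' @param mu_FA Log-seconds intercept of the FA condition.
#' @param gamma_DA Log-seconds shift of the DA condition.
#' @param sigma_person,sigma_inhib,sigma_stim,sigma_noise Standard
#'   deviations (log-seconds) of the person speed, person inhibition,
#'   stimulus, and residual effects. All must be >= 0.
#' @param beta_typ_FA,beta_typ_IC Typicality effects in log-seconds per
#'   z-unit: the FA slope (negative by default: typical cues speed
#'   associative retrieval) and the DA-specific slope (positive by
#'   default: typical cues increase the inhibition cost).
#' @param error_rates Named probabilities `rule_FA`, `rule_DA`,
#'   `repetition`, `strategy_DA` for the rater error categories.
#' @param zipf_exponent Decay exponent (> 0) of the association-frequency
#'   hierarchy; larger values give steeper, more dominant hierarchies.
#' @param vocabulary_size Per-stimulus association vocabulary size (>= 4).
#' @param n_clusters Number of semantic clusters partitioning each
#'   stimulus vocabulary (>= 1).
#' @param within_cluster_mix Probability in \[0, 1\] that an association
#'   after the first is drawn from the cluster of the previous one.
#'
#' @return An object of class `adt_params` (a validated list).
#' @examples
#' p <- adt_params()
#' p$gamma_DA
#' @export
adt_params <- function(mu_FA = 1.123,
                       gamma_DA = 0.555,
                       sigma_person = 0.20,
                       sigma_inhib = 0.15,
                       sigma_stim = 0.10,
                       sigma_noise = 0.35,
                       beta_typ_FA = -0.18,
                       beta_typ_IC = 0.15,
                       error_rates = c(rule_FA = 0.0205, rule_DA = 0.0445,
                                       repetition = 0.03,
                                       strategy_DA = 0.0183),
                       zipf_exponent = 1.1,
                       vocabulary_size = 50,
                       n_clusters = 2,
                       within_cluster_mix = 0.7) {
  sigmas <- c(sigma_person = sigma_person, sigma_inhib = sigma_inhib,
              sigma_stim = sigma_stim, sigma_noise = sigma_noise)
  if (any(sigmas < 0)) {
    stop("all sigma parameters must be >= 0", call. = FALSE)
  }
  need <- c("rule_FA", "rule_DA", "repetition", "strategy_DA")
  if (!all(need %in% names(error_rates))) {
    stop("error_rates must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(error_rates < 0 | error_rates > 1)) {
    stop("error_rates must be probabilities in [0, 1]", call. = FALSE)
  }
  if (zipf_exponent <= 0) stop("zipf_exponent must be > 0", call. = FALSE)
  if (n_clusters < 1) stop("n_clusters must be >= 1", call. = FALSE)
  if (within_cluster_mix < 0 || within_cluster_mix > 1) {
    stop("within_cluster_mix must be in [0, 1]", call. = FALSE)
  }
  if (vocabulary_size < 4) {
    stop("vocabulary_size must be at least 4 (respondents give 4 distinct ",
         "associations per stimulus)", call. = FALSE)
  }
  structure(
    list(mu_FA = mu_FA, gamma_DA = gamma_DA,
         sigma_person = sigma_person, sigma_inhib = sigma_inhib,
         sigma_stim = sigma_stim, sigma_noise = sigma_noise,
         beta_typ_FA = beta_typ_FA, beta_typ_IC = beta_typ_IC,
         error_rates = error_rates[need],
         zipf_exponent = zipf_exponent,
         vocabulary_size = vocabulary_size,
         n_clusters = n_clusters,
         within_cluster_mix = within_cluster_mix),
    class = "adt_params")
}

#' @export
print.adt_params <- function(x, ...) {
  cat("ADT generative parameters\n")
  cat(sprintf("  latency: mu_FA = %.3f, gamma_DA = %.3f (log-seconds)\n",
              x$mu_FA, x$gamma_DA))
  cat(sprintf("  sigmas (person/inhib/stim/noise): %.2f / %.2f / %.2f / %.2f\n",
              x$sigma_person, x$sigma_inhib, x$sigma_stim, x$sigma_noise))
  cat(sprintf("  typicality betas (FA/IC): %.3f / %.3f\n",
              x$beta_typ_FA, x$beta_typ_IC))
  cat("  error rates:",
      paste(sprintf("%s=%.4f", names(x$error_rates), x$error_rates),
            collapse = ", "), "\n")
  cat(sprintf("  norms: zipf = %.2f, vocab = %d, clusters = %d, mix = %.2f\n",
              x$zipf_exponent, x$vocabulary_size, x$n_clusters,
              x$within_cluster_mix))
  invisible(x)
}
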