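#' Parallel analysis for component retention
#'
#' Retains the leading principal components whose sample
#' correlation-matrix eigenvalues exceed the chosen quantile (default the
#' 95th percentile) of eigenvalues from `n_sim` simulated standard-normal
#' datasets of the same shape.
#'
#' @param data Observation x variable table (>= 3 variables, more
#'   observations than variables).
#' @param n_sim Number of simulated datasets (default 500).
#' @param quantile Percentile of the simulated eigenvalues (default
#'   0.95).
#' @param seed Integer seed for the simulations.
#' @return A list with `n_retained` and `eigenvalues` (tibble:
#'   `component`, `observed`, `threshold`, `retained`).
#' @export
parallel_analysis <- function(data, n_sim = 500, quantile = 0.95,
                              seed = 1) {
  X <- as.matrix(data)
  X <- X[complete.cases(X), , drop = FALSE]
  p <- ncol(X)
  n <- nrow(X)
  if (p < 3) stop("need at least 3 variables", call. = FALSE)
  if (n < p + 1) stop("need at least variables + 1 observations",
                      call. = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0] %||% which(sds == 0)
    stop("constant variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  obs <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values

  set.seed(seed_stream(seed, 4001))
  sims <- matrix(NA_real_, n_sim, p)
  for (i in seq_len(n_sim)) {
    Z <- matrix(rnorm(n * p), n, p)
    sims[i, ] <- eigen(cor(Z), symmetric = TRUE, only.values = TRUE)$values
  }
  thr <- apply(sims, 2, stats::quantile, probs = quantile)

  exceeds <- obs > thr
  n_retained <- if (exceeds[1]) {
    rle(exceeds)$lengths[1]  # leading run of exceedances
  } else 0L
  list(n_retained = as.integer(n_retained),
       eigenvalues = tibble::tibble(
         component = seq_len(p), observed = obs, threshold = unname(thr),
         retained = seq_len(p) <= n_retained))
}

#' Principal-component composites with oblimin rotation
#'
#' PCA on the Pearson correlation matrix. With more than one component
#' and `rotation = "oblimin"`, the loadings are obliquely rotated
#' (quartimin criterion) and standardized composite scores are produced
#' from the pattern matrix by regression, so each score captures the
#' unique variance of its component. Component signs are fixed so the
#' variable with the largest absolute loading loads positively.
#'
#' @param data Observation x variable table.
#' @param n_components Number of components to extract (>= 1), e.g. from
#'   [parallel_analysis()].
#' @param rotation `"oblimin"` (default; identical to `"none"` for a
#'   single component) or `"none"`.
#' @return An object of class `composite_model`: list with `loadings`
#'   (pattern matrix), `Phi` (component correlations), `scores`
#'   (standardized, mean 0 / SD 1 per component), `variance_explained`
#'   (proportions of total variance, unrotated) and `rotation`.
#' @export
pca_composites <- function(data, n_components,
                           rotation = c("oblimin", "none")) {
  rotation <- match.arg(rotation)
  X <- as.matrix(data)
  X <- X[complete.cases(X), , drop = FALSE]
  p <- ncol(X)
  if (n_components < 1 || n_components > p) {
    stop("n_components must lie in 1..ncol(data)", call. = FALSE)
  }
  R <- cor(X)
  if (any(!is.finite(R))) stop("correlation matrix is undefined",
                               call. = FALSE)
  if (rcond(R) < 1e-12) stop("correlation matrix is singular",
                             call. = FALSE)
  ev <- eigen(R, symmetric = TRUE)
  k <- n_components
  A <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(k)]), k)
  rownames(A) <- colnames(X)

  if (rotation == "oblimin" && k > 1) {
    rot <- gpa_oblimin(A)
    P <- rot$loadings
    Phi <- rot$Phi
  } else {
    P <- A
    Phi <- diag(k)
  }
  # fix signs: largest-|loading| variable loads positively
  signs <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(P[, j]))
    if (P[i, j] < 0) -1 else 1
  }, numeric(1))
  P <- P %*% diag(signs, k)
  Phi <- diag(signs, k) %*% Phi %*% diag(signs, k)
  rownames(P) <- colnames(X)
  colnames(P) <- paste0("PC", seq_len(k))
  dimnames(Phi) <- list(colnames(P), colnames(P))

  Z <- scale(X)
  Sm <- P %*% Phi                 # structure matrix
  W <- solve(R, Sm)               # regression score weights
  scores <- Z %*% W
  scores <- scale(scores)         # mean 0, SD 1 per component
  colnames(scores) <- colnames(P)

  structure(list(loadings = P, Phi = Phi,
                 scores = tibble::as_tibble(scores),
                 variance_explained = ev$values[seq_len(k)] / p,
                 n_components = k, rotation = rotation),
            class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("PCA composite model: %d component(s), rotation = %s\n",
              x$n_components, x$rotation))
  cat("Variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n\nPattern matrix:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Paired-sample t contrast with Cohen's d
#'
#' Two-sided paired t-test with the repeated-measures effect size
#' \eqn{d = t / \sqrt{n}} (equivalently \eqn{t/\sqrt{df+1}}).
#'
#' @param x,y Paired score vectors (n >= 3).
#' @return A one-row tibble: `t`, `df`, `p`, `d`, `diff` (mean of x - y),
#'   `se`.
#' @export
paired_contrast <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x - y) == 0) {
    stop("zero variance of the paired differences: t is undefined",
         call. = FALSE)
  }
  tt <- t.test(x, y, paired = TRUE)
  t_stat <- unname(tt$statistic)
  tibble::tibble(t = t_stat, df = unname(tt$parameter), p = tt$p.value,
                 d = t_stat / sqrt(n), diff = mean(x - y),
                 se = sd(x - y) / sqrt(n))
}

#' Cohen's d from a paired t statistic
#'
#' Recovers the repeated-measures standardized mean difference from a
#' printed paired t statistic and its degrees of freedom:
#' \eqn{d = t / \sqrt{df + 1}}.
#'
#' @param t Paired t statistic(s).
#' @param df Degrees of freedom (n - 1).
#' @return Cohen's d.
#' @examples
#' cohens_d_from_t(-14.969, 100)  # about -1.489
#' @export
cohens_d_from_t <- function(t, df) {
  t / sqrt(df + 1)
}

#' Holm step-down p-value adjustment
#'
#' Delegates to [stats::p.adjust()] (sort ascending, multiply by
#' m - i + 1, enforce monotonicity, cap at 1).
#'
#' @param pvals Raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "holm")
}

#' Compare two correlation coefficients
#'
#' Tests the difference between two Pearson correlations via the Fisher
#' Z transformation. Two designs are supported: `"independent_fisher"`
#' for correlations from independent samples, and
#' `"dependent_overlapping"` (Steiger-type) for two correlations sharing
#' a variable measured in one sample -- e.g. r(FA, fluency) versus
#' r(DA, fluency) -- which requires `r12`, the correlation between the two
#' non-shared variables. Confidence intervals for the difference use the
#' Zou back-transformed construction, which respects the asymmetry of the
#' correlation scale.
#'
#' @param r1,r2 The two correlations (|r| < 1).
#' @param n Sample size (per sample for the independent design).
#' @param method `"dependent_overlapping"` (default) or
#'   `"independent_fisher"`.
#' @param r12 Correlation between the two non-shared variables (required
#'   for the dependent design).
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `r1`, `r2`, `delta_r` (= r1 - r2, exact),
#'   `z`, `p`, `ci_lower`, `ci_upper`, `method`.
#' @export
compare_correlations <- function(r1, r2, n,
                                 method = c("dependent_overlapping",
                                            "independent_fisher"),
                                 r12 = NULL, conf = 0.95) {
  method <- match.arg(method)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1", call. = FALSE)
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  delta <- r1 - r2
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  zc <- qnorm(1 - (1 - conf) / 2)
  # Fisher-z CIs of the individual correlations, back-transformed
  l1 <- tanh(z1 - zc / sqrt(n - 3)); u1 <- tanh(z1 + zc / sqrt(n - 3))
  l2 <- tanh(z2 - zc / sqrt(n - 3)); u2 <- tanh(z2 + zc / sqrt(n - 3))

  if (method == "independent_fisher") {
    z <- (z1 - z2) / sqrt(2 / (n - 3))
    corr <- 0
  } else {
    if (is.null(r12)) {
      stop("the dependent_overlapping method requires r12 (the ",
           "correlation between the two non-shared variables)",
           call. = FALSE)
    }
    rbar <- (r1 + r2) / 2
    s <- (r12 * (1 - 2 * rbar^2) -
            0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)) / (1 - rbar^2)^2
    z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - s)))
    corr <- (r12 * (1 - r1^2 - r2^2) -
               0.5 * r1 * r2 * (1 - r1^2 - r2^2 - r12^2)) /
      ((1 - r1^2) * (1 - r2^2))
  }
  p <- 2 * pnorm(-abs(z))
  ci_l <- delta - sqrt((r1 - l1)^2 + (u2 - r2)^2 -
                         2 * corr * (r1 - l1) * (u2 - r2))
  ci_u <- delta + sqrt((u1 - r1)^2 + (r2 - l2)^2 -
                         2 * corr * (u1 - r1) * (r2 - l2))
  tibble::tibble(r1 = r1, r2 = r2, delta_r = delta, z = z, p = p,
                 ci_lower = ci_l, ci_upper = ci_u, method = method)
}

#' Pairwise Pearson correlation table
#'
#' Pairwise-complete Pearson correlations with two-sided p-values for
#' every pair of numeric columns. Pairs involving a zero-variance
#' variable are left `NA`.
#'
#' @param scores Observation x variable table of construct scores.
#' @return A list of matrices `r`, `p`, `n`.
#' @export
correlation_table <- function(scores) {
  X <- as.matrix(scores)
  p_vars <- ncol(X)
  vn <- colnames(X) %||% paste0("V", seq_len(p_vars))
  r <- p <- nmat <- matrix(NA_real_, p_vars, p_vars,
                           dimnames = list(vn, vn))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(p_vars)) {
    nmat[i, i] <- sum(complete.cases(X[, i]))
    for (j in seq_len(p_vars)) {
      if (j <= i) next
      ok <- complete.cases(X[, i], X[, j])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3 || sd(X[ok, i]) == 0 || sd(X[ok, j]) == 0) next
      ct <- cor.test(X[ok, i], X[ok, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, n = nmat)
}

#' Stimulus-aggregated latency table and property correlations
#'
#' Averages the filtered trial latencies over participants for every
#' stimulus x condition, derives the per-stimulus inhibition cost
#' (IC = DA - FA), joins the supplied stimulus properties, and correlates
#' each latency measure with each property across stimuli. Also emits the
#' trial-level long-format table (participant, stimulus, condition,
#' latency, properties) ready for external mixed-model fitting.
#'
#' @param records Filtered trial records.
#' @param properties Tibble with `stimulus_id` and numeric property
#'   columns (e.g. typicality/topology composites, vividness, affective
#'   tone).
#' @return A list with `stimulus_table` (one row per stimulus),
#'   `correlations` (tidy tibble: `measure`, `property`, `r`, `p`, `n`;
#'   `NA` with a flag for constant properties) and `long_table`.
#' @export
stimulus_level_table <- function(records, properties) {
  assert_cols(records, c("participant_id", "stimulus_id", "condition",
                         "rt_sec"), "records")
  assert_cols(properties, "stimulus_id", "properties")

  agg <- records |>
    dplyr::group_by(.data$stimulus_id, .data$condition) |>
    dplyr::summarise(mean_rt = mean(.data$rt_sec), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = c("mean_rt", "n"),
                       names_glue = "{.value}_{tolower(condition)}")
  dropped <- setdiff(properties$stimulus_id, agg$stimulus_id)
  if (length(dropped) > 0) {
    warning(length(dropped), " stimulus(-i) had no surviving trials and ",
            "were dropped", call. = FALSE)
  }
  stim_tab <- agg |>
    dplyr::rename(fa = "mean_rt_fa", da = "mean_rt_da") |>
    dplyr::mutate(ic = .data$da - .data$fa) |>
    dplyr::left_join(properties, by = "stimulus_id")

  prop_cols <- setdiff(names(properties), "stimulus_id")
  prop_cols <- prop_cols[vapply(properties[prop_cols], is.numeric,
                                logical(1))]
  rows <- list()
  for (m in c("fa", "da", "ic")) {
    for (pc in prop_cols) {
      ok <- complete.cases(stim_tab[[m]], stim_tab[[pc]])
      if (sum(ok) < 3 || sd(stim_tab[[pc]][ok]) == 0 ||
          sd(stim_tab[[m]][ok]) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          measure = m, property = pc, r = NA_real_, p = NA_real_,
          n = sum(ok), undefined = TRUE)
        next
      }
      ct <- cor.test(stim_tab[[m]][ok], stim_tab[[pc]][ok])
      rows[[length(rows) + 1]] <- tibble::tibble(
        measure = m, property = pc, r = unname(ct$estimate),
        p = ct$p.value, n = sum(ok), undefined = FALSE)
    }
  }
  long <- records[, c("participant_id", "stimulus_id", "condition",
                      "rt_sec")] |>
    dplyr::left_join(properties, by = "stimulus_id")

  list(stimulus_table = stim_tab,
       correlations = dplyr::bind_rows(rows),
       long_table = tibble::as_tibble(long))
}
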