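#' Cronbach's alpha
#'
#' \eqn{\alpha = k/(k-1) (1 - \sum_i var_i / var(rowsums))}, computed
#' from the pairwise-complete item covariance matrix (so rows with a few
#' missing cells still contribute). Latencies share a unit, so the
#' unstandardized (covariance) form is used.
#'
#' @param x Numeric matrix or data frame, participants x items (>= 2
#'   items).
#' @return Alpha coefficient.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("alpha needs at least 2 items", call. = FALSE)
  if (sum(complete.cases(x)) < 2 && nrow(x) < 3) {
    stop("alpha needs at least 2 rows", call. = FALSE)
  }
  k <- ncol(x)
  S <- suppressWarnings(cov(x, use = "pairwise.complete.obs"))
  if (any(!is.finite(S))) {
    stop("covariances are undefined (too much missing data)",
         call. = FALSE)
  }
  total_var <- sum(S)
  if (total_var == 0) {
    stop("total score variance is zero: alpha is undefined", call. = FALSE)
  }
  k / (k - 1) * (1 - sum(diag(S)) / total_var)
}

# Minimum-residual single-factor fit: minimize the sum of squared
# off-diagonal residuals of S - lambda lambda'. Analytic gradient keeps
# this fast enough for resampling loops.
minres_one_factor <- function(S, maxit = 200) {
  p <- ncol(S)
  off <- !diag(p)
  obj <- function(l) {
    R <- S - tcrossprod(l)
    sum(R[off]^2) / 2
  }
  grad <- function(l) {
    R <- S - tcrossprod(l)
    diag(R) <- 0
    -2 * as.vector(R %*% l)
  }
  ev <- eigen(S, symmetric = TRUE)
  l0 <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0))
  if (sum(l0) < 0) l0 <- -l0
  fit <- optim(l0, obj, grad, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  l <- fit$par
  if (sum(l) < 0) l <- -l
  list(loadings = l, converged = fit$convergence == 0)
}

#' McDonald's omega (total) from a single-factor model
#'
#' Fits a one-factor model to the item covariance matrix by minimum
#' residual and returns \eqn{\omega = (\sum\lambda)^2 /
#' ((\sum\lambda)^2 + \sum\theta)} where \eqn{\theta} are the
#' uniquenesses. Heywood cases (negative uniquenesses) are clamped to a
#' small positive fraction of the item variance with a warning. If the
#' optimizer fails to converge an error is raised naming
#' [cronbach_alpha()] as the fallback.
#'
#' @param x Numeric matrix or data frame, participants x items (>= 3
#'   items); covariances are computed over pairwise-complete rows, so
#'   scattered missing cells are tolerated.
#' @param standardize Fit on the correlation instead of the covariance
#'   matrix (default `FALSE`: latencies share a unit).
#' @return Omega, with attributes `loadings`, `uniquenesses` and
#'   `converged`.
#' @examples
#' set.seed(1)
#' lat <- rnorm(500)
#' items <- sapply(1:4, function(i) 0.7 * lat + rnorm(500, sd = sqrt(0.51)))
#' mcdonald_omega(items)
#' @export
mcdonald_omega <- function(x, standardize = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop("omega needs at least 3 items", call. = FALSE)
  if (nrow(x) < 4) {
    stop("omega needs more rows than this", call. = FALSE)
  }
  S <- suppressWarnings(
    if (standardize) cor(x, use = "pairwise.complete.obs")
    else cov(x, use = "pairwise.complete.obs"))
  if (any(!is.finite(S))) {
    stop("covariances are undefined (too much missing data)",
         call. = FALSE)
  }
  fit <- minres_one_factor(S)
  if (!fit$converged) {
    stop("one-factor fit did not converge; consider cronbach_alpha() as ",
         "a fallback", call. = FALSE)
  }
  l <- fit$loadings
  theta <- diag(S) - l^2
  eps <- 1e-3 * diag(S)
  if (any(theta < eps)) {
    warning("Heywood case: uniqueness clamped at a small positive value",
            call. = FALSE)
    theta <- pmax(theta, eps)
  }
  omega <- sum(l)^2 / (sum(l)^2 + sum(theta))
  structure(omega, loadings = l, uniquenesses = theta,
            converged = fit$converged)
}

#' Test-retest correlation between parallel forms
#'
#' Pearson product-moment correlation over the pairs complete in both
#' vectors.
#'
#' @param scores_a,scores_b Paired participant scores.
#' @return Pearson r.
#' @export
test_retest <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  ok <- complete.cases(scores_a, scores_b)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(scores_a[ok]) == 0 || sd(scores_b[ok]) == 0) {
    stop("zero variance: the correlation is undefined", call. = FALSE)
  }
  cor(scores_a[ok], scores_b[ok])
}

#' Trial-sampling reliability curve
#'
#' Emulates the random trial-sampling procedure used to project how
#' reliability depends on test length: for each set size `n` (1 up to
#' `max_n`) and each of `reps` repetitions, one random subset of exactly
#' `n` items (columns) is drawn per form without replacement -- the same
#' subset for every participant within that form and repetition,
#' independent subsets across forms. Participant scores are the means over
#' the sampled items (available cells, if some are missing), and the
#' estimator is computed from those scores:
#' \describe{
#'   \item{`"omega"`}{[mcdonald_omega()] of the sampled item submatrix,
#'     per form; set sizes below 3 are marked unavailable (`NA`).}
#'   \item{`"retest"`}{[test_retest()] of the participant means between
#'     each pair of forms.}
#' }
#'
#' @param matrices Named list of participant x item matrices, one per
#'   parallel form (same participants in the same row order).
#' @param estimator `"omega"` or `"retest"`.
#' @param max_n Largest set size; defaults to the smallest item count
#'   across forms.
#' @param reps Repetitions per set size (default 200).
#' @param seed Integer seed; per-(n, rep) substreams are derived
#'   deterministically.
#' @return An object of class `reliability_curve`: a list with
#'   `estimates` (tidy tibble: `estimator`, `unit` (form or form pair),
#'   `n`, `rep`, `estimate`) and `means` (per unit x n averages over
#'   repetitions).
#' @export
sampling_curve <- function(matrices, estimator = c("omega", "retest"),
                           max_n = NULL, reps = 200, seed = 1) {
  estimator <- match.arg(estimator)
  stopifnot(is.list(matrices), length(matrices) >= 1)
  if (is.null(names(matrices))) {
    names(matrices) <- LETTERS[seq_along(matrices)]
  }
  matrices <- lapply(matrices, as.matrix)
  n_items <- vapply(matrices, ncol, integer(1))
  if (is.null(max_n)) max_n <- min(n_items)
  if (max_n > min(n_items)) {
    stop("max_n exceeds the smallest item count across forms",
         call. = FALSE)
  }
  if (estimator == "retest" && length(matrices) < 2) {
    stop("the retest estimator needs at least 2 forms", call. = FALSE)
  }
  pairs <- if (length(matrices) >= 2) {
    combn(names(matrices), 2, simplify = FALSE)
  } else list()

  rows <- vector("list", max_n * reps)
  ri <- 0L
  for (n in seq_len(max_n)) {
    for (rep_i in seq_len(reps)) {
      set.seed(seed_stream(seed, n * 100000 + rep_i))
      cols <- lapply(matrices, function(m) sort(sample.int(ncol(m), n)))
      ri <- ri + 1L
      if (estimator == "omega") {
        est <- vapply(names(matrices), function(f) {
          if (n < 3) return(NA_real_)
          sub <- matrices[[f]][, cols[[f]], drop = FALSE]
          tryCatch(as.numeric(suppressWarnings(mcdonald_omega(sub))),
                   error = function(e) NA_real_)
        }, numeric(1))
        rows[[ri]] <- tibble::tibble(estimator = estimator,
                                     unit = names(matrices),
                                     n = n, rep = rep_i,
                                     estimate = unname(est))
      } else {
        means <- lapply(names(matrices), function(f) {
          rowMeans(matrices[[f]][, cols[[f]], drop = FALSE], na.rm = TRUE)
        })
        names(means) <- names(matrices)
        est <- vapply(pairs, function(pr) {
          tryCatch(test_retest(means[[pr[1]]], means[[pr[2]]]),
                   error = function(e) NA_real_)
        }, numeric(1))
        rows[[ri]] <- tibble::tibble(
          estimator = estimator,
          unit = vapply(pairs, paste, character(1), collapse = "-"),
          n = n, rep = rep_i, estimate = unname(est))
      }
    }
  }
  estimates <- dplyr::bind_rows(rows)
  means <- estimates |>
    dplyr::group_by(.data$estimator, .data$unit, .data$n) |>
    dplyr::summarise(mean_estimate = mean(.data$estimate, na.rm = TRUE),
                     n_estimates = sum(!is.na(.data$estimate)),
                     .groups = "drop")
  structure(list(estimates = estimates, means = means,
                 reps = reps, seed = seed),
            class = "reliability_curve")
}

#' @export
print.reliability_curve <- function(x, ...) {
  cat(sprintf("Trial-sampling reliability curve (%s, %d reps)\n",
              unique(x$estimates$estimator), x$reps))
  print(utils::head(x$means, 10))
  invisible(x)
}

#' Cronbach-Mesbah curve (backward stepwise item selection)
#'
#' Starting from the full item set, repeatedly removes the item whose
#' removal maximizes Cronbach's alpha of the remaining items (ties broken
#' by the lowest column index), recording alpha at every set size from
#' the full set down to 2 items. A monotone rising curve toward the full
#' set is the signature of a unidimensional scale. If alpha becomes
#' undefined at some step the partial curve is returned with attribute
#' `complete = FALSE`.
#'
#' @param x Participant x item matrix with >= 3 items.
#' @return A tibble with columns `n_items`, `alpha` and `removed` (the
#'   item dropped to reach the next, smaller set; `NA` on the final row),
#'   attribute `complete`.
#' @export
cronbach_mesbah <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(ncol(x)))
  if (ncol(x) < 3) stop("need at least 3 items", call. = FALSE)
  cur <- seq_len(ncol(x))
  out <- list()
  complete <- TRUE
  while (length(cur) >= 2) {
    a <- tryCatch(cronbach_alpha(x[, cur, drop = FALSE]),
                  error = function(e) NA_real_)
    if (is.na(a)) {
      complete <- FALSE
      break
    }
    if (length(cur) == 2) {
      out[[length(out) + 1]] <- tibble::tibble(
        n_items = 2L, alpha = a, removed = NA_character_)
      break
    }
    cand <- vapply(seq_along(cur), function(i) {
      tryCatch(cronbach_alpha(x[, cur[-i], drop = FALSE]),
               error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(cand))) {
      complete <- FALSE
      out[[length(out) + 1]] <- tibble::tibble(
        n_items = length(cur), alpha = a, removed = NA_character_)
      break
    }
    drop_i <- which(cand == max(cand, na.rm = TRUE))[1]  # ties: lowest index
    out[[length(out) + 1]] <- tibble::tibble(
      n_items = length(cur), alpha = a,
      removed = colnames(x)[cur[drop_i]])
    cur <- cur[-drop_i]
  }
  structure(dplyr::bind_rows(out), complete = complete)
}
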