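test_that("schedules satisfy the counterbalance invariants for every seed", {
  for (seed in 1:100) {
    n_stim <- sample(c(4, 6, 8), 1)
    sched <- generate_schedule(n_forms = 1, n_stimuli = n_stim, seed = seed)
    expect_equal(nrow(sched), 2 * n_stim)
    for (b in 1:2) {
      blk <- sched[sched$block == b, ]
      expect_equal(sum(blk$condition == "FA"), n_stim / 2)
      expect_equal(sum(blk$condition == "DA"), n_stim / 2)
      expect_equal(sort(blk$stimulus_id),
                   sort(unique(sched$stimulus_id)))
    }
    # every stimulus swaps condition across blocks
    wide <- tapply(sched$condition, list(sched$stimulus_id, sched$block),
                   identity)
    expect_true(all(wide[, 1] != wide[, 2]))
    # half the stimuli see FA first
    firsts <- tapply(sched$first_condition, sched$stimulus_id, unique)
    expect_equal(sum(firsts == "FA"), n_stim / 2)
  }
})

test_that("a six-stimulus form splits condition orders three and three", {
  sched <- generate_schedule(1, 6, seed = 42)
  b1 <- sched[sched$block == 1, ]
  expect_equal(sum(b1$first_condition == "FA"), 3)
  expect_equal(sum(b1$first_condition == "DA"), 3)
})

test_that("odd stimulus counts are rejected naming the counterbalance", {
  expect_error(generate_schedule(1, 5, seed = 1), "counterbalance")
  expect_error(generate_schedule(1, 0, seed = 1), "even")
})

test_that("DA latencies exceed FA latencies under default parameters", {
  sched <- generate_schedule(1, 20, seed = 3)
  sim <- simulate_trials(sched, adt_params(), n_participants = 100,
                         seed = 3)
  fa <- mean(sim$trials$rt_sec[sim$trials$condition == "FA"])
  da <- mean(sim$trials$rt_sec[sim$trials$condition == "DA"])
  expect_gt(da, fa)
  # calibration scale: a few seconds FA, roughly six DA
  expect_gt(fa, 2); expect_lt(fa, 5)
  expect_gt(da, 4.5); expect_lt(da, 8)
})

test_that("degenerate variance parameters give deterministic latencies", {
  p <- adt_params(sigma_person = 0, sigma_inhib = 0, sigma_stim = 0,
                  sigma_noise = 0, beta_typ_FA = 0, beta_typ_IC = 0)
  sched <- generate_schedule(1, 6, seed = 5)
  sim <- simulate_trials(sched, p, n_participants = 3, seed = 5)
  fa <- sim$trials$rt_sec[sim$trials$condition == "FA"]
  expect_equal(fa, rep(exp(p$mu_FA), length(fa)))
  da <- sim$trials$rt_sec[sim$trials$condition == "DA"]
  expect_equal(da, rep(exp(p$mu_FA + p$gamma_DA), length(da)))
})

test_that("configured error rates are recovered within binomial error", {
  sched <- generate_schedule(1, 40, seed = 7)
  sim <- simulate_trials(sched, adt_params(), n_participants = 100,
                         seed = 7)
  da <- sim$trials[sim$trials$condition == "DA", ]
  rate <- 0.0445  # rule-violation rate configured for DA
  n <- nrow(da)
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(mean(da$error_label == "rule") - rate), 3 * se)
})

test_that("trial generation rejects degenerate participant counts", {
  sched <- generate_schedule(1, 4, seed = 1)
  expect_error(simulate_trials(sched, adt_params(), 1, seed = 1),
               "n_participants")
})

test_that("each respondent contributes four distinct associations", {
  norms <- simulate_norms("cue", n_respondents = 90, seed = 11)
  expect_equal(nrow(norms), 360)
  per_resp <- split(norms$response, norms$respondent_id)
  expect_true(all(vapply(per_resp, function(s) {
    length(s) == 4 && !anyDuplicated(s)
  }, logical(1))))
})

test_that("steep Zipf hierarchies approach the 0.25 dominance ceiling", {
  p <- adt_params(zipf_exponent = 6)
  norms <- simulate_norms("cue", n_respondents = 120, params = p,
                          seed = 12)
  freqs <- table(norms$response)
  prop_dom <- max(freqs) / sum(freqs)
  expect_lte(prop_dom, 0.25 + 1e-12)  # 4-distinct rule imposes the ceiling
  expect_gt(prop_dom, 0.2)
})

test_that("pure within-cluster mixing never crosses clusters", {
  p <- adt_params(within_cluster_mix = 1, n_clusters = 2)
  norms <- simulate_norms("cue", n_respondents = 40, params = p, seed = 13)
  rank_of <- as.integer(sub(".*_w", "", norms$response))
  cl <- (rank_of - 1) %% 2
  per_resp <- split(cl, norms$respondent_id)
  expect_true(all(vapply(per_resp, function(x) length(unique(x)) == 1,
                         logical(1))))
})

test_that("norms generation needs a vocabulary of at least four words", {
  expect_error(adt_params(vocabulary_size = 3), "at least 4")
})

test_that("auxiliary constructs are independent when latents are", {
  aux <- simulate_auxiliary_scores(2000, seed = 21)
  speed <- as.matrix(aux[, paste0("speed_", 1:3)])
  flu <- as.matrix(aux[, paste0("fluency_", 1:3)])
  cross <- cor(speed, flu)
  expect_lt(abs(mean(cross)), 0.05)
})

test_that("zero loadings leave only noise in the indicators", {
  aux <- simulate_auxiliary_scores(
    2000, loading_spec = list(speed = c(0, 0, 0)), seed = 22)
  om <- suppressWarnings(mcdonald_omega(aux[, paste0("speed_", 1:3)]))
  expect_lt(abs(as.numeric(om)), 0.15)
})

test_that("first-eigenvalue share matches the compound-symmetry closed form", {
  aux <- simulate_auxiliary_scores(
    5000, loading_spec = list(wm = c(0.9, 0.9, 0.9)), seed = 23)
  ev <- eigen(cor(aux[, paste0("wm_", 1:3)]))$values
  expect_lt(abs(ev[1] / 3 - (0.81 + 0.19 / 3)), 0.02)
})

test_that("out-of-range loadings are rejected", {
  expect_error(simulate_auxiliary_scores(
    10, loading_spec = list(speed = c(1, 0.5, 0.5))), "loading")
})

test_that("form-mean retest converges to the Spearman-Brown prediction", {
  # parallel items: score = person + noise, so r(n) = s_p^2/(s_p^2 + s_e^2/n)
  s_p <- 1; s_e <- 2; n_items <- 20; n_p <- 800
  set.seed(31)
  person <- rnorm(n_p, 0, s_p)
  mats <- lapply(1:2, function(f) {
    person + matrix(rnorm(n_p * n_items, 0, s_e), n_p, n_items)
  })
  names(mats) <- c("A", "B")
  cv <- sampling_curve(mats, "retest", max_n = n_items, reps = 60,
                       seed = 31)
  oracle <- function(n) s_p^2 / (s_p^2 + s_e^2 / n)
  for (n in c(1, 5, 10, 20)) {
    got <- cv$means$mean_estimate[cv$means$n == n]
    expect_lt(abs(got - oracle(n)), 0.05)
  }
})

test_that("typicality effect signs propagate to stimulus aggregates", {
  sched <- generate_schedule(2, 40, seed = 41)
  sim <- simulate_trials(sched, adt_params(), n_participants = 60,
                         seed = 41)
  filt <- filter_trials(auto_screen(sim$trials, sched))
  res <- stimulus_level_table(
    filt$records, sim$stimuli[, c("stimulus_id", "typicality")])
  r_fa <- res$correlations$r[res$correlations$measure == "fa"]
  r_ic <- res$correlations$r[res$correlations$measure == "ic"]
  expect_lt(r_fa, 0)
  expect_gt(r_ic, 0)
})
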