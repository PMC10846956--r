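test_that("initial-letter runs of three or more DA responses are flagged", {
  rec <- rt_records(c(4, 5, 6), condition = "DA")
  rec$response <- c("rope", "rain", "rice")
  out <- auto_screen(rec)
  expect_equal(out$error_label, rep("strategy", 3))

  rec2 <- rt_records(rep(4, 5), condition = "DA")
  rec2$response <- c("cat", "car", "dog", "den", "cup")  # longest run = 2
  expect_equal(auto_screen(rec2)$error_label, rep("none", 5))
})

test_that("repetitions are scoped to the block and rater labels win", {
  rec <- dplyr::bind_rows(
    rt_records(c(3, 3.2), block = 1),
    rt_records(c(3.1, 3.3), block = 2))
  rec$response <- c("dog", "dog", "dog", "cat")
  out <- auto_screen(rec)
  # second "dog" within block 1 flagged; block-2 "dog" is not
  expect_equal(out$error_label, c("none", "repetition", "none", "none"))

  rec$error_label <- c("rule", "none", "none", "none")
  out2 <- auto_screen(rec)
  expect_equal(out2$error_label[1], "rule")  # never overwritten
})

test_that("screening requires the ordering columns", {
  rec <- rt_records(c(3, 4))
  expect_error(auto_screen(rec[, setdiff(names(rec), "position")]),
               "position")
})

test_that("filtering removes repetitions, errors, then extreme latencies", {
  # 22 trials: 1 rule error, 1 repetition, and among the surviving 20 one
  # latency far above mean + 3 SD of the group
  base <- c(2.8, 2.9, 3.0, 3.1, 3.2, 2.7, 3.3, 3.0, 2.9, 3.1,
            3.0, 2.8, 3.2, 3.1, 2.9, 3.0, 3.3, 2.7, 3.0)
  rts <- c(base, 9.0, 3.0, 3.1)
  rec <- rt_records(rts)
  rec$error_label[21] <- "rule"
  rec$error_label[22] <- "repetition"
  surv <- c(base, 9.0)
  expect_true(9.0 > mean(surv) + 3 * sd(surv))  # fixture sanity
  out <- filter_trials(rec)
  expect_equal(nrow(out$records), 19)
  expect_false(9.0 %in% out$records$rt_sec)
  expect_equal(out$summary$errors, 1 / 22)
  expect_equal(out$summary$repetitions, 1 / 22)
  expect_equal(out$summary$extreme, 1 / 22)
})

test_that("clean, tight data pass the filter untouched", {
  rec <- rt_records(seq(2.8, 3.2, length.out = 10))
  out <- filter_trials(rec)
  expect_equal(nrow(out$records), 10)
  expect_equal(out$summary$retained, 1)
})

test_that("empty input yields an empty result with a warning", {
  rec <- rt_records(numeric(0))
  expect_warning(out <- filter_trials(rec), "no trials")
  expect_equal(nrow(out$records), 0)
  expect_equal(out$summary$retained, 0)
})

test_that("filtering is invariant to input row order", {
  sched <- generate_schedule(1, 20, seed = 8)
  sim <- simulate_trials(sched, adt_params(), 20, seed = 8)
  rec <- auto_screen(sim$trials, sched)
  key <- function(d) sort(paste(d$participant_id, d$form, d$block,
                                d$position))
  a <- filter_trials(rec)
  set.seed(99)
  b <- filter_trials(rec[sample(nrow(rec)), ])
  expect_equal(key(a$records), key(b$records))
})

test_that("study-scale removal proportions match the configured rates", {
  sched <- generate_schedule(3, 40, seed = 14)
  sim <- simulate_trials(sched, adt_params(), 100, seed = 14)
  out <- filter_trials(auto_screen(sim$trials, sched))
  n <- nrow(sim$trials)
  er <- adt_params()$error_rates
  # marginal rates under the rule > repetition > strategy priority
  exp_rep <- mean(c((1 - er[["rule_FA"]]), (1 - er[["rule_DA"]]))) *
    er[["repetition"]]
  exp_err <- mean(c(er[["rule_FA"]], er[["rule_DA"]])) +
    0.5 * er[["strategy_DA"]] * (1 - er[["repetition"]]) *
      (1 - er[["rule_DA"]])
  se_rep <- sqrt(exp_rep * (1 - exp_rep) / n)
  se_err <- sqrt(exp_err * (1 - exp_err) / n)
  expect_lt(abs(out$summary$repetitions - exp_rep), 3 * se_rep)
  expect_lt(abs(out$summary$errors - exp_err), 3 * se_err)
})

test_that("winsorization follows the order-statistic definition", {
  expect_equal(winsorize(1:10, 0.10), c(2, 2, 3, 4, 5, 6, 7, 8, 9, 9))
  expect_equal(winsorize(rep(5, 8), 0.10), rep(5, 8))   # constants
  expect_equal(winsorize(c(9, 1, 5, 3, 7), 0.10), c(9, 1, 5, 3, 7)) # k = 0
  expect_error(winsorize(1:4, 0.5), "trim")
  expect_error(winsorize(numeric(0)), "non-empty")
})

test_that("winsorization is idempotent, bounded and positional", {
  set.seed(17)
  for (i in 1:20) {
    x <- rlnorm(sample(5:60, 1))
    w <- winsorize(x, 0.10)
    expect_equal(winsorize(w, 0.10), w)          # idempotent
    expect_gte(min(w), min(x)); expect_lte(max(w), max(x))
    expect_true(mean(w) >= min(x) && mean(w) <= max(x))
    perm <- sample(length(x))
    expect_equal(winsorize(x[perm], 0.10), w[perm])  # positional
  }
})

test_that("aggregation yields the exact IC identity and NA for empty cells", {
  rec <- dplyr::bind_rows(
    rt_records(rep(3.0, 4), condition = "FA"),
    rt_records(rep(5.5, 4), condition = "DA"))
  sc <- aggregate_trials(rec)
  expect_equal(sc$fa_mean, 3.0)
  expect_equal(sc$da_mean, 5.5)
  expect_equal(sc$ic, 2.5)

  only_fa <- rt_records(2.0, condition = "FA")
  sc2 <- aggregate_trials(only_fa)
  expect_equal(sc2$fa_mean, 2.0)    # singleton mean
  expect_true(is.na(sc2$da_mean))   # missing, not zero
  expect_true(is.na(sc2$ic))
})

test_that("participants beyond the 30% error rate are excluded", {
  rec <- rt_records(rep(3, 80))
  rec$error_label[1:25] <- "rule"         # 31.25%
  filt <- filter_trials(rec)
  sc <- aggregate_trials(filt$records, rec)
  expect_true(sc$excluded)
  expect_equal(sc$error_rate, 25 / 80)

  rec$error_label <- "none"
  rec$error_label[1:24] <- "rule"         # exactly 30%: retained
  sc2 <- aggregate_trials(filter_trials(rec)$records, rec)
  expect_false(sc2$excluded)
})

test_that("the IC identity holds across a simulated sample", {
  sched <- generate_schedule(2, 10, seed = 19)
  sim <- simulate_trials(sched, adt_params(), 25, seed = 19)
  filt <- filter_trials(auto_screen(sim$trials, sched))
  sc <- aggregate_trials(filt$records, sim$trials)
  ok <- complete.cases(sc$fa_mean, sc$da_mean)
  expect_equal(sc$ic[ok], sc$da_mean[ok] - sc$fa_mean[ok])
})
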