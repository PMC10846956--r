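test_that("alpha matches the covariance formula and its edge cases", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  expect_equal(cronbach_alpha(x), 1)

  # hand fixture: k/(k-1) * (1 - sum item variances / variance of sums)
  y <- cbind(c(1, 2, 3, 4, 5), c(2, 2, 3, 4, 4), c(1, 3, 3, 3, 5))
  oracle <- 3 / 2 * (1 - (var(y[, 1]) + var(y[, 2]) + var(y[, 3])) /
                       var(rowSums(y)))
  expect_equal(cronbach_alpha(y), oracle)

  expect_error(cronbach_alpha(y[, 1, drop = FALSE]), "2 items")
  expect_error(cronbach_alpha(matrix(3, 5, 2)), "zero")
})

test_that("alpha of independent items is near zero at large n", {
  set.seed(6)
  x <- matrix(rnorm(5000 * 5), 5000, 5)
  expect_lt(abs(cronbach_alpha(x)), 0.05)
})

test_that("omega reproduces the closed form for known loadings", {
  skip_if_not_installed("MASS")
  l <- rep(0.7, 3)
  Sigma <- tcrossprod(l) + diag(1 - l^2)
  x <- MASS::mvrnorm(400, rep(0, 3), Sigma, empirical = TRUE)
  om <- mcdonald_omega(x)
  expect_equal(as.numeric(om), 4.41 / 5.94, tolerance = 1e-4)
  expect_true(attr(om, "converged"))
  expect_equal(attr(om, "loadings"), l, tolerance = 1e-3)
})

test_that("omega equals alpha for tau-equivalent items", {
  skip_if_not_installed("MASS")
  l <- rep(0.6, 5)
  Sigma <- tcrossprod(l) + diag(1 - l^2)
  x <- MASS::mvrnorm(2000, rep(0, 5), Sigma, empirical = TRUE)
  expect_lt(abs(as.numeric(mcdonald_omega(x)) - cronbach_alpha(x)), 0.02)
})

test_that("omega exceeds alpha for congeneric items", {
  skip_if_not_installed("MASS")
  l <- c(0.9, 0.3, 0.3, 0.3)
  Sigma <- tcrossprod(l) + diag(1 - l^2)
  x <- MASS::mvrnorm(2000, rep(0, 4), Sigma, empirical = TRUE)
  expect_gt(as.numeric(mcdonald_omega(x)), cronbach_alpha(x))
})

test_that("near-duplicate items trigger the Heywood clamp warning", {
  set.seed(7)
  a <- rnorm(300)
  x <- cbind(a, a + rnorm(300, sd = 0.005), rnorm(300))
  expect_warning(mcdonald_omega(x), "Heywood")
})

test_that("test-retest is the Pearson correlation of complete pairs", {
  expect_equal(test_retest(1:5, 1:5), 1)
  expect_equal(test_retest(1:5, -(1:5)), -1)
  # 5-pair hand fixture: cov = 2, both sds sqrt(2.5) -> r = 0.8
  expect_equal(test_retest(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)), 0.8)
  expect_error(test_retest(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(test_retest(c(1, 2), c(1, 2)), "3 complete")
})

test_that("a full-set sample reproduces the direct estimate exactly", {
  set.seed(8)
  mats <- lapply(1:3, function(i) one_factor_data(40, rep(0.7, 5),
                                                  seed = 80 + i))
  names(mats) <- c("A", "B", "C")
  for (est in c("omega", "retest")) {
    cv <- sampling_curve(mats, est, max_n = 5, reps = 8, seed = 9)
    top <- cv$estimates[cv$estimates$n == 5, ]
    if (est == "omega") {
      for (f in names(mats)) {
        full <- as.numeric(suppressWarnings(mcdonald_omega(mats[[f]])))
        expect_equal(unique(top$estimate[top$unit == f]), full)
      }
    } else {
      for (pr in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
        full <- test_retest(rowMeans(mats[[pr[1]]]),
                            rowMeans(mats[[pr[2]]]))
        expect_equal(unique(top$estimate[top$unit ==
                                           paste(pr, collapse = "-")]),
                     full)
      }
    }
  }
})

test_that("omega estimates are unavailable below three sampled items", {
  mats <- list(A = one_factor_data(30, rep(0.7, 6), seed = 10))
  cv <- sampling_curve(mats, "omega", max_n = 4, reps = 3, seed = 10)
  expect_true(all(is.na(cv$estimates$estimate[cv$estimates$n < 3])))
  expect_true(all(!is.na(cv$estimates$estimate[cv$estimates$n >= 3])))
})

test_that("curve means are stable across seeds at moderate set sizes", {
  set.seed(11)
  person <- rnorm(150)
  mats <- lapply(1:2, function(f) person +
                   matrix(rnorm(150 * 20), 150, 20))
  names(mats) <- c("A", "B")
  cv1 <- sampling_curve(mats, "retest", max_n = 20, reps = 200, seed = 1)
  cv2 <- sampling_curve(mats, "retest", max_n = 20, reps = 200, seed = 2)
  m1 <- cv1$means$mean_estimate[cv1$means$n >= 10]
  m2 <- cv2$means$mean_estimate[cv2$means$n >= 10]
  expect_lt(max(abs(m1 - m2)), 0.02)
})

test_that("curve means rise with set size on parallel-item data", {
  set.seed(12)
  person <- rnorm(200)
  mats <- lapply(1:2, function(f) person +
                   matrix(rnorm(200 * 15, 0, 2), 200, 15))
  names(mats) <- c("A", "B")
  cv <- sampling_curve(mats, "retest", max_n = 15, reps = 100, seed = 3)
  m <- cv$means$mean_estimate[order(cv$means$n)]
  # non-decreasing in expectation; allow small Monte-Carlo wiggle
  expect_true(all(diff(m) > -0.02))
  expect_gt(m[15], m[1])
})

test_that("the Cronbach-Mesbah curve drops a pure-noise item first", {
  set.seed(13)
  lat <- rnorm(300)
  good <- sapply(1:5, function(i) lat + rnorm(300, sd = 0.5))
  x <- cbind(good, noise = rnorm(300))
  colnames(x) <- c(paste0("g", 1:5), "noise")
  cmc <- cronbach_mesbah(x)
  expect_equal(cmc$removed[1], "noise")
  expect_true(attr(cmc, "complete"))
})

test_that("a three-item matrix gives a two-point curve", {
  x <- one_factor_data(50, rep(0.7, 3), seed = 14)
  cmc <- cronbach_mesbah(x)
  expect_equal(nrow(cmc), 2)
  expect_equal(cmc$n_items, c(3L, 2L))
  expect_true(is.na(cmc$removed[2]))
})

test_that("unidimensional equal items yield a curve rising toward the full set", {
  x <- one_factor_data(500, rep(0.6, 8), seed = 15)
  cmc <- cronbach_mesbah(x)
  # alpha recorded from k = 8 down to 2 should decline (within noise)
  expect_true(all(diff(cmc$alpha) < 0.02))
  expect_gt(cmc$alpha[1], cmc$alpha[nrow(cmc)])
})

test_that("omega recovers the generating reliability", {
  skip_if_not_installed("MASS")
  # 10 parallel items with trait reliability 0.9 at full length:
  # item loading l solves 10 l^2 / (10 l^2 + 10 (1 - l^2)) ... via
  # Spearman-Brown: item reliability r1 = 0.9/(10 - 9 * 0.9) = 9/19
  l <- sqrt(9 / 19)
  Sigma <- tcrossprod(rep(l, 10)) + diag(1 - l^2, 10)
  x <- MASS::mvrnorm(1000, rep(0, 10), Sigma, empirical = TRUE)
  expect_lt(abs(as.numeric(mcdonald_omega(x)) - 0.9), 0.05)
})
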