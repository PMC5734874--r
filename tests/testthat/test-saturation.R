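test_that("log_likelihood matches hand arithmetic", {
  # two targets, both hit once, k = 2: P = 2!*2!/(2!*1*1) / 2^2 = 1/2
  expect_equal(log_likelihood(k_distribution(c(`1` = 2)), 2), -log(2))
  # one target hit twice, k = 3: 3/9 of all 3^2 assignments
  expect_equal(log_likelihood(k_distribution(c(`2` = 1)), 3), log(1 / 3))
  expect_error(log_likelihood(k_distribution(c(`1` = 3)), 2), ">= occupied")
})

test_that("exp(log_likelihood) equals the exhaustive assignment oracle", {
  # small sweep here; the full m <= 6, k <= 6 sweep runs in the
  # acceptance suite
  for (k in 2:4) {
    for (m in 2:4) {
      probs <- enum_kdist_probs(k, m)
      for (sig in names(probs)) {
        hits <- as.integer(strsplit(sig, ",")[[1]])
        kd <- k_distribution(table(hits))
        expect_equal(exp(log_likelihood(kd, k)), unname(probs[sig]),
                     tolerance = 1e-12)
      }
      expect_equal(sum(probs), 1)
    }
  }
})

test_that("mle_k reproduces the published target-count estimates", {
  # reporter gene 1, residue level
  e1 <- mle_k(k_distribution(c(41, 13, 3)))
  expect_equal(e1$k_hat, 124L)
  # reporter gene 2, residue level
  expect_equal(mle_k(k_distribution(c(`1` = 23, `2` = 7, `3` = 5,
                                      `6` = 1)))$k_hat, 54L)
  # pooled, residue level
  expect_equal(mle_k(k_distribution(c(`1` = 64, `2` = 20, `3` = 8,
                                      `6` = 1)))$k_hat, 170L)
  # nucleotide level: per gene and pooled
  expect_equal(mle_k(k_distribution(c(64, 9, 1)))$k_hat, 296L)
  expect_equal(mle_k(k_distribution(c(`1` = 41, `2` = 11, `3` = 2, `4` = 1,
                                      `5` = 1, `7` = 1, `9` = 1)))$k_hat,
               88L)
  expect_equal(mle_k(k_distribution(c(`1` = 105, `2` = 20, `3` = 3, `4` = 1,
                                      `5` = 1, `7` = 1, `9` = 1)))$k_hat,
               276L)
  # interval properties
  expect_true(e1$ci95[1] <= e1$k_hat && e1$k_hat <= e1$ci95[2])
  expect_true(e1$ci95[1] >= e1$kd$occupied)
})

test_that("all-singleton distributions are flagged unbounded", {
  est <- mle_k(k_distribution(c(`1` = 5)))
  expect_true(est$unbounded)
  expect_true(is.na(est$k_hat))
  expect_error(method1_f(est, 100), "unbounded")
  expect_error(mle_k(k_distribution(stats::setNames(integer(), integer()))),
               "empty")
})

test_that("likelihood profile is unimodal for recurrent distributions", {
  kds <- list(k_distribution(c(41, 13, 3)),
              k_distribution(c(64, 9, 1)),
              k_distribution(c(`1` = 10, `2` = 4)),
              k_distribution(c(`2` = 3)))
  for (kd in kds) {
    est <- mle_k(kd, profile = TRUE)
    ll <- log(est$profile$posterior)
    d <- diff(ll)
    # strictly rising then falling: no second local maximum
    sign_changes <- sum(diff(sign(d[d != 0])) != 0)
    expect_lte(sign_changes, 1)
  }
})

test_that("expected occupancy at k_hat matches the observed occupancy", {
  # E[occupied] = k (1 - (1 - 1/k)^m), within 1 of the data at the MLE
  for (counts in list(c(41, 13, 3),
                      c(`1` = 23, `2` = 7, `3` = 5, `6` = 1),
                      c(`1` = 64, `2` = 20, `3` = 8, `6` = 1))) {
    kd <- k_distribution(counts)
    k <- mle_k(kd)$k_hat
    expect_lt(abs(k * (1 - (1 - 1 / k)^kd$m) - kd$occupied), 1)
  }
})

test_that("f estimators transform k_hat and its interval", {
  e1 <- method1_f(mle_k(k_distribution(c(41, 13, 3))), 265)
  expect_equal(round(e1$f, 2), 0.47)
  e_pool <- method1_f(mle_k(k_distribution(c(`1` = 64, `2` = 20, `3` = 8,
                                             `6` = 1))), 481)
  expect_equal(round(e_pool$f, 2), 0.35)
  expect_equal(e_pool$f_ci95, e_pool$ci95 / 481)
  e2 <- method2_f(mle_k(k_distribution(c(`1` = 105, `2` = 20, `3` = 3,
                                         `4` = 1, `5` = 1, `7` = 1,
                                         `9` = 1))), 3144)
  expect_equal(round(e2$f, 2), 0.09)
  e2b <- method2_f(mle_k(k_distribution(c(`1` = 41, `2` = 11, `3` = 2,
                                          `4` = 1, `5` = 1, `7` = 1,
                                          `9` = 1))), 1405)
  expect_equal(round(e2b$f, 2), 0.06)
  expect_error(method1_f(mle_k(k_distribution(c(41, 13, 3))), 100),
               "exceeds")
})

test_that("method3_f equates STOP and non-synonymous saturation", {
  m3 <- method3_f(48, 212, 132, 3144)
  expect_equal(round(m3$saturation, 2), 0.23)
  expect_equal(round(m3$f, 2), 0.19)
  m3b <- method3_f(29, 116, 74, 1739)
  expect_equal(m3b$saturation, 0.25)
  expect_equal(round(m3b$f, 2), 0.17)
  expect_equal(method3_f(10, 100, 0, 1000)$f, 0)
  expect_error(method3_f(0, 100, 10, 1000), "undefined")
})

test_that("heavy-tailed likelihoods warn about interval truncation", {
  # one recurrence among many singletons: tail mass decays too slowly
  # for any finite grid
  expect_warning(mle_k(k_distribution(c(`1` = 30, `2` = 1)), k_cap = 1e5),
                 "truncated")
})
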