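test_that("dprime matches the bisection inverse-normal oracle", {
  # worked examples: published group-mean hit/FA rates as plain inputs
  expect_equal(dprime(0.846, 0.107, 20, 20),
               qnorm_bisect(0.846) - qnorm_bisect(0.107), tolerance = 1e-6)
  expect_equal(dprime(0.594, 0.076, 20, 20),
               qnorm_bisect(0.594) - qnorm_bisect(0.076), tolerance = 1e-6)
  expect_equal(dprime(0.846, 0.107, 20, 20), 2.26, tolerance = 0.01)
  expect_equal(dprime(0.594, 0.076, 20, 20), 1.67, tolerance = 0.01)
  expect_equal(dprime(0.5, 0.5, 10, 10), 0)
})

test_that("edge corrections follow their definitions", {
  # halfcount: 0 -> 1/(2N), 1 -> 1 - 1/(2N), interior untouched
  expect_equal(dprime(1, 0, 20, 20),
               qnorm(1 - 1 / 40) - qnorm(1 / 40))
  expect_equal(dprime(0.6, 0, 20, 20), qnorm(0.6) - qnorm(1 / 40))
  # loglinear applies everywhere
  expect_equal(dprime(0.6, 0.1, 20, 20, correction = "loglinear"),
               qnorm((12 + 0.5) / 21) - qnorm((2 + 0.5) / 21))
  expect_error(dprime(0.5, 0.5, 0, 10), "counts")
})

test_that("dprime is antisymmetric and monotone on random rate pairs", {
  set.seed(99)
  h <- runif(1000); f <- runif(1000)
  expect_equal(dprime(h, f, 20, 20), -dprime(f, h, 20, 20))
  # monotonicity on interior values
  h2 <- pmin(h + 0.02, 1)
  inc <- dprime(h2, f, 20, 20) - dprime(h, f, 20, 20)
  expect_true(all(inc[h < 0.97 & h > 0.03] > 0))
  f2 <- pmin(f + 0.02, 1)
  dec <- dprime(h, f2, 20, 20) - dprime(h, f, 20, 20)
  expect_true(all(dec[f < 0.97 & f > 0.03] < 0))
})

test_that("score_ax counts hits/FAs over the right pairings", {
  perfect <- data.frame(
    pair_type = rep(c("AA", "AB", "BB", "BA"), each = 10),
    response = rep(c("same", "different", "same", "different"), each = 10))
  s <- score_ax(perfect)
  expect_equal(s$hit_rate, 1)
  expect_equal(s$fa_rate, 0)
  expect_equal(s$dprime, qnorm(1 - 1 / 40) - qnorm(1 / 40))

  # 12/20 hits, 2/20 false alarms: frozen oracle value
  tab <- data.frame(
    pair_type = c(rep("AB", 10), rep("BA", 10), rep("AA", 10), rep("BB", 10)),
    response = c(rep("different", 12), rep("same", 8),
                 rep("different", 2), rep("same", 18)))
  s <- score_ax(tab)
  expect_equal(s$hit_rate, 0.60)
  expect_equal(s$fa_rate, 0.10)
  expect_equal(s$dprime, qnorm_bisect(0.6) - qnorm_bisect(0.1),
               tolerance = 1e-6)
  expect_equal(s$n_different_trials, 20)
  expect_equal(s$n_same_trials, 20)
})

test_that("timeouts are excluded and bad codes are rejected with row numbers", {
  tab <- data.frame(pair_type = c("AB", "AB", "AA", "AA"),
                    response = c("different", "none", "same", "none"))
  s <- score_ax(tab)
  expect_equal(s$n_different_trials, 1)
  expect_equal(s$n_same_trials, 1)
  expect_error(score_ax(data.frame(pair_type = c("AB", "XX"),
                                   response = c("same", "same"))),
               "row 2")
  expect_error(score_ax(data.frame(pair_type = c("AB", "AA"),
                                   response = c("same", "sure"))),
               "row 2")
})

test_that("SDT simulation converges to its closed-form rates and recovers d'", {
  tr <- simulate_ax_trials(2, 1, n_per_pairing = 25000, seed = 3)
  diffp <- tr$pair_type %in% c("AB", "BA")
  hit <- mean(tr$response[diffp] == "different")
  fa <- mean(tr$response[!diffp] == "different")
  expect_equal(hit, pnorm(2 - 1), tolerance = 0.01)
  expect_equal(fa, pnorm(-1), tolerance = 0.01)

  # null sensitivity: hit and FA rates coincide
  tr0 <- simulate_ax_trials(0, 0.5, n_per_pairing = 25000, seed = 4)
  diffp <- tr0$pair_type %in% c("AB", "BA")
  expect_lt(abs(mean(tr0$response[diffp] == "different") -
                  mean(tr0$response[!diffp] == "different")), 0.015)

  # scored d' converges to the planted sensitivity across many subjects;
  # the loglinear correction is near-unbiased at 40 trials (the halfcount
  # rule carries a known positive finite-sample bias of ~0.04-0.08 here)
  set.seed(8)
  bias <- mean(vapply(1:2000, function(i) {
    s <- score_ax(simulate_ax_trials(1, 0.5, 10, seed = 10000 + i),
                  correction = "loglinear")
    s$dprime - 1
  }, numeric(1)))
  expect_lt(abs(bias), 0.05)
})
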