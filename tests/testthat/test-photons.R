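one_state <- function(e) data.frame(model_id = "s", E_DA = e)

test_that("zero-efficiency state yields zero apparent efficiency", {
  cfg <- burst_config(100L, gamma = 1, direct_excitation = 0,
                      n_bursts = 500, seed = 1)
  d <- simulate_bursts(one_state(0), cfg)
  expect_true(all(d$e_app == 0))
})

test_that("single-state bursts reproduce binomial mean and width", {
  e <- 0.2
  n <- 100L
  cfg <- burst_config(n, gamma = 1, direct_excitation = 0,
                      n_bursts = 10000, seed = 2)
  d <- simulate_bursts(one_state(e), cfg)
  se <- sqrt(e * (1 - e) / n) / sqrt(cfg$n_bursts)
  expect_lt(abs(d$mean - e), 3 * se)
  expect_lt(abs(d$sd / sqrt(e * (1 - e) / n) - 1), 0.10)
})

test_that("apparent efficiencies are exactly Binomial(n, E)/n in the ideal case", {
  e <- 0.3
  n <- 20L
  cfg <- burst_config(n, gamma = 1, direct_excitation = 0,
                      n_bursts = 100000, seed = 3)
  d <- simulate_bursts(one_state(e), cfg)
  counts <- tabulate(round(d$e_app * n) + 1L, n + 1L)
  expected <- dbinom(0:n, n, e) * cfg$n_bursts
  # pool tails with expected counts below 5 for a valid chi-square
  pool <- expected >= 5
  obs <- c(counts[pool], sum(counts[!pool]))
  exp <- c(expected[pool], sum(expected[!pool]))
  stat <- sum((obs - exp)^2 / exp)
  pval <- pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
  expect_gt(pval, 1e-3)
})

test_that("direct excitation raises and gamma correction shifts E_app as expected", {
  e <- 0.2
  cfg0 <- burst_config(200L, n_bursts = 4000, seed = 4)
  base <- simulate_bursts(one_state(e), cfg0)$mean
  cfg_de <- burst_config(200L, direct_excitation = 0.3, n_bursts = 4000, seed = 4)
  expect_gt(simulate_bursts(one_state(e), cfg_de)$mean, base)
  # exact per-burst monotonicity in gamma with identical photon records
  cfg_lo <- burst_config(200L, gamma = 0.8, n_bursts = 2000, seed = 5)
  cfg_hi <- burst_config(200L, gamma = 1.4, n_bursts = 2000, seed = 5)
  e_lo <- simulate_bursts(one_state(0.5), cfg_lo)$e_app
  e_hi <- simulate_bursts(one_state(0.5), cfg_hi)$e_app
  expect_true(all(e_hi <= e_lo))
  expect_lt(mean(e_hi), mean(e_lo))
})

test_that("fast exchange is unimodal and narrower than static for two states", {
  rec <- data.frame(model_id = c("lo", "hi"), E_DA = c(0.1, 0.9))
  n <- 300L
  fast <- simulate_bursts(rec, burst_config(n, n_bursts = 4000,
                                            exchange_mode = "fast", seed = 6))
  stat <- simulate_bursts(rec, burst_config(n, n_bursts = 4000,
                                            exchange_mode = "static", seed = 6))
  expect_gt(mean(fast$e_app > 0.3 & fast$e_app < 0.7), 0.95)
  expect_lt(mean(stat$e_app > 0.3 & stat$e_app < 0.7), 0.05)
  expect_gt(mean(stat$e_app < 0.3), 0.4)   # both static modes populated
  expect_gt(mean(stat$e_app > 0.7), 0.4)
  expect_lt(fast$sd, stat$sd)
})

test_that("fast-exchange mean converges to the weight-averaged efficiency", {
  rec <- data.frame(model_id = c("a", "b", "c"), E_DA = c(0.1, 0.4, 0.8))
  w <- fretsel:::new_selection_weights(
    data.frame(model_id = c("a", "b", "c"), multiplicity = c(1L, 2L, 1L)),
    "weighted"
  )
  target <- (0.1 + 2 * 0.4 + 0.8) / 4
  devs <- vapply(c(10L, 100L, 1000L), function(n) {
    d <- simulate_bursts(rec, burst_config(n, n_bursts = 5000, seed = 7),
                         weights = w)
    abs(d$mean - target)
  }, numeric(1))
  expect_lt(devs[3], 0.01)
  sds <- vapply(c(10L, 100L, 1000L), function(n) {
    simulate_bursts(rec, burst_config(n, n_bursts = 5000, seed = 7),
                    weights = w)$sd
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("burst sizes follow the empirical table and trajectory mode links frames", {
  tab <- data.frame(size = c(20L, 80L), freq = c(0.25, 0.75))
  cfg <- burst_config(tab, n_bursts = 4000, seed = 8)
  d <- simulate_bursts(one_state(0.5), cfg)
  expect_equal(length(d$e_app), 4000L)

  # slowly varying trajectory: within-burst frames correlate, so the burst
  # distribution is wider than fast exchange over the same efficiency series
  e_series <- 0.5 + 0.4 * sin(seq(0, 6 * pi, length.out = 600))
  rec <- data.frame(model_id = sprintf("f%03d", 1:600), E_DA = e_series)
  tr <- simulate_bursts(rec, burst_config(50L, n_bursts = 3000,
                                          exchange_mode = "trajectory", seed = 9))
  fa <- simulate_bursts(rec, burst_config(50L, n_bursts = 3000,
                                          exchange_mode = "fast", seed = 9))
  expect_gt(tr$sd, fa$sd)

  expect_error(
    simulate_bursts(one_state(0.5),
                    burst_config(50L, exchange_mode = "trajectory", seed = 1)),
    "time-ordered"
  )
  w <- fretsel:::new_selection_weights(
    data.frame(model_id = "s", multiplicity = 1L), "unweighted"
  )
  expect_error(
    simulate_bursts(one_state(0.5),
                    burst_config(50L, exchange_mode = "trajectory", seed = 1),
                    weights = w),
    "not applicable"
  )
  expect_error(burst_config(data.frame(size = 0L, freq = 1)), ">= 1")
})
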