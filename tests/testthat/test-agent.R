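test_that("boost selection is near-greedy when one level dominates", {
  set.seed(1)
  cfg <- rml_config("speeded")$agent
  ag <- rml_agent(cfg)
  register_state(ag, "s")
  ag$q_mean["s", ] <- 0
  ag$q_mean["s", 4] <- 10  # >> temperature
  picks <- replicate(500, select_boost(ag, "s")$index)
  expect_gt(mean(picks == 4), 0.99)
})

test_that("equal q-means give uniform selection frequencies", {
  set.seed(2)
  cfg <- rml_config("speeded")$agent
  ag <- rml_agent(cfg)
  register_state(ag, "s")
  ag$q_mean["s", ] <- 1
  n <- 10000
  picks <- replicate(n, select_boost(ag, "s")$index)
  p0 <- 1 / ag$n_levels
  se <- sqrt(p0 * (1 - p0) / n)
  freq <- tabulate(picks, ag$n_levels) / n
  expect_true(all(abs(freq - p0) < 3 * se + 1e-9))
})

test_that("softmax probabilities match direct evaluation", {
  q <- c(1, 2, 4)
  tau <- 1
  expected <- exp(q / tau) / sum(exp(q / tau))
  cfg <- rml_config("speeded")$agent
  cfg$boost_levels <- c(0, 1, 2)
  cfg$boost_temperature <- tau
  ag <- rml_agent(cfg)
  register_state(ag, "s")
  ag$q_mean["s", ] <- q
  set.seed(3)
  n <- 20000
  picks <- replicate(n, select_boost(ag, "s")$index)
  freq <- tabulate(picks, 3) / n
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(freq - expected) < 3 * se + 1e-9))
})

test_that("unknown boost states are rejected", {
  ag <- rml_agent(rml_config("speeded"))
  expect_error(select_boost(ag, "nope"), "unknown")
  expect_error(update_boost_q(ag, "nope", 1, 0), "unknown")
})

test_that("boost cost is linear through the origin", {
  expect_equal(boost_cost(0, 0.3), 0)
  b <- runif(5, 0, 6)
  expect_equal(boost_cost(2 * b, 0.3), 2 * boost_cost(b, 0.3))
  expect_error(boost_cost(-1, 0.3), "non-negative")
})

test_that("LC/VTA mapping is anchored, monotone and bounded", {
  cfg <- rml_config("speeded")$agent
  lvls <- cfg$boost_levels
  nm_min <- compute_neuromodulation(min(lvls), cfg)
  expect_equal(nm_min$lc, max(cfg$lc_min, cfg$lc_intercept + cfg$lc_coeff * min(lvls)))
  expect_equal(nm_min$vta, 1)
  lcs <- vapply(lvls, function(b) compute_neuromodulation(b, cfg)$lc, numeric(1))
  expect_true(all(diff(lcs) >= 0))
  expect_true(all(lcs >= cfg$lc_min & lcs <= cfg$lc_max))
  # full sweep against an independently tabulated affine-then-clip map
  expected <- pmin(pmax(cfg$lc_intercept + cfg$lc_coeff * lvls, cfg$lc_min), cfg$lc_max)
  expect_equal(lcs, expected)
  expect_error(compute_neuromodulation(max(lvls) + 1, cfg), "range")
})

test_that("dv is the signed difference of action values and is antisymmetric", {
  ag <- rml_agent(rml_config("speeded"))
  register_option(ag, c("a", "b"))
  ag$act_mean["a"] <- 4.2
  ag$act_mean["b"] <- 4.2
  expect_equal(compute_dv(ag, "a", "b"), 0)
  ag$act_mean["b"] <- 1.1
  expect_equal(compute_dv(ag, "a", "b"), -compute_dv(ag, "b", "a"))
  expect_equal(compute_dv(ag, "a", "b"), 4.2 - 1.1)
})

test_that("the learned boost policy is rational about gain versus cost", {
  # no performance gain from boost: policy concentrates on the lowest level;
  # large gain, negligible cost: on the highest level
  cfg <- rml_config("speeded")$agent
  cfg$boost_levels <- seq(0, 6, length.out = 5)
  learn <- function(gain_per_boost, cost_rate, seed) {
    set.seed(seed)
    cfg$cost_rate <- cost_rate
    cfg$q_init_mean <- 12  # optimistic for this environment's reward range
    ag <- rml_agent(cfg)
    register_state(ag, "s")
    for (i in 1:400) {
      sel <- select_boost(ag, "s")
      reward <- 5 + gain_per_boost * sel$level + rnorm(1, 0, 0.3)
      update_boost_q(ag, "s", sel$index, reward - boost_cost(sel$level, cfg$cost_rate))
    }
    mean(replicate(200, select_boost(ag, "s")$level))
  }
  expect_lt(learn(gain_per_boost = 0, cost_rate = 0.5, seed = 4), 1)
  expect_gt(learn(gain_per_boost = 1, cost_rate = 0.01, seed = 5), 5)
})

test_that("net value is conserved in the trial log", {
  set.seed(6)
  cfg <- tiny_speeded_config()
  rec <- simulate_speeded_participant(cfg, participant = 1, reps_per_type = 2)
  expect_identical(rec$net_value,
                   rec$reward - boost_cost(rec$boost, cfg$agent$cost_rate))
  cfgf <- tiny_foraging_config()
  recf <- simulate_foraging_participant(cfgf, participant = 1, blocks = 1)
  expect_identical(recf$net_value,
                   recf$reward - cfgf$task$forage_cost * recf$n_forages -
                     boost_cost(recf$boost, cfgf$agent$cost_rate))
})
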