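test_that("WM trial generation respects the design", {
  set.seed(14)
  tr <- generate_wm_trials(90, c(1L, 4L, 6L, 8L), 16L)
  expect_equal(nrow(tr), 360)
  expect_equal(unname(table(tr$load)), rep(90L, 4), ignore_attr = TRUE)
  for (l in c(1, 4, 6, 8))
    expect_equal(mean(tr$is_match[tr$load == l]), 0.5)
  # is_match <=> target in word set; |word_ids| = load
  expect_true(all(mapply(function(w, t, m) (t %in% w) == m,
                         tr$word_ids, tr$target_id, tr$is_match)))
  expect_true(all(lengths(tr$word_ids) == tr$load))
  for (r in c(1L, 3L)) {
    trr <- generate_wm_trials(r, c(1L, 4L, 6L, 8L), 16L)
    expect_equal(unname(table(trr$load)), rep(r, 4), ignore_attr = TRUE)
  }
  expect_error(generate_wm_trials(10, c(1L, 8L), 8L), "lexicon")
})

test_that("encoding activates exactly the presented words", {
  cfg <- rml_config("wm")$wm
  st <- encode_words(5L, cfg)
  expect_equal(sum(st$input > 0), 1)
  for (load in c(1, 4, 6, 8)) {
    ids <- sample.int(cfg$n_units, load)
    st <- encode_words(ids, cfg)
    expect_equal(sum(st$input == cfg$encode_value), load)
    expect_equal(sum(st$output == cfg$encode_value), load)
  }
  # permutation equivariance over word identity
  st1 <- encode_words(c(1L, 2L), cfg)
  st2 <- encode_words(c(15L, 16L), cfg)
  expect_equal(sort(st1$output, decreasing = TRUE), sort(st2$output, decreasing = TRUE))
  expect_error(encode_words(c(3L, 3L), cfg), "duplicate")
  expect_error(encode_words(99L, cfg), "range")
})

test_that("retention keeps a single word on top without noise and collapses at zero gain", {
  cfg <- rml_config("wm")$wm
  cfg$noise_sd <- 0
  st <- run_retention(encode_words(4L, cfg), lc = 1, cfg)
  expect_true(all(st$output[4] >= st$output[-4]))
  # gain 0: activation decays to baseline and probe accuracy is at chance
  cfg0 <- cfg
  cfg0$gain_base <- 0; cfg0$gain_lc_coeff <- 0
  st0 <- run_retention(encode_words(4L, cfg0), lc = 0, cfg0)
  expect_lt(st0$output[4], 0.05)
  set.seed(15)
  cfg0$noise_sd <- rml_config("wm")$wm$noise_sd
  n <- 2000
  correct <- replicate(n, {
    ids <- sample.int(cfg0$n_units, 4)
    match <- runif(1) < 0.5
    target <- if (match) ids[1] else sample(setdiff(seq_len(cfg0$n_units), ids), 1)
    st <- run_retention(encode_words(ids, cfg0), lc = 0, cfg0)
    probe_decision(st, target, cfg0)$match == match
  })
  expect_lt(abs(mean(correct) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("retention of presented words is non-increasing in load at fixed gain", {
  set.seed(16)
  cfg <- rml_config("wm")$wm
  mean_act <- vapply(c(1, 4, 6, 8), function(load) {
    mean(replicate(300, {
      ids <- sample.int(cfg$n_units, load)
      st <- run_retention(encode_words(ids, cfg), lc = 0.3, cfg)
      mean(st$output[ids])
    }))
  }, numeric(1))
  expect_true(all(diff(mean_act) <= 0.02))
  expect_lt(mean_act[4], mean_act[1])
})

test_that("the probe readout separates retained from unpresented words", {
  cfg <- rml_config("wm")$wm
  cfg$noise_sd <- 0; cfg$decision_noise_sd <- 0
  st <- run_retention(encode_words(c(2L, 9L), cfg), lc = 1, cfg)
  expect_true(probe_decision(st, 2L, cfg)$match)
  expect_false(probe_decision(st, 12L, cfg)$match)
  # invariance under relabeling of non-probed units
  st_perm <- st
  st_perm$output[-2] <- st$output[c(16:3, 1)]
  expect_equal(probe_decision(st, 2L, cfg)$evidence,
               probe_decision(st_perm, 2L, cfg)$evidence)
})

test_that("probe evidence supports above-chance discrimination when gain is on", {
  set.seed(17)
  cfg <- rml_config("wm")$wm
  sim_evidence <- function(match) {
    ids <- sample.int(cfg$n_units, 6)
    target <- if (match) ids[1] else sample(setdiff(seq_len(cfg$n_units), ids), 1)
    st <- run_retention(encode_words(ids, cfg), lc = 0.8, cfg)
    probe_decision(st, target, cfg)$evidence
  }
  pos <- replicate(400, sim_evidence(TRUE))
  neg <- replicate(400, sim_evidence(FALSE))
  auc <- mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "=="))
  expect_gt(auc, 0.5)
})

test_that("learned control compensates load while clamped control does not", {
  cfg <- tiny_wm_config()
  cfg$base_seed <- 30L
  rec <- simulate_wm_participant(cfg, participant = 1, reps_per_load = 60)
  acc <- tapply(rec$correct, rec$load, mean)
  boost <- tapply(rec$boost, rec$load, mean)
  expect_gt(unname(coef(lm(boost ~ c(1, 4, 6, 8)))[2]), 0)
  expect_gt(min(acc), 0.7)   # far above the uncompensated chance floor
  # clamp boost at its minimum: accuracy decays towards chance with load
  cfg$agent$boost_levels <- c(0, 1e-6)
  rec0 <- simulate_wm_participant(cfg, participant = 2, reps_per_load = 60)
  acc0 <- tapply(rec0$correct, rec0$load, mean)
  expect_lt(acc0[["8"]], acc0[["1"]] - 0.2)
  expect_true(all(rec0$boost <= 1e-6))
})
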