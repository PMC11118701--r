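toy4 <- makeToyArms(2, 1000)  # 4 arms

test_that("aberration counts are unit steps away from diploid", {
  dip <- armsFromStates(toy4, c(1, 1, 1, 1), c(1, 1, 1, 1))
  expect_equal(countAberrations(dip), 0L)
  one <- armsFromStates(toy4, c(3, 1, 1, 1), c(1, 1, 1, 1))
  expect_equal(countAberrations(one), 2L)
  arms39 <- genomeArms()
  doubled <- armsFromStates(arms39, rep(2L, 39), rep(2L, 39),
                            mean_ploidy = 4, median_ploidy = 4L)
  expect_equal(countAberrations(doubled), 78L)
})

test_that("the observed statistic is the fraction of arms with major >= 2", {
  expect_equal(observedWgdStatistic(
    armsFromStates(toy4, rep(1L, 4), rep(1L, 4))), 0)
  expect_equal(observedWgdStatistic(
    armsFromStates(toy4, rep(2L, 4), rep(1L, 4))), 1)
  expect_equal(observedWgdStatistic(
    armsFromStates(toy4, c(2L, 2L, 1L, 1L), rep(1L, 4))), 0.5)
})

test_that("event probabilities are cohort deviation frequencies with a
           spread pseudo-count", {
  # 10 samples, major allele of arm 1q gained in 3
  cohort <- lapply(1:10, function(i) {
    maj <- c(1L, if (i <= 3) 2L else 1L, 1L, 1L)
    armsFromStates(toy4, maj, rep(1L, 4))
  })
  m <- estimateAberrationProbs(cohort)
  p <- m@probs
  expect_equal(sum(p$prob), 1, tolerance = 1e-14)
  hit <- p$arm == "1q" & p$allele == "major" & p$direction == "gain"
  # raw weight 0.3 plus 1/16 pseudo-mass, normalized over total 0.3 + 1
  expect_equal(p$prob[hit], (0.3 + 1 / 16) / 1.3)
  other <- p$arm == "2p" & p$allele == "minor" & p$direction == "loss"
  expect_equal(p$prob[other], (1 / 16) / 1.3)
  # an all-diploid cohort falls back to the uniform distribution
  u <- uniformModel(toy4, 1)
  expect_equal(u@probs$prob, rep(1 / 16, 16))
  expect_error(estimateAberrationProbs(list()), "empty cohort")
})

test_that("the exact null reproduces hand-enumerated probabilities", {
  # a single uniform event: gains (mass 1/2) give statistic 1/4
  m1 <- uniformModel(toy4, 1)
  expect_equal(exactWgdNull(m1, 0.25), 0.5)
  expect_equal(exactWgdNull(m1, 0), 1.0)
  m0 <- uniformModel(toy4, 0)
  expect_equal(exactWgdNull(m0, 0), 1.0)
  # statistic can never exceed 1
  expect_equal(exactWgdNull(m1, 1.01), 0)
  # guard on the enumeration space
  big <- uniformModel(genomeArms(), 10)
  expect_error(exactWgdNull(big, 0.5), "Monte-Carlo|max_states")
})

test_that("the Monte-Carlo null is seeded, degenerate at Ns = 0, and
           monotone in the observed statistic", {
  m0 <- uniformModel(toy4, 0)
  s <- simulateWgdNull(m0, 0, n_sims = 50, seed = 1)
  expect_equal(s$stats, rep(0, 50))
  expect_equal(s$p_value, 1.0)
  m3 <- uniformModel(toy4, 3)
  a <- simulateWgdNull(m3, 0.5, n_sims = 2000, seed = 99)
  b <- simulateWgdNull(m3, 0.5, n_sims = 2000, seed = 99)
  expect_identical(a, b)
  ps <- vapply(c(0, 0.25, 0.5, 0.75, 1),
               function(o) simulateWgdNull(m3, o, n_sims = 2000,
                                           seed = 7)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(simulateWgdNull(m3, 0.5, n_sims = 0, seed = 1), "n_sims")
})

test_that("Monte-Carlo and exact nulls agree on a toy genome", {
  m <- uniformModel(toy4, 3)
  for (obs in c(0.25, 0.5, 0.75)) {
    pe <- exactWgdNull(m, obs)
    pm <- simulateWgdNull(m, obs, n_sims = 10000, seed = 123)$p_value
    se <- sqrt(pe * (1 - pe) / 10000)
    expect_lt(abs(pm - pe), 3 * se + 1e-12)
  }
})

test_that("the strict counting mode and finite-sample correction behave", {
  m <- uniformModel(toy4, 1)
  # under ge counting an all-diploid observation has p exactly 1; under
  # strict counting it drops below 1 only when some simulation exceeds 0
  pge <- simulateWgdNull(m, 0, n_sims = 1000, seed = 5)$p_value
  expect_equal(pge, 1)
  pc <- simulateWgdNull(m, 0, n_sims = 1000, seed = 5,
                        correction = TRUE)$p_value
  expect_equal(pc, 1)
  pgt <- simulateWgdNull(m, 0, n_sims = 1000, seed = 5,
                         mode = "gt")$p_value
  expect_lt(pgt, 1)
  expect_equal(pgt, exactWgdNull(m, 0, mode = "gt"), tolerance = 0.05)
})

test_that("WGD classification applies the ploidy cut and alpha rule", {
  expect_true(classifyWgd(0.5, 3.8))        # ploidy above 3: always WGD
  expect_true(classifyWgd(0.0005, 2.1))     # significant at ploidy <= 3
  expect_false(classifyWgd(0.01, 2.1))      # not significant
  expect_true(classifyWgd(NA, 3.5))         # p not consulted above 3
  expect_error(classifyWgd(NA, 2.5), "required")
})

test_that("wgdTest wires the pieces together and records its decision", {
  arms <- genomeArms()
  doubled <- armsFromStates(arms, rep(2L, 39), rep(2L, 39),
                            mean_ploidy = 4, median_ploidy = 4L)
  r <- wgdTest(doubled, seed = 11)
  expect_true(isWgd(r))
  expect_true(is.na(pValue(r)))  # ploidy rule decided; sims skipped
  r2 <- wgdTest(doubled, seed = 11, lazy = FALSE)
  expect_true(isWgd(r2))
  expect_false(is.na(pValue(r2)))
  quiet <- armsFromStates(arms, rep(1L, 39), rep(1L, 39))
  rq <- wgdTest(quiet, seed = 11)
  expect_false(isWgd(rq))
  expect_equal(pValue(rq), 1)
  # the validity rule rejects inconsistent calls
  expect_error(new("WGDResult", sampleId = "x", observedStat = 0.5,
                   pValue = 0.5, nSims = 10L, ploidyUsed = 2,
                   isWgd = TRUE, alpha = 0.001, seed = 1L),
               "inconsistent")
})

test_that("per-sample and cohort probability modes are both available", {
  arms <- genomeArms()
  maj <- rep(1L, 39); maj[1:5] <- 2L
  sample1 <- armsFromStates(arms, maj, rep(1L, 39))
  cohort <- lapply(1:6, function(i) armsFromStates(arms, rep(1L, 39),
                                                   rep(1L, 39)))
  r1 <- wgdTest(sample1, n_sims = 2000, seed = 3)
  r2 <- wgdTest(sample1, n_sims = 2000, seed = 3, probs_mode = "cohort",
                cohort = cohort)
  # under per-sample probabilities the null reproduces the sample's own
  # gains readily; under a quiet-cohort null the same pattern is rare
  expect_gt(pValue(r1), pValue(r2))
  expect_error(wgdTest(sample1, seed = 3, probs_mode = "cohort"),
               "cohort required")
})
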