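test_that("SEG and BED dialects normalize to the same internal segment", {
  tf <- tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn",
               "s1\tchr1\t1\t1000\t2.0"), tf)
  p <- loadSegments(tf, dialect = "seg_1based")
  gr <- cnSegments(p)
  expect_equal(GenomicRanges::start(gr), 1)
  expect_equal(GenomicRanges::end(gr), 1000)
  expect_equal(as.numeric(GenomicRanges::width(gr)), 1000)
  expect_equal(S4Vectors::mcols(gr)$total_cn, 2.0)

  tb <- tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn",
               "s1\tchr1\t0\t1000\t2.0"), tb)
  pb <- loadSegments(tb, dialect = "bed_0based")
  expect_equal(as.data.frame(cnSegments(pb)), as.data.frame(gr))
})

test_that("overlapping segments are rejected at load", {
  tf <- tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn",
               "s1\tchr1\t0\t500\t2", "s1\tchr1\t400\t900\t2"), tf)
  expect_error(loadSegments(tf, dialect = "bed_0based"), "overlap")
})

test_that("malformed rows are reported with their line number", {
  tf <- tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn",
               "s1\t1\t1\t1000\t2", "s1\t1\t2000\tnope\t2"), tf)
  expect_error(loadSegments(tf), "line 3")
})

test_that("an empty file yields an empty profile that errors downstream", {
  tf <- tempfile(fileext = ".seg")
  writeLines("sample\tchrom\tstart\tend\ttotal_cn", tf)
  p <- loadSegments(tf)
  expect_s4_class(p, "SegmentProfile")
  expect_length(cnSegments(p), 0)
  expect_error(computePloidy(p), "empty profile")
  expect_error(wgii(p), "empty profile")
  expect_error(armProfile(p, makeToyArms()), "empty profile")
})

test_that("ploidy summaries follow the length-weighted definitions", {
  # constant diploid and tetraploid genomes
  expect_equal(computePloidy(toyProfile("1", 1, 1000, total = 2)),
               list(mean_ploidy = 2.0, median_ploidy_int = 2L))
  expect_equal(computePloidy(toyProfile("1", 1, 1000, total = 4)),
               list(mean_ploidy = 4.0, median_ploidy_int = 4L))
  # half the covered length at 2, half at 4: exact 50% tie goes low
  p <- toyProfile("1", c(1, 1001), c(1000, 2000), total = c(2, 4))
  expect_equal(computePloidy(p), list(mean_ploidy = 3.0,
                                      median_ploidy_int = 2L))
})

test_that("ploidy mean is invariant under segment splitting", {
  set.seed(42)
  for (i in 1:20) {
    cuts <- sort(sample(seq(100L, 1900L, by = 50L), 4))
    bounds <- c(1, cuts, 2000)
    tot <- sample(0:5, length(bounds) - 1, replace = TRUE) +
      round(runif(length(bounds) - 1), 2)
    p1 <- toyProfile("1", bounds[-length(bounds)],
                     c(bounds[-c(1, length(bounds))] - 1, 2000),
                     total = tot)
    # split every segment in half with the same CN
    s <- bounds[-length(bounds)]; e <- c(bounds[-c(1, length(bounds))] - 1,
                                         2000)
    mid <- pmax(s, floor((s + e) / 2))
    p2 <- toyProfile("1", c(s, mid + 1)[c(rbind(seq_along(s),
                                                seq_along(s) + length(s)))],
                     c(mid, e)[c(rbind(seq_along(s),
                                       seq_along(s) + length(s)))],
                     total = rep(tot, each = 2))
    expect_equal(computePloidy(p2)$mean_ploidy,
                 computePloidy(p1)$mean_ploidy)
    expect_equal(computePloidy(p2)$median_ploidy_int,
                 computePloidy(p1)$median_ploidy_int)
  }
})

test_that("arm states take the length-weighted modal allelic state", {
  arms <- makeToyArms(2, 1000)  # arms of 1000 bp, chromosomes of 2000
  # one segment spanning a whole arm
  p <- toyProfile("1", 1, 1000, major = 2, minor = 1)
  st <- armStates(armProfile(p, arms))
  expect_equal(st$major[st$arm == "1p"], 2L)
  expect_equal(st$minor[st$arm == "1p"], 1L)
  # 60% of the arm at (1,1), 40% at (2,1): majority wins
  p <- toyProfile("1", c(1, 601), c(600, 1000), major = c(1, 2),
                  minor = c(1, 1))
  st <- armStates(armProfile(p, arms))
  expect_equal(st$major[st$arm == "1p"], 1L)
  # exact 50/50 tie resolves toward the lower total CN
  p <- toyProfile("1", c(1, 501), c(500, 1000), major = c(2, 1),
                  minor = c(1, 1))
  st <- armStates(armProfile(p, arms))
  expect_equal(st$major[st$arm == "1p"], 1L)
})

test_that("segments straddling the centromere are split between arms", {
  arms <- makeToyArms(1, 1000)
  p <- toyProfile("1", 991, 1010, major = 3, minor = 1)
  ap <- armProfile(p, arms)
  st <- armStates(ap)
  # 10 bp land on each side; both arms are covered by the (3,1) state
  expect_true(all(st$covered))
  expect_equal(st$major, c(3L, 3L))
})

test_that("uncovered arms default to diploid and are flagged", {
  arms <- makeToyArms(2, 1000)
  p <- toyProfile("1", 1, 1000, major = 2, minor = 2)
  st <- armStates(armProfile(p, arms))
  expect_equal(st$covered, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(st$major[!st$covered], rep(1L, 3))
  expect_equal(st$minor[!st$covered], rep(1L, 3))
})

test_that("missing allelic CN on an intersecting segment is an error", {
  arms <- makeToyArms(1, 1000)
  p <- toyProfile("1", 1, 1000, total = 2)
  expect_error(armProfile(p, arms), "allelic CN required")
})

test_that("arm profiles are invariant under segment splitting", {
  arms <- makeToyArms(2, 1000)
  set.seed(7)
  for (i in 1:10) {
    maj <- sample(0:3, 2, replace = TRUE) + 1L
    mnr <- pmin(maj, sample(0:2, 2, replace = TRUE))
    p1 <- toyProfile(c("1", "2"), c(1, 1), c(2000, 2000), major = maj,
                     minor = mnr)
    cut <- sample(500:1500, 1)
    p2 <- toyProfile(c("1", "1", "2"), c(1, cut + 1, 1),
                     c(cut, 2000, 2000), major = maj[c(1, 1, 2)],
                     minor = mnr[c(1, 1, 2)])
    expect_equal(armStates(armProfile(p2, arms)),
                 armStates(armProfile(p1, arms)))
  }
})

test_that("segment profiles survive a write/load round trip exactly", {
  arms <- genomeArms()
  sim <- simulateCnCohort(list(stageParams("AIS", 3, wgd_probability = 0.5,
                                           arm_event_rate = 4)),
                          arms, seed = 31)
  tf <- tempfile(fileext = ".seg")
  writeSegments(sim$profiles, tf)
  back <- loadSegments(tf)
  expect_named(back, names(sim$profiles))
  for (nm in names(back)) {
    expect_identical(as.data.frame(cnSegments(back[[nm]])),
                     as.data.frame(cnSegments(sim$profiles[[nm]])))
  }
  # byte-identical re-emission
  tf2 <- tempfile(fileext = ".seg")
  writeSegments(back, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("the bundled arm table has the 39 canonical autosomal arms", {
  arms <- genomeArms()
  expect_length(arms, 39)
  expect_false(any(c("13p", "14p", "15p", "21p", "22p") %in% names(arms)))
  expect_true(all(GenomicRanges::width(arms) > 0))
  # BED round trip preserves coordinates and labels
  tf <- tempfile(fileext = ".bed")
  writeArmsBed(arms, tf)
  back <- readArmsBed(tf)
  expect_identical(names(back), names(arms))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(arms))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(arms))
})
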