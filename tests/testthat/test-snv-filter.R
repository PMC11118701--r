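# builder for a single candidate call with passing defaults
vc <- function(chrom = "1", pos = 100L, ref = "A", alt = "T",
               callers = "mutect,strelka2", tumor_depth = 100L,
               tumor_af = 0.1, normal_depth = 50L, normal_af = 0,
               in_dbsnp = FALSE, in_census = FALSE,
               in_trusted_list = FALSE, artifact_flagged = FALSE,
               lod = NA_real_) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             callers = callers,
             tumor_depth = tumor_depth,
             tumor_alt_count = as.integer(round(tumor_af * tumor_depth)),
             tumor_af = tumor_af, normal_depth = normal_depth,
             normal_af = normal_af, in_dbsnp = in_dbsnp,
             in_census = in_census, in_trusted_list = in_trusted_list,
             artifact_flagged = artifact_flagged, lod = lod,
             stringsAsFactors = FALSE)
}

test_that("caller tables merge by site and allele with union semantics", {
  a <- data.frame(chrom = "1", pos = c(100L, 200L), ref = c("A", "C"),
                  alt = c("T", "G"), tumor_depth = 100L,
                  tumor_alt_count = 10L, tumor_af = 0.1,
                  normal_depth = 50L, normal_af = 0)
  b <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "T",
                  tumor_depth = 90L, tumor_alt_count = 9L,
                  tumor_af = 0.1, normal_depth = 40L, normal_af = 0)
  m <- mergeCallerSets(list(mutect = a, strelka2 = b))
  expect_equal(nrow(m), 2)
  shared <- m[m$pos == 100L, ]
  expect_equal(shared$callers, "mutect,strelka2")
  expect_equal(shared$n_callers, 2L)
  # attributes come from the highest-priority caller (mutect)
  expect_equal(shared$tumor_depth, 100L)
  only <- m[m$pos == 200L, ]
  expect_equal(only$callers, "mutect")
  expect_equal(only$n_callers, 1L)
})

test_that("conflicting reference alleles at one site are an error", {
  a <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "T",
                  tumor_depth = 100L, tumor_alt_count = 10L,
                  tumor_af = 0.1, normal_depth = 50L, normal_af = 0)
  b <- a; b$ref <- "C"; b$alt <- "G"
  expect_error(mergeCallerSets(list(mutect = a, strelka2 = b)),
               "conflicting reference alleles at site 1:100")
})

test_that("non-SNV records are dropped with a message", {
  a <- data.frame(chrom = "1", pos = c(100L, 200L), ref = c("A", "AT"),
                  alt = c("T", "A"), tumor_depth = 100L,
                  tumor_alt_count = 10L, tumor_af = 0.1,
                  normal_depth = 50L, normal_af = 0)
  expect_message(m <- mergeCallerSets(list(mutect = a)), "non-SNV")
  expect_equal(nrow(m), 1)
})

test_that("the binomial LOD has its closed-form values and is monotone", {
  expect_equal(binomialLod(0, 50), 0)
  # all reads alt at error rate 1e-3: LOD = a * log10(1/e) = 3a
  for (a in c(1, 5, 20))
    expect_equal(binomialLod(a, a, 1e-3), 3 * a)
  # brute-force monotonicity in the alt count at every depth up to 200
  for (d in c(10, 50, 200)) {
    lods <- binomialLod(0:d, d, 1e-3)
    expect_true(all(diff(lods) >= -1e-9))
  }
  expect_error(binomialLod(1, 0), "depth")
})

test_that("the consensus cascade keeps and rejects the canonical cases", {
  cases <- rbind(
    vc(pos = 1L, callers = "mutect", tumor_af = 0.10),      # one caller
    vc(pos = 2L, tumor_af = 0.05, lod = 12),                # standard keep
    vc(pos = 3L, tumor_af = 0.03, lod = 15, in_census = TRUE),  # census
    vc(pos = 4L, callers = "mutect,strelka2,lancet", in_dbsnp = TRUE),
    vc(pos = 5L, callers = "mutect,strelka2,lancet",
       artifact_flagged = TRUE),
    vc(pos = 6L, callers = "mutect", in_trusted_list = TRUE))
  r <- consensusFilter(cases)
  expect_equal(r$audit$kept, c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(r$audit$reason,
               c("caller_count", "pass", "pass", "dbsnp", "artifact",
                 "pass"))
})

test_that("the trusted list bypasses downstream but not caller-level
           thresholds by default", {
  weak <- vc(pos = 9L, callers = "mutect", tumor_af = 0.01,
             in_trusted_list = TRUE)
  r <- consensusFilter(weak)
  expect_false(r$audit$kept)
  expect_equal(r$audit$reason, "tumor_af_call")
  r2 <- consensusFilter(weak,
                        filterConfig(trusted_bypass_caller_level = TRUE))
  expect_true(r2$audit$kept)
})

test_that("audit is complete and reports the first failing clause", {
  set.seed(5)
  n <- 300
  calls <- do.call(rbind, lapply(seq_len(n), function(i)
    vc(pos = i,
       callers = paste(sample(c("mutect", "strelka2", "varscan2"),
                              sample(1:3, 1)), collapse = ","),
       tumor_depth = sample(c(10L, 25L, 200L), 1),
       tumor_af = round(runif(1, 0, 0.3), 3),
       normal_depth = sample(c(5L, 15L, 60L), 1),
       normal_af = round(runif(1, 0, 0.03), 3),
       in_dbsnp = runif(1) < 0.2, in_census = runif(1) < 0.2,
       in_trusted_list = runif(1) < 0.1,
       artifact_flagged = runif(1) < 0.2)))
  r <- consensusFilter(calls)
  expect_equal(nrow(r$audit), n)
  expect_equal(sum(r$audit$kept), nrow(r$kept))
  expect_true(all(r$audit$reason[r$audit$kept] == "pass"))
  expect_true(all(r$audit$reason[!r$audit$kept] != "pass"))
})

test_that("relaxing any threshold never shrinks the kept set", {
  set.seed(6)
  calls <- do.call(rbind, lapply(1:200, function(i)
    vc(pos = i,
       callers = paste(sample(c("mutect", "strelka2", "varscan2"),
                              sample(1:3, 1)), collapse = ","),
       tumor_depth = sample(c(15L, 30L, 300L), 1),
       tumor_af = round(runif(1, 0, 0.2), 3),
       normal_depth = sample(c(8L, 20L), 1),
       normal_af = round(runif(1, 0, 0.02), 3),
       in_dbsnp = runif(1) < 0.3, in_census = runif(1) < 0.3)))
  base <- consensusFilter(calls)$audit$kept
  relaxed <- list(
    filterConfig(min_tumor_af_call = 0),
    filterConfig(min_tumor_depth = 0),
    filterConfig(max_normal_af = 1),
    filterConfig(min_normal_depth = 0),
    filterConfig(min_callers = 1),
    filterConfig(min_tumor_af_final = 0),
    filterConfig(min_lod = 0))
  for (cfg in relaxed) {
    kept <- consensusFilter(calls, cfg)$audit$kept
    expect_true(all(kept[base]))
  }
})

test_that("an input LOD column overrides the computed score", {
  low <- vc(pos = 1L, tumor_af = 0.05, tumor_depth = 1000L, lod = 1)
  expect_false(consensusFilter(low)$audit$kept)   # forced low LOD
  low$lod <- NA_real_
  expect_true(consensusFilter(low)$audit$kept)    # computed LOD is high
})

test_that("mutational burden supports count and per-megabase modes", {
  kept <- do.call(rbind, lapply(1:120, function(i) vc(pos = i)))
  expect_equal(tmb(kept, capture_size_mb = 40), 3.0)
  expect_equal(tmb(kept, mode = "count"), 120)
  expect_equal(tmb(kept[0, ], capture_size_mb = 40), 0)
  expect_error(tmb(kept, capture_size_mb = 0), "capture_size_mb")
})
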