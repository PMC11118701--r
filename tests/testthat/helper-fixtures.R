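# shared builders for toy profiles and arm-level states

segGR <- function(chrom, start, end, total = NULL, major = NULL,
                  minor = NULL, n_reads = NULL) {
  gr <- GenomicRanges::GRanges(as.character(chrom),
                               IRanges::IRanges(start, end))
  if (!is.null(total)) S4Vectors::mcols(gr)$total_cn <- total
  if (!is.null(major)) S4Vectors::mcols(gr)$major_cn <- as.integer(major)
  if (!is.null(minor)) S4Vectors::mcols(gr)$minor_cn <- as.integer(minor)
  if (!is.null(n_reads)) S4Vectors::mcols(gr)$n_reads <- as.integer(n_reads)
  gr
}

toyProfile <- function(chrom, start, end, total = NULL, major = NULL,
                       minor = NULL, n_reads = NULL, id = "toy",
                       histology = "unknown") {
  SegmentProfile(id, segGR(chrom, start, end, total, major, minor,
                           n_reads), histology = histology)
}

# ArmProfile built directly from allele-state vectors
armsFromStates <- function(arms, major, minor, mean_ploidy = 2,
                           median_ploidy = 2L, id = "toy") {
  new("ArmProfile", sampleId = id, arm = names(arms),
      chrom = as.character(S4Vectors::mcols(arms)$chrom),
      major = as.integer(major), minor = as.integer(minor),
      covered = rep(TRUE, length(arms)), meanPloidy = mean_ploidy,
      medianPloidyInt = as.integer(median_ploidy))
}

# full-autosome profile at arm resolution from per-arm state vectors
genomeProfile <- function(major, minor, arms = genomeArms(), id = "g",
                          n_reads = 1000L) {
  gr <- segGR(as.character(GenomicRanges::seqnames(arms)),
              GenomicRanges::start(arms), GenomicRanges::end(arms),
              total = as.numeric(major + minor), major = major,
              minor = minor, n_reads = rep(n_reads, length(arms)))
  SegmentProfile(id, gr)
}

# uniform-probability aberration model on an arm table
uniformModel <- function(arms, ns) {
  dip <- armsFromStates(arms, rep(1L, length(arms)), rep(1L, length(arms)))
  estimateAberrationProbs(dip, ns = as.integer(ns))
}

# read built from n repeat copies padded to len with a neutral filler
repeatRead <- function(unit, n, len = 100) {
  body <- strrep(unit, n)
  pad <- len - nchar(body)
  paste0(body, substr(strrep("ACAT", ceiling(pad / 4) + 1), 1, pad))
}
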