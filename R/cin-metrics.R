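# Copy-number-derived chromosomal instability metrics: wGII, SCNA burden
# over evaluable regions, aneuploid-chromosome counts and focal gene calls.

#' Weighted genome instability index (wGII)
#'
#' For each autosome in the arm table, the fraction of the chromosome's
#' covered length whose rounded total copy number differs from the sample's
#' integer median ploidy is computed; wGII is the unweighted mean of these
#' per-chromosome fractions, so every chromosome contributes equally
#' regardless of its size (the "per-chromosome length" weighting of the
#' established index).  A uniformly tetraploid genome therefore scores 0,
#' exactly like a uniformly diploid one — the index measures deviation from
#' the sample's own median ploidy, not from 2.  Chromosomes with no covered
#' length contribute 0 and are reported in the `uncovered` attribute.
#'
#' @param profile a [SegmentProfile-class] with `total_cn` on all segments.
#' @param arms `GRanges` arm table defining the chromosome set.
#' @return wGII in \[0, 1\], with attribute `uncovered` naming chromosomes
#'   that had no segment.
#' @export
wgii <- function(profile, arms = genomeArms()) {
  stopifnot(is(profile, "SegmentProfile"))
  .validateArms(arms)
  gr <- cnSegments(profile)
  if (length(gr) == 0L) stop("empty profile")
  tot <- S4Vectors::mcols(gr)$total_cn
  if (anyNA(tot)) stop("every segment must carry total_cn")
  mp <- computePloidy(profile)$median_ploidy_int
  chroms <- unique(as.character(S4Vectors::mcols(arms)$chrom))
  segch <- as.character(GenomicRanges::seqnames(gr))
  w <- as.numeric(GenomicRanges::width(gr))
  aberrant <- .roundHalfUp(tot) != mp
  fr <- vapply(chroms, function(ch) {
    i <- segch == ch
    if (!any(i)) return(NA_real_)
    sum(w[i][aberrant[i]]) / sum(w[i])
  }, numeric(1))
  uncovered <- chroms[is.na(fr)]
  fr[is.na(fr)] <- 0
  out <- mean(fr)
  attr(out, "uncovered") <- uncovered
  out
}

#' Somatic copy-number alteration burden
#'
#' Length fraction of the evaluable region carrying copy-number gain
#' (total copy number above `gain_threshold`) or loss (below
#' `loss_threshold`).  When read-count filtering is active, only segments
#' supported by at least `min_reads` reads enter numerator and denominator.
#'
#' @param profile a [SegmentProfile-class].
#' @param gain_threshold total CN above which a segment counts as gained
#'   (default 2.5).
#' @param loss_threshold total CN below which a segment counts as lost
#'   (default 1.5).
#' @param min_reads minimum supporting reads for a segment to be evaluable
#'   (default 50); set to `0` or `NULL` to disable filtering (required when
#'   segments carry no `n_reads`).
#' @return List with `gain_fraction` and `loss_fraction`.
#' @export
scnaBurden <- function(profile, gain_threshold = 2.5, loss_threshold = 1.5,
                       min_reads = 50L) {
  stopifnot(is(profile, "SegmentProfile"))
  gr <- cnSegments(profile)
  if (length(gr) == 0L) stop("no evaluable regions")
  m <- S4Vectors::mcols(gr)
  if (anyNA(m$total_cn)) stop("every segment must carry total_cn")
  keep <- rep(TRUE, length(gr))
  if (!is.null(min_reads) && min_reads > 0L) {
    if (anyNA(m$n_reads))
      stop("n_reads required on all segments when min_reads filtering ",
           "is requested")
    keep <- m$n_reads >= min_reads
  }
  w <- as.numeric(GenomicRanges::width(gr))[keep]
  tot <- m$total_cn[keep]
  denom <- sum(w)
  if (denom <= 0) stop("no evaluable regions")
  list(gain_fraction = sum(w[tot > gain_threshold]) / denom,
       loss_fraction = sum(w[tot < loss_threshold]) / denom)
}

#' Aneuploid-chromosome count
#'
#' Counts autosomes carrying at least one arm whose total allele copy
#' number (major + minor) differs from the sample's integer median ploidy.
#' This is an arm-level integer proxy for mosaic-aneuploidy detection from
#' allele-frequency mixtures: it flags the same chromosomes when aberrant
#' states are clonal, but makes no claim of numeric equivalence to
#' mixture-model counts.
#'
#' @param arm an [ArmProfile-class].
#' @param median_ploidy_int integer median ploidy; defaults to the
#'   profile's own.
#' @return Integer count of aneuploid chromosomes.
#' @export
aneuploidChromosomeCount <- function(arm,
                                     median_ploidy_int = medianPloidyInt(arm)) {
  stopifnot(is(arm, "ArmProfile"))
  tot <- arm@major + arm@minor
  aneu <- tot != median_ploidy_int
  length(unique(arm@chrom[aneu]))
}

#' Focal gene copy-number calls
#'
#' The copy number of a gene is the length-weighted mean total copy number
#' of the segments overlapping it; the call is `"gain"` at copy number
#' >= 3, `"loss"` at <= 1, `"neutral"` otherwise.  Genes with no
#' overlapping segment get an `NA` call and `covered = FALSE`.
#'
#' @param profile a [SegmentProfile-class].
#' @param genes `GRanges` of gene intervals with a `gene` metadata column
#'   (see [readGenesBed()]).
#' @param gain_threshold,loss_threshold call thresholds (defaults 3 and 1).
#' @return `data.frame` with columns `gene`, `copy_number`, `call`,
#'   `covered`.
#' @export
geneCnCalls <- function(profile, genes, gain_threshold = 3,
                        loss_threshold = 1) {
  stopifnot(is(profile, "SegmentProfile"), is(genes, "GRanges"))
  gr <- cnSegments(profile)
  tot <- S4Vectors::mcols(gr)$total_cn
  hits <- GenomicRanges::findOverlaps(genes, gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  w <- pmin(GenomicRanges::end(genes)[qh], GenomicRanges::end(gr)[sh]) -
    pmax(GenomicRanges::start(genes)[qh], GenomicRanges::start(gr)[sh]) + 1
  w <- as.numeric(w)
  cn <- rep(NA_real_, length(genes))
  if (length(qh)) {
    num <- tapply(w * tot[sh], qh, sum)
    den <- tapply(w, qh, sum)
    cn[as.integer(names(num))] <- num / den
  }
  call <- ifelse(is.na(cn), NA_character_,
                 ifelse(cn >= gain_threshold, "gain",
                        ifelse(cn <= loss_threshold, "loss", "neutral")))
  data.frame(gene = S4Vectors::mcols(genes)$gene, copy_number = cn,
             call = call, covered = !is.na(cn), stringsAsFactors = FALSE)
}

#' Per-sample chromosomal instability summary
#'
#' Convenience wrapper computing wGII, SCNA burden and the
#' aneuploid-chromosome count for one sample.
#'
#' @inheritParams wgii
#' @inheritParams scnaBurden
#' @return One-row `data.frame`: `sample_id`, `wgii`, `scna_gain_fraction`,
#'   `scna_loss_fraction`, `n_aneuploid_chromosomes`.
#' @export
cinSummary <- function(profile, arms = genomeArms(), min_reads = 50L) {
  g <- wgii(profile, arms)
  b <- scnaBurden(profile, min_reads = min_reads)
  ap <- armProfile(profile, arms)
  data.frame(sample_id = sampleId(profile), wgii = as.numeric(g),
             scna_gain_fraction = b$gain_fraction,
             scna_loss_fraction = b$loss_fraction,
             n_aneuploid_chromosomes = aneuploidChromosomeCount(ap),
             stringsAsFactors = FALSE)
}
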