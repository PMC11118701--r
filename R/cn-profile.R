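# Sample ploidy summaries and arm-level allele-specific states.

# round-half-up, so CN 2.5 -> 3 (avoids banker's rounding surprises)
.roundHalfUp <- function(x) floor(x + 0.5)

# length-weighted median of values v with weights w; at an exact 50% tie
# between two values the lower one is returned (conservative toward the
# lower ploidy).
.weightedMedian <- function(v, w) {
  o <- order(v)
  v <- v[o]; w <- as.numeric(w[o])
  cum <- cumsum(w) / sum(w)
  v[which(cum >= 0.5 - 1e-9)[1L]]
}

#' Length-weighted sample ploidy
#'
#' Mean ploidy is the segment-length-weighted mean of total copy number;
#' the integer median ploidy is the length-weighted median of total copy
#' number rounded to the nearest integer (halves round up; an exact 50%
#' tie between two copy-number values resolves to the lower one).  The
#' integer median anchors the wGII and aneuploidy metrics.
#'
#' @param profile a [SegmentProfile-class]; every segment must carry
#'   `total_cn`.
#' @return A list with `mean_ploidy` (numeric) and `median_ploidy_int`
#'   (integer).
#' @examples
#' arms <- makeToyArms(1, 1000)
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(1, 2000))
#' S4Vectors::mcols(gr)$total_cn <- 2
#' computePloidy(SegmentProfile("s", gr))
#' @export
computePloidy <- function(profile) {
  stopifnot(is(profile, "SegmentProfile"))
  gr <- cnSegments(profile)
  if (length(gr) == 0L) stop("empty profile")
  tot <- S4Vectors::mcols(gr)$total_cn
  if (anyNA(tot)) stop("every segment must carry total_cn")
  w <- as.numeric(GenomicRanges::width(gr))
  if (sum(w) <= 0) stop("empty profile")
  mean_p <- sum(w * tot) / sum(w)
  med <- .weightedMedian(tot, w)
  list(mean_ploidy = mean_p,
       median_ploidy_int = as.integer(.roundHalfUp(med)))
}

#' Arm-level allele-specific copy-number profile
#'
#' Projects a segment profile onto chromosome arms.  Each arm's (major,
#' minor) state is the length-weighted mode of the allelic states of the
#' segments intersecting it (segments straddling a centromere contribute
#' their within-arm length to each side).  Ties between states are broken
#' toward the lower total copy number (then the lower major allele), so
#' ambiguity never creates aberrations.  Arms with no overlapping segment
#' default to the diploid (1,1) state and are flagged `covered = FALSE`.
#'
#' @param profile a [SegmentProfile-class] whose segments carry `major_cn`
#'   and `minor_cn`.
#' @param arms a `GRanges` arm table, e.g. [genomeArms()].
#' @return An [ArmProfile-class].
#' @export
armProfile <- function(profile, arms = genomeArms()) {
  stopifnot(is(profile, "SegmentProfile"))
  .validateArms(arms)
  gr <- cnSegments(profile)
  if (length(gr) == 0L) stop("empty profile")
  pl <- computePloidy(profile)
  # vectorized interval overlap (both tables are small; avoids the
  # constant factor of a full findOverlaps on per-sample calls)
  as_ <- as.numeric(GenomicRanges::start(arms))
  ae_ <- as.numeric(GenomicRanges::end(arms))
  ss_ <- as.numeric(GenomicRanges::start(gr))
  se_ <- as.numeric(GenomicRanges::end(gr))
  ach <- as.character(S4Vectors::mcols(arms)$chrom)
  sch <- as.character(GenomicRanges::seqnames(gr))
  pair <- which(outer(ach, sch, "==") & outer(as_, se_, "<=") &
                  outer(ae_, ss_, ">="), arr.ind = TRUE)
  qh <- pair[, 1L]; sh <- pair[, 2L]
  m <- S4Vectors::mcols(gr)
  if (length(sh) && (anyNA(m$major_cn[sh]) || anyNA(m$minor_cn[sh])))
    stop("allelic CN required: segments intersecting arms must carry ",
         "major_cn and minor_cn")
  # intersection widths (a segment straddling the centromere contributes
  # its within-arm length to each side)
  w <- pmin(ae_[qh], se_[sh]) - pmax(as_[qh], ss_[sh]) + 1
  n_arm <- length(arms)
  major <- rep(1L, n_arm); minor <- rep(1L, n_arm)
  covered <- rep(FALSE, n_arm)
  if (length(qh)) {
    smaj <- m$major_cn[sh]; smnr <- m$minor_cn[sh]
    grp <- paste(qh, smaj, smnr, sep = "_")
    first <- !duplicated(grp)
    ww <- rowsum(w, grp)[grp[first], 1L]
    ga <- qh[first]; gmaj <- smaj[first]; gmnr <- smnr[first]
    # per arm: heaviest state wins; ties go to the lower total CN, then
    # the lower major allele (conservative toward diploid)
    o <- order(ga, -ww, gmaj + gmnr, gmaj)
    top <- o[!duplicated(ga[o])]
    major[ga[top]] <- gmaj[top]
    minor[ga[top]] <- gmnr[top]
    covered[unique(qh)] <- TRUE
  }
  new("ArmProfile", sampleId = sampleId(profile), arm = names(arms),
      chrom = as.character(S4Vectors::mcols(arms)$chrom),
      major = major, minor = minor, covered = covered,
      meanPloidy = pl$mean_ploidy,
      medianPloidyInt = pl$median_ploidy_int)
}
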