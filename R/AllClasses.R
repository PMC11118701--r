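#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect isDisjoint
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

.normChrom <- function(x) sub("^chr", "", as.character(x))

.validSegmentGRanges <- function(gr) {
  msg <- character()
  m <- S4Vectors::mcols(gr)
  need <- c("total_cn", "major_cn", "minor_cn", "n_reads")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    msg <- c(msg, paste0("segments lack metadata columns: ",
                         paste(miss, collapse = ", ")))
  if (length(msg)) return(msg)
  if (any(GenomicRanges::width(gr) < 1L))
    msg <- c(msg, "all segments must have positive width")
  tot <- m$total_cn
  if (!is.numeric(tot)) msg <- c(msg, "total_cn must be numeric")
  else if (any(!is.na(tot) & tot < 0)) msg <- c(msg, "total_cn must be >= 0")
  maj <- m$major_cn; mnr <- m$minor_cn
  both <- !is.na(maj) & !is.na(mnr)
  if (any(both & (maj < mnr)))
    msg <- c(msg, "major_cn must be >= minor_cn on every segment")
  if (any(both & (maj < 0 | mnr < 0)))
    msg <- c(msg, "allelic copy numbers must be >= 0")
  # sortedness and disjointness in one vectorized pass
  if (length(gr) > 1L) {
    ch <- as.character(GenomicRanges::seqnames(gr))
    s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
    o <- order(ch, s)
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "segments must be sorted by (chromosome, start)")
    else {
      i <- seq_len(length(gr) - 1L)
      same <- ch[i] == ch[i + 1L]
      if (any(same & s[i + 1L] <= e[i]))
        msg <- c(msg, "segments overlap within a chromosome")
    }
  }
  msg
}

#' SegmentProfile: one sample's copy-number segments
#'
#' Holds a single sample's segment-level copy-number profile: genomic
#' segments (as a [GenomicRanges::GRanges]) carrying total copy number and,
#' when available, allele-specific (major/minor) integer copy numbers and a
#' supporting read count.  Segments are kept sorted and non-overlapping;
#' coordinates follow the GRanges convention (1-based, closed).
#'
#' @slot sampleId single sample label.
#' @slot histology one of `"AAH"`, `"AIS"`, `"MIA"`, `"ADC"`, `"normal"`,
#'   `"unknown"` — the histologic stage of the lesion.
#' @slot segments `GRanges` with metadata columns `total_cn` (numeric),
#'   `major_cn`, `minor_cn` (integer or `NA`), `n_reads` (integer or `NA`).
#'
#' @seealso [loadSegments()], [computePloidy()], [armProfile()]
#' @export
setClass("SegmentProfile",
  representation(sampleId = "character",
                 histology = "character",
                 segments = "GRanges"),
  validity = function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L)
      msg <- c(msg, "sampleId must be a single string")
    stages <- c("AAH", "AIS", "MIA", "ADC", "normal", "unknown")
    if (length(object@histology) != 1L || !object@histology %in% stages)
      msg <- c(msg, paste0("histology must be one of: ",
                           paste(stages, collapse = ", ")))
    msg <- c(msg, .validSegmentGRanges(object@segments))
    if (length(msg)) msg else TRUE
  })

#' Construct a SegmentProfile
#'
#' @param sample_id sample label.
#' @param segments `GRanges` with metadata columns `total_cn` and optionally
#'   `major_cn`, `minor_cn`, `n_reads` (missing optional columns are added
#'   as `NA`).  When both allelic values are present and `total_cn` is `NA`,
#'   `total_cn` is filled in as `major_cn + minor_cn`.
#' @param histology histologic stage label (default `"unknown"`).
#' @return A [SegmentProfile-class] object.
#' @export
SegmentProfile <- function(sample_id, segments, histology = "unknown") {
  m <- S4Vectors::mcols(segments)
  n <- length(segments)
  pick <- function(col, na) if (is.null(m[[col]])) rep(na, n) else m[[col]]
  tot <- as.numeric(pick("total_cn", NA_real_))
  maj <- as.integer(pick("major_cn", NA_integer_))
  mnr <- as.integer(pick("minor_cn", NA_integer_))
  nrd <- as.integer(pick("n_reads", NA_integer_))
  fill <- is.na(tot) & !is.na(maj) & !is.na(mnr)
  tot[fill] <- maj[fill] + mnr[fill]
  S4Vectors::mcols(segments) <- S4Vectors::DataFrame(
    total_cn = tot, major_cn = maj, minor_cn = mnr, n_reads = nrd)
  o <- order(as.character(GenomicRanges::seqnames(segments)),
             GenomicRanges::start(segments))
  segments <- segments[o]
  new("SegmentProfile", sampleId = as.character(sample_id),
      histology = as.character(histology), segments = segments)
}

#' ArmProfile: arm-level allele-specific copy-number states
#'
#' One sample's major/minor allele copy-number state per chromosome arm,
#' plus the sample ploidy summaries used downstream (length-weighted mean
#' ploidy, integer length-weighted median ploidy).
#'
#' @slot sampleId sample label.
#' @slot arm arm labels (e.g. `"1p"`), parallel to `major`/`minor`.
#' @slot chrom chromosome label per arm.
#' @slot major,minor integer allele copy numbers per arm (`major >= minor`).
#' @slot covered logical; `FALSE` for arms with no overlapping segment,
#'   which were defaulted to the diploid (1,1) state.
#' @slot meanPloidy length-weighted mean total copy number.
#' @slot medianPloidyInt length-weighted median total copy number, rounded
#'   to the nearest integer (halves up).
#' @export
setClass("ArmProfile",
  representation(sampleId = "character", arm = "character",
                 chrom = "character", major = "integer", minor = "integer",
                 covered = "logical", meanPloidy = "numeric",
                 medianPloidyInt = "integer"),
  validity = function(object) {
    msg <- character()
    n <- length(object@arm)
    if (length(object@major) != n || length(object@minor) != n ||
        length(object@covered) != n || length(object@chrom) != n)
      msg <- c(msg, "arm, chrom, major, minor, covered must be parallel")
    if (any(object@major < object@minor))
      msg <- c(msg, "major must be >= minor for every arm")
    if (any(object@major < 0L | object@minor < 0L))
      msg <- c(msg, "allele copy numbers must be >= 0")
    if (n > 0L && !is.na(object@meanPloidy) && object@meanPloidy <= 0)
      msg <- c(msg, "meanPloidy must be > 0 for a non-empty profile")
    if (length(msg)) msg else TRUE
  })

#' AberrationModel: null model for the genome-doubling test
#'
#' Parameters of the randomization null: `nAberrations` (Ns), the number of
#' unit gain/loss steps away from the diploid (1,1) profile, and `probs`
#' (Ps), a categorical distribution over events (arm x allele x direction)
#' from which the null draws sequential aberrations.
#'
#' @slot nAberrations integer >= 0; total unit aberrations relative to
#'   diploid.
#' @slot probs `data.frame` with columns `arm`, `allele` (`"major"`/
#'   `"minor"`), `direction` (`"gain"`/`"loss"`), `prob`; four rows per arm,
#'   probabilities summing to 1.
#' @export
setClass("AberrationModel",
  representation(nAberrations = "integer", probs = "data.frame"),
  validity = function(object) {
    msg <- character()
    p <- object@probs
    need <- c("arm", "allele", "direction", "prob")
    if (!all(need %in% colnames(p)))
      return("probs needs columns arm, allele, direction, prob")
    if (object@nAberrations < 0L) msg <- c(msg, "nAberrations must be >= 0")
    if (any(p$prob < 0)) msg <- c(msg, "probabilities must be >= 0")
    if (abs(sum(p$prob) - 1) > 1e-12)
      msg <- c(msg, "probabilities must sum to 1 (tolerance 1e-12)")
    tab <- table(p$arm)
    if (any(tab != 4L))
      msg <- c(msg, "every arm needs exactly 4 event rows")
    if (length(msg)) msg else TRUE
  })

#' WGDResult: outcome of the whole-genome-doubling test
#'
#' @slot sampleId sample label.
#' @slot observedStat observed proportion of arms with major allele copy
#'   number >= 2, in \[0,1\].
#' @slot pValue randomization p-value (may be `NA` when the ploidy rule
#'   alone decided the call).
#' @slot nSims number of Monte-Carlo simulations (0 for the exact null or
#'   when simulation was skipped).
#' @slot ploidyUsed mean ploidy fed to the classification rule.
#' @slot isWgd logical WGD call: `TRUE` when ploidy > 3, otherwise `TRUE`
#'   iff `pValue < alpha`.
#' @slot alpha significance cut-off (default 0.001).
#' @slot seed RNG seed used for the simulations (`NA` if none were run).
#' @export
setClass("WGDResult",
  representation(sampleId = "character", observedStat = "numeric",
                 pValue = "numeric", nSims = "integer",
                 ploidyUsed = "numeric", isWgd = "logical",
                 alpha = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@observedStat < 0 || object@observedStat > 1)
      msg <- c(msg, "observedStat must lie in [0, 1]")
    if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
      msg <- c(msg, "pValue must lie in [0, 1]")
    expected <- if (object@ploidyUsed > 3) TRUE
                else if (!is.na(object@pValue)) object@pValue < object@alpha
                else NA
    if (!is.na(expected) && !identical(expected, object@isWgd))
      msg <- c(msg, "isWgd inconsistent with the ploidy/p-value rule")
    if (length(msg)) msg else TRUE
  })

#' TelomereContent: telomeric-read summary for one sample
#'
#' @slot sampleId sample label.
#' @slot telomericReads number of reads classified as telomeric.
#' @slot totalReads total reads scanned (> 0).
#' @slot content telomeric reads per million total reads.
#' @export
setClass("TelomereContent",
  representation(sampleId = "character", telomericReads = "integer",
                 totalReads = "integer", content = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@totalReads <= 0L) msg <- c(msg, "totalReads must be > 0")
    if (object@telomericReads < 0L ||
        object@telomericReads > object@totalReads)
      msg <- c(msg, "telomericReads must lie in [0, totalReads]")
    expect <- 1e6 * object@telomericReads / object@totalReads
    if (abs(object@content - expect) > 1e-8)
      msg <- c(msg, "content must equal 1e6 * telomericReads / totalReads")
    if (length(msg)) msg else TRUE
  })

## ---- accessors ------------------------------------------------------------

#' @rdname SegmentProfile-class
#' @param object,x a package object.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname SegmentProfile-class
#' @export
setMethod("sampleId", "SegmentProfile", function(object) object@sampleId)
#' @rdname ArmProfile-class
#' @export
setMethod("sampleId", "ArmProfile", function(object) object@sampleId)
#' @rdname TelomereContent-class
#' @export
setMethod("sampleId", "TelomereContent", function(object) object@sampleId)
#' @rdname WGDResult-class
#' @export
setMethod("sampleId", "WGDResult", function(object) object@sampleId)

#' @rdname SegmentProfile-class
#' @export
setGeneric("histology", function(object) standardGeneric("histology"))
#' @rdname SegmentProfile-class
#' @export
setMethod("histology", "SegmentProfile", function(object) object@histology)

#' @rdname SegmentProfile-class
#' @export
setGeneric("cnSegments", function(object) standardGeneric("cnSegments"))
#' @rdname SegmentProfile-class
#' @export
setMethod("cnSegments", "SegmentProfile", function(object) object@segments)

#' @rdname ArmProfile-class
#' @export
setGeneric("armStates", function(object) standardGeneric("armStates"))

#' Arm states as a data.frame
#'
#' @rdname ArmProfile-class
#' @return `armStates()` returns a `data.frame` with one row per arm and
#'   columns `arm`, `chrom`, `major`, `minor`, `covered`.
#' @export
setMethod("armStates", "ArmProfile", function(object) {
  data.frame(arm = object@arm, chrom = object@chrom, major = object@major,
             minor = object@minor, covered = object@covered,
             stringsAsFactors = FALSE)
})

#' @rdname ArmProfile-class
#' @export
setGeneric("meanPloidy", function(object) standardGeneric("meanPloidy"))
#' @rdname ArmProfile-class
#' @export
setMethod("meanPloidy", "ArmProfile", function(object) object@meanPloidy)

#' @rdname ArmProfile-class
#' @export
setGeneric("medianPloidyInt",
           function(object) standardGeneric("medianPloidyInt"))
#' @rdname ArmProfile-class
#' @export
setMethod("medianPloidyInt", "ArmProfile",
          function(object) object@medianPloidyInt)

#' @rdname WGDResult-class
#' @export
setGeneric("isWgd", function(object) standardGeneric("isWgd"))
#' @rdname WGDResult-class
#' @export
setMethod("isWgd", "WGDResult", function(object) object@isWgd)

#' @rdname WGDResult-class
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname WGDResult-class
#' @export
setMethod("pValue", "WGDResult", function(object) object@pValue)

#' @rdname WGDResult-class
#' @export
setGeneric("observedStat", function(object) standardGeneric("observedStat"))
#' @rdname WGDResult-class
#' @export
setMethod("observedStat", "WGDResult", function(object) object@observedStat)

#' @rdname TelomereContent-class
#' @export
setGeneric("telomereContentPerMillion",
           function(object) standardGeneric("telomereContentPerMillion"))
#' @rdname TelomereContent-class
#' @export
setMethod("telomereContentPerMillion", "TelomereContent",
          function(object) object@content)

## ---- show methods ---------------------------------------------------------

setMethod("show", "SegmentProfile", function(object) {
  cat("SegmentProfile:", object@sampleId,
      sprintf("(%s)\n", object@histology))
  cat("  segments:", length(object@segments), "on",
      length(unique(as.character(GenomicRanges::seqnames(object@segments)))),
      "chromosome(s)\n")
})

setMethod("show", "ArmProfile", function(object) {
  cat("ArmProfile:", object@sampleId, "\n")
  cat(sprintf("  %d arms | mean ploidy %.3f | median ploidy %d | %d uncovered\n",
              length(object@arm), object@meanPloidy, object@medianPloidyInt,
              sum(!object@covered)))
})

setMethod("show", "AberrationModel", function(object) {
  cat("AberrationModel: Ns =", object@nAberrations, "over",
      length(unique(object@probs$arm)), "arms\n")
})

setMethod("show", "WGDResult", function(object) {
  cat(sprintf("WGDResult: %s | observed %.4f | p %s | ploidy %.3f | WGD: %s\n",
              object@sampleId, object@observedStat,
              ifelse(is.na(object@pValue), "NA (ploidy rule)",
                     format(object@pValue, digits = 4)),
              object@ploidyUsed, object@isWgd))
})

setMethod("show", "TelomereContent", function(object) {
  cat(sprintf("TelomereContent: %s | %d / %d reads | %.2f per million\n",
              object@sampleId, object@telomericReads, object@totalReads,
              object@content))
})
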