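# Readers and writers for segment-level copy-number tables.
#
# The on-disk SEG dialect is a tab-separated table with header
#   sample chrom start end total_cn [major_cn minor_cn n_reads]
# in 1-based inclusive coordinates (dialect "seg_1based"); BED-derived
# tables ("bed_0based") use 0-based half-open coordinates. Both are
# normalized into the internal GRanges representation (1-based, closed).

.SEG_COLS <- c("sample", "chrom", "start", "end", "total_cn",
               "major_cn", "minor_cn", "n_reads")

.parseNum <- function(x, what, lines) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !(is.na(x) | x == "" | x == "NA"))
  if (length(bad))
    stop(sprintf("malformed %s at line %d of segment file", what,
                 lines[bad[1L]]), call. = FALSE)
  v
}

#' Load segment-level copy-number profiles
#'
#' Reads a tab-separated segment table (header
#' `sample chrom start end total_cn [major_cn minor_cn n_reads]`) and
#' returns one [SegmentProfile-class] per sample.  SEG-style input is taken
#' as 1-based inclusive, BED-style as 0-based half-open; both are
#' normalized to the internal GRanges convention, sorted, and checked for
#' overlaps.
#'
#' @param path file path.
#' @param dialect `"seg_1based"` (default) or `"bed_0based"`.
#' @param sample optional sample label to extract when the file holds
#'   several samples.
#' @return A [SegmentProfile-class] when the file holds one sample (or
#'   `sample` is given); otherwise a named list of profiles.  An empty file
#'   (header only) yields an empty profile with `sampleId` `"empty"`.
#' @examples
#' tf <- tempfile(fileext = ".seg")
#' writeLines(c("sample\tchrom\tstart\tend\ttotal_cn\tmajor_cn\tminor_cn\tn_reads",
#'              "s1\t1\t1\t1000\t2\t1\t1\t100"), tf)
#' loadSegments(tf)
#' @export
loadSegments <- function(path, dialect = c("seg_1based", "bed_0based"),
                         sample = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("segment file not found: ", path)
  d <- utils::read.delim(path, header = TRUE, colClasses = "character",
                         stringsAsFactors = FALSE)
  miss <- setdiff(.SEG_COLS[1:5], colnames(d))
  if (length(miss))
    stop("segment file lacks required columns: ",
         paste(miss, collapse = ", "))
  for (opt in .SEG_COLS[6:8])
    if (!opt %in% colnames(d)) d[[opt]] <- rep(NA, nrow(d))
  if (nrow(d) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      total_cn = numeric(), major_cn = integer(), minor_cn = integer(),
      n_reads = integer())
    return(SegmentProfile(if (is.null(sample)) "empty" else sample, gr))
  }
  lines <- seq_len(nrow(d)) + 1L  # header is line 1
  start <- .parseNum(d$start, "start", lines)
  end <- .parseNum(d$end, "end", lines)
  if (dialect == "bed_0based") start <- start + 1
  bad <- which(is.na(start) | is.na(end) | end < start)
  if (length(bad))
    stop(sprintf("malformed coordinates at line %d of segment file",
                 lines[bad[1L]]), call. = FALSE)
  tot <- .parseNum(d$total_cn, "total_cn", lines)
  maj <- .parseNum(d$major_cn, "major_cn", lines)
  mnr <- .parseNum(d$minor_cn, "minor_cn", lines)
  nrd <- .parseNum(d$n_reads, "n_reads", lines)
  chrom <- .normChrom(d$chrom)
  out <- list()
  for (s in unique(d$sample)) {
    i <- d$sample == s
    gr <- GenomicRanges::GRanges(chrom[i],
                                 IRanges::IRanges(start[i], end[i]))
    S4Vectors::mcols(gr)$total_cn <- tot[i]
    S4Vectors::mcols(gr)$major_cn <- maj[i]
    S4Vectors::mcols(gr)$minor_cn <- mnr[i]
    S4Vectors::mcols(gr)$n_reads <- nrd[i]
    if (!GenomicRanges::isDisjoint(gr))
      stop("overlapping segments within a chromosome for sample ", s,
           call. = FALSE)
    out[[s]] <- SegmentProfile(s, gr)
  }
  if (!is.null(sample)) {
    if (!sample %in% names(out)) stop("sample not found in file: ", sample)
    return(out[[sample]])
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Write segment profiles to a SEG table
#'
#' Inverse of [loadSegments()] (dialect `"seg_1based"`): re-loading the
#' written file reproduces the segments exactly.
#'
#' @param profiles a [SegmentProfile-class] or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSegments <- function(profiles, path) {
  if (is(profiles, "SegmentProfile")) profiles <- list(profiles)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", as.numeric(x)))
  rows <- lapply(profiles, function(p) {
    gr <- cnSegments(p)
    m <- S4Vectors::mcols(gr)
    data.frame(sample = sampleId(p),
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               total_cn = fmt(m$total_cn),
               major_cn = ifelse(is.na(m$major_cn), "NA", m$major_cn),
               minor_cn = ifelse(is.na(m$minor_cn), "NA", m$minor_cn),
               n_reads = ifelse(is.na(m$n_reads), "NA", m$n_reads),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) d <- as.data.frame(setNames(
    rep(list(character()), length(.SEG_COLS)), .SEG_COLS))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read gene intervals from BED
#'
#' @param path BED file with gene symbols in the name column (0-based
#'   half-open, as BED always is).
#' @return `GRanges` with a `gene` metadata column.
#' @export
readGenesBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomeInfoDb::seqlevels(gr) <- .normChrom(GenomeInfoDb::seqlevels(gr))
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) stop("gene BED needs a name column with gene symbols")
  out <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gr)),
                                IRanges::IRanges(GenomicRanges::start(gr),
                                                 GenomicRanges::end(gr)))
  S4Vectors::mcols(out)$gene <- nm
  out
}
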