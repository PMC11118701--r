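# Telomere-content estimation from sequencing reads.
#
# A read is telomeric when it is densely tiled by telomeric hexamers: the
# canonical TTAGGG plus the ten variant repeats TCAGGG, TGAGGG, TTGGGG,
# TTCGGG, TTTGGG, ATAGGG, CATGGG, CTAGGG, GTAGGG and TAAGGG (and the
# reverse complement of each, for reads from the C-rich strand). Content
# is reported as telomeric reads per million reads; the relative telomere
# length of a tumor is the log2 ratio of its content to the matched
# normal's.

#' Telomeric repeat patterns
#'
#' The canonical hexamer, the ten variant repeats, and the reverse
#' complement of each (the two strand families are scanned separately).
#'
#' @return List with character vectors `forward` (11 hexamers, canonical
#'   first) and `reverse` (their reverse complements).
#' @export
telomereRepeatSet <- function() {
  fwd <- c("TTAGGG",
           "TCAGGG", "TGAGGG", "TTGGGG", "TTCGGG", "TTTGGG",
           "ATAGGG", "CATGGG", "CTAGGG", "GTAGGG", "TAAGGG")
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(fwd)))
  list(forward = fwd, reverse = rev)
}

.asReadStrings <- function(reads) {
  if (is(reads, "DNAStringSet")) return(as.character(reads))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    return(as.character(readReads(reads)))
  as.character(reads)
}

#' Classify reads as telomeric
#'
#' Counts non-overlapping occurrences (greedy, left to right) of any
#' pattern in the repeat set, scanning the forward-strand and
#' reverse-complement pattern families separately and taking the larger
#' count.  A read is telomeric when the count reaches
#' `min_repeats_per_100bp * length / 100`, so the threshold scales with
#' read length.  The default of 6 repeats per 100 bp follows the published
#' default of repeat-count-based telomere quantification.
#'
#' @param reads character vector of read sequences (or a `DNAStringSet`).
#'   Sequences are uppercased; characters outside A/C/G/T/N are an error.
#' @param min_repeats_per_100bp density threshold (default 6).
#' @return Logical vector, one element per read.
#' @examples
#' classifyTelomericRead(strrep("TTAGGG", 17))   # TRUE
#' classifyTelomericRead(strrep("ACGTAC", 17))   # FALSE
#' @export
classifyTelomericRead <- function(reads, min_repeats_per_100bp = 6) {
  s <- toupper(.asReadStrings(reads))
  if (length(s) == 0L) return(logical(0))
  if (any(!nzchar(s))) stop("reads must be non-empty")
  bad <- grep("[^ACGTN]", s)
  if (length(bad))
    stop("read ", bad[1L], " contains characters outside A/C/G/T/N")
  pats <- telomereRepeatSet()
  thr <- min_repeats_per_100bp * nchar(s) / 100
  # prescreen: every repeat in the G-rich family contains a GGG tract (the
  # C-rich family a CCC tract), and disjoint matches have disjoint tracts,
  # so a read with k non-overlapping repeat matches carries at least k
  # non-overlapping GGG (or CCC) occurrences; reads below the tract
  # threshold cannot pass and skip the full regex scan
  tract <- pmax(stringi::stri_count_fixed(s, "GGG"),
                stringi::stri_count_fixed(s, "CCC"))
  cand <- which(tract >= thr)
  n <- integer(length(s))
  if (length(cand)) {
    # stri_count_regex counts greedy left-to-right non-overlapping
    # matches; for equal-length patterns that is the maximal count
    countFam <- function(fam)
      stringi::stri_count_regex(s[cand], paste(fam, collapse = "|"))
    n[cand] <- pmax(countFam(pats$forward), countFam(pats$reverse))
  }
  n >= thr
}

#' Telomere content of a read set
#'
#' Single pass over the reads: counts those classified telomeric by
#' [classifyTelomericRead()] and reports telomeric reads per million total
#' reads.
#'
#' @param reads character vector, `DNAStringSet`, or path to a FASTQ/FASTA/
#'   SAM file (see [readReads()]).
#' @param sample_id sample label.
#' @param min_repeats_per_100bp classification threshold (default 6).
#' @return A [TelomereContent-class].
#' @export
telomereContent <- function(reads, sample_id = "sample",
                            min_repeats_per_100bp = 6) {
  s <- .asReadStrings(reads)
  if (length(s) == 0L) stop("read stream is empty")
  tel <- sum(classifyTelomericRead(s, min_repeats_per_100bp))
  new("TelomereContent", sampleId = as.character(sample_id),
      telomericReads = as.integer(tel), totalReads = length(s),
      content = 1e6 * tel / length(s))
}

#' Relative telomere length (tumor vs matched normal)
#'
#' `log2(tumor content / normal content)` by default, so negative values
#' indicate telomere shortening relative to the matched normal; a linear
#' ratio mode is available.
#'
#' @param tumor,normal [TelomereContent-class] objects.
#' @param scale `"log2"` (default) or `"linear"`.
#' @return Numeric RTL.
#' @export
relativeTelomereLength <- function(tumor, normal,
                                   scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(is(tumor, "TelomereContent"), is(normal, "TelomereContent"))
  if (normal@content <= 0)
    stop("normal telomere content is 0; relative length undefined")
  r <- tumor@content / normal@content
  if (scale == "log2") log2(r) else r
}

#' Read sequences from FASTQ, FASTA or SAM
#'
#' FASTQ/FASTA (optionally gzipped) are read with Biostrings.  For SAM the
#' sequence column of every record (mapped and unmapped) is extracted
#' directly from the text, which keeps the scan free of any alignment
#' index requirement.
#'
#' @param path file path; format inferred from the extension
#'   (`.fastq`/`.fq`, `.fasta`/`.fa`, `.sam`, with optional `.gz`).
#' @return A `DNAStringSet`.
#' @export
readReads <- function(path) {
  stopifnot(file.exists(path))
  base <- sub("\\.gz$", "", path)
  if (grepl("\\.(fastq|fq)$", base))
    return(Biostrings::readDNAStringSet(path, format = "fastq"))
  if (grepl("\\.(fasta|fa|fna)$", base))
    return(Biostrings::readDNAStringSet(path, format = "fasta"))
  if (grepl("\\.sam$", base)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    seqs <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1),
                   10L)
    return(Biostrings::DNAStringSet(seqs[seqs != "*"]))
  }
  stop("unrecognized read file extension: ", path)
}

#' Write reads as FASTQ
#'
#' Minimal plain-text FASTQ writer (constant quality) used by the read
#' simulator; files re-load through [readReads()].
#'
#' @param reads character vector or `DNAStringSet`.
#' @param path output path.
#' @param ids optional read names.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path, ids = NULL) {
  s <- .asReadStrings(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", s, "\n+\n",
                    strrep("I", nchar(s))), con)
  invisible(path)
}
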