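# Chromosome-arm tables. Arm boundaries for the default (hg38) table come
# from the UCSC cytoband centromere (acen) annotation: the p arm runs from
# the chromosome start to the start of the pericentromeric band, the q arm
# from the end of that band to the chromosome end. Acrocentric p arms
# (13p/14p/15p/21p/22p) carry no reliably callable sequence and are
# excluded, leaving 39 autosomal arms; sex chromosomes are excluded from
# all metrics.

.hg38 <- data.frame(
  chrom = as.character(1:22),
  length = c(248956422L, 242193529L, 198295559L, 190214555L, 181538259L,
             170805979L, 159345973L, 145138636L, 138394717L, 133797422L,
             135086622L, 133275309L, 114364328L, 107043718L, 101991189L,
             90338345L,  83257441L,  80373285L,  58617616L,  64444167L,
             46709983L,  50818468L),
  acen_start = c(121700000L, 91800000L, 87800000L, 48200000L, 46100000L,
                 58500000L, 58100000L, 43200000L, 42200000L, 38000000L,
                 51000000L, 33200000L, 16500000L, 16100000L, 17500000L,
                 35300000L, 22700000L, 15400000L, 24200000L, 25700000L,
                 10900000L, 13700000L),
  acen_end = c(125100000L, 96000000L, 94000000L, 51800000L, 50600000L,
               62600000L, 62100000L, 47200000L, 45500000L, 41600000L,
               55800000L, 37800000L, 18900000L, 18200000L, 20500000L,
               38400000L, 27400000L, 21500000L, 28100000L, 30400000L,
               13000000L, 17400000L),
  stringsAsFactors = FALSE)

.acrocentric <- c("13", "14", "15", "21", "22")

.armsFromTable <- function(tab, drop_acro_p = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    ch <- tab$chrom[i]
    if (!(drop_acro_p && ch %in% .acrocentric))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, arm = "p", start = 1L, end = tab$acen_start[i])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, arm = "q", start = tab$acen_end[i] + 1L,
      end = tab$length[i])
  }
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end))
  S4Vectors::mcols(gr)$arm <- d$arm
  S4Vectors::mcols(gr)$chrom <- d$chrom
  names(gr) <- paste0(d$chrom, d$arm)
  gr
}

.validateArms <- function(arms) {
  stopifnot(is(arms, "GRanges"))
  if (is.null(names(arms)) || anyDuplicated(names(arms)))
    stop("arm table needs unique arm names (e.g. '1p')")
  if (any(GenomicRanges::width(arms) < 1L))
    stop("every arm must have positive length")
  if (length(arms) > 1L) {
    ch <- as.character(GenomicRanges::seqnames(arms))
    s <- GenomicRanges::start(arms); e <- GenomicRanges::end(arms)
    o <- order(ch, s)
    i <- seq_len(length(arms) - 1L)
    if (any(ch[o][i] == ch[o][i + 1L] & s[o][i + 1L] <= e[o][i]))
      stop("arms within a chromosome must not overlap")
  }
  invisible(arms)
}

#' Canonical autosomal chromosome-arm table
#'
#' Returns the bundled hg38 arm table: the 39 canonical autosomal arms
#' (acrocentric p arms 13p/14p/15p/21p/22p excluded), with arm boundaries
#' at the pericentromeric cytobands.  All arm-level metrics in the package
#' are computed over this table unless another is supplied.
#'
#' @param build genome build; only `"hg38"` is bundled.
#' @return A `GRanges` with one range per arm, names like `"1p"`, and
#'   metadata columns `arm` (`"p"`/`"q"`) and `chrom`.
#' @examples
#' arms <- genomeArms()
#' length(arms)  # 39
#' @export
genomeArms <- function(build = "hg38") {
  if (!identical(build, "hg38"))
    stop("only the hg38 arm table is bundled")
  .armsFromTable(.hg38)
}

#' Toy chromosome-arm table for small exact analyses
#'
#' Builds an idealized genome of `n_chrom` metacentric chromosomes, each
#' with a p and a q arm of `arm_length` bases, abutting at the centromere.
#' Used for exact enumeration of the genome-doubling null and for per-base
#' oracle checks.
#'
#' @param n_chrom number of chromosomes.
#' @param arm_length arm length in bases.
#' @return A `GRanges` arm table in the same format as [genomeArms()].
#' @examples
#' makeToyArms(2, 1000)  # a 4-arm, 4-kb genome
#' @export
makeToyArms <- function(n_chrom = 2L, arm_length = 1000L) {
  stopifnot(n_chrom >= 1L, arm_length >= 1L)
  ch <- rep(as.character(seq_len(n_chrom)), each = 2L)
  arm <- rep(c("p", "q"), n_chrom)
  start <- ifelse(arm == "p", 1L, arm_length + 1L)
  end <- ifelse(arm == "p", arm_length, 2L * arm_length)
  gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$arm <- arm
  S4Vectors::mcols(gr)$chrom <- ch
  names(gr) <- paste0(ch, arm)
  gr
}

#' Read or write an arm table as BED
#'
#' BED uses 0-based half-open coordinates; the name column carries the arm
#' label (e.g. `"1p"`).
#'
#' @param path BED file path.
#' @return `readArmsBed()` returns a `GRanges` arm table.
#' @export
readArmsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomeInfoDb::seqlevels(gr) <- .normChrom(GenomeInfoDb::seqlevels(gr))
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) stop("arm BED needs a name column with arm labels")
  out <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gr)),
                                IRanges::IRanges(GenomicRanges::start(gr),
                                                 GenomicRanges::end(gr)))
  S4Vectors::mcols(out)$arm <- sub("^.*(p|q)$", "\\1", nm)
  S4Vectors::mcols(out)$chrom <- as.character(GenomicRanges::seqnames(out))
  names(out) <- nm
  .validateArms(out)
  out
}

#' @rdname readArmsBed
#' @param arms a `GRanges` arm table.
#' @export
writeArmsBed <- function(arms, path) {
  .validateArms(arms)
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(arms)),
                  start = GenomicRanges::start(arms) - 1L,
                  end = GenomicRanges::end(arms),
                  name = names(arms))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
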