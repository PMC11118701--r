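# Variant call-set input/output: flat per-caller TSV tables, per-caller
# VCFs (parsed with VariantAnnotation, AF/DP resolved through a documented
# FORMAT-tag priority), site-list annotation, and a minimal VCF emitter
# for the filtered set.

#' Read a per-caller variant table (TSV)
#'
#' Flat tab-separated table with columns `chrom`, `pos`, `ref`, `alt` and
#' any of the quantitative/flag columns (`tumor_depth`, `tumor_alt_count`,
#' `tumor_af`, `normal_depth`, `normal_af`, `in_dbsnp`, `in_census`,
#' `in_trusted_list`, `artifact_flagged`, `lod`).  Missing flag columns
#' default to `FALSE`.
#'
#' @param path file path.
#' @return `data.frame` of candidate calls.
#' @export
readCallerTable <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("caller table lacks columns: ", paste(miss, collapse = ", "))
  d$chrom <- .normChrom(d$chrom)
  for (col in c("in_dbsnp", "in_census", "in_trusted_list",
                "artifact_flagged"))
    if (!is.null(d[[col]])) d[[col]] <- as.logical(d[[col]])
  .completeCalls(d)
}

#' @rdname readCallerTable
#' @param calls `data.frame` of calls.
#' @export
writeCallerTable <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-caller tumor/normal VCF
#'
#' Parses a VCF with paired tumor and normal sample columns and extracts
#' depths and allele fractions per sample using a tag priority: allele
#' fraction from `AF` if present, else `AD[2]/sum(AD)`; depth from `DP` if
#' present, else `sum(AD)`.  Only single-nucleotide substitutions are
#' returned.
#'
#' @param path VCF path (plain or bgzipped).
#' @param tumor,normal sample column names; default to the first and
#'   second genotype columns.
#' @return `data.frame` of candidate calls in the [readCallerTable()]
#'   layout.
#' @export
readCallerVcf <- function(path, tumor = NULL, normal = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  smp <- colnames(vcf)
  if (length(smp) < 2L) stop("VCF needs tumor and normal sample columns")
  if (is.null(tumor)) tumor <- smp[1L]
  if (is.null(normal)) normal <- smp[2L]
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  alt <- vapply(as.list(altl), function(a)
    if (length(a)) as.character(a[[1L]]) else NA_character_, character(1))
  g <- VariantAnnotation::geno(vcf)
  pull <- function(field, sample) {
    if (!field %in% names(g)) return(NULL)
    x <- g[[field]]
    if (is.list(x) || length(dim(x)) == 3L) x[, sample, ] else x[, sample]
  }
  afs <- function(sample) {
    af <- pull("AF", sample)
    ad <- g[["AD"]]
    if (!is.null(af)) {
      if (is.list(af)) af <- vapply(af, function(v) v[1L], numeric(1))
      return(as.numeric(af))
    }
    if (is.null(ad)) return(rep(NA_real_, length(vcf)))
    adm <- ad[, sample, ]
    if (is.list(adm)) adm <- do.call(rbind, adm)
    as.numeric(adm[, 2L] / rowSums(adm))
  }
  dps <- function(sample) {
    dp <- pull("DP", sample)
    if (!is.null(dp)) return(as.integer(dp))
    ad <- g[["AD"]]
    if (is.null(ad)) return(rep(NA_integer_, length(vcf)))
    adm <- ad[, sample, ]
    if (is.list(adm)) adm <- do.call(rbind, adm)
    as.integer(rowSums(adm))
  }
  t_af <- afs(tumor); t_dp <- dps(tumor)
  d <- data.frame(chrom = .normChrom(GenomicRanges::seqnames(rr)),
                  pos = GenomicRanges::start(rr), ref = ref, alt = alt,
                  tumor_depth = t_dp,
                  tumor_alt_count = as.integer(round(t_af * t_dp)),
                  tumor_af = t_af,
                  normal_depth = dps(normal), normal_af = afs(normal),
                  stringsAsFactors = FALSE)
  snv <- !is.na(d$alt) & nchar(d$ref) == 1L & nchar(d$alt) == 1L
  .completeCalls(d[snv, , drop = FALSE])
}

#' Annotate calls against site or gene lists
#'
#' Sets the membership flags consumed by [consensusFilter()] from plain
#' site lists (`data.frame`s with `chrom`+`pos`, or `chrom`+`pos`+`ref`+
#' `alt`) or a character vector of census gene symbols matched against a
#' `gene` column.
#'
#' @param calls `data.frame` of calls.
#' @param dbsnp,trusted optional site lists.
#' @param census_genes optional character vector of census gene symbols.
#' @return The annotated `data.frame`.
#' @export
annotateCalls <- function(calls, dbsnp = NULL, trusted = NULL,
                          census_genes = NULL) {
  keyOf <- function(d) {
    if (all(c("ref", "alt") %in% colnames(d)))
      paste(.normChrom(d$chrom), d$pos, d$ref, d$alt, sep = ":")
    else paste(.normChrom(d$chrom), d$pos, sep = ":")
  }
  calls <- .completeCalls(calls)
  if (!is.null(dbsnp)) {
    k <- keyOf(dbsnp)
    mine <- if (all(c("ref", "alt") %in% colnames(dbsnp)))
      paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
    else paste(calls$chrom, calls$pos, sep = ":")
    calls$in_dbsnp <- calls$in_dbsnp | mine %in% k
  }
  if (!is.null(trusted)) {
    k <- keyOf(trusted)
    mine <- if (all(c("ref", "alt") %in% colnames(trusted)))
      paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
    else paste(calls$chrom, calls$pos, sep = ":")
    calls$in_trusted_list <- calls$in_trusted_list | mine %in% k
  }
  if (!is.null(census_genes) && !is.null(calls$gene))
    calls$in_census <- calls$in_census | calls$gene %in% census_genes
  calls
}

#' Write filtered SNVs as a minimal VCF
#'
#' Emits a VCF 4.2 file with the supporting caller set, tumor allele
#' fraction and LOD in INFO.  Writing only; per-caller input VCFs are
#' parsed with [readCallerVcf()].
#'
#' @param kept filtered calls (`data.frame`).
#' @param path output path.
#' @param sample_id sample label recorded in the header.
#' @return `path`, invisibly.
#' @export
writeFilteredVcf <- function(kept, path, sample_id = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=cinprecursor consensusFilter; sample=",
                  sample_id),
           "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Supporting callers\">",
           "##INFO=<ID=TAF,Number=1,Type=Float,Description=\"Tumor allele fraction\">",
           "##INFO=<ID=LOD,Number=1,Type=Float,Description=\"Tumor log-odds score\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- character(0)
  if (nrow(kept)) {
    info <- sprintf("CALLERS=%s;TAF=%.4f%s",
                    if (!is.null(kept$callers)) kept$callers else ".",
                    kept$tumor_af,
                    ifelse(is.na(kept$lod), "",
                           sprintf(";LOD=%.2f", kept$lod)))
    lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", kept$chrom,
                     as.integer(kept$pos), kept$ref, kept$alt, info)
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
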