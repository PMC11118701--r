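# Multi-caller somatic SNV consensus filtering and mutational burden.
#
# Candidate calls from up to five somatic callers (Mutect, Varscan2,
# Strelka2, Lancet, SomaticSniper) are merged by site and allele, then
# passed through the consensus cascade: caller-level depth/allele-fraction
# thresholds, a curated trusted-list bypass, a >= 2-caller requirement,
# FFPE-artifact and dbSNP exclusion, and a final evidence clause
# (tumor AF >= 0.04 and LOD >= 10, or membership in the cancer gene
# census).

.CALLERS <- c("mutect", "strelka2", "varscan2", "lancet", "somaticsniper")

.VC_COLS <- c("chrom", "pos", "ref", "alt", "tumor_depth",
              "tumor_alt_count", "tumor_af", "normal_depth", "normal_af",
              "in_dbsnp", "in_census", "in_trusted_list",
              "artifact_flagged", "lod")

.completeCalls <- function(d) {
  for (col in c("in_dbsnp", "in_census", "in_trusted_list",
                "artifact_flagged"))
    if (is.null(d[[col]])) d[[col]] <- FALSE
  if (is.null(d$lod)) d$lod <- NA_real_
  d
}

#' Filter configuration for the SNV consensus cascade
#'
#' Defaults follow the calling thresholds (tumor AF >= 0.02 at depth >= 20,
#' normal AF <= 0.01 at depth >= 10) and the final clause (>= 2 callers,
#' tumor AF >= 0.04, LOD >= 10).
#'
#' @param min_tumor_af_call,min_tumor_depth,max_normal_af,min_normal_depth
#'   caller-level thresholds applied to every candidate.
#' @param min_callers minimum number of supporting callers.
#' @param min_tumor_af_final,min_lod final evidence thresholds.
#' @param error_rate sequencing error rate for the binomial LOD model.
#' @param dbsnp_census_exemption if `TRUE`, census-gene variants are exempt
#'   from the dbSNP exclusion (off by default: the cascade is applied in
#'   its stated clause order).
#' @param trusted_bypass_caller_level if `TRUE`, trusted-list variants also
#'   bypass the caller-level thresholds (off by default: the trusted list
#'   preserves variants from the *downstream* filters only).
#' @return A list of class `FilterConfig`.
#' @export
filterConfig <- function(min_tumor_af_call = 0.02, min_tumor_depth = 20L,
                         max_normal_af = 0.01, min_normal_depth = 10L,
                         min_callers = 2L, min_tumor_af_final = 0.04,
                         min_lod = 10, error_rate = 1e-3,
                         dbsnp_census_exemption = FALSE,
                         trusted_bypass_caller_level = FALSE) {
  stopifnot(min_tumor_af_call >= 0, min_tumor_depth >= 0,
            max_normal_af >= 0, min_normal_depth >= 0, min_callers >= 1L,
            min_tumor_af_final >= 0, min_lod >= 0,
            error_rate > 0, error_rate < 1)
  structure(list(min_tumor_af_call = min_tumor_af_call,
                 min_tumor_depth = as.integer(min_tumor_depth),
                 max_normal_af = max_normal_af,
                 min_normal_depth = as.integer(min_normal_depth),
                 min_callers = as.integer(min_callers),
                 min_tumor_af_final = min_tumor_af_final,
                 min_lod = min_lod, error_rate = error_rate,
                 dbsnp_census_exemption = dbsnp_census_exemption,
                 trusted_bypass_caller_level = trusted_bypass_caller_level),
            class = "FilterConfig")
}

#' Merge per-caller variant tables into a consensus call set
#'
#' Takes one candidate table per caller (a named list of `data.frame`s with
#' at least `chrom`, `pos`, `ref`, `alt` plus depth/AF columns) and returns
#' one record per unique SNV with the supporting caller set accumulated.
#' Depths, allele fractions and annotation flags are taken from the
#' highest-priority caller reporting the variant.  Records that are not
#' single-nucleotide substitutions are dropped with a message; conflicting
#' reference alleles at one position are an error.
#'
#' @param per_caller_calls named list of `data.frame`s; names are caller
#'   labels.
#' @param priority caller priority order for attribute resolution; callers
#'   absent from it are appended in input order.
#' @return `data.frame` of merged calls with a `callers` column
#'   (comma-separated, priority order) and `n_callers`.
#' @export
mergeCallerSets <- function(per_caller_calls,
                            priority = .CALLERS) {
  stopifnot(is.list(per_caller_calls), length(per_caller_calls) > 0,
            !is.null(names(per_caller_calls)))
  callers <- names(per_caller_calls)
  ord <- c(intersect(priority, callers), setdiff(callers, priority))
  pieces <- lapply(ord, function(cl) {
    d <- as.data.frame(per_caller_calls[[cl]])
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% colnames(d)))
      stop("caller table '", cl, "' lacks chrom/pos/ref/alt")
    if (nrow(d) == 0L) return(NULL)
    d <- .completeCalls(d)
    d$caller <- cl
    d
  })
  all <- do.call(rbind, lapply(pieces, function(p)
    if (is.null(p)) NULL else p[, c(intersect(.VC_COLS, colnames(p)),
                                    "caller"), drop = FALSE]))
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame())
  snv <- nchar(all$ref) == 1L & nchar(all$alt) == 1L &
    all$ref %in% c("A", "C", "G", "T") & all$alt %in% c("A", "C", "G", "T")
  if (any(!snv))
    message("dropped ", sum(!snv),
            " non-SNV record(s) (indel or multi-nucleotide)")
  all <- all[snv, , drop = FALSE]
  # reference consistency per site
  site <- paste(all$chrom, all$pos, sep = ":")
  nref <- tapply(all$ref, site, function(r) length(unique(r)))
  if (any(nref > 1L)) {
    bad <- names(nref)[nref > 1L][1L]
    stop("conflicting reference alleles at site ", bad)
  }
  key <- paste(all$chrom, all$pos, all$ref, all$alt, sep = ":")
  first <- !duplicated(key)  # rows are in priority order within rbind
  merged <- all[first, setdiff(colnames(all), "caller"), drop = FALSE]
  support <- split(all$caller, key)
  kk <- key[first]
  merged$callers <- vapply(kk, function(k)
    paste(intersect(ord, support[[k]]), collapse = ","), character(1))
  merged$n_callers <- lengths(support)[kk]
  o <- order(merged$chrom, merged$pos, merged$alt)
  merged <- merged[o, , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Binomial log-odds score for a tumor variant
#'
#' Log10 likelihood ratio of the observed alt-read count under the
#' maximum-likelihood allele fraction `f = alt / depth` versus the
#' sequencing-error model with error rate `e`:
#' `log10( f^a (1-f)^(d-a) / (e^a (1-e)^(d-a)) )`, defined as 0 when
#' `a = 0` (no evidence).  Vectorized over `tumor_alt_count` and
#' `tumor_depth`.
#'
#' @param tumor_alt_count alt-supporting read count(s).
#' @param tumor_depth total depth(s), > 0.
#' @param error_rate per-base error rate in (0, 1).
#' @return Numeric LOD score(s).
#' @export
binomialLod <- function(tumor_alt_count, tumor_depth, error_rate = 1e-3) {
  a <- as.numeric(tumor_alt_count); d <- as.numeric(tumor_depth)
  stopifnot(error_rate > 0, error_rate < 1)
  if (any(d <= 0)) stop("tumor_depth must be > 0")
  if (any(a < 0 | a > d)) stop("alt count must lie in [0, depth]")
  f <- a / d
  t1 <- ifelse(a == 0, 0, a * log10(f / error_rate))
  t2 <- ifelse(d - a == 0, 0, (d - a) * log10((1 - f) / (1 - error_rate)))
  ifelse(a == 0, 0, t1 + t2)
}

#' Consensus filter for candidate somatic SNVs
#'
#' Applies the cascade: (i) caller-level thresholds — tumor AF and depth,
#' normal AF and depth; then (ii) trusted-list variants are kept
#' (preserved from further filtering); otherwise a variant must be
#' (1) detected by at least `min_callers` callers, (2) not flagged as an
#' FFPE-type artifact, (3) absent from dbSNP, and (4) have tumor AF >=
#' `min_tumor_af_final` and LOD >= `min_lod`, *or* lie in a census cancer
#' gene.  Pure function of its inputs; the audit records each rejected
#' variant's first failing clause.
#'
#' A `lod` column, where present and non-`NA`, overrides the
#' [binomialLod()] value computed from depths.
#'
#' @param calls `data.frame` of merged calls (see [mergeCallerSets()];
#'   a `callers` or `n_callers` column is required).
#' @param config a [filterConfig()].
#' @return List with `kept` (the passing subset) and `audit` (one row per
#'   input variant: `chrom`, `pos`, `ref`, `alt`, `kept`, `reason`).
#'   Reasons, in test order: `tumor_af_call`, `tumor_depth`, `normal_af`,
#'   `normal_depth`, `caller_count`, `artifact`, `dbsnp`,
#'   `af_lod_census`; kept variants have reason `pass`.
#' @export
consensusFilter <- function(calls, config = filterConfig()) {
  stopifnot(inherits(config, "FilterConfig"))
  calls <- .completeCalls(as.data.frame(calls))
  n <- nrow(calls)
  if (n == 0L)
    return(list(kept = calls,
                audit = data.frame(chrom = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   kept = logical(), reason = character())))
  if (is.null(calls$n_callers)) {
    if (is.null(calls$callers))
      stop("calls need a 'callers' or 'n_callers' column")
    calls$n_callers <- lengths(strsplit(calls$callers, ","))
  }
  lod <- calls$lod
  computed <- binomialLod(calls$tumor_alt_count, calls$tumor_depth,
                          config$error_rate)
  lod[is.na(lod)] <- computed[is.na(lod)]
  reason <- rep("pass", n)
  fail <- function(cond, code) reason <<- ifelse(reason == "pass" & cond,
                                                 code, reason)
  bypass_cl <- config$trusted_bypass_caller_level & calls$in_trusted_list
  fail(!bypass_cl & calls$tumor_af < config$min_tumor_af_call,
       "tumor_af_call")
  fail(!bypass_cl & calls$tumor_depth < config$min_tumor_depth,
       "tumor_depth")
  fail(!bypass_cl & calls$normal_af > config$max_normal_af, "normal_af")
  fail(!bypass_cl & calls$normal_depth < config$min_normal_depth,
       "normal_depth")
  deep <- !calls$in_trusted_list  # trusted variants skip clauses 1-4
  fail(deep & calls$n_callers < config$min_callers, "caller_count")
  fail(deep & calls$artifact_flagged, "artifact")
  dbsnp_hit <- calls$in_dbsnp &
    !(config$dbsnp_census_exemption & calls$in_census)
  fail(deep & dbsnp_hit, "dbsnp")
  evidence <- (calls$tumor_af >= config$min_tumor_af_final &
               lod >= config$min_lod) | calls$in_census
  fail(deep & !evidence, "af_lod_census")
  kept <- reason == "pass"
  audit <- data.frame(chrom = calls$chrom, pos = calls$pos,
                      ref = calls$ref, alt = calls$alt, kept = kept,
                      reason = reason, stringsAsFactors = FALSE)
  list(kept = calls[kept, , drop = FALSE], audit = audit)
}

#' Tumor mutational burden
#'
#' @param kept filtered somatic calls (`data.frame`) or their count.
#' @param capture_size_mb capture region size in megabases (required for
#'   `mode = "per_mb"`).
#' @param mode `"per_mb"` (mutations per megabase, default) or `"count"`.
#' @return Numeric burden.
#' @export
tmb <- function(kept, capture_size_mb = NULL, mode = c("per_mb", "count")) {
  mode <- match.arg(mode)
  n <- if (is.data.frame(kept)) nrow(kept) else as.numeric(kept)
  if (mode == "count") return(n)
  if (is.null(capture_size_mb) || capture_size_mb <= 0)
    stop("capture_size_mb must be > 0 for per-Mb burden")
  n / capture_size_mb
}
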