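# Seeded simulators for synthetic cohorts with known ground truth: arm-level
# copy-number profiles with and without genome doubling, multi-caller
# somatic variant call sets with planted contaminants, and read sets with a
# known fraction of telomeric reads. Stage defaults mimic the qualitative
# gradients across AAH -> AIS -> MIA -> ADC (WGD prevalence, rising
# aberration and mutation rates, telomere shortening); they are simulation
# choices, not estimates from patient data.

#' Stage parameters for the cohort simulators
#'
#' @param stage histologic stage label (`"AAH"`, `"AIS"`, `"MIA"`,
#'   `"ADC"`).
#' @param n_samples samples to simulate for this stage.
#' @param wgd_probability probability a sample is whole-genome doubled.
#' @param arm_event_rate mean unit arm aberrations per sample (Poisson).
#' @param focal_event_rate mean focal (sub-arm) events per sample
#'   (Poisson); 0 keeps profiles exactly arm-resolution.
#' @param somatic_mutation_rate mean true somatic SNVs per sample
#'   (Poisson).
#' @param telomere_fraction fraction of reads that are telomeric.
#' @param gain_prob probability an arm event is a gain (vs a loss).
#' @return A list of class `StageParams`.
#' @export
stageParams <- function(stage, n_samples, wgd_probability = 0,
                        arm_event_rate = 1, focal_event_rate = 0,
                        somatic_mutation_rate = 50,
                        telomere_fraction = 0.001, gain_prob = 0.5) {
  stopifnot(wgd_probability >= 0, wgd_probability <= 1,
            arm_event_rate >= 0, focal_event_rate >= 0,
            somatic_mutation_rate >= 0,
            telomere_fraction >= 0, telomere_fraction <= 1,
            gain_prob >= 0, gain_prob <= 1)
  structure(list(stage = stage, n_samples = as.integer(n_samples),
                 wgd_probability = wgd_probability,
                 arm_event_rate = arm_event_rate,
                 focal_event_rate = focal_event_rate,
                 somatic_mutation_rate = somatic_mutation_rate,
                 telomere_fraction = telomere_fraction,
                 gain_prob = gain_prob),
            class = "StageParams")
}

#' Default stage parameters
#'
#' WGD probabilities follow the reported stage prevalences (0% AAH, 9%
#' AIS, 9% MIA, 30% ADC); aberration and mutation rates rise monotonically
#' with stage and telomere fractions shrink, mimicking the qualitative
#' progression gradients.
#'
#' @param n_samples samples per stage.
#' @return Named list of four [stageParams()] objects.
#' @export
defaultStageParams <- function(n_samples = 50L) {
  list(
    AAH = stageParams("AAH", n_samples, wgd_probability = 0.00,
                      arm_event_rate = 1, somatic_mutation_rate = 40,
                      telomere_fraction = 0.0009),
    AIS = stageParams("AIS", n_samples, wgd_probability = 0.09,
                      arm_event_rate = 2, somatic_mutation_rate = 80,
                      telomere_fraction = 0.0008),
    MIA = stageParams("MIA", n_samples, wgd_probability = 0.09,
                      arm_event_rate = 3, somatic_mutation_rate = 120,
                      telomere_fraction = 0.0006),
    ADC = stageParams("ADC", n_samples, wgd_probability = 0.30,
                      arm_event_rate = 5, somatic_mutation_rate = 200,
                      telomere_fraction = 0.0005))
}

# one sample's arm states: diploid baseline, optional doubling, Poisson
# unit events with floor at 0 (a loss drawn on an allele at 0 is re-drawn)
.simArmStates <- function(arms, wgd, rate, gain_prob) {
  A <- length(arms)
  st <- matrix(if (wgd) 2L else 1L, nrow = A, ncol = 2L)
  n_ev <- stats::rpois(1L, rate)
  for (i in seq_len(n_ev)) {
    for (try in 1:100) {
      a <- sample.int(A, 1L)
      al <- sample.int(2L, 1L)
      dir <- if (stats::runif(1L) < gain_prob) 1L else -1L
      if (st[a, al] + dir >= 0L) { st[a, al] <- st[a, al] + dir; break }
    }
  }
  # order alleles so the first is the major
  cbind(pmax(st[, 1L], st[, 2L]), pmin(st[, 1L], st[, 2L]))
}

#' Simulate a copy-number cohort with known WGD truth
#'
#' Per sample: every arm starts at the diploid (1,1) state; with
#' probability `wgd_probability` both alleles are doubled; then
#' `Poisson(arm_event_rate)` unit gain/loss events hit random arms and
#' alleles (floored at 0).  Arm-resolution segments are emitted (plus
#' optional focal segments when `focal_event_rate > 0`), with per-segment
#' supporting read counts.  Identical seeds give identical cohorts.
#'
#' @param params list of [stageParams()] (e.g. [defaultStageParams()]).
#' @param arms `GRanges` arm table.
#' @param seed integer seed.
#' @param read_depth mean supporting read count per segment (Poisson).
#' @return List with `profiles` (named list of [SegmentProfile-class]) and
#'   `truth` (`data.frame`: `sample_id`, `stage`, `is_wgd`, `true_ploidy`,
#'   `n_arm_events`).
#' @export
simulateCnCohort <- function(params = defaultStageParams(),
                             arms = genomeArms(), seed,
                             read_depth = 400) {
  if (missing(seed)) stop("seed is required")
  if (inherits(params, "StageParams")) params <- list(params)
  set.seed(as.integer(seed))
  .validateArms(arms)
  A <- length(arms)
  # pre-sorted template GRanges shared by all samples; per-sample work is
  # limited to drawing states and swapping in fresh metadata columns
  ord <- order(as.character(GenomicRanges::seqnames(arms)),
               GenomicRanges::start(arms))
  template <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(arms))[ord],
    IRanges::IRanges(GenomicRanges::start(arms)[ord],
                     GenomicRanges::end(arms)[ord]))
  w <- as.numeric(GenomicRanges::width(template))
  proto <- NULL
  profiles <- list()
  truth <- list()
  for (sp in params) {
    hist <- if (sp$stage %in% c("AAH", "AIS", "MIA", "ADC", "normal"))
      sp$stage else "unknown"
    for (j in seq_len(sp$n_samples)) {
      sid <- sprintf("%s_%03d", sp$stage, j)
      wgd <- stats::runif(1L) < sp$wgd_probability
      st <- .simArmStates(arms, wgd, sp$arm_event_rate, sp$gain_prob)[ord, ,
                                                                     drop = FALSE]
      tot <- as.numeric(st[, 1L] + st[, 2L])
      gr <- template
      gr@elementMetadata <- methods::new("DFrame", listData = list(
        total_cn = tot, major_cn = st[, 1L], minor_cn = st[, 2L],
        n_reads = stats::rpois(A, read_depth)), nrows = A)
      if (sp$focal_event_rate > 0) {
        gr <- .addFocalEvents(gr, stats::rpois(1L, sp$focal_event_rate),
                              read_depth)
        prof <- SegmentProfile(sid, gr, histology = hist)
      } else {
        # arm-aligned segments are valid by construction; reuse a
        # validated prototype and swap slots
        if (is.null(proto))
          proto <- SegmentProfile(sid, gr, histology = hist)
        prof <- proto
        prof@sampleId <- sid
        prof@histology <- hist
        prof@segments <- gr
      }
      profiles[[sid]] <- prof
      tot2 <- S4Vectors::mcols(cnSegments(prof))$total_cn
      w2 <- as.numeric(GenomicRanges::width(cnSegments(prof)))
      truth[[sid]] <- list(
        sample_id = sid, stage = sp$stage, is_wgd = wgd,
        true_ploidy = sum(w2 * tot2) / sum(w2),
        n_arm_events = sum(abs(st - if (wgd) 2L else 1L)))
    }
  }
  truth <- do.call(rbind, lapply(truth, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
  rownames(truth) <- NULL
  list(profiles = profiles, truth = truth)
}

# overlay n focal +/-1 total-CN events (5-20% of an arm) onto arm-level
# segments; events landing on an already-split arm are skipped so segments
# stay disjoint
.addFocalEvents <- function(gr, n, read_depth) {
  if (n <= 0L) return(gr)
  used <- rep(FALSE, length(gr))
  for (i in seq_len(n)) {
    cand <- which(!used)
    if (!length(cand)) break
    k <- cand[sample.int(length(cand), 1L)]
    used[k] <- TRUE
    s <- GenomicRanges::start(gr)[k]; e <- GenomicRanges::end(gr)[k]
    wlen <- max(1L, round((e - s + 1L) * stats::runif(1L, 0.05, 0.2)))
    fs <- s + sample.int(max(1L, e - s + 1L - wlen), 1L) - 1L
    fe <- min(e, fs + wlen - 1L)
    m <- S4Vectors::mcols(gr)[k, ]
    dir <- if (stats::runif(1L) < 0.5 || m$total_cn < 1) 1L else -1L
    mk <- function(a, b, dtot, dmaj, dmnr) {
      g <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(gr)[k]),
        IRanges::IRanges(a, b))
      S4Vectors::mcols(g)$major_cn <- m$major_cn + dmaj
      S4Vectors::mcols(g)$minor_cn <- m$minor_cn + dmnr
      S4Vectors::mcols(g)$total_cn <- m$total_cn + dtot
      S4Vectors::mcols(g)$n_reads <- stats::rpois(1L, read_depth)
      g
    }
    # a gain raises the major allele; a loss takes the minor allele when
    # it is the only way to keep major >= minor >= 0
    dmaj <- 0L; dmnr <- 0L
    if (dir > 0L) dmaj <- 1L
    else if (!is.na(m$minor_cn) && m$minor_cn > 0L) dmnr <- -1L
    else if (!is.na(m$major_cn) && m$major_cn > 0L) dmaj <- -1L
    parts <- list()
    if (fs > s) parts <- c(parts, list(mk(s, fs - 1L, 0, 0L, 0L)))
    parts <- c(parts, list(mk(fs, fe, dir, dmaj, dmnr)))
    if (fe < e) parts <- c(parts, list(mk(fe + 1L, e, 0, 0L, 0L)))
    gr <- c(gr[-k], do.call(c, parts))
    o <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
    gr <- gr[o]
    used <- rep(TRUE, length(gr))  # conservatively freeze after a split
    used[GenomicRanges::width(gr) > wlen] <- FALSE
  }
  gr
}

#' Simulate multi-caller somatic variant call sets
#'
#' Plants three classes of candidate calls: true somatic SNVs (tumor
#' allele fraction drawn from `Beta(af_shape1, af_shape2)`, clipped below
#' at `min_af`; each caller detects each one independently with
#' probability `sensitivity`), dbSNP-listed contaminants (heterozygous-like
#' tumor AF but a clean matched normal, i.e. sites that evade the
#' matched-normal check and must be caught by the dbSNP clause), and
#' FFPE-type artifacts (low AF, flagged by the artifact detectors, seen by
#' two callers).  Depths are Poisson; LOD is left to the filter's binomial
#' model.
#'
#' @param params a [stageParams()] (its `somatic_mutation_rate` sets the
#'   expected number of true somatics).
#' @param seed integer seed.
#' @param callers caller labels to emit tables for.
#' @param sensitivity per-caller detection probability for true somatics.
#' @param n_dbsnp,n_artifact expected contaminant counts (Poisson).
#' @param depth_mean mean tumor depth; the matched normal uses half.
#' @param af_shape1,af_shape2 Beta parameters for somatic allele fractions.
#' @param min_af lower clip for somatic allele fractions.
#' @param census_fraction fraction of true somatics in census genes.
#' @param trusted_fraction fraction of true somatics on the trusted list.
#' @param normal_error_rate per-base noise rate in the matched normal
#'   (set to 0 for a perfectly clean normal).
#' @return List with `calls` (named list of per-caller `data.frame`s) and
#'   `truth` (`data.frame` with `chrom`, `pos`, `ref`, `alt`, `class`).
#' @export
simulateVariantCalls <- function(params, seed,
                                 callers = .CALLERS,
                                 sensitivity = 0.9, n_dbsnp = 30,
                                 n_artifact = 20, depth_mean = 300,
                                 af_shape1 = 2, af_shape2 = 5,
                                 min_af = 0.01, census_fraction = 0.05,
                                 trusted_fraction = 0.02,
                                 normal_error_rate = 0.002) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(params, "StageParams"))
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  mkSites <- function(n) {
    if (n == 0L) return(NULL)
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1))
    data.frame(chrom = as.character(sample.int(22L, n, replace = TRUE)),
               pos = sample.int(1e8L, n), ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }
  n_som <- stats::rpois(1L, params$somatic_mutation_rate)
  som <- mkSites(n_som)
  dbs <- mkSites(stats::rpois(1L, n_dbsnp))
  art <- mkSites(stats::rpois(1L, n_artifact))
  fill <- function(d, class) {
    if (is.null(d)) return(NULL)
    n <- nrow(d)
    d$class <- class
    d$tumor_depth <- pmax(20L, stats::rpois(n, depth_mean))
    d$normal_depth <- pmax(10L, stats::rpois(n, depth_mean / 2))
    d$tumor_af_true <- switch(class,
      somatic = pmin(0.95, pmax(min_af, stats::rbeta(n, af_shape1,
                                                     af_shape2))),
      dbsnp = stats::rbeta(n, 20, 20),
      artifact = pmin(0.3, pmax(0.01, stats::rbeta(n, 1.5, 20))))
    d$tumor_alt_count <- stats::rbinom(n, d$tumor_depth, d$tumor_af_true)
    d$tumor_af <- d$tumor_alt_count / d$tumor_depth
    d$normal_af <- stats::rbinom(n, d$normal_depth, normal_error_rate) /
      d$normal_depth
    d$in_dbsnp <- class == "dbsnp"
    d$artifact_flagged <- class == "artifact"
    d$in_census <- class == "somatic" &
      stats::runif(n) < census_fraction
    d$in_trusted_list <- class == "somatic" &
      stats::runif(n) < trusted_fraction
    d
  }
  all <- rbind(fill(som, "somatic"), fill(dbs, "dbsnp"),
               fill(art, "artifact"))
  if (is.null(all) || nrow(all) == 0L)
    return(list(calls = stats::setNames(
      rep(list(data.frame()), length(callers)), callers),
      truth = data.frame()))
  det <- matrix(FALSE, nrow(all), length(callers),
                dimnames = list(NULL, callers))
  for (ci in seq_along(callers)) {
    p <- ifelse(all$class == "somatic", sensitivity,
                ifelse(all$class == "dbsnp", 0.9, 0))
    det[, ci] <- stats::runif(nrow(all)) < p
  }
  # artifacts are seen by exactly two (random) callers so they reach the
  # artifact clause rather than dying at the caller count
  for (i in which(all$class == "artifact"))
    det[i, sample.int(length(callers), 2L)] <- TRUE
  cols <- c("chrom", "pos", "ref", "alt", "tumor_depth",
            "tumor_alt_count", "tumor_af", "normal_depth", "normal_af",
            "in_dbsnp", "in_census", "in_trusted_list", "artifact_flagged")
  calls <- lapply(seq_along(callers), function(ci) {
    d <- all[det[, ci], cols, drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(calls) <- callers
  truth <- all[, c("chrom", "pos", "ref", "alt", "class", "tumor_af_true")]
  names(truth)[6L] <- "true_af"
  rownames(truth) <- NULL
  list(calls = calls, truth = truth)
}

#' Simulate reads with a known telomeric fraction
#'
#' Emits `round(n_reads * telomere_fraction)` telomeric reads — tandem
#' hexamer arrays mixing the canonical repeat and the ten variants, at a
#' random phase and on a random strand — and fills the remainder with
#' uniform random sequence, then shuffles the order.  Planting an exact
#' count keeps the generated fraction known, so downstream estimation
#' error isolates the classifier.
#'
#' @param n_reads total reads.
#' @param telomere_fraction target telomeric fraction in \[0, 1\].
#' @param read_length read length (>= 30).
#' @param seed integer seed.
#' @param canonical_prob probability each hexamer in a telomeric array is
#'   the canonical TTAGGG (variants fill the rest uniformly).
#' @param path optional FASTQ output path.
#' @return List with `reads` (character vector), `truth` (list:
#'   `n_telomeric`, `true_fraction`), and `path` when written.
#' @export
simulateTelomereReads <- function(n_reads, telomere_fraction,
                                  read_length = 100L, seed,
                                  canonical_prob = 0.7, path = NULL) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_reads >= 1L, telomere_fraction >= 0, telomere_fraction <= 1,
            read_length >= 30L)
  set.seed(as.integer(seed))
  pats <- telomereRepeatSet()
  n_tel <- round(n_reads * telomere_fraction)
  n_bg <- n_reads - n_tel
  tel <- character(0)
  if (n_tel > 0L) {
    n_units <- as.integer(ceiling(read_length / 6) + 2L)
    units <- matrix(ifelse(stats::runif(n_units * n_tel) < canonical_prob,
                           pats$forward[1L],
                           sample(pats$forward[-1L], n_units * n_tel,
                                  replace = TRUE)),
                    nrow = n_tel)
    arr <- do.call(paste0, lapply(seq_len(n_units),
                                  function(j) units[, j]))
    off <- sample.int(6L, n_tel, replace = TRUE)
    tel <- substring(arr, off, off + read_length - 1L)
    flip <- stats::runif(n_tel) < 0.5
    if (any(flip))
      tel[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(tel[flip])))
  }
  bg <- if (n_bg > 0L) {
    stringi::stri_rand_strings(n_bg, read_length, "[ACGT]")
  } else character(0)
  reads <- c(tel, bg)[sample.int(n_reads)]
  out <- list(reads = reads,
              truth = list(n_telomeric = n_tel,
                           true_fraction = n_tel / n_reads))
  if (!is.null(path)) {
    writeFastq(reads, path)
    out$path <- path
  }
  out
}
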