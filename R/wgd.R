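# Randomization test for whole-genome doubling.
#
# A sample is summarized as Ns, the number of unit gain/loss steps its
# arm-level allele profile lies away from diploid, and Ps, a categorical
# distribution over events (arm x allele x direction). The null applies Ns
# sequential events drawn from Ps to a diploid profile and asks how often
# the fraction of arms with major allele copy number >= 2 reaches the
# observed fraction. WGD is then called when ploidy > 3, or when the
# p-value falls below alpha (0.001) for samples at ploidy <= 3.

#' Unit aberration count relative to diploid (Ns)
#'
#' Sums, over arms, the unit steps of each allele away from the diploid
#' (1,1) state: `sum(|major - 1| + |minor - 1|)`.
#'
#' @param arm an [ArmProfile-class].
#' @return Integer count.
#' @examples
#' # a fully doubled 39-arm genome lies 78 unit steps from diploid
#' @export
countAberrations <- function(arm) {
  stopifnot(is(arm, "ArmProfile"))
  as.integer(sum(abs(arm@major - 1L) + abs(arm@minor - 1L)))
}

#' Observed genome-doubling statistic
#'
#' The proportion of chromosome arms whose major allele copy number is
#' at least 2.
#'
#' @param arm an [ArmProfile-class].
#' @return Proportion in \[0, 1\].
#' @export
observedWgdStatistic <- function(arm) {
  stopifnot(is(arm, "ArmProfile"))
  mean(arm@major >= 2L)
}

#' Estimate aberration event probabilities (Ps)
#'
#' For every event (arm, allele in {major, minor}, direction in {gain,
#' loss}) the raw weight is the fraction of cohort samples whose allele at
#' that arm deviates from 1 in that direction.  One pseudo-count is spread
#' uniformly over all events so no event has probability zero (an
#' all-diploid cohort therefore yields the uniform distribution), and the
#' weights are normalized to a categorical distribution.  A single-sample
#' "cohort" gives per-sample probabilities.
#'
#' @param cohort an [ArmProfile-class] or a list of them (all on the same
#'   arm table).
#' @param ns optional integer Ns to store in the model; defaults to the
#'   first profile's [countAberrations()].
#' @return An [AberrationModel-class].
#' @export
estimateAberrationProbs <- function(cohort, ns = NULL) {
  if (is(cohort, "ArmProfile")) cohort <- list(cohort)
  if (length(cohort) == 0L) stop("empty cohort")
  arms <- cohort[[1L]]@arm
  A <- length(arms)
  maj <- vapply(cohort, function(p) {
    stopifnot(identical(p@arm, arms)); p@major
  }, integer(A))
  mnr <- vapply(cohort, function(p) p@minor, integer(A))
  maj <- matrix(maj, nrow = A); mnr <- matrix(mnr, nrow = A)
  raw <- rbind(
    data.frame(arm = arms, allele = "major", direction = "gain",
               w = rowMeans(maj > 1L)),
    data.frame(arm = arms, allele = "major", direction = "loss",
               w = rowMeans(maj < 1L)),
    data.frame(arm = arms, allele = "minor", direction = "gain",
               w = rowMeans(mnr > 1L)),
    data.frame(arm = arms, allele = "minor", direction = "loss",
               w = rowMeans(mnr < 1L)))
  k <- nrow(raw)
  w <- raw$w + 1 / k
  probs <- data.frame(arm = raw$arm, allele = raw$allele,
                      direction = raw$direction, prob = w / sum(w),
                      stringsAsFactors = FALSE)
  if (is.null(ns)) ns <- countAberrations(cohort[[1L]])
  new("AberrationModel", nAberrations = as.integer(ns), probs = probs)
}

# Decompose a probs table into parallel event vectors used by the null
# samplers: allele-slot index (1..2A) and direction sign.
.eventTable <- function(model) {
  p <- model@probs
  arms <- unique(p$arm)
  arm_idx <- match(p$arm, arms)
  allele_idx <- ifelse(p$allele == "major", 1L, 2L)
  slot <- (arm_idx - 1L) * 2L + allele_idx
  sign <- ifelse(p$direction == "gain", 1L, -1L)
  list(arms = arms, A = length(arms), slot = slot, sign = sign,
       prob = p$prob)
}

#' Monte-Carlo null for the genome-doubling statistic
#'
#' Each simulation starts every arm at the diploid (1,1) state and applies
#' `Ns` sequential events drawn i.i.d. from `Ps`: +1 to the sampled allele
#' of the sampled arm for a gain, -1 for a loss.  A loss sampled for an
#' allele already at 0 is re-drawn (up to `max_retries` times, then treated
#' as a no-op), so the null never produces negative copy numbers.  The
#' per-simulation statistic is the proportion of arms whose larger allele
#' is >= 2; the p-value is the proportion of simulations reaching the
#' observed statistic (`>=` by default; `mode = "gt"` gives the strict
#' version, and `correction = TRUE` the (k+1)/(n+1) estimator).
#'
#' @param model an [AberrationModel-class].
#' @param observed_stat observed statistic in \[0, 1\].
#' @param n_sims number of simulations (default 10000).
#' @param seed integer RNG seed; identical seeds give identical results.
#' @param mode `"ge"` (count simulations with statistic >= observed,
#'   default) or `"gt"` (strictly greater).
#' @param correction use the (k+1)/(n+1) p-value estimator.
#' @param max_retries bounded re-draws for invalid losses.
#' @return List with `p_value`, `stats` (per-simulation statistics),
#'   `n_sims`, `seed`.
#' @export
simulateWgdNull <- function(model, observed_stat, n_sims = 10000L, seed,
                            mode = c("ge", "gt"), correction = FALSE,
                            max_retries = 100L) {
  mode <- match.arg(mode)
  stopifnot(is(model, "AberrationModel"))
  if (n_sims < 1L) stop("n_sims must be >= 1")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  ev <- .eventTable(model)
  A <- ev$A
  ns <- model@nAberrations
  state <- matrix(1L, nrow = n_sims, ncol = 2L * A)
  cum <- cumsum(ev$prob)
  cum[length(cum)] <- 1
  draw <- function(n) findInterval(stats::runif(n), cum,
                                   left.open = FALSE) + 1L
  if (ns > 0L) {
    for (t in seq_len(ns)) {
      e <- draw(n_sims)
      idx <- cbind(seq_len(n_sims), ev$slot[e])
      prop <- state[idx] + ev$sign[e]
      bad <- which(prop < 0L)
      r <- 0L
      while (length(bad) && r < max_retries) {
        e2 <- draw(length(bad))
        e[bad] <- e2
        idx[bad, 2L] <- ev$slot[e2]
        prop[bad] <- state[idx[bad, , drop = FALSE]] + ev$sign[e2]
        bad <- bad[prop[bad] < 0L]
        r <- r + 1L
      }
      if (length(bad)) prop[bad] <- state[idx[bad, , drop = FALSE]]  # no-op
      state[idx] <- prop
    }
  }
  ge2 <- state >= 2L
  stats_ <- rowMeans(ge2[, seq(1L, 2L * A, by = 2L), drop = FALSE] |
                       ge2[, seq(2L, 2L * A, by = 2L), drop = FALSE])
  k <- if (mode == "ge") sum(stats_ >= observed_stat - 1e-12)
       else sum(stats_ > observed_stat + 1e-12)
  p <- if (correction) (k + 1) / (n_sims + 1) else k / n_sims
  list(p_value = p, stats = stats_, n_sims = as.integer(n_sims),
       seed = as.integer(seed))
}

#' Exact null for the genome-doubling statistic
#'
#' Dynamic-programming enumeration of the null of [simulateWgdNull()]: the
#' distribution over arm-allele states after `Ns` sequential events is
#' propagated exactly, conditioning each step on drawable events (a loss on
#' an allele at 0 is excluded and its mass redistributed — the limit of the
#' Monte-Carlo re-draw rule as retries grow; with the default 100 retries
#' the two differ by at most the invalid-mass to the 101st power, which is
#' negligible).  Serves as the brute-force oracle for the Monte-Carlo null
#' on small genomes.
#'
#' @inheritParams simulateWgdNull
#' @param max_states guard on the ordered-event-sequence space:
#'   `(4 * n_arms)^Ns` must not exceed it.
#' @return Exact `Pr(statistic >= observed_stat)` (or `>` under
#'   `mode = "gt"`).
#' @export
exactWgdNull <- function(model, observed_stat, max_states = 1e6,
                         mode = c("ge", "gt")) {
  mode <- match.arg(mode)
  stopifnot(is(model, "AberrationModel"))
  ev <- .eventTable(model)
  A <- ev$A
  ns <- model@nAberrations
  if ((4 * A)^ns > max_states)
    stop("event-sequence space exceeds max_states; use simulateWgdNull()")
  start <- rep(1L, 2L * A)
  states <- list(start)
  probs <- 1
  keyOf <- function(s) paste(s, collapse = ",")
  if (ns > 0L) {
    for (t in seq_len(ns)) {
      env <- new.env(parent = emptyenv())
      for (i in seq_along(states)) {
        s <- states[[i]]; ps <- probs[i]
        valid <- !(ev$sign < 0L & s[ev$slot] == 0L)
        mass <- sum(ev$prob[valid])
        if (mass <= 0) {  # nothing drawable: event is a no-op
          k <- keyOf(s)
          prev <- if (!is.null(env[[k]])) env[[k]]$p else 0
          env[[k]] <- list(s = s, p = prev + ps)
          next
        }
        for (j in which(valid)) {
          s2 <- s
          s2[ev$slot[j]] <- s2[ev$slot[j]] + ev$sign[j]
          k <- keyOf(s2)
          add <- ps * ev$prob[j] / mass
          prev <- if (!is.null(env[[k]])) env[[k]]$p else 0
          env[[k]] <- list(s = s2, p = prev + add)
        }
      }
      entries <- as.list(env)
      states <- lapply(entries, `[[`, "s")
      probs <- vapply(entries, `[[`, numeric(1), "p")
    }
  }
  statOf <- function(s) {
    mean(pmax(s[seq(1L, 2L * A, by = 2L)], s[seq(2L, 2L * A, by = 2L)]) >= 2L)
  }
  st <- vapply(states, statOf, numeric(1))
  if (mode == "ge") sum(probs[st >= observed_stat - 1e-12])
  else sum(probs[st > observed_stat + 1e-12])
}

#' Classify whole-genome doubling
#'
#' WGD is called for any sample with mean ploidy above 3; for samples at
#' ploidy <= 3 it is called when the randomization p-value falls below
#' `alpha` (0.001 by default).
#'
#' @param p_value randomization p-value in \[0, 1\] (may be `NA` when
#'   `mean_ploidy > 3`, where it is not consulted).
#' @param mean_ploidy length-weighted mean ploidy, > 0.
#' @param alpha significance cut-off.
#' @return Logical WGD call.
#' @export
classifyWgd <- function(p_value, mean_ploidy, alpha = 0.001) {
  stopifnot(mean_ploidy > 0)
  if (mean_ploidy > 3) return(TRUE)
  if (is.na(p_value)) stop("p_value required for samples with ploidy <= 3")
  stopifnot(p_value >= 0, p_value <= 1)
  p_value < alpha
}

#' Whole-genome-doubling test for one sample
#'
#' Runs the full test: counts Ns, estimates Ps (from the sample itself or
#' from a cohort), computes the observed statistic, simulates the null and
#' applies the classification rule.  For samples whose mean ploidy already
#' exceeds 3 the rule does not consult the p-value, so by default the
#' simulation is skipped there (`pValue` is `NA`); set `lazy = FALSE` to
#' force it.
#'
#' @param arm an [ArmProfile-class].
#' @param n_sims Monte-Carlo simulations (default 10000).
#' @param seed integer RNG seed (required; recorded in the result).
#' @param alpha significance cut-off (default 0.001).
#' @param probs_mode `"per_sample"` (Ps estimated from this sample alone)
#'   or `"cohort"` (Ps estimated from `cohort`).
#' @param cohort list of [ArmProfile-class] used when
#'   `probs_mode = "cohort"`.
#' @param lazy skip simulation when the ploidy rule alone decides.
#' @param mode,correction passed to [simulateWgdNull()].
#' @return A [WGDResult-class].
#' @export
wgdTest <- function(arm, n_sims = 10000L, seed, alpha = 0.001,
                    probs_mode = c("per_sample", "cohort"), cohort = NULL,
                    lazy = TRUE, mode = "ge", correction = FALSE) {
  probs_mode <- match.arg(probs_mode)
  stopifnot(is(arm, "ArmProfile"))
  if (missing(seed)) stop("seed is required")
  obs <- observedWgdStatistic(arm)
  ploidy <- meanPloidy(arm)
  ns <- countAberrations(arm)
  if (lazy && ploidy > 3) {
    return(new("WGDResult", sampleId = sampleId(arm), observedStat = obs,
               pValue = NA_real_, nSims = 0L, ploidyUsed = ploidy,
               isWgd = TRUE, alpha = alpha, seed = NA_integer_))
  }
  if (lazy && obs <= 0 && mode == "ge") {
    # every simulated statistic is >= 0, so p is exactly 1 for any seed
    call <- classifyWgd(1, ploidy, alpha)
    return(new("WGDResult", sampleId = sampleId(arm), observedStat = obs,
               pValue = 1, nSims = as.integer(n_sims), ploidyUsed = ploidy,
               isWgd = call, alpha = alpha, seed = as.integer(seed)))
  }
  model <- if (probs_mode == "cohort") {
    if (is.null(cohort)) stop("cohort required when probs_mode = 'cohort'")
    estimateAberrationProbs(cohort, ns = ns)
  } else estimateAberrationProbs(arm, ns = ns)
  sim <- simulateWgdNull(model, obs, n_sims = n_sims, seed = seed,
                         mode = mode, correction = correction)
  call <- classifyWgd(sim$p_value, ploidy, alpha)
  new("WGDResult", sampleId = sampleId(arm), observedStat = obs,
      pValue = sim$p_value, nSims = sim$n_sims, ploidyUsed = ploidy,
      isWgd = call, alpha = alpha, seed = as.integer(seed))
}

#' Whole-genome-doubling test across a cohort
#'
#' Applies [wgdTest()] to each arm profile, deriving one sub-seed per
#' sample from `seed` so the cohort is reproducible as a whole.
#'
#' @param arm_profiles list of [ArmProfile-class].
#' @param ... passed to [wgdTest()].
#' @inheritParams wgdTest
#' @return A `data.frame` with one row per sample: `sample_id`,
#'   `observed_stat`, `p_value`, `ploidy`, `is_wgd`.
#' @export
wgdTestCohort <- function(arm_profiles, seed, ...) {
  if (missing(seed)) stop("seed is required")
  seeds <- .deriveSeeds(seed, length(arm_profiles))
  rows <- lapply(seq_along(arm_profiles), function(i) {
    r <- wgdTest(arm_profiles[[i]], seed = seeds[i], ...)
    data.frame(sample_id = sampleId(r), observed_stat = observedStat(r),
               p_value = pValue(r), ploidy = r@ploidyUsed,
               is_wgd = isWgd(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# derive n reproducible 31-bit sub-seeds from one master seed
.deriveSeeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
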