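---
title: "Quantifying chromosomal instability in lung adenocarcinoma precursors"
author: "cinprecursor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosomal instability in lung adenocarcinoma precursors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinprecursor)
```

## Scope and data model

Lung adenocarcinoma develops through recognizable precursor stages —
atypical adenomatous hyperplasia (AAH), adenocarcinoma in situ (AIS),
minimally invasive adenocarcinoma (MIA) and invasive adenocarcinoma (ADC)
— and chromosomal instability accumulates along this progression. This
package quantifies that instability from three kinds of input that
standard tumor/normal pipelines already produce:

* **allele-specific copy-number segments** (from any segmentation/purity
  caller), carried as a `SegmentProfile`: a `GRanges` of non-overlapping
  segments with total copy number, integer major/minor allele copy
  numbers, and an optional supporting read count;
* **multi-caller somatic SNV candidate tables** (Mutect, Varscan2,
  Strelka2, Lancet, SomaticSniper), as flat tables or VCFs;
* **sequencing reads** (FASTQ or SAM) for telomere-content estimation.

Segmentation, purity fitting and upstream variant calling are consumed,
never re-implemented. All arm-level work uses a bundled table of the 39
canonical autosomal arms (hg38 cytoband centromeres; acrocentric p arms
excluded). Sex chromosomes are excluded from every metric: their copy
number is confounded by sex, and excluding them makes all samples
comparable. Internally, coordinates follow the native `GRanges`
convention (1-based, closed); the readers normalize the common
1-based-inclusive SEG and 0-based half-open BED dialects into it, and all
length-weighted arithmetic is identical under either convention.

## Arm-level profiles and ploidy

`computePloidy()` summarizes a sample by the length-weighted mean of
total copy number (the "ploidy" consumed by the genome-doubling rule) and
by the length-weighted *median* rounded to the nearest integer, which
anchors the instability metrics. Two numerical conventions are fixed
because no standard exists: an exact 50% tie between two copy-number
values resolves to the lower value, and rounding of halves goes up
(2.5 rounds to 3). Both choices are conservative in the direction of not
inflating aberration calls.

`armProfile()` projects segments onto arms. Each arm's (major, minor)
state is the **length-weighted mode** of the allelic states intersecting
it — a mode rather than a mean, so the result stays an integer allelic
state; segments straddling a centromere contribute their within-arm
length to each side. Ties break toward the lower total copy number, and
arms with no overlapping segment default to the diploid (1,1) state with
a `covered = FALSE` flag: exome profiles have gaps, and absence of
evidence must not create aberrations.

## The whole-genome-doubling randomization test

A doubled genome shows major-allele copy number ≥ 2 on most arms. The
test asks whether the observed proportion of such arms could have arisen
from the sample's own burden of sequential single-arm events, without a
doubling:

* **Ns** — the number of unit steps the arm profile lies from diploid,
  `sum(|major − 1| + |minor − 1|)`. Counting unit steps (not aberrant
  arms) matches a null that applies *sequential* unit aberrations.
* **Ps** — a categorical distribution over events
  (arm × allele × gain/loss). Raw weights are the frequencies, across the
  supplied cohort (or the single sample itself), of each deviation from
  allele copy 1; one pseudo-count is spread uniformly over all events so
  quiet cohorts yield a uniform rather than degenerate null, and the
  table is normalized.
* **Null** — each of 10,000 simulations starts every arm at (1,1) and
  applies Ns events drawn i.i.d. from Ps. A loss drawn for an allele
  already at 0 is re-drawn (bounded at 100 retries, then a no-op), so
  copy numbers never go negative. The per-simulation statistic is the
  proportion of arms whose larger allele is ≥ 2.
* **p-value** — the proportion of simulations whose statistic *reaches*
  the observed one. Counting with `>=` rather than a strict `>` is
  deliberate: under strict counting an all-diploid sample (statistic 0)
  would get p = 0 and every quiet lesion would be called doubled, which
  is absurd. A strict mode and a (k+1)/(n+1) correction are available as
  options.
* **Call** — WGD when mean ploidy exceeds 3, otherwise when p < 0.001.
  Because the rule never consults the p-value above ploidy 3, `wgdTest()`
  skips the simulation there by default (`lazy = TRUE`), recording an
  `NA` p-value; `lazy = FALSE` forces it. For an observed statistic of 0
  the p-value is returned as exactly 1 without simulating — every
  simulated statistic is ≥ 0 by construction, so this is an identity,
  not an approximation.

`exactWgdNull()` is the oracle for the Monte-Carlo null on small
genomes: a dynamic program over the distribution of arm-allele states
that conditions each step on drawable events. Exact conditioning is the
limit of the re-draw rule as retries grow; with 100 retries the two
differ by at most the invalid-mass to the 101st power, far below
Monte-Carlo resolution.

Whether Ps should be estimated per sample or across a cohort is
genuinely ambiguous; both are implemented (`probs_mode`), and per-sample
is the default because it asks the sharper question — "could *this
sample's own* event process have produced its doubled-arm fraction?" —
and needs no cohort context.

## Instability metrics

* **wGII** (`wgii()`): for each autosome, the fraction of its covered
  length whose rounded total copy number differs from the sample's
  integer median ploidy; the index is the unweighted mean of the
  per-chromosome fractions, so each chromosome counts equally regardless
  of size — that per-chromosome weighting is what distinguishes wGII
  from a plain fraction-of-genome-altered, and it makes a uniformly
  tetraploid genome score 0, exactly like a diploid one. Comparing
  *rounded integer* copy number against the *integer* median avoids
  float-equality artifacts.
* **SCNA burden** (`scnaBurden()`): the length fraction of evaluable
  regions with total copy number above 2.5 (gain) or below 1.5 (loss);
  segments supported by fewer than 50 reads are excluded from numerator
  and denominator alike.
* **Aneuploid-chromosome count** (`aneuploidChromosomeCount()`): the
  number of autosomes with at least one arm whose major + minor differs
  from the integer median ploidy. This is an arm-level integer proxy for
  mosaic-aneuploidy detection from allele-frequency mixture models; it
  flags the same chromosomes when aberrations are clonal but is not
  numerically equivalent to a mixture-model count, and no such
  equivalence is claimed.
* **Focal gene calls** (`geneCnCalls()`): gene copy number is the
  length-weighted mean total copy number over overlapping segments
  (the summarization is unspecified in common practice; the mean is the
  least surprising choice), called gain at ≥ 3 and loss at ≤ 1.

## SNV consensus filtering

Candidates from up to five callers are merged by (chromosome, position,
ref, alt) with the caller set accumulated; depths and allele fractions
come from a fixed caller priority (Mutect, Strelka2, Varscan2, Lancet,
SomaticSniper). Indels and multi-nucleotide records are dropped with a
message — the final set is SNVs only. The cascade then keeps a variant
iff it passes the caller-level thresholds (tumor AF ≥ 0.02 at depth
≥ 20; normal AF ≤ 0.01 at depth ≥ 10) **and** either sits on the curated
trusted list, or satisfies all of: ≥ 2 callers, not artifact-flagged
(FFPE-type errors marked upstream), not in dbSNP, and
(AF ≥ 0.04 with LOD ≥ 10, **or** in a census cancer gene).

Two parsing decisions deserve a note. First, the final clause is read as
`(AF ∧ LOD) ∨ census` — the only precedence under which low-AF hotspot
mutations in census genes survive, which is the stated purpose of the
census rescue. Second, the trusted list bypasses the downstream clauses
but *not* the caller-level thresholds, because curation protects known
somatic sites from over-filtering, not from having essentially no read
support; `trusted_bypass_caller_level = TRUE` widens the bypass if
wanted. A config flag can also exempt census sites from the dbSNP clause
(off by default; the cascade is applied in its stated order).

The LOD score is supplied as a binomial log10 likelihood ratio of the
observed alt count under the maximum-likelihood allele fraction versus a
sequencing-error model (default error rate 10⁻³), defined as 0 at zero
alt reads; an input LOD column, when present, overrides the computed
value. `tmb()` reports the kept-variant count, per megabase of capture
region by default (40 Mb is a typical comprehensive exome).

Every rejection is audited with the *first* failing clause in cascade
order, so `kept ∪ rejected` always partitions the input and filter
changes are diffable.

## Telomere content

Reads are classified telomeric when densely tiled by telomeric hexamers:
the canonical TTAGGG plus the ten variant repeats TCAGGG, TGAGGG,
TTGGGG, TTCGGG, TTTGGG, ATAGGG, CATGGG, CTAGGG, GTAGGG, TAAGGG, with the
reverse complement of each for C-rich-strand reads. Matching is greedy,
left-to-right and non-overlapping — for equal-length patterns that
attains the maximum non-overlapping count, which also makes
classification exactly invariant under reverse-complementing a read. The
two strand families are counted separately and the larger count is used.
The default density threshold of 6 repeats per 100 bp (scaled to read
length) follows the published default of repeat-count-based telomere
quantification tools; it is configurable. A fast prescreen skips the
full regex scan for reads that lack even the required number of GGG/CCC
tracts, which cannot change any classification.

Content is reported as telomeric reads per million reads. No GC-bias
correction is applied — none is specified for this analysis, and the
relative telomere length `RTL = log2(tumor content / normal content)` on
matched pairs from the same platform largely cancels such biases. The
log2 scale is the default (negative = shortening); a linear-ratio mode
exists.

## The synthetic cohorts

The simulators generate data *with the statistical structure the
analysis assumes*, so every stage is testable without patient data:

* `simulateCnCohort()` — per sample: diploid arms, doubling with the
  stage's probability, then Poisson-many unit gain/loss events on random
  arms/alleles (floored at 0), emitted as arm-resolution segments (plus
  optional focal sub-arm events) with Poisson read support.
* `simulateVariantCalls()` — true somatics (Beta-distributed allele
  fractions, binomial read counts, per-caller detection), dbSNP-listed
  contaminants with a clean matched normal (the sites that *only* the
  dbSNP clause can catch), and FFPE-type artifacts flagged for the
  artifact clause.
* `simulateTelomereReads()` — telomeric reads as tandem hexamer arrays
  (70% canonical by default, random phase and strand) against uniform
  random background. The telomeric read count is planted *exactly* as
  `round(n · f)` — the module's contract is a read set with a *known*
  fraction — so estimation error isolates the classifier rather than
  mixing in sampling noise.

Stage defaults mimic the qualitative progression gradients: WGD
probabilities (0, 0.09, 0.09, 0.30) for AAH/AIS/MIA/ADC, arm-event rates
(1, 2, 3, 5), expected somatic mutation counts (40, 80, 120, 200) on a
40 Mb exome, and telomere fractions shrinking from 9×10⁻⁴ to 5×10⁻⁴.
These are simulation choices that reproduce the reported *direction* of
each trend, not estimates from controlled-access patient data, and the
package claims no numeric correspondence to any cohort. All generators
take explicit seeds and use no hidden global state; identical seeds give
byte-identical output files.

What passing tests on these cohorts shows — and what it does not: the
generators emit clonal integer arm states, independent callers, and
uniform-random background reads. Real lesions add subclonality, purity
dilution, correlated caller errors, GC and mappability structure, and
FFPE damage beyond a binary artifact flag. Recovery results here
therefore validate the *implementations* (the test's calibration, the
filter's logic, the estimators' consistency), not performance on tissue.

## Problem sizes and numerical choices

The shipped checks use: a 4-arm toy genome for exact-vs-Monte-Carlo
calibration of the doubling null (Ns up to 6, 10,000 simulations per
point, agreement within 3 Monte-Carlo SE); 200 + 200 samples for
doubling sensitivity/specificity (both ≥ 0.95 at α = 0.001); 20
cohorts of 200 samples per stage for prevalence recovery inside exact
95% binomial intervals; 50 random 100-kb profiles for exact per-base
wGII agreement; 1,000 randomized calls against an independently coded
boolean oracle for the filter; 100,000-read sets at telomere fractions
0.001–0.05 (recovery within 3 binomial SE, RTL −1 ± 0.05 at a halved
content); and 50 replicate cohorts of 50 samples per stage for the
stage-wise Kruskal–Wallis signal on wGII and TMB (≥ 90% rejection at
0.05). Tolerances follow from the corresponding exact or binomial
sampling distributions rather than ad hoc margins.

## Known limitations

* The aneuploidy count is an arm-level proxy (see above), and wGII on
  sparse exome profiles depends on segment coverage of each chromosome.
* The doubling test models unit events only; it does not time doubling
  relative to mutations and makes no purity adjustment.
* The filter consumes artifact flags; it does not re-derive them.
* Telomere content has no GC correction and no per-repeat composition
  spectrum; chromosome-end assignment is out of scope.
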