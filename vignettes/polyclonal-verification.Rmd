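---
title: "Consensus somatic mutation calling and verification in polyclonal tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus somatic mutation calling and verification in polyclonal tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyclonesmc)
```

## The problem

Somatic single-nucleotide mutations (SSMs) in a bulk tissue sample are
detectable from matched target/reference sequencing only when enough of the
sampled cells carry them. A heterozygous mutation carried by a cell fraction
$f$ in a diploid sample has expected variant allele frequency (VAF) $f/2$;
somatic callers operating on medium-coverage data (10--40x) typically need a
VAF of about 0.15 to emit a call, so roughly

$$ f_\min = t \cdot \frac{\mathrm{ploidy}}{\mathrm{copies}} = 0.15 \cdot \frac{2}{1} = 30\% $$

of the sampled cells must belong to the mutated clone. Airway brushings are
the canonical counter-example: they harvest cells from several square
centimetres of epithelium containing very many small clones (each presumably
in the sub-millimetre range), so each clone's private mutations are diluted
far below this limit. The consensus call sets that the standard
tumour/normal machinery produces on such samples consist almost entirely of
artifacts — a negative result that this package makes reproducible as a
property of the method, using a synthetic clone-mixture generator.

## The pipeline

`run_pipeline()` orchestrates the full analysis from one `run_config()`:

1. **Simulation** — clone mixtures per subject, annotation tracks, shared
   sequencing reads, shared data artifacts, then one emulated call set per
   caller personality.
2. **Consensus** — `combine_callsets()` intersects the per-caller call sets
   on position alone (union and k-of-n are available for comparison);
   `dice()` quantifies concordance as $S = 2|A \cap B| / (|A| + |B|)$;
   `evaluate_calls()` scores any call set against a truth set by predicted
   position only.
3. **Confidence tiering** — `annotate_calls()` flags each consensus call
   against the common-SNP, repeat and 50-mer-mappability tracks and applies
   `assign_tier()`: *high* = no SNP, not repetitive, unique; *low* = SNP
   overlap, or repetitive *and* non-unique; *medium* = no SNP and exactly
   one of the two region problems. This is the only reading of the tier
   definitions under which the three classes partition all eight flag
   combinations; the test suite enumerates them. Rare or unknown-frequency
   SNPs never affect the tier — they enter only the stringent re-assessment
   flags (depth $\ge 20$ in both tissues, zero reference-tissue variant
   reads, no overlap with any catalogued SNP).
4. **Burden metrics** — `smc_power()` counts base pairs with depth $\ge 10$
   in both tissues (the callable genome), `burden()` normalises call counts
   per callable Mb, `imd()` computes within-chromosome intermutation
   distances for rainfall-style review.
5. **Verification** — `select_candidates()` draws a fixed quota per tier
   (default 30) under the study constraints (all nonsynonymous/splice calls
   forced in, at least one call per subject, no chrY). `simulate_pileups()`
   produces ultra-deep amplicon observations for every candidate in every
   sample; `classify_vaf()` applies the decision matrix; `adjudicate()`
   resolves indeterminate values against the other samples;
   `assign_outcome()` maps each candidate to one of five outcome
   categories; `extrapolate()` scales the confirmed fractions to the
   per-tier call totals and reports the genome-wide false-positive
   fraction.
6. **Detection limit** — `min_cell_fraction()` and
   `detection_probability()` (exact binomial tail, no normal
   approximation) quantify when a clone-private mutation is callable at
   all.

## The VAF decision matrix

For one verification measurement (depth $D$, VAF $v$), with good coverage
meaning $D > 1000$:

| condition | class |
|---|---|
| $v < 0.01$ | reference |
| $0.20 \le v \le 0.80$ | heterozygous |
| $v > 0.80$ | homozygous |
| $0.05 \le v < 0.20$ and $D > 1000$ | subclonal |
| otherwise ($0.01 \le v < 0.05$, or $0.05 \le v < 0.20$ at $D \le 1000$) | indeterminate |

Boundary inclusivity follows the verbal definitions ("below 1%", "between
20 and 80%", "over 80%", coverage "> 1000") read as written: the subclonal
and heterozygous intervals are left-closed, homozygous and good coverage are
strict. All boundaries are arguments of `classify_vaf()`. Depth 0 is a
distinct no-data marker, not an indeterminate value.

Indeterminate values were resolved manually in the original experiment by
comparison with the same position in other samples. `adjudicate()` encodes
that comparison as a rule: with $b$ the median VAF of the other samples at
the position, the observation resolves to *reference* when
$v \le \max(2b,\, 0.01)$ (a shared background signal) and to *subclonal*
otherwise (a sample-elevated signal). The factor 2 and the 1% floor are
configurable; every resolution is recorded with the background median used
as evidence. A position observed in a single sample stays indeterminate and
the candidate's outcome becomes *unclear*.

Outcome categories: *confirmed_somatic* requires a subclonal target-tissue
class, a reference blood class, and no variant signal in any other
subject's samples — the strictest consistent reading of "clearly higher VAF
in the brush than in the blood". Heterozygous/homozygous in both target
tissues is a *germline_polymorphism*; variant signal in both target tissues
or subclonal signal in several subjects is *subclonal_shared*; reference in
both is *absent*; class patterns matching none of these definitions (for
example a heterozygous brush over a reference blood, which no planted data
type produces) are reported as *unclear* rather than silently absorbed into
a neighbouring category.

## What the simulator emulates — and what it does not

A `CloneMixture` is a set of clones with fractions summing (with an
infiltrate of mutation-free cells, default 10%, matching >90% epithelial
purity of brushings) to 1. Each clone carries private heterozygous
mutations; germline variants are shared by all cells. Read counts are
binomial at the mixture-implied VAF, with depth Poisson by default
(negative binomial dispersion and a fixed-depth mode are available);
sequencing error is off by default so the binomial oracles in the tests are
exact.

Three caller personalities emulate the observed contrast between tools: two
permissive callers (~1 private false positive per Mb, VAF thresholds 0.10
and 0.15) and one restrictive caller (~0.1/Mb, threshold 0.15), each with a
2% miss rate on detectable mutations — consistent with the high per-caller
sensitivity observed when the intersection strategy was validated on clonal
cancer data. Private false positives are enriched tenfold on common-SNP
positions. All callers of one subject interpret the *same* sampled reads
(`sample_mutation_reads()`): real tools run on the same alignments and
differ in their decision rules, not in the data. Without this, intersection
recall would decay as the product of per-caller recalls, and the validated
"marginal recall loss" property could not hold.

Two further ingredients let the consensus contain calls at all in the
brushing regime, as observed in practice:

* **shared data artifacts** (`simulate_artifacts()`, rate
  `artifact_rate_per_mb`): positions where the data themselves carry a
  spurious somatic-looking signal. Every caller sees them, so they survive
  the intersection; at amplicon depth they vanish (outcome *absent* —
  "sequencing or mapping inaccuracies"). They are placed preferentially
  (weight 5) in repetitive or non-unique regions, which drives them into
  the lower confidence tiers.
* **hidden germline variants** (`n_hidden_germline` per subject, default
  10): real heterozygous germline variants whose blood evidence is lost
  (substandard reference coverage), so every caller miscalls them as
  somatic. Because germline variants are catalogued polymorphisms, the
  pipeline adds all germline positions to the SNP tracks
  (`augment_snp_tracks()`), sending these miscalls to the low tier, where
  verification reveals them as *germline_polymorphism* — the characteristic
  low-tier outcome.

The generator does **not** emulate read-level effects (mapping, base
quality, strand bias), mutational signatures, copy-number alterations, or
spatial clone geometry (no quantitative clone-area data exist for airway
epithelium; clone fractions are exposed as configuration, drawn from a
symmetric Dirichlet by default). Passing tests therefore demonstrate that
the *decision logic* — consensus, tiering, selection, decision matrix,
extrapolation, detection limit — behaves as specified under the stated
statistical model; they do not certify caller behaviour on real
alignments.

## Default study conditions

| parameter | default | rationale |
|---|---|---|
| depth, target / reference tissue | 20x / 27x | medium-coverage design; brushings sequence worse than blood |
| amplicon pileup depth | 27,000x | the verification experiment's median coverage |
| clones per brushing mixture | 200 (Dirichlet, conc. 1) | "very many small clones": every fraction far below the 30% limit |
| mutations per clone | 5 | cumulative loads of hundreds to thousands per sample |
| germline variants / hidden | 100 / 10 | hidden share drives the SNP-overlap excess of consensus calls |
| caller VAF thresholds | 0.10, 0.15, 0.15 | the typical minimal VAF of common somatic callers |
| artifact rate | 0.05 per Mb | of the order of the observed consensus call burden per callable Mb |
| track coverage | repeat 55%, unique 77%, common SNP 0.5%, all SNP 5% | the annotation tracks' genome fractions |
| SMC-power threshold | depth 10 in both tissues | minimal positional depth somatic callers require |
| verification quota | 30 per tier | the experiment's design |
| good coverage | 1000 | decision-matrix cutoff for subclonal calls |

Tests and examples run on genome slices of 0.1--0.5 Mb with 2--12 subjects
and per-tier quotas of 10--30; these sizes keep the suite fast while leaving
the statistical structure (clone dilution, caller contrast, track
fractions) intact. At slice scale the absolute artifact *count* would be
near zero at 0.05/Mb, so end-to-end demonstrations raise
`artifact_rate_per_mb` (e.g. to 100/Mb on 0.2 Mb) to obtain per-subject
call counts of the same order as a genome-wide analysis; the rate is a
scale knob, not a biological claim.

## Numerical choices and degenerate inputs

* Matching key everywhere is (chromosome, position); `chr` prefixes are
  stripped for matching only. Duplicate positions within one call set keep
  the first record and log the rest.
* BED tracks are 0-based half-open, VCF positions 1-based; conversion
  happens exactly once, at track construction.
* The Dice coefficient of two empty sets is undefined and returned as `NA`
  with a warning; precision of an empty call set is reported as 0 with a
  warning, recall is computed normally.
* `extrapolate()` refuses a tier that has calls but no tested candidates
  (the estimate would be undefined); candidates that received no pileup
  data (failed assays) are dropped from testing with a message, so tested
  counts may be smaller than selected counts.
* Tier quotas: forced inclusions and subject-coverage repairs count against
  their own tier's quota; subjects are repaired in sorted order with one
  uniformly drawn eligible call each, which keeps the selection
  deterministic under a seed without solving an assignment problem.
* `detection_probability()` sums the exact binomial tail
  $P[X \ge \max(m, \lceil tD \rceil)]$; the minimum-supporting-reads
  parameter defaults to $m = 3$ (callers do not publish this; $m = 0$
  recovers the pure-threshold model).

## Known limitations

* Consensus attribute reconciliation takes one reporting caller's values
  (default: the restrictive caller, configurable); no per-field merging.
* No statistical uncertainty accompanies the extrapolated false-positive
  fraction, mirroring the original analysis.
* The IMD output supports manual rainfall review only; no automated
  kataegis or outlier rule is applied.
* Functional class (nonsynonymous / splice site) is an input attribute of
  calls, not computed from sequence context.
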