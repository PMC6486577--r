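---
title: "Models and methods behind recseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind recseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recseq)
```

# The assay and its statistic

A site-specific recombinase (SSR) is offered a vast in vitro library of
candidate target sites in which one half-site is partially randomized:
each randomized position carries the wild-type base with probability
0.79 and each of the other three bases with probability 0.07. Molecules
the enzyme recombines become exonuclease-resistant; everything else is
digested. Sequencing the input library and the survivors turns substrate
preference into counting.

The per-position statistic is an odds ratio. At half-site position $i$,
let $A_i$ and $B_i$ be the post-selection read counts of the canonical
base and of the three non-canonical bases combined, and let $\alpha_i$,
$\beta_i$ be the same quantities as pre-selection fractions. The
enrichment score is

$$r_i = \frac{A_i / B_i}{\alpha_i / \beta_i}.$$

$r_i$ is the factor by which selection shifts the canonical-vs-rest odds
at that position; $r_i = 1$ means indifference. We work with one
half-site at a time (the selection chemistry only reports mutations on
the two half-sites that survive into the product), and assemble
full-site profiles by concatenating a left-randomized and a
right-randomized experiment. Positions are numbered outward from the
core — 5 to 17 for a 13-bp half-site around an 8-bp core, right-half
labels primed — so "position 10" names the same ring of the
protein:DNA interface in either half.

Per-base resolution uses the canonical-normalized frequency-ratio matrix
$e_{i,b} = \left(F^{post}_{i,b}/F^{pre}_{i,b}\right) \big/
\left(F^{post}_{i,c}/F^{pre}_{i,c}\right)$, whose canonical cell is 1
(log2 = 0) by construction. The per-base formula is a reconstruction
from the heat-map convention (log2 enrichment of each nucleotide
relative to the canonical base); the canonical-vs-rest $r_i$ is the
primary statistic.

## Numerical choices

- **Pseudocount.** 0.5 is added to $A$, $B$ and to the pre-library
  canonical/non-canonical counts before any ratio. Zero cells otherwise
  produce infinite scores; at the assay's typical 10^5–10^6 reads the
  bias is below 10^-4 relative. Configurable everywhere it appears.
- **Replicate aggregation** is the positionwise geometric mean of $r_i$
  (and of $e_{i,b}$): enrichment scores are ratios, and the geometric
  mean is the only mean that commutes with taking reciprocals. A single
  replicate aggregates to itself; order never matters.
- **Ties and degeneracies** in the statistics module are handled
  explicitly: a zero-variance paired difference with non-zero mean is
  reported as p → 0 with a warning rather than NaN; positionwise t
  statistics with zero pooled variance and equal means give t = 0,
  p = 1.

# Read extraction and the mismatch filter

Reads are anchored on the constant core, which must match exactly — the
core is held fixed in the library (recombination requires complementary
cores between partners), so a read without a perfect core is unusable.
The randomized half-site and the UMI are sliced at fixed offsets
relative to the core; the reverse complement is tried when the forward
strand fails. No gaps are allowed anywhere: a read carrying an indel in
the half-site shifts out of frame against the reference and inflates its
gap-free mismatch count, which is exactly how such reads are removed —
any read with more than six half-site mismatches is discarded. The
boundary is inclusive: six mismatches survive, seven do not. Quality
scores are ignored (no quality filtering is part of the method).

Two small corner cases are resolved by rule. If the 8-bp core happens to
occur twice on the matched strand (a ~0.2% event when a random UMI or a
junction spells it out), the leftmost occurrence is used and the event
is counted in the filter report; the exact-recovery guarantee of the
simulator round-trip therefore applies to single-core reads. Reads whose
slices would run off either end are classed `fail_malformed`, and the
filter report always satisfies
`total = kept + fail_no_core + fail_malformed + fail_too_many_mismatches`.

# The selection simulator as a stated world

The generator emulates the experiment end to end so that every
downstream statistic can be checked against ground truth:

- **Library**: per-position independent draws, canonical fraction 0.79
  (the assay's synthesis design; this makes 13 × 0.21 = 2.73 expected
  mutations per half-site), a uniform random UMI per molecule (10 nt by
  default — the real oligo design is not public, so the length is
  configurable), constant flanks standing in for the hairpin/priming
  regions.
- **Selection**: a molecule with half-site $s$ recombines with
  probability $p_{max} \prod_i w_{i,s_i}^{\gamma}$, weights in (0, 1]
  with canonical weight 1. Multiplicative independence is the simplest
  model consistent with recognition through many weak interactions, and
  is sufficient to exercise every pipeline statistic. The stringency
  exponent $\gamma$ is a protein:DNA-ratio analogue: $\gamma = 0$
  reproduces the specificity erosion seen with excess enzyme (every
  substrate accepted at the same rate).
- **Background**: non-recombined molecules survive digestion
  independently with probability $\varepsilon$, carrying their own UMIs
  into the post pool. The assay does not quantify exonuclease
  survival, so $\varepsilon$ has no anchored default; tests exercise
  $\varepsilon \in \{0, 0.01, 0.1\}$.
- **Reads**: per-molecule counts are zero-truncated Poisson($\mu$),
  binomially thinned when the total overshoots the requested depth;
  molecules can drop out, as in reality. Substitution errors are applied
  per base; quality strings are constant. Identical seed and
  configuration give bit-identical FASTQ and manifest.

Under independence and $\varepsilon = 0$ the enrichment score has the
closed form

$$r^{*}_i \;=\; \frac{\beta}{\sum_{b \neq c} \alpha_b\, w_{i,b}^{\gamma}},
\qquad \alpha_b = \tfrac{1-f}{3},\; \beta = 1-f,$$

independent of $p_{max}$ and of all other positions
(`expected_enrichment()`). This is the oracle the pipeline is validated
against: with error-free reads at 2×10^5 depth, measured $r_i$ lands
within 10% of $r^*_i$ at every position.

What the generator does **not** model: PCR bias and chimeras, quality
deterioration, UMI sequencing errors (deduplication is exact string
match, as in the analysis), supercoiled-substrate geometry, and any
cooperativity between positions. A green test therefore establishes that
the pipeline measures what the independent-position model puts in — not
that real enzymes are position-independent.

# The quality score κ

Each experiment gets a score κ from the relationship between variant
abundance and distinct-UMI support: ordinary least squares of the
distinct UMI count of each half-site variant against its percent read
abundance, slope divided by 10^4. With homogeneous read sampling every
point sits near $u = (M/100)\,x$ for $M$ captured molecules, so
κ ≈ M/10^6 — the number of unique recombination events captured, in
millions. Averaged over replicates, κ_avg > 1.5 marks a well-powered
experiment, 0.5–1.5 modest background influence, and < 0.5 heavy
background influence (boundaries fall in the middle band).

The regression orientation is an interpretive decision: read literally,
"percent abundance versus number of UMIs" would put abundance on the
response side and give slopes far below any reported κ; regressing UMIs
on abundance reproduces both the reported magnitudes and the stated
meaning of κ as captured events. The literal orientation remains
available (`orientation = "abundance_on_umi"`). Note a consequence the
κ ≈ M/10^6 identity makes explicit: surviving background molecules are
*also* unique molecules, so adding background at fixed activity raises
M (and κ) while flattening the profile — κ flags background dominance
through low *activity* (few captured events relative to the fixed
background level), not through the background reads themselves.

# Replicate statistics

All tests operate on log2 enrichment values.

- **Per position**: two-sample pooled-variance (equal-variance) t-test
  of a variant enzyme's replicates against the reference enzyme's, with
  Bonferroni correction over the full-site positions of that enzyme
  (26 for a Cre-family site); significance is called on adjusted
  p ≤ 0.05.
- **Whole profile**: the residual of each replicate × position is its
  log2 enrichment minus the *reference group's* positionwise mean — the
  paper names only "the residuals", so the reference-mean definition is
  recorded as a reconstruction. The pooled absolute residuals of the two
  groups are compared with a two-sided Mann–Whitney U test, Bonferroni
  over the number of enzyme variants in the batch. The U statistic's
  p-value is exact by full enumeration of all $\binom{n_1+n_2}{n_1}$
  group assignments for pooled sizes up to 12 (correct under ties), and
  a tie-corrected normal approximation with continuity correction
  beyond; the two agree within 0.02 at the crossover.
- **Asymmetry**: left and right half-site values at the same center-out
  position number are paired and tested with a paired two-sided t-test;
  a palindromic preference gives t = 0.

Under the null (both groups from one neutral model), the per-position
false-positive rate after Bonferroni stays below 0.05 — conservatively
so, since Bonferroni controls the familywise rate at that level.

The feature matrix (replicates × full-site log2 enrichments) is exported
exactly; the similarity embedding for visualisation is delegated to
classical multidimensional scaling, which is deterministic — the
embedding algorithm itself is explicitly not part of this package's
scope.

# Pseudosite scanning

Positions whose aggregate (geometric-mean) enrichment strictly exceeds
the threshold (default 2) are fixed at the target's canonical base; all
other positions, and the whole core, become N. Leading and trailing
all-N runs are trimmed by rule — applied to the published Tre and Brec1
profiles this reproduces their printed 26- and 24-symbol search strings
exactly. The genome scanner tests every window on both strands: N
matches any of A/C/G/T, genome ambiguity codes match nothing, overlapping
hits are all reported, and coordinates are 0-based half-open on the
forward strand (BED keeps this convention; the TSV adds nothing
1-based — convert on export if needed). Each hit's surrounding full-site
frame (trim offsets restored) is compared against the cognate site
outside the core to annotate the non-core mismatch count; no ranking is
imposed — the published work validated a hand-picked eight sites per
enzyme by an unstated criterion, so selection among hits is left to the
user.

# Known limitations

- Only one half-site is randomized per experiment, so epistasis between
  half-sites is invisible — a property of the assay, inherited here.
- The simulator's independence assumption means parameter-recovery tests
  cannot detect biases that only appear under positional coupling.
- The mismatch filter conditions both pools on ≤ 6 mismatches, which
  perturbs $r_i$ slightly relative to the unfiltered closed form
  (well under the 10% validation tolerance at the default library
  design).
- Desk-scale simulations can never reach κ_avg > 1.5 (that requires
  millions of captured molecules), so power classification is exercised
  on its thresholds and on heavy-background fixtures, not on a
  simulated well-powered experiment.
- Site definitions for rox, loxV, attP and attB ship as placeholders:
  their half-site/core partitions and numbering origins (e.g. a 2-bp
  core serine-integrase site) vary by convention, so they must be
  supplied explicitly rather than guessed.
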