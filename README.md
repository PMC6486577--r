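# recseq

Profiling the DNA specificity of site-specific recombinases (SSRs) from
in vitro selection experiments read out by high-throughput sequencing.

Site-specific recombinases such as Cre directly catalyze cleavage, strand
exchange and rejoining of DNA at defined target sites (for Cre, the 34-bp
*loxP*: two 13-bp inverted-repeat half-sites flanking an asymmetric 8-bp
core). Their promise as genome-editing agents is limited by how hard it
is to understand — let alone retarget — their sequence preferences. This
package implements the analysis side of a selection-sequencing assay that
answers, position by position, *which bases an SSR requires in its target
site*: a partially randomized substrate library (79% wild-type base, 21%
equimolar other bases at each randomized position, one half-site
randomized at a time) is exposed to the recombinase, non-recombined
molecules are destroyed by exonucleases, and both the input library and
the survivors are sequenced.

For each half-site position *i* (numbered 5–17 outward from the core for
Cre-family sites), the per-position enrichment score is

    r_i = (A_i / B_i) / (alpha_i / beta_i)

where `A_i` and `B_i` are the post-selection counts of the canonical base
and of the three non-canonical bases summed, and `alpha_i`, `beta_i` are
the corresponding pre-selection (input library) fractions. `r_i > 1`
means the enzyme prefers the canonical base at that position. Per-base
heat-map matrices (log2 enrichment of each nucleotide relative to the
canonical base), geometric-mean replicate aggregation, a UMI-based
experiment quality score κ (slope of distinct-UMI count against percent
variant abundance, / 10^4; κ_avg > 1.5 = well-powered), replicate
significance tests (equal-variance t per position with Bonferroni
correction, Mann–Whitney U on absolute profile residuals, paired t for
left/right asymmetry) and enrichment-driven genomic pseudosite scanning
(positions with r > 2 fixed at the canonical base, everything else N)
complete the pipeline. A selection simulator with a closed-form
expected-enrichment oracle provides ground truth for every statistic.

## Worked example

Simulate a selection experiment with known per-position preferences, run
the read-level pipeline, and compare with the closed form:

```r
library(recseq)

site <- builtin_site("loxP")
spec <- library_spec(site, randomized_side = "left")      # 79/21 library
weights <- uniform_weights(site, "left", w = 0.5)          # non-canonical w = 0.5
model <- selection_model(weights, site, "left", gamma = 1)

sim <- simulate_recseq(spec, model,
                       sim_config(n_molecules = 5e4, n_reads = 4e4, seed = 7),
                       out_dir = "sim")

layout <- read_layout(site, "left")
pre  <- filter_reads(extract_reads(sim$pre_fastq,  layout))
post <- filter_reads(extract_reads(sim$post_fastq, layout))
pre$report
#>                    total                     kept             fail_no_core
#>                    39786                    39421                        0
#>           fail_malformed fail_too_many_mismatches               multi_core
#>                        0                      365                        0

profile <- enrichment_profile(tally_counts(pre$kept,  site, "left"),
                              tally_counts(post$kept, site, "left"))
round(profile_r(profile), 2)
#>    5    6    7    8    9   10   11   12   13   14   15   16   17
#> 2.02 1.92 1.95 1.94 2.03 2.04 1.93 2.04 2.01 1.96 1.99 1.86 1.95
expected_enrichment(model, spec)[1]
#> 5
#> 2
```

Every measured `r_i` sits near the closed-form expectation
`r* = 0.21 / (3 × 0.07 × 0.5) = 2`: the simulated enzyme penalizes every
non-canonical base two-fold, and the pipeline recovers that from raw
FASTQ. The 365 reads dropped by the mismatch filter (> 6 half-site
mismatches) are genuine library molecules from the tail of the
mutation-count distribution. The quality score scales with captured
unique molecules:

```r
k <- kappa_score(umi_stats(post$kept))
k
#> kappa = 0.012 (slope 118.8, r^2 1.000, 2844 variants)
classify_power(k$kappa)$label
#> [1] "heavy_background"
```

κ·10^6 ≈ 11,900 — the number of distinct molecules surviving selection
in this deliberately small simulation; a desk-scale run is always
"heavy_background" by the wet-lab thresholds (κ_avg > 1.5 needs millions
of captured events).

Off-target prediction from an aggregate full-site profile:

```r
full <- assemble_full_site(left_profile, right_profile)
motif <- build_motif(full, threshold = 2)   # r > 2 positions, core = NNNNNNNN
hits <- scan_pseudosites(motif, "genome.fa")
write_hits_bed(hits, motif, "pseudosites.bed")
```

## Layout

- `R/` — target-site model, simulator (`simlib`), read extraction
  (`readio`), enrichment (`enrich`), quality (`quality`), statistics
  (`stats`), pseudosite scanning (`offtarget`), pipeline orchestration.
- `inst/cli/recseq` — command-line entry point (`simulate`, `run`,
  `scan`, `fixture`).
- `inst/extdata/sites.conf` — bundled site definitions (loxP, loxLTR,
  loxBTR) and placeholders for user-supplied sites.
- `vignettes/recseq-methods.Rmd` — model, assumptions, parameter and
  design rationale.
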