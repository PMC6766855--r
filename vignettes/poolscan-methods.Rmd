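---
title: "Pool-seq exome association scanning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-seq exome association scanning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The experiment this package models

`poolscan` analyses pooled-library ("Pool-seq") exome data from a
discriminating-dose insecticide bioassay. The emulated design is the one used
to map deltamethrin resistance in a field population of *Aedes aegypti*:
several hundred females are exposed to a single discriminating concentration;
individuals still active after exposure are scored *knockdown-resistant*,
individuals knocked down and never recovering are scored *susceptible*, and
individuals that recover during the observation window are set aside because
their phenotype is ambiguous. DNA from 25 individuals per phenotype class is
pooled into a sequencing library, in duplicate, giving four libraries
(resistant 1/2, susceptible 1/2). Allele frequencies are estimated from read
counts at every exome site, so each site is a small contingency table of
nucleotide counts rather than a set of genotype calls.

All pipeline stages operate on this count representation: a
`pool_counts` object holds an `n_sites x 4 x n_libraries` array of A/C/G/T
counts plus the library design.

## Site selection

Sites enter the association scan only after a four-stage cascade
(`filter_sites()`), applied per phenotype group and then intersected:

1. **Depth window.** Every library of the group must have between
   `min_depth` = 25 and `max_depth` = 1000 reads (inclusive). The floor
   guards the frequency estimates; the ceiling removes collapsed repeats
   masquerading as high-coverage sites.
2. **Replicate concordance.** A Pearson χ² compares the nucleotide counts of
   the two replicate libraries on the 2 × *n* table of observed bases, with
   *n* − 1 degrees of freedom; sites with p below `heterogeneity_alpha` are
   removed.
3. **Cross-group intersection.** Only sites retained by both groups are
   analysed, so every comparison uses the same site universe.
4. **Polymorphism call.** In counts pooled over all four libraries the
   second-most-frequent base must reach `min_minor_count` = 2 reads *and*
   `min_minor_freq` = 1% frequency. Both thresholds are configurable and
   recorded in the `filter_report`.

### Why the concordance default is stringent

The replicate χ² treats reads as the only source of noise. But two replicate
pools of 25 individuals are different samples of 50 chromosomes each from the
phenotype class, so their underlying allele frequencies differ before any
sequencing happens. At depth *d* per library and pool size *N* (diploid), the
variance of the replicate frequency difference is inflated over the
read-sampling variance by roughly

$$ 1 + \frac{d}{2N}\,\Big(1 - \tfrac{2N}{\text{class chromosomes}}\Big), $$

about 2.5–3 at 150× with pools of 25. A conventional α = 0.05 would therefore
discard on the order of a quarter of genuinely concordant polymorphic sites —
including, with double-digit probability, the causal locus itself. Published
replicate frequencies for validated resistance loci show exactly this
composition spread (e.g. 0.88 vs 0.73 in resistant replicates at the
*vgsc* V410L site) and were retained in the original analysis, so the filter
cannot have acted at a conventional frequency-test threshold. The package
default is `heterogeneity_alpha = 1e-8`: the filter targets gross technical
discordance (sample swaps, paralogous mis-mapping) and leaves composition
noise to the replication design. The parameter is exposed for users who want
the stricter behaviour.

A related empirical note: with a nonzero miscall rate, error reads create
low-count allele columns that enter *n* and raise the degrees of freedom
without raising the statistic, which makes the (n − 1)-df test conservative
(removal ≈ 3.6–4% at nominal 5%). Calibration checks in the test suite
therefore use a miscall-free technical null, where the empirical removal rate
matches α within Monte-Carlo error.

## Association and FDR control

Replicate counts are **summed** within each group (never averaged), and each
polymorphic site is scored by a Pearson χ² on the 2 × *n* group-by-allele
table (`association_test()`, vectorised in `associate_sites()`):

* *n* counts the alleles observed in the pooled table; columns with zero
  counts in both groups are dropped and df = *n* − 1;
* no continuity correction and no pseudocounts;
* the score is −log₁₀(p); p-values that underflow double precision are
  reported at a configurable cap (default −log₁₀ p = 320) and flagged.

Benjamini–Hochberg control is applied separately per chromosome
(`bh_thresholds()`, α = 0.01 by default): sort the m p-values, find the
largest k with p(k) ≤ kα/m, and flag every site with p ≤ p(k) — the standard
step-up tie convention. The reported per-chromosome threshold is −log₁₀ of
the least significant passing p-value, the same scale on which the original
study reported thresholds of 3.39/3.52/3.22.

The scan assumes significant SNPs are independent. They are not — the sweep
region around the causal locus is one large dependent block — but linkage
structure in the sampled populations is unknown, so the package reproduces
the published procedure rather than attempting an LD-aware correction.

### What the null simulations show

Because read counts are conditionally binomial *given the pool*, while the
pools themselves vary, the association χ² is anti-conservative under a
cohort-level null (no causal locus, survival independent of genotype): its
statistic is inflated by the same composition factor as above, and BH cannot
repair miscalibrated p-values. In 100 null simulations at the default design,
essentially every run yields at least one "discovery", i.e. the realised
false-discovery proportion is ~1 rather than ≤ α. This is a property of the
published method, faithfully reproduced — not an implementation artefact: on
a *technical* null in which all four libraries resample the same pooled
chromosomes (`draw_pools(share_groups = TRUE)`), the same chain of
χ² + per-chromosome BH is well calibrated (mean FDP ≈ 0.02–0.04 at α = 0.01).
Practically this means the scan's FDR statements should be read as
*read-sampling* FDR; biological replication (the duplicate pools and the
concordance filter) and effect ranking carry the inferential weight, which is
how the original study used the scores. An effective-sample-size correction
would fix calibration but would change the published method, so it is out of
scope here.

## Sweep diagnostics

At every FDR-passing SNP the expected heterozygosity
$H_{exp} = 1 - \sum_i p_i^2$ is computed per group from the group-pooled
read counts (`sweep_records()`), consistent with the association table; the
maximum for nucleotide data is 0.75. A recent sweep around a resistance locus
depresses diversity specifically in survivors, so per chromosome the paired
difference Het(alive) − Het(dead) is tested against zero with a two-sided
one-sample t test (`het_difference_test()`), and a chromosome is called
*sweep = Y* only when the mean difference is negative **and** p < 0.05 — a
directional call reported alongside the two-sided p, mirroring the
published table layout. `region_profile()` windows the significant SNPs
around a focal gene (default flank 1.4 Mb) with gene boundaries attached for
plotting.

Degenerate inputs follow fixed conventions: fewer than two finite differences
returns NA statistics and sweep = N; identical nonzero differences return
p = 0; identically zero differences return t = 0, p = 1.

## Category enrichment

`category_polymorphism_enrichment()` asks whether genes of a category
(default `"detox"` = CYP ∪ CCE ∪ GST ∪ Redox) carry an excess of polymorphic
sites. The denominator is **all** filter-passing analysed sites, polymorphic
or not — this is the only reading consistent with published per-chromosome
denominators (e.g. 3932 detox sites on one chromosome against 306 polymorphic
ones). Each per-chromosome 2 × 2 table is tested with an exact Fisher test
(`fisher_exact_2x2()`) computed by accumulating hypergeometric mass over the
full support of the table, so it remains exact at margins in the millions;
the two-sided p follows the minimum-likelihood convention of standard
statistical software. A caution for readers comparing against printed
values: one published "Fisher exact" p for such a table (6.906 × 10⁻¹³) is
actually the continuity-corrected χ² p for the same counts — the genuinely
exact two-sided p is 1.147 × 10⁻¹¹. The package reports the exact value and
the acceptance script recomputes both.

## Pool-vs-genotype validation

`genotype_allele_counts()` converts individual genotypes (RR/RS/SS) of the
pooled mosquitoes into allele counts (2·RR + RS out of 2n), and
`frequency_concordance()` compares two allele-count vectors — replicate vs
replicate, or library reads vs genotyping — with the exact Fisher test and
the Pearson heterogeneity χ², declaring concordance when both p ≥ 0.05. The
library side uses raw read counts, not counts rescaled to the pool's 50
chromosomes; read depth exceeds chromosome count, so these comparisons are
somewhat anti-conservative — a documented caveat, kept because read counts
are what the data provide.

## The synthetic-data generator

`sim_config()` / `simulate_experiment()` generate the full study design with
known truth. Defaults, with the reasoning behind them:

| parameter | default | why |
|---|---|---|
| `n_individuals_exposed` | 390 | the study's bioassay cohort |
| `survival_probs` | RR 0.9, RS 0.3, SS 0.02 | gives ≈38% knockdown-resistant, matching the observed 149/390, with strongly dominant-but-leaky protection |
| `recovery_prob` | 0.39 | ≈24% of the cohort recovered (93/390); recovered individuals are labelled and excluded from pooling |
| `pool_size`, `n_replicates` | 25, 2 | the study's duplicate 25-female pools, drawn without replacement |
| `n_chromosomes`, `sites_per_chromosome`, `site_spacing` | 3, 2000, 500 bp | three chromosomes at a desk-scale density (1 Mb each); test problems scale this down further |
| `polymorphic_fraction` | 0.064 | the study's observed 6.4% polymorphic share |
| `maf_range` | U(0.05, 0.5) | neutral standing variation detectable at pooled depth |
| `resistant_allele_freq` | 0.5 | intermediate frequency after a decade of field selection |
| `depth_mean`, `depth_dispersion` | 150, 10 (negative binomial) | ≈40 M × 100 bp reads over a 26.7 Mb target imply ~150×; size 10 gives CV ≈ 0.33, typical of hybrid capture, and exercises the 25/1000 depth window |
| `error_rate` | 0.002 | Illumina-scale miscall rate, uniform over the three other bases |
| `linked_block_size` | 200 kb | span of distance-decaying association with the causal site |
| `marker_retention_max` | 0.8 | even adjacent markers track the swept haplotype imperfectly: the sweep acted on standing variation spread over several backgrounds |
| `marker_background_freq` | U(0.55, 0.7) | sweep markers also segregate at high frequency off the swept background; because H_exp is concave, this yields strong heterozygosity loss in survivors with only modest group frequency divergence, so the causal site remains the top-ranked association |

The haplotype model is deliberately minimal: each chromosome copy carries a
resistant (R) or susceptible (S) founder background at the causal site with
probability `resistant_allele_freq`; a polymorphic site at distance *d*
within the linked block "retains" that background with probability
`marker_retention_max · (1 − d/L)` — retained copies carry the marker allele
on R backgrounds and the background frequency on S backgrounds; non-retained
copies draw from the marginal marker frequency. This produces group
divergence that decays monotonically with distance (verified as a property
test over 100 seeds) without simulating recombination histories. Phenotype
is Bernoulli in the causal genotype's survival probability; knocked-down
individuals recover with `recovery_prob`, independent of genotype, and are
excluded from pooling — a simplification (real recovery is likely
genotype-biased) that does not matter downstream because recovered
individuals are never sequenced.

Sequencing draws per-site depth from the negative binomial (constant depth
via `depth_dispersion = Inf` for calibration experiments), read alleles
binomially from the pool's 50 chromosomes, and miscalls each read to a
uniformly chosen different base with `error_rate`; counts always sum to the
drawn depth. One master seed feeds per-stage substreams (cohort, pooling,
sequencing, reference emission), so each stage is independently reproducible;
identical seed and configuration reproduce the experiment bit for bit.

Recovery calibration of these defaults (150 seeds): the causal SNP is the
top-ranked score on its chromosome in 98% of runs; the causal chromosome is
flagged sweep Y in 99% and non-causal chromosomes N in 97%.

**What the generator does not emulate:** genome-scale LD block structure away
from the causal region (neutral sites are independent); selection over
multiple generations; capture-probe GC bias and mappability artifacts;
indels and multi-allelic variants beyond miscall noise; genotype-dependent
recovery. Passing recovery tests therefore demonstrate the pipeline's
statistical behaviour under the design's sampling structure, not robustness
to every artifact of real capture data.

## Numerical conventions

* Coordinates are 1-based inclusive throughout (the GFF3/R convention);
  conversion to 0-based half-open happens only in the BED writer.
* χ² tables: columns absent from both rows are dropped before computing the
  statistic and df; monomorphic tables return (0, 0, 1); all-zero input is
  an error.
* BH ties: all sites with p ≤ p(k) are flagged.
* p underflow: −log₁₀ p capped at 320 and flagged.
* Fisher two-sided ties use the customary 1 + 10⁻⁷ relative tolerance.
* Gene models: the canonical transcript is the one with the longest total
  CDS; UTRs are taken from explicit features when present, otherwise derived
  as exonic sequence outside the CDS span, oriented by strand; genes whose
  CDS length is not a multiple of 3 are flagged and excluded from codon
  effects; positions inside overlapping genes yield one annotation per gene
  with a warning.
* Multi-allelic SNPs: the reported alternate allele is the most frequent
  non-reference base in the pooled counts.

## Problem sizes

Unit and property tests run the generator at 400–1200 sites per chromosome;
recovery and error-control studies use the default 2000 sites per chromosome
over 50 seeds and 500 sites per chromosome over 100 seeds respectively —
sizes chosen so the full suite completes in a few minutes on one CPU while
keeping every Monte-Carlo bound meaningful. Residue numbering in annotation
labels is local to the supplied CDS; cross-species numbering conventions
(e.g. house-fly sodium-channel numbering) are a reporting concern outside
the package's scope.
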