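---
title: "Methods: island calling, chromatin states, DMR testing, and multi-omic integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: island calling, chromatin states, DMR testing, and multi-omic integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitriad)
```

# The biological setting

Mammary epithelium contains a progenitor-enriched CD44+ fraction and a
differentiated luminal CD24+ fraction. Their regulatory differences are
visible in three molecular layers measured here as tag counts: H3K4me3 (K4,
an active promoter mark) and H3K27me3 (K27, the Polycomb repressive mark)
from ChIP-seq; gene expression from SAGE-seq; and DNA methylation from
MSDK-seq, where a methylation-sensitive restriction enzyme cuts only
unmethylated sites so that *fewer* tags at a site mean *more* methylation.
An embryonic stem cell (hES) chromatin layer serves as the developmental
reference: promoters bivalent (K4 + K27) in hES resolve toward active or
repressed states during lineage commitment, and tracking those resolutions
across the two mammary fractions is one of the package's central outputs.

All coordinates are 0-based half-open throughout; a single convention
eliminates off-by-one drift between BED input, interval arithmetic, and
output. Tag positions for counting are the 5' ends of aligned reads (no
fragment-shift extension by default).

# Island calling

Enrichment is domain-scale for both marks studied here, so the caller is a
spatial-clustering method rather than a peak-summit model.

1. **Windowing.** Each chromosome is tiled with non-overlapping windows of
   `window_size` bp (default 200). The background rate per window is
   λ_bg = N·w / (G·f_eff), with N the library size, G the genome length and
   f_eff = 0.74 the effective (mappable) genome fraction.
2. **Eligibility.** A window is eligible if its count reaches the smallest
   integer l₀ whose Poisson upper-tail probability under λ_bg is below
   `eligibility_p` (default 0.2). This is deliberately permissive: eligibility
   only nominates windows, it does not declare significance.
3. **Gap merging.** Eligible windows separated by at most `gap_size` bp of
   ineligible windows (default 3 windows = 600 bp, inclusive at exactly the
   gap) merge into candidate islands. Island spans therefore always consist
   of whole windows.
4. **Scoring.** An island's score is Σ −ln P(kᵢ; λ_bg) over its eligible
   member windows — reconstructable from the window counts, which the test
   suite asserts.
5. **Significance.** The island's chip count is compared with the matched
   input count by the exact conditional binomial test for two Poisson rates:
   conditional on n = chip + control, chip ~ Binomial(n, N_chip/(N_chip +
   N_control)) under equal per-tag rates, tested one-sided for enrichment.
   Benjamini–Hochberg q-values are computed across all candidates and
   islands pass at q < 0.001.

**Why the exact conditional test.** A common shortcut treats the scaled
control count as a *known* Poisson mean for the chip count. With deeply
sampled islands that is harmless, but for small candidate islands the
control count is itself a noisy Poisson draw: a 1–3-window candidate with a
lucky zero control (probability e^−λ per window) looks wildly significant
even when chip and control came from identical rates. On featureless
simulations that construction produced dozens of q < 0.001 islands per toy
genome; conditioning on the total removes the control's sampling noise
exactly, and null runs then produce zero islands. The same test (two-sided)
is the DMR test below, so the package uses one canonical two-Poisson-rate
comparison everywhere. When no control library exists, the caller falls
back to a Poisson tail against λ_bg × (span/w) — exact under its stated
null, since the background mean is then a model constant rather than an
estimate.

**Domain-scale preset.** `bloc_params()` switches to 10 kb windows (gap 30
kb) for broad-domain detection. At that window size the background mean is
in the hundreds, and a 0.2-tail eligibility rule would leave ~20 % of
*background* windows eligible, letting random gap-bridging stitch spurious
10–40 kb extensions onto real domains — enough to push a sub-threshold
domain over the 100 kb bloc cutoff. The preset therefore tightens
`eligibility_p` to 0.001, keeping the expected number of spuriously eligible
windows per toy genome near zero while fold ≥ 2 domains remain far above
threshold. At 200 bp windows the classic 0.2 default is kept, where counts
are sparse and the rule behaves as intended.

# Blocs

A bloc is an island from the 10 kb preset whose span is at least 100 kb
(configurable); islands are not merged beyond the caller's own gap rule.
Genes belong to a bloc when their TSS lies inside it — the TSS is the
unambiguous transcriptional control point, whereas any-overlap would make
membership depend on gene length. Per-expression-class occupancy fractions
(`bloc_gene_fractions()`) report, for each class, the fraction of its genes
with TSS inside a bloc; a class with no genes is reported as missing, not as
zero.

# Chromatin states and the 64-pattern table

A gene carries a mark in a cell type when its TSS ± 5 kb promoter window
overlaps an enriched island by ≥ 1 bp (the weakest rule consistent with
"overlap"; a minimum-overlap option exists). K4/K27 booleans give the four
states — bivalent, K4-only, K27-only, neither — an exhaustive, exclusive
partition. Across three cell types there are 4³ = 64 ordered patterns;
seven of them, all starting bivalent in hES, are the named resolution
categories 1–7 (Biv-K4-K4, Biv-K4-Biv, Biv-K4-K27, Biv-Biv-K4, Biv-K27-K4,
Biv-Biv-Biv, Biv-K27-K27). Genes missing a state in any cell type are
excluded from the table and counted in an attribute rather than silently
dropped. hES states may alternatively be supplied as a precomputed
gene-to-state table when that layer comes from published data rather than
tag libraries.

# Expression classes

Counts are normalized to tags per 10 million (the same scaling convention
used for coverage tracks). Classification per gene:

* **not-expressed** — maximum normalized count across all libraries below
  `expressed_floor` (default 5 tags per 10 million; the floor is a
  configurable convention, as "low/no detectable expression" has no
  canonical cutoff);
* **CD44-high / CD24-high** — pseudocounted fold (x+1)/(y+1) ≥ `min_fold`
  (default 2) in at least `consistency` of all cross-replicate library
  pairs (default all pairs, the strictest reading of "consistent");
* **no-difference** otherwise.

Pseudocount 1 on the normalized scale keeps folds defined at zero counts.
Group comparisons of expression use the two-sided Wilcoxon rank-sum test.

# DMR testing

Replicate libraries are pooled per cell type (counts and totals summed) —
between-cell-type variation dominates between-individual variation in this
design, and a per-replicate mode remains available. Each site's pooled
counts (x_A, x_B) with totals (N_A, N_B) are tested by the exact
conditional binomial test: under equal per-tag rates, x_A | x_A + x_B = n ~
Binomial(n, N_A/(N_A+N_B)); the two-sided p-value sums all outcome
probabilities no greater than the observed one (minimum-likelihood
convention, with a 1+1e−7 relative guard against ties lost to floating
error; doubling-one-tail is the conventional alternative). n = 0 returns
p = 1. Sites at p < 0.01 are DMRs, directional by rate deficit: the cell
type with the lower normalized count is the hypermethylated one, because
the enzyme cuts only unmethylated DNA. Equal normalized rates are never
directional regardless of p.

Sites link to genes within ±150 kb of the TSS with strand-aware signed
distances (positive downstream). Promoter is [−5 kb, +2 kb), gene body
[+2 kb, gene end) — mutually exclusive by construction. Positional
association profiles bin links at 5 kb (the plot range is stated as ±150 kb;
the bin width is a display-resolution choice) and normalize expression-class
fractions within each bin; the same profile computed over *all* sites,
without the significance filter, is the control. Mean-expression contrasts
per (region, direction) group are tested against genes linked to any site
in the same region class.

# Integration

Per-gene records join chromatin booleans per cell type, the expression
class, and promoter/gene-body DMR directions. Mark context around DMRs uses
±5 kb flanks for the broad K27 mark and ±0 bp for punctate K4. Joint
patterns (expression class × K27 status in a cell type × DMR direction in a
region) are tested by Fisher's exact test on the 2×2 pattern-by-DMR table.
The background universe for each test is the set of genes carrying at least
one restriction site in the tested region class — the assay only samples
enzyme sites, so testing against all genes would confound site presence
with methylation. Observed/expected ratios come from the table margins; raw
p-values are reported alongside BH-adjusted values across the scanned
family. Degenerate tables (an empty margin) are flagged untestable rather
than given a p-value.

# The synthetic-data generator

`simulation_config()` assembles a toy genome, a gene table, a per-gene truth
profile (expression class, chromatin state per cell type, planted DMR
directions), broad K27 domains, optional free-standing planted islands, and
restriction-site methylation fractions. Ground truth
(`ground_truth()`) is a pure function of the configuration; randomness
enters only when libraries are drawn, each from its own deterministic
sub-seed of the master seed, so any single library is reproducible in
isolation and changing the seed changes draws but not expectations.

* **ChIP.** Tag 5' positions are drawn from a piecewise-constant Poisson
  intensity — background everywhere, background × fold inside planted
  features (max fold where features overlap) — with segment weights scaled
  so the expected total matches the configured library size. Input
  libraries are the featureless case.
* **SAGE.** Per-gene counts are Poisson at library size × relative
  abundance; differential genes multiply a base abundance by the fold in
  their high cell type; abundance-0 genes never produce a tag.
* **MSDK.** Site counts are Poisson at library size × site weight ×
  (1 − methylation fraction); a fully methylated site is silent.

The default desk-scale configuration (`default_simulation_config()`) is a
2 × 10 Mb genome with 300 evenly spaced genes in truth groups that exercise
every stage: 40 CD44-high genes whose promoters are K4 in CD44 and K27 in
CD24 (bivalent in hES), 40 reciprocal CD24-high genes, constitutively
active, bivalent, silent-K27, and unmarked groups; five ≥ 100 kb K27 domains
over progenitor-specific and silent gene clusters; promoter DMRs planted on
the silenced side of differential genes and gene-body DMRs on the active
side (the repressive-promoter / permissive-gene-body coupling); and one
promoter plus one gene-body restriction site per gene with a 400-site
intergenic lattice, methylated 0.9 vs 0.1 at planted DMRs and 0.3/0.3
elsewhere.

Defaults were chosen once for desk-scale statistical power: chip libraries
of 1e5 tags (background ≈ 1.35 tags per 200 bp window — the sparse regime
window-eligibility is designed for, matching deep real libraries on a
gigabase genome), SAGE 2e5 and MSDK 1e5 tags with two replicates per cell
type, expression fold 4 with the low side placed below the expression
background (so that promoter-methylated silenced genes sit below average),
and island folds 5–8. Planted-island recovery demonstrations use fold 10 on
10 kb islands, the regime where boundary recovery (Jaccard ≥ 0.8) is
expected; at marginal folds the caller still detects islands but their
boundaries fray, which is a property of the data, not the implementation.

**What the generator does not emulate:** read sequences, sequencing error,
GC and mappability bias, copy-number variation, overdispersion beyond
Poisson, correlated local backgrounds, isoform structure, or tag-to-gene
assignment ambiguity. Passing tests therefore demonstrate the correctness
of the statistical machinery and the pipeline plumbing under the stated
noise model — not robustness to the full messiness of real libraries, where
input-library structure and overdispersion matter.

# Numerical and design choices

* Duplicate tags are identical (chrom, 5' start, strand) triples; the
  default only reports the duplicate fraction, with collapsing opt-in,
  since duplicate percentages are a QC quantity while collapsing is a
  downstream hygiene decision.
* Multiple transcripts per gene id collapse to the longest span.
* Gap runs exactly equal to `gap_size` merge (inclusive).
* BH is used wherever an FDR is quoted; q ≥ p always holds within a ranked
  list.
* Empty classes/groups propagate as missing values, never as zeros.
* Problem sizes used by the test suite and the acceptance script: 300-gene
  toy genomes, 1,000–20,000 restriction sites, 10 planted islands, and
  libraries of 1e3–1e6 tags — sized so a full run takes seconds to a couple
  of minutes on one core.

# Known limitations

* The island caller has no redundancy (duplicate-read) threshold applied
  internally; apply `deduplicate()` first if desired.
* Bloc detection does not merge islands across gaps beyond the caller's gap
  rule; a merge option records that ambiguity but defaults to off.
* The exact conditional DMR test is conservative at very low totals
  (discreteness), visible as a type-I error fraction slightly below nominal
  in the null calibration.
* SAGE classification has no overdispersion model; with real biological
  replicates a dispersion-aware framework would be the natural extension.
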