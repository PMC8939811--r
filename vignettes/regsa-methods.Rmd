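---
title: "Controlled integration of regulatory interactions into gene-set analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlled integration of regulatory interactions into gene-set analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regsa)
library(dplyr)
```

## The problem

Gene-set analyses for GWAS summary statistics proceed in three steps: map
single-nucleotide variants (SNVs) to genes, aggregate the SNV-level
association p-values into per-gene scores, and test functionally defined
gene sets for enrichment of association relative to all other genes. The
mapping step is decisive. Proximity-based mappings (gene body plus a flank
of a few kilobases) miss distal regulatory elements — enhancers can sit
hundreds of kilobases from their target promoter — while indiscriminately
large flanks drown genuine signal in noise. A natural remedy is to *augment*
the proximity mapping with curated regulatory interactions (RIs):
enhancer–promoter maps or chromatin-contact data that link distal elements
to the genes they regulate.

Augmentation, however, introduces its own confounders: it changes gene
sizes, SNV counts and within-gene LD structure, and any of these can move
gene and gene-set scores regardless of whether the added SNVs carry real
signal. `regsa` implements the augmentation pipeline *together with the
controls* needed to tell genuine improvements from artefacts:

* **EPVP** (extragenic p-value push) — a circular per-chromosome
  permutation null that replaces the association values of exactly those
  SNVs a gene gained through augmentation, emulating "matched, random"
  regulatory interactions while leaving the mapping itself untouched;
* **IRED** (iterative reduction) — a leave-top-genes-out procedure that
  asks how many genes must be removed from a set before its augmentation
  gain disappears, separating broad, robust gains from gains carried by one
  or two genes.

## SNV-to-gene mappings

The **baseline model** maps a SNV to a gene when it lies in the gene body or
within 10 kb of it (strand-aware upstream/downstream flanks anchored at the
transcription start and end sites). A mapping ladder replaces the 10 kb
flanks with 0, 2, 20, 35, 50, 100 kb and beyond; an **augmented model** adds,
on top of the baseline, all SNVs falling inside a gene's regulatory
elements. Per gene, SNVs are deduplicated; a SNV may map to several genes.
Each (gene, SNV) pair carries an *origin* label: `intragenic` if the
baseline model already captures it, `extragenic` if only the augmentation
does. Everything downstream — and in particular EPVP — is built on that
label.

All interval arithmetic is 0-based half-open internally (a 1-based SNV
position `pos` is inside `[start, end)` iff `start < pos <= end`); readers
of 1-based inclusive formats (gene.loc, `.bim`) convert on ingestion, and
boundary behaviour is pinned by tests. Flanks are clipped at position zero
and at chromosome ends. Regulatory-interaction datasets are processed by
dropping inter-chromosomal records, restricting to the background gene
list, and merging overlapping elements per gene. HiC-style locus pairs are
converted to RIs by treating the 2 kb window upstream of a TSS as the
gene's promoter: if one locus of a pair overlaps a promoter, the partner
locus becomes a regulatory element of that gene (symmetrically for both
loci). The human MHC region (chr6:28,477,797–33,448,354) is excluded by
default on real data because of its extreme LD; synthetic genomes pass
`NULL`.

The **coverage** of a mapping is the per-gene union length of its features,
counting only features that contain at least one SNV present in the
processed summary statistics, summed over genes. Coverage is the natural
size measure of a mapping and the x-axis of the more-coverage,
more-significant-genes trend the pipeline reports.

## Summary-statistics processing

Raw GWAS summary statistics pass a fixed filter order — validity QC
(finite effect, positive SE, p in (0,1], positive n; single-nucleotide,
non-identical, strand-unambiguous alleles), harmonization against the
reference-panel dictionary (primary match on chromosome/position/allele
pair; rescue via the original rsid with coordinates overwritten from the
dictionary), then removal of duplicated rsids (all copies when statistics
differ, one copy kept when rows are identical), panel minor-allele
frequency < 1%, exclusion-region SNVs, and finally sample-size outliers
(more than 5 population SDs from the mean; two-sided; skipped below 3
records). The order mirrors the natural QC narrative and is locked by a
regression test.

## Gene scoring

The gene statistic is the **SNP-wise mean**: each SNV p-value becomes a
1-df chi-square via the upper-tail quantile, and the gene score is their
mean, `T = (1/K) Σ χ²₁`. Under the null of no association the SNV z-scores
are correlated through LD, so `T` follows the weighted form
`(1/K) Σ λ_k χ²₁` where `λ_k` are the eigenvalues of the gene's SNV
correlation matrix `R`, estimated from the reference panel (off-diagonals
shrunk by 1e−6 so duplicated variants stay non-singular). A single-SNV gene
score therefore equals the SNV p-value exactly.

The upper-tail probability of the weighted form is computed numerically.
Three regimes are used, chosen for accuracy and cost:

* **Ruben's series** (mixture of central chi-squares, scale
  `β = 0.90625·λ_min`): exact to a bounded truncation error; used whenever
  its geometric convergence (rate `1 − β/λ_max`) needs at most ~2,500
  terms — which covers the block-LD spectra typical of reference panels;
* **Imhof's oscillatory integral** otherwise (adaptive quadrature, with
  eigenvalues collapsed into multiplicity groups so the integrand cost
  scales with the number of distinct weights);
* the **Lugannani–Rice saddlepoint** in deep tails (p below 1e−6), where
  the oscillatory integral loses both accuracy and speed; a moment-matched
  gamma is the last-resort fallback.

The three regimes agree to ~8 decimals in the bulk (tested against each
other and against Monte-Carlo tail estimates); the saddlepoint's worst-case
relative error of a few percent in deep tails amounts to well under 1% on
the probit scale on which scores are compared. P-values are floored at
1e−300, and zero inputs are clipped with a warning.

**Adjustment.** Raw probit-scale scores `z = Φ⁻¹(1 − p)` are winsorized at
the sample mean ± 3 SD (the truncation rule is a configuration knob, since
only the fact of truncation, not its form, is standard), then regressed by
OLS on log SNV count, within-gene LD (mean off-diagonal |r|; switchable to
mean r²), inverse mean minor-allele count (`1 / mean(2·n_panel·MAF)`), and
mean per-SNV sample size. The adjusted score is the residual **recentred at
the winsorized mean**. An earlier variant added the raw OLS intercept
instead; that intercept is an extrapolation to covariates = 0 (a one-SNV
gene with zero minor-allele count) and made the adjusted-score location
swing by ±1.6 probit units between flank sizes, so it was replaced — the
recentring preserves the overall scale, which is what makes scores
comparable across mappings. With fewer than 10 genes adjustment is skipped
with a warning; collinear covariates fall back to a tiny ridge penalty.

Gene significance uses the upper-tail p of the adjusted score with
Benjamini–Hochberg FDR (< 0.05) within each run.

## Competitive gene-set analysis

For each set, the adjusted scores are regressed by generalized least
squares on an intercept and the membership indicator, with covariance given
by the LD-induced **gene–gene correlations**:
`cov(T_i, T_j) = (2/(K_i K_j)) Σ_{a∈i, b∈j} r²_ab` (variances analogously),
zeroed outside a 5 Mb window and eigenvalue-clipped to positive
semi-definiteness. The membership coefficient is tested one-sided (upper
tail) against a t reference with `n_genes − 2` df — enrichment only,
matching the upper-tail convention used throughout. With identity
covariance this reduces exactly to the ordinary two-sample t-test embedded
in OLS, which the tests verify to 1e−10. Set p-values are FDR-adjusted
across tested sets (those with 25–200 scored genes by default) and
transformed to probit-scale set scores `z_set = Φ⁻¹(1 − p_FDR)`, with p
clipped to [1e−300, 1 − 1e−16] so scores stay finite.

Redundancy among significant sets is reduced by a greedy Jaccard-overlap
procedure: sets are accepted in order of ascending FDR p-value (ties broken
by set id) unless they overlap an already-accepted set at Jaccard ≥ 0.7.
This is a deliberately self-contained substitute for GO semantic-similarity
reduction, which needs the ontology graph; the 0.7 threshold keeps
continuity with the conventional default. When novel/known/lost set counts
are compared between two mappings, the union of the two non-redundant
significant lists is used, and a set pruned as redundant in one mapping but
significant in both counts as known.

**Gains.** For a gene, the gain from augmentation is the difference of
adjusted scores (before multiple-testing correction); for a set, the
difference of probit-scale set scores. Comparisons are always restricted to
the common scored universe — entities with a score under every mapping —
so that counts are comparable across the ladder.

## EPVP: the extragenic p-value push

EPVP asks whether a gain survives replacing the genuine regulatory
interactions with matched, random ones. Per permutation, all SNVs in the
processed summary statistics are arranged by position within each
chromosome, and the (p-value, sample size) pairs — permuted jointly,
because sample size affects the p-value — are shifted *en masse* by one
random offset per chromosome, treating chromosomes as circular. Offsets are
drawn uniformly from `[0, L−1]` (0 is allowed; its probability `1/L` is
negligible). Each gene then receives original values at its intragenic
positions and shifted values at its extragenic positions; because the shift
is computed once per permutation rather than per gene, a SNV shared by two
genes receives the same background pair in both, preserving the
inter-correlation of the background.

The mapping itself — per-gene SNV identities, LD matrices, eigenvalues and
gene–gene correlations — is computed once from the genuine augmented
mapping and reused across all permutations, so the null disrupts only the
association values, not the confounders under suspicion. Per permutation,
every gene is rescored, the per-gene mean sample size is recomputed from
the mixed vector, scores are re-adjusted, and the full competitive GSA is
re-run. The default of 20 permutations is the study protocol; at least 2
are required for an SD to exist. All offsets derive from named seed streams
(`"epvp:k"`), so any permutation is individually reproducible.

Each gaining set is then assigned a validation category from
`d = (z_genuine − mean(z_perm)) / sd(z_perm)`: **strongly validated**
(d ≥ 2), **mildly validated** (1 ≤ d < 2), **invalidated** otherwise; a
zero permutation SD falls back to the sign of the difference, with a
warning. Count-level comparisons use a one-sample, one-sided t-test of the
permutation counts against the genuine count, and novel-versus-lost
comparisons an exact one-sided binomial with success probability 0.5; both
are meant to be FDR-adjusted across the mappings of one phenotype.

A known limitation, inherited from circular shifting itself: near baseline
boundaries the shifted p-values no longer match the local LD, so p-value
correlations and true genetic correlations can disagree for extragenic SNVs
close to a gene's baseline footprint. No correction is applied.

## IRED: iterative reduction

A set-level gain can be carried by a single gene. IRED ranks the set's
genes by their gene-level gain (descending, ties broken by gene id; genes
scored in only one model are excluded, and genes with negative gain remain
removable if iteration reaches them), then removes the top-1, top-2, …
genes cumulatively. At each iteration the *full* gene-set analysis —
including FDR across the entire collection, with the reduced set
substituted for the original — is re-run for both the augmented and the
baseline model, and the set gain is recomputed on the probit scale. The
endpoint is the smallest number of removals at which the gain drops to ≤ 0.
A gain is **robust** when at least the top four genes must be removed.
Traces that never lose the gain within the iteration budget (default: set
size minus the minimum testable size) are censored and count as robust with
a flag; sets that shrink below the minimum testable size stop early, also
flagged. Whether the FDR inside IRED should span the full collection or
only the set under test is not externally fixed; the full-collection
recomputation is used because "the gene-set analysis is executed again" is
most naturally read as the whole analysis, and it keeps the probit scale
comparable with the unreduced run.

## The synthetic study

Every stage is exercised on synthetic data with planted, controllable
regulatory architecture; no external data are required.

* **Reference panel** — latent-Gaussian haplotypes thresholded at each
  variant's allele frequency give Hardy–Weinberg dosages with
  block-equicorrelated LD (blocks of 5 SNVs at latent ρ = 0.7 by default;
  thresholding attenuates the realized dosage correlation to ~0.5–0.6,
  typical of tight LD blocks). Variants have unambiguous allele pairs and
  empirical MAF ≥ 1% by construction.
* **Summary statistics** — marginal z-scores drawn per LD block as
  `z ~ MVN(R·λ, R)`, with `R` the block's empirical dosage correlation and
  `λ` the planted per-SNV noncentralities; two-sided p-values, constant
  per-SNV sample size (50,000 by default, optionally jittered). Simulating
  at the summary-statistics level rather than from phenotypes matches the
  abstraction the whole pipeline consumes and is orders of magnitude
  faster; it does not model phenotype-level effects such as winner's curse
  or imputation error, so passing tests speak to the statistical machinery,
  not to those artefacts of real GWAS data.
* **Architecture** — non-overlapping gene bodies (10–30 kb) in evenly
  sized slots on a 30 Mb chromosome; 0–3 distal regulatory elements per
  gene (2 kb wide, midpoints 25 kb–1 Mb from the TSS/TES, echoing the very
  long-range interactions seen in real RI resources); gene sets drawn at
  25–50 genes from a 300-gene pool. In the enriched condition one set is
  planted: 10 of its genes receive a causal SNV (noncentrality λ = 6,
  i.e. a clearly genome-wide-significant locus at n = 50,000) placed inside
  a dedicated distal element and *outside every gene's baseline footprint*,
  so the baseline model misses the planted signal by construction. λ = 6
  with 10 driver genes was chosen as a clearly-enriched regime — roughly a
  third of the planted set carrying one strong regulatory locus each —
  rather than a marginal one, so that recovery is a property of the method,
  not of a lucky seed.
* **Presets** — `"enriched"` (above), `"null"` (no signal; 2,600 small
  genes for calibration at the ~2,000-gene scale), `"dispersed"` (40 causal
  SNVs scattered within 100 kb of genes, so the flank ladder picks up
  progressively more signal — the fixture behind the coverage-trend check),
  and `"specificity"` (600 genes, 30 sets of 15–25). The specificity preset
  exists because breaking signal placement must actually break it: with few
  large sets drawn from a small gene pool, a reassigned causal element
  lands back inside the planted set with probability ~0.7, and EPVP —
  which by design does not test mismapping — then correctly validates the
  (mismapped but genuine) signal. The larger pool and smaller sets make
  recapture unlikely and dilute it when it happens, so the
  reassigned-elements control cleanly yields invalidation.
* **Seeds** — one master seed spawns named child streams (`"panel"`,
  `"architecture"`, `"sumstats"`, `"epvp:k"`), so each module is
  independently reproducible and all three generators are bit-reproducible
  given (inputs, seed).

Problem sizes throughout (300–600 genes, 5,000–7,800 SNVs, 20–30 sets, 20
permutations, 10 reassignment seeds) were chosen so that a full controlled
analysis, the EPVP control and the specificity study each complete in
seconds to a few minutes while keeping every count (significant genes,
gaining sets, validation categories) far from small-sample degeneracy.

## Numerical choices and degenerate inputs

* p-values are floored at 1e−300 everywhere; probit transforms additionally
  cap at `1 − 1e−16` so `z_set` stays finite at p = 1.
* LD matrices: off-diagonal shrinkage 1e−6; eigenvalues clipped at 0;
  monomorphic variants are an error naming the offender.
* Gene–gene correlation matrices are eigenvalue-clipped to PSD and
  renormalized to unit diagonal; the GLS adds no ridge unless the Cholesky
  fails, in which case clipping at 1e−8 is applied with a warning.
* Ties: redundancy reduction and IRED removal order break ties
  lexicographically, making both procedures deterministic.
* Degenerate EPVP inputs: a gene with no extragenic SNVs is provably
  unchanged; all-zero offsets reproduce the genuine run bit-for-bit (the
  identity control in the tests).

## A worked example

```{r example, eval = FALSE}
study <- simulate_regsa_study(seed = 7, preset = "enriched")
arch <- study$architecture

config <- analysis_config(
  panel = study$panel, genes = arch$genes,
  sumstats_raw = study$sumstats, gene_sets = arch$gene_sets,
  ri_datasets = list(RI = arch$elements),
  set_size = c(10, 200), n_perm = 20, seed = 5
)
report <- run_controlled_analysis(config)
tidy(report)                  # per-mapping coverage and significance counts
glance(report$epvp$RI)        # EPVP validation tallies
autoplot(report)              # significant genes vs coverage
```

## Limitations

Beyond the EPVP boundary effect noted above: the generator's
block-equicorrelated LD has no long-range or porous structure, its genes do
not overlap, and regulatory elements are intra-chromosomal by construction
(as in the processing rule). The competitive regression carries no
additional gene-level covariates — they were already removed at score
adjustment — although the configuration allows re-adding log gene size;
whether internal covariates would materially change competitive p-values on
real data is left as a sensitivity study, not guessed. Semantic
similarity between GO terms is out of scope; the Jaccard reduction is a
structural, not a semantic, de-duplication.
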