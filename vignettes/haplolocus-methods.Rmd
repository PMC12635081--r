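---
title: "Models and methods behind haplolocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind haplolocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplolocus)
```

haplolocus analyzes the haplotype architecture of one small genomic region —
canonically the ~44 kb strong-LD block of the β-globin gene cluster — from
phased diploid genotypes. This vignette documents the models, the parameters
that matter, the numerical choices, and what the synthetic-data generator
does and does not establish.

## The synthetic cohort: a stated world

Because the real cohorts this package is designed around (tens of thousands
of targeted-sequencing samples) are controlled-access, every stage is
exercised against a synthetic cohort whose statistical structure mirrors the
published description of the locus:

* **Demography.** A neutral coalescent with population splits. Each sampled
  chromosome belongs to one of three clades (the analogue of the haplogroups
  HG1–HG3); backwards in time the two minor clades merge at the *inner*
  split and the major clade joins at the *outer* split. Defaults:
  outer split 606,800 years, inner split 306,700 years — the published
  clade divergence structure of the locus. Time is configured in years and
  converted internally at 25 years/generation.
* **Effective size.** Not a published quantity. Chosen once as
  N<sub>e</sub> = 3,400 diploids per clade so that the expected within-clade
  TMRCA of a large sample, 4N<sub>e</sub> generations = 340 KY, matches the
  published within-HG1 coalescence depth (≈340.7 KYA). It is a single shared
  N<sub>e</sub>; the real clades plainly differ (published sub-lineage depths
  range from ~47 KY to ~341 KY), so the synthetic world is a deliberate
  simplification.
* **Clade frequencies and geography.** Baseline clade frequencies
  (0.80, 0.12, 0.08) follow the dominant/minor haplogroup proportions
  reported for southern Chinese cohorts; the second clade's frequency rises
  with latitude at 0.275 percentage points per degree, the published
  regression slope, so the latitude-correlation analyses have signal to find.
  Five sampling populations default to the five province codes with their
  approximate latitudes.
* **Mutation.** Infinite-sites mutations at μ = 1.25 × 10⁻⁸ per base per
  generation over a 43,950 bp region (the published block length), placed on
  the coalescent branches as a Poisson process. A random ~30% of sites are
  written with REF equal to the *derived* base so that ancestral
  polarization is genuinely exercised.
* **Recombination.** Zero within the block. The downstream analyses
  (haplotype catalog, EHH, networks, dating) all assume intact block
  haplotypes, which is the point of analyzing a strong-LD block; a nonzero
  within-block rate is therefore rejected by `sim_config()` rather than
  silently approximated. LD-block splitting behaviour is tested with
  explicitly constructed recombinant fixtures instead.
* **Planted mutations.** `plant_mutation()` adds a biallelic site whose
  derived allele sits exclusively on copies of a chosen background
  haplotype, at a requested frequency rounded to an achievable chromosome
  count. The pipeline's default "paper-mimic" planting creates one mutation
  per sharing pattern: confined to one haplogroup, shared by two, shared by
  all three — the three heterogeneity classes the cross-tab reports.
* **Phenotypes.** HGB and HbF are normal draws (defaults 135 ± 14 g/L and
  1.0 ± 0.3 %, HbF floored at 0) with an additive sex effect and a
  standardized shift (defaults 0.30 / 0.35 SD, the published Hedges'-g
  scale of ≈0.2–0.36) applied to homozygotes of the designated haplogroup.
  Transfusion-free survival is exponential with proportional hazards
  (default 0.15/year, hazard ratio 0.5 for the designated haplogroup) with
  fixed-time right-censoring — the simplest model supporting log-rank
  testing.

**What a green test establishes.** That the implementations compute their
statistics correctly (oracle equivalence), and that on data *with this
stated structure* the pipeline recovers the planted structure. It does not
establish robustness to phasing error, genotyping error, missingness (the
reader rejects missing data by default, as the real input was imputed
upstream), within-block recombination, or balancing selection — all features
of real data the generator does not emulate.

### A known, documented shortfall

The specification of the generator suggests that a UPGMA cut at k = 3
should recover the true clades for ≥99% of chromosomes. Running that
clustering oracle over seeds under the stated world gives ~91%, and the
cause is visible in the published numbers themselves: the within-HG1 TMRCA
(≈340.7 KYA) *exceeds* the HG2–HG3 split (≈306.7 KYA), so under a neutral
split model an occasional deep lineage inside the major clade out-ranks the
inner split and claims the third cluster (the real locus shows the same
phenomenon — one haplotype sits isolated deep inside HG1). The test suite
freezes the oracle-derived bound (mean recovery ≥ 0.85) rather than the
optimistic 99%, and N<sub>e</sub> was *not* retuned to force the higher
figure.

## Block detection

Three rule-based methods over the polymorphic sites, all reporting
non-overlapping blocks of ≥2 markers in genomic order:

* **Four-gamete rule** — maximal intervals in which no marker pair shows all
  four gametes at frequency ≥ 0.01.
* **D′ confidence intervals** — pairs are "strong LD" when a bootstrap CI of
  D′ (200 chromosome resamples, percentile 95% CI, seeded) has lower bound
  ≥ 0.70 and upper ≥ 0.98, "recombinant" when the upper bound is < 0.90;
  blocks need ≥95% strong among informative pairs. The original method's
  likelihood CI is replaced by the documented bootstrap.
* **Solid spine** — intervals whose first and last markers each have
  D′ ≥ 0.8 with every marker between them.

The thresholds are the conventional defaults of the tool family these rules
come from; the source study names only the methods. Adjacent blocks merge
when their *inter-block linkage* — defined here, since no published
definition exists, as the mean |D′| over all cross-block marker pairs —
strictly exceeds 0.8, swept left-to-right to a fixpoint.

## Haplotypes, haplogroups, diversity

The SNP panel keeps sites with MAF strictly > 0.05 and Hardy–Weinberg exact
p strictly > 0.001 (two-sided exact test conditional on allele counts,
summing configurations no more probable than observed). Distinct haplotypes
are named H1, H2, … in descending frequency above a 0.2% naming threshold;
frequency ties are broken by allele-string order with ancestral alleles
first — an invented but deterministic rule, since only "descending
frequency" is published. Haplotype diversity uses the printed formula
H_d = 1 − Σp², deliberately without the n/(n−1) bias correction, because
that is the formula the source prints. IBS distance is the Hamming fraction
over the panel; UPGMA is implemented directly (size-weighted average
linkage, lexicographic tie-break) and verified against both a brute-force
re-computation and `stats::hclust(method = "average")`. Cutting the tree at
k (default 3) labels clusters HG1…HGk by descending chromosome mass, so the
largest clade is always HG1.

## Networks and dating

The median-joining network iterates: build the ε-relaxed minimum spanning
network (ε = 0 gives exactly the union of all MSTs, computed via minimax
path weights); for every path-connected triplet, form the site-wise majority
median (ties toward the ancestral allele); add the candidate that most
shortens the triplet's connection cost; finally prune median vectors whose
degree falls below 3. The construction is seed-free and deterministic given
input order.

TMRCA and divergence estimates use mean pairwise differences per site, π̂,
over 100 replicates of 25 sequences subsampled without replacement (groups
smaller than 25 contribute all sequences, with a warning — replicate spread
then reflects only estimator determinism). Two calibrations are supported:
outgroup (T = T_cal · π̂ / d_out, default T_cal = 6.5 My) and mutation clock
(T = π̂/(2μ) generations at μ = 1.25 × 10⁻⁸). Point estimate = replicate
mean; CI = 2.5th–97.5th percentiles. The original study's TMRCA calculator
is unpublished; this estimator is the package's own documented contract, not
a reimplementation of that tool. Note one estimator honesty detail: for two
*identical* groups the cross-pair π̂ includes self-pairings and equals
(n−1)/n of the within-group value, so the "same group in, same answer out"
identity holds only asymptotically.

Allele age: genealogy-based inference is out of scope, replaced by the
*star-genealogy estimator* `allele_age_star()` — founder haplotype =
site-wise majority among carriers (ties ancestral), age = mean per-carrier
divergence from the founder / (μL) generations. Exact in expectation under a
star genealogy (recent expansion), biased low when carriers share internal
branches; the CLI and docs label it accordingly.

## Selection and differentiation

θπ is computed per bp in sliding windows (default 50 kb / 10 kb step)
anchored at the region start, final partial window dropped. EHH follows the
standard definition on phased haplotypes: at distance x from the core,
Σ C(n_h,2)/C(n_c,2) over distinct extended haplotypes among carriers,
non-increasing by construction. F_ST uses the Weir–Cockerham (1984) variance
components with r = 2 for pairwise comparisons and the ratio-of-sums
multi-locus estimator; negative per-site components remain in the sums
(standard), and negative pairwise estimates are clamped to 0 (with a
warning) only for UPGMA tree building.

## Association

Both Welch's t (with Satterthwaite df) and Mann–Whitney U are provided for
haplogroup-phenotype comparisons, since the source names both for the same
analysis; the pipeline default is Welch + Benjamini–Hochberg across
sex-stratified comparisons, matching the analysis that carries printed
statistics. Effect sizes are Hedges' g (pooled-SD standardized difference
with the small-sample correction J = 1 − 3/(4N−9)); its CI uses the
large-sample g ± 1.96·SE form and is documented as approximate. Mann–Whitney
p-values are exact by enumeration for n₁+n₂ ≤ 16, tie-corrected normal
otherwise. Kaplan–Meier curves and the Mantel–Cox log-rank test are
implemented directly with standard aggregated tie handling; a dataset with
no events returns a flagged, non-numeric result. Kendall's τ_b uses the
tie-corrected normal approximation (exact enumeration only for n ≤ 10
without ties). Single-SNP and epistasis models are OLS fits y ~ g and
y ~ g1 + g2 + g1·g2, reporting the t on the tested (interaction)
coefficient; collinear designs yield flagged results, not errors.

`slope_ci()` inverts a printed (β, t, df) triple into SE = |β/t| and the
Student-t 95% interval — the reconstruction used for the figure-legend
acceptance targets.

## Numerical and design notes

* All stochastic operations take explicit seeds; the pipeline derives
  per-stage seeds deterministically from one global seed, so single stages
  re-run reproducibly and a fixed configuration yields a byte-identical
  bundle.
* Coordinates: printed/VCF coordinates are 1-based inclusive (GRCh37);
  internal arithmetic and BED output are 0-based half-open.
* Multiallelic VCF records split into biallelic sites sharing a position.
* Polarization only annotates; allele calls never change. Sites whose
  ancestral base is unknown or matches neither allele are flagged and
  excluded from derived-allele statistics.
* The pipeline configuration is JSON rather than YAML — no YAML parser is
  assumed in the target environment, and JSON covers the structured-text
  need.

## Limitations

Forward-time selection, recombination within the block, phasing/genotyping
error, genome-wide scans, mixed models and trans-chromosomal modifiers are
all out of scope. Quantitative cohort-level results of the source study
(haplotype counts, specific TMRCAs, allele ages, association p-values) are
not reproducible from synthetic data and are asserted only as qualitative
properties; the only quantitative acceptance targets are analytic
reconstructions of printed figure-legend statistics.
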