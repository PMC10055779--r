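---
title: "Ensemble co-occurrence networks for factorial soil-microbiome experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble co-occurrence networks for factorial soil-microbiome experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miconet)
```

`miconet` analyses taxon count tables from a factorial soil experiment:
three levels of indigenous soil microbial biomass (L/M/H, created by
autoclaving), three fertilizer regimes (none, chemical, organic biogas
residue), two soil habitats (bulk vs rhizosphere), and one native-soil
reference, with three replicate pots per cell. This vignette is the
package's own account of the statistical machinery, the defaults, and what
a green test suite does and does not establish.

## The association model

All association inference operates on per-sample **relative abundances**
(counts divided by library size, recomputed on demand and never stored).
For every unordered taxon pair the package computes five measures of
dependence between the two profiles across samples:

1. **Spearman correlation** — rank correlation, average ranks for ties;
2. **Pearson correlation** — on the relative abundances;
3. **symmetrized Kullback–Leibler dissimilarity** — D(p‖q) + D(q‖p) on
   per-taxon profiles normalized after a 0.5 pseudocount (the smallest
   standard continuity correction; KL is undefined at zeros);
4. **Bray–Curtis dissimilarity** — Σ|xᵢ − yᵢ| / Σ(xᵢ + yᵢ);
5. **mutual information** — plug-in estimator on an equal-frequency
   discretization with ⌊√n⌋ bins per margin, ties broken by stable rank
   order so that the binning is deterministic.

Correlations capture monotone/linear co-variation with a sign;
dissimilarities capture both co-presence (unusually small) and exclusion
(unusually large); mutual information captures non-monotone dependence.

### Permutation null

No parametric null applies to all five measures on compositional count
data, so significance is assessed by **sample-label permutation**: one
profile of each pair is shuffled `B` times (default `B = 1000`, minimum
99) and each measure is recomputed. The p-value uses the add-one
estimator `(1 + #extreme)/(B + 1)` — two-sided on |T| for the signed
correlations, upper-tailed for mutual information, and two-sided by
doubling the smaller tail for the dissimilarities. The same permutation
set is shared across pairs (a standard economy that leaves each pair's
marginal null exact) and is generated from an explicit seed. The engine
is compiled (RcppArmadillo): the five measures across all pairs and all
permutations are matrix products plus two tight loops.

### Empirical Brown combination

The five p-values per pair are dependent — they are computed from the same
two profiles. Fisher's statistic X = −2 Σ log pᵢ is therefore calibrated
as c·χ²(f) with

  f = 2·E²/V,  c = V/(2·E),

where E and V are the mean and total covariance of the −2 log p transforms
of the *permutation replicates* of that pair (each replicate's empirical
p-value is its rank among the others). With independent measures the
covariance vanishes and the combination reduces exactly to Fisher's method
with 2k degrees of freedom; with perfectly dependent measures it collapses
to the common p-value (f → 2). A closed-form fallback
(`brown_combine(..., method = "kost")`) replaces the empirical covariance
with the Kost–McDermott polynomial 3.263r + 0.710r² + 0.027r³ of the
permutation correlation r between the raw statistics.

### Edge calling and topology

An edge is retained iff |Spearman| > 0.6 **and** combined p < 0.05 (both
config-exposed; raw p by default, Benjamini–Hochberg deliberately off to
match common practice in this literature). The 0.6 gate is applied to the
Spearman coefficient because the dissimilarity measures carry no sign and
the threshold is a correlation; a flag allows max(|Spearman|, |Pearson|)
instead. Edge sign is the Spearman sign; nodes are the taxa incident to at
least one edge. Abundance filters before inference are strict
mean-relative-abundance gates: 0.1% for genus-level (bacteria) and 0.001%
for family-level (fungi) tables, interpreted as percent.

Topology indices: density 2E/(N(N−1)); mean local clustering coefficient
with nodes of degree < 2 contributing 0; average shortest-path length over
connected pairs only (disconnected pairs are excluded and the component
count is reported — the convention of common network GUIs); positive and
negative edge percentages (always summing to 100); hubs are nodes with
normalized degree ≥ 0.2. Which centrality the 0.2 cutoff was originally
applied to is not documented anywhere we know of; normalized degree is the
implemented default and the cutoff is a parameter.

## Diversity

* **Rarefaction** draws without replacement to a fixed depth (default: the
  minimum library size — the depth used by any given study is rarely
  reported, so it is exposed as a parameter).
* **Chao1** uses the bias-corrected form S_obs + F₁(F₁−1)/(2(F₂+1)),
  finite even without doubletons. **Shannon** uses natural log.
* **Bray–Curtis / PCoA**: classical scaling of the double-centered squared
  distance matrix; negative eigenvalues are dropped (no Cailliez/Lingoes
  correction) and their summed magnitude is reported as the non-Euclidean
  fraction. Published ordinations of such experiments sometimes name
  unweighted UniFrac; UniFrac needs a phylogeny, which is outside this
  package's inputs, so Bray–Curtis is implemented and the discrepancy
  documented rather than guessed around.
* **PERMANOVA / ANOSIM**: one-factor forms from first principles, with
  add-one permutation p-values (999 permutations by default, explicit
  seeds). The test suite checks both against vegan on shared inputs and
  verifies type-I calibration (null p-values uniform by KS test at
  α = 0.01 over 200 replicates).

## Guild scoring

A bundled ~40-entry genus/family table (same TSV schema as full
community-curated guild databases, so a complete one can be dropped in)
assigns trophic mode, guild and confidence. The most specific rank wins:
genus first, then family — so `unclassified_f__Nectriaceae` (a placeholder
genus) falls through to the Nectriaceae family rule. Potential-pathogen
abundance per sample is the summed relative abundance of pathotroph taxa
whose guild matches the filter (plant + animal pathogens by default) at
confidence "Probable" or better; the original confidence filter used by
published analyses is unstated, so it is a parameter.

## Factorial statistics

`factorial_anova` fits the balanced three-way layout with all interactions
using sequential sums of squares — on a balanced complete design all SS
types coincide, which is why unbalanced input is rejected rather than
silently approximated (the SS type used by point-and-click software in
published tables is typically unstated). A constant response is defined to
give F = 0, p = 1. `correlation_screen` reports Pearson or Spearman
coefficients with two-sided t-approximation p-values and a least-squares
slope. `agronomic_efficiency` is (yield_fert − yield_control)/N_applied.

## The synthetic world

`default_soil_profile()` encodes the stated experimental world so that
every downstream stage can be tested against ground truth:

* **Design**: 18 treatment cells × 3 replicates + 3 native replicates =
  57 samples; libraries are negative-binomial with mean 10,000 reads per
  kingdom (a desk-scale stand-in — per-sample depths of the motivating
  study are not reported; real runs are ~15–30k).
* **Composition**: 30 bacterial genera and 20 fungal taxa. Low-biomass
  cells concentrate bacterial mass on survivor phyla (Proteobacteria,
  Firmicutes, Bacteroidetes) with most minor lineages at trace frequency;
  moderate/high/native cells spread mass over seven abundant phyla.
  Rhizosphere fungal cells carry the stated *Fusarium* /
  *unclassified_f__Nectriaceae* shares per cell (87.41%/1.86% in the
  unfertilized low-biomass rhizosphere, 5.03%/4.34% under organic
  fertilizer, 1.59%/0.14% in native soil, etc.).
* **Count model**: per-taxon log-normal variation (σ = 0.30) around the
  cell target, then per-kingdom Dirichlet-multinomial counts with
  overdispersion 0.02 (concentration 50) — compositional amplicon counts
  are strongly overdispersed, and 0.02 is in the range fitted to real soil
  data. Because the softmax and count layers are nonlinear, raw log-means
  are biased; the generator calibrates per-cell log-means against a fixed
  deterministic noise panel so that expected relative abundances hit the
  configured targets (unbiased by construction).
* **Planted associations** are shared latent Gaussian factors. The
  bundled modules are *mirrored*: two taxa load +1.35 and two load −1.35,
  all at equal target abundance (6%), giving positive edges within the
  co-varying pairs and negative edges across them.

### Why loadings of 1.35 at 6% abundance

The Dirichlet-multinomial layer contributes log-scale noise of
approximately trigamma(50·π) for a taxon at relative abundance π — about
0.40 at π = 0.06. A planted pair's observable rank correlation is roughly
λ²/(λ² + σ² + trigamma(50π)), so loadings must exceed ~1.2 at 6%
abundance for planted pairs to clear the |ρ| > 0.6 edge gate with margin.
Unmirrored (all-positive) blocks of that variance swing their total mass
several-fold and induce compositional common-mode correlations with every
bystander taxon — false edges. Mirroring cancels the first-order mass
effect; the convexity residual is small enough that false edges are rare.
These are structural constraints of compositional count data, not tuning:
with weaker loadings the planted world would simply not contain
recoverable associations at the stated gate.

### What the generator does and does not emulate

It emulates: the factorial design and replicate structure, group-specific
composition (biomass level dominates, habitat matters for fungi,
fertilizer is deliberately null for bacterial composition), planted
signed associations, treatment-dependent pathogen loads, overdispersed
compositional counts, and covariates (nutrients, yield) with configured
treatment means and taxon links (e.g. nitrate negatively tied to
*Fusarium*). It does **not** emulate: sequencing error, chimeras, taxon
misclassification, phylogenetic correlation, rare-taxon long tails
(dozens of taxa, not thousands), or temporal dynamics. A green recovery
test therefore establishes that the inference machinery finds planted
dependence of realistic strength in overdispersed compositional counts —
not that it would recover the true network of a real soil.

Planted-edge recovery is evaluated on the bacterial network inferred from
the pooled moderate+high biomass samples (n = 36): their bacterial
composition is identical by design, so every dependence present is
planted, making precision well-defined. Fungal communities vary by
fertilizer and habitat within a biomass level (the pathogen targets), so
treatment-driven co-variation would masquerade as false edges there; the
fungal module exists for network and guild tests but is not part of the
recovery metric.

### Convergence tolerance

The stated check "empirical cell means converge to the targets at ×100
replicates within 10% relative" cannot hold per taxon for the planted
module taxa: their per-sample shares are heavy-tailed by design
(log-normal with total sd ≈ 1.4), so the Monte-Carlo error of a 100-sample
mean is itself ~20% relative. The test therefore asserts the aggregate —
mean and median relative error over all taxa with targets ≥ 2% across all
19 cells below 10% — which a biased generator would fail and an unbiased
one passes.

## Numerical choices and degenerate inputs

* Permutation p-values are never 0 (add-one estimator); Brown p-values
  are floored at the smallest positive double.
* Constant taxon profiles make Spearman/Pearson undefined: the pair is
  recorded as missing with a warning, and Brown combination proceeds on
  the ≥ 2 remaining measures (pairs with fewer are skipped and counted).
* `V ≤ 0` (a numerically degenerate empirical covariance) falls back to
  Fisher's calibration.
* Rarefaction refuses depths above any library size, naming the sample;
  Chao1/Shannon refuse all-zero samples; PERMANOVA/ANOSIM refuse
  singleton groups; density is undefined below 2 nodes.
* Ties: average ranks for Spearman/ANOSIM; stable first-occurrence order
  for the MI binning.

## Limitations

* One-factor PERMANOVA/ANOSIM only; the factorial decomposition is left
  to the ANOVA module on univariate responses.
* The Brown calibration is estimated per pair from B replicates; below
  B ≈ 500 the effective degrees of freedom are noticeably noisy (the
  pipeline default is 1000).
* The guild table is a curated miniature, sufficient for the bundled
  profile's taxa; real studies should drop in a full database.
* Average path length on disconnected graphs ignores unreachable pairs;
  compare across networks of similar connectedness only.
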