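---
title: "Age-aware detection of gut-microbiome disease signatures"
author: "agemark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-aware detection of gut-microbiome disease signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemark)
```

## The problem

Gut-microbiome disease classifiers are usually trained and evaluated
without regard to host age, yet microbiome composition changes markedly
across adulthood, and the taxa that discriminate patients from controls
in young adults need not do so in the elderly. `agemark` implements a
complete workflow for asking, on species-level relative-abundance
profiles, whether a disease's microbiome signature is age-dependent:

1. quality filtering and age binning of multi-cohort sample collections
   (Young 20--39, Middle 40--59, Elderly 60+ years; younger samples are
   excluded);
2. region-matched disease bins: all cases of a disease pooled with every
   control collected in the same country (or continent), which restores
   statistical power across age groups while holding the dominant
   regional covariate fixed;
3. PERMANOVA with confounders ordered first and a disease-by-age-group
   interaction term;
4. an iterative classification framework contrasting same-age with
   different-age test performance of random-forest disease classifiers;
5. stability-based marker selection with a cross-age-group importance
   test and a linear-model deconvolution of general ageing effects;
6. gain/loss directionality, multi-disease shared-response groups
   (G1--G3 gained, L1--L3 lost), and generic any-disease classifiers;
7. frailty regression from taxonomic composition and metabolite-capability
   inference through a binary species-to-metabolite map.

Because real multi-cohort repositories cannot ship with a package, every
stage is validated against a synthetic-cohort generator with planted
ground truth; the generator is first-class, tested code.

## The synthetic generator

For sample $i$ and species $j$ the latent log-abundance is

$$a_{ij} = \mu_j + c_{(\mathrm{country}_i),j} + b_{(\mathrm{study}_i),j}
 + g_{(\mathrm{age}_i),j} + \delta_j(\mathrm{age}_i)\,
 \mathbb{1}[\text{diseased}_i] + \varepsilon_{ij},$$

with species baselines $\mu_j \sim N(\mu_0, \sigma_0^2)$, independent
country, study-batch and age-group random effects
($\sigma_{\mathrm{country}}=0.5$, $\sigma_{\mathrm{batch}}=0.3$,
$\sigma_{\mathrm{age}}=0.3$ by default), Gaussian noise
($\sigma_{\varepsilon}=1$), and planted disease effects $\delta_j$ that
may differ by age group (the disease-by-age interaction). Detection is
logistic in the latent value (threshold $\tau=-2$, slope $s=1$, about
20 % zeros at the defaults), giving both abundance and prevalence
signal channels; detected abundances are exponentiated and renormalised
to sum to one per sample. Age within a group is uniform over the
group's bounds (Elderly capped at 89). One disease per sample;
multi-morbidity is not modelled. Species are drawn independently; no
phylogenetic correlation or sequencing-read simulation is attempted, so
passing tests demonstrate correctness of the machinery under a known
truth, not performance on real cohorts.

Two further mechanisms emulate ageing phenomena reported for real
cohorts: a *carrier* subpopulation of elderly controls can acquire the
gain-marker taxa (a carriage-prevalence shift that makes elderly
controls partially disease-like and masks elderly signatures), and the
residual noise of elderly controls can be inflated (higher
inter-individual dispersion with age).

Frailty scores emulate a functional-independence measure (FIM-like
scale, clipped to 18--126, higher = less frail):
$\mathrm{score}_i = \mathrm{clip}(\beta_0 - \sum_j w_j \log(x_{ij} +
\mathrm{pc}) + \eta_i)$, with positive weights on pathobiont taxa. A
`NULL` base auto-centres scores at the middle of the bounds. The
pseudo-count defaults to $10^{-6}$ of the unit total (configurable);
the source analyses never state one.

## PERMANOVA

`permanova()` partitions the Gower-centred matrix
$G = -\tfrac12 J D^2 J$ by an *ordered* term list using cumulative
hat-matrix projections, $SS_k = \mathrm{tr}(H_k G) -
\mathrm{tr}(H_{k-1} G)$ — the sequential (Type-I) decomposition that the
`adonis`-style formula `country + disease + age_group +
disease:age_group` implies. Confounder adjustment is therefore purely a
matter of term order. Significance uses simultaneous row/column
permutations of $D$ with the add-one rule $p = (1 + \#\{F^* \ge F\}) /
(1 + n_{\mathrm{perm}})$ (never zero; default 999 permutations, enough
to resolve $p < 0.001$), or exhaustive enumeration of all $n!$
permutations for small $n$, where the p-value is exact. Distances
default to Bray--Curtis (the dissimilarity is configurable and recorded
in the result's attributes; Spearman distance $1-\rho$ serves the
variability analyses). Negative PCoA eigenvalues are reported but not
corrected (no Lingoes/Cailliez), and axes with non-positive eigenvalues
are excluded from coordinates. Samples missing a model covariate are
dropped listwise with a warning.

## The age-aware classification framework

For each disease and training age group, `age_aware_evaluation()` runs
`n_outer` iterations (100 by default). Each iteration trains a
probability forest (ranger, 500 trees by default, impurity importances
= mean decrease in Gini) on an equal number of diseased and control
samples from the training group — by default half the minimum diseased
count over age groups, held constant across groups so that performance
differences cannot arise from unequal training sizes. Each of
`n_inner` (20) repeats draws a same-age and a different-age test set of
identical size, disjoint from training; the iteration records median
AUCs. The different-age set pools the two other age groups without
stratification (a stratified option is a config away). The test size
defaults to the training size per class; the per-disease values used in
the source analyses live in supplementary material, so the parameter is
explicit configuration.

Two tests compare arms across iterations. The paired one-sided Wilcoxon
signed-rank (same > different, Holm-corrected within a disease's age
groups) answers the descriptive question for this cohort. The
permutation arm merges the two test sets, permutes the age-band
assignment *within the case stratum and within the control stratum*
(keeping each permuted set balanced), and records the AUC difference of
the two permuted sets; the actual differences are then compared against
these permuted differences. The stratified permutation is a design
choice: it preserves class balance in every permuted set, so the null
differences are attributable to age-band assignment alone.

Both tests are conditional on the sampled cohort: iterations reuse the
same subject pool, so finite-pool idiosyncrasies (an unusually easy set
of young controls, say) are *real* features of the cohort that the
tests will detect. For this reason the no-interaction calibration
scenario (`study_config("invariant")`) makes the age groups exchangeable
— an age-invariant disease effect and no ageing effect on composition —
and uses large per-group pools (150 per arm) with small train/test
draws (20/15), under which both tests hold their nominal level. When
ageing shifts composition, a same-versus-different gap without any
disease-by-age interaction is genuine transfer loss, not a false
positive. The framework inherits the non-independence of overlapping
training samples from its design; the permutation arm exists precisely
to keep that correlation in the null.

## Marker discovery and ageing deconvolution

Per age group, each taxon gets its mean Gini importance across
iterations, a percentile score (percent rank, 0--100) and an inclusion
fraction (share of iterations with importance > 0).
`stability_threshold()` returns the smallest percentile above which all
taxa meet a 95 % inclusion requirement; the conventional operating
point, used as the default selection rule, is the top 15 percentile
(percentile ≥ 85). Cross-age-group differences in the per-iteration
importance distributions use Kruskal--Wallis with Dunn's post-hoc for
three groups (Dunn's rank-sum z with tie correction is implemented
in-package; no installed package provides it) and Mann--Whitney for
two, with Benjamini--Hochberg FDR across taxa on the omnibus p-values
(threshold 0.01); Dunn pairwise p-values are reported raw.

The deconvolution step fits, per taxon, ordinary least squares on
$\log_{10}(x + \mathrm{pc})$ (pseudo-count: half the smallest nonzero
abundance, configurable): `~ country + disease + age_group` against
`~ country + disease * age_group`, and refers $2(\ell_2-\ell_1)$ to a
chi-square with as many degrees of freedom as estimable interaction
coefficients. The statistic is one-sided by construction — the upper
chi-square tail — which is how the "one-sided" likelihood-ratio
phrasing is implemented. Designs in which a disease appears in a single
age group leave the interaction inestimable; such taxa are flagged
not-testable rather than silently dropped (the same situation that
forces region-restricted control sets in skewed real cohorts, which
`filter_samples()` rules can express). Markers that clear all three
screens — top percentile, cross-group FDR, interaction LRT $p<0.05$ —
form the strictly age-specific set (`validated_markers()`).

Directionality is a two-sided Mann--Whitney per taxon between matched
controls and cases within an age group, signed by whether cases rank
higher (+1, gain) or lower (−1, loss). Study-level calls use raw
$p<0.05$; continent-level calls use BH-FDR. The continent threshold
defaults to 0.1 with a strict 0.01 variant, because the source analyses
state both values in different places; both are exposed.

## Shared response, generic classifiers, frailty, metabolites

`assign_shared_groups()` collapses Young/Middle into one band, lets
each disease vote per band (+1 if any gain call and no loss call,
mirrored for losses; conflicts cancel the vote) and requires at least
two distinct diseases agreeing for a band-level call: G1/L1 both bands,
G2/L2 elderly only, G3/L3 young/middle only; anything mixed is `none`.
Distinct diseases are counted once even if sampled by several cohorts.

Generic any-disease classifiers agglomerate an equal number of cases
per disease (10 by default) plus an equal number of controls per band,
repeated five times, with identical per-disease composition across
bands (a disease missing the required cases in either band is dropped
from both). Sensitivity and specificity are evaluated at probability
0.5 — the natural threshold for a balanced probability forest; the
source analyses do not state one.

Frailty regression supports both stated protocols: the 20 %/80 %
train/test split and k-fold cross-validation; the split is the default,
and the cross-validated variant is what the headline predicted-versus-
actual correlation corresponds to. The minimal marker set retrains on
top-k features over a size grid and minimises mean squared test error
("mean error" is not otherwise specified); ties go to the smaller k.
Metabolite capability scores are the inner product of relative
abundances with the binary species-to-metabolite map; profile-frailty
association (Spearman, BH-FDR < 0.25) and marker enrichment (Fisher
exact on capability presence in marker versus non-marker taxa,
BH-FDR < 0.25) mirror the two-step screening strategy. A second
frailty measure (e.g. a Barthel-type score) is just another score
column; no separate code path exists.

## Validation studies and problem sizes

`study_config()` freezes the synthetic scenarios used by the test suite
and `scripts/acceptance.R`; all replicate counts are chosen to keep the
full suite within a desktop coffee break while leaving clear margins on
the assertions:

* **PERMANOVA calibration**: 200 null cohorts (60 samples, 50 species,
  199 permutations), rejection of the disease and interaction terms
  inside the 95 % binomial band around 0.05 and uniform p-values;
  power: 50 cohorts (20 samples per cell) with a Young-only effect of 2
  on 5 % of 200 species.
* **Age-aware framework**: 20 replicates per arm at 25 × 5 iterations,
  train 20 / test 15 per class. The interaction scenario plants a
  Young-only effect of 2 on 5 % of species; the invariant scenario an
  effect of 1 on three species (same-age AUC ≈ 0.65, the regime of
  harder real diseases).
* **Marker recovery**: 8 strictly age-specific (4 gained, 4 lost,
  Young only, |effect| 2) and 8 age-invariant (|effect| 1.5) markers in
  200 species; balancing gains with losses bounds the compositional
  spillover that closure otherwise induces in every other taxon, which
  both the LRT type-I rate and precision are sensitive to.
* **Shared response**: two diseases, four taxa per group G1--L3 at
  |effect| 1.5 in 200 species, again spillover-bounded.
* **Masking mechanism**: age-invariant effects of 2; 25 % of elderly
  controls acquire the gain markers at full strength and elderly
  controls carry 1.6× residual noise. The carrier fraction sets the
  specificity loss; the dispersion term reflects elderly heterogeneity
  and offsets the small sensitivity cost of training-label
  contamination, so the planted truth of the scenario is "specificity
  affected, sensitivity not". Evaluation pools five repeats from each
  of three cohorts.
* **Frailty**: 180 elderly samples, 100 species, five planted taxa
  (weight 3, score noise sd 1, baseline boost +1.5 — frailty-linked
  pathobionts are not rare, and the boost lets them contribute
  materially to capability sums), low zero-inflation ($\tau=-4$) to
  keep the log-linear score well behaved.

## A small worked run

```{r example, eval = FALSE}
cfg <- study_config("interaction", seed = 1)
g <- generate_cohort(cfg)
run <- age_aware_evaluation(g$table, g$metadata, "D1", "Young",
                            n_outer = 25, n_inner = 5,
                            train_size = 20, test_size = 15,
                            num_trees = 200, seed = 2)
run
paired_auc_test(run)
permutation_auc_test(run)
```

## Known limitations

* All inference is conditional on the cohort at hand; the package does
  not correct the iteration-level non-independence of resampled
  classifiers, it mirrors that design and supplies the permutation null
  as the guard.
* The generator's independence across species understates the
  correlation structure of real communities; recovery rates on
  synthetic data are upper bounds for real-data behaviour.
* Compositional closure induces spillover from strong planted effects
  into all other taxa; the validation scenarios bound it by balancing
  gains and losses and diluting over many species, but analyses of real
  data face it in full.
* The metabolite map is consumed as given (a curated file or the
  generator's synthetic map); no curation or pathway validation is
  attempted.
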