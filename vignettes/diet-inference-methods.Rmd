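---
title: "Methods: hierarchical dietary-guild inference from teeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical dietary-guild inference from teeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietguild)
```

## The inference problem

Teeth preserve three independent records of what a mammal ate. Microscopic
wear on the enamel — pits left by hard, brittle items and scratches left by
abrasive ones — records the physical properties of recent meals. The
development of shearing crests records the functional demand for slicing
versus crushing. Body mass constrains what diets are physiologically
possible at all: a mammal subsisting entirely on high-fiber leaves or grass
needs the gut capacity that only comes with a body mass above roughly
500 g, while obligate insectivores are pushed below that size by the
patchiness of their food. None of the three lines of evidence is
diagnostic alone; this package implements a pipeline in which each is used
only where it has discriminating power, ending in an assignment to one of
five specialist feeding guilds: grazer, browser, hard-object feeder
(fruit/nuts/seeds), insectivore, and carnivore (flesh and bone feeders
pooled).

## Data model

The unit of observation is a counting field of 0.04 mm² on a single tooth,
in which four microwear features are tallied: fine scratches ($S_f$),
coarse scratches ($S_c$), small pits ($P_s$) and large pits ($P_l$), with
derived totals $S_t = S_f + S_c$ and $P_t = P_s + P_l$. Up to four fields
are counted per tooth and up to eight individuals per species. A
`specimen_set` stores one row per field; specimen-level data (taxon,
lineage, guild, species-mean body mass, tooth length, width and summed
shearing-crest length in mm) repeat across a specimen's rows and are
validated for consistency. Specimens without microwear are legal
(morphometrics-only material is common); any operation that needs
microwear raises an error naming the offending specimens rather than
silently dropping them.

The **Shearing Crest Score** is

$$\mathrm{SCS} = \frac{\text{summed 2-D crest length}}
{\sqrt{\text{length} \times \text{width}}},$$

a dimensionless quantity invariant under isotropic scaling of the crown,
so upper and lower molars of any size are comparable. Crest lengths
digitised from occlusal images underestimate the true 3-D lengths; no
correction is applied, and none is needed for guild discrimination. For
carnivorans the measured tooth is the carnassial, treated with the same
length-by-width crown-area convention.

## Statistical units

Count comparisons between guilds (ANOVA, LSD) operate at measurement
level — each counting field is one observation — which uses all the data
and matches how per-field tallies are naturally analysed. The
discriminant analyses and the workflow operate on per-specimen mean
vectors (`aggregate_observations()`), because the classification target is
a specimen, not a field. Both levels are exposed, so the opposite choice
costs one line.

All count data are log-transformed before parametric analysis,
$y = \ln(x + c)$ with offset $c = 1$ by default; counts of zero are real
(a field with no large pits), so a positive offset is required. The
offset is configurable, and strictly positive data can use $c = 0$.

## Univariate machinery

`one_way_anova()` and `two_sample_t()` are thin, validated wrappers over
the classical decompositions (computed via `stats::aov`/`stats::t.test`);
`lsd_posthoc()` implements Fisher's least significant difference from the
ANOVA's pooled within-group mean square:
$t_{ab} = (\bar y_a - \bar y_b)/\sqrt{\mathrm{MSW}(1/n_a + 1/n_b)}$ on the
within degrees of freedom. By definition LSD applies **no**
multiple-testing correction; the pairwise grid must be read with that in
mind, and the package does not quietly substitute a corrected procedure.

`nested_anova()` performs a hierarchical decomposition: the nested factor
is re-coded as `outer:nested` (so hierarchy holds by construction), the
outer factor is tested over the nested-within-outer mean square and the
nested factor over the residual. For total-count comparisons the
replication battery places the *feature class* (scratch total vs pit
total) in the outer stratum and diet (or lineage) nested within it. The
reverse orientation — feature class nested inside diet — leaves the diet
test with only the two feature-class mean squares as its error term and
essentially no power; the orientation used here is the one under which
total-count data can resolve group differences at all, and it is the
package's deliberate reading of "both factors nested". The generic
`(values, outer, nested)` surface makes the alternative a one-line change.

Shapiro–Wilk results are reported as diagnostics alongside exported
residuals; they never gate the downstream analyses automatically.

## Canonical discriminant analysis

`fit_canonical_lda()` is implemented from first principles (the
self-written eigenstructure is the point; an established implementation is
used only as a cross-check in the test suite). With within- and
between-group scatter matrices $W$ and $B$, it solves the generalized
eigenproblem $W^{-1}B$ by Cholesky whitening of $W$ (a symmetric
eigendecomposition of $R^{-T} B R^{-1}$ with $W = R^{T}R$), yielding
$\min(p, g-1)$ canonical functions. Conventions:

* canonical scores are scaled to unit pooled within-group variance;
* percent variance per function is $100\,\lambda_i/\sum_j \lambda_j$;
* the structure matrix holds pooled within-group correlations between raw
  features and canonical scores;
* each function is oriented so its largest-magnitude structure coefficient
  is positive (signs are otherwise arbitrary);
* Wilks' $\Lambda = \prod_i (1+\lambda_i)^{-1}$ over all retained
  functions, with Bartlett's approximation
  $\chi^2 = -(n - 1 - (p+g)/2)\ln\Lambda$ on $p(g-1)$ degrees of freedom
  (the classical default; Rao's F is not implemented);
* classification uses linear scores from group means and the pooled
  covariance plus log priors, posteriors by softmax, and a deterministic
  tie-break to the first group label;
* priors default to **equal** across groups, with proportional priors
  available as a sensitivity flag;
* leave-one-out evaluation refits the model for every held-out item —
  naive $O(n)$ refits, chosen for transparency over speed at these sample
  sizes.

Degenerate inputs fail loudly: a singular pooled within-group scatter
reports the collinear or constant features by name; groups of size one are
rejected; `wilks_test()` refuses an `n` inconsistent with the fit.

## The hierarchical workflow

`fit_workflow()` trains the three-stage tree; `classify_specimen()`
descends it deterministically, recording every comparison in a trace:

1. **Body mass vs the insectivore ceiling.** Below the ceiling the
   specimen enters the small-body stage: a microwear LDA over insectivore,
   hard-object feeder and carnivore, the guilds that occur at small size.
   When the insectivore and hard-object posteriors are within 0.2 the
   assignment carries an ambiguity flag — these two guilds exploit foods
   with similar fracture properties and genuinely overlap; the flag
   surfaces the uncertainty rather than forcing a coin flip, while the
   argmax still commits.
2. **SCS vs the carnivore cutoff.** Large-bodied specimens with short
   shearing crests are carnivores; the branch exits without microwear.
3. **Herbivore-triad microwear LDA** over grazer, browser and hard-object
   feeder. Below the 500 g high-fiber floor, grazer and browser are
   physiologically excluded and their posterior mass is renormalised away
   (with a trace entry), which in practice resolves to hard-object feeder.

The ceiling and the SCS cutoff are fitted 1-D thresholds minimising
training misclassification, with the midpoint of tied optima — for
separable training data this is the centre of the separating gap. The
ceiling is fitted between insectivores and the large-bodied guilds
(grazer, browser, carnivore); hard-object feeders are excluded from that
fit because their body masses overlap the insectivores', which would
otherwise drag the ceiling upward. The 500 g floor is a physiological
constant, not fitted, but overridable. Training-error minimisation was
chosen over a distributional model because it is reproducible and
assumption-free; every threshold is a parameter, so a different tree
reading is a configuration change, not a code change.

`evaluate_workflow()` re-assigns every specimen of a labelled set
(resubstitution); `workflow_loo()` refits thresholds and LDAs per fold for
the stricter leave-one-out variant.

## The synthetic-specimen generator

`generate_specimens()` simulates the hierarchical sampling design:
species body mass log-normal per guild (one draw per species), SCS normal
truncated at zero per specimen, tooth length from a log-log allometry on
body mass (default $\ln L = -1.1 + 0.33 \ln \mathrm{BM}$, noise SD 0.1 on
the log scale, width = 0.8 × length), crest length back-computed as
$\mathrm{SCS}\sqrt{LW}$, and per-field counts from a mean/overdispersion
family — Poisson at dispersion 0, gamma-mixed Poisson (negative binomial,
`size = 1/dispersion`) otherwise — so zero counts arise naturally and the
log-offset choice is genuinely exercised. An optional mean-preserving
log-normal per-tooth effect induces intra-tooth correlation between a
tooth's fields. Everything is reproducible from the config seed, and the
provenance string records a hash of the configuration.

`default_config()` is calibrated **only to ordering constraints**, never
to digitized values from any figure: grazers scratch-dominated with more
coarse scratches than browsers; hard-object feeders with the highest pit
totals; carnivores with the lowest SCS; insectivores concentrated two
standard deviations below the 500 g floor; browsers comfortably above it;
and the small-body guilds (insectivore, hard-object, carnivore)
overlapping in microwear — mild overdispersion 0.08 throughout. That
overlap is the scientifically load-bearing feature: it reproduces the
regime in which a flat five-guild microwear LDA degrades badly while the
hierarchy, using body mass and SCS where microwear is uninformative,
holds its accuracy in the low 90s with residual errors concentrated in
the insectivore/hard-object cells. The default problem size — 10 species
× 4 individuals × 3 fields per guild, 200 specimens — was chosen as
representative of a serious museum campaign while keeping every analysis
interactive. `perturb_config(config, overlap)` interpolates all guild
parameters toward their grand mean as a difficulty dial (1 collapses all
guilds onto one distribution).

What the generator does **not** emulate: covariance between microwear
features within a field (no published estimates exist to calibrate it),
phylogenetic signal, seasonal or geographic wear variation, and any
association between lineage and guild composition. Passing tests on
synthetic data therefore demonstrate correctness of the machinery and the
qualitative mechanism of the hierarchy — not field performance on real
assemblages.

## Numerical choices

* Thresholds and tie-breaks: candidate 1-D thresholds are midpoints of
  adjacent pooled values; tied optima resolve to the midpoint of the tied
  range. Classification ties resolve to the first group label.
* Eigenvalues are clipped at zero (whitened between-scatter is PSD up to
  round-off); Wilks identities hold to 1e-9 in the test suite.
* p-values come from exact F, t and χ² distributions, matching the
  parametric framing of the analyses; no permutation variants.
* The log-transform offset (default 1) and the LDA priors (default equal)
  are the two knobs most likely to matter when replicating externally
  published statistics; both are exposed wherever they enter.

## Limitations

The pipeline assumes dietary **specialists**; mixed feeders violate the
five-guild premise and will be forced into the nearest specialist guild.
The 92%-regime accuracy observed on default synthetic data is a
resubstitution figure on data that satisfy the generator's assumptions;
`workflow_loo()` gives the honest out-of-sample analogue (typically a few
points lower). The insectivore/hard-object ambiguity is intrinsic to the
evidence, not a software limitation — downstream users should treat
flagged assignments as a two-guild call.
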