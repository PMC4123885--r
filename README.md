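# dietguild

Dietary guild inference for mammals from three independent dental lines of
evidence: low-magnification dental microwear, shearing-crest morphometrics,
and body mass.

Paleoecologists and mammalogists routinely need to assign a feeding guild —
grazer, browser, hard-object feeder, insectivore, or carnivore — to museum
specimens or fossils whose ecology was never observed. Each classical
proxy fails somewhere: microwear separates the herbivorous guilds cleanly
but confuses carnivores, insectivores and hard-object feeders, whose foods
have similar fracture properties; shearing-crest development separates
carnivores from herbivores but not herbivores from each other; body mass
alone only brackets what is physiologically possible. `dietguild`
implements each proxy's statistics and then a hierarchical classifier that
applies them in succession, each deciding only what it is good at.

## What is computed

* **Microwear counts** per 0.04 mm² field: fine/coarse scratches
  (S<sub>f</sub>, S<sub>c</sub>), small/large pits (P<sub>s</sub>,
  P<sub>l</sub>), totals S<sub>t</sub>, P<sub>t</sub>; log-transformed
  (offset 1) before parametric analysis.
* **Shearing Crest Score**: SCS = crest length / √(tooth length × width),
  dimensionless and scale-invariant.
* **Univariate statistics**: one-way ANOVA, pooled-variance t-test,
  Fisher LSD pairwise grids (uncorrected, by definition), hierarchical
  nested ANOVA, Shapiro–Wilk diagnostics.
* **Canonical LDA**, written from first principles: eigenstructure of
  W⁻¹B, percent variance, structure matrix, Wilks' Λ = Π(1+λᵢ)⁻¹ with
  Bartlett's χ² = −(n − 1 − (p+g)/2)·lnΛ, equal-prior classification, and
  leave-one-out evaluation by full refits.
* **The hierarchical workflow**: body mass vs a fitted insectivore
  ceiling → small-body microwear LDA (with an insectivore/hard-object
  ambiguity flag); SCS vs a fitted carnivore cutoff; herbivore-triad
  microwear LDA with a 500 g floor excluding high-fiber diets at small
  size. Every threshold is fitted by training-error minimisation and
  every decision is recorded in a trace.
* **A guild-structured simulator** so the full pipeline runs and is tested
  without museum material.

## Worked example

```r
library(dietguild)

set <- generate_specimens(default_config(seed = 1))  # 200 specimens
model <- fit_workflow(set)
print(model)
#> hierarchical guild workflow
#>   insectivore body-mass ceiling: 2912 g
#>   high-fiber herbivory floor:    500 g
#>   carnivore SCS cutoff:          1.668

evaluate_workflow(model, set)
#> classification: 95.0% correct
#>              predicted
#> true          grazer browser hard_object insectivore carnivore
#>   grazer          38       2           0           0         0
#>   browser          0      40           0           0         0
#>   hard_object     0       0          38           1         1
#>   insectivore     0       0           4          34         2
#>   carnivore       0       0           0           0        40

classify_specimen(model, set[set$specimen_id == "insectivore_sp03_ind2", ])
#> guild assignment: hard_object (insectivore/hard-object ambiguity)
#>   step      quantity      value threshold      branch
#> 1    1   body_mass_g 84.8985181  2911.582  small_body
#> 2    2 lda_posterior  0.4719215        NA hard_object
```

Reading the output: the fitted tree puts the insectivore ceiling at
~2.9 kg and the carnivore SCS cutoff at 1.67; re-assigning all 200
simulated specimens recovers 95%, with the residual errors concentrated in
the insectivore/hard-object cells — the two guilds whose foods (hard
brittle insect cuticle vs seeds) wear teeth alike. The example specimen
is an 85 g animal routed to the small-body stage; its posterior is split
almost evenly, so the assignment carries the ambiguity flag.

The numbered scripts under `analysis/` run the full study over simulated
data — `01_simulate.R` through `05_replication_battery.R` — writing tables
under `results/`. `replication_battery()` runs every analysis (univariate
grid, nested ANOVAs, three LDAs with LOO, workflow) on both the global and
the limited (≥ 3 individuals per species) data sets, and accepts a named
list of externally transcribed reference values for side-by-side
comparison.

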