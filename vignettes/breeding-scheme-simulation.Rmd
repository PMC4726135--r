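---
title: "Simulating recurrent genomic selection with whole-genome prediction"
author: "breedsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating recurrent genomic selection with whole-genome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedsim)
```

## The problem

Genomic selection (GS) chooses breeding parents by their genomic
estimated breeding values (GEBVs) — predictions from a whole-genome
regression of phenotype on marker dosages — rather than by observed
phenotype. Before committing years of crossing work to a GS programme, a
breeder wants to know whether a realistic scheme of crossing and
selection, starting from an actual panel of varieties, can accumulate the
predicted merit, and what happens to the traits that are *not* under
selection. `breedsim` answers this by coupling three components:

1. a **meiosis simulator** on a genetic linkage map, so that virtual
   crosses recombine exactly as the map says they should;
2. **whole-genome prediction (WGP)** models trained once on the founder
   panel and used, unchanged, to score every simulated descendant;
3. a **recurrent selection scheme**: per-trait truncation selection of
   parents, round-robin crossing at constant population size, repeated
   over generations and replicates.

Around these sit the supporting analyses such a study needs: marker
quality control, additive kinship, linkage disequilibrium (LD),
broad-sense heritability from replicated trials, mixed-model and
shrinkage-based association scans, and leave-one-out cross-validation
(LOOCV) of prediction accuracy. The motivating application is tomato —
a selfing crop with 12 chromosomes, where total fruit weight and soluble
solids content (°Brix) are antagonistic breeding goals — but nothing in
the package is tomato-specific.

## The meiosis model

The genome is the linkage map itself, discretized into bins of
0.1 cM (`build_bins()`). Each simulated haplotype is a vector over bins
holding *founder-haplotype identifiers*; marker genotypes are
materialized by looking up the allele carried by the nearest bin's
founder haplotype. Meiosis per chromosome:

* the crossover count is Poisson with rate equal to the chromosome's
  genetic length in **Morgans** — the map length *is* the expected
  crossover number;
* crossover positions are i.i.d. uniform on the chromosome (no
  interference), rounded to the nearest bin boundary;
* the gamete starts from either parental haplotype with probability 1/2
  and switches source at each crossover.

No mutation, no interference model, no sex differences — these are fixed
properties of the model, not options. Two closed-form consequences make
the simulator testable against independent oracles: the recombination
fraction between loci d Morgans apart must follow Haldane's map function
r = (1 − e^(−2d))/2, and single-seed-descent selfing must halve
heterozygosity each generation, leaving (1/2)^6 ≈ 1.6% after the default
six generations of inbreeding. The test suite checks both, plus the
Poisson mean/variance, on 10^4-gamete samples.

Inbreeding is implemented as self-fertilization with single-seed descent.
The choice matters for crops that are outcrossed in practice; for a
selfing crop it is the standard route to inbred lines, and it is the only
inbreeding mode provided.

## Whole-genome prediction

All fitters return a `marker_effect_model`; for the linear kinds the GEBV
of a genotype vector x is exactly `mu + sum(x * beta)`.

* **RR (ridge / RR-BLUP)** — `fit_rr()`: effects
  β ~ N(0, σ²_β I); variance components by REML via spectral
  decomposition of the centered dosage cross-product, which makes the fit
  identical to GBLUP with the matched kinship (a property the tests
  verify directly).
* **BL, EBL, Bayes C** — `fit_shrinkage()`: Gibbs samplers with conjugate
  updates, written in C++. BL places a double-exponential prior on every
  effect with a common shrinkage parameter; EBL gives each marker its own
  shrinkage parameter with gamma hyperpriors, of which the rate `theta`
  (default 10⁻⁴) controls how freely individual markers may escape
  shrinkage — small values make the scan sensitive to single large QTLs;
  Bayes C uses a spike-and-slab with common slab variance and an
  estimated inclusion probability π, reporting per-marker posterior
  inclusion probabilities. Posterior means over the post-burn-in draws
  are the returned effects. Gibbs sampling was chosen over variational
  approximations because every conditional is exact and the whole
  machine is verifiable by parameter-recovery tests; the cost at panel
  scale (10²–10³ individuals, 10³–10⁴ markers) is seconds.
* **RKHS** — `fit_rkhs()`: Gaussian kernel
  K(i,k) = exp(−d²(i,k)/(h·m)) on squared Euclidean marker distances,
  fitted as a kernel mixed model by the same REML machinery; the default
  bandwidth is the median of the per-marker-scaled squared distances.
  In the purely additive limit its LOOCV accuracy matches RR's, which is
  one of the tests.

`loocv()` refits the model n times, holding out one individual per fold;
accuracy is the Pearson correlation between observed phenotypes and
held-out GEBVs, and `select_best_models()` picks the per-trait winner,
which is how GEBV engines for the breeding simulation are chosen.

Two numerical caveats are worth knowing. First, LOOCV correlation is
*negatively biased under the null*: each fold's prediction leans on the
leave-one-out training mean, which anti-correlates with the held-out
observation, and when REML finds no genetic variance the fit collapses to
the intercept and the correlation degenerates toward −1. A permuted
phenotype therefore yields zero-or-negative accuracy, not exactly zero;
the tests assert the absence of *positive* accuracy. Second, sampler
fits are bit-reproducible given `shrinkage_config(seed=)`, and the
sampler restores the caller's RNG stream so that reproducible fits do
not perturb a surrounding simulation.

## Association scans

`mlm_scan()` is the mixed-linear-model GWAS: per marker,
y = PCα + x_j b_j + u + e with u ~ N(0, σ²_g K) on the VanRaden kinship
K and (by default) six genotype principal components as fixed
covariates. Variance components are estimated once on the null model and
reused for every marker — the standard "population parameters previously
determined" approximation; `exact = TRUE` re-estimates per marker.
Wald t-tests give p-values, and `fdr_significant()` applies
Benjamini–Hochberg step-up control (default 5% FDR). Null calibration
under kinship structure is part of the acceptance checks.

`ebl_scan()` reuses the EBL fitter (identical effects, same seed) and
reports posterior-mean effects per marker. The underlying method has no
intrinsic significance rule — it produces effect sizes, not p-values —
so the packaged call rule (flag markers beyond `k_sd` standard deviations
of all effects) is an explicit policy of this package. Its default is
k = 10: posterior-mean effects under this prior are heavy-tailed, and on
traits with *no* genetic signal the most extreme of a few hundred markers
routinely reaches 5–8 SD, so a 5-SD rule would call false associations
on most null traits while a 10-SD rule stays quiet on nulls yet still
flags a QTL explaining ~30% of variance (≈13 SD in our recovery tests).

`sig_marker_regression()` mirrors the marker-assisted-selection
assessment: OLS of the trait on the GWAS-significant markers with
bidirectional AIC stepwise selection (two or more candidates), reporting
candidate count, selected count and model r².

## The breeding scheme

`run_recurrent_gs()` implements the recurrent scheme with the defaults of
the motivating design: population size N = 96, five generations, five
replicates. Generation 1 is produced from the founders by selecting the
top **two** candidates per target trait by GEBV; later generations select
the top **four** per trait from the current progeny (founders do not
re-enter). Parents are arranged in a ring that interleaves the two trait
groups — trait-1 parent, trait-2 parent, trait-1 parent, … — so that
*every* cross combines a high-GEBV parent for one target with a
high-GEBV parent for the other; with 4 parents each cross contributes
96/4 = 24 progeny, with 8 parents 96/8 = 12. The interleaving is our
policy choice: the ring order is otherwise unconstrained, and
interleaving is the only ordering under which every cross can combine
both selected traits, which is the point of the scheme. When one
individual tops both trait lists it is kept for the trait where it ranks
better and the other list takes its next-ranked candidate, preserving
the stated parent counts; ties break deterministically by candidate
index.

Models are trained on the founders once and never retrained on simulated
progeny — the simulation asks what the *founder-trained* predictor
accumulates, not what an oracle could. GEBVs of **all** traits are
recorded every generation, so correlated responses of non-target traits
come for free. `derive_inbred_population()` produces one six-generation
inbred per individual of any generation, scored with the same models.
Replicate r uses master seed + r, so replicates are independent but the
whole run is reproducible; `selection = "random"` gives a negative
control in which parent choice ignores GEBVs, used in the tests to show
that the observed response is selection, not simulator drift.

## The synthetic panel

`simulate_founders()` builds a phased founder panel as mosaics of a small
ancestral haplotype pool (default 8 ancestors) with exponentially
distributed segment lengths at an LD scale of 20 cM — a haplotype-copying
emulation, chosen because it is cheap, seedable, and produces the two
properties the analyses rely on: allele-frequency diversity passing the
5% missing / 5% MAF filters for >99% of markers, and LD that decays over
tens of cM. It is *not* a claim about any real crop's history: there is
no demography, no selection, no mutation, and the allele-frequency
spectrum is flatter than a real panel's. Passing tests on this panel
show the machinery is correct, not that any particular real-data result
will reproduce.

Default dimensions emulate the motivating study: 96 individuals, 12
chromosomes of 110 cM, 9600 markers, physical positions on a smooth
nonlinear monotone bp/cM curve with a noisy anchor table to exercise the
map-projection tools (local polynomial regression with span 0.189,
degree 2; negative projected gaps replaced by 10⁻⁶ cM with cumulative
re-accumulation, so positions stay strictly increasing — re-accumulation
rather than local insertion is our choice, the alternative would shift
only the offending marker).

`simulate_phenotypes()` places a shared set of QTLs on markers (default
100) and draws additive effects so that true breeding values have unit
variance and **exactly** the target genetic correlation matrix (the
drawn effect matrix is recoloured against the realized covariance —
still a linear, purely additive architecture). The default 20 traits
span broad-sense heritabilities 0.1–1.0 observed over 4 replicate years,
and the first two traits are negatively correlated (−0.5), emulating the
yield/quality antagonism that makes simultaneous improvement the
interesting case. Per-year noise is scaled as σ²_E = σ²_G (1 − h²)/h², so
the one-way-ANOVA estimator `estimate_heritability()` (σ²_E = within
mean square, σ²_G = (between − within)/years, negatives truncated to 0)
recovers the targets — the closing of that loop is itself a test.

## Problem sizes and numerical choices

The test and acceptance runs use: 10⁴ gametes for the Poisson and
Haldane oracles, 2000 selfing replicates, n = 200 × 4 years for
heritability recovery, 2200 null markers at n = 150 for GWAS
calibration, a 1000-marker/10-QTL Bayes C recovery at n = 200, and the
full 96 × ~9500-marker panel for the five-generation, five-replicate
selection runs. These sizes put every Monte-Carlo band (3 standard
errors) well below the effect sizes being checked while keeping a full
run in tens of seconds on one core.

Other fixed numerical choices: dosage-centered kinship is normalized by
2Σp(1−p) (monomorphic-only input is an error); mean imputation per
marker precedes model fitting (the upstream study phased and imputed
externally; mean imputation keeps the pipeline self-contained); LD r² is
computed directly from phased haplotypes (both real post-phasing data
and simulated data are phased, so no EM phase inference is needed);
marker-to-bin assignment takes the nearest bin midpoint with exact ties
to the lower bin; REML profiles the variance ratio on a log grid in
[e⁻¹², e¹²] by Brent search; the RKHS kernel receives a 10⁻⁸ diagonal
jitter.

## Limitations

* Purely additive genetics: no dominance or epistasis in either the
  generator or the linear models (RKHS can absorb some non-additivity at
  prediction time but the simulator never creates any).
* Single-trait models only; the negative trait correlation enters
  through the genetic architecture, not through multi-trait prediction.
* No crossover interference or recombination hotspots; the 0.1-cM bin
  lattice bounds map resolution.
* The synthetic panel is an emulation for testing machinery, not a
  surrogate for real data; results on it bound nothing about a real
  panel beyond correctness of the computations.
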