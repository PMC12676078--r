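---
title: "Methods: host-genotype microbiome structure and microbe-contingent nitrogen adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host-genotype microbiome structure and microbe-contingent nitrogen adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rhizoadapt implements a two-experiment analysis that asks whether plant
genotypes carry a signature of their historic environment in the
rhizosphere microbiomes they recruit, and whether their growth response
to nitrogen depends on the presence of soil microbes. The package
couples the statistical pipeline with a synthetic-data generator that
reproduces the structure of both experiments, so every stage can be
exercised and calibrated without any sequencing data.

## The two experiments

**Common garden.** A panel of grass genotypes (by default 40, collected
across a Mediterranean-climate region) is grown in a common glasshouse
environment with a shared soil inoculum, one plant of each genotype in
each of five blocks. Rhizosphere communities are profiled by amplicon
markers: a universal bacterial marker (from which ammonia-oxidizing
lineages can be subset by taxonomy) and a diazotroph (nitrogen-fixer)
marker. Each genotype also carries coordinates, SSR marker genotypes,
and a vector of historic-environment covariates (soil nitrogen and
phosphorus, CEC, pH, temperature, seasonal precipitation, elevation).

**Nitrogen response.** A subset of 10 genotypes spanning the historic
soil-nitrogen gradient is grown under 2 glasshouse nitrogen levels
crossed with live vs sterilized inoculum, 10 pots per cell, in
randomized blocks; about a quarter of pots fail to germinate. Height,
biomass and tillering status are recorded per plant.

## Community descriptors

- **Rarefaction** is a single seeded draw without replacement to the
  target depth; samples below the depth are dropped and reported. One
  draw (rather than an average over draws) matches how a single
  rarefied table is carried through the rest of the analysis; the seed
  makes it reproducible.
- **Alpha diversity**: richness, Shannon entropy with natural
  logarithms, and Pielou evenness H / log(richness). Pielou is
  undefined (flagged `NA`) for richness < 2 because of the log
  denominator; it is not coerced to 0.
- **Bray-Curtis** is delegated to `vegan::vegdist`; a pair of all-zero
  samples, undefined under the formula, is set to distance 0 with a
  warning.
- **Weighted UniFrac** is computed directly on the rooted tree: for
  each branch the absolute difference in the fraction of reads
  descending from it, weighted by branch length. The default is the
  *raw* (non-normalized) variant, matching common amplicon-pipeline
  defaults; `normalized = TRUE` divides by the total abundance-weighted
  path length. Taxa present in the table but absent from the tree are
  an explicit error -- tables are never silently pruned; extra tree
  leaves are pruned.
- **Beta-dispersion** is the distance to the group centroid in
  principal-coordinate space with the negative-axis correction
  (sqrt(real^2 - imaginary^2), floored at 0), via `vegan::betadisper`
  with `type = "centroid"`. The centroid (not the spatial median) is
  used; median-based defaults elsewhere will differ slightly.

## Distance-based inference

All inference shares one construction: the Gower-centered matrix
G = -1/2 J D^2 J, whose trace is the total sum of squares
((1/n) sum of squared distances over pairs).

- **PERMANOVA** partitions trace(G) sequentially (Type-I) over the
  design terms in user order via hat-matrix projections; order matters
  and is deliberate (genotype before block, matching the study's
  reporting). P-values use free relabeling of samples and the
  (1 + b)/(1 + m) convention, which includes the observed statistic and
  keeps p in (0, 1].
- **dbMEM**: distances beyond a truncation threshold (default: the
  longest edge of the minimum spanning tree) are replaced by 4x the
  threshold, the truncated matrix is decomposed by principal
  coordinates, and positive-eigenvalue eigenvectors are retained. On a
  regular transect the construction agrees with `vegan::pcnm` to
  machine precision; the leading eigenfunction is a half-sine whose
  correlation with the coordinate is about 0.83 (it is smooth and
  monotone-like, not linear).
- **Conditioning choice.** With 40 genotypes, the union of *all*
  positive-eigenvalue geographic and SSR-Hamming eigenvectors spans the
  entire 39-dimensional between-genotype space: every genotype-level
  predictor would be exactly aliased and no environmental signal could
  ever be detected, however strong. `condition_basis()` therefore
  conditions on the broad-scale subset -- eigenvectors whose eigenvalue
  exceeds the mean positive eigenvalue of their source (roughly half
  the between-genotype dimensions). This controls broad spatial and
  kinship autocorrelation while leaving degrees of freedom for the
  predictors; `dbmem()` itself still returns the full positive basis by
  default.
- **dbRDA** residualizes G and the (z-scored) predictors on the
  condition block and reports the inertia decomposition
  (conditioned + constrained + unconstrained = total). On Euclidean
  distances the constrained proportion equals the multivariate
  regression R^2; against `vegan::capscale` the components agree up to
  vegan's 1/(n-1) scaling.
- **Forward selection** adds, at each step, the candidate with the
  smallest marginal permutation p (ties broken by the larger
  pseudo-F), permuting under the current reduced model, and stops when
  the best p exceeds alpha. Marginal tests permute candidate scores at
  the *genotype* level when `groups` is supplied: genotype-level
  covariates are constant across a genotype's replicates, and replicate
  communities of one genotype are correlated, so free sample-level
  permutation treats pseudoreplicates as independent and lets pure
  noise into the model far above the nominal rate (we measured ~50%
  entry for a noise covariate at alpha = 0.05; blocked permutation
  restores ~alpha). Geographic distances are great-circle (haversine,
  Earth radius 6371 km); SSR Hamming distance is the mismatch share
  over pairwise non-missing loci.

## Trait models

Height and biomass are modeled as
`trait ~ histN * microbe * glasshouseN + (1 | genotype) + (1 | block)`
by REML (`lme4`); tillering uses the binomial equivalent. Historic
nitrogen enters as a continuous standardized covariate. Three
conventions matter:

- **Singular fits are kept.** When a random-effect variance collapses
  to zero (common for biomass) the term is retained and the fit is
  flagged, because replicates within a genotype are pseudoreplicates
  regardless of the estimated variance; with zero variance the fixed
  estimates coincide with ordinary least squares (asserted in tests).
- **Denominator df** for Gaussian F tests is n - rank(X): no fixed
  term in this design is nested in a random factor, so the containment
  denominator is the residual stratum (291 plants - 8 parameters = 283
  in the full design). Kenward-Roger/Satterthwaite approximations are
  out of scope by design.
- **Binomial term tests** are sequential likelihood-ratio chi-squared
  statistics from nested refits; `type = "marginal"` gives Wald tests
  instead. Interactions always follow their lower-order terms, so
  marginality is enforced by construction.

Diversity-vs-environment analyses (`fit_env_diversity_model`) regress a
per-sample metric on one standardized environment variable with
genotype and block random intercepts.

## Microbial effect and the slope-difference test

The microbial effect for genotype g in glasshouse nitrogen level e is
the response ratio ME = (live - sterile)/sterile of the genotype's raw
cell means (no block adjustment by default -- a flag provides the
adjusted variant through the model machinery if wanted). ME >= -1
whenever the live mean is non-negative; a sterile mean <= 0 flags the
estimate unusable, and cells with fewer than 2 live or sterile plants
are dropped.

**Uncertainty propagation** is Monte-Carlo by default (more faithful
for a ratio): cell means are drawn from normal(mean, SE of the mean),
sterile draws below 5% of the observed sterile mean are redrawn (the
ratio is unstable near zero), and `me_se` is the SD of the simulated
ratios. The delta method
Var(ME) = Var(L)/S^2 + L^2 Var(S)/S^4 is provided as a fast
cross-check; the two agree within a few percent when cell CVs are below
about 10%, and a sterile CV above 0.33 triggers a heavy-tail warning.

**Reaction norms** are unweighted ordinary least-squares lines of ME on
a genotype-level predictor (historic soil nitrogen, or a microbiome
trait such as diazotroph richness treated as a conserved genotype
trait). Inverse-variance weighting is available behind a flag but is
not the default, since the displayed fits are ordinary lines.

**Slope comparison between nitrogen environments** is a parametric
bootstrap: every genotype's ME is perturbed independently in both
environments as normal(ME, me_se), both reaction norms are refit, and
the two-sided p-value for delta = slope_high - slope_low uses the
(1 + b)/(1 + m) convention capped at 1. Perturbations are independent
across environments; correlating them (or regression-based
propagation) would be an alternative reading of the procedure, and the
independence assumption is stated here deliberately. Under a null
generator the test holds its size (unit- and acceptance-tested); its
power at 10 genotypes x ~7 surviving replicates exceeds 0.8 for the
default opposite-sign slopes.

## The synthetic study

The generator's defaults are the study conditions; they are not tuning
knobs.

- **Panel**: coordinates uniform over a Turkey-like bounding box (lon
  26-45, lat 36-42); environment variables are exponential-kernel
  Gaussian fields (default range 200 km, 50% nugget) cross-correlated
  by a fixed, plausible matrix (soils 0.3 among themselves,
  precipitation 0.6, temperature weakly negative with precipitation)
  and mapped to plausible units. The standardized soil nitrogen is the
  downstream predictor; no units are asserted for it.
- **Counts** are Dirichlet-multinomial: concentration =
  dispersion x softmax(logits), logits = taxon baseline (SD 1.2) +
  genotype loading + responder slope x soil N + block shift. The
  universal marker uses 400 taxa at depth 2000 and dispersion 300; the
  diazotroph marker 60 taxa at depth 1000, dispersion 200 and a flatter
  baseline (SD 0.6) so occupied taxa are reliably detected.
- **Diazotroph richness gradient** (25 -> 12 expected occupied taxa
  across the soil-N range) is implemented by Bernoulli occupancy
  thinning per taxon per genotype, not abundance scaling, because the
  planted signal is in richness. **Ammonia-oxidizer relative
  abundance** (0.85% -> 1.12%) is planted exactly in expectation by
  rescaling the flagged group's share of the concentration mass.
- **Calibrated effect sizes.** Two magnitudes have no natural unit and
  were fixed once by the package's bisection calibration helpers:
  `genotype_sd = 0.14`, at which the genotype term explains ~25% of
  Bray-Curtis variation at the default design (inside the 21-31% band
  typical of host-genotype studies; note that a 40-level factor on 200
  samples already absorbs ~20% under pure noise, so the planted effect
  is the increment above that); and `env_beta = 0.315`, at which
  standardized soil nitrogen explains ~2% of community variation after
  conditioning (the ~1-3% range typical of environment effects in such
  panels).
- **Trait experiment**: trait = baseline x (1 + nitrogen effect x
  high-N) x (1 + ME x live) + baseline x (genotype + block + residual
  noise), with relative SDs 0.06/0.04/0.12 and ME = 0.2 + slope_e x
  soil N (slopes -0.15 and +0.15 in low and high glasshouse N).
  Germination failure removes 25% of pots completely at random,
  leaving ~291 of 400 plants.

What the generator does **not** emulate: read-level sequencing error
and chimeras, taxon-taxon ecological interactions, phylogenetic signal
in the planted effects (trees are independent coalescents), plasticity
of microbiome traits between experiments, and non-MCAR germination
failure. Passing tests therefore demonstrate that the estimators
recover the planted statistical structure at the study's design size --
not that real communities satisfy these models.

## Numerical choices and problem sizes

P-values everywhere include the observed statistic ((1+b)/(1+m)).
Eigenvalues are called positive above a relative tolerance of ~1e-8;
predictors absorbed by a condition block (residual norm ~0) are dropped
with a warning. Forward-selection ties on p break toward the larger F.
Dirichlet draws that are all-zero (all concentrations zero) fall back
to the largest-concentration taxon. Seeds derive child seeds by fixed
offsets so stages are independently reproducible.

The test suite exercises the full design (40 x 5 and 10 x 2 x 2 x 10)
where a property is about that design (variance shares, selection
recovery, power) and reduced designs (4-12 genotypes, 60 taxa, depth
300-1000; 1000-replicate null batteries) where the property is
size-free, keeping the suite fast while the acceptance checks still
run the study-scale configurations.

## Known limitations

- The slope-comparison bootstrap treats propagated SEs as known;
  with ~7 replicates per cell they are noisy, which the calibration
  tests show is tolerable at this design but would bias p slightly at
  much smaller sizes.
- Sequential (Type-I) PERMANOVA R^2 depends on term order; the package
  follows the fixed order genotype, block.
- The residual-df rule for mixed-model F tests is anticonservative for
  genotype-level covariates when genotype variance is substantial; the
  package reports the singular flag so users can judge, and the
  between-genotype tests of primary interest are also covered by the
  permutation machinery.
- `aggregate_to_rank` pools unlabeled ASVs into one "unclassified"
  lineage, which can merge unrelated taxa at coarse ranks.
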