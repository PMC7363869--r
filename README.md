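# hierSDM

Hierarchical presence-only species distribution models and
priority-management zoning for invasive terrestrial vertebrates.

## The problem

Invasive species break the two assumptions classical species
distribution models (SDMs) lean on. Their niche need not transfer from
the native to the invaded range, and they are rarely at equilibrium
with the invaded environment: a grid cell without records may be
perfectly suitable but not yet reached, so treating background cells as
absences biases regional models. `hierSDM` implements the hierarchical
two-tier design built for this situation, plus the multi-species
synthesis around it, for anyone modelling invasion risk from
opportunistic presence-only portals (GBIF-style records with
coordinate-uncertainty fields, duplicated and erroneous coordinates,
and uneven sampling effort).

## The method

For each species:

1. **Global climate-only tier.** Records from the native and invaded
   ranges (the *certain + NA* dataset: coordinate uncertainty ≤ 15,000 m
   or unknown) are filtered, cleaned of common coordinate errors,
   and thinned to one presence per 0.25° cell. An ensemble of five
   learners (GLM, spline GAM, FDA-style discriminant, boosted trees,
   regularized logistic) is fitted against uniformly sampled
   pseudo-absences, members with held-out TSS ≥ 0.7 are kept (top 10%
   as fallback), and their binarized predictions are committee-averaged
   into a global climatic suitability map `projG` in [0, 1].
2. **Pseudo-absence weighting.** Regional pseudo-absences are weighted
   by how climatically *unsuitable* their cell is, via the inverse
   logistic transform

   ```
   Weight(x) = 1 / (1 + (projG(x) / (projG(x) − 1))²),   Weight(x) = 0 when projG(x) = 1
   ```

   so a pseudo-absence in hostile climate counts as a near-certain
   absence (weight → 1) and one in fully suitable climate is ignored
   (weight → 0). The weight is strictly decreasing and satisfies
   `Weight(p) + Weight(1 − p) = 1`.
3. **Regional full-predictor tier.** The regional ensemble (precise,
   *certain*-only records; climate plus habitat descriptors screened by
   stepwise VIF at threshold 4) is fitted with those case weights, and
   its committee average is binarized at the TSS-maximizing cutoff.

Across species, binary maps stack into predicted richness; a
classification tree on (mean ensemble CV, regional richness, global
richness) labels each cell as one of six priority-management zones
(A coldspot, B hotspot, C uncertain coldspot, D uncertain climatic
hotspot, E uncertain environmental hotspot, F uncertain hotspot).
Extrapolation is flagged by MESS (multivariate environmental similarity
surfaces), sampling-effort gaps by a half-ignorance index
`h / (n + h)` on per-cell record counts, and prediction-map divergence
by Bhattacharyya distances.

A virtual-species module generates the whole study at desk scale:
autocorrelated environmental fields (with planted collinear layers),
a known suitability surface, and biased presence-only sampling with
log-normal coordinate uncertainty, missing-uncertainty records and
injected coordinate errors, so every stage of the pipeline is testable
against a known truth.

## Worked example

```r
library(hierSDM)

config <- demoRunConfig(masterSeed = 1)   # 2 virtual species, 40 x 40 region
res <- runPipeline(config)

res$report$regional
#>           Species   n  TSS Sensitivity Specificity Cut-off binary Mean CV Range filling
#> 1 virtualis_clima 203 0.70       87.68       81.83           0.43    0.06          0.42
#> 2 virtualis_silva 197 0.72       95.94       76.16           0.01    0.09          0.34

res$report$zoneFractions
#>   zone                           label nCells fraction
#> 1    A                        coldspot   1242 0.776250
#> 2    B                         hotspot    330 0.206250
#> 3    C              uncertain_coldspot     14 0.008750
#> 4    D      uncertain_climatic_hotspot     11 0.006875
#> 5    E uncertain_environmental_hotspot      1 0.000625
#> 6    F               uncertain_hotspot      2 0.001250
```

Reading the output: `n` is the number of presence cells fitted; `TSS`
(sensitivity + specificity − 1) is the skill of the binarized committee
average at its reported cut-off, with sensitivity/specificity printed
as percentages; `Mean CV` is the standardized among-member coefficient
of variation (prediction disagreement); `Range filling` is the fraction
of the predicted suitable range holding observed records — low values
mean the species has room to spread. The zone table partitions the
region: here ~21% of cells are certain richness hotspots (zone B),
where prevention and control effort would concentrate, and the small
C–F fractions are cells whose predictions disagree enough to need more
survey data. The run directory (`res$dir`) holds every layer as a
plain-text grid plus per-stage CSV reports.

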