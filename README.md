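# CropSuit

Multi-criteria crop-suitability mapping in R: Analytic Hierarchy Process
(AHP) weighting with a consistency gate, per-crop subclass reclassification
of environmental raster layers, weighted-overlay scoring, equal-interval
classification, land-cover constraint masking, area tabulation and
presence/absence AUROC validation — with a seeded synthetic coastal
landscape so the whole pipeline runs end-to-end with no external data.

It is written for agro-ecological and land-evaluation analysts who have
co-registered gridded layers (elevation, slope, soil depth/drainage/texture/
pH/SOC, rainfall, temperature, land cover) and want a reproducible,
scriptable implementation of the classic AHP + weighted-overlay workflow
for rice and coconut (or their own schemes and judgment matrices).

## The model

Criterion weights come from a Saaty pairwise comparison matrix A
(judgments 1–9 and reciprocals). Weights W are the column-normalization
approximation (normalize each column to sum 1, average rows). Consistency
is gated by

    CI = (λ_max − n) / (n − 1),   CR = CI / RI,   accept iff CR < 0.1

where λ_max summarizes the consistency vector (A·W)/W (the package default
reports its maximum, mirroring the common spreadsheet workflow; mean and
exact-eigenvalue estimators are also available) and RI is Saaty's random
index. Each criterion layer is reclassified into subclasses carrying AHP
subclass weights w_ik, and the suitability index is the weighted overlay

    S(cell) = Σ_i  W_i · w_i(cell)

classified into S1/S2/S3/N by equal intervals of the observed index range,
then masked by a cropland/non-cropland land-cover partition. Maps are
validated by AUROC (Mann–Whitney with midrank ties) of presence records
against random absences drawn outside the highly suitable class.

## Worked example

```r
library(CropSuit)

# 1. AHP analysis of the packaged rice criterion matrix
ahpAnalyze(ricePairwiseMatrix())
#> ConsistencyReport (n = 9, lambda_max estimator 'rowmax')
#>   rainfall       0.2903
#>   temperature    0.0255
#>   drainage       0.2468
#>   depth          0.1121
#>   texture        0.1557
#>   slope          0.0576
#>   elevation      0.0576
#>   soc            0.0367
#>   ph             0.0179
#>   lambda_max = 9.9122  CI = 0.1140  RI = 1.46  CR = 0.0781 -> accepted (CR < 0.1)

# 2. Full pipeline on a seeded synthetic coastal landscape
cfg    <- landscapeConfig(seed = 101)     # 64 x 64 grid of 250 m cells
bundle <- generateLandscape(cfg)
result <- runPipeline(bundle, "rice")
result
#> SuitabilityResult for rice
#>   index range [0.091, 0.443], breaks 0.1788, 0.2670, 0.3552
#>   criterion CR = 0.0781 (accepted)
#>          class cells area_ha area_pct
#> 1           S1   699    4369   17.065
#> 2           S2  1273    7956   31.079
#> 3           S3   442    2762   10.791
#> 4            N   167    1044    4.077
#> 5 non-cropland  1515    9469   36.987

# 3. Validate against synthetic presences planted on the true index
occ <- generateOccurrences(suitabilityIndex(result), cfg, n = 200)
validateSuitability(suitabilityIndex(result), maskedClasses(result),
                    occurrencePoints(occ), seed = 7)
#> RocResult: AUROC = 0.992 (very high accuracy), 200 presence / 200 absence
```

Reading the output: rainfall (0.29) and drainage (0.25) dominate the rice
weighting, and the matrix passes the CR < 0.1 gate. On the synthetic
landscape the index spans [0.091, 0.443]; equal intervals of that range
give the three breaks, ~37 % of the area is masked as non-cropland, and
occurrences planted with a strong dependence on the true index are
recovered with near-perfect AUROC — the expected behaviour when the map is
right.

A thin command-line wrapper over the same functions ships in
`inst/scripts/suit.R` (`weights`, `simulate`, `run`, `validate`
subcommands).

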