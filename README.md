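# ipsoseg

Maximum-entropy gray-scale image segmentation driven by an improved particle
swarm optimizer, with the evaluation machinery for comparing segmentations
and diagnostic modalities. The motivating application is prenatal MRI of
placenta accreta — delineating the bright placental region from the
myometrial band and grading the depth of villous invasion (adhesive /
implantable / penetrated) — but every component operates on plain 8-bit
rasters and ships with a synthetic phantom generator, so the whole method is
reproducible without clinical data.

## The method

**Optimizer.** A global-best PSO whose velocity update is damped by a
*shrinkage (constriction) factor* decreasing linearly over iterations,

$$P(n) = P_{\max} - (P_{\max} - P_{\min})\,\frac{n}{n_{\max}}, \qquad
v_i \leftarrow P(n)\big[w\,v_i + c_1 r_1 (p_i - x_i) + c_2 r_2 (g - x_i)\big],$$

so the swarm explores early ($P \approx P_{\max}$) and refines late
($P \to P_{\min}$). A fixed-factor baseline (`pso_optimize_standard()`) is
included for comparison runs.

**Objective.** Kapur's maximum-entropy criterion over the gray-level
histogram: thresholds $t_1 < \dots < t_k$ maximize the summed Shannon
entropies of the resulting intensity classes (in nats; empty classes are
infeasible). An exhaustive search (`exhaustive_threshold_search()`) serves
as the brute-force oracle against which the PSO search is validated.

**Pipeline.** `segment_image()` chains linear percentile contrast stretch,
optional Gaussian smoothing, the PSO entropy-threshold search, strict
binarization at the largest threshold (brightest class = target),
8-connected component labeling and area filtering. Everything is a pure
function of the image and one integer seed.

**Evaluation.** Jaccard (intersection-over-union) against reference masks;
sensitivity / specificity / accuracy from 2×2 confusion counts (zero
denominators reported as *undefined*, never silently 0); McNemar's paired
chi-square test — with the continuity correction clamped at zero — for
comparing two modalities on the same cases; and a repeated 2-fold
cross-validation harness with light per-fold tuning of the preprocessing
parameters.

## Worked example

```r
library(ipsoseg)

# A degraded uterine phantom with known ground truth
ph <- make_phantom(phantom_params(noise_sigma = 5, bias_amplitude = 0.1, seed = 8))
ph
#> <phantom_case phantom_seed8: 256x256, grade implantable, truth area 3360 px>

# Segment it: two thresholds because the phantom has three tissues
# (background / myometrium / placenta); the brightest class is the target
res <- segment_image(ph$image, pipeline_config(entropy_k = 2, seed = 42))
res
#> <segmentation_result: thresholds [35, 139], Kapur score 9.0833, 3579 foreground px>
jaccard_index(res$mask, ph$truth_mask)
#> [1] 0.9388097
```

The two thresholds split the stretched histogram into background,
myometrial band, and placenta; binarizing above 139 recovers 3579 of the
3360 true placental pixels' region with Jaccard 0.94 despite noise and a
10% bias field. On the uniform histogram the search reproduces the
closed-form optimum — threshold 127 with entropy `2*log(128)`:

```r
pso_threshold_search(gray_histogram(rep(1, 256)), 1, pso_config(seed = 7))[c("thresholds", "score")]
#> $thresholds
#> [1] 127
#> $score
#> [1] 9.704061
```

Comparing two simulated imaging modalities on one pathology-confirmed
cohort (all cases disease-positive, so specificity is undefined by design):

```r
calls <- simulate_reader_calls(200, 0.92, 0.9, 0.80, 0.9, correlation = 0.3, seed = 3)
rep <- cohort_report(calls)
dplyr::filter(rep$tests, stratum == "overall")
#> # A tibble: 1 × 7
#>   stratum     n     b     c statistic  p_value significant
#> 1 overall   200    37    10      14.4 0.000149 TRUE
```

Modality A was correct on 37 cases where B erred, B on 10 where A erred;
McNemar's corrected statistic 14.4 (p ≈ 1.5e-4) declares the sensitivity
difference significant at α = 0.05.

A thin command-line wrapper over the same functions lives at
`inst/cli/ipsoseg.R` (subcommands `segment`, `crossval`, `eval`, `diag`,
`phantom`, `compare-pso`).

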