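# dentalabel

Automatic tooth numbering for 3D intra-oral scans (IOS) is usually split
into three steps: detect tooth instances on the scan surface, segment each
detection into tooth and gingiva points, and finally decide which FDI code
(11–48) each detection carries. The first two steps are well served by
learned detectors; the third is a combinatorial problem — the 32 codes must
be distributed over a variable number of detections so that jaws, left-right
order and inter-tooth spacing all stay anatomically consistent, including
when teeth are missing or detections are spurious.

`dentalabel` implements that third step for dental researchers and
engineers building IOS pipelines, together with everything needed to
exercise and evaluate it without a scanner: mesh I/O with instance
annotations, the geometric preprocessing used around a detector
(bounding boxes, fixed-size point sampling, grid max-pooling), a
distance-prior estimator, the full detection/segmentation/numbering metric
suite, and a seeded synthetic dental-arch and detector simulator.

## The assignment model

Detections are summarized by the centers of mass (COM) of their segmented
tooth points. With `E ∈ {0,1}^{N×32}` the assignment matrix (`e_nc = 1`:
detection `n` carries code `c`, row sums ≤ 1), labels are refined in three
stages:

1. **Greedy jaw-consistent assignment** minimizing

   `f1(E) = f11(E) + λ12·f12(E) + λ13·f13(E)`

   where `f11 = Σ_c max(Σ_n e_nc − 1, 0)` penalizes duplicated codes,
   `f12` counts assignments whose COM lies on the wrong side of the axial
   watershed `COM⊙^z` (the mean COM height, separating the two half jaws),
   and `f13 = Σ_n max(1 − Σ_c e_nc, 0)` counts unassigned detections.
   Defaults `λ12 = 0.1`, `λ13 = 0.01` rank the concerns strictly.

2. **Left-right sorting**: within each jaw the assigned codes are permuted
   so that COM x grows with the code's position along the arch, driving the
   pairwise inversion count `f2` to its global minimum of 0.

3. **Slot placement against a distance prior**: keeping the sorted order,
   the jaw's detections are placed into its 16 arch slots (blank slots model
   missing teeth) by exhaustive enumeration of all `C(16, N)` order-
   preserving placements, minimizing

   `f3(E) = Σ pairs (|COM_n1 − COM_n2| − D_c1c2)²`

   where `D` is a 32×32 matrix of mean inter-tooth COM distances (mm)
   estimated from labeled scans (`estimate_distance_prior()`), or computed
   analytically from a template arch (`template_prior()`).

A brute-force lexicographic oracle (`brute_force_label()`) and literal
penalty transcriptions in the test suite verify each stage's optimality on
small scenes.

## Worked example

Simulate an upper arch missing two teeth, push it through a noisy detector,
label it, and evaluate against the ground truth:

```r
library(dentalabel)

tpl    <- default_template("upper")
prior  <- template_prior(tpl)
truth  <- generate_scene(tpl, simulation_config(seed = 42,
                                                missing_codes = c(18L, 25L)))
sim    <- simulate_detector(truth, simulation_config(seed = 43,
                                                     com_jitter_sigma = 0.3,
                                                     miss_rate = 0.05))
result <- label_teeth(sim$scene, prior)
result
#> <labeling_result> 14/14 detections assigned
#> # A tibble: 3 × 4
#>   stage    f1    f2     f3
#>   <chr> <dbl> <int>  <dbl>
#> 1 E1        0     0 5413.
#> 2 E2        0     0 5413.
#> 3 E3        0     0   19.6
```

The stage table shows the refinement at work: stages 1–2 already assign
each detection a unique, jaw-consistent, left-to-right sorted code
(`f1 = f2 = 0`), but with two teeth missing the codes are crammed into the
wrong slots — the distance penalty `f3 ≈ 5413` mm² flags pair distances far
from the prior. Stage 3 re-opens the slot choice and drops `f3` to
19.6 mm² (residual COM jitter), skipping the slots of the two absent teeth.

```r
head(tidy(result), 4)
#> # A tibble: 4 × 2
#>   detection_id   fdi
#>          <int> <int>
#> 1            1    17
#> 2            2    16
#> 3            3    15
#> 4            4    14

report <- evaluate_scene(sim$scene, truth$scene, tidy(result))
report
#> <detection_matching> 14 matched, 0 unmatched predictions, 0 unmatched ground truths
#> <labeling_eval> mean per-tooth accuracy 1 over 14 codes
```

All 14 surviving detections are matched and numbered correctly despite the
0.3 mm COM jitter. `autoplot(sim$scene, labels = tidy(result))` draws the
labeled occlusal view; `autoplot(report$labeling)` renders the per-jaw
confusion heatmaps.

A command-line workflow (simulate → fit-prior → label → eval) is available
through the dispatcher installed at
`system.file("cli", "dentalabel.R", package = "dentalabel")`.

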