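# ki67cells

Automated cell detection, classification and clinical scoring for Ki-67
immunohistochemistry (IHC) images of breast tumors.

Pathologists grade tumor proliferation by the **Ki-67 index** — the
fraction of tumor cells whose nuclei take up the Ki-67 stain,

    Ki-67 = pos / (pos + neg),

and quantify the immune infiltrate by the **TILs score** — the fraction of
tumor-infiltrating lymphocytes among all counted cells,

    TILs = lym / (lym + pos + neg),

each mapped to clinical cut-off categories (Ki-67: &lt;16 % / 16–30 % /
&gt;30 %; TILs: ≤10 % / &lt;40 % / ≥40 %). Counting the thousands of
touching nuclei behind those two ratios is the bottleneck this package
automates, for image analysts and computational pathology researchers.

The pipeline:

1. **Point annotations → density maps.** Expert labels are cell centers
   plus a class (immunopositive, immunonegative, lymphocyte). Each center
   becomes a truncated Gaussian bump (σ = 3 px by default) in one of three
   density channels — a smooth regression target that tolerates small
   localization error (`encode_density()`).
2. **Density regression.** A U-Net-like encoder–decoder built from
   *residual dilated inception modules* — parallel plain and dilation-4
   convolution paths summed with a residual — regresses the three channels
   from the RGB tile (`build_density_net()`, `train_network()`, MSE + Adam,
   lr 1e-4 decaying ×0.1 every 10 epochs).
3. **Watershed post-processing.** Per channel: threshold, Euclidean
   distance transform, negation, deterministic priority-flood watershed;
   one detection per basin at the distance-transform maximum, so touching
   cells are split (`extract_centers()`).
4. **Scoring.** Detections match ground truth within a radius (strict
   `< R`, greedy by distance); precision/recall/F1 per class plus
   support-weighted averages, Ki-67 and TILs scores with their cut-off
   categories, and RMSE between predicted and true scores
   (`match_detections()`, `evaluate_detections()`, `aggregate_patients()`).

A seeded synthetic-tile generator with exact ground truth
(`generate_image()`, `generate_dataset()`) makes the whole pipeline
testable end to end without any external dataset.

## A worked example

```r
library(ki67cells)

# an easy synthetic tile with known ground truth
s <- generate_image(easy_synth_params(seed = 7), image_id = "demo")
class_counts(s$truth)
#> immunopositive immunonegative     lymphocyte
#>              2              2              2

# train the reduced network briefly and run the full pipeline
bm <- run_synthetic_benchmark(n_train = 300, n_test = 50, epochs = 25,
                              seed = 1)
tidy(bm$report)
#> # A tibble: 3 × 8
#>   class class_name        tp    fp    fn precision recall    f1
#>   <int> <chr>          <int> <int> <int>     <dbl>  <dbl> <dbl>
#> 1     0 immunopositive   100     0     0         1      1     1
#> 2     1 immunonegative   100     0     0         1      1     1
#> 3     2 lymphocyte       100     0     0         1      1     1
glance(bm$report)[, c("f1", "rmse_ki67", "rmse_til")]
#> # A tibble: 1 × 3
#>      f1 rmse_ki67 rmse_til
#>   <dbl>     <dbl>    <dbl>
#> 1     1         0        0
```

Every cell on the 50 held-out tiles is recovered with the correct class
(per-class F1 = 1), so the per-image Ki-67 and TILs scores match the truth
exactly (RMSE 0). On real stained tissue — where weakly stained nuclei and
lymphocyte/immunonegative confusion dominate — published methods of this
family reach weighted F1 around 0.79 after long GPU training; the synthetic
benchmark verifies the machinery, not clinical performance.

The clinical score path on its own:

```r
agg <- aggregate_patients(data.frame(
  patient_id = c("P1", "P1"),
  immunopositive = c(10, 30), immunonegative = c(30, 30),
  lymphocyte = c(0, 20)))
agg[, c("ki67_index", "til_score", "ki67_category", "til_category")]
#> # A tibble: 1 × 4
#>   ki67_index til_score ki67_category til_category
#>        <dbl>     <dbl> <fct>         <fct>
#> 1        0.4     0.167 high          intermediate
```

A thin command-line front end (`inst/cli/ihccount`) exposes the same
functions as `synth`, `train`, `predict`, `evaluate` and `score`
subcommands.

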