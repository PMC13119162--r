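# dissolvis

Predictive–interpretive modelling of tablet **surface dissolution imaging**.

Flow-cell dissolution imagers record dual-wavelength absorbance maps of a
dissolving tablet: a 280 nm UV channel in which the dissolved drug absorbs
(where release happens) and a 520 nm visible channel that tracks the tablet
matrix itself (erosion fronts, gel layers). `dissolvis` is for formulation
scientists and method developers who want to (a) predict the dissolved drug
percentage Q% directly from such images and (b) see *where in the image* the
model finds that information.

The package contains the whole loop, self-contained in R:

* **Simulator** — a physics-inspired generator of paired 280/520 nm image
  sequences for eight tablet formulations (acetylsalicylic acid, sodium
  salicylate or salicylamide with lactose or methylcellulose, plus two
  placebos) in two compendial media (pH 1.2, pH 6.8), with known Q(t),
  edge-initiated erosion vs. gel-layer morphology, pH-dependent kinetics via
  tabulated solubilities, and ground-truth edge/core/holder saliency masks.
* **Dataset stage** — Beer–Lambert calibration fits, the replaced-volume
  cumulative release correction
  (m_n = C_n·V + V_s·Σ_{i<n} C_i), bilinear image preprocessing to [0,1],
  the constant "time matrix" tensor (value t/240), seeded 80:20 record
  splits (ceiling rule: 153 records → 122/31), and canonical one-hot
  condition encoding.
* **Model ladder** — a from-scratch multimodal convolutional regression
  network (two image branches, a time branch, a composition vector fused by
  concatenation into a 128→64→1 dense head; Adam, MSE), its ablations
  (images only; images+time; everything), a numeric-only network and an
  ordinary least-squares baseline. Convolution/pooling kernels and exact
  backpropagation are implemented in RcppArmadillo — no external deep
  learning framework.
* **Grad-CAM for regression** — saliency of the scalar Q% prediction per
  image branch, validated at machine precision on an analytic toy network
  and rank-checked against an occlusion oracle; edge/core/holder
  localization statistics against the simulator's masks.
* **Pipeline** — `run_pipeline()` / `run_ladder()` orchestrate
  simulate → dataset → train → evaluate → explain with full seed control,
  and a thin CLI lives in `inst/cli/dissolvis.R`.

## The model in brief

Each record is (x₂₈₀, x₅₂₀, t, c): two RGB frames, the sampling time and a
one-hot composition vector. The full network predicts

Q̂ = f(x₂₈₀, x₅₂₀, t, c) ∈ [0, 100] (%),

minimizing mean squared error; performance is reported as R² = 1 −
SS_res/SS_tot and RMSE in Q% units, overall and stratified by medium.
Grad-CAM weights the final convolution layer's activations A_f by
global-average-pooled gradients α_f = GAP(∂Q̂/∂A_f) and reports
ReLU(Σ_f α_f A_f), min–max normalized and upsampled onto the frame.

## Worked example

```r
library(dissolvis)

# 1. simulate the 16-experiment study design and assemble the dataset
sdi   <- simulate_dataset(seed = 1)
ds    <- build_dataset(sdi, size = 64)
split <- make_split(length(ds$q), 0.2, seed = 1)

# 2. train the full multimodal network (desk-scale protocol)
cfg <- model_config("full_multimodal", epochs = 35, learning_rate = 0.01,
                    batch_size = 4, seed = 1, time_size = 16)
m   <- train_model(build_model(cfg, condition_dim = ncol(ds$cond),
                               input_size = 64), ds, split)

# 3. evaluate on the held-out records
evaluate_model(m, ds, split$test)
#> <eval_report> full_multimodal: R^2 = 0.999, RMSE = 1.06% (n = 22)
#> # A tibble: 2 × 4
#>      ph r_squared  rmse     n
#>   <dbl>     <dbl> <dbl> <int>
#> 1   1.2     0.999 1.22      10
#> 2   6.8     0.998 0.905     12
```

The printout says the network recovers the simulator's dissolved-percentage
labels on unseen records nearly perfectly at desk scale (the average
prediction error is about one percentage point of dose) in both media. An
explanation for one held-out record:

```r
sm <- gradcam(m, ds, split$test[1], branch = "280")
localization_stats(sm, sdi$experiments[[ds$meta$experiment[split$test[1]]]]$truth)
#> # A tibble: 1 × 5
#>   branch edge_mean core_mean holder_mean edge_core_ratio
#>   <chr>      <dbl>     <dbl>       <dbl>           <dbl>
#> 1 280       0.0272  0.000424      0.0469            64.3
autoplot(sm)
```

`localization_stats()` returns the mean importance inside the edge annulus,
the tablet core and the holder bracket, and the edge/core ratio — for this
record the 280 nm saliency sits almost entirely on the release front (ratio
~64), with some importance on the static holder, the dissociation the
dual-wavelength design predicts. Holder activation is reported, not
suppressed.

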