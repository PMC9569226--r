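# mvfcc — multiview deep learning for brain functional connectivity classification

`mvfcc` classifies subjects (for example patients with a neuropsychiatric
disorder versus controls) from resting-state functional connectivity built
under **several brain atlases at once**. Each atlas parcellates the cortex
into a different set of regions of interest, so the same subject yields
several connectivity *views*; the package exploits the complementary
information across views at two points in the pipeline — feature selection
and deep feature fusion — rather than analysing one atlas at a time.

It is aimed at researchers working with ROI time series exported from
standard fMRI preprocessing (e.g. the whitespace-delimited `.1D` dialect of
the Preprocessed Connectomes Project). Raw image preprocessing is out of
scope: the package consumes region-by-timepoint tables and everything
downstream of them.

## Method

**Connectivity features.** For each atlas with *n* regions, the Pearson
correlation between every pair of regional time series is Fisher
z-transformed and the strict upper triangle is vectorized row-major into
*n(n−1)/2* features per subject (19 900 for a 200-region parcellation, 4 005
for 90 regions, 12 720 for 160).

**View-weighted sparse selection.** With view *v* as the *primary* view and
all others *auxiliary*, the selection weights ω solve

    min_ω  (1/2N) Σᵢ (yᵢ − ωᵀxᵢ)²  +  λ (a₁‖ω₁‖₁ + a₂‖ω₂‖₁),   a₁ + a₂ = 1,

where ω₁/ω₂ are the primary/auxiliary weight blocks. A small a₁ (default
0.2) penalizes the primary view lightly, so its discriminative features
survive while the auxiliary views act as guidance. The problem is solved by
proximal gradient (ISTA) with fixed step 1/L — L the largest eigenvalue of
XᵀX/N — whose proximal map is the per-position soft threshold with
θₚ = λ·a_g/L. Each view keeps the support from the run in which it was
primary.

**Deep features and fusion.** The selected features of each view pass
through a per-view stacked autoencoder (tanh layers, optional greedy
layer-wise reconstruction pretraining). At the fusion layer each view is
linearly mapped to a common K-dimensional space, u_v = W_v v_v, and the
fused representation is z = Σ_v u_v. A normalized cross-correlation (NCC)
term over consecutive view pairs, computed per sample over the K fused
coordinates, is *maximized* during training to align the views in the
common space.

**Prototype classification.** Each class is represented by a prototype
(the class mean in the final feature space, recomputed every epoch).
Classification uses the distances d_c = ‖g(x) − p_c‖²: probabilities
P(c|x) ∝ exp(−γ d_c) feed a distance-based cross-entropy loss, a margin
term max(0, d_y − d_r + m) keeps the true prototype closer than the nearest
rival, and the full objective

    L = L_DCE + λ₁ L_MP − λ₂ L_MV

is minimized by Adam (defaults: batch 96, learning rate 1e-4).

**Evaluation.** Rotating 5-fold cross-validation at a 3:1:1
train/validation/test ratio with disjoint test folds; accuracy,
sensitivity, specificity, PPV and NPV as percentages; ablation harnesses
over view subsets, the primary-view weight a₁, and fusion mode/position.

A synthetic generator (`generate_multiview()`, `generate_timeseries()`)
plants known discriminative edges — partially driven by a latent factor
shared across views — so every stage can be validated against ground truth
without any data download.

## Worked example

```r
library(mvfcc)

gen <- generate_multiview(synth_config(N = 200, seed = 42))
gen$data
#> Multiview dataset: 200 subjects, 3 views (D = 376)
#>   view1: 190 features
#>   view2: 66 features
#>   view3: 120 features
#>   classes: control=100, patient=100

sel <- run_per_view_selection(gen$data, a1 = 0.2, lam = 0.5)
vapply(sel$support, length, integer(1))
#> view1 view2 view3
#>    13    14    12
round(mapply(support_jaccard, sel$support, gen$truth$planted), 2)
#> view1 view2 view3
#>  0.64  0.71  0.83

res <- run_experiment(gen$data, synthetic_benchmark_config(), seed = 42)
res
#> Cross-validated multiview classification (5 folds)
#>  fold  ACC   SEN    SPE    PPV   NPV
#>     1 90.0 88.24  91.30  88.24 91.30
#>     2 92.5 95.24  89.47  90.91 94.44
#>     3 97.5 96.00 100.00 100.00 93.75
#>     4 92.5 89.47  95.24  94.44 90.91
#>     5 85.0 83.33  86.36  83.33 86.36
#> mean: ACC 91.50  SEN 90.46  SPE 92.48  PPV 91.38  NPV 91.35
```

Each view carries 10 planted discriminative edges; the selection keeps
12–14 features per view with Jaccard overlaps of 0.64–0.83 against the
planted truth, and the full pipeline reaches a mean cross-validated
accuracy of 91.5% on this replicate.

The same pipeline is scriptable from a shell via `inst/cli/mvfcc`
(subcommands `simulate`, `select`, `train`, `predict`, `evaluate`,
`ablate`; one YAML config, one master seed).

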