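# lotra: local topological recurrence analysis of time-series data

Classical recurrence analysis of a dynamic signal thresholds the pairwise
phase-space distance matrix `D` with a Heaviside step,
`R_ij = Θ(ε − ‖V_i − V_j‖)`, discarding everything the threshold does not
keep. **lotra** implements an un-thresholded alternative: every interior
cell of `D` is replaced by an 8-bit local-binary-pattern code describing the
inequality structure of its 3×3 neighbourhood,

    code(i, j) = Σ_{n=1..8} s(g_n − g_0) · 2^(n−1),   s(x) = 1 iff x ≥ 0,

where `g_0 = D_ij` and `g_1..g_8` are its eight neighbours (bit order
starting at the preceding-time corner `D_{i−1,j−1}`). The resulting code
matrix (values 0–255) retains graded curvature and directionality
information about the phase-space trajectory that a single ε cut-off throws
away; the "high-curvature" code band 64–191 yields a binary sparse matrix
whose recurrence statistics make a compact, discriminative feature vector.

The package is aimed at people analysing biomedical time series — digitised
handwriting/drawing tests, wearable-sensor gait records, fibre-photometry
population signals — and provides the full pipeline:

* **Embedding** — time-delay embedding `V_i = (x_i, x_{i+t}, …, x_{i+(m−1)t})`
  with data-driven selection of delay `t` (first local minimum of average
  mutual information) and dimension `m` (false-nearest-neighbour fraction
  falling below a floor).
* **Transform** — distance matrices, the 8-bit code transform, code-band
  masks, and classical ε-thresholded recurrence matrices with exact
  calibration of ε to a target recurrence rate (e.g. 4–5% for periodic
  gait, ~2% for non-periodic photometry).
* **RQA** — recurrence rate, diagonal-line histograms, Shannon entropy of
  the line-length distribution, and the full 9-statistic feature vector
  (RR, DET, mean/max diagonal length, DIV, ENT, LAM, TT, max vertical
  length).
* **Classification** — an RBF-SVM over the 9 features, evaluated by nested
  leave-one-out cross-validation with fold-internal standardisation and
  hyperparameter selection (no leakage of the held-out subject).
* **Simulators** — the 300-point sine test signal, the Lorenz attractor
  (r = 28, σ = 15, β = 8/3, Δt = 0.025, RK4), and a synthetic labelled
  spiral-drawing cohort with a controllable tremor effect.
* **I/O** — readers for digitised spiral-drawing records
  (semicolon-delimited `X;Y;Z;Pressure;GripAngle;Timestamp;TestID` by
  default, fully remappable), downsampling/z-scoring, quadratic photometry
  detrending, CSV and sparse-mask serialisation, and quartile-coloured PNG
  rendering of code matrices.

## Worked example

The canonical illustration: a 300-point sine wave embedded in 2-D with
delay 15 (a quarter period, giving a near-circular trajectory), transformed
and summarised.

```r
library(lotra)

s   <- sine_series()                       # 300 samples, sin(0.1 .. 30)
fit <- lotra(s$values, delay = 15, scale = FALSE)
fit
#> Local topological recurrence analysis
#>   trajectory: 285 points in 2 dims (t = 15, m = 2)
#>   code matrix: 283 x 283, band [64, 191] occupancy 2.5%

summary(fit)
#> Recurrence statistics of the band-[64, 191] mask (N = 285):
#>          rr         det mean_diag_l  max_diag_l         div         ent
#>      0.0248      0.9990     16.6975    282.0000      0.0035      2.8684
#>         lam          tt  max_vert_l
#>      0.2866      2.0000      2.0000

cal <- calibrate_epsilon(fit$distance, 0.045)   # classical route, RR ~ 4.5%
sprintf("epsilon = %.4f, achieved RR = %.4f", cal$epsilon, cal$rr)
#> "epsilon = 0.1371, achieved RR = 0.0450"
```

The band occupancy (2.5% here) is what separates trajectories of different
eccentricity: repeating the call with `delay = 20` and `delay = 3` gives
occupancies of 9.4% and 23.5% — the three embeddings are cleanly
distinguished by the code transform even when their ε-calibrated recurrence
matrices are pinned to the same recurrence rate.

End-to-end classification on the synthetic cohort:

```r
co <- synthetic_cohort(seed = 1)   # 20 + 20 subjects, 8% tremor effect
ft <- cohort_features(co)          # 40 x 9 feature matrix
cv <- nested_loocv(ft$features, ft$labels)
cv$rates["accuracy"]               # 1.0 on this strong, clean effect
```

## Command line

A thin CLI over the same functions lives at `inst/scripts/lotra`:

```sh
Rscript inst/scripts/lotra simulate --kind lorenz --out lorenz
Rscript inst/scripts/lotra transform --input lorenz.csv --dimension 1 --out lz
Rscript inst/scripts/lotra rqa --input lz_mask.txt --out features.csv
```

Every output carries a JSON sidecar recording the command, options and
seed.
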