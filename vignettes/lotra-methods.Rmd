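---
title: "Local topological recurrence analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local topological recurrence analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lotra)
```

## The problem and the model

A recurrence, in a dynamical system, is a return of the trajectory into the
neighbourhood of a previously visited state. The classical tool for finding
recurrences in a measured signal is the recurrence plot: embed the scalar
series $x = (x_1,\dots,x_n)$ as
$V_i = (x_i, x_{i+t}, \dots, x_{i+(m-1)t})$, form the Euclidean distance
matrix $D_{ij} = \lVert V_i - V_j\rVert$, and binarise it with a Heaviside
step at radius $\varepsilon$:
$R_{ij} = \Theta(\varepsilon - D_{ij})$. Everything then rests on
$\varepsilon$: too small and structure is lost, too large and spurious
recurrences flood in, and in either case the *graded* geometry of the
trajectory — how sharply it curves, in which direction it runs — is reduced
to inside/outside a ball.

The transform at the heart of this package removes the threshold. Each
interior cell of $D$ is compared with its own 3×3 neighbourhood

$$T_{ij} = \begin{pmatrix}
D_{i-1,j-1} & D_{i-1,j} & D_{i-1,j+1}\\
D_{i,j-1}   & D_{ij}    & D_{i,j+1}\\
D_{i+1,j-1} & D_{i+1,j} & D_{i+1,j+1}
\end{pmatrix}$$

and replaced by the local-binary-pattern code
$\sum_{n=1}^{8} s(g_n - g_0)\,2^{n-1}$ with $s(x) = 1$ iff $x \ge 0$, where
$g_0 = D_{ij}$ and $g_1..g_8$ are the eight neighbours. Two cells with
identical distances but different surrounding inequality patterns — a
shallow pass versus a vertex of the trajectory — receive different codes,
so the code matrix preserves curvature and directionality information that
thresholding destroys. Codes live in $\{0,\dots,255\}$; the band 64–191
(bit 7 set, bit 8 clear, i.e. patterns asymmetric in the "future" corner
directions) empirically concentrates on high-curvature structure and is the
default mask for feature extraction.

## Neighbour order and ties

"Moving around the centre" fixes the bit order only up to orientation and
starting point; exact code values depend on that choice, while all
statistics computed from band occupancies or masks are invariant up to a
bit permutation. The package fixes, once,

```
g1 (i-1,j-1)  g2 (i-1,j)  g3 (i-1,j+1)  g4 (i,j+1)
g5 (i+1,j+1)  g6 (i+1,j)  g7 (i+1,j-1)  g8 (i,j-1)
```

starting at the preceding-time corner, with weights $2^0\dots 2^7$, and
takes the tie rule literally: $s(0) = 1$, so a neighbour equal to the
centre sets its bit. Two consequences are used as internal checks: the
image of the line of identity is always coded 255 (centre distance 0,
neighbours $\ge 0$), and for symmetric $D$ transposition permutes bits as
$(g_1,g_8,g_7,g_6,g_5,g_4,g_3,g_2)$.

Codes are computed only at interior cells — the output is
$(N-2)\times(N-2)$ with a recorded index offset of 1 — because padding the
border would require inventing distances that were never measured.

## Embedding-parameter selection

The delay $t$ comes from the average mutual information profile (first
strict local minimum, else the first lag whose relative change drops below
`level_off_frac`, default 0.05) and the dimension $m$ from the false
nearest-neighbour profile (first $m$ with FNN fraction below 0.05, else the
first level-off). FNN uses the classical distance-ratio and attractor-size
criteria with defaults $r_{tol} = 15$, $a_{tol} = 2$.

AMI is estimated by a plug-in equal-width 2-D histogram. The bin count
defaults to $\max(8, \lfloor n^{1/3}\rfloor)$: the plug-in estimator's bias
for independent data is of order $(B-1)^2/(2n)$ nats, so a $\sqrt{n}$-bin
rule would put roughly half a nat of spurious "information" into every lag
of a $n = 10^4$ white-noise series, swamping the profile's structure,
whereas the cube-root rule keeps the bias near 0.02 nats at that length
while leaving short series with at least 8 bins. Equal-width binning over
the observed range makes the estimate exactly invariant to
orientation-preserving affine transforms.

Multi-channel recordings (e.g. x/y/pressure tablet traces) are treated as
already living in phase space: the default is $m = 1$, no embedding, and
AMI/FNN operate on a user-selected channel (first by default) when an
embedding is wanted anyway.

## Threshold calibration

For the classical route the package never asks for $\varepsilon$ directly.
`calibrate_epsilon()` searches the empirical distance spectrum — the sorted
unique off-diagonal values — and returns the smallest value whose
recurrence rate (diagonal included, per the density definition
$RR = N^{-2}\sum R_{ij}$) reaches the target. Because the spectrum is
searched exactly rather than bisected, recomputing the recurrence matrix at
the returned $\varepsilon$ reproduces the achieved rate to the last bit,
and the only deviation from the target is the discreteness of the spectrum
(at most one step of $2/N^2$). Typical operating points are 4–5% for
periodic gait-like signals and ~2% for non-periodic physiological signals.

## Recurrence statistics

`rqa_features()` returns the nine classical statistics
(RR, DET, mean/max diagonal line length, DIV, ENT, LAM, TT, max vertical
length), with $l_{min} = v_{min} = 2$ — two points define a line. The
diagonal-line entropy $ENT = -\sum_{l \ge l_{min}} p(l)\ln p(l)$ is the
package's complexity measure. Numerical conventions, chosen so feature
vectors are always finite: an empty line set gives $ENT = 0$ and zeroes
for the affected ratios (DET, DIV, LAM, TT); runs touching the matrix
border count at their observed length (no censoring correction); the line
of identity is excluded from diagonal statistics by default for
thresholded matrices (for the default 64–191 band mask the flag is moot —
the diagonal codes are all 255 and fall outside the band). The nine-member
composition itself is the standard recurrence-quantification canon; it is
exposed positionally so alternates can be substituted upstream of the
classifier.

Two non-obvious facts, encoded in the test suite because they are easy to
get wrong: a checkerboard matrix consists of *solid* diagonals (its
diagonal-line set is not empty), and an all-ones $N \times N$ matrix has
$DET = (N^2-2)/N^2 < 1$ at $l_{min}=2$ because the two corner cells sit on
length-1 diagonals.

## Simulators and what they do (not) show

*Sine.* 300 samples of $\sin(u)$, $u = 0.1, 0.2, \dots, 30$. With $m = 2$
the delays 15, 20 and 3 give loops of increasing eccentricity; their
band-64–191 occupancies (2.5%, 9.4%, 23.5%) separate by far more than a
percentage point while their calibrated recurrence matrices are pinned to
one recurrence rate — the core demonstration that the code transform sees
what thresholding cannot.

*Lorenz.* $\dot x = \sigma(y-x)$, $\dot y = x(r-z)-y$, $\dot z = xy-\beta z$
with $r = 28$, $\sigma = 15$ (a strongly chaotic variant of the classical
$\sigma = 10$, implemented as specified), $\beta = 8/3$, integrated by
fixed-step RK4 at $\Delta t = 0.025$ — fixed-step so that identical
parameters give bit-identical trajectories; a convergence test confirms the
expected $O(\Delta t^4)$ behaviour. The integrator, initial state
$(1,1,1)$, 4000 default steps and optional burn-in are package choices
where no canonical values exist. For the chaotic-vs-periodic entropy
benchmark the package uses 1000 steps with 200 discarded ($N = 801$, about
twenty characteristic oscillations): diagonal-line entropy is
trajectory-length sensitive — at a few hundred points the border-truncated
long lines of a *periodic* signal can carry more length diversity than a
short chaotic record, and the expected ordering
$ENT_{Lorenz} > ENT_{sine}$ (at matched calibrated RR) emerges reliably
only once the chaotic trajectory is several hundred points long. This size
is stated here as the benchmark's operating condition.

*Synthetic cohort.* Forty subjects (20 per class, 300 samples at a nominal
50 Hz, four spiral turns) emulate digitised spiral drawing: class 0 traces
a smooth Archimedean spiral $r = a\theta$ with 1% motor jitter and a
smooth pressure arc; class 1 adds a 5 Hz tremor (the parkinsonian 4–6 Hz
band) of amplitude 8% of the outer radius on x and y, with subject-level
log-normal variation, plus a few intermittent pressure dips. The generator
is deterministic per seed and entirely synthetic: it has known ground
truth and a single effect axis, so it can certify that the pipeline
*recovers* a strong tremor effect (nested-LOOCV accuracy ≥ 0.9; in
practice 1.0) and stays at chance when the effect is removed — it cannot
certify performance on real patients, where effects are weaker, collinear
and confounded. With amplitude 0 the two classes are draws from one
generative law, making the null control exact.

## The classifier

Features are the nine recurrence statistics of the band-64–191 mask of
each subject's per-channel z-scored trace (no embedding; the traces are
already 3-D). Evaluation is nested leave-one-out: the outer loop holds out
one subject; the inner loop, a leave-one-out over the remaining subjects,
scores every point of an RBF-SVM grid (cost $\{0.1, 1, 10, 100\}$ × gamma
$\{0.01, 0.1, 1, 10\}$) and picks the best inner accuracy, breaking ties
towards the smallest cost then the smallest gamma. Feature standardisation
is refitted inside every (inner-)training split, which makes the procedure
exactly invariant to feature rescaling and is verified by a leakage test:
corrupting a held-out subject's features cannot move that fold's chosen
hyperparameters. Classes are left unweighted. Diagnostic rates with empty
denominators are reported as 0 alongside an explanatory note rather than
NaN.

## Known limitations

* Exact code values are convention-dependent (neighbour order); only
  compare code matrices produced under one convention.
* The plug-in AMI estimator is biased upward for short series; profiles are
  meant for locating minima/level-offs, not for absolute MI values.
* Diagonal-line entropy depends on trajectory length and on the border
  policy; compare entropies only at matched $N$ and matched recurrence
  rate.
* The nested LOOCV is $O(n^2 \cdot |grid|)$ SVM fits; for cohorts much
  beyond ~10² subjects a k-fold variant would be preferable.
* The cohort generator's tremor is additive and stationary; real
  parkinsonian drawing shows amplitude drift, micrographia and speed
  changes it does not attempt to model.
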