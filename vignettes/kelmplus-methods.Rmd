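---
title: "Classifying blood-pressure grades from brain morphometry with privileged-information kernel ELMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying blood-pressure grades from brain morphometry with privileged-information kernel ELMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sustained high blood pressure is associated with regional brain atrophy:
gray- and white-matter volume, cortical thickness and surface area tend to
decrease — and cerebrospinal fluid volume to increase — as pressure rises
through the 2017 ACC/AHA grades (normal, elevated, hypertension stages 1 and
2). `kelmplus` implements a feature pipeline and classifier ensemble for
asking, from regional morphometry alone, *which grade is this brain* and
*which regions carry the discrimination*.

The package starts where image processing ends: its inputs are per-subject
tables of regional features over the 90-region AAL parcellation (gray-matter
volume GMV, white-matter volume WMV, cerebrospinal-fluid volume CSFV,
cortical thickness, cortical surface area), plus per-region thickness
summaries (mean and variance over the region's surface vertices) from which
a sixth feature type — a single-subject morphometric network — is built.
Reading NIfTI/DICOM images, segmentation and surface reconstruction are out
of scope.

## The pipeline

### Per-subject normalization

Each feature type is normalized strictly within subject, so no information
crosses subjects and the step commutes with any train/test split:

* **volumes** (GMV, WMV, CSFV) are divided by the subject's total brain
  volume (the summed GMV + WMV + CSFV over all 90 regions when no external
  value is supplied), removing head-size differences;
* **thickness** is divided by the subject's standard deviation of thickness
  across the 90 regional values (population form, divisor *n*), leaving
  every row with unit spread. The within-subject reading is the only one
  computable for a subject in isolation, which is what pairs it with the
  other per-subject rules;
* **area** is divided by the subject's summed area, so rows sum to one.

Each rule refuses to run twice (`normalized` flag), and a zero
within-subject thickness spread is an error rather than a silent division.

### Single-subject thickness networks

A subject's regional thickness is summarized as a Gaussian
$N(\mu_i, \sigma_i^2)$ per region (mean and variance over the region's
vertices). The association between regions $i$ and $j$ is

$$w_{ij} = \exp\{-\mathrm{KL}_{sym}(N_i, N_j)\}, \qquad
\mathrm{KL}_{sym} = \tfrac12\left(\mathrm{KL}(N_i\|N_j) +
\mathrm{KL}(N_j\|N_i)\right),$$

using the closed-form Gaussian Kullback–Leibler divergence. This is the
standard single-subject morphometric-network construction that consumes
exactly a mean and a variance per region; a Pearson-correlation variant
(`pearson_vertex`) is available when vertex-level thickness vectors exist. A
literal per-subject Pearson correlation "between regions" is not computable
from one scalar pair per region, which is why the Gaussian-similarity form
is the default. Entries lie in $(0, 1]$ with unit diagonal; zero variances
are rejected.

Twelve deep gray-matter regions (bilateral hippocampus, amygdala, caudate,
putamen, pallidum, thalamus) are excluded by default, leaving a
$78 \times 78$ matrix whose strict upper triangle — row-major, giving a
fixed, documented ordering — is the subject's 3003-dimensional network
feature vector. The exclusion list is a configurable argument rather than a
constant because the literature is not unanimous about which regions count
as sub-cortical; any subset of the registry may be excluded.

### Two-stage feature selection

Inside every training fold (never on test data), each feature type is
filtered by a two-sample Welch *t*-test keeping features with $p < 0.05$
strictly (a pooled-variance variant is available), then ranked by estimated
mutual information with the class label, keeping the top $k$. By default
$k$ caps at the number of training subjects. Features constant in both
groups get $p = 1$ and are flagged degenerate; if nothing survives the
filter, the fold falls back to all features with a warning rather than
dying.

The MI estimator for a continuous feature against a discrete label is the
nearest-neighbor estimator (radius set by the $k$-th within-class neighbor,
digamma correction terms), with an equal-frequency 8-bin plug-in as the
alternative. No tie-breaking noise is injected: identical columns receive
identical scores, and rank ties resolve by ascending column index, so
selection is a deterministic function of the data.

### Empirical kernel mapping

Kernel machines see data only through inner products; the empirical kernel
map (EKM) makes that feature space explicit. Eigendecomposing the training
Gram matrix $K = P \Lambda P^\top$ and keeping eigenvalues above
$10^{-10} \times \lambda_{\max}$ (rank $r$), any sample $x$ maps to

$$\Phi(x) = \Lambda^{-1/2} P^\top
\big(k(x, x_1), \ldots, k(x, x_m)\big)^\top \in \mathbb{R}^r,$$

so that $\Phi(X)\Phi(X)^\top$ reproduces $K$ up to the discarded spectral
mass. Eigenvector signs are fixed by forcing each vector's
largest-magnitude component non-negative, making the map identical across
linear-algebra backends. Kernels are RBF
($\exp(-\gamma\|x - z\|^2)$, $\gamma$ defaulting to the median heuristic
$1/(2\,\mathrm{median}\,\|x_i - x_j\|^2)$) and linear; no polynomial kernel
is offered.

### KELM, ELM+ and KELM+

With $\pm 1$ one-vs-all label matrix $T$ ($n \times m$) and training Gram
$\Omega$, the kernel extreme learning machine solves ridge regression in
closed form,

$$\beta = \left(\tfrac{1}{C} I + \Omega\right)^{-1} T,
\qquad f(X_{te}) = K(X_{te}, X_{tr})\,\beta,$$

predicting the argmax column. ELM+ extends this with learning using
privileged information (LUPI): privileged features, available only for
training subjects, enter through their own hidden layer $\tilde H$. Its
closed form, and the kernelized KELM+ with privileged Gram $\tilde\Omega$,
are

$$\beta = H^\top\!\left(\tfrac{1}{\varepsilon}\tilde H\tilde H^\top +
\tfrac{1}{C} I\right)^{-1}\!\left(T - \tfrac{C}{\varepsilon}\tilde H\tilde
H^\top J\right), \qquad
\beta_{k} = \left(\tfrac{1}{\varepsilon}\tilde\Omega + \tfrac{1}{C}
I\right)^{-1}\!\left(T - \tfrac{C}{\varepsilon}\tilde\Omega J\right),$$

with $J$ the $n \times m$ all-ones matrix — the only conformable placement
of the ones factor consistent with the KKT derivation — and prediction
again $K_{main}(X_{te}, X_{tr})\,\beta_k$. The two models coincide exactly
when linear kernels are applied to the explicit hidden matrices
($\tilde\Omega = \tilde H \tilde H^\top$); that equivalence is the central
correctness oracle in the test suite. ELM+ is retained as that oracle and
as a baseline; its hidden layers are seeded sigmoid units with uniform
$[-1, 1]$ weights, so it is reproducible but carries the usual
random-feature instability that motivates the kernel version.

Two properties of the closed form deserve explicit note, because they are
easy to miss:

* the subtracted term $(C/\varepsilon)\tilde\Omega J$ has identical
  columns, so it shifts all class scores of a test point equally and never
  changes the argmax decision;
* the main-feature Gram never appears in the weight computation — only the
  test-against-train kernel block uses main features. The privileged
  information therefore acts as a data-dependent regularizer of the solve,
  shaping the metric in which training targets are smoothed. The weights are
  implemented exactly in this form.

Regularization defaults are $C = \varepsilon = 1$ when tuning is off.

### The LUPI ensemble and its evaluation

One feature type (GMV by default) is the *main* feature, available at train
and test time; each of the other five types serves as privileged
information for one KELM+ member. Per member: select features on main and
privileged tables, lift both through EKMs fitted on the training fold,
compute the privileged Gram, solve for $\beta_k$. At test time only the
main table is accepted — the interface enforces the LUPI contract — and the
five member labels are fused by majority vote, ties (impossible for binary
tasks with five members) broken by the largest summed member score.

Evaluation is repeated stratified cross-validation, by default
$5 \times 5$: within each training fold the full pipeline is refitted
(selection, EKM, tuning, members), and seven metrics are computed on the
held-out fold — ACC, SEN, SPC, Youden index $YI = SEN + SPC - 1$, PPV,
NPV, $F1 = 2\,PPV\cdot SEN/(PPV + SEN)$ — reported as mean ± sample SD over
the 25 fold values. The positive class is the higher blood-pressure grade,
recorded in every report. Metrics with zero denominators are `NA` and
excluded from means, never coerced to zero. A plain KELM on the selected
main features (no EKM, no PI) is evaluated alongside as the single-feature
baseline. How often each feature survives selection is tallied across the
25 fits (maximum frequency 25), feeding the "most discriminative features"
report, with regional and network ("correlative") features listed
separately.

Hyperparameters are tuned per member by exhaustive inner 3-fold stratified
CV over $C, \varepsilon \in \{2^{-5}, 2^{-3}, \ldots, 2^{5}\}$ (a coarse
log-2 grid; denser grids and a multiplier grid on the median-heuristic RBF
width are configuration options), maximizing mean accuracy with ties going
to the earliest grid point. Selection and EKM are fitted once per inner
fold and shared across grid points, so each point costs one linear solve.
Per-member rather than global tuning was chosen because members face
different privileged Gram matrices; both are supported.

## The synthetic cohort generator

The study data the method was designed for are private clinical MRI
tables, so the package ships a generator that emulates their statistical
structure and makes every stage testable end to end. It is first-class,
tested code, not a fixture.

Defaults follow the study conditions: 73 subjects per grade; grade effects
as standardized mean shifts of $d$ per grade step ($-d$ SD for
GMV/WMV/thickness/area, $+d$ SD for CSFV, the directions reported for
hypertension) applied to 15 designated cortical regions in
frontal/temporal/parietal territories where hypertension-related atrophy is
typically reported; exchangeable inter-ROI correlation $\rho = 0.2$
(moderate regional co-variation; the true cortical covariance is unknown);
baseline means/SDs in native units (e.g. GMV $8 \pm 0.8$ cm³ per region,
thickness $2.5 \pm 0.18$ mm) with a coefficient of variation near 0.1, a
realistic scale for regional morphometry. Blood pressures are drawn inside
each grade's band, so the grade rules round-trip exactly.

The inter-ROI correlation is produced by a per-subject **multiplicative**
log-normal size factor (one shared by the volumetric/area types, an
independent one for thickness), with log-SD calibrated as
$\nu = (\sigma/\mu)\sqrt{\rho/(1-\rho)}$ so the raw correlation converges
to $\rho$. The multiplicative form matters: it models head-size allometry,
which is exactly what the per-subject normalizations exist to remove, so
the normalized null cohort is clean. An additive common factor would
survive total-brain-volume division and hand the classifier a latent
variable unrelated to what the normalization is for. Vertex-level thickness
variance is log-normal per region, scaled by the squared thickness factor
for coherence, and drifts upward with grade in affected regions so the
network features carry signal too.

What the generator does **not** emulate: site effects, age/sex structure,
non-Gaussian tails, spatially structured covariance beyond the single size
factor, and any real registration/segmentation noise. Passing tests on
synthetic cohorts therefore demonstrate the pipeline's statistical
soundness and the classifier's correctness, not clinical performance.

## Numerical choices and degenerate inputs

* Gram matrices are symmetrized before eigendecomposition;
  `eigen(symmetric = TRUE)` is used throughout, and solves go through base
  `solve` on the ridge-stabilized systems.
* Eigenvalue retention threshold $10^{-10}\lambda_{\max}$; an all-zero
  kernel is a degenerate-kernel error.
* The argmax label decision takes the first of tied columns; the ensemble
  vote breaks ties by summed scores.
* Degenerate inputs fail loudly: non-positive pressures, zero thickness
  spread, zero variances in network construction, misaligned subject rows,
  unknown ROI names, double normalization.
* All randomness (hidden layers, folds, cohorts) flows through explicit
  integer seeds via `withr::with_seed`; every fitted object and report is
  bit-reproducible given its seed.

## Protocol sizes used by the tests

The shipped tests and the acceptance script exercise the full protocol at
the study scale where it matters and smaller elsewhere: the power/null
checks run 73 subjects per grade (grades 1 vs 2, $d = 1.5$ and $d = 0$)
under $5\times5$ stratified CV, with the null accuracy averaged over three
independent null cohorts — a single finite cohort can contain a chance
feature–label association (on one draw used by the tests, a single noise
column separates the groups at $p \approx 10^{-6}$) that honest CV will
legitimately learn, so the average is what isolates pipeline optimism bias
from draw-level flukes. Unit tests for the classifier core use tens of
subjects, where the closed forms are checked against generic solvers and
the ELM+/KELM+ equivalence to $10^{-6}$ or better.

## Known limitations

* The KELM+ weight formula ignores the main-feature Gram during
  training (see above); consequently the ensemble's advantage over a plain
  KELM baseline is modest on easily separable data, where both sit at
  ceiling.
* The nearest-neighbor MI estimator degrades on heavily tied (effectively
  discrete) features; the binned estimator is the better choice there.
* Grade assignment folds the hypertensive-crisis band into stage 2
  (grade 4), and uses the $\geq 140 / \geq 90$ reading of the stage-2
  thresholds.
* Multi-class evaluation is out of scope for the report machinery (the
  protocol is defined for binary grade pairs), though the classifiers
  themselves are multi-class.
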