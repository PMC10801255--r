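---
title: "Methods: distributionally robust fair federated learning in fedufo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distributionally robust fair federated learning in fedufo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedufo)
```

## The problem and the objective

Federated learning trains one model across clients (hospitals) that never
exchange raw records. Averaging local updates optimizes the pooled risk, so
under non-IID client data the shared model can be systematically worse for
some hospitals, or for some patient groups (by sex, race, outcome). `fedufo`
enforces *performance uniformity* over a configurable group structure G by
minimizing a distributionally robust risk,

$$
R_{\mathrm{dro}}(\theta) \;=\; \max_{\lambda \in \Delta^{|G|-1}}
\sum_{g} \lambda_g f_g(\theta)
\quad\text{s.t.}\quad
D_f\!\big(|G|\lambda \,\|\, \mathbf{1}\big) \le \rho ,
$$

with $f_g$ the mean cross-entropy of group $g$ and $D_f$ the
$\chi^2$-divergence $f(t) = (t-1)^2$, i.e.
$D_f(|G|\lambda\|\mathbf 1) = \tfrac1{|G|}\sum_g(|G|\lambda_g-1)^2$.
This robust risk is the tractable surrogate of a variance-penalized
objective $\bar R(\theta) + C\,\mathrm{Var}(R_g)/|G|$ (implemented as
`variance_penalized_risk()` for reference); the penalty constant and the
radius play the same role, and only $\rho$ is exposed as the training dial.
The divergence family is deliberately fixed to $\chi^2$: it yields a ball
with a one-dimensional dual, an exact projection, and clean limits —
$\rho = 0$ is empirical risk minimization, $\rho \ge |G|^2$ contains the
vertex of the worst group, so the robust risk interpolates between the mean
and the maximum of the group risks (a property the tests check on a
$\rho$-grid).

Four group structures are supported by `build_grouping()` /
`uncertainty_set_spec()`:

* **client** — groups are the N clients (horizontal fairness);
* **attribute** — groups are observed value-combinations of named
  categorical columns (vertical fairness);
* **multilevel** — both maps are kept; during training each sampled row is
  weighted by its client weight with probability $\beta$ and by its
  attribute-group weight otherwise;
* **agnostic** — groups are the *occupied* client×attribute cells, a wide
  uncertainty set that prepares the model for deployment sites whose mix of
  clients and attributes was not seen in training.

Unobserved attribute combinations and empty cells are never given groups:
an empty group would have an undefined risk, and a zero weight is absorbing
under the multiplicative update below.

## The optimization algorithm

The saddle point is solved by stochastic mirror descent ascent. The
$\theta$-player takes minibatch gradient steps on the per-sample-weighted
cross-entropy; the $\lambda$-player maximizes a linearization of
$F(\theta, \lambda) = \sum_g \lambda_g f_g$ plus a
$(1/\gamma)$-weighted Bregman proximity term. With the negative-entropy
mirror map the ascent step has the closed form
$\lambda_g \propto \lambda_g e^{\gamma v_g}$ (`exponentiated_update()`),
where $v$ is the vector of current group losses — the exact
$\lambda$-gradient of $F$. After each ascent step the weights are projected
back into the $\chi^2$ ball (`project_weights()`).

In the federated loop (`run_fedufo()`), one round is: broadcast
$(\theta, \lambda)$, run $E$ local weighted iterations on each client,
average the local models parameter-wise, and update the weights with
exponent $\gamma E v$, where $v$ are **snapshot losses** — each client
evaluates the *round-start* model on its full local set (client weight
path) and on each of its attribute subgroups (attribute path). Snapshotting
makes the weight update an unbiased stand-in for $E$ per-iteration updates
at the cost of zero extra communication: exactly R broadcasts and R uploads.
Attribute losses are *summed* (not averaged) across clients in the exponent;
a client that holds no rows of some attribute group reports a flagged
missing value that contributes zero to the sum, which keeps the update
defined under extreme heterogeneity where some cells vanish.

### Numerical and design choices

* **Weight rescaling.** The per-sample multiplier is $|G|\lambda_g$, not
  $\lambda_g$. At uniform weights the multiplier is exactly 1, so the
  $\rho = 0$ run reproduces FedAvg *bitwise* at the same stepsize (a test
  asserts round-by-round parameter identity). The literal rule
  ($\lambda_g$ alone) would shrink the effective stepsize by $|G|$ at
  uniformity and break that degeneration; `rescale_weights = FALSE`
  restores it for completeness.
* **Projection geometry.** An infeasible weight vector is contracted along
  the segment toward uniform until the ball constraint holds with equality.
  For the $\chi^2$ ball this has a closed form
  ($\lambda = u + \sqrt{\rho / D(w)}\,(w - u)$) and coincides with the
  Euclidean projection onto the ball–simplex intersection (the contraction
  is a convex combination of two simplex points, so nonnegativity never
  binds). Whether a KL or Euclidean geometry is "the" right projection for
  a negative-entropy mirror map is genuinely open; the Euclidean/contraction
  choice was made because it is exact, idempotent, and verifiable against an
  independent active-set enumeration oracle to machine precision. Feasibility
  after projection is enforced to within 1e-7 and tested after every round.
* **The DRO inner maximum** (`dro_risk()`) is computed by bisection on the
  dual stepsize $t$ of the ball: the maximizer is the simplex projection of
  $u + t\,(f - \bar f)$, with $t$ driven until the ball constraint is
  active (or the best simplex face is reached). The ascent direction is
  normalized so the bisection operates on an O(1) bracket regardless of the
  loss scale.
* **Weight floor.** Simplex feasibility is checked at 1e-9; weights are kept
  strictly positive by the exponentiated form itself (a zero weight could
  never recover).
* **Optimizers.** Plain SGD is the default for all correctness and fairness
  runs. Adam (0.9, 0.999, 1e-8) is provided, but note an interaction: at the
  client level the fairness multiplier is a *constant scalar within a round*,
  and Adam's per-parameter normalization is nearly invariant to constant
  gradient rescaling — under Adam, client-level reweighting is largely
  neutralized. The fairness comparisons in the tests and acceptance script
  therefore use SGD, where the multiplier acts as intended. Local Adam
  accumulators are re-initialized each round (they cannot be meaningfully
  averaged across clients).
* **Hidden layer.** One fully connected ReLU layer, width 64 by default
  (256 is conventional for larger tables); weights uniform on
  $\pm 1/\sqrt{\text{fan-in}}$, biases zero. The activation is not dictated
  by the protocol this package follows; ReLU is the package's choice and is
  configurable in code.
* **E counts minibatch iterations.** Protocols often quote "local epochs";
  the orchestrator (`run_experiment()`) accepts `local_epochs` and converts
  via `epochs × ceiling(n_client / batch_size)`, while the core loop always
  counts iterations.
* **Aggregation** is the unweighted parameter mean over clients, even with
  unequal client sizes; `size_weighted_agg = TRUE` offers the conventional
  $n_i/n$ variant.
* **Model selection** restores checkpoints (every 5 rounds by default) and
  picks the one with the lowest pooled training loss, ties to the earliest.
* **Seeding.** One master seed fans out to named substreams (partition,
  split, initialization, per-(round, client) batches, per-(round, client)
  mixing draws), so any component reproduces independently and FedAvg/FedUFO
  runs with the same seed follow identical sample paths. All operations are
  pure given (inputs, seed).

## Evaluation metrics and their conventions

`disparity()` is the **sample standard deviation** of per-group accuracies,
$\sqrt{\sum_g (a_g - \bar a)^2 / (|G|-1)}$. The variance reading of the
same formula is rejected because only the standard deviation reproduces the
published arithmetic this suite reconstructs (accuracies 0.6880 and 0.5429
give 0.1026). At two groups the sample form is the unique match; for more
groups the $|G|-1$ denominator is retained.

Two *different* harmonic conventions are deliberately exposed:
`harmonic_disparity(a, b) = 1/(1/a + 1/b)` (no factor 2; equal inputs give
$x/2$) combines the client- and attribute-level disparities, while
`harmonic_accuracy(a, b) = 2/(1/a + 1/b)` (the standard harmonic mean)
combines the worst-group accuracies. Both conventions were verified
numerically against multiple published cells before being frozen into
`verify_paper_arithmetic()`; they differ by exactly a factor 2 and are kept
as separate, documented operations rather than one function with a flag.

`eo_gap()` defaults to the printed form
$|P(Y{=}1 \mid \hat Y{=}1, A{=}0) - P(Y{=}1 \mid \hat Y{=}1, A{=}1)|$ — a
predictive-parity-style conditional — with `mode = "standard"` giving the
textbook equal-opportunity TPR gap; the mode is recorded in the report.
`worst_tpr()` is the minimum within-group TPR. Undefined conditionals
(an empty conditioning cell) yield flagged `NA`s rather than silent zeros.

`agnostic_evaluate()` re-partitions the held-out rows with a fresh
Dirichlet draw at an evaluation $\alpha$, rebuilds groupings and recomputes
the suite — simulating deployment under a client mix the model never saw.

## The synthetic benchmark generator

No clinical tables are bundled; `synthetic_spec()` / `make_benchmark()`
emulate their *structure*: K-class tabular data, feature dimension d,
categorical attributes, client heterogeneity. Specifically:

* class-conditional means sit on a regular simplex scaled so every pairwise
  distance equals `class_separation` (default 2; with unit Gaussian noise
  this gives Bayes accuracy in the high-80s for K = 2, comparable to the
  mid-size clinical risk tables this mimics);
* each attribute value displaces the mean by `attribute_shift` (default 1)
  along a unit direction drawn once per seed — so attribute groups differ in
  difficulty and plain training has genuinely positive disparity;
* labels are flipped with probability `label_noise` (default 0.05,
  a typical clinical label-error rate);
* rows are allocated to `n_clients` (default 4) clients by a per-class
  symmetric Dirichlet draw with concentration `alpha` (default 0.1, the
  strong-heterogeneity end of the protocol this follows), rounded by the
  largest-remainder method with ties to the lower client index, resampled
  (up to 100 times) until every client holds at least 2 rows;
* each client is split 80/20 into train/test, stratified by label, with
  singleton label cells falling back to an unstratified split (logged).

Defaults: `n = 2000`, `d = 20`, `K = 2`, one binary 50/50 attribute
(`sex`). These sizes were chosen once as representative of the smaller
clinical tables (1,000–7,000 rows) the simulated protocol targets, and they
are the sizes the test suite and the acceptance script run at (training
runs use R = 10 rounds, E = 30 iterations, batch 32, hidden width 64).

Whether the Dirichlet split should draw client proportions per class or
class proportions per client is not observable from published summaries;
per-class is used because it reproduces the characteristic label-count skew
across clients, and it is the standard construction in the federated
heterogeneity literature. At extreme concentrations the gamma sampler can
underflow to an all-zero draw; the implemented limit is a point mass on one
uniformly chosen client, which is the correct $\alpha \to 0$ behavior.

What the generator does **not** emulate: real feature semantics
(ICD codes, cardiotocography channels, one-hot blocks), missingness,
measurement error correlated with attributes, temporal drift, or
client-specific feature distributions beyond the label/attribute mechanism.
Passing tests on this benchmark show the algorithmic machinery behaves as
designed under controlled heterogeneity; they do not certify fairness
improvements on any particular real clinical dataset.

## What the tests establish

* exact reconstruction of the published metric arithmetic at printed
  precision (`verify_paper_arithmetic()`);
* bitwise equality of the $\rho = 0$ robust run with FedAvg, round by
  round, under SGD with rescaled weights;
* agreement of `dro_risk()` and `project_weights()` with an independent
  active-set enumeration oracle (1e-5) over random instances with
  $|G| \in \{2, 3, 5\}$, and of `exponentiated_update()` with a numeric
  proximal maximization (1e-8);
* monotonicity of the robust risk in $\rho$ and attainment of the
  worst-group risk at $\rho = |G|^2$;
* on the synthetic heterogeneous benchmark ($\alpha = 0.1$, N = 4), lower
  client disparity than FedAvg in at least 8 of 10 paired seeds with
  overall accuracy within 3 points, and mean disparity non-increasing as
  $\rho$ rises through $\{10^{-8}, 10^{-4}, 10^{-1}\}$.

The last two are stochastic properties of the benchmark distribution; the
suite fixes its seeds, and a wider 30-seed check during development showed
the paired-seed win rate near 0.83 with a clearly lower mean disparity.

## Known limitations

* Single-process simulation only: no transport, stragglers, client
  sampling, compression, or secure aggregation; privacy properties are
  those of the federated protocol itself, nothing is added.
* Only the $\chi^2$ ball is implemented; other f-divergences would need
  their own projection.
* The quantitative correspondence between the variance-penalty constant C
  and the radius $\rho$ is not implemented — only $\rho$ is a dial.
* Tabular MLP only; no calibration or threshold-tuning metrics.
* `run_local()` trains per-client models with no communication; its
  disparity is computed from per-client models each evaluated on its own
  client, which is the conventional "without FL" reference.
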