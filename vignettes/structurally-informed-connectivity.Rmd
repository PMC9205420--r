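---
title: "Structurally informed adaptive filtering of time-varying directed connectivity"
author: "sistok package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structurally informed adaptive filtering of time-varying directed connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sistok)
```

## The estimation problem

Electrophysiological recordings (epoched EEG, LFP, source-reconstructed
activity) sample a network of brain regions at millisecond resolution.
Directed functional connectivity asks which regions *drive* which others,
and when. The working model is a time-varying multivariate autoregressive
(tv-MVAR) process over $d$ channels,

$$ Y_t = \sum_{k=1}^{p} A_{k,t}\, Y_{t-k} + \varepsilon_t,
   \qquad t = 1 \ldots N, $$

where $Y_t$ collects the present sample of all trials, the $d \times d$
matrices $A_{k,t}$ hold the lag-$k$ coefficients *at sample* $t$, and
$\varepsilon_t$ is zero-mean white innovation noise with covariance
$\Sigma_\varepsilon$. Everywhere in this package the orientation is fixed
as **receiver row, sender column**: `A[i, j, k, t]` is the influence of
node $j$ on node $i$ at lag $k$ — a single convention shared by the
coefficient arrays, the structural matrices, and the derived metrics, so a
transposition can never pass silently.

In state-space form the coefficients are a latent random-walk state $x_t$
observed through the lag-stacked design $H_t$ (one row per trial holding
the $p$ most recent past samples of all channels) with $z_t = H_t x_t +
\nu_t$. Columns of $H_t$ are ordered in lag-major blocks of channels
(ch1 lag1, ..., ch$d$ lag1, ch1 lag2, ...); `buildLagDesign()` documents
and tests this contract.

## The STOK filter

`stokFit()` implements the self-tuning optimized Kalman (STOK) filter: at
each sample the state is updated as a weighted average of the previous
estimate and a least-squares reconstruction from the present measurement,

$$ \hat{x}^{+}_t = \frac{\hat{x}^{-}_t + c\, \tilde{H}^{+}_t z_t}{1 + c}, $$

with $\hat{x}^{-}_t = \hat{x}^{+}_{t-1}$ and the state initialized at zero
(the no-connectivity expectation). Estimates are defined from sample
$p + 1$ (`validFrom`); earlier samples are `NA` rather than padded.

$\tilde{H}^{+}$ is a *damped* Moore–Penrose pseudoinverse
(`dampedPinv()`): the SVD of $H_t$ is truncated to the smallest leading
set of singular values whose cumulative squared sum reaches a fraction
$f$ (`varianceFraction`) of the total, and the remaining directions are
zeroed. This suppresses the ill-conditioned directions of the design that
amplify noise — important under the multicollinearity typical of source
EEG. Two numerical details matter:

* singular values exactly tied with the last retained one are also
  retained (tied directions carry equal variance and cannot be ranked
  against each other — with an orthonormal design and any $f$, nothing is
  truncated);
* the default is $f = 0.99$, suitable for low-dimensional recordings;
  $f = 0.9$ is a common choice for high-dimensional source data.

The adaptation constant $c$ sets the speed/stability trade-off:
$c \to \infty$ gives the raw per-sample least-squares estimate, $c = 0$
freezes the state. The self-tuning rule implemented here,

$$ c_t = \mathrm{clip}\!\left(c_{\mathrm{base}}\,
   \frac{e_t}{\bar{e}_t},\; c_{\min},\, c_{\max}\right), $$

raises the speed when the mean squared one-step innovation $e_t$ exceeds
its exponential moving average $\bar{e}_t$ (half-life 10 samples by
default), i.e. when the network is changing faster than the filter is
tracking. Defaults are $c_{\mathrm{base}} = 0.05$, $c_{\min} = 10^{-3}$,
$c_{\max} = 1$. The rule is deliberately simple and replaceable: any
fixed $c$ can be supplied instead, and all recursive-update tests are run
in the fixed-$c$ mode where the algebra is exactly checkable.

## Structural priors: si-STOK

`siStokFit()` replaces the measurement estimate with a per-receiver
*generalized Tikhonov* solution. For receiver $i$,

$$ b^{*}_{i \leftarrow \cdot, t} =
   \left(\tilde{H}^{\mathsf T}\tilde{H} + Q_i^{-1}\right)^{-1}
   \tilde{H}^{\mathsf T} z_{i,t}, $$

where $Q_i^{-1}$ is a diagonal precision built from structural
connectivity (`buildPrecision()`): the normalized structural weight
$W_{ij} \in [0, 1]$ of the connection $j \to i$ is mapped to a prior
*variance* and its reciprocal is replicated across the $p$ lag positions
of sender $j$. In the Bayesian reading this is the posterior mode under a
zero-mean Gaussian prior on each incoming connection: strong anatomy
permits the coefficient to follow the data; weak or absent anatomy
shrinks it toward zero. Because the prior acts through a variance rather
than a mask, a strongly supported functional connection can still
overcome an absent structural link, and a strong structural link alone
cannot conjure a connection the data do not support. The general form
with a nonzero prior expectation $x_0$ is available in
`tikhonovSolve()`; the pipeline default is $x_0 = 0$.

### Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `order` ($p$) | lags of the MVAR model | 4 | 4 suits ~1 kHz epicranial data; 10 is typical for human source EEG |
| `varianceFraction` ($f$) | design variance retained by damping | 0.99 | 0.9 for high-$d$ source data |
| `scaling` $(lo, hi)$ | prior-variance range | $(10^{-4}, 0.1)$ | see below |
| `scaleMethod` | SC-to-variance map | linear | `"log"` gives geometric interpolation |
| `cBase`, `cMin`, `cMax`, `halfLife` | self-tuning rule | 0.05, $10^{-3}$, 1, 10 | fixed `c` available |

The scaling range maps $W = 0$ to variance $lo$ (never zero — the
precision must stay finite, and "absent" is a strong belief, not a hard
mask) and $W = 1$ to $hi$. The default range produces clear
regularization without excessive global shrinkage. A linear map is the
minimal assumption between the stated endpoints; a log-spaced option is
exposed for connectomes whose weights span decades. Because nothing in
the theory picks $hi$ automatically, `sweepScalingMax()` refits the model
over a candidate grid and reports, per candidate, (a) the Spearman
correlation between structural weights and estimated influence — how
strongly the prior imprints — and (b) the Pearson correlation between the
informed and uninformed estimates — how far the result drifts from the
data-only solution. A practical maximum raises (a) without collapsing
(b); the choice is reported, never made silently.

Structural matrices enter through `normalizeSC()` (diagonal overwritten
*before* dividing by the maximum, matching the convention of rank-coded
connectomes where self-connections get the top rank) and optionally
`thresholdSC()` (proportional thresholding of the strongest off-diagonal
connections, ties at the cutoff all retained, diagonal set to 1).

### Numerical implementation

The regularized solve is performed in the SVD basis as an augmented
least-squares problem, QR-factorizing
$\bigl[\tilde{S}V^{\mathsf T};\ \mathrm{diag}(\sqrt{q})\bigr]$. Damped-out
directions are *exact* zero rows there, so the solution converges cleanly
to the damped least-squares estimate as the precision vanishes —
reconstructing $\tilde{H}$ explicitly and solving normal equations
instead amplifies rounding in the nulled directions by the reciprocal of
the smallest penalty, which is why that route is not taken. Degenerate
inputs fail loudly: zero-variance channels are named, non-finite designs
and singular systems raise errors with a condition estimate.

## Derived metrics

**MDI.** The magnitude of directed influence collapses the lag dimension
per edge and sample:
$\mathrm{MDI}_{i \leftarrow j, t} = \bigl(\sum_k a_{i\leftarrow j,k,t}^2\bigr)^{1/2}$
by default (`mode = "rss"`); the plain sum of squares (`"ss"`) is exposed
and the choice travels with the result object. MDI is nonnegative and
zero exactly when all lag coefficients vanish.

**Outflow and drivers.** `summedOutflow()` averages, over a time window,
each node's summed outgoing MDI (diagonal excluded by default — the
summaries describe the network, not self-dynamics). `driverScore()` is a
node's excess outflow over the network mean, so scores sum to zero and a
positive score reads "drives more than average". `rankOutflows()` sorts
stably, breaking ties by node label.

**Adjacency and consistency.** `proportionalAdjacency()` binarizes a
connectivity slice by keeping the top fraction of off-diagonal entries
(ties at the cutoff retained). `consistency()` is the fraction of
reference edges preserved — by construction 1 against itself — with a
Jaccard variant (`denominator = "union"`) for symmetric comparisons.

**Group statistics.** `signPermutationTest()` flips the sign of each
subject's difference map, recomputes group means, and reports two-sided
p-values per edge/time with the add-one correction
$(1 + \#\mathrm{exceedances})/(n_{\mathrm{perm}} + 1)$ (no permutation
p-value can be 0) doubled from the smaller one-sided tail. No
multiplicity correction is applied by default, matching the uncorrected
thresholds conventional in this literature; FDR is available. The seed is
mandatory.

## The simulator and what passing tests mean

`simulateTVMVAR()` generates multi-trial realizations of the tv-MVAR
recursion under a piecewise-constant coefficient schedule, with Gaussian
innovations and a per-trial burn-in under the baseline coefficients.
Every scheduled tensor must have a companion-matrix spectral radius below
1 — instability is a construction-time error naming the offending
segment. Realizations are exactly reproducible from (specification,
seed).

The default evoked fixture (`evokedSimulationSpec()`) is a sparse 5-node,
order-2 network: stable self-dynamics on every node, two static cross
connections, and a driver node that sends three step connections during
an active window — an abrupt-onset analogue of evoked dynamics with a
defined peak latency. The stationary variant
(`stationarySimulationSpec()`) keeps the driver connections on
throughout, providing constant ground truth for coefficient-recovery
checks. Structural-prior scenarios (`scScenario()`) either agree with the
true edge set (`concordant`, `dense_uniform`) or deliberately contradict
it (`sc_false_negative` removes a true edge from the prior;
`sc_false_positive` adds a maximal prior on a functionally absent edge).

`mixNoise()` implements the noise-perturbation protocol: a convex mixture
$(1 - r)\,\mathrm{data} + r\,\eta$ with $\eta$ i.i.d. Gaussian whose
standard deviation equals the 95th percentile of the absolute data values
(the "amplitude" of near-maximal excursions; percentile, signedness and
distribution are configurable). `runNoiseBenchmark()` fits both filters
at ratios 0–0.5, 30 regenerations per ratio by default, sharing each
noise realization between filters so the comparison is paired, and scores
each fit by (a) the consistency of its thresholded peak-latency network
with that filter's own zero-noise network and (b) the driver score of the
designated driver. Zero-noise consistency is 1 by definition and the
harness never mutates its input.

The simulator emulates trial structure, evoked step dynamics, stable
sparse coupling and controlled noise. It does **not** emulate volume
conduction or leadfield mixing, 1/f spectra, nonstationary innovation
variance, or nonlinearity. Tests passing on these fixtures therefore
certify the estimator's algebra, its shrinkage behavior, and its relative
noise robustness — not performance on any particular recording system.

## Problem sizes and observed behavior

The packaged checks run at desk scale, chosen to finish in minutes while
keeping the estimation problems non-trivial: coefficient recovery at
$d = 5$, $p = 2$, 100 trials, 300 samples; prior scenarios at 60 trials,
200 samples, 30 seeded repetitions; the noise benchmark at ratios
0–0.5 with 30 regenerations. On these fixtures, time-averaged STOK
coefficient error is below 0.05 RMSE; edges with functional support but
no structural prior remain clearly above the structure-absent,
function-absent floor in every repetition; maximal structural priors on
functionally absent edges stay within the uninformed filter's null range;
and the informed filter's network consistency under noise matches or
exceeds the uninformed filter's at every ratio tested.

Two reference-distribution choices deserve a note. In the
false-negative scenario the manipulated edge is compared against the
informed fit's own null edges — they share the same low prior variance,
so the comparison is matched by construction. In the false-positive
scenario no matched within-fit reference exists (the manipulated edge is
the only maximal-prior, function-absent edge), so inflation is judged
against the *uninformed* filter's null edges: the question "did the
prior inflate this edge beyond what the data alone support?" is answered
against what the data alone report.

## Known limitations

* The self-tuning rule for $c$ is this package's documented stand-in
  honoring the stated behavior (speed follows residuals); it is
  intentionally replaceable and all exactness checks use fixed $c$.
* Shrinkage is a bias/variance trade. With many trials the uninformed
  estimator's variance on structure-absent edges is already small, and
  the prior's multiplicative bias on strong coefficients can then
  slightly worsen *whole-matrix* coefficient RMSE even while network
  consistency and driver detection — the quantities that matter for
  topology — improve. The packaged benchmark computes both sides of this
  trade; users optimizing pointwise coefficient accuracy on
  high-trial-count data should widen the scaling maximum or use the
  sweep diagnostics rather than assume the default range.
* Priors are defined per node pair and replicated across lags; there is
  no lag-specific anatomy (e.g. conduction-delay priors).
* The consistency metric divides by the reference edge count; with tie
  retention the two adjacencies may hold different edge counts, which is
  reported rather than hidden (a Jaccard option exists).
* No volume-conduction forward model: simulated and real inputs are
  node-level signals. Source leakage must be handled upstream.

## A worked example

```{r example, eval = FALSE}
spec <- evokedSimulationSpec(seed = 1)
sim <- simulateTVMVAR(spec)
prior <- scScenario(trueEdges(spec), "concordant", d = 5)

fit <- siStokFit(sim$data, order = 2, prior = prior)
m <- mdi(fit)
outflow <- summedOutflow(m, window = 80:140)
rankOutflows(outflow)

bench <- runNoiseBenchmark(sim$data, prior, peakT = 120, driver = 1,
                           iters = 30, seed = 1)
bench
```
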