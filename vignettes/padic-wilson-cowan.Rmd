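---
title: "Wilson-Cowan dynamics on a p-adic tree: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wilson-Cowan dynamics on a p-adic tree: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padicwc)
```

## The model

The Wilson-Cowan equations describe the mean activity $E(x,t)$ and
$I(x,t)$ of excitatory and inhibitory neural populations coupled through
distance-dependent kernels.  Classically $x$ ranges over the real line,
which restricts the couplings to short range.  `padicwc` instead places
the populations on the compact ultrametric domain $\mathbb{Z}_p$, the
ring of $p$-adic integers: neurons are organized as the leaves of an
infinite rooted $p$-ary tree, distance is measured by the depth of the
first common ancestor, and *every* pair of sites interacts — the
hierarchical analogue of a small-world cortical network.

The dynamics are

$$\tau \partial_t E = -E + (1 - r_E E)\,
  S_E\!\big(w_{EE} * E - w_{EI} * I + h_E\big),$$
$$\tau \partial_t I = -I + (1 - r_I I)\,
  S_I\!\big(w_{IE} * E - w_{II} * I + h_I\big),$$

with $*$ the convolution over $(\mathbb{Z}_p, +)$ under the normalized
Haar measure, $S_A$ a sigmoid gain with $S_A(0) = 0$, and
$(1 - r\,\cdot)$ the refractory saturation.  With $r_E = r_I = 0$ (two
coupled perceptrons) the problem is globally well posed and the
solution obeys the a-priori bound
$|E(x,t)| \le \|E_0\|_\infty + \tau \|S_E\|_\infty$, which the package
monitors (never enforces) and the tests verify.

## Discretization

At level $l$ the domain is the finite group $G_l = \mathbb{Z}_p /
p^l\mathbb{Z}_p \cong \mathbb{Z}/p^l\mathbb{Z}$: a field becomes a
vector of $p^l$ values (one per tree leaf), each representing a locally
constant function on a ball of radius $p^{-l}$.  Key choices:

* **Quadrature.** The Haar measure gives every leaf the equal weight
  $p^{-l}$.  `haar_integral()` computes $p^{-l}\sum_i \phi_i$ as a
  single sum divided once by $p^l$, so the constant field 1 has mass
  exactly 1 in floating point (a naive sum of $p^{-l}$ weights does not
  for $p^l = 729$).
* **Convolution.** Because $G_l$ is cyclic, the Haar-weighted group
  convolution $(w * \phi)_k = p^{-l}\sum_i w_{(k-i) \bmod p^l}\phi_i$
  is a circular convolution, evaluated by FFT in $O(p^l \log p^l)$;
  the tests compare it against a direct double sum at $10^{-10}$
  relative tolerance.  The Haar factor $p^{-l}$ is deliberately part of
  the discrete operator: it makes the discrete convolution consistent
  with the continuum integral, keeps coupling strengths independent of
  grid resolution, and is what makes the level-refinement experiment
  below converge.
* **Sigmoid.** $S(z) = \mathrm{logis}(v(z - \theta)) -
  \mathrm{logis}(-v\theta)$ is applied entrywise (the leaf supports are
  disjoint) through `stats::plogis`, which is overflow-safe; with
  matrix-backed couplings the argument can reach the hundreds.
* **Level transfer.** `coarse_project()` samples a fine field at the
  coarse representatives $0,\dots,p^l-1$; `refine_embed()` repeats each
  value across the children, leaving the step function unchanged on
  $\mathbb{Z}_p$.  Projection after embedding is the identity, and the
  test suite checks that the level-to-level solution gaps
  $\sup_{t \le 20}\max_x |P_l u_{l+1} - u_l|$ shrink as $l$ grows
  ($l = 2, 3, 4$ at $p = 3$): the finite-tree runs approximate the
  continuum model.
* **Time stepping.** `wc_integrate()` delegates to `deSolve::ode` with
  the classical fixed-step 4th-order Runge-Kutta scheme at $dt = 0.05$
  by default (explicit Euler is available for comparison); every step
  is recorded and runs are bit-reproducible.  The scheme is a package
  choice — only the step size is inherited from the reference
  experiments — and the decay test verifies 4th-order convergence.
  State is never clipped; the a-priori bound is only monitored.
* **Initial conditions** default to rest, $E_0 = I_0 = 0$: the
  reference experiments show responses developing from quiescence
  after stimulus onset.

## Parameters of the reference network

All pulse and hysteresis presets use $p = 3$, $l = 6$ (729 sites),
$\tau = 10$ (one time unit $\approx$ a membrane time constant; $\tau$
sets the relaxation scale), $r_E = r_I = 1$, and the radial kernels
$w_{AB}(x) = b_{AB}(e^{\sigma_{AB}} - e^{\sigma_{AB}|x|_p})$, which
decrease from $b(e^{\sigma}-1)$ at distance 0 to exactly 0 at the
maximal distance $|x|_p = 1$:

| coupling | $b$ | $\sigma$ |   | sigmoid | $v$ | $\theta$ |
|---|---|---|---|---|---|---|
| $w_{EE}$ | 1.5  | 4 |  | $S_E$ | 2.75 | 9  |
| $w_{EI}$ | 1.35 | 6 |  | $S_I$ | 0.3  | 17 |
| $w_{IE}$ | 1.35 | 6 |  |       |      |    |
| $w_{II}$ | 1.8  | 3 |  |       |      |    |

Stimuli: a localized excitatory pulse of amplitude 3.7 on the ball
$4 + p^2\mathbb{Z}_p$ over $t \in [0,\delta]$, an optional spatially
uniform inhibitory pulse at level $Q$ (its ball has radius exponent 0,
i.e. it covers the whole space — that is the literal reading of the
protocol and it is kept configurable), and the binocular hysteresis
stimulus
$\tilde h(x,t) = e^{-(30(0.5-m(x)) - 0.5t)^2} +
 e^{-(30(0.5-m(x)) + 0.5t)^2}$
written in the Monna coordinate $m(x)$ — the digit-reversal map sending
every ball to an interval, so the two Gaussian peaks drift apart at
speed $1/60$.  The return protocol plays $\tilde h(x,t)$ up to $t=18$
and $\tilde h(x, 36-t)$ on $(18, 36]$ (the half-open second window
avoids double-counting the shared endpoint) and vanishes afterwards.

## Connection matrices as couplings

Empirical cortical connection matrices are directed weighted adjacency
matrices.  To use one as a coupling, the package

1. pads it with zeros to $p^k \times p^k$ (`pad_matrix()`),
2. partitions it into $p^{2r}$ blocks by residue mod $p^r$ — rows in
   the ball $a + p^r\mathbb{Z}_p$, columns in $b + p^r\mathbb{Z}_p$
   (`block_partition()`), and
3. replaces, within each block, every difference class
   $(i-j) \bmod p^k$ by its arithmetic mean
   (`local_circulant_average()`).

Step 3 is the mean-square orthogonal projection onto kernels that are
translation invariant within each block pair — the unique averaging
choice that is idempotent, preserves block sums, and returns the input
exactly at $r = k$.  The resulting $K_r(x,y)$ enters the dynamics as
the Haar-weighted integral operator $p^{-l} K \phi$
(`integral_operator()`), interchangeable with a convolutional coupling;
when $K$ is circulant the two code paths agree to machine precision.
The resolution $r$ interpolates between a fully translation-invariant
(convolutional) kernel at $r = 0$ and the raw matrix at $r = k$, and
the mean-square approximation error is nonincreasing in $r$.

### The synthetic hierarchical generator

The empirical cat-cortex matrix is an external dataset and is not
bundled.  For testing, `synthetic_hierarchical_matrix()` emulates a
matrix with the assumed ultrametric structure:
$a_{ij} = A\,e^{-\mathrm{decay}\,(k - v)} + \varepsilon_{ij}$, where
$v$ is the depth of the leaves' first common ancestor (so $k - v$
counts the tree levels separating them), truncated at zero, zero
diagonal.  Defaults, chosen once: amplitude $A = 3$ (the ordinal 0-3
weight scale used by published cortical connectivity matrices),
`decay = 1` (about an e-fold of coupling per tree level), `noise_sd =
0.1` (weak heterogeneity that breaks exact translation invariance, as
empirical matrices do).  What it does *not* emulate: the sparsity,
asymmetric in/out-degree structure, and community deviations from
exact hierarchy of real connectomes — so tests passing on it show the
kernel algebra and dynamics are correct, not that real cortical
matrices are ultrametric.  With `noise_sd = 0` the matrix is exactly
circulant, which provides the equivalence oracle between the matrix
and convolution code paths.

## Readouts

Heat maps are exported as site-by-time matrices; rows default to the
Monna (tree) order, under which every ball is a contiguous band (the
integer order is also available — the leaf layout of the display tree
is a convention, not part of the model).  `count_spatial_peaks()` and
`count_temporal_oscillations()` operationalize the visual readouts
"single vs twin pulse" and "pulse train": strict local maxima after
collapsing runs of equal values (step-function fields are constant on
balls, and on symmetric grids a bump's two top samples can tie
exactly), ignoring values at or below 10% of the maximum.  The 10%
threshold is a package choice; the reference readouts are only visual.

## Reference experiments and what they show

`wc_preset()` encodes six experiments (pulse, maintained pulse,
maintained pulse with uniform inhibition, two hysteresis protocols,
and a connection-matrix run at $p = 2$, $l = 6$ with constant stimuli
$h_E = 3.5$ on $1 + 4\mathbb{Z}_2$ and $h_I = -30$).  Two regimes
matter when interpreting them:

* With the reference sigmoid parameters the stimuli are sub-threshold
  ($S_E(3.7) \approx 4.5\times 10^{-7}$ for $\theta_E = 9$,
  $v_E = 2.75$), so from rest the network responds in its linear
  regime: responses are small, track the stimulus, and decay after
  offset.  The brief-pulse experiment (transient localized response),
  the peak-splitting of the opening hysteresis protocol, and the
  growth of spatial complexity with the resolution $r$ of a
  connection-matrix kernel are all reproduced in this regime.
* Phenomena that require supra-threshold recurrent dynamics —
  self-sustained pulse trains under a maintained stimulus, and the
  memory effect in which twin response pulses survive after the
  binocular stimuli re-merge — need the sigmoid drive to reach its
  steep region, which these stimulus amplitudes cannot do from rest
  under any convolution normalization (the recurrent gain only
  rescales feedback, not the stimulus-to-sigmoid path).  The
  corresponding acceptance checks are retained and fail under the
  default parameters; users exploring ignited regimes can lower
  `theta_E` or raise stimulus amplitudes through the configuration
  overrides.

A quick scaled-down run:

```{r example, eval = FALSE}
cfg <- wc_preset("sim1_pulse", l = 3, time = list(t_end = 20))
ex <- run_experiment(cfg)
ex$metrics$final_spatial_peaks_E   # 1: a single localized response pulse
export_heatmap(ex$trajectory, "E_heatmap.tsv", ordering = "monna")
```

## Problem sizes used by the tests

The unit tests exercise grids up to $p^l = 729$ exhaustively for
algebraic properties (ultrametricity, ball dichotomy, quadrature) and
use the full reference grids ($p = 3$, $l = 6$; $p = 2$, $l = 6$) with
$dt = 0.05$ for the end-to-end experiment checks; the level-refinement
study uses $l = 2\dots5$ over $t \le 20$.  These sizes reproduce the
reference settings exactly while keeping a full test run in the order
of a minute.

## Known limitations

* Fixed-step explicit integration only; no adaptive or stiff solvers.
  The dynamics are bounded and non-stiff at the reference parameters.
* The additive group and norm of $\mathbb{Z}_p$ are implemented at
  finite level only; there is no general $\mathbb{Q}_p$ arithmetic.
* The sub-threshold regime discussed above: the reference parameter
  set does not ignite recurrent pattern formation from rest.
* Connection matrices must fit the grid ($p^k = p^l$) after padding;
  node ordering is taken as given in the input file, and no
  symmetrization or rescaling is applied.
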