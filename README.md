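# padicwc

Hierarchical (p-adic) Wilson–Cowan neural-field models in R.

## The problem

The Wilson–Cowan equations describe the coupled activity of excitatory
and inhibitory neural populations,

    τ ∂t E = −E + (1 − r_E E) · S_E( w_EE∗E − w_EI∗I + h_E ),
    τ ∂t I = −I + (1 − r_I I) · S_I( w_IE∗E − w_II∗I + h_I ),

with distance-dependent coupling kernels `w_AB`, sigmoid gains `S_A`
and external inputs `h_A`.  On the real line the kernels are
short-ranged, which is at odds with the small-world connectivity seen
in cortical connection matrices.  `padicwc` formulates the model on the
compact ultrametric domain **Z_p**, the ring of p-adic integers:
populations sit on the leaves of a rooted p-ary tree, distance is
p-adic (`|x − y|_p = p^−v`, with `v` the depth of the first common
ancestor), and every pair of sites interacts.  Truncating the tree at
level `l` gives the finite group `G_l = Z/p^l Z`, on which convolution
is cyclic and Haar-weighted, so the whole system becomes a
`2 p^l`-dimensional ODE that provably approximates the continuum model
as `l → ∞`.

The package is for computational neuroscientists and applied
mathematicians who want to

* simulate E/I population dynamics on hierarchical (tree) topologies,
  with the classical pulse, maintained-stimulus and binocular
  hysteresis protocols built in;
* approximate an empirical **connection matrix** by a locally
  translation-invariant p-adic kernel `K_r(x, y)` — exact at
  resolution `r = k`, fully convolutional at `r = 0` — and plug it
  into the dynamics as the excitatory–excitatory coupling.

## Worked example

```r
library(padicwc)

## A locally constant test field: +1 on the singleton balls at 0, 1, 7,
## −1 at 2, on the level-4 dyadic tree (16 leaves)
g <- padic_grid(2, 4)
phi <- ball_indicator(g$indices, 0, 4, g) - ball_indicator(g$indices, 2, 4, g) +
       ball_indicator(g$indices, 1, 4, g) + ball_indicator(g$indices, 7, 4, g)
phi
#>  [1]  1  1 -1  0  0  0  0  1  0  0  0  0  0  0  0  0

## Brief localized pulse on the reference network (p = 3, l = 6)
ex <- run_experiment(wc_preset("sim1_pulse"))
ex
#> experiment: sim1_pulse
#> Wilson-Cowan trajectory: 2001 time points (dt = 0.05, rk4), 729 sites
#>   t in [0, 100]; max |E| = 1.841e-07, max |I| = 9.2e-09
#>   final spatial peaks (E): 1; temporal maxima at site 4: 1
```

The pulse (amplitude 3.7 on the ball `4 + 9 Z_3`, duration 5) produces
a transient response confined to the stimulated ball — it rises while
the stimulus is on, peaks once at site 4, and relaxes back toward rest
(the amplitude is small because the stimulus is sub-threshold for the
reference sigmoid; see the vignette for the regime discussion).

```r
## Kernel approximation of a (synthetic) hierarchical connection matrix
A <- synthetic_hierarchical_matrix(2, 3, decay = 1, noise_sd = 0.2, seed = 4)
for (r in 0:3) {
  K <- local_circulant_average(A, 2, 3, r)
  cat(sprintf("r = %d: mean-square error %.6f\n",
              r, approximation_error(A, K)$mean_square))
}
#> r = 0: mean-square error 0.022164
#> r = 1: mean-square error 0.021099
#> r = 2: mean-square error 0.015739
#> r = 3: mean-square error 0.000000
```

The error decreases monotonically with the resolution `r` and vanishes
when the kernel matches the matrix exactly.  `export_heatmap()` writes
any trajectory as a site-by-time text matrix (rows in Monna/tree order,
so that balls are contiguous bands) plus an optional PNG.

A command-line front end is installed with the package:

```sh
padicwc=$(Rscript -e 'cat(system.file("exec", "padicwc", package = "padicwc"))')
Rscript "$padicwc" simulate --preset sim1_pulse --out out/
Rscript "$padicwc" synthesize-matrix --p 2 --k 6 --seed 1 --out A.csv
Rscript "$padicwc" kernelize --matrix A.csv --p 2 --r 0,3,5 --out kernels/
```

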