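---
title: "Phase-ordering kinetics in the long-range 2D Ising model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-ordering kinetics in the long-range 2D Ising model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
set.seed(1)
```

`spinquench` simulates domain coarsening in a two-dimensional ferromagnetic
Ising model whose spins couple through a power law,

$$H \;=\; -\sum_{\langle ij\rangle} \frac{J}{r_{ij}^{\,n}}\, s_i s_j,
\qquad s_i = \pm 1,\; J > 0,$$

on a periodic square lattice. The exponent $n$ interpolates between
genuinely long-range couplings ($n < 4$ in $d = 2$, where the integrated
interaction diverges with system size) and the short-range regime
($n > 4$). A configuration of $\pm 1$ spins can be read as a pattern of
active and inactive units — the same model family is used as a coarse
description of neural activity patterns, binary alloys, and uniaxial
ferromagnets; everything below is phrased in the magnet's language.

The package's concern is *nonequilibrium* behaviour: a balanced random
configuration (infinite-temperature state) is quenched instantaneously to a
temperature below criticality and evolves by single-spin-flip (Glauber)
kinetics, which does not conserve the magnetization. Domains of aligned
spins emerge and coarsen; the package measures how.

## Dynamics

One Monte Carlo step (MCS) is $N = L_s^2$ attempted flips, each at an
independently and uniformly chosen site, applied sequentially. A proposed
flip of $s_i$ changes the energy by $\Delta H = 2 s_i h_i$ with
$h_i = \sum_{j} w_{ij} s_j$ the local field over the coupling kernel, and is
accepted with the Metropolis probability $\min(1, e^{-\beta \Delta H})$.
Two conventions deserve note:

* **Ties are accepted.** $\Delta H = 0$ moves are accepted with probability
  $e^0 = 1$, the standard Metropolis convention.
* **Random site selection**, not typewriter sweeps, so a single MCS may
  visit a site twice or not at all.

The sweep engine is compiled C++. Local fields are maintained
incrementally: an attempt costs $O(1)$, and only *accepted* flips touch the
kernel's offset list. After the early transient, the acceptance rate of a
coarsening system is set by the shrinking interface density, so the cost of
a long run is dominated by its first few sweeps. This is an exact
implementation, not an approximation: the maintained fields equal the
freshly summed ones up to floating-point addition order, and the engine is
bit-reproducible under a fixed seed. Run $i$ of an ensemble uses the
derived seed $\mathrm{seed} + 1009\,(i-1)$, so ensembles are reproducible
and extensible.

## The coupling kernel and its cutoff

`coupling_kernel(n, J)` enumerates every integer offset with
$0 < r \le r_c$ and weight $J/r^n$. The default cutoff is
$r_c = 2.5^{6/n}$ — about 2.5 for $n = 6$ (20 neighbours), 6.25 for
$n = 3$ (120 neighbours), and 15.625 for $n = 2$ (768 neighbours) — which
keeps the truncated tail comparable across exponents. The boundary is
inclusive, so the $n = 6$ kernel retains the $r = \sqrt 5$ shell and the
$n = 12$ kernel the $r = \sqrt 2$ shell. Pairs interact through their
minimum periodic image only; configurations with $r_c \ge L_s/2$ are
refused rather than silently double-counted.

```{r kernel}
library(spinquench)
coupling_kernel(6)
```

## Observables

**Correlation function.** The equal-time correlation
$C(\vec r, t) = \langle s_i s_j \rangle - \langle s_i\rangle\langle
s_j\rangle$ is computed from the full 2D periodic autocorrelation (via FFT)
averaged over the ensemble of independent runs. The subtracted mean is the
single ensemble-and-volume average magnetization at that time: the system
is translationally invariant, and per-site means over a handful of runs
would be noise-dominated. Profiles are normalized so $C(0) = 1$ and
spherically averaged into radial bins of unit width centred on the integers
(an `"exact"` binning mode resolves individual shells for analytic test
configurations). During coarsening the per-run magnetization drifts, which
leaves a floor of order $\langle m^2\rangle - \bar m^2$ under the
large-$r$ tail of $C$; at the default $512^2$ scale and $t \le 500$ this
floor is small compared with the collapse tolerances used.

**Structure factor.** $S(\vec k, t)$ is the discrete Fourier transform of
the unbinned correlation field, spherically averaged over shells of one
grid mode ($k = 2\pi s / L_s$). The convention makes Parseval's identity
exact: the full 2D spectrum sums to $N \cdot C(0)$, which the tests assert
to $10^{-9}$.

**Characteristic length.** $L(t)$ is the distance at which $C(r, t)$ first
decays through one half, linearly interpolated between bins. Alternative
definitions (first zero, first moment of $S$) differ by constant factors in
the scaling regime and are not implemented. If $C$ never crosses the level
the profile is degenerate — domains are comparable to the box — and the
operation fails with instructions to enlarge $L_s$ rather than return a
number.

**Growth law.** `growth_exponent()` fits $\log L$ on $\log t$ by ordinary
least squares. Curvature-driven nonconserved coarsening gives the
Cahn-Allen exponent $\phi = 1/2$; a renormalization-group argument predicts
$t^{1/(n-2)}$ for $2 < n < 4$, and the package's simulations — like the
measurements they reproduce — show $\phi \simeq 1/2$ with no crossover at
$n = 4$, the long range appearing only through larger prefactors.

**Scaling collapse.** Dynamical scaling asserts $C(r, t) = g(r/L(t))$ and
$S(k, t) = L^2 f(kL)$. `scaling_collapse()` rescales each profile by its
own measured length, interpolates onto a common grid ($x \in [0, 2]$ in
steps of 0.05 for $C$; 40 log-spaced points on $[0.5, 8]$ for scaled $S$),
and reports pairwise RMS deviations. Correlation collapses are also
compared with the Ohta-Jasnow-Kawasaki (OJK) form
$g(x) = \tfrac{2}{\pi}\arcsin e^{-x^2}$. Because the collapse coordinate
uses the *half-height* length, the OJK reference is evaluated as
$g(x_0 x)$ with $x_0 = \sqrt{\ln 2 / 2} \approx 0.5887$, the point where
the raw form crosses one half; with that convention an exactly OJK-shaped
profile collapses with zero deviation, which the tests verify.

**Porod tail.** Sharp interfaces give $S(k) \sim k^{-(d+1)} = k^{-3}$ at
large $kL$. `porod_tail_slope()` fits the log-log tail over a caller-chosen
window; the end-to-end checks use $kL \in [4, 20]$, inside the Porod regime
but below the lattice cutoff.

## A worked quench

```{r quench}
cfg <- quench_config(L_s = 128, n = 6, temp = 1,
                     snapshot_times = c(50, 100, 200, 400, 800),
                     seed = 1, n_runs = 5)
exp6 <- experiment_quench(cfg)
exp6$fit
glance(exp6$collapse)
```

```{r plots, fig.height = 3}
autoplot(exp6$fit)
autoplot(exp6$collapse)
```

## Thermodynamics of the power-law potential

The integrated potential per spin, approximated by the radial integral
$U(n) \approx J\int_1^{\sqrt N} r^{3-n}\,\mathrm d r$ with pair
distribution $g(r) \approx 1$, splits into three branches: $\tfrac J2\ln N$
at the marginal $n = 4$; $\tfrac J{n-4}(1 - N^{2-n/2})$, finite as
$N \to \infty$, for $n > 4$; and $\tfrac J{4-n} N^{2-n/2}$, diverging with
size, for $n < 4$. Here $N$ is the *site count* and the linear size is
$\sqrt N$ — the only reading consistent with the integral's upper limit —
and the long-range branch keeps only its growing term, so comparisons near
$n = 4^-$ must restore the dropped constant $J/(4-n)$ (the tests do). The
leading-order critical-point condition $U/(k_B T_c) \approx 1$ then gives
$T_c \approx J/(k_B(n-4))$ for short range — e.g. $T_c = 0.5\,J/k_B$ at
$n = 6$ — growing like $\ln N$ at $n = 4$ and like $N^{2-n/2}$ below it.
The second-moment lattice sum $f_2 = \sum w^2$ of the next order is
computed (`f2_lattice_sum()`) but deliberately not propagated into $T_c$.

These asymptotic formulas describe the *untruncated* coupling; no claim is
made that they match the empirical critical temperature of the simulated,
cutoff-regularized kernel at small $n$ — the cutoff removes the divergence.
The empirical $T_c$ comes instead from a temperature sweep.

```{r theory}
theory_table(c(2, 3, 4, 6, 12), N = c(1e4, Inf))
```

## Temperature sweeps and the empirical critical point

`temperature_sweep()` anneals downward through a grid, reusing the previous
temperature's final state, discards the first half of the steps at each
temperature and samples $m$ every 5 MCS thereafter (the protocol is a
package default — the underlying study does not specify one). The
empirical $T_c$ is the susceptibility-peak temperature,
$\chi = N\beta(\langle m^2\rangle - \langle|m|\rangle^2)$, with $|m|$ used
because a finite system below criticality breaks symmetry toward either
sign; a threshold on $\langle|m|\rangle$ was rejected as bin-sensitive.
For the nearest-neighbour-dominated $n = 12$ kernel the estimate lands
within a few percent of the exact square-lattice value
$2/\ln(1+\sqrt 2) \approx 2.269$, and the estimates decrease with $n$
across $n = 2, 3, 6, 12$ as the integrated coupling shrinks.

## Near-critical quenches

`experiment_near_critical()` quenches to a default of $0.9\times$ the
susceptibility-peak temperature estimated at the same $(n, L_s)$. Two
implementation findings shape that default. First, for long-range kernels
the apparent $T_c$ depends on the fraction of the box inside the cutoff, so
an estimate from a much smaller lattice does not transfer. Second, a quench
from disorder launched *exactly at* the finite-size peak develops no
real-space ordering within a few hundred MCS — the peak sits marginally
above the ordering temperature, and for the quasi-mean-field $n = 2$ kernel
the correlation function then decays within a couple of sites, the opposite
of the near-critical phenomenology (correlations spanning many tens of
sites, with the decay range increasing with interaction range). Just below
the peak the expected picture is robust: weak global ordering compared with
a deep quench, long-ranged correlations ordered as
$n = 2 > 3 > 6$, and profiles that still collapse under $r/L$.

## Scales, defaults, and what the tests show

The reference protocol (`reference_quench_config()`) is the study scale: a
$512^2$ lattice, 10 independent runs, quench temperature $T = 1$ in units
of $J/k_B$ ($k_B = 1$ throughout), snapshots at 100, 200, and 500 MCS. The
package's own analyses use: the full $512^2$ scale with 5 runs for the
collapse and Porod measurements (the incremental-field engine makes this a
matter of a minute); $128^2$ for the $n = 6$ growth law; and $256^2$ for
the $n = 3$ growth law, where smaller boxes intermittently coarsen to a
single phase by $t = 800$ and the half-height length stops existing.
Magnetization drift is the relevant finite-size failure mode everywhere:
spin-flip kinetics lets $|m|$ wander, and once a phase percolates the
correlation analysis degenerates — the package raises errors rather than
extrapolating.

The synthetic ensembles are exactly the model's own draws — balanced random
initial states evolved by the model dynamics — so passing tests demonstrate
internal consistency of simulator and analysis at the stated scales, plus
agreement with external anchors (OJK form, Porod exponent, the
nearest-neighbour $T_c$). They do not, and cannot, validate the model as a
description of any particular physical or biological system.

## Known limitations

* Ferromagnetic couplings only ($J > 0$), zero external field, $d = 2$;
  conserved-order-parameter (Kawasaki) dynamics and cluster algorithms are
  out of scope — the single-flip kinetics *is* the object of study.
* The closed-form $T_c$ is a leading-order mean-field-style estimate for
  the untruncated potential; it is not expected to match the simulated
  kernel for $n \lesssim 4$.
* Near-critical analyses inherit the ambiguity of any finite-size critical
  point; results there are qualitative (orderings, contrasts), not
  estimates of universal quantities.
* The half-height length requires $C$ to cross $1/2$ inside the box;
  late-time analyses on small lattices fail loudly and should be rerun
  larger.
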