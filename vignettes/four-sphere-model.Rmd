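---
title: "The four-sphere head model: methods and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The four-sphere head model: methods and numerical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foursphere)
```

## The model

EEG electrodes record, at the scalp, the potential set up by current dipoles
in the brain.  The four-sphere model idealises the head as four concentric
homogeneous shells — brain, cerebrospinal fluid (CSF), skull and scalp, with
outer radii $r_1 < r_2 < r_3 < r_4$ and scalar conductivities
$\sigma_1,\dots,\sigma_4$.  Under the quasi-static approximation the
potential obeys the Poisson equation
$\nabla\cdot\sigma\nabla\Phi = -C$ in each shell, with

* continuity of the potential across each internal interface,
* continuity of the radial current density
  $\sigma\,\partial\Phi/\partial r$ across each internal interface,
* zero radial current at the outer scalp surface (no current leaves the
  head).

For an ideal current dipole of magnitude $p$ at radius $r_z$ inside the
brain shell the solution is a Legendre series.  With the dipole on the $+z$
axis, a **radial** dipole gives, in shell $s$,
$$\Phi^s(r,\theta) = \frac{p}{4\pi\sigma_1 r_z^2} \sum_{n\ge 1}
  \Big[A_n^s\big(\tfrac{r}{r_s}\big)^{n} +
       B_n^s\big(\tfrac{r_s}{r}\big)^{n+1}\Big]\, n\,P_n(\cos\theta),$$
where in the brain shell the $B$ term is replaced by the known source term
$(r_z/r)^{n+1}$.  A **tangential** dipole (moment along $+y$) replaces
$n P_n$ by $P_n^1(\cos\theta)$ and carries a $\sin\varphi$ azimuthal factor;
the expansion coefficients are identical.  An arbitrary dipole is the
superposition of its radial and tangential parts; `canonical_frame()`
performs that decomposition and the package evaluates the two pure solutions
with one shared coefficient table.

The coefficients $A_n^s, B_n^s$ follow from the boundary conditions through
auxiliaries $V_n, Y_n, Z_n$ (ratios built from the conductivity ratios
$\sigma_{ij} = \sigma_i/\sigma_j$ and radius ratios $r_{ij} = r_i/r_j$), and
satisfy three linkage identities, of which $B_n^4 = \frac{n}{n+1} A_n^4$ is
the per-harmonic expression of the scalp Neumann condition.

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `radii` | 7.9, 8.0, 8.5, 9.0 | cm | outer radii of brain, CSF, skull, scalp |
| `sigma_brain` | 0.33 | S/m | brain (and scalp) conductivity |
| CSF multiplier | 5 | — | $\sigma_2 = 5\sigma_1$ |
| `skull_divisor` (K) | 20 | — | $\sigma_3 = \sigma_1/K$; 40 and 80 are common presets |
| `n_max` | 5000 | — | hard cap on the harmonic index |
| `rel_tol` | 1e-12 | — | relative tail tolerance of the adaptive truncation |
| `consecutive_small` | 10 | — | successive negligible terms required to stop |

The canonical test source throughout the package is a dipole 1 mm below the
brain surface ($r_z$ = 7.8 cm) with $|p| = 10^{-7}$ A·m, which produces scalp
potentials of some tens of microvolts — the familiar EEG scale:

```{r}
m <- four_sphere()
d <- dipole(c(0, 0, 7.8), c(0, 0, 1e-7), units = "cm")
predict(m, d, read_electrodes(system.file("extdata",
  "electrodes_1020_idealized.csv", package = "foursphere"), units = "cm"),
  units = "uV")
```

Internally everything is SI (m, S/m, A·m, V); constructors and file readers
accept centimetres, and outputs offer microvolts, because those are the
units of practice.

## Conventions pinned by physics

Two conventions in the tangential solution are not fixed by the formulas
alone and differ between software libraries:

* **Associated Legendre sign.**  The package generates $P_n^1$ by upward
  recurrence in the Condon–Shortley-free convention,
  $P_1^1(\cos\theta) = \sin\theta \ge 0$.
* **Azimuth factor.**  With that convention the tangential prefactor is
  $+p\sin\varphi/(4\pi\sigma_1 r_z^2)$ for a moment along canonical $+y$,
  azimuth measured from $+x$.  (This is algebraically identical to the
  $-\sin\varphi$ form often written with Condon–Shortley-phased $P_n^1$.)

The pair of choices is pinned, not assumed: in an equal-conductivity model
whose radii are scaled to infinity at fixed source–electrode geometry, the
potential must converge to the infinite-medium dipole formula
$\mathbf p\cdot(\mathbf r-\mathbf r_0)/(4\pi\sigma|\mathbf r-\mathbf r_0|^3)$
— in particular, a $+y$ dipole must give positive potentials on the $+y$
side.  `check_infinite_limit()` verifies exactly this, and the sign
combination above is the one that satisfies it.

## Numerical design

**Stable coefficient evaluation.**  Written naively, the coefficient
formulas mix decaying powers $r_{34}^n$ with growing powers
$r_{43}^{n+1} \approx 1.059^n$ that overflow doubles near $n \approx 12{,}000$.
Every ratio is therefore rewritten so only decaying powers
$r_{ij}^{2n+1}$ (inner radius over outer) appear.  One further hardening
matters: for equal conductivities — the model's own homogeneous control —
the auxiliary $V_n$ *genuinely diverges* once $r_{34}^{2n+1}$ falls below
machine epsilon (around $n = 327$ for the standard radii), and evaluating
$B_n^3 = V_n A_n^3$ as a product then produces `Inf * 0 = NaN`.  The
auxiliaries are therefore carried as numerator/denominator pairs that are
folded directly into the $A, B$ coefficients, which remain finite and
accurate; `V` itself is reported as the pair ratio and may legitimately be
`Inf` in that limit.

**Stability-safe range.**  With the standard geometry the scalp coefficient
$A_n^4 \sim (r_z/r_4)^n$ underflows to exact zero near $n \approx 4950$.
Adaptive truncation always stops far earlier (about 200 harmonics for
scalp-surface evaluation; about 2200 for the hardest case, evaluation at the
brain surface just above the dipole, where the term ratio is
$r_z/r_1 \approx 0.987$), so potentials are unaffected.  Requests for
coefficients or series terms beyond the representable range raise a classed
`series-range` error naming the failing harmonic; diagnostic residual sweeps
are run to $n = 3000$, inside the safe range.

**Truncation.**  Summation proceeds in blocks of 256 harmonics and stops
once 10 successive terms each fall below `rel_tol` of the running sum
(10, not 1, because odd/even Legendre terms can vanish individually on
symmetry axes).  The homogeneous-limit deviation is truncation-limited by
construction: tightening `rel_tol` cannot worsen it.

**Interface points.**  An evaluation radius equal to an interface radius is
assigned to the inner shell; the continuity conditions make the choice
immaterial to well below any tolerance used here, and a deterministic
tie-break keeps outputs bit-reproducible.

**Rejected regions.**  Points with $r \le r_z$ are rejected rather than
extrapolated: the series above is only valid outside the source radius, and
scalp-EEG use never needs the interior expansion.  Dipoles exactly at the
centre are rejected (the $1/r_z^2$ prefactor is indeterminate there); the
documented workaround is a small offset.

**The linear-system oracle.**  `solve_coefficients_linear()` rederives the
coefficients per harmonic from a 7×7 system assembled directly from the
seven boundary equations — three potential continuities, three current
continuities, one Neumann row — sharing nothing with the closed-form
recursion but the boundary conditions themselves.  The system is assembled
in an inner-anchored scaled basis ($B$-columns anchored at the inner
interface radius) so all entries stay bounded for any $n$, row-equilibrated,
solved by LAPACK, and rescaled to the series normalisation, which keeps even
coefficients fifty orders of magnitude below the dominant one accurate in a
relative sense.  Agreement between the two routes (typically $10^{-13}$,
asserted at $10^{-9}$) plays the logical role a finite-element cross-check
would play, at desk scale and with a far tighter bound.

## The validation suite

`run_validation()` packages four checks, each returning a report that
records its statistic, sample count, tolerance and the tolerance's
provenance (tolerances are configuration, not constants):

1. **Boundary conditions** — worst normalised residual of potential and
   current continuity over 100 interface directions (both dipole kinds), and
   the scalp Neumann residual relative to the interior derivative scale.
   Because the coefficients satisfy the interface equations per harmonic,
   these residuals sit at round-off ($\sim 10^{-14}$), far below the
   $10^{-8}$/$10^{-10}$ tolerances.
2. **Homogeneous limit** — the equal-$\sigma$ four-sphere series against the
   closed-form single-sphere surface potential on a 180-point polar grid,
   normalised by the peak magnitude (pointwise ratios are undefined at the
   potential's zero crossing).  Observed $\sim 10^{-14}$ against a $10^{-6}$
   tolerance.
3. **Infinite-medium limit** — deviations at radius scales ×10/×100/×1000
   must decrease monotonically and end below 1 %.  Observed $\sim 10^{-10}$
   at ×1000.
4. **Oracle equivalence** — both coefficient routes through the full
   summation pipeline at 1000 scalp points.

Property tests draw random valid models with radii increasing in
[5, 12] cm (gaps ≥ 1 mm) and conductivities log-uniform in [0.004, 2] S/m —
log-uniform because the physics responds to conductivity *ratios*; the
spread covers skull-like to CSF-like values well beyond the physiological
presets.

## What the checks do and do not show

All inputs here are exact by construction: ideal dipoles, perfectly
concentric spheres, noiseless electrodes.  Passing checks therefore
demonstrate the *mathematical* correctness of the forward solution — the
boundary conditions, the limits, the symmetries — not that the four-sphere
idealisation describes any particular head.  Real heads are not spherical,
skull conductivity is uncertain by the very factor the `K` presets span, and
tissue anisotropy and frequency dependence are outside the model class
(deliberately: conductivities here are scalar and frequency-independent).
Sensitivity of published results to `K` should be reported with the preset
used.

## Problem sizes

The shipped test-and-validation configuration uses 100 interface directions
per boundary check, 180-point polar grids for the closed-form comparisons,
1000-point Fibonacci scalp lattices for oracle comparisons, harmonic sets
$\{1..50, 100, 500, 1000\}$ over the standard model plus 20 random models
for coefficient equivalence, and a 200-node Gauss–Legendre × 90-azimuth
quadrature for the zero-surface-mean (no monopole) statistic.  These sizes
make every check deterministic-to-tolerance and keep the whole suite in the
tens of seconds on one core.

## Known limitations

* No interior expansion ($r < r_z$) and no magnetic counterpart (MEG).
* Single-dipole evaluations; a multi-dipole lead field is a loop over
  sources (coefficients are cached per source radius, so looping is cheap
  when sources share a radius).
* The closed-form single-sphere control covers the radial orientation only;
  tangential behaviour is controlled through the infinite-medium limit and
  the oracle instead.
* Conductivities are isotropic and frequency-independent by model class.
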