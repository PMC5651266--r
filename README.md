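# foursphere

Analytical four-sphere head model for EEG forward computation in R.

## The problem

The EEG signal is generated by current dipoles in the brain; a *forward
model* maps a dipole (position and moment) to the potential it produces at
scalp electrodes.  The four-sphere model idealises the head as four
concentric homogeneous shells — brain, cerebrospinal fluid (CSF), skull and
scalp, with radii `r1 < r2 < r3 < r4` and conductivities `σ1..σ4` — and
solves the quasi-static Poisson equation `∇·σ∇Φ = −C` in each shell, with
continuity of potential and radial current across the internal interfaces
and zero radial current at the scalp surface.  Because the solution is a
closed Legendre series it is fast, transparent, and serves as ground truth
for numerical solvers (FEM/BEM) and as a test bed for inverse methods.  The
coefficient algebra is notoriously error-prone — published versions of the
formulas disagree — so this package ships the series solution *together
with* an independent per-harmonic linear-system solver derived directly from
the boundary conditions, plus an executable validation suite.

For a radial dipole of magnitude `p` at radius `r_z` the potential in shell
`s` is

    Φ_s(r, θ) = p / (4π σ1 r_z²) · Σ_{n≥1} [ A_n^s (r/r_s)^n + B_n^s (r_s/r)^(n+1) ] n P_n(cos θ)

(in the brain shell the `B` term is the known source term `(r_z/r)^(n+1)`);
a tangential dipole replaces `n P_n` by `P_n^1` with a `sin φ` azimuthal
factor and uses the same coefficients.  Any dipole is the superposition of
its radial and tangential parts.

Audience: computational neuroscientists and EEG methodologists who need a
trustworthy analytic forward model — for intuition, for benchmarking
numerical head models, or for generating test data for source localisation.

## Worked example

A radial dipole 1 mm below the brain surface (`r_z` = 7.8 cm) with moment
1e-7 A·m — the canonical benchmark configuration — evaluated at an
idealized 10-20-style montage:

```r
library(foursphere)
m <- four_sphere()                                   # radii 7.9/8.0/8.5/9.0 cm, K = 20
d <- dipole(c(0, 0, 7.8), c(0, 0, 1e-7), units = "cm")
el <- read_electrodes(system.file("extdata", "electrodes_1020_idealized.csv",
                                  package = "foursphere"), units = "cm")
predict(m, d, el, units = "uV")
```

```
   label        x        y       z potential_uV
1     Cz  0.00000  0.00000 0.09000      96.5888
2     Fz  0.00000  0.05290 0.07281       5.1999
3     Pz  0.00000 -0.05290 0.07281       5.1999
4    Fpz  0.00000  0.08560 0.02781      -2.2089
...
```

The vertex electrode directly above the dipole sees ~97 µV; the potential
falls off steeply and reverses sign beyond ~50° polar angle — the familiar
dipolar EEG topography at the familiar tens-of-microvolts scale.

The built-in physical controls:

```r
run_validation(m)
```

```
Four-sphere validation report
                                     check statistic samples tolerance pass
   potential continuity (interfaces r1-r3) 6.655e-15     200     1e-08 PASS
     current continuity (interfaces r1-r3) 5.163e-14     200     1e-08 PASS
 scalp Neumann (zero radial current at r4) 3.664e-17     200     1e-10 PASS
           homogeneous single-sphere limit 1.836e-14     180     1e-06 PASS
         infinite homogeneous medium limit 2.146e-10      72     1e-02 PASS
       closed-form vs linear-system oracle 4.383e-16    1000     1e-09 PASS
```

Rows 1–3 are the defining boundary conditions; row 4 compares the
equal-conductivity model against the closed-form single-sphere solution;
row 5 scales the radii ×10/×100/×1000 against the infinite-medium dipole
formula; row 6 runs the full pipeline with coefficients from the
independent 7×7 boundary-condition solve.

There is also a small CLI (`inst/exec/foursphere`) with `compute`, `map`
and `validate` subcommands driven by a YAML/JSON configuration
(`inst/extdata/example_config.yaml`) and electrode CSVs, writing plain CSV
potentials, long-format scalp maps, and JSON validation reports.

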