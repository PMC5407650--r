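# burstbif

Burst noise can rewrite the stability landscape of a chemical reaction
system without touching its rate equation. `burstbif` studies this on
the minimal system where it happens: the Schlogl model, a one-species
mass-action scheme

```
∅ →(k1) X     X →(k2·x) ∅     2X →(k3·x²) 3X     3X →(k4·x³) 2X
```

with the autocatalytic step replaced by a burst variant
`2X → (2+r)X` firing at rate `k3·x²/r` — one firing makes `r`
molecules, `r` times less often. The deterministic drift
`A(x) = k1 − k2·x + k3·x² − k4·x³` is identical for every burst size
`r`, but the Fokker–Planck diffusion
`B(x) = k1 + k2·x + r·k3·x² + k4·x³` is not, and the extrema of the
stationary density `Ps(x) ∝ B⁻¹ exp ∫ 2A/B` sit at the roots of

```
α(x) = A(x) − B′(x)/2 ,
```

which do move with `r`. Counting and tracking those extrema — the
phenomenological definition of a stochastic saddle-node bifurcation,
detected when two extrema merge — shows burst noise destroying and
*creating* bistability in a system whose ODE never changes.

The package is aimed at people working on stochastic chemical
kinetics, noise-induced transitions, and bursty production in gene
expression who want an exact, cross-validated reference implementation
of the full analysis chain:

* **Deterministic layer** — fixed points by closed-form cubic solution,
  stability labels, the cusp discriminant
  `Δ = −27k̃1² + 18k̃1k̃2k̃3 − 4k̃1k̃3³ − 4k̃2³ + k̃2²k̃3²`
  (reduced rates `k̃i = ki/k4`).
* **Fokker–Planck layer** — stationary densities by log-space Simpson
  quadrature for any `r`, the exact partial-fraction closed form for
  `r = 1`, and extremum location/classification via `α`.
* **Master-equation layer** — exact stationary distributions of the
  truncated chain (sparse nullspace solve), with the detailed-balance
  recurrence as an independent `r = 1` oracle.
* **Simulation layer** — an exact direct-method Gillespie simulator
  (Rcpp core, R RNG stream, time-weighted occupancy accumulated in
  place for arbitrarily long runs).
* **Bifurcation layer** — extremum counting across parameter grids and
  burst sizes, bisection-refined phase boundaries, and the analytic
  implicit-function mode shifts `∂k̃1/∂r = k̃3·x`,
  `∂k̃2/∂r = −2k̃3x/(2x+1) → −k̃3`, `∂k̃3/∂r = k̃3/(x−r)`.

Everything is tibble-in/tibble-out with `tidy()`, `glance()` and
`autoplot()` methods, plus a thin CLI (`inst/exec/burstbif`) with
`simulate | stationary | extrema | scan | shifts | fixtures`
subcommands over YAML/JSON configs.

## Worked example

The canonical burst-induced transition uses
`k1 = 3e6, k2 = 77518, k3 = 601, k4 = 1`:

```r
library(burstbif)
p25 <- schlogl_params(k1 = 3e6, k2 = 77518, k3 = 601, r = 25)

glance(fixed_points(p25))
#>   n_roots n_stable discriminant bistable
#> 1       1        1     -2.50e13 FALSE

tidy(find_extrema(p25))
#>   location type    boundary
#> 1     43.2 maximum FALSE
#> 2    184.  minimum FALSE
#> 3    372.  maximum FALSE

distribution_mode(stationary_distribution(p25))
#> [1]  41 366

tidy(track_extrema_vs_r(schlogl_params(3e6, 77518, 601), 1:25))
#>   r_lower r_upper n_lower n_upper r_star x_star
#> 1       1       2       1       2   1.71   82.6
```

Read: the rate equation has exactly one stable state (near 440.5,
`Δ < 0`, and independent of `r`), yet at burst size 25 the stationary
law is bimodal — density maxima at 43.2 and 372.3 molecules, exact
master-equation modes at 41 and 366 (the upper plateau is flat to
~0.3%, so different mode estimators land within a few molecules of
each other). Tracking `r` upward finds the bifurcation born at
`r* ≈ 1.71`; running the track out to `r = 60` shows it dying again
near `r* ≈ 37.5`. At `r = 1` the same rates give a single mode at 436.
The analytic shift formulas say how fast the modes move per unit burst
size, e.g. at the upper mode:

```r
shift_derivative(p25, "k2", x = 372.28, r = 25)
#>   parameter     x     r analytic simplified finite_difference rel_error
#> 1 k2         372.    25    -600.      -600.             -600.  4.55e-15
```

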