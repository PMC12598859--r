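# dissipmap

Particle-based nonequilibrium simulations and trajectory-ensemble statistics
for **spatially resolved dissipation and entropy production** in driven and
active two-dimensional fluids.

## What it does

When a fluid is driven out of equilibrium, the work done on it is dissipated
as heat — but not uniformly in space. `dissipmap` simulates three
color-field-driven WCA model systems, integrates the dissipation function

&nbsp;&nbsp;&nbsp;&nbsp;Ω<sub>t</sub> = β F<sub>e</sub> J<sub>x,t</sub> + β ∫ Σ<sub>i</sub> ξ<sub>i</sub> p<sub>x,i</sub> dt&nbsp;&nbsp;&nbsp;&nbsp;(second term: active fluid)

along every trajectory, partitions it into spatial bins, and tests the
**local fluctuation theorem**

&nbsp;&nbsp;&nbsp;&nbsp;ln [ p(Ω<sub>L,t</sub> = A) / p(Ω<sub>L,t</sub> = −A) ] = (1 + κ<sub>L,t</sub>) A,

where κ<sub>L,t</sub> = Cov(Ω\*, Ω<sub>L</sub>) / Var(Ω<sub>L</sub>) measures
how strongly the local region is correlated with its surroundings. For a
region spanning the whole system κ → 0 and the global theorem (slope 1) is
recovered; for small regions the slope is tilted away from 1.

The three scenarios (`make_scenario(kind)`):

- **`channel`** — fluid driven through a channel of varying width whose
  tethered wall atoms are held at constant temperature by a Gaussian
  isokinetic thermostat (F<sub>e</sub> = 0.3, periodic in x).
- **`obstacle`** — fully periodic fluid driven past a repulsive disk
  (R = 5) under a Gaussian ergostat, so dissipation *equals* entropy
  production bin by bin.
- **`active`** — weakly driven fluid (F<sub>e</sub> = 0.05) in which every
  particle carries an Ornstein–Uhlenbeck self-propulsion, under an
  all-particle isokinetic thermostat.

The MD kernel (Rcpp, Verlet neighbor list, closed-form isokinetic kicks) is
exactly constraint-conserving: the thermostatted kinetic energy is held to
10⁻¹⁰ relative per step, the ergostat energy to 10⁻⁸ over five time units,
and the channel dynamics retraces under momentum reversal to machine
precision.

## Worked example

Drive the channel fluid, measure the local dissipation in a 2σ-wide slab at
the channel's narrowest point, and test the local fluctuation theorem
(~30 s on one CPU):

```r
library(dissipmap)

spec <- make_scenario("channel")
spec
#> <scenario_spec> channel
#>   Fe = 0.3  beta = 1  dt = 0.002
#>   box = 50.6 x 14  density = 0.5  n_fluid = 116
#>   channel width 8 modulation 2 spring k = 50

ens <- run_ensemble(spec, n_traj = 400, t = 5, base_seed = 1)
ens
#> <dissipation_ensemble> channel : 400 trajectories of t = 5
#>   <Omega_t> = 14.8 +/- 0.305

# local dissipation in slabs of width 2 (center slab = narrowest point)
part <- region_partition(50.6, 2)
om <- omega_ensemble(ens, part)
b <- findInterval(50.6 / 2, part$edges)
local <- om$omega_bins[, b]
round(c(mean = mean(local), sd = sd(local), neg_fraction = mean(local < 0)), 3)
#>         mean           sd neg_fraction
#>        0.396        0.627        0.268

curve <- asymmetry_function(local)
curve
#> <asymmetry_curve> 4 points, bin width 0.171
#>   slope = 1.718 +/- 0.345

k <- kappa(local, om$omega_star_bins[, b])
unlist(local_ft_check(curve, k$kappa, k$stderr))
#>             slope         slope_err         predicted     predicted_err
#>         1.7182460         0.3453497         1.9375713         0.4449326
#> discrepancy_sigma        consistent
#>         0.3894041         1.0000000
```

The slab-level slope (1.72 ± 0.35) is far from the global value 1 — more
than a quarter of the trajectories *consume* entropy locally — and agrees
with the prediction 1 + κ from the measured local–surroundings correlation.
The global distribution, in contrast, has ⟨Ω⟩ ≈ 14.8 and essentially no
negative mass.

## Command line

```sh
# generate a chunked, resumable ensemble and analyze it
Rscript -e 'dissipmap::cli()' run --scenario active --ntraj 1000 --out runs/a1
Rscript -e 'dissipmap::cli()' analyze --out runs/a1 --L 2.2 --L 11
# 2D dissipation maps and MD-free Gaussian fixtures
Rscript -e 'dissipmap::cli()' map --scenario obstacle --ntraj 200 --out maps
Rscript -e 'dissipmap::cli()' fixture --kappa 0.5 --n 100000 --out fix
```

The installed `inst/cli/dissipmap` script wraps the same entry point.

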