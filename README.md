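# cdipatterns

Simulator and analysis toolkit for the competition between two bacterial
species, one of which wields **contact-dependent inhibition (CDI)** — a
widespread mechanism in which a toxin-equipped (CDI+) cell injects
growth-inhibiting effectors into its immediate neighbours on direct
cell-cell contact. Carrying the CDI machinery costs the CDI+ species growth
rate, so the competition is a tradeoff: local poisoning versus faster
growth. The package answers, quantitatively, when that tradeoff ends in
extinction of one species, when it ends in bistability, and when — in
space — it produces stable localized stripe patterns in which both species
coexist.

## The model

The two concentrations, $u$ (CDI-, growth rate $\alpha$) and $v$ (CDI+,
growth rate $\beta < \alpha$), evolve on a periodic grid:

$$\dot u_i = u_i\bigl(\alpha - u_i - v_i - c_1(v_{i+1} + v_i +
v_{i-1})\bigr) + \tfrac{D}{\delta^2}(u_{i+1} - 2u_i + u_{i-1}),$$

$$\dot v_i = v_i(\beta - u_i - v_i) + \tfrac{D}{\delta^2}(v_{i+1} - 2v_i +
v_{i-1}),$$

with $c_1 = c/3$ the per-site inhibition (toxin reaches on-site plus two
neighbours in 1D; in 2D, $c_2 = c/5$ over the von-Neumann neighbourhood
with a 5-point Laplacian). Uniform states obey the well-mixed system
$\dot u = u(\alpha - u - (1+c)v)$, $\dot v = v(\beta - u - v)$, whose
linear stability partitions the $(\alpha/\beta, c)$ plane into
CDI--always-wins ($\alpha/\beta > 1+c$), CDI+-always-wins
($\alpha/\beta < 1$), and a bistable regime in between — well-mixed
coexistence is impossible. In space, however, both species can persist as
alternating stripes; an exact zero-diffusion steady state with single-site
transition layers ($u^\ast = \alpha - c_1\beta$) yields the analytic
necessary condition for patterned coexistence at slow diffusion:

$$1 + c_1 \;<\; \alpha/\beta \;<\; 1 + 2c_1.$$

The package provides the well-mixed/1D/2D right-hand sides, an adaptive
Runge-Kutta 4(5) integrator with negativity clamping and steady-state
detection, closed-form steady states with stability analysis and a Lyapunov
surface, the trial-state construction and the analytic interval, all
initial-condition families (representative two-domain splits, seeded random
fields, nested squares), run-length-based pattern classification, and
drivers for phase-diagram scans and ensemble statistics. See the vignette
(`vignettes/cdi-competition-model.Rmd`) for the full methods account.

## Worked example

Classify the steady states reached from random initial conditions in the
patterned regime (growth advantage 3.5, inhibition $c_1 = 2$, diffusion
$10^{-3}$):

```r
library(cdipatterns)
p <- cdi_params(alpha = 3.5, beta = 1, c1 = 2.0, D = 1e-3)

run <- integrate_cdi(random_ic(p, "1d", seed = 4), p)
classify_pattern(run$state, p)
#> CDI pattern: single_stripe (u occupancy 0.812)
#>   u stripes: 26 | v stripes: 6

ens <- run_random_ensemble(p, 500, seed = 42)
ensemble_stats(ens$records, p$delta)
#>        category   n abundance width_mean width_sd v_width_mean
#> 1  extinction_v  38     0.076         NA       NA           NA
#> 2 single_stripe 145     0.290       8.62    0.769         1.38
#> 3 double_stripe 216     0.432       3.74    1.833         1.26
#> 4  multi_stripe 101     0.202       2.09    1.214         1.12

coexistence_condition(2)
#>   c1 lower upper
#> 1  2     3     5
```

Reading the output: a single random start converged to a single-stripe
pattern in which the CDI- species dominates 81% of the ring (26 of 32
sites); its CDI+ competitor survives as one 6-site stripe. Over 500 random
starts at these parameters the double-stripe pattern is the most likely
outcome (43%), extinction is rare (7.6%, always of the CDI+ species here),
and the pooled mean CDI- single-stripe width is 8.62 space units
(`width_mean`; widths are sites × δ with δ = 10/32). The growth advantage
3.5 lies inside the analytic coexistence interval (3, 5) for $c_1 = 2$,
consistent with patterns being reachable at all.

A command-line driver for the larger experiments (phase-diagram scans,
abundance tables, the diffusion demo, 2D scans) is in `exec/cdipatterns`;
run it with `Rscript exec/cdipatterns <subcommand> key=value ...` — see the
file header for the subcommands.

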