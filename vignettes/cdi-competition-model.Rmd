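---
title: "Modelling bacterial competition with contact-dependent inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bacterial competition with contact-dependent inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdipatterns)
set.seed(1)
```

## The model

Contact-dependent inhibition (CDI) is a bacterial competition mechanism in
which a toxin-equipped (CDI+) cell injects growth-inhibiting effectors into
neighbouring cells on direct contact. `cdipatterns` simulates a two-species
Lotka-Volterra competition between a CDI-deficient species $u$ (fast grower,
no toxin) and a CDI-equipped species $v$ (slower grower because of the
metabolic burden of the CDI machinery), with the inhibition acting only over
nearest neighbours on a periodic grid.

On a ring of $N$ sites the nondimensional dynamics are

$$\frac{du_i}{dt} = u_i\left(\alpha - u_i - v_i -
  c_1 (v_{i+1} + v_i + v_{i-1})\right) +
  \frac{D}{\delta^2}(u_{i+1} - 2u_i + u_{i-1}),$$
$$\frac{dv_i}{dt} = v_i\left(\beta - u_i - v_i\right) +
  \frac{D}{\delta^2}(v_{i+1} - 2v_i + v_{i-1}),$$

with periodic indices, $c_1 = c/3$ (the toxin reaches three locations in one
dimension: on-site and both neighbours), and equal diffusion $D$ for both
species. In two dimensions the inhibition sum runs over the von-Neumann
neighbourhood with weight $c_2 = c/5$ and diffusion uses the 5-point
Laplacian on a torus. For any spatially uniform state both reduce exactly to
the well-mixed system

$$\dot u = u(\alpha - u - v(1 + c)), \qquad \dot v = v(\beta - u - v),$$

because $3c_1 = 5c_2 = c$. The total inhibition $c$ is the canonical stored
parameter of `cdi_params()`; $c_1$ and $c_2$ are derived views, so the three
can never disagree.

The key parameters and their meaning:

| parameter | meaning | typical values |
|---|---|---|
| $\alpha$ | growth rate / carrying capacity of the CDI- species | 1--5 |
| $\beta$ | growth rate / carrying capacity of the CDI+ species | fixed at 1 in scans, so $\alpha$ equals the growth advantage $\alpha/\beta$ |
| $c$ ($c_1$, $c_2$) | inhibition strength of the CDI toxin | $c_1 \in [0, 4]$ |
| $D$ | diffusion constant (cell motility), equal for both species | $10^{-4}$--$10^{-1}$ |
| $N$, $\delta$ | grid points and spacing | 32 sites, $\delta = 10/N$ |

## Geometry and units

The canonical configuration discretizes a nondimensional domain of length 10
into $N = 32$ sites, so the default grid spacing is $\delta = 10/N =
0.3125$. Only $D/\delta^2$ enters the dynamics; all diffusion constants
quoted in this package (e.g. the pattern regime at $D = 10^{-3}$) are
defined with respect to this geometry, and stripe widths are reported in
the same space units (sites $\times\ \delta$). With these conventions the
characteristic single-stripe width of the CDI+ species in the patterned
regime is about 1.2--1.5 space units and the ensemble tables produced by
`abundance_sweep()` are directly comparable across grid resolutions. Users
who prefer widths in raw grid points can pass `delta = 1` to
`ensemble_stats()`.

## Well-mixed competition is mutually exclusive

`steady_states()` returns the four homogeneous equilibria: total extinction
$(0,0)$, the single-species states $(\alpha, 0)$ and $(0, \beta)$, and the
interior state $\bigl(\beta - (\alpha-\beta)/c,\ (\alpha-\beta)/c\bigr)$.
Linear stability (`classify_stability()`) partitions the
$(\alpha/\beta,\ c)$ plane into three regimes:

* $\alpha/\beta > 1 + c$ — the CDI- species always wins;
* $\alpha/\beta < 1$ — the CDI+ species always wins;
* $1 < \alpha/\beta < 1 + c$ — both extinction states are stable
  (bistability) and the initial condition picks the winner; the interior
  state is a saddle, so stable coexistence is impossible in the well-mixed
  limit.

```{r wellmixed}
classify_stability(cdi_params(alpha = 2, beta = 1, c = 2))
```

For the bistable regime the package provides an explicit Lyapunov surface

$$V(u, v) = -\alpha u + \tfrac{u^2}{2} +
  (1 + c)\left(uv - \beta v + \tfrac{v^2}{2}\right),$$

chosen because the flow obeys $\dot V = -u F^2 - (1+c) v G^2 \le 0$ exactly,
where $F$ and $G$ are the per-capita growth rates. Among the standard
competitive Lotka-Volterra constructions this is the one whose weights make
the cross-derivatives match, giving an exact (not merely local) descent
property on the nonnegative quadrant. Its restriction to the quadrant has
minima at the two extinction states and a saddle at the interior
equilibrium; these three properties, plus monotone descent along simulated
trajectories, are what the package validates and what `lyapunov_surface()`
is for. Absolute values of $V$ carry no meaning and no attempt is made to
match any particular published rendering of such a surface.

## Numerical integration

`integrate_cdi()` advances the system with an embedded Cash-Karp
Runge-Kutta 4(5) pair and proportional step-size control. The specific
tableau is an implementation choice; correctness is pinned by a fixed-step
Euler oracle in the test suite rather than by the choice of coefficients.
The controls (all in `integration_settings()`) are:

* `max_error_per_step = 1e-6` — absolute per-step error cap, max-norm over
  all sites and both species;
* `max_step = 0.1` — hard ceiling on the step size;
* negativity handling — a proposed step that would drive any concentration
  below `-max_error_per_step` is rejected and retried smaller; residual
  negatives within the error cap of zero are set to exactly zero before the
  next step, so accepted states are always nonnegative and an extinct
  species can never resurrect;
* convergence — the run is declared steady when the per-step maximal state
  change, averaged over the last `convergence_window = 1000` *accepted
  steps*, falls below `convergence_tol_factor = 1e-8` times the largest
  carrying capacity $\max(\alpha, \beta)$. Averaging over accepted solver
  steps (rather than fixed time units) is the cheaper reading and the one
  implemented; the window is configurable if the other reading is wanted;
* `max_time = 1e6` — a safety cap; runs that reach it are returned with
  `converged = FALSE` and the ensemble drivers report them separately so
  they never bias a statistic.

## The zero-diffusion coexistence skeleton

At $D = 0$ every steady state factorizes site by site, and the simplest
coexistence state is two single-species domains joined by two one-site
transition layers. The layer carries $u^\ast = \alpha - c_1\beta$ and no
$v$: the inhibition $c_1\beta$ received from the single adjacent CDI+ site
exactly cancels the growth surplus, which is what makes the state an exact
equilibrium (`trial_state()`, verified to machine precision). Positivity of
$u^\ast$ needs $\alpha > c_1\beta$. Linear stability of the full $2N \times
2N$ Jacobian (`stability_D0()`) destabilizes through the $v$-equation at a
layer exactly when $\alpha/\beta < 1 + c_1$, and requiring the slow-diffusion
perturbation of the state to stay positive and bounded gives the analytic
necessary condition for patterned coexistence

$$1 + c_1 < \frac{\alpha}{\beta} < 1 + 2c_1,$$

exposed by `coexistence_condition()`. Only this zeroth-order construction
and the final interval are implemented; the order-$D$ correction fields are
deliberately out of scope and replaced by direct numerical stability at
small $D$ (`coexistence_interval_1d()`), which at $c_1 = 2$, $D = 10^{-4}$
yields a numerical coexistence range of growth advantages contained in the
analytic interval $(3, 5)$.

## Initial-condition families

Three generators cover the families used by the experiment drivers:

* `representative_ics_1d()` — the $N-1$ two-domain states: CDI+ at capacity
  on sites $1..j$, CDI- on the rest. These map the coexistence phase
  boundary cheaply because any patterned attractor reachable from a
  two-domain state marks the parameter point as coexistence-capable.
* `random_ic()` — independent per-site uniform draws $u_i \sim U(0,
  \alpha)$, $v_i \sim U(0, \beta)$. The law is a deliberate design choice:
  it is unbiased over the physically meaningful range bounded by the
  carrying capacities. It is also configurable (`law =`) precisely because
  ensemble statistics — especially 2D occupancies, where the CDI+ species
  must win contiguous patches to survive — are sensitive to it; see
  "Limitations".
* `nested_square_ic()` — a centred square of one species in a sea of the
  other, both at capacity, for the 2D scans.

Seeding is strict: every replicate derives a child seed from a master seed
via `spawn_seeds()`, results record their seeds, and identical master seeds
reproduce whole result tables bitwise.

## Pattern classification and statistics

A converged state is classified by `classify_pattern()`:

* a species is *extinct* when its maximum concentration is below
  $10^{-4}\max(\alpha,\beta)$ — far above the $10^{-8}$-scale convergence
  tolerance and far below any patterned amplitude, so the verdict is
  insensitive to the exact factor;
* otherwise the per-site dominant species ($u_i > v_i$) is run-length
  encoded under periodic wraparound, and the number of CDI- domains defines
  the category: single, double, or multi stripe (counting CDI+ domains
  gives the same number on a ring, by alternation);
* stripe widths of both species are recorded; width statistics are *pooled
  per stripe* (each stripe is one observation), which is why multi-stripe
  categories show larger spreads than per-run averaging would give — the
  pooled convention is the one whose spreads grow with category mixing,
  and the per-run alternative can be recovered from the stored records.

In the patterned regime (growth advantage 3.5, $c_1 \approx 1.5$--$2.2$,
$D = 10^{-3}$) the CDI- species occupies most of the space and its domains
are much wider than the CDI+ stripes. The width disparity is a genuine
kernel effect: re-running with the inhibition collapsed on-site
(`onsite_only = TRUE`, same total strength $c$) shrinks the mean width gap
several-fold. It does not vanish entirely under the default ensemble
because the uniform initial-condition law itself favours the
faster-growing species; the two contributions are separated in the test
suite.

## Problem sizes

The experiment drivers default to desk-scale ensembles chosen to make the
statistics reproducible in minutes on one core: 1000--2000 random initial
conditions for 1D abundance and width tables (binomial standard errors of
roughly one percentage point), 20 runs for 2D occupancy means, and the
31-member representative family per parameter point for phase-diagram
scans. All replicate counts are arguments, so ten-fold larger ensembles are
one keystroke away.

## Limitations

* The model is deterministic; demographic noise, which matters near phase
  boundaries where several patterns compete, is out of scope, as are
  growth-phase-dependent CDI expression and unequal diffusion constants.
* Domain walls are pinned at small $D$ on the discrete grid, so converged
  stripe widths are frozen records of the coarsening transient — ensemble
  width statistics therefore depend on the initial-condition law, not only
  on the dynamics.
* The 2D occupancy averages are particularly sensitive to that law: under
  the default iid uniform draws the CDI+ species rarely wins the contiguous
  patches it needs, so its surviving share of space is smaller than under
  spatially correlated or amplitude-matched alternatives. Conclusions about
  2D occupancy should state the law used; the default is reported verbatim
  by the acceptance script.
* Whether the 2D grid is periodic is a modelling choice (periodic here, by
  analogy with 1D); fronts this model produces are steep, so boundary
  handling mainly matters for patterns comparable in size to the domain.
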