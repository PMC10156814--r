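---
title: "Surrogate-assisted inverse design of axial blood-pump blades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-assisted inverse design of axial blood-pump blades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bladeforge)
```

## The design problem

Miniature axial-flow left ventricular assist devices (LVADs) for infants
must deliver clinically useful pressure heads (50--70 mmHg) at flows of
0.5--2 L/min through an annulus only a few millimetres across. At the
2 L/min / 70 mmHg design point and 15,000 rpm the dimensionless specific
speed is

$$N_s = \frac{\omega\sqrt{Q}}{(gH)^{3/4}} \approx 1.76,$$

which places the machine near the axial end of the Cordier spectrum while
anatomical constraints fix the layout: a 2-blade impeller followed by a
3-blade diffuser between a 1 mm hub and a 3.85 mm shroud. Blade shape is
then the main lever on hydraulic efficiency. `bladeforge` implements the
full inverse-design loop for that problem: parameterise the blades, predict
performance curves, scale them to the clinical operating point, train cheap
surrogates of design-point efficiency, and search the design space with a
constrained genetic algorithm under progressively widened bounds.

## Blade parameterisation

Five parameters govern the mid-span blade geometry: the impeller inlet and
outlet angles $\beta_1 < \beta_2$, the diffuser inlet angle $\alpha_2$ (all
in degrees from the tangential direction; the diffuser outlet is fixed at
90°, i.e. swirl-free outflow) and the two chord lengths. Camber lines are
circular arcs: given a chord $C$ and turning angle
$\theta = \beta_2 - \beta_1$, the arc radius is $R = C / (2\sin(\theta/2))$.
Arcs are constructed in the unwrapped two-dimensional blade-to-blade plane
at the mid-span radius $(r_{hub} + r_{shroud})/2 = 2.425$ mm, with the
inlet at the origin and the chord along the stagger direction
$(\beta_1 + \beta_2)/2$; sweeping the section from hub to shroud is out of
scope. A two-level full factorial over the five parameters gives the 32
base designs (8 unique impellers crossed with 4 unique diffusers), ordered
lexicographically so design ids are stable.

```{r}
head(factorial_designs(), 4)
constraint_box(0)
```

The optimisation bounds start at the factorial extremes (iteration 0) and
widen by 5° per side per iteration for the angles and 1 mm per side for the
chords, with $\beta_2$ capped at 90°. Five nested boxes (iterations 0--4)
are provided; the widest two deliberately push the surrogates into
extrapolation.

## The analytic virtual pump

The training data come from an analytic mean-line model rather than CFD, so
the whole pipeline runs at desk scale. With blade speed
$U = \omega r_{mid}$, axial velocity $c_x = Q/A$ and slip factor
$\sigma_s$, the slipped exit swirl is
$c_\theta = \sigma_s (U - c_x \cot\beta_2)$ and

$$\Delta P = \rho U c_\theta
  - k_{inc}\tfrac{\rho}{2}(U - c_x\cot\beta_1)^2
  - k_{dif}\tfrac{\rho}{2}(c_\theta - c_x\cot\alpha_2)^2
  - k_{fric}\tfrac{C_{imp}+C_{diff}}{C_{ref}}\tfrac{\rho}{2}(c_x^2 + U^2),$$

with shaft power $P = \rho Q U c_\theta + k_{par}\rho\omega^3 r_{mid}^5$
and hydraulic efficiency $\eta = Q\,\Delta P / P$. Every head term is
homogeneous of degree two and the power of degree three in $(\omega, Q)$,
so the model satisfies the turbomachinery affinity laws *exactly*:
$\psi$ and $\eta$ are functions of the flow coefficient $\phi$ alone. That
exactness is what lets the scaling machinery be verified to $10^{-9}$
rather than to a CFD-sized residual. Efficiency is reported raw and may be
negative or non-monotone off-design; downstream interpolation tolerates
this.

Default coefficients ($\sigma_s = 0.85$, $k_{inc} = k_{dif} = 0.6$,
$k_{fric} = 0.04$, $k_{par} = 1$, $C_{ref} = 23$ mm) give pressure heads of
roughly 75--140 mmHg and design-point efficiencies of 0.3--0.5 across the
factorial box at 20,000 rpm — the right order of magnitude for a pump of
this size. One qualitative departure from a textbook HQ curve is worth
stating plainly: at these blade angles the model's zero-incidence flow
($c_x \cot\beta_1 = U$, about 6--8 L/min) lies *above* the clinical window,
so over 0.5--4 L/min the incidence losses shrink faster with flow than the
Euler head falls and the modelled head *rises* with flow. The scaling step
is unaffected — the affinity parabola $\Delta P_1 (Q/Q_1)^2$ grows from
zero, so it crosses the curve exactly once in range — and all curve-shape
properties that genuinely need a falling characteristic are exercised on
hand-built monotone affinity-exact curves in the test-suite instead.
Optional Gaussian noise (applied to the pressure head only, under a
mandatory seed) mimics simulation scatter for robustness studies.

The model has no turbulence, tip-leakage, roughness or Reynolds-dependence;
passing tests demonstrate that the *workflow* is correct, not that the
analytic pump matches any particular device.

## Similitude scaling

Each design is simulated once at 20,000 rpm over 0.5--4 L/min in steps of
0.5 (eight flows). A quartic
$\Delta P = c_1Q^4 + c_2Q^3 + c_3Q^2 + c_4Q + c_5$ is fitted to the HQ
samples by ordinary least squares; equating it with the affinity parabola
through the target $(Q_1, \Delta P_1)$ yields

$$c_1Q_2^4 + c_2Q_2^3 + \left(c_3 - \frac{\Delta P_1}{Q_1^2}\right)Q_2^2
  + c_4Q_2 + c_5 = 0,$$

whose real positive root $Q_2$ is the match point; the required speed is
$\omega_1 = \omega_2 Q_1/Q_2$ and the whole curve (head and efficiency) is
rescaled to it. Roots are found through the polynomial companion matrix
(`polyroot`); roots with $|\mathrm{Im}| < 10^{-9}\max(1, |\mathrm{Re}|)$
count as real, roots inside the fitted flow range are preferred, ties go to
the root nearest $Q_1$ with a warning, and an out-of-range-only root set is
used but flagged as extrapolated. Efficiency is *always* interpolated
linearly in flow and never polynomial-fitted; queries outside the sampled
range are errors rather than silent extrapolations. All interfaces use
clinical units (L/min, mmHg, rpm) with SI internally
(1 mmHg = 133.322 Pa).

```{r}
crv <- simulate_curve(blade_design(32.5, 82.5, 32.5, 11.5, 11.5), 20000)
sc <- scale_curve_to_op(crv, operating_point(2, 70))
glance(sc)
```

## Surrogates of design-point efficiency

Scaling every curve through the target makes rotational speed intrinsic to
the geometry, so a surrogate needs only the five geometric inputs and one
output: the efficiency interpolated at the target flow on the scaled curve.
Features and target are affinely mapped to $[-1, 1]$ over the training
data (a zero-span column maps to 0); metrics are always reported back on
the natural efficiency scale.

Three models are implemented:

* **MLR** — ordinary least squares with intercept, trained on all data,
  resubstitution RMSE reported. The benchmark.
* **GPR** — Gaussian-process regression with a constant (profiled) mean,
  an isotropic stationary kernel (Matern 5/2 by default; squared
  exponential, exponential and rational quadratic available for the kernel
  comparison) and a fitted noise term. Hyperparameters maximise the log
  marginal likelihood (L-BFGS-B on log-parameters, three deterministic
  starts, bounds $\ell \in [10^{-2}, 10^2]$,
  $\sigma_n \in [10^{-6}, 1]$); the Cholesky jitter starts at $10^{-10}$
  and escalates tenfold to at most $10^{-6}$ before erroring. Validation is
  5-fold cross-validation — hyperparameters refitted per fold, held-out
  RMSE averaged — followed by a final refit on all data.
* **BRANN** — a 5-input, five-tanh-neuron, linear-output network trained by
  Levenberg--Marquardt on $\beta E_D + \alpha E_W$ with the
  regularisation pair re-estimated by the Gauss--Newton evidence
  approximation ($\gamma = p - 2\alpha\,\mathrm{tr}(H^{-1})$,
  $\alpha = \gamma/2E_W$, $\beta = (N-\gamma)/2E_D$). Two numerical
  choices stabilise the scheme on a 27-row training set with 36 weights:
  a 25-iteration pure-LM warm-up before the evidence updates switch on
  (turning regularisation on immediately drives the weights to zero), and
  the cap $\gamma \le N - 1$ in the $\beta$ update, which keeps $\beta$
  positive when the network has more weights than rows. In the
  exact-interpolation limit $E_D \to 0$ makes $\beta$ diverge and $\gamma$
  approach $p$, so the "spare capacity" reading of $\gamma$ is only
  meaningful with a noise floor in the targets. Validation is a simple
  seeded holdout of 5 of the 32 designs (15%) — the regularisation itself
  guards against over-fitting. Fits are bit-reproducible given the seed.

```{r}
bl <- run_baseline(pipeline_config(seed = 1))
glance(fit_gpr(bl$dataset, seed = 1))
```

## Genetic algorithm

The GA minimises negated predicted efficiency over the five parameters:
population 50, rank-scaled stochastic-universal selection, 3 elites,
intermediate crossover on a 0.8 fraction of the non-elite offspring,
Gaussian mutation on the remainder with a per-coordinate standard deviation
of one box width shrunk linearly over the run. Offspring are clamped to the
box and the orientation constraint $\beta_2 > \beta_1$ is repaired by
lifting $\beta_2$ to $\min(90, \beta_1 + 10^{-3})$ *before* evaluation, so
the objective only ever sees feasible designs. Convergence is declared when
the generation-best objective changes by no more than $10^{-6}$ (relative)
over a 50-generation window. Elitism makes the best-fitness history
non-increasing, and a fixed seed makes the whole run deterministic. The
repeatability study reruns the GA under distinct seeds and reports the
maximum per-parameter relative spread $100(\max-\min)/\max$, flagging a
flat (non-identifiable) objective separately instead of letting it pass.

## Pipeline, seeds and problem sizes

`run_pipeline()` chains the stages: factorial designs → curves at
20,000 rpm → scaling through 2 L/min / 70 mmHg → dataset → one GA per
surrogate and constraint iteration → verification of each returned optimum
by a fresh analytic-pump simulation scaled to the target (the verified
value never comes from the surrogate; the relative prediction error uses
the simulated value as denominator) → retargeting of the best design to
1 L/min / 60 mmHg and 0.5 L/min / 50 mmHg by rescaling its existing curve,
with no further simulation. A master seed derives per-stage seeds
deterministically, so stages are independently reproducible; reports
record the configuration hash, seeds and package version.

The packaged studies use the sizes natural to the method: 32 training
designs, 8 flow samples per curve, 5-fold cross-validation, 5-design
holdout, populations of 50 with at most 500 generations, 5-seed
repeatability studies, $5^5$ brute-force grids as optimisation oracles and
batches of 20--100 randomised scaling cases; each complete run takes
seconds on a laptop.

## Known limitations

The analytic pump is a stand-in truth: smooth, affinity-exact and sensitive
to all five parameters, but blind to turbulence transition, tip-gap
leakage, surface roughness, unsteady rotor--stator interaction and 3-D
blade effects. Conclusions about *which* blade angles are optimal therefore
apply to the analytic model only; the package's claims are about the
correctness and reproducibility of the design loop around whatever
simulator supplies the curves. The efficiency definition is hydraulic
($Q\Delta P$ over shaft power) throughout, and efficiency is treated as
exactly invariant under affinity scaling — no Reynolds correction is
applied when the speed changes.
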