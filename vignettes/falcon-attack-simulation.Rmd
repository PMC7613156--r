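---
title: "Simulating falcon attacks on maneuvering prey: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating falcon attacks on maneuvering prey: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoopsim)
```

`stoopsim` is a physics-based aerial predator-prey simulator built to study
how flight morphology shapes catch success when peregrine falcons attack
erratically maneuvering prey. It couples a quasi-steady, wingbeat-averaged
blade-element flight-performance model to pursuit by pure proportional
navigation (PPN) with delayed, noisy vision, and to open-loop erratic
("jinking") evasion by the prey, and then asks Monte Carlo questions:
which sex of falcon catches which prey species how often, from which
attack geometry, and which dimensions of flight performance drive the
answer.

This vignette documents the model, its assumptions, the constants that
matter and why they have the values they do, and the known limitations.

## Morphology and allometric closures

Each species is described by eight quantities (wingbeat frequency $f$,
wingspan $b$, body mass $m_b$, wing mass $m_w$ for the pair, wing area
$S_w$, aspect ratio $AR$, and body drag coefficient $C_{db}$), loaded from
a packaged table in its original units (cm, g, dm²) and converted to SI.
Validation enforces positivity, $m_w < m_b$ and $|b^2/S_w - AR|/AR < 5\%$.

Two body quantities are closed allometrically:

* frontal area $S_b = k_{Sb}\, m_b^{0.68}$, with $k_{Sb}$ anchored in
  closed form so that the male falcon's terminal dive speed
  $\sqrt{2 m_b g / (\rho S_b C_{db})}$ is 104 m/s (a Pennycuick-style
  alternative, $8.13\times10^{-3} m^{0.666}$, is available and gives
  ~99.7 m/s);
* body width $w_b = k_{wb}\, m_b^{0.35}$ with $k_{wb} = 0.07$; only
  ratios between species matter downstream.

Roll inertia uses a uniform-rod wing pair plus a cylindrical body term,
$I = (m_w/12) b_\mathrm{eff}^2 + (m_b/8) w_b^2$, with the effective span
shrinking linearly under wing retraction $\zeta$:
$b_\mathrm{eff} = b (1 - 0.6\,\zeta)$ (and likewise the lift-bearing
area). The wing mass is interpreted as the pair, as the table gives one
value per species.

## The flight-performance model

All forces are wingbeat-averaged and quasi-steady. Three limits define
the envelope at an airspeed $v$:

* **Stall.** $L_\mathrm{stall} = C_{L,\max}\,\tfrac12 \rho
  (v^2 + u_\mathrm{tip}^2/6)\, S_\mathrm{eff}$ with
  $C_{L,\max} = 1.6$; flapping augments the elementwise dynamic
  pressure through the peak flap tip speed
  $u_\mathrm{tip} = 2\pi f \Phi\, b_\mathrm{eff}/2$ (amplitude
  $\Phi = 1.05$ rad; the factor 1/6 is the span-time average of a
  sinusoidal stroke on a uniform-chord wing).
* **Muscle (normal force).** The wingbeat-averaged force the flight
  muscles can hold grows linearly with airspeed and scales with the
  flight-muscle (wing) mass: $L_\mathrm{musc} = k_\mathrm{musc}\,
  m_w^{0.70}\, v$. The linear speed dependence is what the printed
  falcon chase states trace out (load factor roughly proportional to
  speed between 38 and 102 m/s); $k_\mathrm{musc}$ is tied so the
  male's envelope load factor at 102 m/s is 11.
* **Roll asymmetry.** The lift asymmetry available for rolling has its
  own, steeper wing-mass allometry,
  $\min(L_{\max},\; k_\mathrm{roll}\, m_w^{1.08}\, v)$, acting at a
  quarter of the effective span over the roll inertia, scaled by
  $\tau = 0.9$. $k_\mathrm{roll}$ is anchored so the male's available
  roll acceleration at 102 m/s with half-retracted wings is
  5078 rad/s². The separate exponent is required: a single wing-mass
  exponent cannot simultaneously give the small passerines their roll
  advantage at their own top speeds and the falcon its roll advantage
  at terminal dive speeds.

Drag at lift $L$ sums body parasite drag $q S_b C_{db}$, wing profile
drag with a parabolic polar $q S (1-\zeta) C_{d0} + C_{d2} L^2/(q
S_\mathrm{eff})$ (with $C_{d0} = 0.02$; the $C_{d2}$ term is what makes
maneuvering slow a bird down), and span-limited induced drag
$k\,L^2/(q \pi b_\mathrm{eff}^2)$ with $k = 1.1$. The zero-lift wing
drag vanishes at full retraction — folded wings shed their exposed
area — which is exactly the assumption under which the terminal-speed
formula above holds.

Gross flapping thrust is taken as speed-independent with an allometric
scale, $T = k_G\, (f b)^{a_u} (S_w m_w)^{a_G} f^{a_{fG}}$. The form
comes from the blade-element picture: with a parabolic profile polar,
tilting the elementwise force forward on the downstroke and feathering
the upstroke yields a propulsive force whose scale follows the squared
flap tip speed and an effective propulsive area, while the drag side of
the polar is charged in the drag model. A strong hint that the flap
tip speed is the right backbone: the two falcons' printed top level
speeds are in the exact ratio of their flap tip speeds (1.039). Net
forward force while flapping is $T - D(v, L)$, and the top sustained
level speed is its root at $L = W$; the maximum-range speed minimises
drag at $L = W$ (equivalently, mechanical cost of transport).

### Calibration protocol

The starred constants were fitted once, jointly, on the two falcon rows
and then frozen for every species:

1. $k_{Sb}$ in closed form from the male terminal speed (104 m/s);
2. $k_\mathrm{musc}$ tied to the male envelope load factor 11 at
   102 m/s, and $k_\mathrm{roll}$ to 5078 rad/s² as above;
3. $(k_G, C_{d2}, a_G, a_u, a_{fG})$ by least squares against the
   printed anchors — top level speeds 28.1/29.2 m/s, maximum carry
   loads 0.50/0.76 kg and their ratio — plus soft anchors from the
   printed per-species chase states (speed and load factor at the
   moment of intercept) and hinge penalties enforcing the qualitative
   orderings between falcons and prey (who out-turns whom at top level
   speeds, the reversal at terminal speeds, and which species can
   out-sprint the falcons).

`calibration_anchors()` recomputes the anchor table; the frozen defaults
reproduce the top speeds within ~4%, the terminal speeds within 0.5%,
and the carry loads within ~5% (ratio 1.37 vs ~1.5).

The carried-prey test adds the prey's weight to the required lift and
the parasite drag of its body (frontal area from the $m^{0.68}$
allometry, drag coefficient 0.35) to the budget, and bisects on the
carried mass for the existence of a level-flight speed.

## Flight dynamics

State is position, velocity, a bank (roll) angle about the velocity
axis, roll rate, wing retraction and flap/glide mode. Orientation is
parameterised as velocity direction plus roll (coordinated flight, no
sideslip): the model's control degrees of freedom are lift magnitude,
lift direction (via roll) and forward force, which is all the guidance
laws command. Translation integrates with fixed-step RK4 at
$\Delta t = 5$ ms; within a step the roll, mode and lift magnitude are
frozen while drag and thrust follow the instantaneous speed, and
halving the step changes a 10 s trajectory endpoint by well under 0.1%
of path length. Intercepts are detected continuously against the step
segment (at stoop speeds a bird covers ~0.5 m per step, more than the
whole 0.2 m capture radius).

Turning works in three stages each step: the commanded normal
acceleration is converted to a required lift vector (gravity
compensation included); the bird rolls toward that direction under
minimum-time bang-bang control at its available roll acceleration; and
while the roll is still in transit it pulls only the component of the
demanded lift along the currently achievable direction (it unloads
while rolling — without this, frequent jink reversals pump energy into
a spurious climb-and-slow phugoid). Lift saturates at the envelope with
direction preserved, and the bird then flaps or glides (with the
drag-minimising retraction) according to which maximises forward force,
ties to glide: model birds always race, which is the behaviour the
escape-and-pursuit theory prescribes for both parties.

Capped agents are purely kinematic performance probes: constant speed,
commanded normal acceleration clipped at $n_{\max} g$, force direction
re-oriented under the same bang-bang rule at their roll-acceleration
cap, gravity ignored.

## Guidance

**Pursuit.** The falcon senses the line of sight as it was `delay`
seconds ago, rotated by a Gaussian angular error (SD `sigma_v`) about a
random perpendicular axis. Sightings are taken at a fixed guidance
cadence (`guidance_dt`), the line-of-sight rate is a finite difference
of consecutive sightings passed through a fading-memory filter (gain
0.5), and the command is pure proportional navigation in vector form,
$a = N\, (\omega \times v)$, held between updates.

The timing defaults — 30 ms delay, $\sigma_v = 2\times10^{-4}$ rad,
50 Hz updates — were chosen by sensitivity analysis against two
printed behaviours: straight-flying prey must almost always be caught,
and the high-speed stoop must out-perform the low-level attack. The
published description constrains these only qualitatively
("realistically short", "small degree of visual error"; raptor visual
acuity is of order $10^{-4}$ rad). With a substantially larger noise or
delay the finite-difference rate estimate poisons the endgame: the
residual first-pass miss exceeds the 0.2 m capture radius at stoop
speeds and the altitude ordering inverts.

**Evasion.** The prey is open-loop: it banks a fraction `c3` of its
maximum available lift to alternating sides, holding each side for
`c2 + Exp(c1 - c2)` seconds, with the jink plane tilted out of the
horizontal by `c4`; the vertical lift component is held at the weight
(a coordinated, quasi-level jink), so the lateral acceleration is
$\sqrt{(c_3 a_{\max})^2 - g^2}$. This functional form is a
reconstruction: the published account names four free parameters and
their qualitative roles (random timing, strong alternating lateral
accelerations, a directional bias) without equations. Two properties
drove the final form. First, with gravity support the prey settles at
the speed where thrust balances drag at its banked lift — which is what
generates the printed per-species spread of sustained load factors from
morphology alone. Second, a form that permits sustained descent is
degenerate under optimisation: in an unbounded airspace the fitness
below rewards an ever-steeper dive (speed is free downhill and the
muscle cap grows with speed), which no real chase sustains.

## Evolution of the guidance parameters

A minimal genetic algorithm evolves positive parameters on the log
scale: the fittest half of each population contributes one exact and
one mutated copy ($g \to g e^{\mu}$, $\mu \sim N(0, \sigma^2)$,
$\sigma = 0.3$), which preserves the best individual unmutated. Two
stages follow the study design: first the evasion parameters, with the
prey's mean sustained centripetal acceleration flying alone (15 s
horizon) as the fitness — independent of the predator — under two
structural constraints of the jinking family (switching intervals
bounded sub-second, net descent below 1 m/s); then the falcon's $N$,
with catch success against the evolved prey at its best (high-altitude)
strategy as the fitness. Stochastic fitnesses are re-evaluated every
generation so no individual locks in a lucky draw.

The shipped defaults (`default_guidance()`) are the medians of repeated
development-time runs from different initialisations, which converged
consistently: jink hold times of 0.6-1.1 s, full lift fraction, small
up-tilt; and $N^* \approx 5.5$-$7$ against the agile prey with the
mallard preferring the lowest value. The published optimum is
$N \approx 3$ with the same qualitative mallard exception; our higher
optimum is a known consequence of the filtered 50 Hz sensing chain,
which removes most of the noise-amplification penalty that pushes the
optimum down when the rate estimate is raw. `optimize_guidance()`
re-derives everything.

## Engagements and experiments

The prey starts at the origin, heading uniform in azimuth, at its
maximum-range speed, and evades alone for a 10 s head start; the falcon
then starts `dx` m away and `dz` m up, heading at the prey, at its own
maximum-range speed. The attack ends at the first of: intercept
(distance < 0.2 m), near-miss (having come within 5 m, the prey falls
inside the falcon's blind zone — a 90° spherical wedge behind its
heading), or a 60 s timeout (counted as a miss; no published timeout
exists, but single-attempt chases from these geometries resolve well
inside it). There is no re-engagement after a near-miss. Every
engagement draws its random stream from (master seed, engagement index)
via a counter-based generator, so batches shard and reproduce exactly.

Three experiment harnesses mirror the study: (1) both sexes against six
prey species from high (1500 m / 50 m), moderate (200 m / 100 m) and
low (50 m / 200 m) start geometries; (2) the male falcon against capped
prey with speed, load-factor and roll-acceleration caps sampled
uniformly on [0, 100] m/s × [0, 15] × [0, 8000] rad/s² (the printed
upper bound is taken as rad/s²; the chase table prints roll
acceleration in those units), for a horizontal (low-altitude) and a
stoop geometry; (3) a generic capped raptor against the full-physics
blue tit and mallard. Full scale is 1e5 engagements per condition and
1e6 sampled triples; the `scale` argument runs desk-scale versions.
The test suite uses 600 engagements per condition for the
sex × strategy × species grid and 1500 triples per geometry; the
reproduction script uses 2000 engagements per condition for the
catch-success ratios and pools ≥500 intercepts for the chase-state
means. These sizes put Monte Carlo CIs well inside the effect sizes
being checked.

Analysis helpers provide Wilson score intervals (stable at extreme
rates, unlike Wald), the additive logistic response surface
$\mathrm{logit}\, E(C) = s(L) + s(R) + s(S) + s(L, R, S)$ fitted by
penalized likelihood with GCV-selected smoothing (univariate thin-plate
smooths plus a low-rank tensor interaction; basis dimensions follow the
default heuristics rather than being capped), sustained-load-factor
summaries, chase-state tables at the moment of intercept, and the
escape-by-turning condition in its centripetal-acceleration form
($a > 1$).

## Known limitations

* The original model's supplementary formulation was not available;
  the blade-element closure, muscle-limit allometries and the erratic
  guidance family are calibrated reconstructions, documented above as
  this package's own design.
* The muscle cap's single wing-mass exponent over-credits the
  heaviest-winged species: the simulated mallard sustains a load factor
  near 2.3 where the published chase table prints 1.56, which also
  leaves the high/low catch-success ratios somewhat above their printed
  values (the low-altitude attack is harder here than in the original).
* The common swift's sustained maneuvering is under-predicted (its
  thrust allometry ranks it low), and the rock dove's slightly
  over-predicted, producing one inversion in the otherwise monotone
  success-versus-sustained-load-factor relation.
* The evolved navigation constant sits above the published ~3, as
  discussed under Guidance.
* No wind, gusts, ground, water refuges or flock targets; prey cannot
  see the predator; unsteady aerodynamics (leading-edge vortices) and
  metabolic energetics are out of scope.

## Reproducing the study numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates the
morphology-driven carry loads, the high/low catch-success ratios for
mallard and chaffinch, the mean male intercept speed in high stoops and
the mallard's intercept load factor, from scratch, writing them as
JSON. The acceptance test suite (`tests/testthat/test-acceptance.R`)
asserts the same headline structure at desk scale.
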