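---
title: "Modelling regulated toxin warfare: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling regulated toxin warfare: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxwar)
```

## The model

`toxwar` studies how bacteria should regulate the production of
anti-competitor toxins (bacteriocins, antibiotics).  The ecological core is
a pairwise competition between two strains, A and B, growing on a shared
nutrient pool under Monod kinetics and poisoning each other:

$$
\begin{aligned}
\frac{dC_A}{dt} &= (1-f_A)\,\mu_{max} M C_A - k\,T_B C_A, &
\frac{dT_A}{dt} &= f_A M C_A - l_T T_A,\\
\frac{dC_B}{dt} &= (1-f_B)\,\mu_{max} M C_B - k\,T_A C_B, &
\frac{dT_B}{dt} &= f_B M C_B - l_T T_B,\\
\frac{dN}{dt} &= -M\,(C_A + C_B), &
M &= \frac{N}{N + K_N},
\end{aligned}
$$

where $C$ is strain biomass (gC), $T$ toxin (gT), and $N$ nutrient (gN).
The investment fraction $f \in [0,1]$ is the strategic variable: a strain
diverts a fraction $f$ of its nutrient uptake into toxin and grows at only
$(1-f)$ of its maximal rate — a linear allocative trade-off.  Toxins kill
the *other* strain with efficiency $k$ and are lost at rate $l_T$; both
strains' toxins share identical kinetics so only the production *strategy*
differs.

Two threshold rules close the continuous model.  Any state variable below
$10^{-8}$ is set to zero (a numerical guard against negative
concentrations), and a strain whose biomass falls below $10^{-6}$ gC is
treated as stochastically extinct: its biomass is removed for the rest of
the competition while its already-released toxin keeps decaying.
Extinction is irreversible because growth is multiplicative in $C$.

Default parameters are the standard set used throughout: $K_N = 5$ gN,
$\mu_{max} = 10$ /hr, $k = 20$ /(gT·hr), $l_T = 0.1$ /hr, $N_0 = 1$ gN,
equal seeding $C_A(0) = C_B(0) = 0.1$ gC, and a 24-hour competition
window (the lifetime of a local resource patch before dispersal).

### Regulation

Four strategy classes are modelled, matching the major classes of
bacterial regulatory networks.  Constitutive producers fix $f$.  Regulated
producers switch between $f_{initial}$ and $f_{induced}$ when a cue
crosses a threshold, via a Heaviside step with $H(0) = 1$:

* **nutrient sensing** — cue is depletion $N_0 - N(t)$ (threshold $U_N$),
  a stress-response proxy for ecological competition;
* **toxin sensing** — cue is the opponent's toxin $T_B(t)$ (threshold
  $U_{TB}$), i.e. reciprocation triggered by cell damage;
* **quorum sensing** — cue is the strain's own biomass $C_A(t)$
  (threshold $U_{QS}$).

The induced value may be lower than the initial one, so the same
machinery expresses both activators and repressors (attack-then-disarm
tactics).

### From patches to evolution

Local competitions are embedded in a metapopulation: empty patches are
seeded, strains compete for 24 h, and dispersal weights each strategy by
the cells it produced.  For a rare mutant this reduces to the invasion
index

$$
I_{inv} = \frac{w(f_{inv} \mid f_{res})}{w(f_{res} \mid f_{res})},
$$

the mutant's final biomass against the resident over the resident's final
biomass against itself.  `invasion_index()` also classifies the outcome by
crossing the local result (who wins inside the mixed patch) with the
global one ($I_{inv}$ vs 1); all four combinations occur, and the two
aligned cases dominate.  `stable_invasion()` adds the back-invasion test:
a replacement is *stable* only if the displaced resident cannot re-invade
from rare.  Mutual invasibility is reported as a `mixed` outcome and, over
full sensing-vs-constitutive scans, affects a small minority
(about 1–2% here) of successful invasions.

## Numerical design

**Integrator.**  The production solver is an implicit (backward) Euler
scheme with step $dt = 0.01$ hr, solved per step by Newton iteration with
the analytic Jacobian (tolerance $10^{-10}$, at most 50 iterations, with
step-halving on the rare non-convergence).  Investments are evaluated from
the state at the *start* of each step and held constant through it, which
keeps the discontinuous Heaviside switch outside the implicit solve; the
clamp and extinction rules apply after each step.  Backward Euler
preserves the model's linear invariant exactly: with $k = l_T = 0$,
$C_A + C_B + \mu_{max}(T_A + T_B + N)$ is conserved along trajectories to
within the Newton tolerance, which the test suite checks for arbitrary
regulated strategies.

**Accuracy.**  Backward Euler is first-order accurate.  Against an
adaptive high-order reference (`deSolve::lsoda` on a compiled right-hand
side, with regulation held piecewise-constant per $dt$ interval and the
same clamp/extinction rules), final biomasses at $dt = 0.01$ deviate by
roughly 1–5% and the error scales linearly in the step.
`simulate_competition(..., substeps = n)` refines the integration between
rule applications without changing the rule grid; at `substeps = 200` the
panel deviation is below $10^{-3}$, which is how
`validate_against_reference()` certifies the integrator.  The evolutionary
quantities reported by the package (invasion verdicts, ESS location,
tournament rankings) are insensitive to the step: they are unchanged from
$dt = 0.01$ down to $dt/20$.

**ESS search.**  `find_ess()` computes the full pairwise invasibility
matrix on a grid over $[0,1]$ (each unordered pair simulated once, with
cached resident self-fitnesses) and applies two quantifier checks: a
strict evolutionarily stable strategy must invade every other grid
strategy and be invaded by none.  A neutrality band $|I - 1| \le 10^{-6}$
absorbs floating-point noise on the diagonal.  Self-extinguishing
residents ($w_{res} = 0$, for which the index is undefined) are excluded.

A structural subtlety makes the strict quantifier too strong at many
parameter settings: the non-producing resident $f = 0$ converts the whole
nutrient pool into biomass in its own patches and, at the standard
parameters, no producer can beat that benchmark from a 50:50 seeding —
killing the non-producer frees nutrient too late to repay the growth
sacrificed on toxin.  The pacifist corner is thus globally *uninvadable*
yet also *inert* (it invades nothing, since in any mixed patch against a
producer it is poisoned down to a biomass below the producer's
self-fitness).  When the strict check therefore fails, `find_ess()`
reports the *evolutionary attractor*: the strategy no other grid strategy
can invade and that invades the largest number of others.  This coincides
with the strict ESS whenever one exists, and with the fixed point of the
best-response dynamics otherwise; the certificate records which case
applied.  At standard parameters the attractor sits at $f^* = 0.31$ on
the 0.01 grid.

## What the simulations show — and a caveat

The qualitative comparative statics are robust here and match the
intuition of warfare economics: optimal investment $f^*$ rises with
killing efficiency $k$, toxin persistence ($l_T$ down), nutrient
saturation $K_N$, and initial density, falls with the maximal growth rate,
and peaks at intermediate initial nutrient (scarce nutrients cannot fund
an effective attack, while abundant nutrients favour pure growth).  The
four local-vs-global invasion outcomes are all reachable, aggressive
winners that impoverish themselves do fail to spread, and a small
percentage of successful sensing invaders can be re-invaded by their
former resident.

Under this exact parameterisation, however, the *timing economics* of a
toxin attack are slow: toxin must accumulate in proportion to past
biomass before the kill rate $k T$ rivals the growth rate.  Strategies
that attack pre-emptively and disarm later (for instance nutrient sensors
with $f_{initial} > f_{induced}$, which fight early and stand down once
the pool is half depleted) therefore outperform pure reciprocators in our
tournaments, and the standing-diversity ranking favours nutrient-based
first-strike regulation over toxin sensing.  Doubling the effective kill
rate (equivalently, halving the effective cost of early toxin) flips this
ranking and makes the pacifist corner invadable, with the strict
constitutive ESS then landing near $f^* = 0.35$; the qualitative story —
regulation beats constitutive production, and disarming after victory is
the key saving — is common to both regimes.  Results that depend on this
balance (the exact $f^*$, the identity of the best sensing mode, the
coevolved $f_{induced}$ ordering) should be read as conditional on the
kill-rate parameterisation; the package exposes every constant so either
regime can be explored (`eco_params(k = 40)` reproduces the fast-kill
regime).

## The genetic algorithm

`run_ga()` coevolves sensing strategies.  Each generation of $n = 60$
strategies is scored by a full round robin: every strategy competes
against all $n$ strategies including itself, and its fitness is the sum
of its own final biomasses ($n(n+1)/2$ unordered competitions are
simulated once).  The update rule copies the 4 fittest parents unchanged,
draws 46 offspring with probability proportional to fitness and perturbs
exactly one uniformly chosen parameter by $N(0, 0.001)$ (the increment is
redrawn until the constraint interval is respected, with a clip after
1,000 attempts), and adds 10 fresh immigrants drawn uniformly within the
constraints ($f$'s in $[0,1]$; $U_N \in [0,1]$, $U_{TB} \in [0,4]$,
$U_{QS} \in [0,1.2]$, the observed ranges of each cue).  Mixed
three-mode tournaments start every lineage at its within-type optimum and
spend the first 20 generations replacing the population wholesale with
immigrants (no selection), so that later selection acts on a well-mixed
strategy pool.  One master seed derives separate sub-streams for
initialisation, selection, mutation, and immigration, so changing the
draw count of one stage does not perturb the others and runs are exactly
reproducible.

Reported summaries are the mean parameters of the top 4 strategies per
generation (the fraction-based "top 5%" alternative is available via
`top_k`), and per-type population fractions and mean fitnesses for mixed
runs.

## Grids, tournaments and problem sizes

The reference scan and optimisation grids are deliberately dense
(investment steps of 0.02–0.05 and threshold steps down to 0.0005),
implying millions of competitions at full scale.  `sensing_grid()` takes
a `scale` factor that coarsens every step proportionally, and the
examples, tests, and reproduction script in this package run at desk
scale: invasion maps with investment steps of 0.1 and about ten
thresholds per mode, diversity tournaments with roughly a thousand
strategies per mode, GA runs with $n = 30$ populations over 40
generations and two replicate seeds, and ESS searches over the full 101-
point constitutive grid.  The threshold ladders used at desk scale always
include the extreme low thresholds (e.g. $U_{TB} = 0.001$), since
hair-trigger reciprocation is the strategically distinguished corner of
the space.  Sweep ladders for the comparative statics default to ×/÷2 and
×/÷4 around the standard values; the initial-nutrient ladder extends down
to $N_0 = 0.05$ so that both flanks of the interior optimum are visible.

## What the generators emulate — and what they do not

All inputs are synthetic by construction: strategy samplers draw
uniformly within the documented constraint ranges, the opponent ladder
for standing-diversity tournaments is the fixed symmetric family
$\{0.5\}, \{0.4,0.5,0.6\}, \dots, \{0.1,\dots,0.9\}$, and the fixture
corpus pins one representative competition per dynamical regime
(asymmetric duel, conservation case, attack-then-disarm, reciprocate-
then-disarm, quorum activation and repression, extinction).  The model is
a well-mixed, single-toxin, two-strain caricature: no spatial structure
within patches, no toxin resistance or multiple weapons, no biochemical
asymmetry between strains' toxins, and extinction by threshold rather
than demographic noise.  Passing tests therefore certify the solver, the
game-theoretic machinery, and the qualitative comparative statics of this
model family — not quantitative predictions for any real community.

## Known limitations

* The strict grid-ESS certificate fails at parameter settings where a
  globally uninvadable inert corner exists (see above); the attractor
  fallback is then reported and flagged.
* Backward Euler's absolute biomass error at the production step is at
  the percent level; analyses that need tighter absolute accuracy should
  raise `substeps`.
* Threshold-crossing times are resolved to one $dt$ interval; strategies
  whose cues graze a threshold can flip their switching interval under
  integrator refinement.
* The regression summary of tournament fitness treats competitions as
  exchangeable observations; it is a descriptive contrast, not a causal
  model.
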