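# toxwar

Eco-evolutionary modelling of regulated toxin warfare in bacteria.

Bacteria attack competing strains with bacteriocins and antibiotics, and
these attacks are usually under tight regulatory control — by quorum
sensing, by nutrient stress, or by stress responses that detect damage
from an incoming toxin.  `toxwar` is for evolutionary microbiologists and
theoreticians who want to ask *when* each kind of regulation should win.
It couples a mechanistic competition model to metapopulation game theory:

* **Ecological layer.**  Two strains share a nutrient pool with Monod
  kinetics and poison each other.  A strain investing a fraction *f* of
  its uptake into toxin grows at only (1 − *f*) of its maximal rate
  (linear allocative trade-off):

  d*C_A*/dt = (1 − *f_A*) µ_max *M* *C_A* − *k* *T_B* *C_A*,
  d*T_A*/dt = *f_A* *M* *C_A* − *l_T* *T_A*,
  d*N*/dt = −*M*(*C_A* + *C_B*),   with *M* = *N*/(*N* + *K_N*),

  solved by an implicit-Euler scheme (compiled core) with extinction and
  clamping rules.  Regulated strategies switch investment between
  *f_initial* and *f_induced* when their cue (nutrient depletion,
  opponent toxin, or own density) crosses a threshold.

* **Evolutionary layer.**  Invasion analysis with the invasion index
  *I_inv* = *w*(*f_inv* | *f_res*) / *w*(*f_res* | *f_res*), pairwise
  invasibility plots and ESS search for constitutive investment, grid
  tournaments that ask which sensing strategies stably displace the whole
  constitutive range or dominate a standing diversity of opponents, and a
  genetic algorithm (elitism + fitness-proportional mutation +
  immigration) for coevolving regulation strategies.

Results come back as tibbles with `tidy()`/`glance()` methods and
`autoplot()` graphics.

## Worked example

```r
library(toxwar)

# A reciprocator meets a weak constitutive producer
reciprocator <- strategy_sensing("toxin_sensing",
                                 f_initial = 0.01, f_induced = 0.73,
                                 threshold = 0.005)
out <- simulate_competition(reciprocator, strategy_constitutive(0.1),
                            keep_trajectory = TRUE)
out
#> <competition_outcome>
#>   A: toxin_sensing(0.01->0.73 @ 0.005) -> final biomass 0.863764 gC
#>   B: constitutive(f=0.1) -> final biomass 0 gC (extinct)
#>   local winner: A
```

The reciprocator stays passive (investment 0.01) until the opponent's
toxin crosses the threshold, retaliates at 0.73, drives the opponent
extinct, and — once the opponent's toxin has decayed — disarms again:
`out$trajectory$f_A` rises from 0.01 to 0.73 and returns to 0.01, the
energy saving that makes regulated attack pay.

The evolutionarily stable constitutive investment comes from pairwise
invasion analysis on the full grid:

```r
ess <- find_ess(eco_params(), grid_step = 0.01)
ess
#> <ess_result>
#>   f* = 0.31 (grid step 0.01, evolutionary attractor certificate)
```

meaning a population fixed at f = 0.31 cannot be displaced by any other
constitutive investment, and 0.31 displaces every investment that can be
displaced at all.  (The non-producer f = 0 is an inert corner: nothing
invades it, and it invades nothing — see the methods vignette.)
Comparative statics follow the economics of warfare: `sweep_ess("k",
c(10, 20, 40))` shows optimal investment rising with killing efficiency,
and the `N0` sweep has an interior optimum — toxins pay neither when
nutrients cannot fund them nor when growth potential is huge.

A command-line front end wraps the same functions
(`exec/toxwar.R simulate|pip|ess|invasion-map|diversity|ga|sweep`), with
YAML configs, per-run resolved-config echoes and seeded logs.

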