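---
title: "Assessing drug-combination synergy on signaling motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing drug-combination synergy on signaling motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(synmotif)
```

## The model and the score

synmotif screens inhibitor pairs on kinetic models of signaling networks
using the Bliss independence criterion. The system's readout is the
steady-state concentration of a designated output species; an inhibitor is
a multiplicative scaling of one kinetic parameter. Writing $a$ and $b$ for
the two scaled parameters ($a_0, b_0$ their baseline values, i.e. scale 1),
the **survival ratio**

$$r(a, b) \;=\; \frac{\text{output}(a, b)}{\text{output}(a_0, b_0)}$$

is the fraction of activity remaining under inhibition. Under Bliss
independence two inhibitors with independent mechanisms combine
multiplicatively, so the **Synergism Assessment Factor**

$$S \;=\; r(a, b) \; - \; r(a, b_0)\, r(a_0, b)$$

compares the observed combined survival with the expected product:
$S < 0$ is synergism (the pair suppresses the output more than the product
predicts), $S > 0$ antagonism, and $S = 0$ the additive critical point.
Because stronger inhibition means *lower* survival, synergy corresponds to
the *negative* sign; this direction is easy to trip over and is fixed
throughout the package.

Two algebraic forms of $S$ share the critical point: the difference form
above and a log form $\ln r(a,b) - \ln[r(a,b_0)\,r(a_0,b)]$. Both vanish
identically on multiplicatively separable (Bliss-independent) surfaces and
on the baseline edges $a = a_0$ or $b = b_0$; the difference form is the
package default because it is the classical fractional-product deviation,
and every result records which form produced it.

The **derivative index** is the second-order mixed partial

$$DS \;=\; \frac{\partial^2 S}{\partial a\, \partial b},$$

taken in scale space (so it is dimensionless). Since $S$ vanishes on both
baseline edges,

$$S(a, b) \;=\; \int_1^{a}\!\!\int_1^{b} DS \; \mathrm{d}a'\,\mathrm{d}b',$$

so a uniformly negative $DS$ over a dose rectangle *guarantees* synergy at
its corner. `s_from_ds()` evaluates this integral by composite Simpson
quadrature as an internal consistency oracle, and `ds_estimate()` provides
the pointwise index.

```{r closed-form}
surf <- interaction_surface(gamma = 0.5)   # r = exp(-u - v - 0.5 u v)
synergy_s(surf, 0.5, 0.5)
ds_estimate(surf, c(0.7, 0.8), form = "log")   # constant -gamma
```

## Numerical estimation of DS

$DS$ is a second difference of model outputs, which makes it the most
noise-sensitive quantity in the package; three choices follow from that.

* **Stencils.** The default `four_point_s` stencil applies the standard
  mixed central difference to $S$; the `two_term_r` stencil differences the
  survival ratio and subtracts the product of single-axis slopes. The two
  are algebraically identical for the difference form, so their agreement
  (to $10^{-4}$ in the test-suite) is a pure cross-check of the
  implementation.
* **Step control.** The step starts at $10^{-3}$ of each coordinate and is
  halved until two successive estimates agree to $10^{-3}$ relative; the
  accepted value is Richardson-extrapolated from the final pair. Estimates
  whose magnitude sits below $10^{-9}$ are accepted as numerically zero --
  halving further would only amplify roundoff, which matters on exactly
  Bliss-null surfaces. Failure to converge is carried in the result as
  `reliable = FALSE`, never silently.
* **Steady-state precision.** Solver noise at the default `rtol = 1e-8`
  would corrupt a second difference, so steady states found by integration
  are polished by a damped Newton iteration on pool-reduced coordinates
  (residual near machine precision). Tight defaults
  (`rtol = 1e-8`, `atol = 1e-10`) are kept for the trajectory itself.

## Simulating reaction networks

A `network_model` is data, not code: species (optionally in conserved
inactive/active pairs), reaction records in five rate laws
(Michaelis-Menten activation/deactivation $v = V_{max}[M][S]/(K_m+[S])$,
mass action, zeroth-order synthesis, first-order degradation), a designated
output, and clamped inputs. The ODE right-hand side is assembled from the
records, so any pathway expressible in these rate laws -- including a
user-transcribed published pathway model -- is simulatable without new
code. The same JSON schema (`synmotif-model/1`) round-trips models exactly.

Time units are arbitrary and never converted. Steady-state detection stops
the integrator at the root of (derivative max-norm $-$ `steady_tolerance`,
default $10^{-9}$); this both avoids integrating degenerate tails (fully
converted pools with underflowing rates) and makes the readout horizon
self-selecting. Negative concentrations within $100 \cdot$ `atol` of zero
are treated as roundoff and clipped at readout only; anything larger raises
an error, since it indicates an inconsistent model rather than solver
noise.

```{r serial}
m <- serial_motif()
steady_state(m)
```

## The built-in motifs and their inhibitor convention

Three canonical structures ship as parameterized builders, each a chain of
covalent-modification cycles with conserved totals:

* `serial_motif()` -- input A drives the B cycle; activated B drives the C
  cycle; activated C is the output.
* `parallel_motif()` -- two independent upstream cycles converge on C
  through separate saturating activation routes, so their rates add (logic
  OR: either branch alone sustains the output).
* `negative_feedback_motif()` -- the serial cascade plus an extra B-P
  deactivation mediated by the output, closing a negative loop.

Default parameters (totals 1, input 1, activation $V_{max} = 1$,
$K_m = 0.5$, deactivation $V_{max} = 0.5$, $K_m = 0.5$, feedback
$V_{max} = 1$, $K_{m} = 0.5$, all arbitrary units) put each cycle in a
partially saturated regime. They are package defaults, not published
measurements, and every structural claim checked against them is a sign or
order property, not a magnitude.

The motif inhibitor slots follow the competitive convention: a dose scales
the *Michaelis constant* of an activation step up by a factor $> 1$
(apparent $K_m = K_m(1 + [I]/K_i)$). The default screening window
`motif_dose_scales()` spans fold-increases 1.2--8, i.e. an inhibitor from
about 0.2 to 7 times its $K_i$ -- the moderate-inhibition window around the
IC50 that dose-finding experiments typically probe. The window's upper end
is a deliberate choice: with the default kinetics the serial cascade's
Bliss synergy is a moderate-dose phenomenon, and at near-saturating doses
of both inhibitors its $S$ crosses to weak antagonism. The velocity-constant
convention (scales in $(0, 1]$, built by `make_grid()` from 0.9 down to
$10^{-4}$) is used instead when inhibition acts on $V_{max}$-type
parameters, as in pathway case studies.

```{r curves}
tg <- motif_targets("serial")
s_curve(model_surface(serial_motif(), tg$a, tg$b), motif_dose_scales(4))
```

## Structural simplification

When an inhibitor acts on an upstream process, its effect reaches the
output only through that process's product. The transfer function
$x = \Phi(a)$ -- the steady-state level of the intermediate as a function
of the scaled parameter -- carries the whole effect, so the analysis can be
moved to a **simplified system** in which the intermediate is clamped as a
constant input and a *virtual* inhibitor scales the clamp level directly.
`simplify_clamp()` performs the construction and verifies that clamping at
the baseline levels reproduces the full model's baseline output to
$10^{-6}$ relative; the derivative indices then satisfy the exact sign
relation

$$\operatorname{sign}(DS) \;=\; \operatorname{sign}(\Phi')\,
\operatorname{sign}(\Psi')\,\operatorname{sign}(DS').$$

For the serial motif, $\Phi' < 0$ (a $K_m$ increase lowers the activated
intermediate) while the second inhibitor already acts inside the retained
cycle ($\Psi$ = identity), so the sign *flips*: the simplified system's
antagonism verdict predicts the full cascade's synergy. For the parallel
motif both transfer slopes are negative and the sign is *preserved*. Where
the virtual inhibitor should act is genuinely ambiguous for the serial
structure -- on the incoming activation or on the intermediate itself --
and both readings are expressible through `target_mapping()`'s
`identity` flag; the package default places one virtual inhibitor on the
clamped intermediate and keeps the downstream parameter as itself, which
makes the sign flip come entirely from $\Phi'$.

`corollary_check()` verifies the relation point by point on a dose grid,
together with the quantitative chain rule $DS = \Phi'\,\Psi'\,DS'$ (to
$10^{-3}$ relative in the test-suite) and the reconstruction of the full
system's $S$ from simplified-system evaluations ($S(a,b) =
S'(\Phi(a)/x_0, \Psi(b)/y_0)$ exactly, at normalized virtual scales).

```{r corollary}
glance(corollary_check(serial_motif(), "serial"))
```

## Feedback and effect preservation

Adding a feedback loop to a system changes its dynamics; whether it can
*weaken* an established combination effect is decided by a comparison
principle. Writing $g$ for the feedback term's contribution to the state
variable's rate and $\partial f/\partial x$ for the downstream rate's
sensitivity to that state, the preservation condition holds in two cases:
negative feedback ($g < 0$) with $\partial f/\partial x > 0$, or positive
feedback ($g > 0$) with $\partial f/\partial x < 0$. `feedback_check()`
classifies both signs *by evaluation* along the trajectory -- $g$ from the
feedback reaction's net contribution, $\partial f/\partial x$ by finite
difference of the output species' rate -- sampling at no fewer than 32
trajectory points; any sign change yields the conservative verdict
`mixed` and the condition is not asserted. Output domination (the feedback
trajectory never exceeding the feedback-free one, within $10 \cdot$
`atol`) is always verified pointwise on the shared time grid, never
deduced from the condition alone.

```{r feedback}
feedback_check(serial_motif(), negative_feedback_motif(),
               perturbations = list(perturbation("activation_B.km", 3),
                                    perturbation("activation_C.km", 3)))
```

## The fixture generator, and what passing tests do not show

`random_motif()` draws motif parameters log-uniformly within
`motif_ranges()` (factors of 2--5 around the defaults, deterministic in the
seed). The generator emulates exactly the structural class the method
addresses: activation/deactivation Michaelis-Menten cycles with conserved
totals, one to three inhibitable parameters, monotone steady states. It
does **not** emulate transcriptional delays, stochastic fluctuations,
spatial gradients, oscillatory or bistable regimes, or measured rate
constants of any real pathway. Consequently, passing the fixture suites
shows that the sign relations and the preservation condition hold
robustly across the intended structural class -- it does not validate any
quantitative prediction for a particular biological system, which requires
a faithfully parameterized model of that system supplied as data.

The shipped `nfkb_like_synthetic.json` is in that spirit: a synthetic
TNF-driven kinase-cascade/inhibitor-release pathway whose species names
follow the NF-κB system, used to exercise the JSON loader, the
target-mapping table and the screening workflow end to end. It is *not* a
transcription of any published NF-κB model, and no published synergy
values are claimed for it. To reproduce a published case study, transcribe
the published supplementary model into `synmotif-model/1` JSON and run the
same workflow.

## Problem sizes and tolerances used by the checks

The package's own verification suite runs at these sizes, chosen to
exercise each claim well inside a single-core minute-scale budget:
a 66-surface boundary/Bliss-null battery; quadrature meshes of 32
intervals per axis for the integral consistency checks ($\le 10^{-3}$
relative agreement required, observed $\sim 10^{-5}$ on motif surfaces);
20 serial and 20 parallel random fixtures on 8×8 dose grids for the sign
relations (100% agreement at determinate points required, where
determinate means $|DS| > 10^{-10}$); and 64-point trajectory sampling for
the feedback classification. The additivity tolerance for classification
defaults to $10^{-6}$.

## Known limitations

* Predictions are qualitative (signs and orderings); absolute $S$ values
  depend on the kinetic parameterization.
* The simplification machinery assumes a steady state exists and is
  reached; oscillatory systems are detected and rejected with a pointer to
  endpoint-mode readouts.
* Loewe additivity, combination-index and isobologram analyses are out of
  scope; the score is Bliss-based throughout.
* Clamping removes an intermediate's dynamics entirely; feedback edges
  onto a clamped species are dropped with it, which is the intended
  reading of the simplification but worth remembering when mapping targets
  on feedback-rich pathways.
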