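---
title: "Quantifying reproductive isolation between flower colour forms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reproductive isolation between flower colour forms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobarrier)
```

## The problem

When two colour forms of an animal-pollinated plant co-occur, gene flow
between them is filtered through a sequence of reproductive barriers:
they must flower at the same time, share pollinators that move between
them, and — once heterospecific pollen arrives — pollen tubes must grow,
fruits must set, and seeds must develop. `isobarrier` quantifies each of
these barriers with a standardised reproductive-isolation (RI) index,
composes them sequentially into a total, and attributes the total to
individual barriers. It was built around a study system of two colour
forms (white and pink) of a terrestrial orchid with partially
overlapping seasons, bee pollinators of differing floral constancy, and
reciprocal hand-pollination experiments, but the machinery applies to
any two-taxon, two-direction barrier study.

## The indices

Two closed forms are used, and they are deliberately different.

**Phenology.** With $S$ the maternal form's shared flowering time and
$U$ its unshared time,

$$\mathrm{RI}_{\mathrm{phen}} = 1 - \frac{S}{S+U}.$$

Complete co-flowering gives 0 (no barrier), complete separation gives 1.
Day counts are inclusive of both endpoints: a form flowering 24 July to
9 September flowers for 48 days. This convention is load-bearing — it is
what reproduces two-decimal phenological RI values from calendar dates —
and is applied uniformly by `overlap_days()`.

**All other barriers.** With $C$ the conspecific (intraform) and $H$ the
heterospecific (interform) success measure for one maternal direction,

$$\mathrm{RI} = 1 - \frac{2H}{H+C} \in [-1, 1],$$

0 at random mating ($C=H$), 1 at complete isolation, negative when
heterospecific crosses outperform conspecific ones (as pollen-tube
counts can). The index depends only on the ratio $H/C$, so counts,
means, and proportions are all admissible provided the pair is
co-measured; `success_pair()` keeps the pair in one record for exactly
this reason. `C = H = 0` is an error, not a zero: observing no mating
events of either kind carries no information about isolation.

Directional **asymmetry** is the absolute difference between a barrier's
RI in the two maternal directions, computed on unrounded values.

## Sequential composition

Barriers act in life-history order: phenology, pollinator foraging,
pollinia–pistil interaction, fruit production, seed development. The
cascade normalises each post-phenology barrier to its relative
heterospecific success $h_j = H_j / C_j$ and assumes

* no heterospecific pollination outside the co-flowering period
  ($H_U = 0$), and
* conspecific success unaffected by co-flowering ($C_S = C_U$,
  normalised to 1).

Under these assumptions the four-term total-RI expression

$$\mathrm{RI}_{\mathrm{total}} =
  1 - \frac{2(S H_S + U H_U)}{(S H_S + U H_U) + (S C_S + U C_U)}$$

reduces to $1 - 2 S \prod_j h_j / (S \prod_j h_j + 1)$ with
$S + U = 1$; the package evaluates the reduced form and the test suite
verifies its equivalence to the literal form to machine precision.
Heterospecific effects multiply across stages, i.e. stages are treated
as acting independently given the preceding ones.

A deliberate mixed convention: stage 1 (phenology alone) uses the first
index (no factor of 2), later stages the second. The two formulas do not
coincide in any limit; the mixed convention is the one under which both
the per-barrier values and the totals of a published study recompose
correctly from its printed inputs, so it is canonical here and
`cumulative_ri(cascade, 1)` always returns $U$.

Contributions telescope: $AC_i = \mathrm{RI}_{[1,i]} -
\mathrm{RI}_{[1,i-1]}$ with $\mathrm{RI}_{[1,0]} = 0$, so
$\sum_i AC_i = \mathrm{RI}_{\mathrm{total}}$ (exact up to floating-point
summation, asserted at $10^{-12}$), and $RC_i = AC_i /
\mathrm{RI}_{\mathrm{total}}$. Contributions are order-dependent —
a barrier acting after strong earlier barriers has little left to
remove — so reports always state the order used, and a stage with
$h_j > 1$ contributes negatively.

When a study publishes only a barrier's RI and not its underlying rates
(fruit production is the usual case), `h_from_ri()` inverts
$h = (1-\mathrm{RI})/(1+\mathrm{RI})$; the shipped published-summary
fixture uses this for the fruit stage and records the fact in a comment
in its config file.

```{r cascade-example}
casc <- barrier_cascade("white", shared = 41, unshared = 7, data.frame(
  barrier = c("pollinator", "pollen_tube", "fruit", "seed"),
  conspecific = c(370, 118.93, 1, 72.42),
  heterospecific = c(20, 125.62, h_from_ri(0.39), 45.51)))
cascade_contributions(casc)
```

## Pollinator constancy

A transition is a move between two distinct plants; consecutive records
on one plant are collapsed, and transitions never bridge bouts. Gegear's
index per forager is

$$CI = \frac{c - e}{(c + e) - 2ce}, \qquad e = p^2 + (1-p)^2,$$

with $c$ the observed proportion of same-form transitions and $p$ the
forager's proportion of visits to the focal form ($e$ is invariant to
which form is focal; the package fixes the alphabetically first label
for determinism). $CI$ is $-1$ at complete inconstancy, 0 at random
choice, 1 at complete constancy. The denominator vanishes when
$c = e = 1$ — a forager that only ever visited one form — and the index
is then reported as missing, not zero, and excluded from species means
with an explicit count. This matters in practice: highly constant
species produce many such foragers, and treating them as 0 (or as 1)
would move species means materially in opposite directions.

Two small-sample properties of the plug-in estimator are worth knowing.
First, under availability-random foraging the estimator is biased
*below* zero by $O(1/L)$ in bout length $L$ (at $L \approx 12$ the bias
is about $-0.1$); the random-choice null is recovered in the long-bout
regime, and the test suite checks it at mean bout length 80. Second,
because the undefined-CI foragers are exactly the perfectly constant
ones, species means over defined CIs are conservative for highly
constant species.

## The colour-hexagon model

Floral reflectance is assessed through trichromatic hymenopteran vision:
quantum catches for UV, blue and green receptors are trapezoid-rule
integrals of stimulus × illuminant × sensitivity over a canonical 1-nm
grid from 300 to 700 nm, normalised by the catch from an adapting
background (von Kries), transduced as $E = P/(P+1)$, and projected to
hexagon coordinates $x = (\sqrt{3}/2)(E_g - E_{uv})$,
$y = E_b - (E_{uv}+E_g)/2$. The background maps to the origin, loci are
bounded by $|x| \le \sqrt3/2$, $|y| \le 1$, and chromatic distance is
Euclidean in hexagon units. Discrimination uses a just-noticeable-
difference threshold of 0.1 hexagon units by default — the value under
which published distances of 0.21 and 0.06 fall on opposite sides — and
is configurable; a threshold of 0.01 also circulates in the literature
for the same model, so the choice is always recorded in output.

Von Kries normalisation cancels any *common positive factor* applied to
stimulus and background exactly (the test suite asserts this at
$10^{-10}$); a wavelength-*dependent* illuminant shift is only
approximately discounted, which is a property of the model itself, not
of the implementation — the tests bound the residual locus shift under
a slowly varying rescaling instead of asserting exact invariance.

Defaults, all overridable and all recorded in the model's metadata:
receptor sensitivities from the standard A1 visual-pigment nomogram
(alpha plus beta band, peak normalised to 1) at 344/436/544 nm for the
honeybee model and 353/434/542 nm for the bumblebee model; a standard
daylight (D65) illuminant shipped at 5-nm resolution; and a synthetic
green-foliage background (low UV/blue, chlorophyll bump near 550 nm,
start of the red edge), shipped as
`green_foliage_background_synthetic.csv` — the filename flags that it is
a constructed typical curve, not a measurement. Resampling is linear
interpolation with no extrapolation; negative spectrometer noise is
clipped to zero with a warning.

## The synthetic-data generator

The generator exists so that every stage of the analysis is testable
without field data, and its defaults are the study conditions the
package was built around: 77 white and 40 pink plants with ~6-week
windows offset by a week, per-plant flowering spans around a mean
flower lifespan of 10 days; two bee species foraging over an equal
20:20 array — one with stay-probability $\kappa = 0.95$ and one with
$\kappa = 0.85$, 30 and 26 foragers, geometric bout lengths with mean
10 — chosen to mimic the observed contrast between a highly constant
and a less constant species; a four-treatment crossing design (self,
intraform, interform, control) with 30 flowers per cell, fruit
probabilities matching observed natural fruit-set levels (0.8 intraform
white, 0.35 interform white; 0.76 and 0.67 for pink; controls 0 —
mechanical autogamy does not occur in this system), negative-binomial
pollen-tube counts at the published cell means with dispersion 1.5
(the field counts have standard deviations close to their means, which
a Poisson model cannot produce), and multinomial embryo categories over
large/small/aborted/empty with the large-embryo rates at the published
cell means and the remainder split in field-plausible proportions; and
white / pink / intermediate spectra as smooth parametric curves with
Gaussian noise (SD 0.005) clipped to [0, 1], the intermediate a
0.75/0.25 white-weighted mixture so that, as in the field, bees can
separate pink from white but not intermediate from white.

The forager model is a two-state Markov chain: stay on the current form
with probability $\kappa$, otherwise choose by availability. Its
stationary visit shares equal availability, which gives a closed-form
expected relative success for the pollinator barrier
($h = a_o(1-\kappa)/(\kappa + (1-\kappa)a_f)$ for arrivals at a form
with availability share $a_f$) — used as the independent truth in the
recovery tests.

What the generator does *not* emulate: spatial structure of foraging,
weather-driven gaps in observation, plant-level covariance between
barriers (a plant with poor fruit set also tending to poor seed
development), inheritance of the intermediate phenotype, and measured
(as opposed to template) receptor sensitivities. Passing recovery tests
therefore demonstrates correctness of the estimators under the model's
independence assumptions, not robustness to these field realities.

## Numerical and reporting choices

* Reported RI values are rounded half *away from zero* to 2 decimals
  (`round_half_up()`), only at report rendering; full precision flows
  through the cascade and into serialized outputs.
* Bootstrap intervals for RI are percentile intervals over resamples of
  the underlying per-trial observations within each class; degenerate
  resamples (both class means zero) are dropped with a warning, and
  fixed seeds make intervals exactly reproducible.
* Dates are ISO-8601 throughout; day arithmetic is inclusive.
* Degenerate inputs error early with classed conditions
  (`isobarrier_invalid_input`, `isobarrier_undefined_ri`,
  `isobarrier_io_error`, `isobarrier_pipeline_error`) so callers can
  distinguish bad data from bad configuration.

Problem sizes in the shipped tests were chosen to give stable Monte
Carlo checks at interactive runtimes: 200 replicates at 100 trials per
crossing cell for total-RI recovery (observed bias well under 0.02),
150 foragers per $\kappa$ level for constancy ordering, and 100
replicates for bootstrap-coverage checks.

## Known limitations

* The pollinator-barrier RI computed from a transition table uses
  arrivals at the maternal form; published per-direction values derived
  from other weightings (e.g. bout-level proportions) can differ by a
  few hundredths, and one published white-direction value (0.88) is not
  recoverable from its own printed transition counts (which give 0.90).
  The package computes from counts and does not force agreement.
* Recomposing a published total from *rounded* printed inputs can land
  a hundredth away from the published total computed on unrounded field
  data (0.67 vs 0.68 in the pink direction of the motivating study);
  this is propagation of printing precision, not an implementation
  discrepancy, and the package does not tune inputs to match.
* Relative contributions are undefined when total RI is 0 and are
  flagged missing rather than forced.
* The colour-hexagon outputs depend on illuminant and background
  choices; with the shipped defaults they support ordering and
  threshold statements, not absolute comparisons against distances
  measured under unknown conditions.
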