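---
title: "Bee-subjective colorimetry and dual-choice analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bee-subjective colorimetry and dual-choice analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexabee)
```

hexabee models how trichromatic bees perceive colour stimuli and analyses
the dual-choice experiments used to probe colour preferences in stingless
bees. This vignette is the package's account of its science: the colour
model and its assumptions, the experimental design it encodes, the
statistical conventions, the synthetic-data generator, and the numerical
and design choices that were genuinely open.

## The colour hexagon model

Bees carry three photoreceptor classes with sensitivity maxima near 340 nm
(UV), 430 nm (blue) and 540 nm (green). For a stimulus with reflectance
$I(\lambda)$ viewed under illuminant $D(\lambda)$, receptor $i$ catches

$$Q_i = \int_{300}^{700} S_i(\lambda)\, I(\lambda)\, D(\lambda)\, d\lambda ,$$

where $S_i$ is the receptor's spectral sensitivity. Receptors adapt to the
background (von Kries adaptation): the sensitivity factor
$R_i = 1 / \int_{300}^{700} S_i(\lambda) I_B(\lambda) D(\lambda)\,
d\lambda$ scales the catch so the adapted background catch is exactly
$P = Q R = 1$. Phototransduction saturates hyperbolically,

$$E = \frac{P}{P + 1} \in [0, 1),$$

so the adapted background sits at half-maximal excitation $E = 0.5$ in all
three receptors. The excitation triple maps into the colour hexagon,

$$x = \sin 60^\circ\,(E_G - E_{UV}), \qquad
  y = E_B - \tfrac{1}{2}(E_{UV} + E_G),$$

placing the background at the origin and the three single-receptor
vertices at distance 1. Derived quantities:

* **chromatic contrast** — Euclidean distance between two loci (to the
  background: distance from the origin);
* **spectral purity (SP)** — the distance of the stimulus from the
  background divided by the distance from the background to the spectral
  line along the same hue direction (bee-subjective saturation, in
  $[0,1]$);
* **dominant wavelength** — the wavelength at that intersection
  (bee-subjective hue; undefined on the purple closing segment);
* **intensity** — the mean of the three excitations (bee-subjective
  brightness; background: 0.5);
* **physical saturation and luminance** — receiver-independent
  descriptors from the reflectance alone: mean reflectance (luminance) and
  the Michelson spectral contrast $(R_{max}-R_{min})/(R_{max}+R_{min})$
  (saturation). The literature source for these physical measures does not
  print a formula, so the Michelson convention was chosen and isolated in
  one function (`physical_metrics`) so it can be swapped.

Receptor sensitivities default to A1 visual-pigment templates
(Govardovskii-type alpha band, beta band off) at 340/430/540 nm. The
template lives on the normalised abscissa $\lambda_{max}/\lambda$, peaks
exactly at the grid point nearest $\lambda_{max}$, and the maxima are
overridable — measured species-specific curves (e.g. for *Melipona
quadrifasciata*) can be substituted through `receptor_set()` when
available, which is also why the defaults are a documented stand-in rather
than a claim about any one species.

### The spectral line

The hexagon performs no intensity normalisation, so a monochromatic
light's locus depends on how bright it is: it traces a loop from the
centre (too dim to see) back towards the centre (all receptors saturated).
A spectral-purity denominator needs one definite curve. The package
defines the spectral line at the **adaptation-matched intensity**: each
monochromatic light is scaled so its total adapted catch equals the
background's own total, $\sum_i P_i = 3$, i.e.
$P_i = 3 s_i / \sum_j s_j$ with relative drives
$s_i = S_i(\lambda) D(\lambda) R_i$. This construction is closed-form,
unique, independent of any spike-amplitude choice (the amplitude cancels
in the ratio), bounded ($E_i \le 0.75$), and yields the familiar horseshoe
with its ends near the UV and green vertices. Two alternatives were
rejected after implementation: a fixed large amplitude saturates all three
receptors and collapses the curve to the centre, and choosing the
per-wavelength intensity that maximises chromatic distance is ill-posed
because hexagon distance plateaus near 1 along entire edges, leaving the
locus direction arbitrary.

The curve is closed by default with the **purple line**, the chord joining
the 700 nm and 300 nm ends, so that every hue direction — including the
bee-purples (UV plus green, where UV-reflecting long-wavelength stimuli
live) — has a defined SP denominator. Whether the original analyses closed
their spectral line is not documented; closing it is the choice that
leaves SP defined everywhere. Ray–polyline intersection takes the nearest
intersection along the ray, treats segments as closed, and uses a
$10^{-12}$ parallelism tolerance; a stimulus at the origin has SP 0 by
convention. Because broadband lights are not convex combinations of
monochromatic loci in these nonlinear coordinates, a sufficiently
saturated stimulus could in principle fall outside the closed curve; the
intersection then still defines the ratio, and the synthetic stimulus sets
are certified to lie inside (all SP in $[0, 1]$).

### Numerical conventions

Integrals use the trapezoidal rule on a uniform 300–700 nm grid with 1 nm
steps (the integration bounds are the model's; the step is chosen to make
discretisation error negligible — the analytic checks in the test suite
hold to $10^{-10}$ or better). The bundled CIE D65 table (5 nm, energy
basis, 100 at 560 nm) is linearly interpolated; quantum catches use the
photon basis (energy $\times\ \lambda$) by default, as photon-counting
receptors require. Spectra measured on sparser or narrower grids are
linearly interpolated and extended with their endpoint values; no
smoothing is applied. The background defaults to a spectrally flat 30%
reflector, mirroring a grey foam background that reflects constantly
across the UV and visible range.

## The dual-choice design

The experiment crosses six colour categories (UV-blue, blue, UV-yellow,
yellow, red, white) with four stimuli each: two spectral-purity levels
(P+/P−) times two intensity levels (I+/I−), except white, where the purity
axis is replaced by UV reflectance (UV+/UV−). Every bee performs 57 dual
choices: all 6 within-category pairs for each category (36 tests) and all
21 pairs of the seven hue representatives — the most intense, spectrally
purest member of each chromatic category plus both full-intensity whites.
One pair (the two white representatives) necessarily occurs in both
contexts.

`generate_schedule()` reproduces the design constraints rather than any
literal published order (which is available only as an image): the order
is randomised under the rule that no two consecutive tests come from the
same block, sides are randomised with overall left/right balance within
one test, and `reversed = TRUE` emits the order back-to-front, as done for
part of the bees to cancel order effects. How many bees received the
reversed order is not documented; it is left to the caller.

## Statistical conventions

Per-family inference follows the original pipeline: a binomial GLMM on the
per-bee choice counts with stimulus as fixed effect and a per-bee random
intercept (`lme4::glmer`, Laplace approximation, deterministic defaults),
model comparison by AIC, and single-step Tukey all-pair comparisons
(`multcomp::glht`; the quasi-Monte-Carlo adjustment runs under a fixed
internal seed so repeated calls are identical). Normality is screened with
Shapiro–Wilk; two-sample comparisons use Student's t or the
Wilcoxon–Mann–Whitney test, two-sided throughout.

The pooled purity and intensity comparisons need a pooling convention,
and the reported degrees of freedom pin it down: the sampling unit is the
**dual test**, not the bee. Exactly 10 within-category tests oppose the
two purity levels at equal intensity (2 per chromatic category), and 12
oppose the two intensity levels at equal purity or UV level (2 per
category). A paired t across tests then has df 9 and 11 respectively —
matching the printed df — while a rank-sum statistic near its maximum of
100 for 10-vs-10 counts matches the printed W under the unpaired R
convention. `pooled_preference_test()` implements both and reports the
per-test counts it pooled.

`mann_whitney_u()` reports `W` in the R convention (the U statistic of the
first sample, counting ties as 1/2) alongside the smaller U, because a
printed "W" is only reproducible under the right convention; exact
enumeration p-values apply for small untied samples and a tie-corrected
normal approximation otherwise. The test suite verifies the exact p
against full enumeration over all rank assignments for every layout with
$n + m \le 10$.

## The synthetic-data generator

The generator produces everything the analysis consumes, with known ground
truth.

**Spectra.** Idealised pigments stand in for the artist pigments of the
physical stimuli: a Gaussian blue (peak 450 nm), long-pass yellow (edge
520 nm) and red (edge 600 nm), UV variants adding a modest 300–400 nm
shoulder, and achromatic diluents (UV-reflecting white, UV-absorbing
white, grey, a dark UV-absorbing grey, black). Mixing is subtractive via
the weighted geometric mean $R_{mix} = \prod_k R_k^{w_k}$ — a
single-constant Kubelka–Munk-like rule that is monotone in every
component; reflectances are floored at $10^{-4}$. The swap-in point for a
two-constant mixing model is `mix_pigments()`.

**Series selection.** Dilution with white desaturates, dilution with black
darkens — but darkening also desaturates in the hexagon, because every
excitation falls. The physical experiment handled this by computing colour
parameters for many mixtures and *selecting* four stimuli per category;
the generator emulates that selection: recipe weights are chosen so that
the two members of each intensity pair are matched in spectral purity
(within 0.1), while the purity levels stay separated. Each series is
certified by the colorimetry module itself (SP(P+) > SP(P−) at both
intensity levels, intensity(I+) > intensity(I−) at both purity levels, SP
matched within intensity pairs); if a weight schedule fails certification
the next one on a fixed ladder is tried, and an error is raised if none
passes. The red series comes out near-achromatic (chromatic contrast
< 0.2, green-receptor-dominated loci) — the hexagon's own account of why
red flowers are nearly invisible to bees.

**Choices.** A simulated bee assigns each stimulus the utility
$u = \beta_{SP}\, SP + \beta_I\, I + h_{cat}$ (log-odds scale) and in each
dual test chooses the alphabetically first stimulus of the pair with
probability $\mathrm{logit}^{-1}(u_{first} - u_{second} + b)$, with a
per-bee intercept $b \sim N(0, \sigma_{bee})$. Attaching the intercept to
the canonical (side-free) member of the pair rather than to a side keeps
it orthogonal to the randomised side assignment while still inducing the
per-bee correlation that the GLMM's random intercept absorbs. Two presets
encode the study's contrast: a purity-driven chooser with a bluish hue
bias and a red penalty ($\beta_{SP} = 4$, hue effects blue +1.2, UV-blue
+0.6, white +0.8, red −2, $\sigma_{bee} = 0.5$), and a generalist null
(all coefficients zero, $\sigma_{bee} = 0.5$). The preset magnitudes were
fixed once as plausible effect sizes: the purity coefficient times the
generated SP gaps gives per-test choice probabilities around 0.75–0.85,
strong but not deterministic preferences of the kind the assay is designed
to detect.

**What the generator does not emulate.** Real reflectance spectra carry
measurement noise, specular structure and pigment-batch variation; real
bees learn within a session, vary in motivation, and may be influenced by
position or scent marks despite the controls. Passing tests on synthetic
data therefore demonstrate that the pipeline recovers what it assumes —
not that the assumptions hold for any particular bee.

## Calibration experiments and their sizes

`recovery_experiment()` re-estimates the purity coefficient from simulated
choice data by a binomial GLMM on per-choice predictor differences
(`chose_first ~ 0 + dSP + dI + (1 | bee)`). At the study's size (24 bees,
57 tests) and 50 replicates the mean estimate is within a few percent of
the truth; the acceptance script recomputes this from scratch.

`null_calibration()` measures the family-wise rejection rate of the
per-family GLMM + Tukey analysis when choices are fair coin flips (500
replicates of the full 57-test schedule, 20 bees, one four-level family).
These sizes keep the default runs to a few minutes on one core and are
stated here as the package's chosen experiment sizes.

### A known limitation of the GLMM pipeline

The calibration exposes a real property of the original analysis, not an
implementation artefact: within a dual test the two stimuli's counts are
perfectly negatively coupled (one chosen means the other not), so per-bee
counts across the four stimuli of a family are negatively correlated,
while the binomial GLMM treats them as independent. The variance of a
pairwise contrast is understated by roughly a third, and the realised
family-wise error of the nominal 5% Tukey procedure comes out near 10%
(the acceptance suite computes it at 500 replicates). Significance letters
from this pipeline on forced-choice data should therefore be read as
mildly anticonservative; a multinomial or conditional-logit formulation
would be the principled repair and is out of scope here.

## Open questions resolved by choice

* The exact species sensitivity curves behind the original calculations
  are not published; templates at 340/430/540 nm are the documented
  stand-in, overridable.
* The physical saturation/luminance formulas are not printed; Michelson
  contrast and mean reflectance were chosen, isolated behind one function.
* Whether the spectral line was closed by a purple segment is not
  documented; it is closed here so SP is defined for every hue direction.
* The pooled-test convention (per-test counts; paired t, unpaired
  rank-sum) is the unique convention consistent with the reported degrees
  of freedom and W statistics, as derived above.
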