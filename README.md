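# hexabee

Bee-subjective colorimetry with the colour hexagon, plus the design and
statistics of dual-choice colour-preference experiments on stingless bees
(Meliponini).

Bees see the world through three photoreceptors (UV ~340 nm, blue
~430 nm, green ~540 nm), and their flower choices track a handful of
colour parameters — dominant wavelength (hue), spectral purity
(saturation) and, possibly, intensity (brightness). hexabee is for
researchers who want to (a) compute those bee-subjective parameters from
reflectance spectra, (b) encode and analyse the 57-test dual-choice assay
used to probe colour preferences, and (c) validate the whole analysis
chain on synthetic data with known ground truth.

## The model

For a stimulus with reflectance I(λ) under illuminant D(λ) (CIE D65,
photon basis, bundled), receptor *i* catches

    Q_i = ∫₃₀₀⁷⁰⁰ S_i(λ) I(λ) D(λ) dλ

and is von Kries-adapted to the background I_B through
R_i = 1/∫ S_i I_B D dλ, so the adapted catch is P = Q·R (background: P = 1)
and the excitation

    E = P / (P + 1)  ∈ [0, 1)

maps into the colour hexagon, x = sin 60° (E_G − E_UV),
y = E_B − (E_UV + E_G)/2, with the background at the origin and the
receptor vertices at distance 1. From the locus the package derives
chromatic contrast (distance to the background), spectral purity
SP = H(target−background) / H(spectral line−background), dominant
wavelength, intensity (E_UV + E_B + E_G)/3, and receiver-independent
physical saturation/luminance. The spectral line is computed at the
adaptation-matched intensity (total adapted catch of the monochromatic
light equal to the background's), closed by the purple line — see the
methods vignette (`vignettes/hexabee-methods.Rmd`) for why.

The experimental layer reproduces the dual-choice design — 6 colour
categories × 4 stimuli (P±/I±, whites UV±/I±), 36 within-category tests
plus 21 hue comparisons in a semi-randomised order with no two
consecutive same-category tests — and the statistical battery: binomial
GLMM with per-bee random intercept (lme4), Tukey all-pair comparisons
(multcomp), Shapiro–Wilk, Student's t and Mann–Whitney/Wilcoxon with the
per-test pooling convention for purity and intensity preferences. A
synthetic-data module generates pigment-mixture stimulus spectra
(self-certified by the colorimetry module) and simulated foragers with
parameterised preferences.

## Worked example

```r
library(hexabee)

grid       <- wl_grid()                      # 300-700 nm, 1 nm
receptors  <- receptor_set(grid = grid)      # templates at 340/430/540 nm
background <- flat_spectrum(0.30, grid)      # flat grey background
setup      <- default_stimulus_set(receptors, background)

head(setup$metrics[, c("stimulus_id", "chromatic_contrast",
                       "spectral_purity", "dominant_wavelength",
                       "intensity")], 4)
#>     stimulus_id chromatic_contrast spectral_purity dominant_wavelength intensity
#> 1 UV-blue_P+_I+             0.2128           0.345                 396     0.497
#> 2 UV-blue_P+_I-             0.2252           0.358                 397     0.380
#> 3 UV-blue_P-_I+             0.0975           0.165                 392     0.640
#> 4 UV-blue_P-_I-             0.1063           0.179                 393     0.467
```

The four UV-blue stimuli realise the design: the P+ pair is about twice
as spectrally pure as the P− pair at each intensity level, and each I−
member is darker than its I+ partner at matched spectral purity.
Simulating a purity-driven species and analysing its choices:

```r
schedule <- generate_schedule(setup$stimuli, seed = 42)
records  <- simulate_bees(helleri_model(), schedule, setup$stimuli,
                          setup$metrics, n_bees = 24, seed = 1)
tally    <- tally_choices(records, schedule, setup$stimuli)

pooled_preference_test(tally, "purity", method = "wilcoxon")
#> purity: W = 88, p = 0.0044 (mean choices 15.3 vs 8.7 per test)

family_choice_model(tally, "blue")$comparisons[, c("level_a", "level_b",
                                                   "estimate", "z", "p_adj")]
#>      level_a    level_b estimate     z   p_adj
#> 1 blue_P-_I+ blue_P-_I-    0.062  0.18 0.99807
#> 2 blue_P+_I- blue_P-_I-    1.514  4.23 0.00014
#> 3 blue_P+_I+ blue_P-_I-    1.204  3.45 0.00320
#> 4 blue_P+_I- blue_P-_I+    1.452  4.08 0.00027
#> 5 blue_P+_I+ blue_P-_I+    1.142  3.29 0.00564
#> 6 blue_P+_I+ blue_P+_I-   -0.310 -0.88 0.81613
```

The pooled rank-sum test detects the simulated purity preference (the 10
purity-contrast tests' P+ counts dominate the P− counts, W = 88 of a
possible 100), and the per-category Tukey table separates both P+ stimuli
from both P− stimuli while finding no difference along the intensity axis
— the pattern the assay is designed to resolve. `run_pipeline()` wires
the whole chain (simulate or ingest → metrics → tally → models) into one
reproducible run with serialised configuration.

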