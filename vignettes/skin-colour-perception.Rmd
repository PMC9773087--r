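---
title: "Methods: scaling skin-colour impressions from forced-choice judgements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scaling skin-colour impressions from forced-choice judgements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinpercept)
```

## The problem

How does facial skin colour — summarised as *whiteness* and *hue angle* —
change the impressions a face makes, specifically femininity–masculinity
and likeability? The experimental logic is: render one face at many skin
colours so that colour is the only thing that varies, collect bipolar
forced-choice ratings, convert the ordinal ratings to an interval scale,
and test the colour factors inferentially. This vignette documents the
models, the tunable parameters, and the design choices at each stage.

## Colorimetry and the whiteness model

All image processing runs in CIELAB under D65 with the 10° standard
observer (white point X = 94.811, Y = 100, Z = 107.304). The sRGB decode
uses the standard IEC 61966-2-1 matrices; sRGB is nominally defined for the
2° observer, but the experiment's stated colorimetry (10°) is applied
throughout the bridge, which shifts neutral white to a* ≈ 0.41, b* ≈ −0.97
— well below a visible difference for these purposes.

Whiteness is the scalar

$$W = L^* - \frac{\beta\, C^*_{ab}}{C^*_{ab} + \beta},$$

strictly increasing in lightness and decreasing in chroma, with $W = L^*$
for achromatic colours. The typeset source of this formula is corrupted in
the literature it comes from; the form above is the only reading consistent
with its printed symbol set and the achromatic limit, and it is isolated in
`whiteness()` so an alternative form is a one-line change. Each subject
carries a profile (`L_sub`, `C_sub`, `beta`); the packaged fixture holds
the two study faces (OM: 63.74 / 21.38 / 76.0, whiteness 47.05; OF:
66.83 / 17.99 / 76.0, whiteness 52.28).

**Inverting (W, h) to a colour.** The design specifies stimuli by
(whiteness, hue angle) only. `resolve_skin_color()` holds chroma at the
subject's natural `C_sub` and solves the whiteness formula for lightness,
$L^* = W + \beta C_{sub}/(C_{sub}+\beta)$ — the minimal perturbation of the
subject's own skin, and a unique closed-form inverse. The requested hue is
passed through untouched.

**Gamut.** A consequence worth knowing: at the study chromas (≈ 18–21),
every W = 80 grid point — and the warmest W = 70 points for the
higher-chroma subject — resolves to a lightness (≈ 95–97) outside the sRGB
gamut. Such colours are clipped channel-wise in linear RGB; the clip is
reported as a warning carrying the CIELAB error it introduces, and the
stimulus manifest records a `gamut_clipped` flag and `clip_de` per grid
point (up to ΔE\*ab ≈ 13 at W = 80). Analyses that need an exact round trip
(e.g. verifying that recoloured skin measures the requested whiteness)
should use targets inside the gamut; the acceptance script does this with a
low-chroma synthetic subject (`C_sub = 8`).

## Stimulus preparation

*Segmentation* uses per-channel RGB box thresholds at the skin-sample mean
± k·SD (default k = 2.5), the simplest rule consistent with deriving a
threshold from database skin colours. Because box thresholds admit speckle,
the largest connected component is kept and interior holes up to
`max_hole_area` (default 64 px) are filled; larger interior non-skin
regions (eyes, lips) stay excluded, and an optional exclusion-mask image
reproducibly replaces manual retouching of regions such as the sclera. An
exclusion mask is re-applied after hole filling.

*Texture* is the per-pixel CIELAB deviation from the mean skin colour; by
construction the deltas average to zero over the mask. *Recolouring* adds
the target colour to the deltas and converts back to sRGB; pixels outside
the mask are copied bit-exactly, and all arithmetic stays in floating point
with quantisation to 8 bits only at file write. For in-gamut targets the
mean recoloured colour lands within ΔE\*ab 0.5 of the target and the
texture field survives the 8-bit round trip within ±1.5 units; at the gamut
boundary the brightest texture tails clip, which is why the texture
tolerance is scored at mid-grid targets.

The default grid (4 whiteness × 5 hue levels, 2 faces, 4 repeat-flagged
stimuli drawn uniformly without replacement under the grid seed) reproduces
the study design: 40 stimuli from 20 distinct colours.

## From forced choices to scale values

Each judgement is a pole (e.g. *feminine* vs *masculine*) plus a 1–5
strength score. These fold into 10 ordered categories with no neutral
cell: second-pole scores map 5→1 … 1→5, first-pole scores 1→6 … 5→10.

Scaling follows Thurstone's Case V realised for rating categories (the
method of categorical judgement, Torgerson's Condition D): per attribute,

1. count responses per stimulus × category (repeat second presentations
   excluded — they exist only for the repeatability estimate);
2. cumulative category proportions per stimulus (the implicit final 1 is
   dropped);
3. inverse-normal transform, with proportions clipped to
   $[1/(2n),\ 1 - 1/(2n)]$ so observed 0s and 1s stay finite — the
   standard finite-sample correction, configurable via `clip`;
4. category-boundary estimates $\tau_k$ = column means over stimuli, and
   stimulus values $\mu_s = \mathrm{mean}_k(\tau_k - z_{sk})$, centred to
   mean zero.

The centring reflects that a translation of every latent value is
unidentifiable; only differences carry information. Degenerate inputs are
handled explicitly: a single stimulus scales to 0 with a warning,
indistinguishable stimuli scale to equal values, and stochastic dominance
in the cumulative rows implies the corresponding ordering of scale values.

Observer variation is reported as RMS in encoded-category units:
intra-observer over repeat pairs (first minus second presentation),
inter-observer over deviations from the per-stimulus panel mean, plus the
same numbers as a percentage of the 9-step scale span, since the original
report of these quantities leaves its unit undefined.

## Inference

Group construction treats each observer's encoded response within a factor
level as the unit, pooling over the other factor (one-way per factor; the
interaction is deliberately out of scope). `welch_anova()` wraps the
standard Welch statistic (weights $n_i/s_i^2$, Welch–Satterthwaite
denominator df) and adds classical $\eta^2 = SS_{between}/SS_{total}$,
labelled as such rather than inventing a Welch-specific effect size.
`games_howell()` compares each pair with $SE = \sqrt{s_i^2/n_i +
s_j^2/n_j}$, pairwise Welch df, and the studentized-range distribution
($q = t\sqrt{2}$, k groups) via R's `ptukey`, which meets the ≤ 1e-6
quantile-accuracy requirement without a hand-rolled routine. At k = 2 it
reduces to the Welch t-test; with identical groups every adjusted p is 1.
Pearson correlations between the two attribute scales are labelled strong
iff |r| > 0.6 (strict at the boundary).

## The synthetic module: what it emulates, what it does not

`make_synthetic_face()` builds an elliptical skin region at a known CIELAB
colour with Gaussian texture (default SD 2 units per channel, a realistic
magnitude for facial skin), non-skin eye/lip patches whose colours sit far
outside any plausible skin threshold box, and a dark background — enough
structure to exercise segmentation, texture extraction and recolouring
against an exact ground-truth mask. It does not attempt photorealism:
no shading, specular highlights, landmarks or pose, so segmentation scores
here (IoU ≥ 0.99) bound what thresholding achieves under ideal contrast,
not on photographs.

`simulate_responses()` draws, for each observer × stimulus × attribute, a
latent value plus observer bias plus Normal(0, σ) noise, discretised
through nine category boundaries. The latent family — linear in whiteness
(centred at W = 65) plus a Gaussian hue bump — is the simplest form that
reproduces the qualitative findings of interest (monotone whiteness
effects; a unimodal hue preference near 40°). Defaults: σ = 1 sets the
latent unit; boundaries evenly spaced on [−2, 2] so scale values span
roughly ±1, the magnitude typical of categorical-judgement z-scores; the
whiteness slope for the male face's femininity (0.035/unit) is taken from
the spread of the reported group means it emulates; per-observer bias SD
1.5 makes panel disagreement (inter-RMS) exceed repeat inconsistency
(intra-RMS), the ordering seen in real panels — note the intra-RMS
contains the trial noise twice (√2 factor), so this requires bias SD > σ.

Parameter recovery at the design size (40 observers, σ = 1, 20-point grid)
is assessed on the male-face femininity model, whose effect size is
anchored to the reported means; recovery correlates ≥ 0.9 with the truth.
Weaker latent signals (the female-face femininity model is deliberately
faint) recover proportionally less — attenuation by estimation noise, a
known limitation of desk-scale designs. Observer bias additionally
attenuates recovered values; the recovery figure quoted above uses the
default (biased) panel and still clears 0.9.

The null-calibration property (Welch rejects ~5% under no effect) is
simulated with observer bias 0: shared observer bias across factor levels
violates the independence Welch assumes and makes the test conservative in
the balanced design — visible as deflated F statistics in the default
pipeline, and another reason the printed inferential numbers of a real
panel cannot be reproduced from simulated ones.

## Numerical and design notes

- All quantile/distribution computations use base R (`qnorm`, `ptukey`,
  `pf`, `pt`); the Welch statistic itself comes from `stats::oneway.test`.
- Problem sizes: tests and the acceptance script use 100×120–160×170 px
  fixtures, 40-observer simulations, 200-replicate detectability studies
  and 10,000-replicate null calibration — sizes chosen so the full suite
  runs in well under a minute while keeping Monte-Carlo error far from the
  asserted bands.
- Ties at category boundaries in the simulator occur with probability zero
  (continuous noise); `findInterval` resolves the measure-zero case
  downward.
- The response CSV schema is validated strictly with line-numbered errors;
  duplicate (observer, stimulus, attribute, presentation) rows are
  rejected rather than silently averaged.
- Reports are deterministic given the seed: the simulator and fixture
  generators save and restore the global RNG state, so seeded stages do
  not perturb each other.

## Known limitations

- The whiteness inversion holds chroma fixed; other inverses (fix
  lightness, scale chroma) are equally consistent with the index and would
  yield different stimuli. The choice is isolated in
  `resolve_skin_color()`.
- High-whiteness stimuli are gamut-limited in sRGB (above); on a
  wide-gamut display a different clip policy would be appropriate.
- Scaling assumes equal discriminal dispersions (Case V); systematically
  heteroscedastic stimuli would need a Case III treatment, which is out of
  scope.
- Passing synthetic-data tests demonstrates correctness of the pipeline
  machinery, not that real observers behave like the latent model; in
  particular real repeatability, panel structure and hue preferences must
  be estimated from real response files.
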