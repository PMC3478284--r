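---
title: "Ploidy inference from nuclear-area cytometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ploidy inference from nuclear-area cytometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(areaPloidy)
```

## The measurement model

DNA image cytometry estimates relative nuclear DNA content from the stained
area of DAPI-labelled nuclei, exploiting the positive correlation between
DNA content and nuclear size. In coenocytic green algae such as *Caulerpa*,
absolute calibration in picograms against an external standard is often
impossible (the algal nuclei are far dimmer than standard chicken
erythrocytes), so all inference in this package runs on relative areas in
µm². Everything downstream is therefore ratio-based: rescaling all areas
and the area unit by a common factor leaves every classification unchanged.

A population of nuclei measured from one tissue produces an area histogram
with a dominant peak — G1, unreplicated nuclei, where most of the cell
cycle is spent — and a minor peak at twice its value (G2, replicated
nuclei). When somatic endopolyploidy is present, further peaks appear at
successive doublings. The analysis model is a *doubling series*: size
classes at centres proportional to integer multiples of a monoploid area
unit `c` (µm² per 1 Cx), with the multipliers drawn from doubling chains
(2, 4, 8, 16, 32 and 3, 6, 12 by default).

### Gamete anchoring

The unit is anchored in gametes, the only material whose minimum ploidy
can be asserted independently. Gamete G1 nuclei are interpreted as 2Cx
(unreduced gametes), so `c` is half the gamete G1 peak:

```{r unit}
gametes <- sample_nuclei(preset_cytotype("prolifera_gametes", seed = 1))
estimate_unit(gametes$area)
```

Because G2 nuclei carry exactly twice the G1 content, both gamete classes
inform the unit: after a provisional peak-based estimate, each gamete is
snapped to its doubling class and the unit is refined as the
count-weighted geometric mean of class mean over class multiplier. On a
26-nucleus gamete sample this roughly halves the sampling error of the
anchor. If gametes were instead reduced (1Cx), the unit would double and
every class label would halve, but no assignment would change; the
interpretation is exposed through the `gamete_cx` argument.

### Class construction

Per sample (species × thallus portion × reproductive state):

1. **Histogram.** Half-open bins of width 0.1 µm² (default), a 3-bin
   moving-average smoothing pass, and mode detection. The bin width is
   the coarsest that still separates a diploid G1 (≈0.5 µm²) from a
   triploid G1 (≈0.7 µm²). Mode centres are refined as the mean of the
   observations in the modal bin ± one bin.
2. **Family choice.** Candidate multiplier families are the doubling
   chains of the allowed set. Detected peaks are snapped to the nearest
   family member in log space and the family with the smallest mean
   squared log residual wins. Peaks of all portions of a species are
   pooled, because a single portion can be ambiguous: a G1 peak at 2.3
   units reads as diploid alone, but as triploid when its sibling
   portions place their G2 at three units. Ties go to the smaller base.
3. **Grid span.** The tallest mode defines the lowest class (the
   dominant G1 is, by construction, the minimum ploidy level). The grid
   runs from there to the highest mode, and extends further while the
   next level's predicted window holds at least `max(3, 0.5% n)` nuclei
   — a class buried in a larger neighbour's tail can be a plateau rather
   than a peak and must still be represented.
4. **Class centres.** The dominant class centre is an iterated windowed
   median (window = grid window clipped to ±30% around the running
   estimate), robust to modal-bin noise in broad classes. A minor class
   centre is the centroid of its window's bin counts after subtracting
   the expected right tail of the class below, modelled as a normal with
   centre from step 4 (processed bottom-up), spread from that class's
   uncontaminated left flank, and size twice its left-half count. Bins
   where the subtracted tail exceeds 70% of the observation are dropped;
   residuals are otherwise left unclipped so Poisson fluctuations cancel
   instead of accumulating at the shared boundary.
5. **Boundaries and assignment.** Class boundaries sit at geometric means
   of adjacent centres — the unique split consistent with multiplicative
   doubling structure, and the one that reproduces a 0.70/0.71 split
   between classes at 0.5 and 1.0 µm². Assignment is nearest centre in
   log space over half-open intervals. Records below the lowest bound
   stay in the lowest class (flagged `below_series`): smaller areas are
   measurement spread of G1, not a lower ploidy level. Records beyond the
   last class found an *extension class* at the next family multiplier
   only if they fall within ±30% of its predicted centre; otherwise they
   are flagged `out_of_series` and kept in the nearest class. The 30%
   cap sits safely inside the √2 ≈ 1.41 half-spacing of a doubling
   series.
6. **Overlap splitting.** Where adjacent somatic levels overlap, records
   inside a ±10% (multiplicative) interval around the shared boundary
   are sorted by area and split half/half between the two levels (lower
   `floor(n/2)` down, rest up), flagged `overlap_split`. The split
   emulates the manual curation applied to overlapping frond levels; the
   interval width is configurable because no published definition of
   "overlapping" exists.
7. **Cytotype.** The base multiplier is the lowest occupied level; a
   sample is endopolyploid when more than two somatic classes occur;
   bases 2Cx/3Cx are haplophasic (gamete-equivalent genome), 4Cx and
   above diplophasic. If the lowest class centre is further than 25%
   (multiplicative) from its predicted position on the grid, inference
   stops with an unresolved-cytotype error rather than guessing.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `bin_width` | 0.1 | µm² | histogram resolution; must separate 0.5 from 0.7 |
| `min_height` | 2 | counts | smallest smoothed mode accepted as a peak |
| `multipliers` | 2,3,4,6,8,12,16,32 | – | allowed Cx levels (the eight observed) |
| `overlap` | 0.1 | – | half-width of the overlap-splitting interval |
| `out_tolerance` | 1.3 | – | cap for founding extension classes |
| `gamete_cx` | 2 | – | ploidy attributed to gamete G1 (unreduced) |
| `pixel_scale` | 0.1 | µm/px | image calibration; 0.6 µm nuclei span 6 px |

The multiplier set is restricted to the eight observed levels by default
so that stray outliers cannot found arbitrarily high classes; it is fully
configurable.

## The synthetic generator

`synthetic_spec()`/`sample_nuclei()` draw per-nucleus areas from a mixture
of truncated-at-zero normal components: one component per size class,
parameterised by a centre and a coefficient of variation, with multinomial
class membership. `preset_cytotype()` instantiates the published
species × portion rows: centres are the printed class means, weights the
printed per-class counts, and dispersions the printed SDs converted to
cv = sd/mean. One class (the single-nucleus 12Cx class of the racemosa
frond) has no printed SD; it inherits the cv of the nearest class in its
row, the most local defensible imputation. Sampling is fully reproducible
from the spec's seed, and nuclei are drawn independently — the analysis
treats nuclei within a portion as exchangeable, so no within-individual
correlation is simulated.

`render_field()` draws those nuclei into a synthetic epifluorescence
field: nuclei as homogeneous anti-aliased discs, chloroplasts as larger
bodies with a bright DNA-containing rim around a dim core, bacteria as
much smaller bright dots, plus additive Gaussian noise. Ground-truth
areas are analytic (πr²), not rasterised pixel counts, which keeps the
area-accuracy checks independent of rasterisation. The default scale of
0.1 µm/pixel gives the smallest admissible nuclei (0.6 µm diameter) a
6-pixel footprint.

### What passing tests do and do not show

The generator reproduces the *statistical* structure the analysis assumes:
doubling-series mixtures with published counts and dispersions, and
fields whose confounders match the published identification criteria
(nuclei homogeneous and 0.6–4 µm; plastids larger with peripheral signal;
bacteria much smaller). It does not emulate trabeculae, epiphytes, focal
drift, uneven illumination, photobleaching, or spectral crosstalk from
bacterial autofluorescence — a single channel is rendered and bacteria
are separated by size alone. Detection figures near 100% on these fields
therefore bound the algorithmic error, not the error on real micrographs.

A deeper caveat concerns regeneration from printed summary statistics.
The printed class means and SDs are *post-classification* descriptions of
manually sorted groups. Treating them as generative component parameters
produces heavier inter-class overlap than the curated data had: with a
G1 of 389 nuclei at cv 0.35 next to a 38-nucleus class one doubling up,
roughly a fifth of the upper class's window is occupied by the lower
class's tail, and a background-subtracted centroid with oracle knowledge
of the lower component still carries a 5–7% standard error. Centre
recovery within 10% is therefore assessed for classes with at least 20
realised members, and single-nucleus classes can be absent from a
multinomial draw altogether (the realised draw, not the printed row, is
the ground truth for recovery). Likewise a 26-nucleus gamete anchor
leaves a small seed-dependent chance that a species whose G1 sits near
the boundary between two multiplier readings is assigned the neighbouring
base.

## Image quantification

Background is estimated by a robust global statistic (median + 5 MAD);
connected components above it are filled, separated by watershedding the
distance map, and each object is locally refined to the half-maximum of
its own intensity plateau, which makes the pixel area of a homogeneous
disc an almost unbiased estimate of its analytic area. Objects touching
the border are discarded (censored areas). Features per object: calibrated
area (pixel area × scale²), equivalent diameter, interior homogeneity
(1 − interior cv, clipped to [0, 1]), and the peripheral ratio (mean
2-pixel-rim over mean eroded-interior intensity). Classification follows
the morphological criteria: chloroplast if the peripheral ratio exceeds
1.5 (rim-dominant signal); bacterium if the diameter is below the 0.6 µm
nuclear minimum; nucleus if the diameter is within 0.6–4 µm, homogeneity
at least 0.5 and the peripheral ratio at most 1.5; otherwise unclassified.

## Statistics

Group comparisons mirror the published design: per-group n/mean/SD
summaries (denominator n − 1), one-way fixed-effects ANOVA across
species/phase groups, and two-sample t tests. The Student (pooled) form
is the default because every published df equals n₁ + n₂ − 2; Welch is
available by flag. The conventional significance level in this literature
is a conservative 0.001. "Minimum genome size" is the G1 subset — nuclei
in the lowest occupied class — and "first ploidy level" additionally
includes the class at twice that level. Reported p values are floored at
machine precision rather than printed as exact zeros.

## Worked example

```{r pipeline, eval = FALSE}
report <- run_pipeline(run_config(seed = 1))
report$analysis$group_profiles
report$table1
report$anova_min_genome
```

At seed 1 this regenerates all ten published rows (3156 nuclei), anchors
the unit at ≈0.237 µm²/Cx, and recovers four cytotypes: diploid
reproductive *C. prolifera* (with somatic classes up to 16Cx), tetraploid
sterile *C. prolifera* (4–32Cx, endopolyploid), triploid *C. racemosa*
var. *cylindracea* and diploid *C. taxifolia* (two classes only, no
endopolyploidy).

## Numerical choices and degenerate inputs

* Ties between equally tall histogram modes resolve toward the smaller
  area (G1 precedes G2), with a warning; a flat histogram is an error.
* An empty image or a constant image yields an empty detection table, not
  an error; an empty area vector is an error.
* Two constant, equal samples give t = 0, p = 1 rather than an error.
* A single class spans all positive areas; outer boundaries of larger
  grids extrapolate the ratio to the missing neighbour geometrically.
* The printed 3Cx "approximation" of 0.7 µm² sits below the arithmetic
  3 × 0.25 = 0.75 because the triploid G1 was anchored on its measured
  mean; class centres here are likewise empirical, with the arithmetic
  grid used only for prediction and extension, so both conventions
  coexist without conflict.
* All randomness flows from explicit seeds; identical configuration and
  seed give byte-identical machine-readable reports.

## Problem sizes

The test suite regenerates every published row at its printed count
(3156 nuclei total), runs the assignment oracle on 100 random populations
of up to 200 nuclei, and scores detection on 20 rendered 512×512 fields
of 20 nuclei with chloroplast and bacterium confounders; the full suite
completes in well under two minutes on one CPU.

## Known limitations

* Cytotype identification is only as strong as the gamete anchor; for
  taxa without reproductive material the unit must be supplied.
* The boundary-based procedure deliberately avoids mixture-likelihood
  fitting; when two classes overlap heavily the half/half overlap split
  is a coarse curation rule, and class means inherit its bias.
* Bacteria are separated by size only; a bright sub-0.6 µm nuclear
  fragment would be miscounted as a bacterium.
* No 3-D stacks, no multi-channel unmixing, no absolute genome sizes.
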