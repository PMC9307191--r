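---
title: "Quantifying leaf greenness from palette-quantized canopy images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leaf greenness from palette-quantized canopy images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafgreen)
```

## The problem

Soil disinfestation trials (for example steam versus a chloropicrin fumigant
versus an untreated control in strawberry beds) need a plant-health readout
that is fast, non-destructive and robust to camera position. Plant size and
green *area* are sensitive to distance and angle; the *degree of greenness*
within the green leaf area is not. Healthy, well-nourished leaves are dark
green (high chlorophyll), stressed leaves are light green. `leafgreen`
implements a pipeline that turns ordinary RGB canopy photographs into a small
set of interpretable greenness statistics and treatment comparisons suited to
very small numbers of field plots.

## The method

**Color tables.** Each photograph is reduced to a coarse palette (default at
most 256 colors, the GIF palette size) and summarized as a table of RGB codes
with pixel counts. `quantize_image()` uses median-cut quantization without
dithering: dithering would scatter pixel mass across fabricated intermediate
codes, which is exactly what a count-based analysis must avoid. Because the
palette that produced any particular historical data set is usually unknown,
a user-supplied fixed palette is also accepted; pixels are then mapped to the
nearest palette code in Euclidean RGB distance with ties broken by the lowest
palette index, so the mapping is deterministic.

**Green classification and weights.** A palette code $(R_i, G_i, B_i)$ is
*green* when $G_i > R_i$ and $G_i > B_i$, both strict; grays and equalities
are excluded. With $A_i$ the pixels of the $i$-th green code, the weights are
$W_i = A_i / \sum_j A_j$, so they describe composition *within* the green
area only — the property that makes the statistics insensitive to plant size
and camera distance. Five pixel-weighted statistics summarize a profile:
$\sum W_i R_i$, $\sum W_i G_i$, $\sum W_i B_i$, $\sum W_i R_i/G_i$,
$\sum W_i B_i/G_i$. The ratio statistics are means of per-code ratios (not
ratios of means), lie strictly below 1 for green profiles, and approach 0 for
dark canopies. Darkness is ordered by the index $(R+B)/G$: the canonical dark
green $(0,43,0)$ scores 0 and the canonical light green $(102,128,102)$
scores $204/128 = 1.59375$, whence its R/G = B/G value of
$102/128 = 0.796875 \approx 0.80$. Note that the conventional dark-to-light
listing of the five common codes swaps the middle pair relative to this
index; no standard darkness metric reproduces that listing, so the package
always orders by the index and lets users supply an explicit code list when a
fixed convention matters.

By default `build_profile()` can keep the `top_k` most abundant green codes
(the field convention is the five most common ones), with ties broken by
darkness and then lexicographic RGB order so truncation is reproducible.

**Bootstrap.** The sampling distribution of each statistic is approximated by
resampling codes with probability $W_i$: each of `n_rep` replicates (default
2000) draws `n_draw` codes i.i.d. from the categorical distribution
$\{W_i\}$, realized as one multinomial count vector, and recomputes the
statistics from the empirical weights. Intervals are percentile bootstrap
intervals at level $1-\alpha$ (default 95%), using R's default
linear-interpolation quantile; the percentile construction is the simplest
one consistent with reporting "bootstrap confidence intervals" and is
isolated in `ci_percentile()` so it can be swapped. Treatment contrasts
difference the replicate vectors of independently resampled groups pairwise
by replicate index, which makes contrasts exactly antisymmetric. `n_draw` is
a genuine modeling choice the source analyses leave open (codes versus
pixels per draw); the default resamples the profile's own green pixel
population at its own size — the standard nonparametric bootstrap — capped at
$10^5$ draws, and is configurable so the sensitivity can be examined. No
multiplicity adjustment is applied across the five statistics.

**Dark:light ratio and mixed model.** The headline health index is the pixel
ratio of the designated dark code to the designated light code; values above
1 indicate a darker, healthier canopy. Images missing either code are flagged
and excluded from modeling (a Haldane-style +0.5 correction is available but
off by default, since fabricating counts changes a ratio statistic more than
dropping a degenerate image does). The log (base $e$; the base is a
convention, not an estimate) of the ratio is compared across treatments with
a linear mixed model: fixed effects `treatment * month` with month
categorical, and a random intercept per plot for the repeated monthly
observations of each experimental unit, fitted by REML with
`lme4`/`lmerTest`. Treatment contrasts are averaged over months and tested
with Satterthwaite denominator degrees of freedom — a small-sample correction
appropriate for 4 plots per treatment. When every plot contributes a single
observation the random intercept is confounded with the residual and the
model reduces to ordinary least squares; the package detects this and fits
`lm()`, in which case the balanced two-treatment contrast reproduces the
pooled-variance two-sample t test exactly. Residual normality (the
assumption the log transform is meant to secure) is checked with the
Shapiro–Wilk test. Yield is related to the first-month (May) ratio by
ordinary least squares of cumulative grams per plant on the ratio, reporting
slope, intercept and $R^2$.

## The synthetic trial generator

No photographs accompany the original field trials, so the package ships a
generator, `simulate_trial()`, that emulates their design: 3 treatments
(control, steam, chloropicrin) × 4 plots × 3 months (May–July) × 2 trial
years, with one image per plot-month. Each treatment has a mixture over the
five common green codes; the defaults make steam and chloropicrin
dark-dominant (expected dark:light ratio above 1) and the control
light-dominant (below 1), mirroring the qualitative pattern reported for
disinfested versus untreated beds — the exact field proportions are unknown
and not claimed. Plot effects are drawn once per plot and applied on the
mixture logits along a centered dark–light score axis, so a plot effect of
size $b$ shifts the plot's expected log dark:light ratio by exactly $b$ and
ratios remain positive by construction; month effects (default 0, 0.2, 0.4
for May–July: canopies darken as the season progresses) act on the same
axis. Image-to-image jitter is a Dirichlet perturbation of the mixture
(concentration 200 by default, which puts the residual SD of the log ratio
near 0.3, a realistic within-plot month-to-month variation), pixels are
allocated multinomially ($10^5$ green pixels per image), and non-green
background codes (a fruit red and a soil brown, 30% of the image) are
appended so the green filter has something to remove. Yield follows
$\text{g/plant} = 1000 + 400 \cdot \log(\text{May ratio}) + \varepsilon$,
$\varepsilon \sim N(0, 150^2)$, scaled to the magnitudes typical of
strawberry yield trials (roughly 1000 g/plant in untreated beds, substantially
more after disinfestation).

`simulate_ratio_records()` generates log-ratio records directly (treatment
effects 0/1/1, plot SD 0.2, residual SD 0.3 by default) for studies of the
mixed model alone, and `render_image()` turns any color table back into a
raster so the quantizer can be exercised end to end: rendering and
re-quantizing under a palette containing the table's codes is the identity.

What the generator does *not* emulate: spatial structure within an image
(pixels are exchangeable), lighting gradients, camera noise, occlusion and
segmentation error, or block structure in the field layout. Tests passing on
synthetic trials therefore validate the statistical machinery and its
contracts, not the photographic front end on real canopies.

## Numerical choices and edge cases

- Quantization is deterministic: median-cut always splits the box with the
  widest channel range at the pixel-weighted median, ties in sorting resolved
  lexicographically; an image with no more colors than the palette size is
  returned unchanged.
- Weights are renormalized after every construction, truncation and pooling
  step and sum to 1 within `1e-12`; all statistics are invariant to scaling
  every pixel count by the same factor.
- A single-code profile is a degenerate categorical distribution: bootstrap
  replicates are constant and intervals have zero width, by design rather
  than by error.
- Seeds are applied with `withr::with_seed`, so seeded calls are bit
  reproducible and never disturb the caller's RNG stream.
- Tables with no green codes raise an error that lists the dominant non-green
  codes, the most useful diagnostic when a segmentation upstream has failed.

## Validation, and what the simulations show

The test suite checks the two worked single-code values (R/G = B/G =
0.796875 for the light code, 0 for the dark code), the equivalence of the
weighted statistics with brute-force per-pixel means on random tables,
percentile-interval coverage for mean R/G (nominal 95%, required within
92–98% over 500 simulated profiles at 5000 draws and 500 replicates — sizes
chosen to give a stable Monte Carlo estimate at desk scale), mixed-model
type-I error for a null contrast (required within 1–10% at nominal 5% over
200 replicates), the qualitative treated-versus-control pattern on the
default trial, and all round-trip identities.

One documented expectation is knowingly not met: requiring the
treated-versus-control effect estimate to fall within ±0.2 of the true value
in at least 90% of replicates is incompatible with the generating design
itself. In the balanced default design the contrast estimator's standard
error is $\sqrt{2(\sigma_p^2/4 + \sigma_e^2/12)} = 0.187$ with plot SD 0.2
and residual SD 0.3, so the within-±0.2 probability is about 71% — a property
of the design (4 plots per treatment), not of the estimator, which the same
simulations show to be unbiased with the predicted spread. The corresponding
test states the 90% requirement and fails; it is retained deliberately as a
record of the discrepancy.

## Limitations

- The palette of any particular historical imaging tool is unknown; raw
  photographs quantized with median-cut are not guaranteed to reproduce a
  specific code set such as the five common greens. Supply a fixed palette
  when comparability with legacy tables matters.
- The green rule is a linear inequality in RGB; it does not separate green
  vegetation from green non-vegetation and is no substitute for segmentation.
- With 4 plots per treatment, power for plot-level comparisons is inherently
  low; the bootstrap over pixels sharpens *color* comparisons but cannot
  manufacture plot-level replication.
- GIF input is not supported (no installed reader); use PNG/JPEG/TIFF or
  pre-computed CSV color tables.
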