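# vesselfractal

Scale-resolved fractal morphometry of blood-vessel architecture in
CD31/DAB-immunostained histology, for pathology image-analysis groups
who need to quantify vascular *organization* — not just vessel density —
across annotated tissue regions (tumoral, peritumoral, non-tumoral) of
whole-slide images.

## What it computes

Starting from an RGB tile with a known pixel spacing (0.5 µm/px for the
slides this package targets), `vesselfractal`:

1. **Segments vessels** with a deterministic colour gate: non-brown
   pixels (dominant G/B channel, or HSV hue outside 20–40°) are
   whitened, the blue channel is binarized at 220, an adaptive median
   filter (aperture 15 px on bright/noisy tiles, else 5 px) removes
   chromogen debris, and dilation → hole-filling → erosion completes the
   vessel lumina. Quality against a reference mask is reported as Dice
   `2|P∩R|/(|P|+|R|)` and PPV `|P∩R|/|P|`.
2. **Box counting.** For box sizes *s* on a fixed grid, `N(s)` = number
   of boxes containing vessel pixels. The scale-resolved fractal
   dimension is the negative local log–log derivative,
   `D_f(s) = −d log N / d log s`, read out at physical scales (1, 16,
   128 µm).
3. **Hurst index.** Every maximal background run bounded by vessels on
   both ends along a row or column scan is a *lag*; ordinary least
   squares of `log10 count` vs `log10 lag` over a 20–200 µm window gives
   a slope whose magnitude is `2H`. For ideal planar fractals
   `D_f = 2 − H`; the package tests this as a consistency property.
4. **Vessel shapes.** Per 8-connected component: area *A*, Crofton
   perimeter *P*, and the equal-area-circle perimeter
   `P* = 2√(πA)` (`P ≥ P*` by the isoperimetric inequality). The density
   of `(log10 P, log10 P*)` — the perimeter plane — separates round from
   elongated vessel populations.
5. **Regional statistics.** Whole slides tile at 1024 px; tiles take the
   label of the GeoJSON annotation polygon covering ≥95 % of their area
   (necrotic overlap excludes a tile outright); groups are compared with
   two-sided Mann–Whitney U tests banded at p < 0.001 / < 0.05 / > 0.1.

Because no public slide archive exists for this task, a synthetic module
(`generate_vessel_tile()`, `generate_ideal_fractal()`,
`generate_powerlaw_gap_pattern()`) renders DAB-like tiles with exact
ground-truth masks, ideal fractals of known dimension, and gap patterns
with prescribed power-law exponents, so every estimator is validated
against constructions whose answer is known.

## Worked example

```r
library(vesselfractal)

# a synthetic DAB tile with ground truth, 1024 px at 0.5 um/px
out <- generate_vessel_tile(non_tumoral_like_spec(seed = 1), 1024)
seg <- segment_vessels(out$tile)
dice_ppv(seg, out$mask)
#> $dice
#> [1] 0.9881301
#>
#> $ppv
#> [1] 0.9870417

profile <- local_dimension(box_count(seg))
df_at_scale(profile, 16)      # fractal dimension at a 16-um box
#> [1] 1.352608

fit_hurst(collect_lags(seg))  # lag-distribution Hurst fit, 20-200 um
#> <hurst_estimate> H = 0.7991 (2H = 1.5981), window 20-200 um, n = 347, R2 = 0.759
```

The Dice/PPV near 0.99 say the colour gate recovers the rendered
vessels almost exactly (real slides, with texture and focal blur, score
lower). `D_f ≈ 1.35` at 16 µm is the mesoscale dimension — the scale at
which tissue architectures separate most clearly, higher for layouts
rich in small round vessels. The Hurst fit on this single dense tile is
steep (`2H ≈ 1.6`): long lags are scarce inside one 1024-px tile, which
is why the pipeline pools lag histograms over all tiles of a region
before fitting, and why the anti-persistent regime (`H < 0.5`) emerges
for sparser architectures and larger analysis regions (see the methods
vignette).

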