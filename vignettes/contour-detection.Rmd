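---
title: "A hierarchical surround-modulated contour detector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical surround-modulated contour detector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiercontour)
```

## The model

`hiercontour` detects region boundaries in colour images with a cascade
modelled on the early primate visual system. Contour detection differs from
edge detection: texture *inside* a region produces strong local edges that
must be suppressed, while the (possibly weaker) boundary between regions
must be kept. The cascade has three feedforward stages and one lateral
(surround) stage:

1. **Retina/LGN** (`single_opponent()`). The image is smoothed with an
   isotropic Gaussian of scale $\sigma$ and combined into two opponent
   signals, $U_{rg} = I_r * G + w\, I_g * G$ and
   $U_{by} = I_b * G + w\, I_y * G$ with $I_y = (I_r + I_g)/2$ and a
   negative retina-to-ganglion weight $w$. Each signal is split into a
   half-wave rectified on/off pair (`rg`/`gr`, `by`/`yb`), modelling the
   four single-opponent cell types. For achromatic input the pair carries
   $(1+w)\,I$: with $w = -1$ luminance cancels exactly, with the default
   $w = -0.8$ a fifth of it passes, so both chromatic and achromatic
   boundaries reach V1.

2. **V1** (`v1_response()`). A bank of $N$ oriented first-derivative-of-
   Gaussian filters $V(\theta_i)$ (width $k\sigma$, aspect $\lambda$)
   models double-opponent simple cells. Each channel combines the two
   opposite-polarity LGN inputs,
   $E(\theta_i) = \lfloor S^{+} * V \rfloor + \lfloor S^{-} * (-V) \rfloor$,
   complex cells take the MAX over orientations, and the result is
   self-normalised, $D = \tilde E^2 / (\max \tilde E^2 + \varepsilon)$,
   bounding responses in $[0, 1)$ independently of image contrast.

3. **V2** (`v2_pool()`, `combine_feedforward_feedback()`). Each channel is
   pooled with an elliptical Gaussian whose long axis ($\sigma'$) follows
   the local contour tangent, integrating collinear evidence. The four
   channels are combined as $\sum_c V2_c + \max_c V2_c$: the sum is the
   feedforward stream, the across-channel maximum a one-shot global-shape
   feedback that reinforces the channel carrying the contour.

4. **Surround modulation** (`surround_weights()`, `detect()`). A
   non-classical-receptive-field annulus — the rectified difference of two
   Gaussians, $\lfloor G(\rho\sigma) - G(\sigma)\rfloor$, L1-normalised
   ($W_d$) — weights three similarity cues between a pixel and its
   surround: local luminance ($W_L$), local luminance contrast ($W_C$),
   both Gaussians of the feature difference with scale $\sigma_1$, and
   colour-orientation difference ($W_\theta$, scale $\sigma_2$), computed
   from centre vs. surround means of the orientation stacks. Where the
   coarse-minus-fine response difference $\Delta D$ is non-negative the
   pixel is treated as internal texture and the *strongest* suppression
   weight applies; otherwise the *weakest*. The final map is
   $CD = \lfloor D_\sigma - \alpha\, W\, (D_\sigma * W_d)\rfloor$.

Post-processing (`non_maxima_suppress()`, `hysteresis_binarise()`) thins
the map along the local edge normal and optionally binarises it with
quantile hysteresis. `pr_curve()` scores any response map against boundary
ground truth with distance-tolerant one-to-one matching.

## Parameters

| name | meaning | unit | default |
|------|---------|------|---------|
| `w` | retina-to-ganglion opponent weight | — | −0.8 |
| `sigma` | classical receptive field scale | px | 1.1 |
| `k` | V1/LGN receptive-field size ratio | — | 2 |
| `lambda` | V1 filter aspect ratio | — | 0.5 |
| `n_orient` | orientations in the V1 bank | — | 6 |
| `rho_dog` | NCRF/CRF diameter ratio | — | 4 |
| `window_size` | local-statistics window side | px | 11 |
| `sigma1` | luminance/contrast attenuation | feature units | 0.05 |
| `sigma2` | orientation attenuation | response units | 0.2 |
| `alpha` | texture attenuation factor | — | 1.0 |
| `sigma_prime` | V2 pooling long axis | px | 2·`sigma` |
| `scale_factor` | coarse/fine scale ratio | — | 2 |
| `eval_tol_frac` | matching tolerance | fraction of diagonal | 0.0075 |

`w` and `alpha` are the two free parameters a user would tune per image
collection; everything else is anatomy-derived and fixed. The tuning probe
(`tuning_profile()`) uses 36 orientations; the pipeline itself uses 6.

## Design choices at genuinely open points

Several details are under-determined by the published description; the
package settles them as follows, preferring the reading that keeps every
stated property of the model true at once.

* **Rectification in the V1 double-opponent combination.** The two
  sub-fields could be wired with the rectified kernel lobes as separate
  non-negative kernels, or with the signed kernel and rectified responses.
  The lobes reading gives a constant positive pedestal on uniform input
  ($c \sum \lfloor V\rfloor$), which contradicts the model's own
  requirements that a structureless image has (near-)zero response — the
  "white wall" case that $\varepsilon$ exists to guard — and that tuning
  profiles inside uniform regions are flat at zero. The package therefore
  rectifies the responses:
  $E = \lfloor S^{+} * V\rfloor + \lfloor S^{-} * (-V)\rfloor$. Since $V$
  integrates to zero, uniform input produces exactly zero response.

* **Scale of the colour-orientation comparison.** $\sigma_2 = 0.2$ only
  discriminates if the orientation responses entering the centre–surround
  comparison are of order one. Raw oriented responses of a $[0,1]$ image
  are of order $10^{-2}$, which would leave $W_\theta \approx 1$
  everywhere and disable the orientation cue. The stacks are therefore
  normalised to unit scale (`normalise_stack()`, division by the global
  stack maximum — linear, not squared, so moderate responses keep their
  relative weight) before `colour_orientation_map()` feeds the surround
  comparison.

* **The surround annulus ratio.** A ratio below 1 turns the rectified
  difference of Gaussians into a centre blob rather than an annulus,
  contradicting the anatomy it models (a surround 2–5× the CRF diameter);
  the default is `rho_dog = 4`. The degenerate ratio 0.4 remains available
  through `strict_paper`/`strict` flags so its behaviour is demonstrable.

* **The elliptical cross term.** The product-form $y^2$ coefficient that
  sometimes appears for rotated Gaussians is dimensionally inconsistent
  with the other two coefficients; the standard rotated-Gaussian sum form
  is used (and the product form again kept behind `strict`).

* **Normalisation denominator.** The V1 self-normalisation uses the global
  per-channel maximum of the squared pooled response. A per-position
  denominator was rejected: with an "extremely small" $\varepsilon$ it
  saturates every non-zero pixel to 1. The global form is scale-invariant
  but lets one dominant structure (e.g. a saturated chromatic edge)
  compress all weaker responses in its channel — a real property of the
  model, visible in the cluttered-scene fixture.

* **Boundary matching.** Greedy nearest-first one-to-one matching stands
  in for min-cost bipartite assignment; on desk-scale fixtures without
  dense parallel structure the two coincide.

## Numerical conventions

Matrices are indexed `[row, col]` with x rightward, y downward, and angles
counter-clockwise from +x. All filtering is cross-correlation with mirror
(symmetric) border padding, so constant fields are fixed points of every
unit-sum kernel; since the orientation bank sweeps the full circle,
correlation versus convolution is immaterial. Kernels are truncated at 3
standard deviations and renormalised. Gaussian kernels sum to 1 within
1e-12 and derivative kernels to 0 within 1e-10. Linear rescaling to
$[0,1]$ treats fields whose range is below 1e-12 as constant (mapping to
zero) so FFT noise is never amplified. The local-contrast denominator
$L^2$ is floored at 1e-4 in dark regions. The $\Delta D \ge 0$ sign test
is discontinuous at its tie: pixels with $\Delta D \approx 0$ may switch
between the max- and min-weight branches under tiny perturbations (for
example a sub-pixel translation), which bounds but does not eliminate
response differences there.

## The synthetic fixtures, and what passing them shows

The generators (`make_grating()`, `make_textured_square()`,
`make_isoluminant_edge()`, `make_two_tone_edge()`,
`make_cluttered_scene()`) are pure functions of their arguments with exact
ground truth, sized for desk-scale runs (64–128 px): gratings probe
orientation tuning; the textured square is a pure second-order boundary
(orientation contrast only, density-matched, bar density 0.08 and length
7 px); the isoluminant edge has zero luminance gradient by construction;
the cluttered scene emulates a natural scene's structure — toned regions
(salient first-order perimeters) filled with disorderly random-orientation
bar texture, plus one isoluminant red/green patch.

They are parametric stimuli, not natural images: no 1/f statistics, no
shading, no annotator disagreement, no object occlusion. Passing the suite
shows the mechanisms behave as specified (tuning, opponency, bounds,
suppression geography, evaluation algebra); it does not certify benchmark
performance on photographic datasets, for which the evaluation harness
accepts user-supplied images and annotator masks.

Two structural observations from the ablation fixtures are worth stating
plainly, because the component-wise F ordering expected of the full model
does not fully materialise on them. On the pure second-order square, the
surround release zone has the spatial grain of the NCRF annulus (several
pixels), while the desk-scale matching tolerance is about one pixel, so
inhibition — although correctly weaker on the boundary (the suppression-
geography checks pass) — cannot raise best-threshold F above the raw
fine-scale map. On sparse bar textures, V2's elongated pooling
($\sigma' = 2\sigma$, support comparable to the 7-px bars) lengthens each
bar's response crest almost as much as it reinforces long contours, so the
V2-less variant can score slightly higher there; the noise-scale patches
that elongated pooling removes on natural images are absent from these
stimuli by construction. Both effects are properties of the model on these
stimulus classes and are reported as-is by the ablation tests rather than
smoothed over.

## Problem sizes

The test suite and the acceptance script run the full pipeline on 64–128
px fixtures (a 96×96 detection takes on the order of a second), with 25
threshold levels per precision-recall sweep and a 16×16 image for the
literal nested-loop surround oracle. These sizes were chosen so the whole
suite exercises every stage, both scales, and all ablations in well under
a minute of compute per fixture.

## Known limitations

* Uniform chromatic regions excite a tonic single-opponent response; only
  its spatial structure (not its mean) reaches the contour map, but a
  strongly saturated colour region still dominates its channel's global
  normaliser.
* The surround stage assumes the fine scale for all weights; no per-pixel
  scale selection is attempted.
* Hysteresis parameters (`p`, `low_ratio`) are exposed but not
  auto-calibrated; evaluation defaults to the non-binarised thinned map.
* BSDS-style `.mat` ground truth is out of scope; masks are supplied as
  PNG or 0/1 text matrices.
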