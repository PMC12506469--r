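---
title: "Quantifying mycelial biofilm and bacterial attachment in SEM micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mycelial biofilm and bacterial attachment in SEM micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Scanning electron micrographs of fungal–bacterial cocultures show three
kinds of structure: wide tubular hyphae (here about 2.3–4.5 µm across),
rod-shaped bacteria attached to their surfaces (lengths about 0.5–2.6 µm,
widths 0.25–0.85 µm), and thin curvilinear strands of exopolymeric
substances (EPS) — the residual biofilm matrix, including the ~0.3 µm
attachment structures that anchor bacteria to hyphae. `epsquant`
quantifies all three: how much of the field the EPS covers, and the
dimensions of the cells and of the attachment structures.

The pipeline is: grayscale conversion and min–max intensity
normalization, Hessian-eigenvalue ridge detection over a scale sweep,
Otsu thresholding of the response into a biofilm ("vessel") mask,
segmentation of the detected material into hyphae / bacteria / residual
EPS, and micron-unit morphometry with exclusion of partially visible or
deformed cells.

## The ridge model

Let $I$ be the image. At smoothing scale $\sigma$ the Hessian

$$H = \begin{pmatrix}
\partial^2 I/\partial x^2 & \partial^2 I/\partial x \partial y \\
\partial^2 I/\partial y \partial x & \partial^2 I/\partial y^2
\end{pmatrix}$$

is computed by separable convolution with Gaussian-derivative kernels
(reflect boundary). With eigenvalues ordered $|\lambda_1| \le
|\lambda_2|$, a bright ridge is a locus where intensity varies slowly
along the structure ($\lambda_1 \approx 0$) and is strongly concave
across it ($\lambda_2 \ll 0$). The response is the hard-conditioned
form

$$R = \begin{cases}|\lambda_2| & \text{if } \lambda_1 \approx 0 \text{ and } \lambda_2 \ll 0\\ 0 & \text{otherwise.}\end{cases}$$

The two qualitative conditions are made operational by two parameters:
$|\lambda_1| \le \alpha\,|\lambda_2|$ with $\alpha = 0.25$ by default
(a relative test, so the condition is invariant to intensity rescaling)
and $\lambda_2 < -\tau$ with $\tau = 0$ (any strict concavity; noise
rejection is left to the response threshold). This hard-conditioned
response — not the smooth classical vesselness — is deliberately the
reference behavior. The smooth variants are out of scope.

Kernels are moment-calibrated after sampling so the discrete operator
is exact on quadratics (a constant image gives exactly zero, $I = x^2$
gives $\partial^2 I/\partial x^2 = 2$ at any $\sigma$); without this,
truncation bias at small $\sigma$ is a few percent.

### Scale sweep

Single-scale detection at $\sigma = 1$ px picks out the thin EPS
strands; the sweep $\sigma \in [1, 50]$ px (10 geometrically spaced
scales, $\sigma^2$-normalized so responses are comparable across
scales, per-pixel maximum with the attaining scale recorded) responds
to every structure from sub-pixel filaments to the widest hyphae.
Geometric spacing is standard scale-space practice; without
$\gamma$-normalization the maximum would always be attained at the
smallest scale. $\sigma$ is in pixel units throughout.

## Segmentation

The response map is thresholded by Otsu's criterion on a 256-bin
histogram (a manual threshold can be supplied instead); pixels strictly
above threshold are biofilm ("vessel") pixels. The paper-level chain
then separates biofilm from the cells:

1. A *three-class* Otsu on the grayscale image yields two thresholds
   separating background, mid-bright EPS material, and bright cell
   bodies. The cell mask (above the upper threshold) is despeckled by a
   1 px opening and pixel-noise holes are filled — a single false
   background pixel would otherwise void an entire structuring disc
   under the wide erosion that follows.
2. Hyphae: a disc opening of radius half the minimum hyphal width
   (default 1.5 µm) removes everything narrower; components must also
   be elongated, measured as area / (2 × max inscribed radius)², which
   stays large for two crossing tubes merged into an X.
3. Bacteria: remaining cell components survive a small opening and are
   vetted as rods by moment-ellipse length (default range 0.25–3.0 µm,
   spanning the observed 0.53–2.6 µm with margin), width (0.2–1.0 µm),
   and solidity ≥ 0.8 ("approximately convex"); failures are labeled
   `excluded`.
4. EPS is residual — what the ridge filter detected that is not part of
   any cell. The thresholded ridge response reliably covers a
   filament's centerline but not its full photometric width, so the
   mid-brightness band (between the two grayscale thresholds) provides
   the spatial extent, and band components are kept when they contain
   ridge-detected seed pixels. Coverage is then computed at the
   photometric width of the material rather than the (narrower) ridge
   support.

Area and coverage follow the vessel-pixel formulas exactly:
$A_v = \text{vessel\_pixels} \times \text{scale}^2$,
$A_t = M N \times \text{scale}^2$,
$P_v = 100\,\text{vessel\_pixels}/(MN)$, with scale in µm/px from a
per-image pixels-per-micron calibration file (an explicit JSON sidecar;
vendor TIFF metadata dialects are unstable, so they are not parsed).

## Morphometry

* **Rods** — length and width are the axis extents of the region's
  second-moment ellipse (with the 1/12 unit-square correction), robust
  to boundary pixelation; `length >= width` is enforced.
* **Tube width** — twice the distance-transform value sampled along the
  region's medial axis (the ridge of the Euclidean distance transform).
  Samples limited by the image frame rather than by the tube's own
  boundary are dropped, since hyphae run out of the field. Because
  hyphae frequently cross within a field, the samples from one merged
  component are a mixture of per-tube width modes; a one-dimensional
  Gaussian mixture (fitted for 1–6 components, preferring fits whose
  components are tight, since a real tube has near-constant width)
  separates them, and the component width is the unweighted mean of the
  mode centers. Modes implying a width no single hypha can have
  (default bound 5 µm, carrying margin over the observed ≤ 4.5 µm, like
  the rod bounds) are crossing-region plateaus — the inscribed disc at
  a crossing spans both tubes — and are split once and discarded.
* **Attachment structures** — for every bacterium with adjacent EPS,
  the geodesic path along the EPS skeleton from that bacterium to a
  hypha, extended by the end gaps, measured with calibrated digital
  step weights (0.948 / 1.343; plain 1/√2 chain-code weights
  overestimate digitized curve length at intermediate orientations).
  Among admissible connectors the most direct (lowest
  length-to-chord ratio) set is considered and the shortest of those
  taken: a raw minimum over all routes would bias short, while
  directness alone admits long quasi-straight detours. Paths longer
  than 1.5 µm or more tortuous than 1.6 are not attachment structures.
  Working per bacterium keeps the measurement well defined when EPS
  strands fuse into one connected network. Attachments are traced on
  the photometric band rather than the ridge-confirmed mask because a
  short filament squeezed between two bright cell walls has no ridge
  response at all — the along-structure eigenvalue is dominated by the
  walls.
* **Exclusion** — objects whose bounding box touches the frame are
  flagged `partial`; bacteria with solidity < 0.8 are `deformed`.
  Occlusion cannot be detected automatically and is approximated by the
  border rule. The border rule is not applied to hyphae: a tube always
  runs out of the frame, and its measured quantity (local width) is
  unaffected by truncation. Flagged objects stay in the tables but are
  omitted from all summaries.
* **Summaries** — per-sample and pooled mean ± population SD
  (`ddof = 0`, configurable); a single value gets SD 0; an empty metric
  is reported with `n = 0` and `NA`, never silently zero.

### Boundary conventions and calibration

Measuring lengths at the 0.05 µm/px working resolution needs sub-pixel
care. Two conventions are exposed. For crisp masks, widths are
`2 d − 1` (to the far side of the last foreground pixel) and attachment
end gaps are center-to-center distances minus half a pixel. For masks
obtained by thresholding a blurred image — the pipeline's case — the
mask boundary sits about half a pixel inside the true surface per side,
so boundary-pixel *centers* track the surface: widths are `2 d` and end
gaps are plain center-to-center distances. The pipeline's conventions
were validated on rendered reference objects of known dimensions
(single tubes, and single filaments in otherwise empty scenes), the
image-analysis equivalent of measuring a calibration standard: they
remove a systematic ≈ 1 px underestimate without using any knowledge of
the generator's blur or thresholds at analysis time.

## The synthetic scene generator

The original micrographs are not publicly deposited, so every stage is
validated against generated scenes with exact ground truth. The
generator's defaults are the study conditions: rod lengths
1.4 ± 0.4 µm truncated to the observed [0.53, 2.6] µm, rod widths
0.5 ± 0.1 µm truncated to [0.25, 0.85] µm, coculture hyphal widths
3.0 ± 0.5 µm truncated to [2.3, 4.2] µm (normals truncated to the
printed minima and maxima honor all four reported statistics),
attachment filaments 0.3 ± 0.1 µm (truncated to [0.1, 0.6] µm, about
±3 SD) and 0.08 µm wide, and an EPS coverage target of 18.33 %.

Scenes are built in continuous coordinates: smooth wavy tube
centerlines (a course is redrawn when it would run along — or hug
within 4 px of — an existing tube, since fields where hyphae are
indistinguishable are not measurable and a sub-resolution gap fuses
under blur; point crossings are fine and are handled by the mixture
estimator); rods placed broadside along the tube surface, attached rods
at exactly their filament's length from it (with the clearance
enforced, so the drawn filament is the rod's closest connection, as a
visible anchoring strand would be); filaments as quadratic arcs of
exact recorded arc length; then random-walk EPS strands (2–8 µm long,
0.08 µm wide) added until the coverage target is within one strand of
being met (a warning reports the achieved coverage if the placement
budget runs out first). Rendering is per-class intensity plateaus
(background 0.05, EPS 0.45, hypha 0.70, bacterium 0.85), a 0.5 px
Gaussian blur, and additive Gaussian noise (SD 0.05, about SNR 8 for
the faintest class) — sufficient to exercise thresholding and ridge
detection; it is deliberately not a physical SEM simulation (no
charging, edge effect, or detector noise model). Truth masks come from
the same geometry before degradation, carved disjoint with priority
bacterium > hypha > EPS, and the whole scene is a deterministic
function of one seed.

Default raster: 1024×1024 px at 20 px/µm (a ≈ 51 µm field), which puts
the 0.08 µm filaments at ≈ 1.6 px — near the detectability limit, as in
the real data. The validation and acceptance runs in this package use
512×512 px at the same 20 px/µm (a 25.6 µm field, 20 scenes), and the
workflow's triplicate emulation uses the same size; these are
problem-size choices that keep the ensemble large at the same
resolution and local geometry.

What passing these tests does *not* show: robustness to real SEM
artifacts (charging halos, drift, dehydration collapse, depth
occlusion), to uneven illumination, or to 3-D structure — all
measurements are 2-D projections, a recorded divergence from
measurements that account for the sample's three-dimensional
structure.

## Numerical choices

* Reflect (half-sample symmetric) boundary for every convolution;
  avoids spurious border ridges.
* Eigenvalues by the closed form for symmetric 2×2 matrices;
  magnitude-ordered, ties broken toward the more positive value as
  $\lambda_1$.
* Otsu ties take the lowest maximizing bin edge (determinism); an
  all-zero response yields an empty mask with a warning, not an error;
  a constant image is a degenerate-input error for the threshold but
  normalizes to zeros (with a warning) on load.
* Connected components are 8-connected throughout — thin diagonal
  filaments must not fragment.
* Components under 10 px are dropped as noise.
* The coverage placement loop stops within one strand (≈ 0.1 % of the
  field) above target, so achieved truth coverage sits in
  [target, target + 0.2] against a ±1 point contract.

## Known limitations

* Two hyphae fused side by side over a long run are reported as one
  structure; the mixture estimator handles point crossings, not
  bundles.
* Binary-fission chains of bacteria are measured as single objects if
  fused (no watershed splitting).
* Attachment identification in a dense EPS net is ambiguous at the
  ~1 px scale; very short filaments (≲ 0.15 µm, ≈ 3 px) sit at the
  resolution limit and their lengths carry relative errors of tens of
  percent.
* Whether the original analysis thresholded the raw grayscale or the
  ridge response is not recorded; both are supported
  (`threshold_biofilm` accepts either source), defaulting to the
  response. Whether its scale sweep was $\sigma^2$-normalized is
  likewise not recorded; normalization is a flag, on by default in the
  sweep.
* "σ = [1, 50]" is read as the endpoints of a sweep rather than two
  discrete scales; the single-scale panel uses σ = 1 exactly.
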