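---
title: "Quantifying arterial biomechanics and histology with vasomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying arterial biomechanics and histology with vasomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasomech)
```

vasomech implements the quantitative workflow of an intermittent
hypobaric-hypoxia study of the rat thoracic aorta: uniaxial tensile
parameterization, longitudinal and circumferential residual-strain
quantification, wire-myography dose-response analysis, and histological
morphometry. Because the study's raw data are not deposited, the package
pairs every analysis stage with a synthetic generator whose ground truth is
known exactly, so each stage is validated by parameter recovery. This
vignette documents the models, the tunable parameters, and the numerical
decisions — including where the underlying protocol leaves the method open
and a concrete choice had to be made.

## Uniaxial tensile analysis

A specimen of gauge length $l_0$, width $w_0$ and thickness $e_0$ (mm) is
stretched while recording force $F$ (N) and jaw displacement $\Delta$ (mm).
Stretch and Cauchy stress follow

$$\lambda = \frac{l_0 + \Delta}{l_0}, \qquad
  \sigma = \frac{F}{w_0 e_0}\,\lambda \;\;(\text{reported in kPa}),$$

the stress formula assuming incompressibility (deformed cross-section
$w_0 e_0 / \lambda$). Arterial stress-stretch curves show four zones: a
low-stiffness linear zone (slope $E_1$), a stiffening "elbow", a
high-stiffness nearly linear zone (slope $E_2$), and failure. The
transition point is defined as the midpoint between the end of zone 1
($\lambda_a$) and the start of zone 3 ($\lambda_b$):
$\lambda_t = (\lambda_a + \lambda_b)/2$,
$\sigma_t = (\sigma(\lambda_a) + \sigma(\lambda_b))/2$. Strain energy
densities $E_t$ and $E_r$ integrate $\sigma\,d\lambda$ to the transition and
rupture stretches with composite Simpson's rule; stress in kPa over
dimensionless stretch gives $\mu J/mm^3$ directly.

### Zone segmentation

The experimental protocol states that the four zones exist but not how
their boundaries were located; this is the largest methodological gap the
package had to fill. Two obvious candidates fail quantitatively:

* **Expanding-window $R^2$ thresholds.** $R^2$ is scale-invariant, so a
  window anchored in the steep zone 3 keeps $R^2 \ge 0.995$ deep into the
  curved transition (the transition's deviations are small relative to zone
  3's huge stress range). In recovery experiments this mislocated
  $\lambda_b$ by several tenths of a stretch unit.
* **Free-knot piecewise-linear least squares.** The optimal knots of a
  3-segment fit sit well inside the transition, which contaminates the
  $E_1$ window.

`segment_zones()` therefore uses *anchored boundary walks*: a line is fitted
to an anchor window at each end of the pre-rupture curve (8% of the
samples), then extended sample by sample while the curve stays within
`dev_mult` (default 3) local noise levels of the fit's prediction; the fit
is refreshed from the trusted inner 80% of the accepted window so the
transition cannot tilt it. The local noise level is estimated
nonparametrically from the high-frequency residual (raw minus moving
average), so additive and proportional noise are handled without assuming a
noise model. Two details matter:

* **Correlated smoothing noise.** The 5-sample moving average makes
  neighbouring smoothed values share 4/5 of their samples, so consecutive
  excursions are not independent evidence; the stop rule requires `consec`
  (default 3) out-of-band samples spaced one smoothing window apart.
* **Creep de-bias.** A $C^1$ stiffening onset only exceeds a noise
  threshold $\tau$ about $\delta = \sqrt{2\tau/\kappa}$ past the true
  boundary ($\kappa$ = local curvature, estimated by a windowed quadratic
  fit); the stop position is pushed back by $\hat\delta$. On noise-free
  curves the walk runs on the raw series and both boundaries land within
  ~0.02 stretch units of truth.

Degenerate inputs are flagged: if the walks meet, the curve is a sharp
bilinear elbow and both boundaries collapse to the fitted-line
intersection; if they cross the whole domain, the curve is a single line
with no distinct stiffening stage.

$E_1$ and $E_2$ are ordinary least-squares slopes on $[1, \lambda_a]$ and
$[\lambda_b, \lambda_{\sigma\max}]$ of the *raw* curve (smoothing is used
only for segmentation). Whether the original analysis used regressions or
endpoint secants is unstated; regression was chosen as the
lower-variance estimator. Rupture is the maximum-stress sample whose stress
falls by more than `drop_frac` (default 20%) within the next 5 samples —
the protocol names only "the breaking point", so the drop rule
operationalizes it and is configurable; with no qualifying drop the last
sample is returned with `ruptured = FALSE` and $E_r$ is withheld.

Simpson integration resamples the curve to a uniform 1001-node grid by
linear interpolation (the rule needs an even interval count and
experimental sampling is not uniform). On that grid the rule is exact for
polynomials up to degree 3 and agrees with high-resolution quadrature of
the synthetic hyperelastic curve to well under 0.1%.

### The tensile generator

`gen_tensile_record()` builds a noise-free curve from closed-form pieces:
linear ($E_1$) up to $\lambda_a$, a cubic Hermite bridge to $\lambda_b$,
linear ($E_2$) to rupture, then a modelled post-rupture drop to 5% of
$\sigma_r$ over 2% stretch (so rupture detection has a defined drop to
find). The Hermite end value is set to
$\sigma_a + \tfrac{E_1+E_2}{2}(\lambda_b - \lambda_a)$, which keeps the
slope-to-secant ratios inside the Fritsch–Carlson monotonicity region, so
the bridge is monotone and $C^1$ by construction, and all ground-truth
energies are exact polynomial integrals. Forces are back-computed by
inverting the Cauchy relation.

Two noise models are provided. `noise_sd` adds i.i.d. Gaussian noise in
kPa — the simplest model, but physically it implies enormous *relative*
noise in the low-stress zone (a few kPa of signal against a fixed-sd
floor), under which no estimator can recover $E_1$ reliably. `noise_frac`
scales the noise with the local stress (5% of $\sigma(\lambda)$ by
convention in the recovery tests), which matches how load-cell error
behaves across a curve spanning three orders of magnitude of stress. The
recovery suite uses the proportional model at 5%; the additive model
remains the generator default for single-zone studies.

`gen_tensile_cohort()` draws per-animal parameters from normal
distributions centred on the tabulated group means (NN/STH/LTH) with
between-animal SD = SEM$\times\sqrt{6}$, the sample size behind the
printed SEMs. Zone boundaries are placed symmetrically around the drawn
transition stretch with half-width 0.4 — the tables constrain
$\lambda_t$ but not the transition width, and 0.4 reproduces the visual
width of published aortic curves. Cohort-level recovery reproduces the
$E_2$(STH) > $E_2$(NN) > $E_2$(LTH) ordering in over 90% of seeded
cohorts; the occasional inversion is real sampling noise at $n = 6$ with
these SEMs, not estimation error.

## Residual strain

**Longitudinal pre-stretch.** Markers are placed ~10 mm apart along the
artery in situ; after excision the vessel retracts. Per segment,
$\lambda_i = d^{\text{in-situ}}_i / d^{\text{ex-vivo}}_i \ge 1$ (the
protocol never writes the ratio's direction; this orientation makes
retraction give $\lambda \ge 1$). Segments are binned into
proximal/middle/distal thirds by normalized in-situ midpoint position,
following the tabulated 0–33.3 / 33.6–66.6 / 66.6–100% convention;
positions in the 33.3–33.6% gap go to the middle third. The ratio cancels
any common µm/pixel calibration factor but *not* a calibration mismatch
between the two photographs — a mismatched scale multiplies every
$\lambda$ (tested as a property).

**Opening angle.** After a radial cut a ring springs open. The angle
$\alpha$ is measured at the midpoint of the opened ring's perimeter,
between the rays to the two cut ends. Conventions differ between
laboratories; this one (vertex at the perimeter midpoint) gives
$\alpha \to 0°$ for an unopened ring and $180°$ for a ring that springs
flat, and for a circular arc of central angle $2\varphi$ it satisfies
$\alpha = 180° - \varphi$ — the analytic oracle used throughout the tests
(recovery within 0.1° on noiseless contours).

`opening_angle_from_image()` handles binary photographs: the wall band is
thinned to a skeleton (Zhang–Suen; no installed package provides binary
thinning, so it is implemented here), the midline is the longest geodesic
between skeleton endpoints (which prunes thinning spurs), and a closed
skeleton (no endpoints) is reported as "no cut detected". Two geometric
refinements fix systematic rasterization errors: near a flat radial cut
the skeleton forks toward the cap corners, so the path ends are trimmed by
the wall half-width before use; and the cut ends are relocated from the
angular extremes of the foreground about the arc's fitted centre (a radial
cut lies at constant polar angle, so this is accurate to about one pixel).
Shallow arcs (opening angles near 180°, where the sagitta is small) use a
quadratic midline fitted to per-column band midpoints in the principal
frame instead of a circle fit, which degenerates gracefully to the flat
strip. One resolution limit remains: a nearly flat ring whose sagitta is
under ~3 pixels cannot be measured to 2°; at 3 µm/pixel all tested
openings from 5° to 170° recover within 2° (most within 0.5°).

**Reliability.** Three measurements per ring are summarized by per-sample
SD and Cronbach's alpha,
$\alpha_C = \frac{k}{k-1}\left(1 - \sum_i \mathrm{var}(x_i) /
\mathrm{var}(\sum_i x_i)\right)$, computed across replicate positions over
samples. The protocol's phrase "minimum intraclass correlation … of the
three measurements per sample" is ambiguous about grouping; computing one
coefficient across replicate positions for the whole dataset is the
standard reading, and a per-group value can be obtained by subsetting the
replicate matrix. Perfect agreement gives exactly 1; independent items
give 0 in expectation (checked by simulation at $n = 10{,}000$).

## Vasoreactivity

Wire-myograph responses are expressed as wall tension (mN/mm); the mounted
ring spans the wires with two wall strips, so tension = force / (2 ×
segment length), the divisor being configurable since only the unit is
documented. The basal tension equivalent to 80 mmHg comes from Laplace's
relation $T = P r$ (1 mmHg = 0.133322 kPa; kPa·mm = mN/mm).
Vasoconstrictor series are normalized to the maximal potassium contraction
(%Kmax), vasodilator series to the phenylephrine preconstriction (%Rmax,
preconstriction dose $10^{-6}$ M recorded as protocol metadata).

Sensitivity and maximal response come from the four-parameter logistic in
log dose,

$$R(c) = \text{bottom} + \frac{\text{top} - \text{bottom}}
  {1 + 10^{(\log EC_{50} - \log_{10} c)\,h}},$$

fitted by Levenberg–Marquardt (minpack.lm) with multi-start initialization
over a log-EC50 grid and $h \in \{0.5, 1, 2\}$; pD2 = $-\log_{10} EC_{50}$
by definition (the identity pd2 + log10(ec50) = 0 holds to machine
precision). No fitting software or model is named in the protocol; the
4PL is the standard CCRC model and the Hill slope is left free. Fits are
performed on normalized responses by default (configurable): pD2 and the
Hill slope are invariant under affine rescaling of the response, so the
choice affects only the units of the maximal response. Whether a fitted
top or the largest observed response is reported as Emax is likewise
configurable (`emax = "fitted"` default). A relaxation record whose fitted
span is under 10% of the preconstriction is flagged "response abolished"
and its pD2 withheld — mirroring how an endothelium-dependent response
that disappears in a treatment group is reported as "not assessed" rather
than as a meaningless number.

## Histomorphometry

The counting protocol is: select an ROI in the tunica media; Gaussian blur
and grayscale; threshold; watershed; particle analysis. `vasomech`
implements it with ITU-R 601 luminance, EBImage's Gaussian blur, Otsu's
threshold on the in-ROI values (the protocol says only "a thresholding
filter method"; Otsu is deterministic and parameter-free, and a fixed
threshold can be supplied), and EBImage's distance-transform watershed.
Objects are filtered to 5–200 µm². Per-object area is pixel count ×
pixel\_size²; the major axis is the moment-equivalent ellipse axis
($4\sqrt{\lambda_{\max}}$ of the coordinate covariance), and roundness is
the particle-analysis definition $4A/(\pi\,\text{major}^2)$ — 1 for a
disc, $b/a$ for an ellipse (no formula is given in the protocol; this is
the ImageJ convention). Blur sigma should scale with resolution: the
default 2 px suits ~2 µm/pixel overview images, while the 0.7 µm/pixel
phantom recovery runs use 0.8 px so that 24 µm² nuclei are not smeared
(at sigma 2 px their apparent area inflates by tens of percent).

Fiber content uses color deconvolution: per pixel,
$OD = -\log_{10}(\max(I,1)/255)$ per channel and concentrations =
stain-matrix$^{-1}$·OD, negatives clipped. The staining batch's matrix is
never published, so the default vectors are documented constants (unit-norm
OD triples for a dark elastin-like stain, a pink collagen-like stain and a
residual); real analyses must supply their measured matrix. A pixel is
fiber-positive above concentration 0.15 (the protocol's "pixel area
division" implies a binarization without stating the cutoff; 0.15 is the
package default and fractions are monotone in it, which is tested).
Deconvolution inverts the phantom's painting to machine precision and
stays within 5% under additive RGB noise of sd 3/255.

Vessel geometry derives diameters from traced layer perimeters assuming
effective circularity ($d = P/\pi$), then intima-media and adventitia
thicknesses, the media/lumen ratio and the annular cross-section area.
Two deliberate choices: `trace_perimeters()` converts segmented region
*areas* to perimeters via $P = 2\sqrt{\pi A}$ rather than summing raster
boundary steps, because boundary walks on rasters carry a systematic
2–5% length bias while the area estimator converges as $O(1/r)$ for the
near-circular sections this operation contracts for; and the
media–adventitia split uses a recursive Otsu rule (re-split the bright
class until the dark class is at least 25% of the wall) because dark
stain speckle inside the media otherwise hijacks a single bimodal
threshold. Note the tabulated cross-section area for these vessels is
inconsistent with the annulus formula applied to the tabulated mean
diameters (~458,000 µm² printed vs ~1.39 × 10⁶ µm² computed); the package
implements the annulus formula and makes no attempt to reproduce that
figure, whose definition is unclear.

### The histology phantom

`gen_histology_image()` paints in OD space, so every quantity has exact
ground truth: elastin/collagen-positive pixels are painted in *exact
counts* among non-nucleus ROI pixels (fractions match the prescription to
one pixel); nuclei are non-overlapping ellipses of prescribed mean area
and aspect placed with bounded retries (failure reports the achievable
count); layer perimeters are analytic circles. Paint strengths are chosen
so that the fiber speckle stays well above the 0.15 positivity cutoff but
clearly lighter in grayscale than nuclei — otherwise Otsu separates fibers
from base tissue instead of nuclei, and 25–40% fiber speckle percolates
into giant connected components. The phantom emulates pixel-exact stain
mixing, hard region boundaries and elliptical nuclei; it does not emulate
stain diffusion, uneven illumination, sectioning artifacts, overlapping or
clustered nuclei, or fibrous (spatially correlated) stain texture — so
passing recovery tests demonstrate the correctness of the measurement
chain, not robustness to real-slide artifacts.

## Study orchestration

`run_study()` generates a full synthetic cohort (three groups × n animals)
from the reference group means, runs each enabled stage per animal,
aggregates mean ± SEM per group (SEM with $n = 1$ reported as 0 with a
flag, keeping tables rectangular) and computes the headline relative
differences, $100(\bar x_{\text{comp}} - \bar x_{\text{ref}})/
\bar x_{\text{ref}}$. The ring stage's group-level opening angles
(defaults NN 100°, hypoxic groups 50–55°, between-animal SD 8°) are
realistic values consistent with a marked circumferential residual-strain
loss under intermittent hypoxia; they are conditions of the synthetic
study, not measurements. Hypothesis testing (normality checks, ANOVA,
Kruskal–Wallis, post-hoc comparisons) is deliberately left to R's standard
routines (`ks.test`, `aov`, `kruskal.test`, `TukeyHSD`) on the per-animal
tables the report exposes; the package does not wrap them.

Determinism: every generator takes a seed and restores the caller's RNG
state, so identical seeds give bit-identical synthetic data and reports
(timestamps excluded). Problem sizes in the test suite — 50 seeded tensile
curves, 200 dose-response replicates, 100 six-animal cohorts, one
fine-resolution and one full-size histology phantom — were chosen so the
whole recovery suite expresses each criterion at meaningful statistical
resolution while remaining comfortable to run locally.

## Known limitations

* Zone segmentation assumes one monotone stiffening transition; curves
  with multiple elbows (e.g. slipping grips) will be segmented at the
  dominant one and flagged only if fully degenerate.
* The opening-angle convention must match between laboratories before
  comparing values; conversions from other conventions are the user's
  responsibility.
* Near-flat rings (α within ~8° of 180°) need fine rasterization
  (sagitta ≥ 3 px) for the 2° image-based accuracy.
* The histology phantom's idealizations listed above; on real slides the
  stain matrix must be measured, and the fixed positivity cutoff should be
  checked against a negative control.
* No constitutive (hyperelastic/viscoelastic) modelling: the tangent
  moduli and energies are curve descriptors, not material-model fits.
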