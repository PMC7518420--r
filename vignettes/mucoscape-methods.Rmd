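---
title: "Quantifying host–microbe spatial architecture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying host–microbe spatial architecture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucoscape)
```

## The problem

In the healthy colon, a dense luminal microbiota is held away from the
epithelium by a bacteria-free inner mucus layer. Barrier damage thins that
layer, and in mucosa-associated *biofilms* — a state linked to colorectal
neoplasia — dense bacterial colonies sit in direct contact with the
epithelial surface. Multichannel fluorescence imaging (a universal 16S
FISH probe for bacteria, DAPI for nuclei, lectins such as WGA for mucus)
captures all of this in a single tissue section; `mucoscape` turns such
images into numbers:

1. **compartment masks** — a mucosal region of interest from DAPI
   thresholding, and a luminal mask from FISH-channel thresholding minus
   the mucosa;
2. **inner mucus layer thickness** — minimal distances between the two
   mask edges, sampled at 100 random luminal-edge points;
3. **per-compartment mean fluorescence** for any stain;
4. **volumetric bacterial density** — spot counts converted to per-ml
   units through the optical-section volume;
5. **biofilm positivity** — more than 10⁹ bacteria/ml within 1 µm of the
   epithelium over at least 200 µm of contiguous epithelial surface, plus
   the expert-style screening sheet with its score > 2.5 cutoff.

A companion module fits thermoreversible-gelation temperature sweeps
(storage modulus vs. temperature) with the four-parameter dose–response
sigmoid and reports the half-gelation temperature — the analysis used to
characterize a poloxamer-based fixative's sol–gel transition.

Because no public image accessions exist for this kind of study, the
package ships a **synthetic phantom generator** that emulates colonic
cross-sections with exact ground truth; every claim the test suite makes
is computed against that stated world.

## The phantom's stated world

`phantom_spec()` describes a colonic cross-section as: an epithelial band
(default depth 40 µm) of nucleated tissue at the bottom of the field; a
bacteria-free inner mucus layer of controllable thickness above it
(default 30 µm, a mid-range murine value; severe damage can set it to 0);
and a lumen populated by bacteria at a controllable volumetric density.
Parameters and defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `pixel_size_um` | 0.5 | µm/px | typical 20–40× widefield sampling; the analysis itself is resolution-agnostic, so this is a stated choice |
| `section_thickness_um` | 5 | µm | standard histology sections |
| `inner_mucus_thickness_um` | 30 | µm | mid-range rodent inner layer |
| `bacterial_density_per_ml` | 1e11 | ml⁻¹ | colonic luminal content (~10¹¹ organisms/g) |
| `bacterium_radius_um` | 0.5 | µm | ~1 µm rods/cocci; rendered as Gaussian spots with σ = radius/2 (diffraction-limited appearance, so thresholding is a genuine task) |
| `biofilm$band_density_per_ml` | caller-set | ml⁻¹ | dense mucosa-associated colonies approach cell-packing densities (10¹¹–10¹²/ml); the end-to-end tests use 10¹² |
| `noise` | Poisson + N(0, 2) + 5 | counts | standard shot noise/read noise/background model |

The volumetric-to-2D conversion is the load-bearing arithmetic: a region
of area *A* µm² in a section of thickness *t* µm samples a volume
*A·t·10⁻¹²* ml, so the expected bacterium count is
`density_per_ml × A × t × 1e-12`, with Poisson-distributed realizations.
The same formula runs in reverse in `bacterial_density()`. Ten bacteria
in 2000 µm² of a 5 µm section are exactly 10⁹ per ml.

Debris — the "autofluorescent objects (larger than bacteria)" that
confound luminal FISH — is rendered as wide Gaussian blobs (σ = 4×
bacterium radius, FWHM ≈ 4.7 µm) visible in the FISH channel only; it has
no DAPI signal, which is why DAPI-based mucosal masks ignore it by
construction.

What the phantom does **not** emulate: crypt lumina and 3D tissue
topology (the surface is flat or sinusoidal), rod orientation and shape
(spots are isotropic), spectral bleed-through, multi-round registration
error, and spatially varying autofluorescence. A green test therefore
establishes that the algorithms recover a known geometry under realistic
noise and density — not that they are robust to every artifact of real
slides.

## Segmentation

Masks follow the published recipe: threshold the DAPI channel for the
mucosa, threshold the FISH channel and eliminate the mucosal mask for the
lumen. The threshold defaults to Otsu's method (the original work names
only "thresholding"); a fixed value is available for strict
reproducibility. Raw nucleus thresholding yields speckle, so both masks
get standard morphological cleanup — closing with a 2 µm disc, hole
filling, removal of components under 50 µm², and (for the mucosa only)
largest-component selection; these values are explicit substitutes for
whatever manual cleanup the original workflow applied, and all are
configurable. Disjointness of the two masks is enforced by re-subtracting
the mucosa after cleanup, making it exact rather than statistical.

**Edges.** A boundary pixel is a mask pixel with a background 4-neighbour
(the image frame does not count as background, so masks touching the
frame do not grow spurious edges). The published procedure measures the
distance "between the outer edges" of the two masks; we read *outer* as
the two boundaries that bound the bacteria-free gap, and operationalize
it with a visibility test: a boundary pixel belongs to the facing edge
when the straight segment to its nearest point on the other boundary
crosses neither mask. This removes far-side and bay boundaries that would
otherwise inflate distances. Edge points are chain-ordered (greedy
nearest neighbour) so the epithelial surface can be parameterized by arc
length.

## Thickness

`inner_mucus_thickness()` samples up to 100 luminal-edge points uniformly
*without replacement* (with-replacement duplicates would inflate
variance; the published "100 random points" does not state replacement
semantics) and records each point's exact Euclidean distance to the
nearest mucosal-edge pixel, pixel centre to pixel centre — the same
convention as the brute-force oracle the tests compare against, so oracle
agreement is exact, not approximate. Both mean and median are returned.
The distance distribution is one-sided — a bacterium can sit at, but
never inside, the gap — so the mean carries a small positive excess
(≈ 0.5–1 µm at the default luminal density) while the median recovers
true thickness to within one pixel; recovery tests therefore assert on
the median. Multi-component lumens are handled by pooling all luminal
boundary pixels before sampling.

## Bacterial counting and the debris filter

`detect_bacteria()` counts local maxima of the FISH channel above a
threshold (Otsu, floored at median + 6·MAD of the region so that a
signal-free field yields zero rather than bisected noise), merges maxima
closer than one bacterium diameter, and excludes *debris* by peak width:
a maximum whose full width at half maximum exceeds 3× the bacterium
diameter is an autofluorescent object, not a bacterium. Width is measured
per peak rather than per connected component deliberately — a dense
bacterial aggregate forms one large component and would be wrongly
discarded under a component-size rule, while its individual peaks stay
diffraction-limited.

Spot counting is accurate in the sparse regime (it is how the density
calibration at 10⁹/ml is verified) but saturates in confluent carpets,
where adjacent bacteria merge into single maxima. For that reason the
*pipeline's* epithelial-contact test does not use spot centres:
`contact_footprint()` marks every above-threshold, non-mucosal pixel
within the 1 µm contact band as one unit of bacterial presence. For
isolated bacteria at 0.5 µm/px the above-threshold footprint is about one
pixel, so footprint and spot counts agree where both are valid; in a
carpet the footprint keeps growing where maxima cannot.

## Biofilm classification and scoring

`classify_biofilm()` implements the operational rule: parameterize the
epithelial edge by arc length; mark positions contacted when bacterial
presence lies within the 1 µm band; merge contacted positions into runs,
bridging gaps of at most 5 µm (biofilms are dense but not
pixel-continuous; the tolerance is configurable and recorded); compute
each run's density over its band volume (span × 1 µm × section
thickness); call the sample positive when a run reaches 200 µm *and*
exceeds 10⁹/ml.

A quantitative caveat worth stating precisely: at the rule's own
threshold density, the *expected* bacterial count in the band is one
organism per 200 µm of edge. A tissue exactly at threshold therefore
cannot exhibit a contiguous 200 µm contact run under any finite gap
tolerance — the rule is a density floor applied to colonies that are in
practice orders of magnitude denser (10¹¹–10¹²/ml), where contacts sit
every 1–2 µm and the rule behaves exactly as written. This is why the
classifier's truth-table tests use either exactly constructed contact
configurations or dense phantoms, and why a truth table over
near-threshold densities (0.5–2 × 10⁹/ml) is statistically undecidable
from a single section.

`score_sample()` reproduces the screening sheet: mucus grade (0–2 in half
steps), bacterial abundance per 200 µm of epithelial surface (0 = none,
1 = ≤ 5, 2 = ≤ 20, 3 = more — the published scale stops at 2 while its
graded samples score 3, so grade 3 is an explicit extrapolation),
coverage percent, and a DAPI-without-Cy3 quality flag that deliberately
does not enter the score. The composite score defaults to the abundance
grade — the reading consistent with both published rows (abundance 3,
reported positive at the > 2.5 cutoff) — and the combiner is pluggable
because the original consensus scheme is defined across several prior
studies rather than in one formula.

## Gelation fitting

`fit_gelation()` fits
`response(T) = bottom + (top − bottom) / (1 + 10^(hill_slope · (t_half − T)))`
by bounded least squares (`nls`, port algorithm), the standard
"dose–response" sigmoid with temperature as the dose axis.
Initialization is deterministic — bottom/top from the data range, `t_half`
at the sample nearest the half-range crossing, slope 1 — with five
seed-fixed jittered restarts and a Nelder–Mead fallback, so fits are
reproducible for given data. Raw storage modulus and pre-normalized
gelation fractions fit identically (the model is affine in the response);
`normalize_gelation()` provides min–max scaling. Translation of the
temperature axis shifts `t_half` exactly; scaling the response leaves it
unchanged.

## Numerical and engineering choices

- Coordinates are 1-based `(row, col)` per R convention; all distances are
  pixel-centre to pixel-centre times the pixel size, so the convention
  cancels out of every physical quantity.
- Images travel as plain multi-page TIFF (uncompressed, 64-bit float
  pages, channel names in per-page JSON descriptions) written and read by
  a minimal in-package codec — no TIFF library exists in the supported
  toolchain — and validated against an independent reader in the tests.
  Masks are 8-bit 0/255 TIFFs viewable in standard tools.
- Configuration, provenance and truth sidecars are JSON; provenance
  records the configuration's MD5, the global seed and the package
  version, and deliberately no timestamps, so reruns are byte-identical.
- Per-stage seeds derive from `hash31(global_seed, stage, sample_id)`, a
  31-bit string hash: samples are independent yet the whole batch is
  reproducible from one integer.
- Degenerate inputs fail loudly and specifically: empty compartments
  raise an "undefined statistic" error rather than returning zero; a
  degenerate threshold (all pixels on one side) warns and returns the
  mask as computed; constant rheology curves are a degenerate-data error.

## Known limitations

- Thickness is 2D: distances within the section plane underestimate
  nothing, but out-of-plane geometry is invisible.
- Spot-based density saturates above roughly one bacterium per merge
  radius; carpet densities reported by the classifier are
  footprint-based and accurate only to a small factor.
- The phantom's intensity levels are fixed constants; algorithms are
  exercised at realistic contrast but not across staining variability.
- The biofilm rule's behaviour *at* its density threshold is undecidable
  from one section (see above); decisions near the boundary should rest
  on the reported spans and densities, not the binary call alone.
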