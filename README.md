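# mucoscape

Spatial quantification of host–microbe architecture in colonic tissue
sections imaged by multiplex fluorescence (bacterial 16S FISH + DAPI +
lectins), plus the rheological half-gelation-temperature fit used to
characterize thermoreversible fixatives.

## Who this is for

Groups imaging the gut mucosa who need reproducible numbers out of their
FISH/immunofluorescence sections: how thick is the bacteria-free inner
mucus layer, how bright is a stain inside each tissue compartment, how
many bacteria per ml sit in the lumen, and — clinically — does the sample
carry a mucosa-associated **biofilm**, operationally defined as more than
10⁹ bacteria/ml within 1 µm of the epithelium along at least 200 µm of
contiguous epithelial surface (screening-sheet score > 2.5).

## What it computes

For a calibrated multichannel image (pixel size in µm, 5 µm section):

- **Masks** — mucosal region of interest by DAPI thresholding; luminal
  mask by FISH (`Eub`) thresholding with the mucosa eliminated; Otsu by
  default, fixed thresholds supported; exact mask disjointness.
- **Thickness** — the inner mucus layer as minimal distances between the
  facing mask edges, sampled at 100 random luminal-edge points
  (mean and median, µm).
- **Intensity** — mean fluorescence of any channel within any mask.
- **Density** — bacteria counted as diffraction-limited FISH maxima
  (debris excluded by peak width), converted to per-ml by the
  optical-section volume: `density = count / (area_µm² × 5 µm × 1e-12)`.
- **Biofilm call** — arc-length spans of epithelial contact, band
  density, coverage percent, and the positivity rule above; plus the
  per-sample screening sheet (mucus grade, abundance per 200 µm, coverage
  %, DAPI-without-Cy3 flag, composite score).
- **Gelation** — four-parameter dose–response fit of temperature sweeps,
  `r(T) = bottom + (top − bottom)/(1 + 10^(slope·(t_half − T)))`,
  reporting the half-gelation temperature `t_half`.

Because studies of this kind deposit no raw images, the package includes
a first-class synthetic **phantom generator** (`phantom_spec()`,
`generate_phantom()`) producing colonic cross-sections with exact ground
truth — true masks, true thickness, every bacterial centre — which the
entire test suite runs against.

## Worked example

```r
library(mucoscape)

spec <- phantom_spec(512, 512, pixel_size_um = 0.5,
                     inner_mucus_thickness_um = 30,
                     bacterial_density_per_ml = 1e11, seed = 42)
ph <- generate_phantom(spec)
ph$image
#> <multichannel_image> 512 x 512 px (256 x 256 um), 0.5 um/px, section 5 um
#>   channels: DAPI, Eub, WGA

m <- mucosal_mask(ph$image)
l <- luminal_mask(ph$image, m)
edges <- mask_edges(m, l)

inner_mucus_thickness(edges$mucosal_edge, edges$luminal_edge, seed = 1)
#> <thickness_estimate> mean 30.06 um, median 30.09 um (n = 100, seed 1)

bacterial_density(ph$image, l)
#> <density_estimate> 11353 bacteria / 4.73e+04 um^2 / 2.37e-07 ml = 4.8e+10 per ml

fp <- contact_footprint(ph$image, edges$mucosal_edge, m$grid)
classify_biofilm(edges$mucosal_edge, fp$centers)
#> <biofilm_call> negative: max span 0.0 um, band density 0/ml, 0 run(s)

fit_gelation(gelation_curve(5:40, 100 / (1 + 10^(0.4 * (19 - 5:40)))))
#> <gelation_fit> t_half = 19.00 C, slope 0.4, range [8.39e-11, 100], SSE 3.3e-17
```

Reading the output: the estimator recovers the simulated 30 µm inner
mucus layer to a tenth of a micrometre; the measured luminal density
(4.8×10¹⁰/ml against 10¹¹ simulated) illustrates spot-count saturation at
carpet densities — at the 10⁹/ml screening threshold recovery is within
Poisson error (see the acceptance checks); the intact mucus layer keeps
every bacterium out of the 1 µm contact band, so the biofilm call is
negative with zero contacted span; and the gelation fit returns the exact
half-gelation temperature of a noiseless 19 °C sigmoid.

A biofilm-bearing phantom pair runs end to end with:

```r
inputs <- list(
  biofilm = phantom_spec(360, 500, pixel_size_um = 0.5,
                         inner_mucus_thickness_um = 30,
                         biofilm = list(span_um = 220, band_density_per_ml = 1e12),
                         seed = 2),
  sham = phantom_spec(360, 500, pixel_size_um = 0.5,
                      inner_mucus_thickness_um = 30, seed = 2))
out <- run_pipeline(inputs, run_config(seed = 42), "results/run")
out$quantification[, c("sample_id", "max_span_um", "biofilm_positive")]
```

which reports exactly one positive sample (`biofilm`) and writes
`quantification.csv`, the screening sheet `scores.csv`, mask TIFFs and a
provenance JSON; reruns with the same config and seed are byte-identical.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/mucoscape.R", package = "mucoscape"))')
Rscript $CLI simulate     --config spec.json --seed 3 --out sim/
Rscript $CLI segment      --image sim/phantom.tif --out masks/
Rscript $CLI quantify     --image sim/phantom.tif --seed 3 --out report.csv
Rscript $CLI score        --image sim/phantom.tif --out scores.csv
Rscript $CLI rheology-fit --in sweep.csv --out fit.json
Rscript $CLI run          --config run.json --seed 5 --out results/
```

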