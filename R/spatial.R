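#' Mean fluorescence intensity within a mask
#'
#' Arithmetic mean of a channel's intensities over the foreground pixels of
#' a compartment mask — the per-compartment statistic used to compare FISH
#' or antibody staining between conditions.
#'
#' @param img a [multichannel_image()].
#' @param channel channel name.
#' @param mask a [binary_mask()] of matching shape.
#' @return non-negative scalar.
#' @export
mean_intensity <- function(img, channel, mask) {
  ch <- get_channel(img, channel)
  if (!all(dim(mask$grid) == dim(ch))) {
    stop_mucoscape("mucoscape_validation_error", "mask shape does not match image")
  }
  if (!any(mask$grid)) {
    stop_mucoscape("mucoscape_empty_compartment_error",
                   "mask is empty: mean intensity is undefined (not zero)")
  }
  mean(ch[mask$grid])
}

#' Inner mucus layer thickness from mask edges
#'
#' Estimates the thickness of the bacteria-free inner mucus layer as the
#' minimal distance between the luminal and mucosal mask edges, evaluated at
#' `n_points` random points sampled (without replacement) along the luminal
#' edge; each sampled point contributes its exact Euclidean distance (in um,
#' pixel centre to pixel centre) to the nearest mucosal edge pixel. If the
#' luminal edge has fewer pixels than `n_points`, all of them are used.
#'
#' @param mucosal_edge,luminal_edge [edge_contour()]s from [mask_edges()].
#' @param n_points number of random luminal-edge points (default 100).
#' @param seed integer seed making the sample reproducible.
#' @return object of class `thickness_estimate`: list with
#'   `per_point_distances_um`, `n_points`, `mean_um`, `median_um`, `seed`,
#'   and the sampled points.
#' @export
inner_mucus_thickness <- function(mucosal_edge, luminal_edge, n_points = 100,
                                  seed = 1) {
  stopifnot(inherits(mucosal_edge, "edge_contour"),
            inherits(luminal_edge, "edge_contour"))
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 1) {
    stop_mucoscape("mucoscape_parameter_error", "'n_points' must be >= 1")
  }
  n_avail <- nrow(luminal_edge$points)
  n_use <- min(n_points, n_avail)
  idx <- with_seed(seed, sample.int(n_avail, n_use, replace = FALSE))
  pts <- luminal_edge$points[idx, , drop = FALSE]
  nn <- .cpp_nearest_point(pts * 1.0, mucosal_edge$points * 1.0)
  d_um <- nn$dist * luminal_edge$pixel_size_um
  structure(list(
    per_point_distances_um = d_um,
    n_points = as.integer(n_use),
    mean_um = mean(d_um),
    median_um = median(d_um),
    seed = as.integer(seed),
    sampled_points = pts
  ), class = "thickness_estimate")
}

#' @export
print.thickness_estimate <- function(x, ...) {
  cat(sprintf("<thickness_estimate> mean %.2f um, median %.2f um (n = %d, seed %d)\n",
              x$mean_um, x$median_um, x$n_points, x$seed))
  invisible(x)
}

# Automatic spot threshold: Otsu with a robust noise floor. On a field with
# no true signal Otsu simply bisects the noise distribution, so the floor
# (median + 6 MAD of the region) keeps empty fields empty; with real spots
# present Otsu dominates.
robust_spot_threshold <- function(v) {
  max(otsu_threshold(v), median(v) + 6 * mad(v))
}

#' Spot-detection parameters for bacterial counting
#'
#' @param intensity_threshold absolute intensity above which a local maximum
#'   counts as a candidate bacterium; `NULL` (default) uses the Otsu
#'   threshold of the FISH channel.
#' @param bacterium_diameter_um expected bacterial diameter; maxima closer
#'   than one diameter are merged (brightest wins).
#' @param debris_diameter_factor peaks whose full width at half maximum
#'   exceeds this multiple of the bacterial diameter are treated as
#'   autofluorescent debris (objects larger than bacteria) and excluded
#'   (default 3).
#' @return object of class `spot_params`.
#' @export
spot_params <- function(intensity_threshold = NULL, bacterium_diameter_um = 1,
                        debris_diameter_factor = 3) {
  check_positive_scalar(bacterium_diameter_um, "bacterium_diameter_um")
  check_positive_scalar(debris_diameter_factor, "debris_diameter_factor")
  structure(list(intensity_threshold = intensity_threshold,
                 bacterium_diameter_um = bacterium_diameter_um,
                 debris_diameter_factor = debris_diameter_factor),
            class = "spot_params")
}

#' Detect individual bacteria in the FISH channel
#'
#' Bacteria are counted as local intensity maxima of the `Eub` channel above
#' threshold within a region of interest; maxima closer than one bacterium
#' diameter are merged (the brighter survives), and maxima falling inside
#' large connected objects (equivalent diameter above the debris cutoff)
#' are excluded as autofluorescent debris.
#'
#' @param img a [multichannel_image()] with an `Eub` channel.
#' @param region a [binary_mask()] restricting the count.
#' @param params a [spot_params()].
#' @return `list(centers = n x 2 matrix, count = n, threshold = used value)`.
#' @export
detect_bacteria <- function(img, region, params = spot_params()) {
  ch <- get_channel(img, "Eub")
  if (!any(region$grid)) {
    stop_mucoscape("mucoscape_empty_compartment_error",
                   "region is empty: bacterial count is undefined")
  }
  px <- img$pixel_size_um
  thr <- params$intensity_threshold
  if (is.null(thr)) thr <- robust_spot_threshold(ch[region$grid])
  sep_px <- params$bacterium_diameter_um / px
  offs <- disc_offsets(max(sep_px, 1))
  mx <- .cpp_max_filter(ch, offs)
  cand <- ch >= mx & ch > thr & region$grid
  centers <- which(cand, arr.ind = TRUE)
  # merge candidates closer than one diameter: greedy by brightness
  if (nrow(centers) > 1) {
    o <- order(ch[centers], decreasing = TRUE)
    centers <- centers[o, , drop = FALSE]
    keep <- .cpp_merge_close_points(centers * 1.0, sep_px)
    centers <- centers[keep, , drop = FALSE]
  }
  # debris filter: a peak whose full width at half maximum exceeds the
  # cutoff is an autofluorescent object, not a bacterium. Measured per
  # maximum (half-max radius), so dense bacterial aggregates - whose
  # individual peaks stay narrow - are not mistaken for debris.
  if (nrow(centers) > 0) {
    cutoff_um <- params$debris_diameter_factor * params$bacterium_diameter_um
    max_r_px <- (cutoff_um / 2) / px
    hw <- .cpp_halfmax_radius(ch, centers - 1L, max_r_px)
    centers <- centers[2 * hw * px < cutoff_um, , drop = FALSE]
  }
  colnames(centers) <- c("row", "col")
  list(centers = unname(centers), count = nrow(centers), threshold = thr)
}

#' Volumetric bacterial density over a region
#'
#' Counts bacteria by spot detection ([detect_bacteria()]) and converts the
#' 2D count to a per-ml density through the optical-section volume:
#' `volume_ml = area_um2 * section_thickness_um * 1e-12`. This is the
#' quantity compared against the 1e9 bacteria/ml biofilm threshold.
#'
#' @inheritParams detect_bacteria
#' @return object of class `density_estimate`: `bacterium_count`,
#'   `area_um2`, `volume_ml`, `density_per_ml`, `centers`.
#' @export
bacterial_density <- function(img, region, params = spot_params()) {
  det <- detect_bacteria(img, region, params)
  area_um2 <- sum(region$grid) * img$pixel_size_um^2
  volume_ml <- area_um2 * img$section_thickness_um * 1e-12
  structure(list(
    bacterium_count = det$count,
    area_um2 = area_um2,
    volume_ml = volume_ml,
    density_per_ml = det$count / volume_ml,
    centers = det$centers,
    threshold = det$threshold
  ), class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate> %d bacteria / %.3g um^2 / %.3g ml = %.3g per ml\n",
              x$bacterium_count, x$area_um2, x$volume_ml, x$density_per_ml))
  invisible(x)
}

#' Bacterial signal footprint in the epithelial contact band
#'
#' Individual bacteria stop being resolvable as separate intensity maxima
#' inside a confluent biofilm carpet, so epithelial *contact* is assessed
#' from the thresholded FISH signal footprint rather than from spot
#' detections: every above-threshold, non-mucosal pixel within the contact
#' band counts as one unit of bacterial presence (an isolated bacterium's
#' above-threshold footprint is about one pixel at 0.5 um/px, so in the
#' sparse regime this agrees with spot counting). The returned pixel
#' coordinates feed [classify_biofilm()] directly.
#'
#' @param img a [multichannel_image()] with an `Eub` channel.
#' @param mucosal_edge an [edge_contour()] of the epithelial surface.
#' @param mucosal_grid logical matrix of the mucosal mask (excluded).
#' @param contact_band_um band depth (default 1 um).
#' @param intensity_threshold absolute threshold; `NULL` uses Otsu over the
#'   non-mucosal pixels.
#' @return `list(centers = n x 2 pixel matrix, band = binary_mask,
#'   threshold = value)`.
#' @export
contact_footprint <- function(img, mucosal_edge, mucosal_grid,
                              contact_band_um = 1, intensity_threshold = NULL) {
  ch <- get_channel(img, "Eub")
  band <- epithelial_band(mucosal_edge, dim(ch), mucosal_grid, contact_band_um)
  thr <- intensity_threshold
  if (is.null(thr)) thr <- robust_spot_threshold(ch[!mucosal_grid])
  hit <- band$grid & ch > thr
  list(centers = which(hit, arr.ind = TRUE), band = band, threshold = thr)
}

#' Epithelial contact band
#'
#' The set of non-mucosal pixels within `band_width_um` of the mucosal edge
#' — the "within 1 um of the epithelium" zone of the biofilm definition.
#'
#' @param mucosal_edge an [edge_contour()].
#' @param shape image dimensions `c(nrow, ncol)`.
#' @param mucosal_grid optional logical matrix to exclude mucosal pixels.
#' @param band_width_um band depth in um (default 1).
#' @return a [binary_mask()] labelled `other`.
#' @export
epithelial_band <- function(mucosal_edge, shape, mucosal_grid = NULL,
                            band_width_um = 1.0) {
  stopifnot(inherits(mucosal_edge, "edge_contour"))
  if (!is.numeric(band_width_um) || band_width_um <= 0) {
    stop_mucoscape("mucoscape_parameter_error", "'band_width_um' must be > 0")
  }
  px <- mucosal_edge$pixel_size_um
  r_px <- band_width_um / px
  nr <- shape[1]; nc <- shape[2]
  seed_grid <- matrix(FALSE, nr, nc)
  seed_grid[mucosal_edge$points] <- TRUE
  cand <- .cpp_dilate(seed_grid, disc_offsets(ceiling(r_px) + 1))
  idx <- which(cand, arr.ind = TRUE)
  nn <- .cpp_nearest_point(idx * 1.0, mucosal_edge$points * 1.0)
  ok <- nn$dist <= r_px + 1e-9
  grid <- matrix(FALSE, nr, nc)
  grid[idx[ok, , drop = FALSE]] <- TRUE
  if (!is.null(mucosal_grid)) grid <- grid & !mucosal_grid
  binary_mask(grid, "other", pixel_size_um = px)
}
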