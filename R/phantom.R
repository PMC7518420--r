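#' Specification of a synthetic colonic cross-section phantom
#'
#' Describes the stated world the pipeline is tested against: an epithelial
#' band of nucleated cells at the bottom of the field, a bacteria-free inner
#' mucus layer of controllable thickness above it, a bacteria-laden lumen of
#' controllable volumetric density, an optional mucosa-associated biofilm
#' patch contacting the epithelium, autofluorescent luminal debris (objects
#' larger than bacteria, visible in the FISH channel but DAPI-negative),
#' and a Poisson shot noise + Gaussian read noise + constant background
#' intensity model.
#'
#' Volumetric densities are converted to 2D expected counts through the
#' optical-section volume: `E(count) = density_per_ml * area_um2 *
#' section_thickness_um * 1e-12` (1 ml = 1e12 um^3).
#'
#' @param image_height_px,image_width_px image dimensions in pixels.
#' @param pixel_size_um lateral pixel size, um/px (default 0.5; the imaging
#'   magnification is not dictated by the analysis, so this is a stated
#'   choice).
#' @param section_thickness_um section thickness, um (default 5, standard
#'   histology).
#' @param epithelium_profile `"flat"` or `"sinusoidal"` epithelial surface.
#' @param amplitude_um,period_um sinusoid geometry (ignored for flat).
#' @param epithelium_depth_um depth of the nucleated epithelial band.
#' @param inner_mucus_thickness_um bacteria-free gap above the epithelium;
#'   may be 0 (e.g. severe barrier damage).
#' @param bacterial_density_per_ml volumetric density of luminal bacteria
#'   (default 1e11/ml, typical colonic luminal content).
#' @param bacterium_radius_um bacterium radius (default 0.5 um); rendered as
#'   diffraction-limited Gaussian spots with sigma = radius / 2.
#' @param biofilm `NULL`, or `list(span_um =, band_density_per_ml =)`: a
#'   contiguous stretch of epithelial surface with bacteria within 1 um of
#'   the epithelium and no mucus gap.
#' @param n_debris number of autofluorescent debris objects in the lumen
#'   (diameter 4x the bacterial diameter, FISH channel only).
#' @param noise `list(poisson_scale =, gaussian_sd =, background =)`.
#' @param seed integer; identical spec + seed gives bit-identical output.
#' @return object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(256, 256, inner_mucus_thickness_um = 30, seed = 7)
#' ph <- generate_phantom(spec)
#' names(ph$image$channels)
#' ph$truth$inner_mucus_thickness_um_true
phantom_spec <- function(image_height_px = 512, image_width_px = 512,
                         pixel_size_um = 0.5, section_thickness_um = 5,
                         epithelium_profile = c("flat", "sinusoidal"),
                         amplitude_um = 10, period_um = 100,
                         epithelium_depth_um = 40,
                         inner_mucus_thickness_um = 30,
                         bacterial_density_per_ml = 1e11,
                         bacterium_radius_um = 0.5,
                         biofilm = NULL,
                         n_debris = 0,
                         noise = list(poisson_scale = 1, gaussian_sd = 2,
                                      background = 5),
                         seed = 1) {
  epithelium_profile <- match.arg(epithelium_profile)
  for (f in c("image_height_px", "image_width_px")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || v < 8 || v != round(v)) {
      stop_mucoscape("mucoscape_parameter_error",
                     sprintf("field '%s' must be an integer >= 8", f))
    }
  }
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_positive_scalar(section_thickness_um, "section_thickness_um")
  check_positive_scalar(epithelium_depth_um, "epithelium_depth_um")
  check_positive_scalar(inner_mucus_thickness_um, "inner_mucus_thickness_um",
                        allow_zero = TRUE)
  check_positive_scalar(bacterial_density_per_ml, "bacterial_density_per_ml",
                        allow_zero = TRUE)
  check_positive_scalar(bacterium_radius_um, "bacterium_radius_um")
  if (epithelium_profile == "sinusoidal") {
    check_positive_scalar(amplitude_um, "amplitude_um")
    check_positive_scalar(period_um, "period_um")
  }
  if (!is.null(biofilm)) {
    if (!is.list(biofilm) || is.null(biofilm$span_um) ||
        is.null(biofilm$band_density_per_ml)) {
      stop_mucoscape("mucoscape_parameter_error",
        "field 'biofilm' must be NULL or list(span_um =, band_density_per_ml =)")
    }
    check_positive_scalar(biofilm$span_um, "biofilm$span_um")
    check_positive_scalar(biofilm$band_density_per_ml, "biofilm$band_density_per_ml",
                          allow_zero = TRUE)
    if (biofilm$span_um > image_width_px * pixel_size_um) {
      stop_mucoscape("mucoscape_parameter_error",
        "field 'biofilm$span_um' exceeds the physical image width")
    }
  }
  if (!is.numeric(n_debris) || length(n_debris) != 1 || n_debris < 0 ||
      n_debris != round(n_debris)) {
    stop_mucoscape("mucoscape_parameter_error",
                   "field 'n_debris' must be a non-negative integer")
  }
  if (!is.list(noise)) {
    stop_mucoscape("mucoscape_parameter_error", "field 'noise' must be a list")
  }
  noise <- utils::modifyList(list(poisson_scale = 1, gaussian_sd = 2,
                                  background = 5), noise)
  check_positive_scalar(noise$poisson_scale, "noise$poisson_scale")
  check_positive_scalar(noise$gaussian_sd, "noise$gaussian_sd", allow_zero = TRUE)
  check_positive_scalar(noise$background, "noise$background", allow_zero = TRUE)
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
    stop_mucoscape("mucoscape_parameter_error", "field 'seed' must be an integer")
  }
  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_size_um = pixel_size_um,
    section_thickness_um = section_thickness_um,
    epithelium_profile = epithelium_profile,
    amplitude_um = amplitude_um, period_um = period_um,
    epithelium_depth_um = epithelium_depth_um,
    inner_mucus_thickness_um = inner_mucus_thickness_um,
    bacterial_density_per_ml = bacterial_density_per_ml,
    bacterium_radius_um = bacterium_radius_um,
    biofilm = biofilm, n_debris = as.integer(n_debris),
    noise = noise, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Rendering constants: intensity levels chosen once for realistic contrast
# (dim constant background, moderately autofluorescent tissue, bright
# nearly-confluent nuclei as in colonic crypt epithelium, bright
# diffraction-limited FISH spots). Not tunable through the public API.
PHANTOM_LEVELS <- list(
  dapi_tissue = 80, dapi_nucleus = 80, nucleus_sigma_um = 1.5,
  nucleus_per_um2 = 1 / 25,
  eub_spot = 120, debris_amp = 100, wga_mucus = 80, wga_lumen = 8
)

# First mucosal (epithelial surface) row for every column, 1-based.
phantom_surface_rows <- function(spec) {
  nr <- spec$image_height_px
  nc <- spec$image_width_px
  px <- spec$pixel_size_um
  base <- nr - round(spec$epithelium_depth_um / px) + 1
  base <- max(2, min(nr, base))
  if (spec$epithelium_profile == "flat") {
    rep(base, nc)
  } else {
    amp <- spec$amplitude_um / px
    per <- spec$period_um / px
    s <- base - round(amp * (sin(2 * pi * (seq_len(nc) - 1) / per) + 1) / 2)
    pmax(2, pmin(nr, s))
  }
}

# Poisson draw of pixel positions at a volumetric density over a pixel set.
sample_density_pixels <- function(idx_rc, density_per_ml, px_um, section_um) {
  if (nrow(idx_rc) == 0 || density_per_ml <= 0) {
    return(idx_rc[0, , drop = FALSE])
  }
  area_um2 <- nrow(idx_rc) * px_um^2
  lambda <- density_per_ml * area_um2 * section_um * 1e-12
  n <- rpois(1, lambda)
  if (n == 0) return(idx_rc[0, , drop = FALSE])
  idx_rc[sample.int(nrow(idx_rc), n, replace = TRUE), , drop = FALSE]
}

apply_noise <- function(clean, noise) {
  n <- length(clean)
  shot <- rpois(n, pmax(clean, 0) * noise$poisson_scale) / noise$poisson_scale
  read <- if (noise$gaussian_sd > 0) rnorm(n, 0, noise$gaussian_sd) else 0
  out <- shot + read + noise$background
  matrix(pmax(out, 0), nrow(clean), ncol(clean))
}

splat <- function(nr, nc, centers_rc, amp, sigma_px) {
  if (nrow(centers_rc) == 0) return(matrix(0, nr, nc))
  .cpp_splat_gaussians(nr, nc, cbind(centers_rc[, 1] - 1, centers_rc[, 2] - 1),
                       rep_len(amp, nrow(centers_rc)), sigma_px)
}

#' Generate a synthetic colonic cross-section with ground truth
#'
#' Renders the phantom described by a [phantom_spec()] and returns both the
#' noisy multichannel image (channels `DAPI`, `Eub`, `WGA`) and the exact
#' ground truth used to render it: true compartment masks, true inner mucus
#' thickness, all bacterial centres, and the biofilm parameters.
#'
#' Geometry: rows increase downward; the epithelium occupies the bottom
#' band, its surface at `truth$surface_rows`. Bacterial centres sit on
#' pixel centres; all distances are pixel-centre to pixel-centre times the
#' pixel size.
#'
#' @param spec a [phantom_spec()].
#' @return `list(image = multichannel_image, truth = list(...))`. Truth
#'   fields: `mucosal_mask_true`, `luminal_mask_true` (logical matrices,
#'   disjoint), `inner_mucus_thickness_um_true`, `bacteria_centers`
#'   (n x 2 matrix of 1-based row/col), `band_centers` (subset in the
#'   biofilm contact band), `band_density_per_ml_true`, `biofilm_true`,
#'   `surface_rows`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    nr <- spec$image_height_px
    nc <- spec$image_width_px
    px <- spec$pixel_size_um
    st <- spec$section_thickness_um
    lv <- PHANTOM_LEVELS

    s <- phantom_surface_rows(spec)
    rows <- matrix(seq_len(nr), nr, nc)
    smat <- matrix(s, nr, nc, byrow = TRUE)
    mucosal_true <- rows >= smat

    gap_px <- spec$inner_mucus_thickness_um / px
    # luminal compartment: pixels whose Euclidean distance to the epithelial
    # surface point set is >= the mucus gap (exact also for sinusoidal walls)
    k <- floor(gap_px)
    rmax <- s - gap_px
    if (k >= 1 && spec$epithelium_profile != "flat") {
      spad <- c(rep(s[1], k), s, rep(s[nc], k))
      for (dc in -k:k) {
        rmax <- pmin(rmax, spad[seq_len(nc) + k + dc] -
                       sqrt(max(gap_px^2 - dc^2, 0)))
      }
    }
    rmax <- pmin(floor(rmax), s - 1)
    rmax_mat <- matrix(rmax, nr, nc, byrow = TRUE)
    lum_true <- rows <= rmax_mat

    # biofilm span (columns), centred
    bf <- spec$biofilm
    span_cols <- integer(0)
    if (!is.null(bf)) {
      span_px <- max(1, round(bf$span_um / px))
      c0 <- max(1, floor((nc - span_px) / 2) + 1)
      span_cols <- c0:min(nc, c0 + span_px - 1)
      # no mucus gap over the span: lumen reaches the epithelium there
      lum_true[, span_cols] <- (rows <= smat - 1)[, span_cols]
    }

    lum_idx <- which(lum_true, arr.ind = TRUE)
    bulk <- sample_density_pixels(lum_idx, spec$bacterial_density_per_ml, px, st)

    band <- matrix(integer(0), 0, 2)
    if (!is.null(bf)) {
      band_px <- max(1, round(1 / px))       # "within 1 um of the epithelium"
      in_band <- rows >= smat - band_px & rows <= smat - 1
      in_band[, -span_cols] <- FALSE
      band_idx <- which(in_band, arr.ind = TRUE)
      band <- sample_density_pixels(band_idx, bf$band_density_per_ml, px, st)
    }
    centers <- rbind(unname(bulk), unname(band))
    colnames(centers) <- c("row", "col")

    # --- channels (clean signal first, then noise model) ---
    spot_sigma <- (spec$bacterium_radius_um / 2) / px
    eub <- splat(nr, nc, centers, lv$eub_spot, spot_sigma)
    if (spec$n_debris > 0 && nrow(lum_idx) > 0) {
      dpos <- lum_idx[sample.int(nrow(lum_idx), spec$n_debris, replace = TRUE), ,
                      drop = FALSE]
      # FWHM = 2.355 sigma ~ 4.7 um: well above 2x the bacterial diameter
      debris_sigma <- (4 * spec$bacterium_radius_um) / px
      eub <- eub + splat(nr, nc, dpos, lv$debris_amp, debris_sigma)
    }

    dapi <- matrix(0, nr, nc)
    dapi[mucosal_true] <- lv$dapi_tissue
    n_nuc <- round(sum(mucosal_true) * px^2 * lv$nucleus_per_um2)
    if (n_nuc > 0) {
      muc_idx <- which(mucosal_true, arr.ind = TRUE)
      nuc <- muc_idx[sample.int(nrow(muc_idx), n_nuc, replace = TRUE), ,
                     drop = FALSE]
      dapi <- dapi + splat(nr, nc, nuc, lv$dapi_nucleus, lv$nucleus_sigma_um / px)
    }

    wga <- matrix(0, nr, nc)
    mucus_region <- !mucosal_true & rows > rmax_mat
    if (!is.null(bf)) mucus_region[, span_cols] <- FALSE
    wga[mucus_region] <- lv$wga_mucus
    wga[lum_true] <- lv$wga_lumen

    img <- multichannel_image(
      list(DAPI = apply_noise(dapi, spec$noise),
           Eub = apply_noise(eub, spec$noise),
           WGA = apply_noise(wga, spec$noise)),
      pixel_size_um = px, section_thickness_um = st
    )
    truth <- list(
      mucosal_mask_true = mucosal_true,
      luminal_mask_true = lum_true,
      inner_mucus_thickness_um_true = spec$inner_mucus_thickness_um,
      bacteria_centers = centers,
      band_centers = unname(band),
      band_density_per_ml_true = if (is.null(bf)) 0 else bf$band_density_per_ml,
      biofilm_true = !is.null(bf),
      surface_rows = s
    )
    list(image = img, truth = truth)
  })
}

#' Write a phantom to disk (image + truth sidecar)
#'
#' The image goes to a multi-page TIFF via [write_image()]; the spec and the
#' ground truth go to a JSON sidecar with masks run-length encoded.
#'
#' @param ph result of [generate_phantom()].
#' @param spec the generating [phantom_spec()].
#' @param dir output directory (created if needed).
#' @param name basename for the two files.
#' @return named character vector of the written paths.
#' @export
write_phantom <- function(ph, spec, dir, name = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".tif"))
  json_path <- file.path(dir, paste0(name, "_truth.json"))
  write_image(ph$image, img_path)
  rle_pack <- function(m) {
    r <- rle(as.logical(m))
    list(dim = dim(m), lengths = r$lengths, values = r$values)
  }
  truth <- ph$truth
  truth$mucosal_mask_true <- rle_pack(truth$mucosal_mask_true)
  truth$luminal_mask_true <- rle_pack(truth$luminal_mask_true)
  jsonlite::write_json(list(spec = unclass(spec), truth = truth), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  c(image = img_path, truth = json_path)
}
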