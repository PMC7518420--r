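#' Segmentation parameters for compartment masks
#'
#' The compartment masks come from per-channel thresholding (the mucosa from
#' the nuclear DAPI channel, the lumen from the bacterial FISH channel) with
#' standard morphological cleanup. The threshold itself defaults to Otsu's
#' method; a fixed value can be supplied for strict reproducibility.
#'
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold required iff `threshold_method = "fixed"`.
#' @param min_object_area_um2 connected components smaller than this are
#'   dropped (default 50 um^2, about half a nucleus).
#' @param closing_radius_um disc radius for morphological closing (default
#'   2 um; bridges gaps between adjacent nuclei / bacteria).
#' @param keep_largest_component keep only the largest 8-connected
#'   component (sensible for the mucosa, not for a fragmented lumen).
#' @param fill_holes fill enclosed background holes after closing.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_object_area_um2 = 50,
                                closing_radius_um = 2,
                                keep_largest_component = TRUE,
                                fill_holes = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed") {
    if (is.null(fixed_threshold) || !is.finite(fixed_threshold)) {
      stop_mucoscape("mucoscape_parameter_error",
                     "'fixed_threshold' is required when threshold_method = 'fixed'")
    }
  } else if (!is.null(fixed_threshold)) {
    stop_mucoscape("mucoscape_parameter_error",
                   "'fixed_threshold' must be NULL unless threshold_method = 'fixed'")
  }
  check_positive_scalar(min_object_area_um2, "min_object_area_um2", allow_zero = TRUE)
  check_positive_scalar(closing_radius_um, "closing_radius_um", allow_zero = TRUE)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_object_area_um2 = min_object_area_um2,
                 closing_radius_um = closing_radius_um,
                 keep_largest_component = isTRUE(keep_largest_component),
                 fill_holes = isTRUE(fill_holes)),
            class = "segmentation_params")
}

#' Otsu threshold of an intensity matrix
#'
#' Maximizes between-class variance over a 256-bin histogram spanning the
#' data range; returns the threshold on the original intensity scale (pixels
#' strictly above it are foreground). Degenerate (constant) input returns
#' the constant itself, so the foreground is empty.
#'
#' @param x numeric matrix or vector.
#' @param n_bins histogram resolution.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(pmax(floor((v - lo) / (hi - lo) * n_bins) + 1, 1), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  lo + k * (hi - lo) / n_bins
}

threshold_mask <- function(channel, params) {
  thr <- if (params$threshold_method == "otsu") {
    otsu_threshold(channel)
  } else {
    params$fixed_threshold
  }
  bw <- channel > thr
  if (all(bw) || !any(bw)) {
    warning(sprintf("degenerate threshold %.4g: mask is %s", thr,
                    if (all(bw)) "full" else "empty"))
  }
  bw
}

cleanup_mask <- function(bw, params, pixel_size_um) {
  r_px <- params$closing_radius_um / pixel_size_um
  if (r_px > 0 && any(bw)) {
    offs <- disc_offsets(r_px)
    bw <- .cpp_erode(.cpp_dilate(bw, offs), offs)
  }
  if (params$fill_holes && any(bw)) bw <- .cpp_fill_holes(bw)
  if (any(bw) && (params$min_object_area_um2 > 0 || params$keep_largest_component)) {
    lab <- .cpp_label_components(bw, 8L)
    sizes <- tabulate(lab[lab > 0])
    keep <- sizes * pixel_size_um^2 >= params$min_object_area_um2
    if (params$keep_largest_component && any(keep)) {
      keep <- keep & sizes == max(sizes[keep])
    }
    bw <- matrix(lab > 0 & keep[pmax(lab, 1)], nrow(bw), ncol(bw))
  }
  bw
}

#' Mucosal mask from DAPI thresholding
#'
#' Thresholds the nuclear (DAPI) channel, then applies morphological closing,
#' hole filling, small-object removal and (optionally) largest-component
#' selection, yielding a contiguous region of interest limited to the mucosa.
#' Luminal autofluorescent debris is excluded by construction because it
#' carries no DAPI signal.
#'
#' @param img a [multichannel_image()] with a `DAPI` channel.
#' @param params a [segmentation_params()].
#' @return a [binary_mask()] labelled `mucosal`.
#' @export
mucosal_mask <- function(img, params = segmentation_params()) {
  ch <- get_channel(img, "DAPI")
  bw <- threshold_mask(ch, params)
  bw <- cleanup_mask(bw, params, img$pixel_size_um)
  binary_mask(bw, "mucosal", pixel_size_um = img$pixel_size_um)
}

#' Luminal mask from FISH thresholding minus the mucosa
#'
#' Thresholds the bacterial FISH (`Eub`) channel, eliminates the mucosal
#' mask, then applies the same morphological cleanup. The returned mask is
#' guaranteed disjoint from the mucosal mask (re-subtracted after cleanup).
#'
#' @param img a [multichannel_image()] with an `Eub` channel.
#' @param mucosal the mucosal [binary_mask()].
#' @param params a [segmentation_params()]; for the lumen
#'   `keep_largest_component = FALSE` is the sensible default since luminal
#'   content is often fragmented.
#' @return a [binary_mask()] labelled `luminal`.
#' @export
luminal_mask <- function(img, mucosal,
                         params = segmentation_params(keep_largest_component = FALSE)) {
  ch <- get_channel(img, "Eub")
  if (!all(dim(mucosal$grid) == dim(ch))) {
    stop_mucoscape("mucoscape_validation_error",
                   "mucosal mask shape does not match the image")
  }
  bw <- threshold_mask(ch, params) & !mucosal$grid
  bw <- cleanup_mask(bw, params, img$pixel_size_um)
  bw <- bw & !mucosal$grid  # hard disjointness postcondition
  binary_mask(bw, "luminal", pixel_size_um = img$pixel_size_um)
}

#' Ordered edge contour of a mask
#'
#' @param points n x 2 matrix of 1-based (row, col) pixel coordinates,
#'   chain-ordered.
#' @param pixel_size_um pixel calibration.
#' @return object of class `edge_contour`.
#' @export
edge_contour <- function(points, pixel_size_um) {
  if (!is.matrix(points) || ncol(points) != 2 || nrow(points) == 0) {
    stop_mucoscape("mucoscape_empty_compartment_error",
                   "edge contour requires a non-empty n x 2 coordinate matrix")
  }
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  structure(list(points = unname(points), pixel_size_um = pixel_size_um),
            class = "edge_contour")
}

#' @export
print.edge_contour <- function(x, ...) {
  cat(sprintf("<edge_contour> %d pixels, %.3g um/px\n",
              nrow(x$points), x$pixel_size_um))
  invisible(x)
}

# Boundary pixels: mask pixels with >= 1 background 4-neighbour.
# Out-of-image counts as foreground so the frame does not create edges.
boundary_pixels <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  pad <- matrix(TRUE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- grid
  up <- pad[1:nr, 2:(nc + 1)]
  down <- pad[3:(nr + 2), 2:(nc + 1)]
  left <- pad[2:(nr + 1), 1:nc]
  right <- pad[2:(nr + 1), 3:(nc + 2)]
  grid & !(up & down & left & right)
}

#' Facing edges of the mucosal and luminal masks
#'
#' Identifies the outer edges bounding the bacteria-free gap between the two
#' compartments: the lumen-facing boundary of the mucosal mask and the
#' mucosa-facing boundary of the luminal mask. A boundary pixel is a mask
#' pixel with at least one background 4-neighbour (the image frame does not
#' count as background); a boundary pixel "faces" the other compartment if
#' stepping one pixel toward its nearest point on the other boundary leaves
#' its own mask. Points are returned chain-ordered for arc-length use.
#'
#' @param mucosal,luminal [binary_mask()] objects of matching shape.
#' @return `list(mucosal_edge =, luminal_edge =)` of [edge_contour()]s.
#' @export
mask_edges <- function(mucosal, luminal) {
  for (m in list(mucosal, luminal)) {
    if (!any(m$grid)) {
      stop_mucoscape("mucoscape_empty_compartment_error", sprintf(
        "%s mask is empty: thickness is undefined for this sample", m$label))
    }
  }
  px <- mucosal$pixel_size_um
  if (is.null(px)) px <- luminal$pixel_size_um
  if (is.null(px)) px <- 1
  bm <- which(boundary_pixels(mucosal$grid), arr.ind = TRUE)
  bl <- which(boundary_pixels(luminal$grid), arr.ind = TRUE)
  blocked <- mucosal$grid | luminal$grid
  facing <- function(pts, other_pts) {
    nn <- .cpp_nearest_point(pts * 1.0, other_pts * 1.0)
    q <- other_pts[nn$index, , drop = FALSE]
    keep <- .cpp_segment_clear(pts - 1.0, q - 1.0, blocked, skip_px = 1.9)
    pts[keep, , drop = FALSE]
  }
  fm <- facing(bm, bl)
  fl <- facing(bl, bm)
  if (nrow(fm) == 0) fm <- bm
  if (nrow(fl) == 0) fl <- bl
  fm <- fm[.cpp_chain_order(fm * 1.0), , drop = FALSE]
  fl <- fl[.cpp_chain_order(fl * 1.0), , drop = FALSE]
  list(mucosal_edge = edge_contour(fm, px),
       luminal_edge = edge_contour(fl, px))
}

#' Jaccard index of two binary masks (utility)
#' @param a,b logical matrices or [binary_mask()]s.
#' @return intersection over union; 1 if both empty.
#' @export
mask_jaccard <- function(a, b) {
  ga <- if (inherits(a, "binary_mask")) a$grid else a
  gb <- if (inherits(b, "binary_mask")) b$grid else b
  u <- sum(ga | gb)
  if (u == 0) return(1)
  sum(ga & gb) / u
}
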