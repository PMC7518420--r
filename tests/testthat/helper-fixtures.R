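# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures are stored.

# Compact phantom used by most tests: 1 um/px so geometry is easy to reason
# about, shallow epithelium so small frames still contain all compartments.
small_phantom_spec <- function(seed, inner_mucus_thickness_um = 15,
                               height = 128, width = 128, ...) {
  phantom_spec(height, width, pixel_size_um = 1, epithelium_depth_um = 30,
               inner_mucus_thickness_um = inner_mucus_thickness_um,
               seed = seed, ...)
}

segment_phantom <- function(ph) {
  m <- mucosal_mask(ph$image)
  l <- luminal_mask(ph$image, m)
  list(mucosal = m, luminal = l, edges = mask_edges(m, l))
}

# Brute-force nearest-distance oracle, independent of the compiled path.
brute_min_dist <- function(query, ref) {
  vapply(seq_len(nrow(query)), function(i) {
    sqrt(min((ref[, 1] - query[i, 1])^2 + (ref[, 2] - query[i, 2])^2))
  }, numeric(1))
}

# Two full-width horizontal bands separated by a clean gap.
band_masks <- function(nr = 30, nc = 40, luminal_rows = 1:5, mucosal_rows = 25:30,
                       px = 0.5) {
  gm <- matrix(FALSE, nr, nc); gm[mucosal_rows, ] <- TRUE
  gl <- matrix(FALSE, nr, nc); gl[luminal_rows, ] <- TRUE
  list(mucosal = binary_mask(gm, "mucosal", pixel_size_um = px),
       luminal = binary_mask(gl, "luminal", pixel_size_um = px))
}

# Solid inner square ("lumen") inside a square annulus ("mucosa"),
# separated by gap g pixels on every side.
annulus_masks <- function(n = 41, inner_half = 6, gap = 8, px = 0.5) {
  ctr <- (n + 1) / 2
  d <- pmax(abs(row(matrix(0, n, n)) - ctr), abs(col(matrix(0, n, n)) - ctr))
  inner <- d <= inner_half
  outer <- d > inner_half + gap & d <= inner_half + gap + 4
  list(luminal = binary_mask(inner, "luminal", pixel_size_um = px),
       mucosal = binary_mask(outer, "mucosal", pixel_size_um = px),
       gap_px = gap + 1)  # pixel-centre distance across the empty gap
}

# Straight horizontal epithelial edge for constructed classifier scenarios.
straight_edge <- function(row = 50, n_cols = 1000, px = 0.5) {
  edge_contour(cbind(rep(row, n_cols), seq_len(n_cols)), pixel_size_um = px)
}

# Bacteria placed every `spacing_um` along a span starting at `start_um`,
# `depth_px` pixels above the edge row.
band_centers_along <- function(edge_row, start_um, span_um, spacing_um, px,
                               depth_px = 1) {
  cols_um <- seq(start_um, start_um + span_um, by = spacing_um)
  cbind(rep(edge_row - depth_px, length(cols_um)), round(cols_um / px) + 1)
}

# Closed-form four-parameter log-logistic used to synthesize sweeps.
logistic_response <- function(T, t_half, slope = 0.5, bottom = 0, top = 100) {
  bottom + (top - bottom) / (1 + 10^(slope * (t_half - T)))
}
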