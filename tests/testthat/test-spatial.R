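test_that("mean intensity is the arithmetic mean over the mask", {
  img <- multichannel_image(list(Eub = matrix(c(1, 5, 3, 7), 2, 2)), 1)
  left <- binary_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2), "other")
  expect_equal(mean_intensity(img, "Eub", left), 3)
  const <- multichannel_image(list(Eub = matrix(4.2, 3, 3)), 1)
  any_mask <- binary_mask(matrix(c(TRUE, rep(FALSE, 8)), 3, 3), "other")
  expect_equal(mean_intensity(const, "Eub", any_mask), 4.2)
  empty <- binary_mask(matrix(FALSE, 2, 2), "other")
  expect_error(mean_intensity(img, "Eub", empty), "undefined",
               class = "mucoscape_empty_compartment_error")
})

test_that("luminal FISH intensity increases with bacterial density", {
  dense <- generate_phantom(small_phantom_spec(6, bacterial_density_per_ml = 1e9))
  sparse <- generate_phantom(small_phantom_spec(6, bacterial_density_per_ml = 1e7))
  region <- binary_mask(dense$truth$luminal_mask_true, "luminal", pixel_size_um = 1)
  expect_gt(mean_intensity(dense$image, "Eub", region),
            mean_intensity(sparse$image, "Eub", region))
})

test_that("parallel straight edges recover the exact gap", {
  bm <- band_masks(nr = 60, nc = 50, luminal_rows = 1:5, mucosal_rows = 45:60,
                   px = 0.5)
  e <- mask_edges(bm$mucosal, bm$luminal)
  th <- inner_mucus_thickness(e$mucosal_edge, e$luminal_edge, n_points = 100,
                              seed = 3)
  expect_equal(th$n_points, 50)  # edge shorter than requested: all points used
  expect_true(all(th$per_point_distances_um == 20))
  expect_equal(th$mean_um, 20)
  expect_equal(th$median_um, 20)
})

test_that("annulus gap matches the brute-force oracle and closed form", {
  am <- annulus_masks(n = 41, inner_half = 6, gap = 8, px = 0.5)
  e <- mask_edges(am$mucosal, am$luminal)
  th <- inner_mucus_thickness(e$mucosal_edge, e$luminal_edge, n_points = 100,
                              seed = 5)
  oracle <- brute_min_dist(th$sampled_points, e$mucosal_edge$points) * 0.5
  expect_equal(th$per_point_distances_um, oracle)
  # axis-aligned faces see exactly the gap; corners a touch more
  ctr <- 21
  on_face <- abs(th$sampled_points[, 1] - ctr) < 6 |
    abs(th$sampled_points[, 2] - ctr) < 6
  expect_true(all(abs(th$per_point_distances_um[on_face] - am$gap_px * 0.5) < 1e-9))
  expect_lt(abs(mean(th$per_point_distances_um[on_face]) - am$gap_px * 0.5), 0.5)
})

test_that("sampled minimal distances equal the exhaustive minimum on phantoms", {
  for (sd in 1:4) {
    seg <- segment_phantom(generate_phantom(small_phantom_spec(sd)))
    th <- inner_mucus_thickness(seg$edges$mucosal_edge, seg$edges$luminal_edge,
                                n_points = 100, seed = sd)
    oracle <- brute_min_dist(th$sampled_points, seg$edges$mucosal_edge$points) * 1
    expect_equal(th$per_point_distances_um, oracle)
  }
})

test_that("thickness estimation is deterministic and validates inputs", {
  seg <- segment_phantom(generate_phantom(small_phantom_spec(8)))
  a <- inner_mucus_thickness(seg$edges$mucosal_edge, seg$edges$luminal_edge, seed = 7)
  b <- inner_mucus_thickness(seg$edges$mucosal_edge, seg$edges$luminal_edge, seed = 7)
  expect_identical(a, b)
  c <- inner_mucus_thickness(seg$edges$mucosal_edge, seg$edges$luminal_edge, seed = 8)
  expect_false(identical(a$sampled_points, c$sampled_points))
  expect_error(inner_mucus_thickness(seg$edges$mucosal_edge,
                                     seg$edges$luminal_edge, n_points = 0),
               class = "mucoscape_parameter_error")
})

test_that("100-point sampling tracks the full-edge mean on smooth phantoms", {
  for (sd in 1:5) {
    seg <- segment_phantom(generate_phantom(
      small_phantom_spec(sd, height = 160, width = 160)))
    full <- inner_mucus_thickness(seg$edges$mucosal_edge, seg$edges$luminal_edge,
                                  n_points = 1e6, seed = sd)
    sub <- inner_mucus_thickness(seg$edges$mucosal_edge, seg$edges$luminal_edge,
                                 n_points = 100, seed = sd)
    expect_lt(abs(sub$mean_um - full$mean_um), 0.10 * full$mean_um)
  }
})

test_that("thinned-mucus phantoms are separable from normal ones", {
  seg30 <- segment_phantom(generate_phantom(
    phantom_spec(360, 256, pixel_size_um = 0.5, inner_mucus_thickness_um = 30,
                 seed = 14)))
  seg10 <- segment_phantom(generate_phantom(
    phantom_spec(360, 256, pixel_size_um = 0.5, inner_mucus_thickness_um = 10,
                 seed = 14)))
  t30 <- inner_mucus_thickness(seg30$edges$mucosal_edge, seg30$edges$luminal_edge,
                               seed = 1)
  t10 <- inner_mucus_thickness(seg10$edges$mucosal_edge, seg10$edges$luminal_edge,
                               seed = 1)
  expect_gt(t30$mean_um, t10$mean_um)
  q30 <- quantile(t30$per_point_distances_um, c(0.25, 0.75))
  q10 <- quantile(t10$per_point_distances_um, c(0.25, 0.75))
  expect_gt(q30[1], q10[2])  # non-overlapping interquartile ranges
})

test_that("bacterial density follows the optical-section volume conversion", {
  # hand-computable case: 10 bacteria over 2000 um^2, 5 um section -> 1e9/ml
  nr <- 80; nc <- 100  # 40 x 50 um at 0.5 um/px = 2000 um^2
  eub <- matrix(0, nr, nc)
  pos <- cbind(seq(10, 70, length.out = 10), seq(10, 90, length.out = 10))
  eub[round(pos)] <- 120
  img <- multichannel_image(list(Eub = eub), pixel_size_um = 0.5,
                            section_thickness_um = 5)
  region <- binary_mask(matrix(TRUE, nr, nc), "luminal", pixel_size_um = 0.5)
  d <- bacterial_density(img, region, spot_params(intensity_threshold = 50))
  expect_equal(d$bacterium_count, 10)
  expect_equal(d$area_um2, 2000)
  expect_equal(d$volume_ml, 1e-8)
  expect_equal(d$density_per_ml, 1e9)
})

test_that("zero-bacteria phantoms give zero density, empty regions error", {
  ph <- generate_phantom(small_phantom_spec(3, bacterial_density_per_ml = 0))
  region <- binary_mask(ph$truth$luminal_mask_true, "luminal", pixel_size_um = 1)
  d <- bacterial_density(ph$image, region)
  expect_equal(d$bacterium_count, 0)
  expect_equal(d$density_per_ml, 0)
  empty <- binary_mask(matrix(FALSE, 128, 128), "luminal", pixel_size_um = 1)
  expect_error(bacterial_density(ph$image, empty),
               class = "mucoscape_empty_compartment_error")
})

test_that("density recovery at the screening threshold is Poisson-consistent", {
  ph <- generate_phantom(phantom_spec(800, 800, pixel_size_um = 0.5,
                                      inner_mucus_thickness_um = 30,
                                      bacterial_density_per_ml = 1e9, seed = 5))
  region <- binary_mask(ph$truth$luminal_mask_true, "luminal", pixel_size_um = 0.5)
  d <- bacterial_density(ph$image, region)
  expect_gt(d$area_um2, 1e5)
  expected_n <- 1e9 * d$volume_ml
  expect_lt(abs(d$bacterium_count - expected_n), 3 * sqrt(expected_n))
})

test_that("autofluorescent debris is excluded from counts", {
  clean <- generate_phantom(small_phantom_spec(40, bacterial_density_per_ml = 1e10))
  dirty <- generate_phantom(small_phantom_spec(40, bacterial_density_per_ml = 1e10,
                                               n_debris = 8))
  region <- binary_mask(clean$truth$luminal_mask_true, "luminal", pixel_size_um = 1)
  n_true <- nrow(dirty$truth$bacteria_centers)
  d <- bacterial_density(dirty$image, region)
  # debris adds 8 large objects; the count must stay close to the true one
  expect_lt(abs(d$bacterium_count - n_true), 3 * sqrt(n_true) + 3)
})

test_that("contact footprint stays empty on signal-free fields", {
  ph <- generate_phantom(small_phantom_spec(3, bacterial_density_per_ml = 0))
  m <- mucosal_mask(ph$image)
  edge <- edge_contour(cbind(ph$truth$surface_rows,
                             seq_along(ph$truth$surface_rows)), 1)
  fp <- contact_footprint(ph$image, edge, m$grid)
  expect_equal(nrow(fp$centers), 0)
  # and matches spot counts in the sparse regime
  ph2 <- generate_phantom(small_phantom_spec(
    3, inner_mucus_thickness_um = 0, bacterial_density_per_ml = 5e9))
  m2 <- mucosal_mask(ph2$image)
  edge2 <- edge_contour(cbind(ph2$truth$surface_rows,
                              seq_along(ph2$truth$surface_rows)), 1)
  fp2 <- contact_footprint(ph2$image, edge2, m2$grid)
  truth_in_band <- sum(brute_min_dist(ph2$truth$bacteria_centers, edge2$points) <= 1)
  expect_lt(abs(nrow(fp2$centers) - truth_in_band),
            max(3, 3 * sqrt(truth_in_band)))
})

test_that("epithelial band has the right depth, nesting, and distances", {
  bm <- band_masks(nr = 40, nc = 30, luminal_rows = 1:3, mucosal_rows = 30:40,
                   px = 0.5)
  e <- mask_edges(bm$mucosal, bm$luminal)
  band1 <- epithelial_band(e$mucosal_edge, c(40, 30), bm$mucosal$grid,
                           band_width_um = 1)
  # 1 um at 0.5 um/px: exactly rows 28 and 29 along the straight edge
  expect_true(all(band1$grid[28:29, ]))
  expect_false(any(band1$grid[c(1:27, 30:40), ]))
  band2 <- epithelial_band(e$mucosal_edge, c(40, 30), bm$mucosal$grid,
                           band_width_um = 2)
  expect_true(all(band2$grid[band1$grid]))  # monotone nesting
  idx <- which(band2$grid, arr.ind = TRUE)
  d <- brute_min_dist(idx, e$mucosal_edge$points) * 0.5
  expect_true(all(d <= 2 + 1e-9))
  expect_error(epithelial_band(e$mucosal_edge, c(40, 30), band_width_um = 0),
               class = "mucoscape_parameter_error")
})
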