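# Constructed contact configurations give exact control over the
# density/span rule; phantom-based checks then exercise the same logic on
# rendered images with ground truth.

test_that("the density/contact/span rule is applied exactly", {
  px <- 0.5
  edge <- straight_edge(row = 50, n_cols = 1000, px = px)  # 500 um of edge
  crit <- biofilm_criteria()

  # dense contacts (every 2 um) along 250 um -> positive
  dense250 <- band_centers_along(50, start_um = 100, span_um = 250,
                                 spacing_um = 2, px = px)
  call <- classify_biofilm(edge, dense250, crit, 5)
  expect_true(call$positive)
  expect_gte(call$max_contiguous_span_um, 250 * 0.95)
  # density over the run: 126 bacteria / (span x 1 um x 5 um) >> 1e9
  expect_gt(call$band_density_per_ml, 1e9)

  # same density but only 150 um -> fails the span criterion
  dense150 <- band_centers_along(50, start_um = 100, span_um = 150,
                                 spacing_um = 2, px = px)
  call150 <- classify_biofilm(edge, dense150, crit, 5)
  expect_false(call150$positive)
  expect_lt(call150$max_contiguous_span_um, 200)

  # long but sparse (spacing > gap tolerance) -> runs fragment -> negative
  sparse <- band_centers_along(50, start_um = 100, span_um = 300,
                               spacing_um = 10, px = px)
  call_sp <- classify_biofilm(edge, sparse, crit, 5)
  expect_false(call_sp$positive)
  expect_lt(call_sp$max_contiguous_span_um, 5)

  # span passes but density below a raised threshold -> negative
  crit_hi <- biofilm_criteria(density_threshold_per_ml = 1e12)
  call_hi <- classify_biofilm(edge, dense250, crit_hi, 5)
  expect_false(call_hi$positive)
  expect_gte(call_hi$max_contiguous_span_um, 250 * 0.95)

  # no bacteria at all -> negative with zero span
  call0 <- classify_biofilm(edge, matrix(numeric(0), 0, 2), crit, 5)
  expect_false(call0$positive)
  expect_equal(call0$max_contiguous_span_um, 0)
  # bacteria far from the edge are never contacts
  far <- cbind(rep(10, 50), seq(100, 900, length.out = 50))
  expect_false(classify_biofilm(edge, far, crit, 5)$positive)
})

test_that("positivity is monotone in span and in contact density", {
  px <- 0.5
  edge <- straight_edge(50, 1000, px)
  crit <- biofilm_criteria()
  pos_by_span <- vapply(c(50, 150, 210, 300), function(s) {
    classify_biofilm(edge, band_centers_along(50, 100, s, 2, px), crit, 5)$positive
  }, logical(1))
  expect_identical(pos_by_span, c(FALSE, FALSE, TRUE, TRUE))
  pos_by_spacing <- vapply(c(12, 6, 3, 1.5), function(sp) {
    classify_biofilm(edge, band_centers_along(50, 100, 250, sp, px), crit, 5)$positive
  }, logical(1))
  expect_true(all(diff(pos_by_spacing) >= 0))  # denser never turns a call off
})

test_that("dense biofilm phantoms classify positive, shams negative", {
  spec_bf <- phantom_spec(300, 400, pixel_size_um = 1,
                          inner_mucus_thickness_um = 25,
                          biofilm = list(span_um = 250, band_density_per_ml = 1e12),
                          seed = 31)
  ph <- generate_phantom(spec_bf)
  edge <- edge_contour(cbind(ph$truth$surface_rows,
                             seq_along(ph$truth$surface_rows)), 1)
  call <- classify_biofilm(edge, ph$truth$bacteria_centers, biofilm_criteria(), 5)
  expect_true(call$positive)
  expect_gte(call$max_contiguous_span_um, 250 * 0.95)

  sham <- generate_phantom(phantom_spec(300, 400, pixel_size_um = 1,
                                        inner_mucus_thickness_um = 25, seed = 31))
  edge_s <- edge_contour(cbind(sham$truth$surface_rows,
                               seq_along(sham$truth$surface_rows)), 1)
  call_s <- classify_biofilm(edge_s, sham$truth$bacteria_centers,
                             biofilm_criteria(), 5)
  expect_false(call_s$positive)
  expect_equal(call_s$max_contiguous_span_um, 0)
})

test_that("coverage percent is the contacted fraction of the edge", {
  px <- 0.5
  edge <- straight_edge(50, 1000, px)  # ~500 um
  crit <- biofilm_criteria()
  half <- band_centers_along(50, start_um = 0.5, span_um = 249, spacing_um = 1,
                             px = px)
  call <- classify_biofilm(edge, half, crit, 5)
  expect_equal(coverage_percent(call, 500), 50, tolerance = 0.02)
  none <- classify_biofilm(edge, matrix(numeric(0), 0, 2), crit, 5)
  expect_equal(coverage_percent(none, 500), 0)
  expect_error(coverage_percent(call, 0), class = "mucoscape_parameter_error")

  # phantom with one 250 um biofilm on a ~1000 um edge -> ~25%
  spec <- phantom_spec(300, 1000, pixel_size_um = 1, inner_mucus_thickness_um = 25,
                       biofilm = list(span_um = 250, band_density_per_ml = 1e12),
                       seed = 77)
  ph <- generate_phantom(spec)
  edge_ph <- edge_contour(cbind(ph$truth$surface_rows,
                                seq_along(ph$truth$surface_rows)), 1)
  call_ph <- classify_biofilm(edge_ph, ph$truth$bacteria_centers,
                              biofilm_criteria(), 5)
  expect_equal(coverage_percent(call_ph), 25, tolerance = 2 / 25)
})

test_that("the screening-sheet rows score as published", {
  s1 <- score_sample("MPP00048A1", mucus_grade = 0.5, abundance_grade = 3,
                     coverage_pct = 50, dapi_without_cy3 = FALSE)
  expect_equal(s1$composite_score, 3)
  expect_true(s1$biofilm_positive)       # 3 > 2.5
  s2 <- score_sample("MPP00049A1", mucus_grade = 1, abundance_grade = 3,
                     coverage_pct = 35, dapi_without_cy3 = FALSE)
  expect_true(s2$biofilm_positive)
  s3 <- score_sample("clean", mucus_grade = 2, abundance_grade = 0,
                     coverage_pct = 0)
  expect_false(s3$biofilm_positive)
  # a sample_score doubles as a report row
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(list(unclass(s1), unclass(s2)), path)
  expect_match(readLines(path)[2], "MPP00048A1.*50%")
})

test_that("score inputs are validated and the combiner is pluggable", {
  expect_error(score_sample("x", mucus_grade = 0.7, abundance_grade = 1,
                            coverage_pct = 10),
               "mucus_grade", class = "mucoscape_validation_error")
  expect_error(score_sample("x", mucus_grade = 1, abundance_grade = 1,
                            coverage_pct = 135),
               "coverage", class = "mucoscape_validation_error")
  s <- score_sample("x", 1, 1, 10,
                    combiner = function(m, a, cov, dapi) m + a + cov / 50)
  expect_equal(s$composite_score, 2.2)
  expect_false(s$biofilm_positive)
})

test_that("abundance grades follow the per-200-um scale", {
  expect_equal(abundance_grade(0), 0)
  expect_equal(abundance_grade(4), 1)
  expect_equal(abundance_grade(5), 1)
  expect_equal(abundance_grade(19), 2)
  expect_equal(abundance_grade(21), 3)  # beyond the published scale
})

test_that("image-level call and image-derived score agree on clear phantoms", {
  cfg <- run_config(pixel_size_um = 1, seed = 5)
  spec_bf <- phantom_spec(300, 400, pixel_size_um = 1, inner_mucus_thickness_um = 25,
                          biofilm = list(span_um = 250, band_density_per_ml = 1e12),
                          seed = 61)
  res_bf <- analyze_sample(generate_phantom(spec_bf)$image, "bf", cfg)
  expect_true(res_bf$call$positive)
  expect_true(res_bf$score$biofilm_positive)
  spec_neg <- phantom_spec(300, 400, pixel_size_um = 1,
                           inner_mucus_thickness_um = 25, seed = 61)
  res_neg <- analyze_sample(generate_phantom(spec_neg)$image, "neg", cfg)
  expect_false(res_neg$call$positive)
  expect_false(res_neg$score$biofilm_positive)
})
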