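#' Biofilm positivity criteria
#'
#' Operational definition of a mucosa-associated biofilm: more than
#' `density_threshold_per_ml` bacteria per ml invading the mucus layer
#' (within `contact_band_um` of the epithelium) for at least `min_span_um`
#' of contiguous epithelial surface. The `score_cutoff` applies to the
#' expert-style composite score of [score_sample()].
#'
#' @param density_threshold_per_ml volumetric density threshold (default 1e9).
#' @param contact_band_um epithelial contact band depth (default 1 um).
#' @param min_span_um minimal contiguous span (default 200 um).
#' @param score_cutoff composite score cutoff for positivity (default 2.5).
#' @param gap_tolerance_um contacted runs may bridge gaps up to this arc
#'   length (default 5 um): real biofilms are dense but not pixel-continuous.
#' @return object of class `biofilm_criteria`.
#' @export
biofilm_criteria <- function(density_threshold_per_ml = 1e9,
                             contact_band_um = 1, min_span_um = 200,
                             score_cutoff = 2.5, gap_tolerance_um = 5) {
  check_positive_scalar(density_threshold_per_ml, "density_threshold_per_ml")
  check_positive_scalar(contact_band_um, "contact_band_um")
  check_positive_scalar(min_span_um, "min_span_um")
  check_positive_scalar(gap_tolerance_um, "gap_tolerance_um")
  structure(list(density_threshold_per_ml = density_threshold_per_ml,
                 contact_band_um = contact_band_um,
                 min_span_um = min_span_um,
                 score_cutoff = score_cutoff,
                 gap_tolerance_um = gap_tolerance_um),
            class = "biofilm_criteria")
}

#' Classify a sample as biofilm positive or negative
#'
#' Parameterizes the mucosal edge by arc length; marks an edge position
#' "contacted" when at least one bacterium lies within the contact band;
#' merges contacted positions into maximal contiguous runs (bridging arc
#' gaps up to the criteria's tolerance); computes each run's volumetric
#' density over its band area (`span x contact_band x section thickness`);
#' and calls the sample positive when some run satisfies both the span and
#' the density threshold. Deterministic.
#'
#' @param mucosal_edge an [edge_contour()] (ordered along the epithelium).
#' @param bacteria_centers n x 2 matrix of (row, col) pixel coordinates
#'   (e.g. truth centres from [generate_phantom()] or detections from
#'   [detect_bacteria()]).
#' @param criteria a [biofilm_criteria()].
#' @param section_thickness_um section thickness for the volume conversion.
#' @return object of class `biofilm_call`: `positive`,
#'   `max_contiguous_span_um`, `band_density_per_ml` (over the longest run),
#'   `spans` (data.frame start_um/end_um/count/density_per_ml),
#'   `total_edge_length_um`.
#' @export
classify_biofilm <- function(mucosal_edge, bacteria_centers, criteria = biofilm_criteria(),
                             section_thickness_um = 5) {
  stopifnot(inherits(mucosal_edge, "edge_contour"),
            inherits(criteria, "biofilm_criteria"))
  px <- mucosal_edge$pixel_size_um
  pts <- mucosal_edge$points
  n <- nrow(pts)
  seg <- if (n > 1) {
    sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2) * px
  } else numeric(0)
  arc <- c(0, cumsum(seg))
  total_len <- arc[n]

  empty_call <- function() {
    structure(list(positive = FALSE, max_contiguous_span_um = 0,
                   band_density_per_ml = 0,
                   spans = data.frame(start_um = numeric(0), end_um = numeric(0),
                                      count = integer(0),
                                      density_per_ml = numeric(0)),
                   total_edge_length_um = total_len,
                   criteria = criteria), class = "biofilm_call")
  }
  if (is.null(bacteria_centers) || nrow(bacteria_centers) == 0) {
    return(empty_call())
  }
  band_px <- criteria$contact_band_um / px
  nn <- .cpp_nearest_point(pts * 1.0, bacteria_centers * 1.0)
  contacted <- which(nn$dist <= band_px + 1e-9)
  if (length(contacted) == 0) return(empty_call())

  # which run does each bacterium in the band belong to: via its nearest
  # contacted edge position
  bn <- .cpp_nearest_point(bacteria_centers * 1.0, pts * 1.0)
  in_band <- bn$dist <= band_px + 1e-9

  s_cont <- sort(arc[contacted])
  gap_breaks <- which(diff(s_cont) > criteria$gap_tolerance_um)
  run_id_sorted <- cumsum(c(1, as.integer(seq_along(s_cont)[-1] %in% (gap_breaks + 1))))
  runs <- lapply(split(s_cont, run_id_sorted), range)

  spans <- do.call(rbind, lapply(runs, function(rg) {
    span <- rg[2] - rg[1]
    # bacteria whose nearest edge position falls inside this run's arc range
    b_arc <- arc[bn$index]
    cnt <- sum(in_band & b_arc >= rg[1] - 1e-9 & b_arc <= rg[2] + 1e-9)
    eff_span <- max(span, px)  # a single-contact run still has one pixel of edge
    vol_ml <- eff_span * criteria$contact_band_um * section_thickness_um * 1e-12
    data.frame(start_um = rg[1], end_um = rg[2], count = cnt,
               density_per_ml = cnt / vol_ml)
  }))
  rownames(spans) <- NULL
  span_len <- spans$end_um - spans$start_um
  pos_runs <- span_len >= criteria$min_span_um &
    spans$density_per_ml > criteria$density_threshold_per_ml
  imax <- which.max(span_len)
  structure(list(
    positive = any(pos_runs),
    max_contiguous_span_um = span_len[imax],
    band_density_per_ml = spans$density_per_ml[imax],
    spans = spans,
    total_edge_length_um = total_len,
    criteria = criteria
  ), class = "biofilm_call")
}

#' @export
print.biofilm_call <- function(x, ...) {
  cat(sprintf("<biofilm_call> %s: max span %.1f um, band density %.3g/ml, %d run(s)\n",
              if (x$positive) "POSITIVE" else "negative",
              x$max_contiguous_span_um, x$band_density_per_ml, nrow(x$spans)))
  invisible(x)
}

#' Percent of the epithelial surface covered by bacterial contact
#'
#' @param call a `biofilm_call` from [classify_biofilm()].
#' @param total_edge_length_um total arc length of the epithelial edge;
#'   defaults to the length recorded in the call.
#' @return coverage in `[0, 100]`.
#' @export
coverage_percent <- function(call, total_edge_length_um = call$total_edge_length_um) {
  stopifnot(inherits(call, "biofilm_call"))
  if (!is.numeric(total_edge_length_um) || total_edge_length_um <= 0) {
    stop_mucoscape("mucoscape_parameter_error", "'total_edge_length_um' must be > 0")
  }
  covered <- sum(call$spans$end_um - call$spans$start_um)
  min(max(100 * covered / total_edge_length_um, 0), 100)
}

#' Bacterial abundance grade per 200 um of epithelial surface
#'
#' Grades the screening sheet's abundance column: 0 = none, 1 = up to 5
#' bacteria, 2 = up to 20 bacteria per 200 um of colonic epithelial cell
#' surface, 3 = more than 20 (the published scale stops at 2 but graded
#' specimens score 3; the extrapolation is deliberate).
#'
#' @param count_per_200um bacteria per 200 um of epithelial edge.
#' @return grade in `{0, 1, 2, 3}`.
#' @export
abundance_grade <- function(count_per_200um) {
  check_positive_scalar(count_per_200um, "count_per_200um", allow_zero = TRUE)
  if (count_per_200um == 0) 0
  else if (count_per_200um <= 5) 1
  else if (count_per_200um <= 20) 2
  else 3
}

#' Per-sample composite biofilm score
#'
#' Builds a screening-sheet record and applies the positivity cutoff
#' (score > 2.5). The composite score equals the abundance grade by
#' default — the published score sheets carry abundance 3 for
#' biofilm-positive samples, consistent with this reading — but the
#' combiner is pluggable. The DAPI-without-Cy3 flag is a quality control
#' field (guards against non-bacterial DAPI objects) and does not enter
#' the score.
#'
#' @param sample_id sample identifier.
#' @param mucus_grade mucus quality in half steps 0-2
#'   (0 = none, 1 = some, 2 = excellent).
#' @param abundance_grade abundance grade (>= 0; see [abundance_grade()]).
#' @param coverage_pct percent of epithelial surface covered, in `[0, 100]`.
#' @param dapi_without_cy3 logical quality flag.
#' @param criteria a [biofilm_criteria()] providing the score cutoff.
#' @param combiner function(mucus, abundance, coverage, dapi) -> score.
#' @param notes free text.
#' @return object of class `sample_score` (also a valid [write_report()] row).
#' @export
score_sample <- function(sample_id, mucus_grade, abundance_grade, coverage_pct,
                         dapi_without_cy3 = FALSE,
                         criteria = biofilm_criteria(),
                         combiner = function(mucus, abundance, coverage, dapi) abundance,
                         notes = "") {
  if (!is.numeric(mucus_grade) || !mucus_grade %in% seq(0, 2, by = 0.5)) {
    stop_mucoscape("mucoscape_validation_error",
                   "'mucus_grade' must be one of 0, 0.5, 1, 1.5, 2")
  }
  check_positive_scalar(abundance_grade, "abundance_grade", allow_zero = TRUE)
  if (!is.numeric(coverage_pct) || coverage_pct < 0 || coverage_pct > 100) {
    stop_mucoscape("mucoscape_validation_error",
                   "'coverage_pct' must lie in [0, 100]")
  }
  composite <- combiner(mucus_grade, abundance_grade, coverage_pct,
                        isTRUE(dapi_without_cy3))
  structure(list(
    sample_id = as.character(sample_id),
    mucus_grade = mucus_grade,
    abundance_grade = abundance_grade,
    coverage_pct = coverage_pct,
    dapi_without_cy3 = isTRUE(dapi_without_cy3),
    composite_score = composite,
    biofilm_positive = composite > criteria$score_cutoff,
    notes = as.character(notes)
  ), class = "sample_score")
}

#' @export
print.sample_score <- function(x, ...) {
  cat(sprintf("<sample_score> %s: score %.2g -> %s (mucus %.2g, abundance %.2g, coverage %g%%)\n",
              x$sample_id, x$composite_score,
              if (x$biofilm_positive) "biofilm POSITIVE" else "negative",
              x$mucus_grade, x$abundance_grade, x$coverage_pct))
  invisible(x)
}
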