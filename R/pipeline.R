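#' Pipeline configuration
#'
#' Bundles every stage's parameters with one global seed from which all
#' per-sample, per-stage seeds are derived deterministically.
#'
#' @param pixel_size_um,section_thickness_um default calibration for images
#'   that carry none.
#' @param channel_map optional page-to-channel names for [read_image()].
#' @param mucosal_params,luminal_params [segmentation_params()] per
#'   compartment.
#' @param n_points luminal-edge points for the thickness estimate.
#' @param spot a [spot_params()].
#' @param criteria a [biofilm_criteria()].
#' @param seed global integer seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(pixel_size_um = 0.5, section_thickness_um = 5,
                       channel_map = NULL,
                       mucosal_params = segmentation_params(),
                       luminal_params = segmentation_params(keep_largest_component = FALSE),
                       n_points = 100,
                       spot = spot_params(),
                       criteria = biofilm_criteria(),
                       seed = 1) {
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_positive_scalar(section_thickness_um, "section_thickness_um")
  stopifnot(inherits(mucosal_params, "segmentation_params"),
            inherits(luminal_params, "segmentation_params"),
            inherits(spot, "spot_params"),
            inherits(criteria, "biofilm_criteria"))
  structure(list(pixel_size_um = pixel_size_um,
                 section_thickness_um = section_thickness_um,
                 channel_map = channel_map,
                 mucosal_params = mucosal_params,
                 luminal_params = luminal_params,
                 n_points = as.integer(n_points),
                 spot = spot, criteria = criteria,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Coarse image-derived mucus grade from the measured inner mucus thickness:
# 2 ("excellent") for a clearly intact layer, 1 ("some") for a thin one,
# 0 for essentially absent. Thresholds are stated, not tuned: half and a
# tenth of a typical 20 um murine inner layer.
mucus_grade_from_thickness <- function(thickness_um) {
  if (!is.finite(thickness_um)) return(0)
  if (thickness_um >= 10) 2 else if (thickness_um >= 2) 1 else 0
}

#' Analyze one calibrated image
#'
#' Runs segmentation, edge extraction, intensity quantification, thickness
#' estimation, bacterial density, biofilm classification and scoring on a
#' single [multichannel_image()].
#'
#' @param img a [multichannel_image()].
#' @param sample_id sample identifier for reports.
#' @param config a [run_config()].
#' @return `list(row = wide per-sample record, score = sample_score,
#'   masks = list(mucosal, luminal), call = biofilm_call, ...)`.
#' @export
analyze_sample <- function(img, sample_id, config = run_config()) {
  seed_thick <- hash31(config$seed, "thickness", sample_id)
  mucosal <- mucosal_mask(img, config$mucosal_params)
  luminal <- luminal_mask(img, mucosal, config$luminal_params)
  edges <- mask_edges(mucosal, luminal)
  thick <- inner_mucus_thickness(edges$mucosal_edge, edges$luminal_edge,
                                 n_points = config$n_points, seed = seed_thick)
  dens <- bacterial_density(img, luminal, config$spot)
  # contact from the thresholded signal footprint in the 1 um band: robust
  # where confluent biofilm carpets defeat individual spot resolution
  fp <- contact_footprint(img, edges$mucosal_edge, mucosal$grid,
                          contact_band_um = config$criteria$contact_band_um,
                          intensity_threshold = config$spot$intensity_threshold)
  call <- classify_biofilm(edges$mucosal_edge, fp$centers, config$criteria,
                           section_thickness_um = img$section_thickness_um)
  cov <- coverage_percent(call)
  band_count <- sum(call$spans$count)
  per200 <- if (call$total_edge_length_um > 0) {
    band_count / call$total_edge_length_um * 200
  } else 0
  score <- score_sample(
    sample_id,
    mucus_grade = mucus_grade_from_thickness(thick$mean_um),
    abundance_grade = abundance_grade(per200),
    coverage_pct = cov,
    dapi_without_cy3 = FALSE,
    criteria = config$criteria,
    notes = sprintf("max span %.1f um; band density %.3g/ml",
                    call$max_contiguous_span_um, call$band_density_per_ml)
  )
  means <- list(
    dapi_mucosal = mean_intensity(img, "DAPI", mucosal),
    eub_luminal = mean_intensity(img, "Eub", luminal),
    eub_mucosal = mean_intensity(img, "Eub", mucosal)
  )
  row <- data.frame(
    sample_id = as.character(sample_id),
    mean_dapi_mucosal = means$dapi_mucosal,
    mean_eub_luminal = means$eub_luminal,
    mean_eub_mucosal = means$eub_mucosal,
    thickness_mean_um = thick$mean_um,
    thickness_median_um = thick$median_um,
    n_points = thick$n_points,
    density_per_ml = dens$density_per_ml,
    bacterium_count = dens$bacterium_count,
    max_span_um = call$max_contiguous_span_um,
    band_density_per_ml = call$band_density_per_ml,
    coverage_pct = cov,
    composite_score = score$composite_score,
    biofilm_positive = score$biofilm_positive,
    stringsAsFactors = FALSE
  )
  list(row = row, score = score, masks = list(mucosal = mucosal, luminal = luminal),
       call = call, thickness = thick, density = dens, edges = edges)
}

#' Run the full pipeline over a batch of samples
#'
#' Orchestrates simulate/read, segment, quantify, classify, score and
#' report for a list of inputs; each input is either a [phantom_spec()]
#' (simulated on the fly with a per-sample derived seed) or a TIFF path.
#' Failures are isolated per sample: remaining samples still run, and the
#' failed ids are reported.
#'
#' Outputs under `out_dir`: `quantification.csv` (wide per-sample record),
#' `scores.csv` (screening sheet via [write_report()]), per-sample mask
#' TIFFs under `masks/`, and `provenance.json`. Reruns with the same
#' config and inputs are byte-identical.
#'
#' @param inputs named list of [phantom_spec()]s and/or file paths; names
#'   become sample ids.
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @param write_masks write per-sample compartment masks (default TRUE).
#' @return `list(results, failures, quantification, scores_path, ...)`,
#'   invisibly.
#' @export
run_pipeline <- function(inputs, config = run_config(), out_dir, write_masks = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names(inputs)) && length(inputs) > 0) {
    names(inputs) <- sprintf("sample%02d", seq_along(inputs))
  }
  results <- list()
  failures <- character(0)
  for (sid in names(inputs)) {
    res <- tryCatch({
      inp <- inputs[[sid]]
      img <- if (inherits(inp, "phantom_spec")) {
        inp$seed <- hash31(config$seed, "simulate", sid)
        generate_phantom(inp)$image
      } else {
        read_image(inp, channel_map = config$channel_map,
                   pixel_size_um = config$pixel_size_um,
                   section_thickness_um = config$section_thickness_um)
      }
      analyze_sample(img, sid, config)
    }, error = function(e) {
      message(sprintf("sample %s failed: %s", sid, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failures <- c(failures, sid) else results[[sid]] <- res
  }
  quant <- if (length(results) > 0) {
    do.call(rbind, lapply(results, `[[`, "row"))
  } else {
    analyze_sample_empty_frame()
  }
  quant <- quant[order(quant$sample_id), , drop = FALSE]
  rownames(quant) <- NULL
  quant_path <- file.path(out_dir, "quantification.csv")
  write.csv(format(quant, digits = 10, trim = TRUE, scientific = NA),
            quant_path, row.names = FALSE)
  scores_path <- file.path(out_dir, "scores.csv")
  write_report(lapply(results, function(r) unclass(r$score)), scores_path)
  if (write_masks && length(results) > 0) {
    mdir <- file.path(out_dir, "masks")
    dir.create(mdir, showWarnings = FALSE)
    for (sid in names(results)) {
      write_mask(results[[sid]]$masks$mucosal,
                 file.path(mdir, sprintf("%s_mucosal.tif", sid)))
      write_mask(results[[sid]]$masks$luminal,
                 file.path(mdir, sprintf("%s_luminal.tif", sid)))
    }
  }
  write_provenance(file.path(out_dir, "provenance.json"),
                   config = unclass_recursive(config), seed = config$seed)
  invisible(list(results = results, failures = failures,
                 quantification = quant,
                 quantification_path = quant_path,
                 scores_path = scores_path))
}

analyze_sample_empty_frame <- function() {
  data.frame(sample_id = character(0), mean_dapi_mucosal = numeric(0),
             mean_eub_luminal = numeric(0), mean_eub_mucosal = numeric(0),
             thickness_mean_um = numeric(0), thickness_median_um = numeric(0),
             n_points = integer(0), density_per_ml = numeric(0),
             bacterium_count = integer(0), max_span_um = numeric(0),
             band_density_per_ml = numeric(0), coverage_pct = numeric(0),
             composite_score = numeric(0), biofilm_positive = logical(0),
             stringsAsFactors = FALSE)
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_recursive)
  } else x
}
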