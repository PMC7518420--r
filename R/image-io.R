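#' Calibrated multichannel fluorescence image
#'
#' Container for a set of named 2D intensity channels (e.g. `"DAPI"`,
#' `"Eub"`, `"WGA"`) sharing one physical calibration: the lateral pixel
#' size and the histological section thickness. The section thickness is
#' what turns 2D bacterial counts into volumetric densities (per ml).
#'
#' @param channels named list of numeric matrices, all the same dimension,
#'   finite and non-negative.
#' @param pixel_size_um lateral pixel size in micrometres (> 0).
#' @param section_thickness_um physical section thickness in micrometres
#'   (> 0); standard histology sections are 5 um.
#' @return an object of class `multichannel_image`.
#' @export
#' @examples
#' img <- multichannel_image(
#'   list(DAPI = matrix(0, 4, 4), Eub = matrix(0, 4, 4)),
#'   pixel_size_um = 0.5, section_thickness_um = 5
#' )
#' channel_names(img)
multichannel_image <- function(channels, pixel_size_um, section_thickness_um = 5) {
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop_mucoscape("mucoscape_validation_error",
                   "'channels' must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), TRUE))) {
    stop_mucoscape("mucoscape_validation_error", "all channels must be numeric matrices")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop_mucoscape("mucoscape_validation_error", "all channels must share identical dimensions")
  }
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop_mucoscape("mucoscape_validation_error", sprintf(
        "channel '%s' must be finite and non-negative", nm))
    }
  }
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_positive_scalar(section_thickness_um, "section_thickness_um")
  structure(
    list(channels = channels,
         pixel_size_um = pixel_size_um,
         section_thickness_um = section_thickness_um),
    class = "multichannel_image"
  )
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multichannel_image> %d x %d px (%.3g x %.3g um), %.3g um/px, section %.3g um\n",
              d[1], d[2], d[1] * x$pixel_size_um, d[2] * x$pixel_size_um,
              x$pixel_size_um, x$section_thickness_um))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname multichannel_image
#' @param img a `multichannel_image`.
#' @export
channel_names <- function(img) names(img$channels)

#' @rdname multichannel_image
#' @param channel channel name.
#' @export
get_channel <- function(img, channel) {
  if (!channel %in% names(img$channels)) {
    stop_mucoscape("mucoscape_configuration_error",
                   sprintf("channel '%s' not present (have: %s)", channel,
                           paste(names(img$channels), collapse = ", ")))
  }
  img$channels[[channel]]
}

#' Binary compartment mask
#'
#' A boolean raster labelling one tissue compartment, matching the source
#' image shape. Labels follow the segmentation vocabulary: `mucosal`
#' (DAPI-defined tissue region of interest), `luminal` (bacterial signal
#' outside the mucosa), or `other`.
#'
#' @param grid logical matrix.
#' @param label one of `"mucosal"`, `"luminal"`, `"other"`.
#' @param pixel_size_um optional pixel calibration carried along for
#'   area computations.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(grid, label = c("other", "mucosal", "luminal"),
                        pixel_size_um = NULL) {
  label <- match.arg(label)
  if (!is.matrix(grid) || !is.logical(grid) || any(is.na(grid))) {
    stop_mucoscape("mucoscape_validation_error", "mask grid must be a logical matrix without NA")
  }
  structure(list(grid = grid, label = label, pixel_size_um = pixel_size_um),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask:%s> %d x %d px, %d foreground px\n",
              x$label, nrow(x$grid), ncol(x$grid), sum(x$grid)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Minimal baseline TIFF 6.0 codec (uncompressed, grayscale, multi-page).
## No R TIFF reader/writer is available in this toolchain, so the package
## carries its own: little-endian, single-sample pixels, float64 for
## intensity channels (lossless round trip) and uint8 for masks.

TIFF_TYPE_ASCII <- 2L
TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG <- 4L

tiff_entry <- function(tag, type, count, value_raw4) {
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value_raw4)
}

raw_long <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
raw_short4 <- function(x) c(writeBin(as.integer(x), raw(), size = 2, endian = "little"),
                            as.raw(c(0, 0)))

# Serialize one page: returns list(data = raw pixel strip, ifd_builder)
tiff_page_raw <- function(m, bits, sample_format, description) {
  if (bits == 64) {
    px <- writeBin(as.numeric(t(m)), raw(), size = 8, endian = "little")
  } else if (bits == 8) {
    px <- as.raw(as.integer(t(m)))
  } else {
    stop_mucoscape("mucoscape_io_error", "unsupported bit depth for writing")
  }
  list(px = px, bits = bits, fmt = sample_format,
       desc = c(charToRaw(description), as.raw(0)),
       width = ncol(m), height = nrow(m))
}

write_tiff_pages <- function(pages, path) {
  n_entries <- 11L
  ifd_size <- 2L + n_entries * 12L + 4L
  # layout: header, all pixel/description blocks (word-aligned), all IFDs
  pos <- 8L
  data_off <- desc_off <- integer(length(pages))
  for (i in seq_along(pages)) {
    data_off[i] <- pos
    pos <- pos + length(pages[[i]]$px)
    desc_off[i] <- pos
    pos <- pos + length(pages[[i]]$desc)
    if (pos %% 2 == 1) pos <- pos + 1L
  }
  ifd_off <- pos + (seq_along(pages) - 1L) * ifd_size
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    writeBin(p$px, con)
    writeBin(p$desc, con)
    if ((desc_off[i] + length(p$desc)) %% 2 == 1) writeBin(as.raw(0), con)
  }
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    entries <- list(
      tiff_entry(256, TIFF_TYPE_LONG, 1, raw_long(p$width)),
      tiff_entry(257, TIFF_TYPE_LONG, 1, raw_long(p$height)),
      tiff_entry(258, TIFF_TYPE_SHORT, 1, raw_short4(p$bits)),
      tiff_entry(259, TIFF_TYPE_SHORT, 1, raw_short4(1)),
      tiff_entry(262, TIFF_TYPE_SHORT, 1, raw_short4(1)),
      tiff_entry(270, TIFF_TYPE_ASCII, length(p$desc), raw_long(desc_off[i])),
      tiff_entry(273, TIFF_TYPE_LONG, 1, raw_long(data_off[i])),
      tiff_entry(277, TIFF_TYPE_SHORT, 1, raw_short4(1)),
      tiff_entry(278, TIFF_TYPE_LONG, 1, raw_long(p$height)),
      tiff_entry(279, TIFF_TYPE_LONG, 1, raw_long(length(p$px))),
      tiff_entry(339, TIFF_TYPE_SHORT, 1, raw_short4(p$fmt))
    )
    writeBin(as.integer(length(entries)), con, size = 2, endian = "little")
    for (e in entries) writeBin(e, con)
    next_off <- if (i < length(pages)) ifd_off[i + 1] else 0L
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) {
    stop_mucoscape("mucoscape_io_error", sprintf("file not found: %s", path))
  }
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 8 || rawToChar(bytes[1:2]) != "II") {
    stop_mucoscape("mucoscape_io_error",
                   "not a little-endian TIFF file (or unreadable)")
  }
  get_int <- function(off, size) {
    readBin(bytes[(off + 1):(off + size)], "integer", size = size,
            endian = "little", signed = size >= 4)
  }
  magic <- get_int(2, 2)
  if (magic != 42) stop_mucoscape("mucoscape_io_error", "bad TIFF magic number")
  ifd <- get_int(4, 4)
  pages <- list()
  while (ifd != 0) {
    n <- get_int(ifd, 2)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd + 2 + (k - 1) * 12
      tag <- get_int(e, 2)
      type <- get_int(e + 2, 2)
      count <- get_int(e + 4, 4)
      val_off <- e + 8
      read_vals <- function() {
        size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)[[as.character(type)]]
        total <- size * count
        off <- if (total <= 4) val_off else get_int(val_off, 4)
        if (type == TIFF_TYPE_ASCII) {
          return(rawToChar(bytes[(off + 1):(off + count - 1)]))
        }
        vapply(seq_len(count), function(i) get_int(off + (i - 1) * size, size), 0)
      }
      tags[[as.character(tag)]] <- read_vals()
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop_mucoscape("mucoscape_io_error",
                                             sprintf("TIFF tag %d missing", tag))
        default
      } else v
    }
    if (need(259, 1) != 1) {
      stop_mucoscape("mucoscape_io_error", "compressed TIFF not supported")
    }
    width <- need(256); height <- need(257)
    bits <- need(258, 8); fmt <- need(339, 1)
    offs <- need(273); counts <- need(279)
    strip <- unlist(lapply(seq_along(offs), function(i) {
      bytes[(offs[i] + 1):(offs[i] + counts[i])]
    }))
    if (fmt == 3 && bits == 64) {
      v <- readBin(strip, "numeric", n = width * height, size = 8, endian = "little")
    } else if (fmt == 3 && bits == 32) {
      v <- readBin(strip, "numeric", n = width * height, size = 4, endian = "little")
    } else if (fmt == 1 && bits == 8) {
      v <- as.numeric(strip)
    } else if (fmt == 1 && bits == 16) {
      v <- readBin(strip, "integer", n = width * height, size = 2,
                   endian = "little", signed = FALSE)
    } else {
      stop_mucoscape("mucoscape_io_error",
                     sprintf("unsupported sample format %d / %d bits", fmt, bits))
    }
    m <- matrix(v, nrow = height, ncol = width, byrow = TRUE)
    pages[[length(pages) + 1]] <- list(data = m, description = need(270, ""))
    ifd <- get_int(ifd + 2 + n * 12, 4)
  }
  pages
}

#' Write a multichannel image as a multi-page TIFF
#'
#' One grayscale 64-bit float page per channel (lossless round trip); the
#' channel name and physical calibration are stored in each page's
#' ImageDescription as JSON.
#'
#' @param img a [multichannel_image()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "multichannel_image"))
  pages <- lapply(names(img$channels), function(nm) {
    desc <- jsonlite::toJSON(list(channel = nm,
                                  pixel_size_um = img$pixel_size_um,
                                  section_thickness_um = img$section_thickness_um),
                             auto_unbox = TRUE, digits = NA)
    tiff_page_raw(img$channels[[nm]], bits = 64, sample_format = 3,
                  description = as.character(desc))
  })
  write_tiff_pages(pages, path)
  invisible(path)
}

#' Read a multichannel image from a multi-page TIFF
#'
#' Pages map to channels either through `channel_map` (names indexed by page
#' number) or, when absent, through the per-page JSON description written by
#' [write_image()]. Missing calibration falls back to the supplied defaults
#' with a warning.
#'
#' @param path TIFF file path.
#' @param channel_map optional character vector naming each page in order,
#'   e.g. `c("DAPI", "Eub", "WGA")`; overrides embedded names.
#' @param pixel_size_um,section_thickness_um calibration overrides/defaults
#'   (used when the file carries none).
#' @param required_channels channels that must be present after mapping;
#'   default `c("DAPI", "Eub")`, the two channels the segmentation needs.
#' @return a [multichannel_image()].
#' @export
read_image <- function(path, channel_map = NULL, pixel_size_um = NULL,
                       section_thickness_um = NULL,
                       required_channels = c("DAPI", "Eub")) {
  pages <- read_tiff_pages(path)
  metas <- lapply(pages, function(p) {
    m <- try(jsonlite::fromJSON(p$description), silent = TRUE)
    if (inherits(m, "try-error") || !is.list(m)) list() else m
  })
  nms <- if (!is.null(channel_map)) {
    if (length(channel_map) != length(pages)) {
      stop_mucoscape("mucoscape_configuration_error", sprintf(
        "channel_map has %d names but file has %d pages",
        length(channel_map), length(pages)))
    }
    as.character(channel_map)
  } else {
    vapply(seq_along(pages), function(i) {
      nm <- metas[[i]]$channel
      if (is.null(nm)) sprintf("page%d", i) else nm
    }, character(1))
  }
  missing_req <- setdiff(required_channels, nms)
  if (length(missing_req) > 0) {
    stop_mucoscape("mucoscape_configuration_error", sprintf(
      "required channel(s) not mapped: %s", paste(missing_req, collapse = ", ")))
  }
  px <- pixel_size_um
  st <- section_thickness_um
  if (is.null(px)) px <- metas[[1]]$pixel_size_um
  if (is.null(st)) st <- metas[[1]]$section_thickness_um
  if (is.null(px)) {
    warning("no pixel size in file or arguments; falling back to 0.5 um/px")
    px <- 0.5
  }
  if (is.null(st)) {
    warning("no section thickness in file or arguments; falling back to 5 um")
    st <- 5
  }
  multichannel_image(setNames(lapply(pages, `[[`, "data"), nms),
                     pixel_size_um = px, section_thickness_um = st)
}

#' Write / read a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask a [binary_mask()].
#' @param path file path.
#' @return `path` (write) or a [binary_mask()] (read).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  desc <- jsonlite::toJSON(list(label = mask$label,
                                pixel_size_um = mask$pixel_size_um),
                           auto_unbox = TRUE, null = "null", digits = NA)
  page <- tiff_page_raw(matrix(as.integer(mask$grid) * 255L,
                               nrow(mask$grid), ncol(mask$grid)),
                        bits = 8, sample_format = 1,
                        description = as.character(desc))
  write_tiff_pages(list(page), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  pages <- read_tiff_pages(path)
  meta <- try(jsonlite::fromJSON(pages[[1]]$description), silent = TRUE)
  label <- "other"
  px <- NULL
  if (!inherits(meta, "try-error") && is.list(meta)) {
    if (!is.null(meta$label)) label <- meta$label
    if (!is.null(meta$pixel_size_um)) px <- meta$pixel_size_um
  }
  binary_mask(pages[[1]]$data > 127, label = label, pixel_size_um = px)
}

## ---------------------------------------------------------------------------
## Score sheets and provenance

#' Write a per-sample biofilm score sheet
#'
#' Produces the standard screening sheet: one row per sample with the mucus
#' grade, the bacterial abundance grade per 200 um of colonic epithelial
#' cell (CEC) surface, the percent biofilm coverage, the DAPI-without-Cy3
#' quality flag and free-text notes. Rows are sorted by sample id; coverage
#' is rendered with a percent sign.
#'
#' @param rows a data.frame (or list of lists) with fields `sample_id`,
#'   `mucus_grade`, `abundance_grade`, `coverage_pct` (0-100),
#'   `dapi_without_cy3` (logical), `notes`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  fields <- c("sample_id", "mucus_grade", "abundance_grade", "coverage_pct",
              "dapi_without_cy3", "notes")
  if (is.data.frame(rows)) rows <- lapply(seq_len(nrow(rows)), function(i) as.list(rows[i, ]))
  for (i in seq_along(rows)) {
    missing <- setdiff(fields, names(rows[[i]]))
    if (length(missing) > 0) {
      stop_mucoscape("mucoscape_validation_error", sprintf(
        "record %d (%s) is missing field(s): %s", i,
        if (!is.null(rows[[i]]$sample_id)) rows[[i]]$sample_id else "<no id>",
        paste(missing, collapse = ", ")))
    }
  }
  header <- c("Sample ID", "Mucus present",
              "Bacteria abundance per 200 μm CEC",
              "Percentage of biofilm coverage", "DAPI without Cy3", "Notes")
  df <- data.frame(
    a = vapply(rows, function(r) as.character(r$sample_id), character(1)),
    b = vapply(rows, function(r) format(r$mucus_grade), character(1)),
    c = vapply(rows, function(r) format(r$abundance_grade), character(1)),
    d = vapply(rows, function(r) sprintf("%g%%", r$coverage_pct), character(1)),
    e = vapply(rows, function(r) if (isTRUE(r$dapi_without_cy3)) "Yes" else "No",
               character(1)),
    f = vapply(rows, function(r) as.character(r$notes), character(1)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$a), , drop = FALSE]
  names(df) <- header
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a score sheet written by [write_report()]
#' @param path CSV path.
#' @return data.frame with the canonical field names and numeric coverage.
#' @export
read_report <- function(path) {
  df <- read.csv(path, check.names = FALSE, encoding = "UTF-8")
  out <- data.frame(
    sample_id = as.character(df[[1]]),
    mucus_grade = as.numeric(df[[2]]),
    abundance_grade = as.numeric(df[[3]]),
    coverage_pct = as.numeric(sub("%$", "", df[[4]])),
    dapi_without_cy3 = df[[5]] == "Yes",
    notes = as.character(df[[6]]),
    stringsAsFactors = FALSE
  )
  out
}

#' Write a provenance sidecar
#'
#' Records the configuration fingerprint, global seed and package version
#' next to any pipeline output, so a run can be reproduced exactly.
#' Deliberately excludes timestamps: reruns must be byte-identical.
#'
#' @param path output JSON path.
#' @param config any serializable configuration object.
#' @param seed integer seed that governed the run.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, seed) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(
    list(config_md5 = hash, seed = seed,
         package = "mucoscape",
         version = as.character(utils::packageVersion("mucoscape"))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
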