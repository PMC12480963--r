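# Image and results I/O.
#
# Multichannel fluorescence stacks are stored as multi-page 16-bit TIFF with
# an adjacent OME-XML companion document ("<base>.companion.ome.xml") that
# carries the physical pixel size and the channel names.  Brightfield RGB is
# stored as PNG or single-page TIFF.  PNG carries no calibration, so reading
# it requires an explicit pixel-size override -- never a silent default.

ome_companion_path <- function(path) {
  sub("\\.(ome\\.)?tiff?$", "", path, ignore.case = TRUE) |>
    paste0(".companion.ome.xml")
}

#' Write a multichannel fluorescence image as TIFF + OME-XML companion
#'
#' @param channels named list of [channel_image] objects sharing one shape
#'   and calibration.
#' @param path output path (`.ome.tif` recommended). The OME-XML companion
#'   is written next to it.
#' @return `path`, invisibly.
#' @export
write_ome_tiff <- function(channels, path) {
  stopifnot(length(channels) >= 1L)
  ps <- vapply(channels, function(ch) ch$pixel_size_um, numeric(1))
  if (diff(range(ps)) > 0) stop("write_ome_tiff: channels disagree on pixel size")
  pages <- lapply(channels, function(ch) {
    m <- round(ch$pixels)
    if (max(m) > 65535) stop("write_ome_tiff: intensity exceeds 16-bit range")
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  names <- vapply(channels, function(ch) ch$channel_name, character(1))
  dims <- dim(channels[[1]]$pixels)
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    sprintf('  <Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYCZT" Type="uint16" SizeX="%d" SizeY="%d" SizeC="%d" SizeZ="1" SizeT="1" PhysicalSizeX="%.10g" PhysicalSizeY="%.10g" PhysicalSizeXUnit="µm" PhysicalSizeYUnit="µm">',
            dims[2], dims[1], length(channels), ps[1], ps[1]),
    sprintf('    <Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
            seq_along(names) - 1L, names),
    '  </Pixels></Image>',
    '</OME>')
  writeLines(xml, ome_companion_path(path))
  invisible(path)
}

read_ome_companion <- function(path) {
  cp <- ome_companion_path(path)
  if (!file.exists(cp)) return(NULL)
  doc <- xml2::read_xml(cp)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  list(pixel_size_um = as.numeric(xml2::xml_attr(px, "PhysicalSizeX")),
       channel_names = xml2::xml_attr(xml2::xml_find_all(doc, ".//Channel"), "Name"))
}

#' Read a calibrated image
#'
#' Reads TIFF (optionally with OME-XML companion metadata) or PNG. A
#' fluorescence stack returns one [channel_image] (when `channel` is given)
#' or a named list of them; an RGB file returns an H x W x 3 intensity array
#' (0-255 scale) with a `pixel_size_um` attribute.
#'
#' @param path file path (`.tif`, `.tiff`, `.ome.tif`, `.png`).
#' @param channel optional channel name to extract (e.g. `"DAPI"`).
#' @param pixel_size_um explicit calibration override in micrometres;
#'   required when the file carries no OME metadata.
#' @return [channel_image], list of them, or calibrated RGB array.
#' @export
read_image <- function(path, channel = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  meta <- if (!is_png) read_ome_companion(path) else NULL
  ps <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(ps) || !is.finite(ps))
    stop("read_image: no pixel-size metadata in ", basename(path),
         " and no `pixel_size_um` override given; refusing to guess calibration")
  if (is_png) {
    a <- png::readPNG(path)
    return(calibrated_rgb(a * 255, ps))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1L && length(dim(pages[[1]])) == 3L) {
    return(calibrated_rgb(pages[[1]] * 255, ps))
  }
  nm <- meta$channel_names %||% sprintf("channel_%d", seq_along(pages))
  chs <- lapply(seq_along(pages), function(i)
    channel_image(pages[[i]] * 65535, ps, nm[i]))
  names(chs) <- nm
  if (!is.null(channel)) {
    if (!channel %in% nm)
      stop("read_image: channel '", channel, "' not found; available: ",
           paste(nm, collapse = ", "))
    return(chs[[channel]])
  }
  chs
}

calibrated_rgb <- function(a, pixel_size_um) {
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3]
  attr(a, "pixel_size_um") <- pixel_size_um
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an RGB brightfield image as PNG
#'
#' @param rgb H x W x 3 array on the 0-255 scale.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(pmin(pmax(rgb / 255, 0), 1), path)
  invisible(path)
}

# ---- GeoJSON ---------------------------------------------------------------
# Polygons are exported in image pixel coordinates: x to the right, y down,
# 0-based, vertices at pixel corners.  Calibration is recorded in feature
# properties so the export is lossless.

#' Write polygons to GeoJSON
#'
#' @param polygons named list of 2-column (x, y) vertex matrices, open rings
#'   (the closing vertex is added on write and removed on read).
#' @param path output `.geojson` path.
#' @param pixel_size_um calibration recorded in each feature's properties.
#' @param properties optional list (parallel to `polygons`) of extra
#'   per-feature property lists.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(polygons, path, pixel_size_um = NA_real_,
                          properties = NULL) {
  feats <- lapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    ring <- rbind(p, p[1, , drop = FALSE])
    props <- c(list(name = names(polygons)[i] %||% as.character(i),
                    pixel_size_um = pixel_size_um),
               if (!is.null(properties)) properties[[i]])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) as.numeric(ring[j, ])))),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' Read polygons from GeoJSON written by [write_geojson()]
#' @param path `.geojson` path.
#' @return named list of 2-column (x, y) vertex matrices (closing vertex dropped).
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], as.numeric))
    ring[-nrow(ring), , drop = FALSE]
  })
  names(out) <- vapply(fc$features, function(f)
    as.character(f$properties$name %||% ""), character(1))
  out
}

#' Write result tables, masks and polygons with a reproducibility manifest
#'
#' Tables go to CSV (header always written, even for empty tables), polygon
#' sets to GeoJSON, label masks to 16-bit TIFF; a JSON manifest records the
#' package version, an md5 hash of the configuration, the seed and the files
#' written, so two runs with the same config and seed are byte-comparable.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if needed).
#' @param masks named list of integer matrices (written as 16-bit TIFF).
#' @param polygons named list of polygon sets for [write_geojson()].
#' @param config configuration list hashed into the manifest.
#' @param seed integer seed recorded in the manifest.
#' @param pixel_size_um calibration for polygon properties.
#' @return the manifest, invisibly.
#' @export
write_results <- function(tables, out_dir, masks = NULL, polygons = NULL,
                          config = list(), seed = NA_integer_,
                          pixel_size_um = NA_real_) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    ok <- tryCatch({ write.csv(tables[[nm]], f, row.names = FALSE); TRUE },
                   error = function(e) stop("write_results: failed writing ", f,
                                            ": ", conditionMessage(e)))
    files <- c(files, f)
  }
  for (nm in names(masks)) {
    f <- file.path(out_dir, paste0(nm, ".tif"))
    tiff::writeTIFF(masks[[nm]] / 65535, f, bits.per.sample = 16L)
    files <- c(files, f)
  }
  for (nm in names(polygons)) {
    f <- file.path(out_dir, paste0(nm, ".geojson"))
    write_geojson(polygons[[nm]], f, pixel_size_um = pixel_size_um)
    files <- c(files, f)
  }
  manifest <- list(package = "myohisto",
                   version = as.character(utils::packageVersion("myohisto")),
                   config_hash = config_hash(config),
                   seed = seed,
                   files = basename(files))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
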