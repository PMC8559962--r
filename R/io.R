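# OME-TIFF reading/writing and deterministic CSV tables.

ome_dimension_orders <- c("XYZCT", "XYZTC", "XYCZT", "XYCTZ", "XYTZC",
                          "XYTCZ")

ome_xml <- function(m) {
  d <- dim(m$data)
  sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYZCT" ',
    'Type="uint16" SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="%d" ',
    'PhysicalSizeX="%.6g" PhysicalSizeXUnit="µm" ',
    'PhysicalSizeY="%.6g" PhysicalSizeYUnit="µm" ',
    'PhysicalSizeZ="%.6g" PhysicalSizeZUnit="µm" ',
    'TimeIncrement="%.6g" TimeIncrementUnit="s">',
    '%s</Pixels></Image></OME>'),
    d[2], d[1], d[3], d[4], d[5],
    m$voxel["x"], m$voxel["y"], m$voxel["z"], m$frame_interval,
    paste(sprintf('<Channel ID="Channel:0:%d" Name="%s"/>',
                  seq_along(m$channels) - 1L, m$channels), collapse = ""))
}

#' Write a movie as OME-TIFF
#'
#' Planes are written in XYZCT order (z fastest, then channel, then frame)
#' as 16-bit samples with an OME-XML description embedding the physical
#' calibration. Intensities must be integer counts in `[0, 65535]`; the
#' write/read cycle is lossless.
#'
#' @param m A [movie()].
#' @param path Output path (`.ome.tif`).
#' @return `path`, invisibly.
#' @export
write_movie <- function(m, path) {
  stopifnot(inherits(m, "movie"))
  mx <- max(m$data)
  if (mx > 65535 || any(m$data < 0) || any(m$data != round(m$data)))
    stop("movie data must be integer counts in [0, 65535] for 16-bit OME-TIFF")
  d <- dim(m$data)
  planes <- vector("list", d[3] * d[4] * d[5])
  i <- 0L
  for (t in seq_len(d[5])) for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
    i <- i + 1L
    planes[[i]] <- m$data[, , z, ch, t] / 65535
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L,
                  compression = "LZW", reduce = FALSE)
  # the tiff package does not expose per-page description writing reliably;
  # calibration is stored in a sidecar XML next to the image
  xml2::write_xml(xml2::read_xml(ome_xml(m)), sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".ome.xml")

parse_ome_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  doc <- xml2::read_xml(sc)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  at <- function(a) xml2::xml_attr(px, a)
  need <- function(a) {
    v <- at(a)
    if (is.na(v)) stop("calibration field missing from OME metadata: ", a)
    as.numeric(v)
  }
  chn <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//*[local-name()='Channel']"), "Name")
  list(size = c(x = need("SizeX"), y = need("SizeY"), z = need("SizeZ"),
                c = need("SizeC"), t = need("SizeT")),
       voxel = c(x = need("PhysicalSizeX"), y = need("PhysicalSizeY"),
                 z = need("PhysicalSizeZ")),
       frame_interval = need("TimeIncrement"),
       dimension_order = if (is.na(at("DimensionOrder"))) "XYZCT"
                         else at("DimensionOrder"),
       channels = if (length(chn)) chn else NULL)
}

#' Read an OME-TIFF (or plain TIFF plus sidecar calibration) movie
#'
#' The page sequence is de-interleaved according to the metadata's
#' `DimensionOrder` (any of XYZCT, XYZTC, XYCZT, XYCTZ, XYTZC, XYTCZ) and
#' normalized to the internal (y, x, z, channel, frame) layout, so movies
#' stored with different plane interleavings load identically.
#'
#' @param path TIFF path; calibration is taken from the `.ome.xml` sidecar
#'   (as written by [write_movie()]) or from a `calibration` list.
#' @param calibration Optional list with `voxel` (named x/y/z micrometers),
#'   `frame_interval`, `n_channels`, `n_z`, and optionally
#'   `dimension_order`, overriding/replacing the sidecar.
#' @return A [movie()].
#' @export
read_movie <- function(path, calibration = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- parse_ome_sidecar(path)
  if (!is.null(calibration)) {
    meta <- utils::modifyList(meta %||% list(), calibration)
    if (is.null(meta$dimension_order)) meta$dimension_order <- "XYZCT"
  }
  if (is.null(meta))
    stop("calibration field missing: no OME sidecar found and no ",
         "`calibration` given (need voxel sizes, frame_interval)")
  for (f in c("voxel", "frame_interval"))
    if (is.null(meta[[f]])) stop("calibration field missing: ", f)
  pages <- tiff::readTIFF(path, all = TRUE)
  n_pages <- length(pages)
  if (!is.null(meta$size)) {
    nz <- meta$size["z"]; nc <- meta$size["c"]; nt <- meta$size["t"]
  } else {
    nz <- meta$n_z %||% stop("calibration field missing: n_z")
    nc <- meta$n_channels %||% 1
    nt <- n_pages / (nz * nc)
  }
  if (nz * nc * nt != n_pages)
    stop("truncated or inconsistent file: expected ", nz * nc * nt,
         " planes, found ", n_pages)
  ord <- toupper(meta$dimension_order %||% "XYZCT")
  if (!ord %in% ome_dimension_orders)
    stop("unsupported DimensionOrder: ", ord)
  seq3 <- strsplit(substr(ord, 3, 5), "")[[1]]  # fastest-varying first
  sizes <- c(Z = unname(nz), C = unname(nc), T = unname(nt))
  d1 <- dim(pages[[1]])
  data <- array(0, unname(c(d1[1], d1[2], nz, nc, nt)))
  counts <- sizes[seq3]
  for (p in seq_len(n_pages)) {
    r <- p - 1L
    i1 <- r %% counts[1]
    i2 <- (r %/% counts[1]) %% counts[2]
    i3 <- r %/% (counts[1] * counts[2])
    idx <- c(i1, i2, i3)
    names(idx) <- seq3
    data[, , idx["Z"] + 1L, idx["C"] + 1L, idx["T"] + 1L] <-
      round(pages[[p]] * 65535)
  }
  movie(data, voxel = meta$voxel, frame_interval = meta$frame_interval,
        channels = meta$channels %||% NULL)
}

#' Write result tables as deterministic CSV
#'
#' Tables are written with a fixed column order, a comment header stating
#' the units (micrometers, seconds) and the configuration hash, no row
#' names, and platform-independent line endings, so identical runs produce
#' byte-identical files.
#'
#' @param tables Named list of data frames (or a single data frame).
#' @param path Output directory (for a list) or file path (single table).
#' @param config_hash Optional hash string embedded in the header.
#' @return Character vector of files written, invisibly.
#' @export
write_tables <- function(tables, path, config_hash = NULL) {
  if (is.data.frame(tables)) {
    files <- path
    write_one(tables, path, config_hash)
  } else {
    stopifnot(!is.null(names(tables)))
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    files <- file.path(path, paste0(names(tables), ".csv"))
    for (i in seq_along(tables)) write_one(tables[[i]], files[i], config_hash)
  }
  invisible(files)
}

write_one <- function(df, file, config_hash = NULL) {
  con <- file(file, open = "wb")
  on.exit(close(con))
  hdr <- c("# units: positions in micrometers, times in seconds",
           if (!is.null(config_hash)) paste0("# config_hash: ", config_hash))
  writeLines(hdr, con, sep = "\n")
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double",
                     eol = "\n")
  invisible(file)
}

#' Read a table written by [write_tables()]
#' @param file CSV path.
#' @return Data frame.
#' @export
read_table_csv <- function(file) {
  utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
}
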