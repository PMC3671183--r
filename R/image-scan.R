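# RISH image container, inversion, lamina geometry and line-intensity scans.

#' RISH image container
#'
#' Wraps a 2D intensity grid with its physical pixel size and inversion
#' state. Pixel coordinates are 0-based (row, col) with pixel centers at
#' integer coordinates; row 0 is the apical (top) edge. `dtype` records the
#' value convention: `"uint8"`/`"uint16"` store integer levels, `"real"`
#' stores intensities in \[0,1\].
#'
#' @param pixels numeric matrix of intensities.
#' @param pixel_size_um physical pixel size in micrometers.
#' @param dtype one of `"real"`, `"uint8"`, `"uint16"`.
#' @param inverted has [invert_image()] been applied?
#' @param source_id opaque identifier (e.g. animal/image).
#' @return object of class `rish_image`.
#' @export
rish_image <- function(pixels, pixel_size_um, dtype = "real",
                       inverted = FALSE, source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) < 1L)) {
    stop("pixels must be a nonempty numeric matrix", call. = FALSE)
  }
  dtype <- match.arg(dtype, c("real", "uint8", "uint16"))
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-9)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 dtype = dtype, inverted = isTRUE(inverted),
                 source_id = source_id),
            class = "rish_image")
}

#' @export
print.rish_image <- function(x, ...) {
  cat(sprintf("<rish_image> %d x %d px (%s), %.3f um/px, inverted=%s\n",
              nrow(x$pixels), ncol(x$pixels), x$dtype, x$pixel_size_um,
              x$inverted))
  invisible(x)
}

#' @export
dim.rish_image <- function(x) dim(x$pixels)

dtype_max <- function(dtype) switch(dtype, uint8 = 255, uint16 = 65535, real = 1)

#' Read a RISH image from TIFF or PNG
#'
#' RGB images are converted to luminance using Rec.709 weights
#' (0.2126, 0.7152, 0.0722) before any further processing; an alpha channel,
#' if present, is dropped. Grayscale content is preserved at its native bit
#' depth (`uint8`/`uint16` integer levels); RGB content is stored as `real`.
#'
#' @param path TIFF or PNG file.
#' @param pixel_size_um physical pixel size.
#' @param source_id optional identifier.
#' @return a `rish_image` with `inverted = FALSE`.
#' @export
read_rish_image <- function(path, pixel_size_um, source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, info = TRUE),
    png = png::readPNG(path, info = TRUE),
    stop("unsupported image format: .", ext, call. = FALSE))
  bits <- attr(arr, "bits.per.sample") %||% attr(arr, "info")$bit.depth %||% 8L
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch >= 3L) {
      px <- 0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
      dtype <- "real"
    } else {  # gray (+alpha)
      px <- arr[, , 1]
      dtype <- if (bits >= 16) "uint16" else "uint8"
      px <- round(px * dtype_max(dtype))
    }
  } else {
    dtype <- if (bits >= 16) "uint16" else "uint8"
    px <- round(arr * dtype_max(dtype))
  }
  if (any(dim(px) < 1L)) stop("zero-sized image: ", path, call. = FALSE)
  px <- matrix(as.numeric(px), nrow = nrow(px))  # drop reader attributes
  rish_image(px, pixel_size_um = pixel_size_um, dtype = dtype,
             source_id = source_id)
}

#' Write a RISH image to TIFF or PNG
#'
#' Real-valued images are written as 16-bit grayscale; integer images at
#' their native bit depth. Round-trips through [read_rish_image()] are exact
#' for integer images.
#'
#' @param img a `rish_image`.
#' @param path destination `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_rish_image <- function(img, path) {
  stopifnot(inherits(img, "rish_image"))
  m <- img$pixels / dtype_max(img$dtype)
  bits <- switch(img$dtype, uint8 = 8L, uint16 = 16L, real = 16L)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = bits),
    png = png::writePNG(m, path),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Invert image intensities
#'
#' Colorimetric label is dark on a bright field; inversion makes label
#' intensity increase with signal. Integer images map to
#' `dtype_max - value`, real-valued images to `1 - value`. Inverting an
#' already-inverted image is an error (the operation is tracked, not
#' idempotent).
#'
#' @param img a `rish_image` with `inverted = FALSE`.
#' @return the inverted `rish_image`.
#' @export
invert_image <- function(img) {
  stopifnot(inherits(img, "rish_image"))
  if (img$inverted) stop("image is already inverted", call. = FALSE)
  img$pixels <- dtype_max(img$dtype) - img$pixels
  img$inverted <- TRUE
  img
}

# ---------------------------------------------------------------------------
# Lamina trace and scan geometry

#' Basal lamina trace
#'
#' An ordered polyline of (row, col) pixel coordinates following the basal
#' lamina, typically traced manually or exported by the synthetic generator.
#'
#' @param points 2-column matrix or data.frame with columns `row`, `col`
#'   (0-based, real-valued); at least 2 points, consecutive points distinct.
#' @return object of class `lamina_trace`.
#' @export
lamina_trace <- function(points) {
  pts <- if (is.matrix(points)) points[, c("row", "col"), drop = FALSE] else
    as.matrix(as.data.frame(points)[, c("row", "col")])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 2L) stop("a lamina trace needs at least 2 points", call. = FALSE)
  if (any(rowSums(abs(diff(pts))) == 0)) {
    stop("consecutive trace points must be distinct", call. = FALSE)
  }
  structure(list(points = pts), class = "lamina_trace")
}

#' Read / write a lamina trace as CSV (columns: row, col)
#' @param path CSV file.
#' @return a `lamina_trace` (read) or `path` invisibly (write).
#' @export
read_lamina_trace <- function(path) lamina_trace(utils::read.csv(path))

#' @rdname read_lamina_trace
#' @param trace a `lamina_trace`.
#' @export
write_lamina_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace$points), path, row.names = FALSE)
  invisible(path)
}

#' Local tangent of the lamina polyline
#'
#' Central difference over neighboring vertices; one-sided differences at the
#' endpoints. The result is normalized to unit length.
#'
#' @param trace a `lamina_trace`.
#' @param anchor_index vertex index (1-based).
#' @return unit 2-vector `c(drow, dcol)`.
#' @export
local_tangent <- function(trace, anchor_index) {
  stopifnot(inherits(trace, "lamina_trace"))
  pts <- trace$points
  n <- nrow(pts)
  if (anchor_index < 1L || anchor_index > n) stop("anchor_index out of range",
                                                  call. = FALSE)
  i0 <- max(1L, anchor_index - 1L)
  i1 <- min(n, anchor_index + 1L)
  d <- pts[i1, ] - pts[i0, ]
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("degenerate tangent", call. = FALSE)
  unname(d / nrm)
}

#' Construct a scan line perpendicular to the lamina
#'
#' Anchored on a lamina vertex and pointing apically (toward row 0), the scan
#' direction is the unit normal to the local lamina tangent. The scan samples
#' from its apical end (`basal_anchor + direction * length`) down to the
#' anchor, matching a line drawn from the apical surface to the basal lamina.
#'
#' @param trace a `lamina_trace`.
#' @param anchor_index lamina vertex to anchor on (1-based).
#' @param length_um scan length in micrometers; `NULL` extends the scan to
#'   the apical image edge (row 0).
#' @param pixel_size_um pixel size used to convert between um and px.
#' @param step_um sampling step (default one pixel).
#' @return object of class `scan_line` with fields `basal_anchor`,
#'   `direction` (unit vector, apical), `length_um`, `step_um`.
#' @export
scan_line <- function(trace, anchor_index, length_um = NULL, pixel_size_um,
                      step_um = pixel_size_um) {
  tg <- local_tangent(trace, anchor_index)
  anchor <- trace$points[anchor_index, ]
  perp <- c(-tg[2], tg[1])
  if (perp[1] > 0) perp <- -perp              # point apically (row decreasing)
  if (perp[1] == 0) stop("lamina is locally vertical; apical direction undefined",
                         call. = FALSE)
  if (is.null(length_um)) {
    # distance along the ray to the apical edge (row 0)
    length_um <- (anchor[1] / -perp[1]) * pixel_size_um
  }
  assert_scalar_num(length_um, "length_um", lower = 1e-9)
  assert_scalar_num(step_um, "step_um", lower = 1e-9)
  structure(list(basal_anchor = unname(anchor), direction = unname(perp),
                 length_um = length_um, step_um = step_um),
            class = "scan_line")
}

#' Extract a line-intensity profile along a scan
#'
#' Samples the (inverted) image by bilinear interpolation at positions
#' `0, step_um, ..., length_um` along the scan, ordered from the apical end
#' to the basal anchor, so that returned `x` (micrometers from the apical
#' start) increases toward the basal lamina.
#'
#' @param img an inverted `rish_image`.
#' @param scan a [scan_line()].
#' @param meta named list of identity fields (`animal_id`, `image_id`,
#'   `scan_id`, `probe`).
#' @return object of class `intensity_profile` with fields `x`, `y`,
#'   `normalized = FALSE`, `meta`.
#' @export
extract_scan <- function(img, scan, meta = list()) {
  stopifnot(inherits(img, "rish_image"), inherits(scan, "scan_line"))
  if (!img$inverted) stop("image must be inverted before scanning", call. = FALSE)
  t_um <- seq(0, scan$length_um, by = scan$step_um)
  if (scan$length_um - t_um[length(t_um)] > 1e-9 * scan$step_um) {
    t_um <- c(t_um, scan$length_um)
  }
  # apical start = anchor + direction * length; x measures distance from it
  t_px <- (scan$length_um - t_um) / img$pixel_size_um
  pos_r <- scan$basal_anchor[1] + scan$direction[1] * t_px
  pos_c <- scan$basal_anchor[2] + scan$direction[2] * t_px
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  tol <- 1e-6  # forgive floating-point spill at the image border
  if (any(pos_r < -tol | pos_r > nr - 1 + tol |
          pos_c < -tol | pos_c > nc - 1 + tol)) {
    stop("scan exits image bounds", call. = FALSE)
  }
  pos_r <- pmin(pmax(pos_r, 0), nr - 1)
  pos_c <- pmin(pmax(pos_c, 0), nc - 1)
  y <- bilinear_sample(img$pixels, pos_r, pos_c)
  intensity_profile(x = t_um, y = y, normalized = FALSE, meta = meta)
}

#' Line-intensity profile container
#'
#' @param x strictly increasing positions (apical end first). Raw profiles
#'   carry micrometers; normalized profiles span \[0,1\].
#' @param y intensities, same length as `x` (at least 2 points).
#' @param normalized have both axes been normalized to their maxima?
#' @param meta named list of identity fields.
#' @return object of class `intensity_profile`.
#' @export
intensity_profile <- function(x, y, normalized = FALSE, meta = list()) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2L) {
    stop("x and y must have equal length >= 2", call. = FALSE)
  }
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  if (isTRUE(normalized) &&
      (abs(max(x) - 1) > 1e-12 || abs(max(y) - 1) > 1e-12)) {
    stop("normalized profiles must have max(x) == 1 and max(y) == 1",
         call. = FALSE)
  }
  structure(list(x = x, y = y, normalized = isTRUE(normalized), meta = meta),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d points, x in [%g, %g], normalized=%s\n",
              length(x$x), min(x$x), max(x$x), x$normalized))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a set of profiles as CSV
#'
#' Long format with columns `probe`, `animal_id`, `image_id`, `scan_id`,
#' `x`, `intensity`, `normalized`.
#'
#' @param profiles list of `intensity_profile`.
#' @param path CSV file.
#' @return `path` invisibly (write); list of `intensity_profile` (read).
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(
      probe = p$meta$probe %||% NA_character_,
      animal_id = p$meta$animal_id %||% NA_character_,
      image_id = p$meta$image_id %||% NA_character_,
      scan_id = p$meta$scan_id %||% NA_character_,
      x = p$x, intensity = p$y, normalized = p$normalized,
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(df$probe, df$animal_id, df$image_id, df$scan_id,
                     drop = TRUE)
  lapply(split(df, key), function(d) {
    intensity_profile(d$x, d$intensity, normalized = d$normalized[1],
                      meta = list(probe = d$probe[1], animal_id = d$animal_id[1],
                                  image_id = d$image_id[1],
                                  scan_id = d$scan_id[1]))
  })
}
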