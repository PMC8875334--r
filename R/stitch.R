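#' Slide scan container
#'
#' A stitched 8-bit RGB scan with its pixel-size calibration, marker label and
#' provenance (source tile count and the correction/stitching parameters that
#' produced it).
#'
#' @param image `h x w x 3` numeric array, values 0..255.
#' @param pixel_size micrometres per pixel.
#' @param marker section label.
#' @param provenance named list of processing parameters.
#' @return object of class `slide_scan`.
#' @export
slide_scan <- function(image, pixel_size = 1, marker = "unknown",
                       provenance = list()) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L,
            min(image) >= 0, max(image) <= 255)
  structure(list(image = image, pixel_size = pixel_size, marker = marker,
                 provenance = provenance),
            class = "slide_scan")
}

#' @export
print.slide_scan <- function(x, ...) {
  cat(sprintf("Slide scan [%s]: %d x %d px, %.3f um/px\n",
              x$marker, dim(x$image)[1], dim(x$image)[2], x$pixel_size))
  invisible(x)
}

#' Write a slide scan as an 8-bit TIFF with a metadata sidecar
#' @param scan a `slide_scan`.
#' @param path output TIFF path; a `<path>.yml` sidecar carries pixel size,
#'   marker and provenance.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "slide_scan"))
  tiff::writeTIFF(scan$image / 255, path, bits.per.sample = 8L)
  yaml::write_yaml(list(pixel_size = scan$pixel_size, marker = scan$marker,
                        provenance = scan$provenance),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Read a slide scan written by [write_scan()]
#' @param path TIFF path (expects the `<path>.yml` sidecar next to it).
#' @return a `slide_scan`.
#' @export
read_scan <- function(path) {
  img <- round(tiff::readTIFF(path) * 255)
  side <- paste0(path, ".yml")
  meta <- if (file.exists(side)) yaml::read_yaml(side)
  else list(pixel_size = 1, marker = "unknown", provenance = list())
  slide_scan(img, meta$pixel_size, meta$marker,
             if (is.null(meta$provenance)) list() else meta$provenance)
}

# Background classification for flat-field estimation: bright and achromatic.
# Tissue under either stain is chromatic (channel spread >> chroma_max).
background_pixels <- function(tile, min_brightness = 120, chroma_max = 25) {
  mn <- pmin(tile[, , 1], tile[, , 2], tile[, , 3])
  mx <- pmax(tile[, , 1], tile[, , 2], tile[, , 3])
  (mn > min_brightness) & ((mx - mn) < chroma_max)
}

#' Estimate a multiplicative flat field from a tile set
#'
#' Vignetting is a property of the optics and is shared by every tile of a
#' section, so the gain at each tile pixel is estimated as the per-channel
#' median over tiles of the background (bright, achromatic) pixels observed
#' at that position, smoothed by coarse block averaging with bilinear
#' upsampling, and normalized to mean gain 1 per channel. Positions never seen
#' as background borrow the channel's global median before smoothing.
#'
#' @param tiles a `tile_set`.
#' @param block block edge in px for the smoothing grid; the gain surface is
#'   fit as per-block medians bilinearly interpolated back to pixels.
#' @param min_brightness,chroma_max background classification thresholds
#'   (0..255 gray levels).
#' @return object of class `flat_field`: `field` is a `h x w x 3` gain array,
#'   strictly positive, mean 1 per channel.
#' @export
estimate_flatfield <- function(tiles, block = 64L, min_brightness = 120,
                               chroma_max = 25) {
  stopifnot(inherits(tiles, "tile_set"))
  th <- tiles$tile_shape[1]; tw <- tiles$tile_shape[2]
  bg_masks <- lapply(tiles$tiles, background_pixels,
                     min_brightness = min_brightness, chroma_max = chroma_max)
  if (!any(vapply(bg_masks, any, TRUE))) {
    warning("no background pixels found; returning identity flat field")
    return(structure(list(field = array(1, c(th, tw, 3L)),
                          identity = TRUE), class = "flat_field"))
  }
  br <- max(2L, ceiling(th / block)); bc <- max(2L, ceiling(tw / block))
  ridx <- pmin(ceiling(seq_len(th) / (th / br)), br)
  cidx <- pmin(ceiling(seq_len(tw) / (tw / bc)), bc)
  block_id <- matrix(ridx, th, tw) + br * matrix(cidx - 1L, th, tw, byrow = TRUE)
  field <- array(1, c(th, tw, 3L))
  rc <- as.numeric(tapply(seq_len(th), ridx, mean))  # block-center coords
  cc <- as.numeric(tapply(seq_len(tw), cidx, mean))
  for (ch in 1:3) {
    vals <- unlist(lapply(seq_along(tiles$tiles), function(i)
      tiles$tiles[[i]][, , ch][bg_masks[[i]]]))
    ids <- unlist(lapply(bg_masks, function(b) block_id[b]))
    med <- vapply(split(vals, ids), median, 0)
    bm <- matrix(NA_real_, br, bc)
    bm[as.integer(names(med))] <- med
    bm[is.na(bm)] <- median(med)        # blocks never seen as background
    g <- interp_grid(bm, rc, cc, th, tw)
    g <- g / mean(g)
    field[, , ch] <- pmax(g, 0.05)
  }
  structure(list(field = field, identity = FALSE,
                 params = list(block = block, min_brightness = min_brightness,
                               chroma_max = chroma_max)),
            class = "flat_field")
}

#' Apply a flat field to a tile set
#'
#' Divides every tile by the gain field, rescales per channel to preserve the
#' set's global mean brightness, and clips back to 8-bit. Dimensions, grid
#' layout and marker label are unchanged.
#'
#' @param tiles a `tile_set`.
#' @param field a `flat_field` with gain of tile shape.
#' @return corrected `tile_set`.
#' @export
correct_tiles <- function(tiles, field) {
  stopifnot(inherits(tiles, "tile_set"), inherits(field, "flat_field"))
  if (!identical(dim(field$field)[1:2], as.integer(tiles$tile_shape)))
    stop("flat field shape does not match tile shape", call. = FALSE)
  gain <- field$field
  # per-channel mean-brightness preservation over the whole set
  pre_mean <- vapply(1:3, function(ch)
    mean(vapply(tiles$tiles, function(t) mean(t[, , ch]), 0)), 0)
  corrected <- lapply(tiles$tiles, function(t) {
    for (ch in 1:3) t[, , ch] <- t[, , ch] / gain[, , ch]
    t
  })
  post_mean <- vapply(1:3, function(ch)
    mean(vapply(corrected, function(t) mean(t[, , ch]), 0)), 0)
  scale <- ifelse(post_mean > 0, pre_mean / post_mean, 1)
  corrected <- lapply(corrected, function(t) {
    for (ch in 1:3) t[, , ch] <- t[, , ch] * scale[ch]
    round(clip255(t))
  })
  tile_set(corrected, tiles$grid_layout, tiles$overlap,
           tiles$pixel_size, tiles$marker)
}

#' Stitch a tile set into a single slide scan
#'
#' Tiles are placed at the positions declared by the grid layout (scanner
#' stages report positions; no correlation-based placement). Overlap regions
#' are blended by linear feathering, which reduces seams without inventing
#' content; at zero overlap stitching is an exact inverse of tile cutting.
#'
#' @param tiles a `tile_set`.
#' @return a `slide_scan` of the mosaic.
#' @export
stitch <- function(tiles) {
  stopifnot(inherits(tiles, "tile_set"))
  rows <- tiles$grid_layout[1]; cols <- tiles$grid_layout[2]
  th <- tiles$tile_shape[1]; tw <- tiles$tile_shape[2]
  ov <- tiles$overlap
  H <- rows * (th - ov) + ov; W <- cols * (tw - ov) + ov
  if (ov == 0L) {                 # exact inverse of tile cutting
    img <- array(0, c(H, W, 3L))
    k <- 1L
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      t <- tiles$tiles[[k]]
      if (is.null(t))
        stop(sprintf("missing tile at grid position (%d, %d)", r, c),
             call. = FALSE)
      img[(r - 1L) * th + seq_len(th), (c - 1L) * tw + seq_len(tw), ] <- t
      k <- k + 1L
    }
    return(slide_scan(img, tiles$pixel_size, tiles$marker,
                      provenance = list(n_tiles = length(tiles$tiles),
                                        grid = tiles$grid_layout, overlap = 0L)))
  }
  acc <- array(0, c(H, W, 3L))
  wacc <- matrix(0, H, W)
  wr <- feather_weights(th, ov); wc <- feather_weights(tw, ov)
  wt <- wr %o% wc
  k <- 1L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    t <- tiles$tiles[[k]]
    if (is.null(t)) stop(sprintf("missing tile at grid position (%d, %d)", r, c),
                         call. = FALSE)
    y <- (r - 1L) * (th - ov) + seq_len(th)
    x <- (c - 1L) * (tw - ov) + seq_len(tw)
    # edge tiles keep full weight on outer borders
    w <- wt
    if (r == 1L) w[seq_len(ov), ] <- matrix(wc, ov, tw, byrow = TRUE)
    if (r == rows) w[th - seq_len(ov) + 1L, ] <- matrix(wc, ov, tw, byrow = TRUE)
    if (c == 1L) w[, seq_len(ov)] <- matrix(wr, th, ov)
    if (c == cols) w[, tw - seq_len(ov) + 1L] <- matrix(wr, th, ov)
    for (ch in 1:3) acc[y, x, ch] <- acc[y, x, ch] + t[, , ch] * w
    wacc[y, x] <- wacc[y, x] + w
    k <- k + 1L
  }
  img <- array(0, c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- acc[, , ch] / wacc
  slide_scan(round(clip255(img)), tiles$pixel_size, tiles$marker,
             provenance = list(n_tiles = length(tiles$tiles),
                               grid = tiles$grid_layout, overlap = ov))
}

# Linear feather: ramps from ~0 to 1 over the overlap zone on each edge.
feather_weights <- function(n, ov) {
  w <- rep(1, n)
  if (ov > 0) {
    ramp <- seq_len(ov) / (ov + 1)
    w[seq_len(ov)] <- ramp
    w[n - seq_len(ov) + 1L] <- ramp
  }
  w
}
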