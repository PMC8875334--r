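#' Detect tissue in a slide scan
#'
#' A pixel is tissue iff its smoothed brightness (Rec. 601 luma) is below
#' `white_threshold`. Small holes inside tissue are filled and speckles below
#' `min_speck_px` removed, so the area denominator is not inflated by dust or
#' deflated by pale lumens. A threshold of 255 or more classifies every pixel
#' as tissue (degenerate but well-defined). On uncorrected vignetted tiles the
#' background can fall below the default threshold near tile corners; either
#' flat-field correct first or lower `white_threshold`.
#'
#' @param scan a `slide_scan`.
#' @param white_threshold gray level (0..255) below which a pixel is tissue.
#' @param smooth_radius mean-filter radius (px) applied before thresholding.
#' @param min_speck_px connected tissue components smaller than this are
#'   dropped; holes smaller than this are filled.
#' @return logical matrix of scan shape.
#' @export
tissue_mask <- function(scan, white_threshold = 240, smooth_radius = 2L,
                        min_speck_px = 64L) {
  stopifnot(inherits(scan, "slide_scan"))
  gray <- rgb_to_gray(scan$image)
  if (smooth_radius > 0) gray <- box_blur(gray, smooth_radius)
  if (white_threshold >= 255) {
    return(matrix(TRUE, nrow(gray), ncol(gray)))
  }
  m <- gray < white_threshold
  if (!any(m)) return(m)
  m <- drop_small_components(m, min_speck_px)
  # fill small holes: drop small components of the complement
  holes <- !m & !drop_small_components(!m, min_speck_px)
  m | holes
}

drop_small_components <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- as.integer(EBImage::bwlabel(EBImage::Image(mask * 1)))
  sizes <- tabulate(lab)
  lut <- c(FALSE, sizes >= min_px)      # label 0 = background
  matrix(lut[lab + 1L], nrow(mask), ncol(mask))
}

#' Build an ROI mask from labeled polygons
#'
#' @param polygons list of records `list(label =, xy =)` where `xy` is an
#'   `n x 2` matrix of `(x, y)` vertices in 0-based scan pixel coordinates
#'   (origin top-left). Recognised labels: muscle, villous, vessel, gland,
#'   poor_morphology, other.
#' @param shape scan shape `(rows, cols)` the mask applies to.
#' @return object of class `roi_mask` with the polygon list and the combined
#'   exclusion raster.
#' @export
roi_mask <- function(polygons, shape) {
  stopifnot(length(shape) == 2L)
  known <- c("muscle", "villous", "vessel", "gland", "poor_morphology", "other")
  polys <- lapply(polygons, function(p) {
    stopifnot(is.list(p), !is.null(p$xy))
    xy <- as.matrix(p$xy)
    if (nrow(xy) < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
    lab <- if (is.null(p$label)) "other" else p$label
    if (!lab %in% known) lab <- "other"
    if (any(xy[, 1] < 0) || any(xy[, 2] < 0) ||
        any(xy[, 1] > shape[2]) || any(xy[, 2] > shape[1]))
      warning("polygon extends outside the canvas; clipped to canvas")
    list(label = lab, xy = xy)
  })
  excl <- rasterize_polygons(lapply(polys, `[[`, "xy"), shape[1], shape[2])
  structure(list(polygons = polys, exclusion = excl, shape = shape),
            class = "roi_mask")
}

#' Apply regions of disinterest to a tissue mask
#'
#' Included tissue is tissue outside every exclusion polygon; tissue area is
#' the included pixel count converted with the pixel size. The denominator
#' uses tissue-only pixels (not the enclosing rectangle), and adding polygons
#' can only shrink it.
#'
#' @param tissue logical tissue raster.
#' @param roi a `roi_mask` of the same shape (or `NULL` for no exclusions).
#' @param pixel_size micrometres per pixel.
#' @return list with `included` (logical raster) and `area_mm2`.
#' @export
apply_roi <- function(tissue, roi = NULL, pixel_size) {
  stopifnot(is.matrix(tissue), is.logical(tissue))
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_mask"))
    if (!identical(dim(tissue), as.integer(roi$shape)) &&
        !identical(dim(tissue), roi$shape))
      stop("tissue raster and ROI mask shapes differ", call. = FALSE)
    included <- tissue & !roi$exclusion
  } else included <- tissue
  area_mm2 <- sum(included) * (pixel_size / 1000)^2
  list(included = included, area_mm2 = area_mm2)
}

#' Write ROI polygons as a delimited text file
#'
#' One vertex per row: `polygon<TAB>label<TAB>x<TAB>y`, 0-based pixel
#' coordinates, origin top-left, x = column, y = row.
#' @param roi a `roi_mask` (or bare polygon list as taken by [roi_mask()]).
#' @param path output path.
#' @export
write_roi <- function(roi, path) {
  polys <- if (inherits(roi, "roi_mask")) roi$polygons else roi
  rows <- do.call(rbind, lapply(seq_along(polys), function(i) {
    data.frame(polygon = i, label = polys[[i]]$label,
               x = polys[[i]]$xy[, 1], y = polys[[i]]$xy[, 2])
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ROI polygons written by [write_roi()]
#' @param path delimited ROI file.
#' @param shape scan shape `(rows, cols)`.
#' @return a `roi_mask`.
#' @export
read_roi <- function(path, shape) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  polys <- lapply(split(d, d$polygon), function(p)
    list(label = p$label[1], xy = cbind(p$x, p$y)))
  roi_mask(unname(polys), shape)
}

#' Parse a WKT POLYGON string into a vertex matrix
#'
#' Accepts the outer ring of `POLYGON ((x y, x y, ...))`; a closing vertex
#' equal to the first is dropped. Interior rings are not supported.
#' @param wkt a WKT POLYGON string.
#' @return `n x 2` matrix of `(x, y)` vertices.
#' @export
parse_wkt_polygon <- function(wkt) {
  m <- regmatches(wkt, regexec("POLYGON\\s*\\(\\(([^)]*)\\)", wkt))[[1]]
  if (length(m) < 2L) stop("not a WKT POLYGON string", call. = FALSE)
  parts <- strsplit(trimws(strsplit(m[2], ",")[[1]]), "\\s+")
  xy <- do.call(rbind, lapply(parts, function(p) as.numeric(p[1:2])))
  if (nrow(xy) > 3L && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), ]
  if (anyNA(xy)) stop("malformed WKT coordinates", call. = FALSE)
  xy
}

#' Write a binary mask as a single-channel TIFF
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}
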