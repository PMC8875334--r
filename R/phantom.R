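#' Generate a synthetic decidual slide phantom
#'
#' Builds a ground-truth model of a decidual tissue section: extravillous
#' trophoblasts placed both as clusters and as single cells within a smooth
#' maternal stroma field, plus polygonal exclusion regions standing in for
#' vessels, glands and muscle. The same phantom is rendered once per marker
#' (CK7 / NRF2 / KEAP1) as a serial section, so downstream stages can be
#' validated against exact truth.
#'
#' Cells are packed without overlap (minimum gap `cell_gap` px between disk
#' boundaries, also within clusters), so connected-component counting has an
#' unambiguous truth. An impossible packing request raises an error rather
#' than silently truncating.
#'
#' @param canvas_size integer `(height, width)` of the section canvas in px.
#' @param n_clusters number of trophoblast clusters.
#' @param cells_per_cluster cells per cluster.
#' @param n_singles number of isolated trophoblasts.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param cell_radius trophoblast disk radius in px.
#' @param cell_gap minimum boundary gap between any two cells in px.
#' @param cluster_spread radius (px) of the disc a cluster's cells occupy.
#' @param stroma_fill target fraction of the canvas covered by maternal stroma
#'   (0 disables stroma entirely).
#' @param n_exclusions number of rectangular exclusion polygons to draw.
#' @param marker_strengths named list: marker -> `c(trophoblast=, maternal=)`
#'   DAB stain strengths in `[0, 1]`.
#' @param section_offsets named list: marker -> integer `c(dy, dx)` rigid
#'   translation of that serial section; `NULL` draws offsets uniformly in
#'   `[-max_offset, max_offset]` for the non-reference markers (CK7 stays at
#'   the origin as the reference section).
#' @param max_offset bound on |dy|, |dx| in px.
#' @param seed integer seed; the phantom is a pure function of its arguments.
#' @return An object of class `slide_phantom`.
#' @examples
#' ph <- generate_phantom(canvas_size = c(256, 256), n_clusters = 1,
#'                        cells_per_cluster = 4, n_singles = 3, seed = 1)
#' nrow(ph$trophoblast_cells)  # 7
#' @export
generate_phantom <- function(canvas_size = c(1536L, 1536L),
                             n_clusters = 4L,
                             cells_per_cluster = 19L,
                             n_singles = 20L,
                             pixel_size = 0.662,
                             cell_radius = 9,
                             cell_gap = 2,
                             cluster_spread = 45,
                             stroma_fill = 0.85,
                             n_exclusions = 2L,
                             marker_strengths = list(
                               CK7  = c(trophoblast = 0.80, maternal = 0.04),
                               NRF2 = c(trophoblast = 0.60, maternal = 0.15),
                               KEAP1 = c(trophoblast = 0.50, maternal = 0.20)),
                             section_offsets = NULL,
                             max_offset = 50L,
                             seed) {
  stopifnot(length(canvas_size) == 2L, all(canvas_size >= 32L),
            cell_radius > 0, stroma_fill >= 0, stroma_fill <= 1)
  for (m in names(marker_strengths)) {
    s <- marker_strengths[[m]]
    if (any(s < 0) || any(s > 1))
      stop("marker_strengths must lie in [0, 1]", call. = FALSE)
  }
  nr <- as.integer(canvas_size[1]); nc <- as.integer(canvas_size[2])
  n_cells <- n_clusters * cells_per_cluster + n_singles

  # coarse feasibility guard before attempting the packing at all
  margin <- cell_radius + 1
  if (n_clusters > 0 &&
      cells_per_cluster > length(hex_lattice(cluster_spread,
                                             2 * cell_radius + cell_gap)$x))
    stop("impossible packing: cells_per_cluster does not fit in cluster_spread",
         call. = FALSE)
  if (n_cells * (2 * cell_radius + cell_gap)^2 > 0.5 * nr * nc)
    stop("impossible packing: requested cells exceed canvas capacity",
         call. = FALSE)

  with_seed(seed, {
    stroma <- if (stroma_fill > 0) {
      f <- smooth_field(nr, nc, coarse = 16L, coarse_blur = 2L)
      # quantile on a subsample: the field is smooth, the cut is not exact
      # in stroma_fill anyway, and sorting the full canvas is wasteful
      q <- quantile(f[seq.int(1L, length(f), by = 7L)], 1 - stroma_fill)
      occ <- matrix(0, nr, nc)
      inside <- f > q
      occ[inside] <- 0.6 + 0.4 * (f[inside] - q) / max(max(f) - q, 1e-9)
      occ
    } else matrix(0, nr, nc)

    # trophoblasts invade the decidual stroma: every cell must sit on tissue
    # (unless the phantom has no stroma at all)
    cells <- place_cells(nr, nc, n_clusters, cells_per_cluster, n_singles,
                         cell_radius, cell_gap, cluster_spread, margin,
                         stroma = if (stroma_fill > 0) stroma else NULL)

    exclusions <- list()
    if (n_exclusions > 0) {
      labels <- c("vessel", "gland", "muscle")
      # each rectangle <= ~6% of canvas; total stays well below the 30% cap
      for (k in seq_len(n_exclusions)) {
        w <- runif(1, 0.08, 0.25) * nc
        h <- runif(1, 0.08, 0.25) * nr
        x0 <- runif(1, 0, nc - w); y0 <- runif(1, 0, nr - h)
        xy <- cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
        exclusions[[k]] <- list(label = labels[1 + (k - 1) %% 3], xy = xy)
      }
      cov <- sum(rasterize_polygons(lapply(exclusions, `[[`, "xy"), nr, nc))
      if (cov > 0.3 * nr * nc)
        stop("exclusion regions cover more than 30% of the canvas", call. = FALSE)
    }

    if (is.null(section_offsets)) {
      section_offsets <- lapply(names(marker_strengths), function(m) {
        if (identical(m, "CK7")) c(dy = 0L, dx = 0L)
        else c(dy = sample.int(2L * max_offset + 1L, 1L) - max_offset - 1L,
               dx = sample.int(2L * max_offset + 1L, 1L) - max_offset - 1L)
      })
      names(section_offsets) <- names(marker_strengths)
    }
    for (off in section_offsets)
      if (any(abs(off) > max_offset))
        stop("section offsets exceed max_offset", call. = FALSE)

    structure(list(
      canvas_size = c(nr, nc), pixel_size = pixel_size,
      trophoblast_cells = cells, stroma_field = stroma,
      exclusion_regions = exclusions,
      marker_strengths = marker_strengths,
      section_offsets = section_offsets,
      cell_radius = cell_radius, max_offset = max_offset, seed = seed),
      class = "slide_phantom")
  })
}

# Hexagonal lattice points (relative coordinates) within `radius`, spaced
# `s` apart, ordered by distance from the origin. Dense non-touching packing:
# clustered trophoblasts sit nearly shoulder to shoulder, which is what makes
# >50%-fraction patches attainable without overlapping disks.
hex_lattice <- function(radius, s) {
  n <- ceiling(radius / s) + 1L
  pts <- expand.grid(i = -n:n, j = -n:n)
  x <- s * (pts$i + 0.5 * (pts$j %% 2))
  y <- s * pts$j * sqrt(3) / 2
  d <- sqrt(x^2 + y^2)
  keep <- d <= radius
  ord <- order(d[keep])
  list(x = x[keep][ord], y = y[keep][ord])
}

# Non-overlapping disk packing: clusters on a jittered hex lattice, singles
# by rejection sampling; errors when it cannot satisfy the request (no
# silent truncation).
place_cells <- function(nr, nc, n_clusters, cells_per_cluster, n_singles,
                        r, gap, spread, margin, stroma = NULL) {
  ys <- numeric(0); xs <- numeric(0); ids <- character(0)
  min_d2 <- (2 * r + gap / 2)^2   # lattice jitter eats at most half the gap
  on_tissue <- function(cy, cx) {
    if (is.null(stroma)) return(TRUE)
    # probe the cell center and 4 points just inside the disk boundary
    py <- pmin(pmax(round(cy + c(0, -r, r, 0, 0)), 1L), nr)
    px <- pmin(pmax(round(cx + c(0, 0, 0, -r, r)), 1L), nc)
    all(stroma[cbind(py, px)] > 0)
  }
  ok_place <- function(cy, cx) {
    if (cy < margin || cy > nr - margin || cx < margin || cx > nc - margin)
      return(FALSE)
    if (length(ys) && any((ys - cy)^2 + (xs - cx)^2 < min_d2)) return(FALSE)
    on_tissue(cy, cx)
  }
  if (n_clusters > 0) {
    lat <- hex_lattice(spread, 2 * r + gap)
    jit <- gap / 8
    centers_y <- numeric(0); centers_x <- numeric(0)
    for (k in seq_len(n_clusters)) {
      placed <- FALSE
      for (i in seq_len(3000L)) {
        cy <- runif(1, spread + margin, nr - spread - margin)
        cx <- runif(1, spread + margin, nc - spread - margin)
        if (length(centers_y) &&
            any((centers_y - cy)^2 + (centers_x - cx)^2 <= (2.5 * spread)^2))
          next
        theta <- runif(1, 0, 2 * pi)        # random cluster orientation
        cyj <- cy + lat$x[seq_len(cells_per_cluster)] * sin(theta) +
          lat$y[seq_len(cells_per_cluster)] * cos(theta) +
          runif(cells_per_cluster, -jit, jit)
        cxj <- cx + lat$x[seq_len(cells_per_cluster)] * cos(theta) -
          lat$y[seq_len(cells_per_cluster)] * sin(theta) +
          runif(cells_per_cluster, -jit, jit)
        feasible <- TRUE
        for (j in seq_len(cells_per_cluster))
          if (!ok_place(cyj[j], cxj[j])) { feasible <- FALSE; break }
        if (!feasible) next
        centers_y <- c(centers_y, cy); centers_x <- c(centers_x, cx)
        ys <- c(ys, cyj); xs <- c(xs, cxj)
        ids <- c(ids, rep(as.character(k), cells_per_cluster))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("impossible packing: could not place cluster on tissue",
             call. = FALSE)
    }
  }
  for (j in seq_len(n_singles)) {
    ok <- FALSE
    for (i in seq_len(5000L)) {
      cy2 <- runif(1, margin, nr - margin); cx2 <- runif(1, margin, nc - margin)
      if (ok_place(cy2, cx2)) {
        ys <- c(ys, cy2); xs <- c(xs, cx2); ids <- c(ids, "single")
        ok <- TRUE; break
      }
    }
    if (!ok) stop("impossible packing: could not place single cell", call. = FALSE)
  }
  data.frame(y = ys, x = xs, radius = rep(r, length(ys)), cluster_id = ids,
             stringsAsFactors = FALSE)
}

# Rasterize trophoblast disks into a logical matrix (pixel centers inside radius).
rasterize_cells <- function(cells, nr, nc, dy = 0, dx = 0) {
  m <- matrix(FALSE, nr, nc)
  if (!nrow(cells)) return(m)
  for (i in seq_len(nrow(cells))) {
    cy <- cells$y[i] + dy; cx <- cells$x[i] + dx; r <- cells$radius[i]
    r0 <- max(1L, floor(cy - r)); r1 <- min(nr, ceiling(cy + r + 1))
    c0 <- max(1L, floor(cx - r)); c1 <- min(nc, ceiling(cx + r + 1))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - 0.5 - cy)^2, (cc - 0.5 - cx)^2, `+`)
    m[rr, cc] <- m[rr, cc] | (d2 <= r^2)
  }
  m
}

#' Ground-truth tissue mask of a phantom (stroma plus trophoblast disks)
#' @param phantom a `slide_phantom`.
#' @return logical matrix of canvas shape.
#' @export
phantom_tissue_truth <- function(phantom) {
  stopifnot(inherits(phantom, "slide_phantom"))
  d <- phantom$canvas_size
  (phantom$stroma_field > 0) |
    rasterize_cells(phantom$trophoblast_cells, d[1], d[2])
}

#' @export
print.slide_phantom <- function(x, ...) {
  cat("Synthetic decidual slide phantom\n")
  cat(sprintf("  canvas: %d x %d px (%.3f um/px)\n",
              x$canvas_size[1], x$canvas_size[2], x$pixel_size))
  cat(sprintf("  trophoblasts: %d (%d clustered, %d single)\n",
              nrow(x$trophoblast_cells),
              sum(x$trophoblast_cells$cluster_id != "single"),
              sum(x$trophoblast_cells$cluster_id == "single")))
  cat(sprintf("  markers: %s\n", paste(names(x$marker_strengths), collapse = ", ")))
  cat(sprintf("  exclusion regions: %d\n", length(x$exclusion_regions)))
  invisible(x)
}

# H-DAB reference absorbance vectors (unit length), bright-field two-stain
# Lambert-Beer model on a white background.
STAIN_H   <- c(0.650, 0.704, 0.286) / sqrt(sum(c(0.650, 0.704, 0.286)^2))
STAIN_DAB <- c(0.269, 0.568, 0.778) / sqrt(sum(c(0.269, 0.568, 0.778)^2))
HEMATOXYLIN_TISSUE <- 0.8   # hematoxylin amount on full-occupancy stroma
HEMATOXYLIN_CELL   <- 0.5   # nuclear counterstain inside trophoblast disks

#' Render one serial section of a phantom as a tile set
#'
#' Renders the phantom for a given marker using Lambert-Beer mixing of the
#' hematoxylin and DAB reference absorbance vectors on a white background,
#' shifts the whole section by the phantom's per-marker rigid offset, applies
#' an optical radial vignette (a smooth multiplicative shading field shared by
#' all tiles of the section, as lens vignetting is), adds Gaussian noise in
#' absorbance space, and cuts the canvas into an overlapping tile grid as a
#' slide scanner would.
#'
#' Rendered gray level is strictly decreasing in stain strength at zero noise,
#' matching the inverse-intensity convention used throughout (0 = black =
#' maximal staining, 255 = white = none).
#'
#' @param phantom a `slide_phantom`.
#' @param marker one of the phantom's markers.
#' @param vignette_strength shading amplitude in `[0, 1)`; corner gain is
#'   `1 - vignette_strength`.
#' @param noise_sd SD of absorbance-space Gaussian noise.
#' @param tile_shape `(height, width)` of each tile in px.
#' @param overlap tile overlap in px; canvas must equal
#'   `rows * (tile - overlap) + overlap` in each dimension.
#' @return A `tile_set`.
#' @export
render_section <- function(phantom, marker, vignette_strength = 0,
                           noise_sd = 0, tile_shape = c(512L, 512L),
                           overlap = 0L) {
  stopifnot(inherits(phantom, "slide_phantom"))
  if (!marker %in% names(phantom$marker_strengths))
    stop(sprintf("unknown marker '%s'", marker), call. = FALSE)
  if (vignette_strength < 0 || vignette_strength >= 1)
    stop("vignette_strength must be in [0, 1)", call. = FALSE)
  nr <- phantom$canvas_size[1]; nc <- phantom$canvas_size[2]
  off <- phantom$section_offsets[[marker]]
  s <- phantom$marker_strengths[[marker]]

  occ <- translate_image(phantom$stroma_field, off[1], off[2], fill = 0)
  cellmask <- rasterize_cells(phantom$trophoblast_cells, nr, nc,
                              dy = off[1], dx = off[2])

  a_h <- HEMATOXYLIN_TISSUE * occ
  a_d <- s[["maternal"]] * occ
  a_h[cellmask] <- HEMATOXYLIN_CELL
  a_d[cellmask] <- s[["trophoblast"]]

  mseed <- phantom$seed + 7919L * match(marker, names(phantom$marker_strengths))
  canvas <- with_seed(mseed, {
    v <- render_channels_cpp(as.vector(a_h), as.vector(a_d),
                             STAIN_H, STAIN_DAB, noise_sd)
    array(v, dim = c(nr, nc, 3L))
  })

  g <- if (vignette_strength > 0)
    vignette_field(tile_shape[1], tile_shape[2], vignette_strength)
  else matrix(1, 1L, 1L)
  if (overlap == 0L) {
    # no shared pixels between tiles: shade, clamp and round on the canvas
    canvas <- array(vignette_round_cpp(canvas, nr, nc, g), dim = dim(canvas))
    tiles <- cut_canvas(canvas, tile_shape, overlap)
  } else {
    tiles <- cut_canvas(canvas, tile_shape, overlap)
    tiles$tiles <- lapply(tiles$tiles, function(t) {
      if (vignette_strength > 0) for (ch in 1:3) t[, , ch] <- t[, , ch] * g
      round(clip255(t))
    })
  }
  tile_set(tiles$tiles, tiles$grid, overlap, phantom$pixel_size, marker)
}

# Radial multiplicative shading: gain 1 at tile center, 1 - v at the corners.
vignette_field <- function(nr, nc, v) {
  ry <- (seq_len(nr) - 0.5 - nr / 2) / (nr / 2)
  rx <- (seq_len(nc) - 0.5 - nc / 2) / (nc / 2)
  rho2 <- outer(ry^2, rx^2, `+`) / 2   # normalized so corner rho2 = 1
  1 - v * rho2
}

# Cut a canvas into a grid of tiles with the given overlap; dimensions must
# tile exactly (slide scanners report their grid, we do not invent padding).
cut_canvas <- function(canvas, tile_shape, overlap) {
  nr <- dim(canvas)[1]; nc <- dim(canvas)[2]
  th <- tile_shape[1]; tw <- tile_shape[2]
  step_r <- th - overlap; step_c <- tw - overlap
  if (step_r <= 0 || step_c <= 0) stop("overlap must be smaller than tile")
  rows <- (nr - overlap) / step_r; cols <- (nc - overlap) / step_c
  if (rows != round(rows) || cols != round(cols))
    stop("canvas dimensions are not compatible with tile_shape and overlap",
         call. = FALSE)
  rows <- as.integer(rows); cols <- as.integer(cols)
  tiles <- vector("list", rows * cols)
  k <- 1L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    y0 <- (r - 1L) * step_r; x0 <- (c - 1L) * step_c
    tiles[[k]] <- canvas[y0 + seq_len(th), x0 + seq_len(tw), , drop = FALSE]
    k <- k + 1L
  }
  list(tiles = tiles, grid = c(rows, cols))
}

#' Density band of a trophoblast fraction
#'
#' Fixed banding by CK7-positive fraction: `0` -> `maternal`; `(0, 0.5]` ->
#' `low`; `(0.5, 1]` -> `high`. A fraction of exactly 0.5 is `low`: the high
#' band is strictly greater than 50%.
#'
#' @param fraction numeric vector of trophoblast fractions in `[0, 1]`.
#' @return factor with levels `maternal`, `low`, `high`.
#' @export
density_band <- function(fraction) {
  stopifnot(all(fraction >= 0 & fraction <= 1, na.rm = TRUE))
  factor(ifelse(fraction <= 0, "maternal",
                ifelse(fraction <= 0.5, "low", "high")),
         levels = c("maternal", "low", "high"))
}

#' Ground-truth patch table of a phantom
#'
#' Tessellates the phantom canvas (reference frame, no section offset) into
#' `patch_size` x `patch_size` patches and reports, per patch, the true
#' trophoblast pixel fraction, its density band and whether it intersects an
#' exclusion polygon. Partial edge patches are kept and their fraction is
#' computed over the actual patch area.
#'
#' @param phantom a `slide_phantom`.
#' @param patch_size patch edge in px (default 50, the analysis grid).
#' @return data.frame with one row per patch: `row`, `col`, 0-based half-open
#'   bounds `y0,y1,x0,x1`, `area_px`, `fraction`, `band`, `excluded`.
#' @export
phantom_patch_truth <- function(phantom, patch_size = 50L) {
  stopifnot(inherits(phantom, "slide_phantom"), patch_size >= 1L)
  nr <- phantom$canvas_size[1]; nc <- phantom$canvas_size[2]
  troph <- rasterize_cells(phantom$trophoblast_cells, nr, nc)
  excl <- if (length(phantom$exclusion_regions))
    rasterize_polygons(lapply(phantom$exclusion_regions, `[[`, "xy"), nr, nc)
  else matrix(FALSE, nr, nc)
  agg <- patch_aggregate(nr, nc, patch_size,
                         list(troph = troph, excl = excl))
  agg$fraction <- agg$troph / agg$area_px
  agg$band <- density_band(agg$fraction)
  agg$excluded <- agg$excl > 0
  agg$troph <- agg$excl <- NULL
  agg
}

# Patch tessellation bookkeeping: one row per patch (row index fastest),
# 0-based half-open pixel bounds, actual patch area.
patch_frame <- function(nr, nc, patch_size) {
  pr <- ceiling(nr / patch_size); pc <- ceiling(nc / patch_size)
  out <- data.frame(
    row = rep(seq_len(pr), times = pc),
    col = rep(seq_len(pc), each = pr))
  out$y0 <- (out$row - 1L) * patch_size
  out$y1 <- pmin(out$row * patch_size, nr)
  out$x0 <- (out$col - 1L) * patch_size
  out$x1 <- pmin(out$col * patch_size, nc)
  out$area_px <- (out$y1 - out$y0) * (out$x1 - out$x0)
  out
}

# Sum each logical/numeric layer over the patch tessellation. Returns a
# data.frame keyed by (row, col) with bounds, area and one column per layer.
patch_aggregate <- function(nr, nc, patch_size, layers) {
  out <- patch_frame(nr, nc, patch_size)
  all_true <- matrix(TRUE, nr, nc)
  for (nm in names(layers))
    out[[nm]] <- as.vector(patch_sums_cpp(layers[[nm]] * 1, all_true,
                                          as.integer(patch_size))$sum)
  out
}
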