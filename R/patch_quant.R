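# Core quantification: CK7-guided patch classification and density-banded
# marker intensity on spatially aligned serial sections.

OD_CEILING <- log10(255)   # saturated (0) pixels clip here

#' Separate a bright-field scan into hematoxylin and DAB optical densities
#'
#' Inverts the two-stain Lambert-Beer model with fixed reference absorbance
#' vectors (Ruifrok-Johnston H-DAB basis): per-pixel channel optical density
#' `-log10(I/255)` is projected onto the stain basis by least squares, and
#' negative concentrations are clipped at zero. Saturated pixels clip at an
#' OD ceiling of `log10(255)`. A pure white pixel yields zero in both stains.
#'
#' @param scan a `slide_scan` (8-bit RGB).
#' @return list with matrices `hematoxylin` and `dab` of per-pixel stain OD.
#' @export
separate_hdab <- function(scan) {
  stopifnot(inherits(scan, "slide_scan"))
  img <- pmax(scan$image, 1)               # avoid log of zero; OD ceiling
  d <- dim(img)
  od <- -log10(img / 255)
  dim(od) <- c(d[1] * d[2], 3L)
  S <- cbind(STAIN_H, STAIN_DAB)
  proj <- solve(crossprod(S), t(S))        # 2 x 3 least-squares projector
  conc <- od %*% t(proj)
  conc[conc < 0] <- 0
  conc[conc > OD_CEILING] <- OD_CEILING
  list(hematoxylin = matrix(conc[, 1], d[1], d[2]),
       dab = matrix(conc[, 2], d[1], d[2]))
}

# One-pass DAB-only separation (same model as separate_hdab).
dab_od_fast <- function(scan) {
  d <- dim(scan$image)
  S <- cbind(STAIN_H, STAIN_DAB)
  proj <- solve(crossprod(S), t(S))
  dab_od_cpp(scan$image, d[1], d[2], proj[2, ], OD_CEILING)
}

#' CK7-positive mask from a DAB optical-density raster
#'
#' Pixels at or above `od_threshold` are positive; connected objects smaller
#' than `min_object_px` are removed as speckle.
#'
#' @param dab_od DAB OD matrix from [separate_hdab()].
#' @param od_threshold positivity threshold in OD units (> 0).
#' @param min_object_px minimum object size kept, in px.
#' @return logical matrix.
#' @export
ck7_positive_mask <- function(dab_od, od_threshold = 0.15, min_object_px = 16L) {
  stopifnot(is.matrix(dab_od), od_threshold > 0)
  m <- dab_od >= od_threshold
  drop_small_components(m, min_object_px)
}

#' Build the trophoblast-density patch grid
#'
#' Tessellates the scan into `patch_size` x `patch_size` patches (partial edge
#' patches kept) and classifies each by its trophoblast fraction: CK7-positive
#' pixels over included tissue pixels within the patch. Patches with no
#' included tissue are flagged not-included. Banding is the fixed function of
#' fraction (`0` maternal, `(0, 0.5]` low, `(0.5, 1]` high).
#'
#' @param scan_shape `(rows, cols)` of the scan in px.
#' @param patch_size patch edge in px (default 50).
#' @param ck7_mask logical CK7-positivity raster of scan shape.
#' @param included_mask logical included-tissue raster of scan shape (tissue
#'   minus regions of disinterest).
#' @param min_tissue_px patches with fewer included tissue pixels than this
#'   are flagged not-included.
#' @return object of class `patch_grid`: `patches` data.frame plus the masks
#'   needed for intensity quantification.
#' @export
build_patch_grid <- function(scan_shape, patch_size = 50L, ck7_mask,
                             included_mask, min_tissue_px = 1L) {
  nr <- scan_shape[1]; nc <- scan_shape[2]
  stopifnot(identical(dim(ck7_mask), dim(included_mask)),
            nrow(ck7_mask) == nr, ncol(ck7_mask) == nc)
  agg <- patch_frame(nr, nc, patch_size)
  incnum <- included_mask * 1
  agg$ck7 <- as.vector(patch_sums_cpp(incnum, ck7_mask & included_mask,
                                      as.integer(patch_size))$count)
  agg$tissue_px <- as.vector(patch_sums_cpp(incnum, included_mask,
                                            as.integer(patch_size))$count)
  agg$included <- agg$tissue_px >= max(1L, min_tissue_px)
  agg$trophoblast_fraction <- ifelse(agg$included, agg$ck7 / agg$tissue_px,
                                     NA_real_)
  agg$band <- factor(NA, levels = c("maternal", "low", "high"))
  agg$band[agg$included] <- density_band(agg$trophoblast_fraction[agg$included])
  agg$ck7 <- NULL
  structure(list(patches = agg, patch_size = as.integer(patch_size),
                 shape = c(nr, nc), included_mask = included_mask),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  p <- x$patches[x$patches$included, ]
  cat(sprintf("Patch grid: %d x %d px scan, %d px patches, %d/%d included\n",
              x$shape[1], x$shape[2], x$patch_size, nrow(p), nrow(x$patches)))
  print(table(band = p$band))
  invisible(x)
}

#' Count trophoblasts and compute density
#'
#' Connected components of the CK7 mask after a light morphological opening.
#' Components up to `max_cell_px` count as one cell; larger components
#' (touching clusters) are split by area, contributing
#' `round(area / single_cell_area)` cells, where the single-cell area is the
#' first mode of the observed component-area distribution (components at or
#' below `max_cell_px`). Density is count over tissue area.
#'
#' @param ck7_mask logical CK7-positivity raster.
#' @param min_cell_px components below this area are debris, dropped.
#' @param max_cell_px area above which a component is treated as a cluster.
#' @param area_mm2 included tissue area in mm^2.
#' @param opening_radius radius (px) of the opening brush (0 disables).
#' @return list with `count` (cells) and `density` (cells/mm^2).
#' @export
count_trophoblasts <- function(ck7_mask, min_cell_px = 20L, max_cell_px = 400L,
                               area_mm2, opening_radius = 1L) {
  stopifnot(is.matrix(ck7_mask), min_cell_px > 0, min_cell_px < max_cell_px)
  m <- ck7_mask
  if (opening_radius > 0 && any(m)) {
    brush <- EBImage::makeBrush(2L * opening_radius + 1L, shape = "disc")
    m <- EBImage::opening(EBImage::Image(m * 1), brush) > 0.5
  }
  if (!any(m)) return(list(count = 0L, density = 0))
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  areas <- tabulate(as.integer(lab))
  areas <- areas[areas >= min_cell_px]
  if (!length(areas)) return(list(count = 0L, density = 0))
  if (area_mm2 <= 0)
    stop("tissue area is zero but trophoblasts were found", call. = FALSE)
  singles <- areas[areas <= max_cell_px]
  single_area <- if (length(singles) >= 3L) {
    d <- stats::density(singles, bw = "nrd0")
    d$x[which.max(d$y)]
  } else if (length(singles)) median(singles) else max_cell_px / 2
  single_area <- max(single_area, min_cell_px)
  n <- sum(ifelse(areas <= max_cell_px, 1,
                  pmax(1, round(areas / single_area))))
  list(count = as.integer(n), density = n / area_mm2)
}

#' Register two serial-section scans by translation
#'
#' Finds the integer translation (within `search_radius`) maximizing the
#' normalized cross-correlation of the two zero-mean tissue masks, computed
#' in one pass via FFT. Serial sections cut microns apart and scanned on the
#' same stage differ by translation only, so rotation and scale are not
#' fitted. If the best score falls below `score_floor` the identity transform
#' is returned with a warning.
#'
#' @param reference the reference `slide_scan` (the CK7 section).
#' @param moving the scan to align onto the reference.
#' @param search_radius maximum |dy|, |dx| considered, px.
#' @param score_floor minimum acceptable correlation score.
#' @param white_threshold passed to [tissue_mask()] for both scans.
#' @param ref_mask,mov_mask optional precomputed logical tissue masks (skip
#'   the internal [tissue_mask()] calls, e.g. when a mask already exists).
#' @return list of class `rigid_transform`: `dy`, `dx`, `score`.
#' @export
register_sections <- function(reference, moving, search_radius = 100L,
                              score_floor = 0.2, white_threshold = 240,
                              ref_mask = NULL, mov_mask = NULL) {
  stopifnot(inherits(reference, "slide_scan"), inherits(moving, "slide_scan"))
  if (!isTRUE(all.equal(reference$pixel_size, moving$pixel_size)))
    stop("scans must share pixel_size", call. = FALSE)
  if (is.null(ref_mask))
    ref_mask <- tissue_mask(reference, white_threshold = white_threshold)
  if (is.null(mov_mask))
    mov_mask <- tissue_mask(moving, white_threshold = white_threshold)
  a <- ref_mask * 1; b <- mov_mask * 1
  if (!identical(dim(a), dim(b)))
    stop("scans must share dimensions for registration", call. = FALSE)
  if (sum(a) == 0 || sum(b) == 0)
    stop("tissue masks are empty; registration score undefined", call. = FALSE)
  if (stats::var(as.vector(a)) == 0 || stats::var(as.vector(b)) == 0)
    stop("tissue masks are constant; registration score undefined",
         call. = FALSE)
  # coarse peak on 2x-downsampled masks via circular FFT cross-correlation,
  # then exact zero-mean correlation on the full masks over a +/-2 px window
  # around the upsampled candidate
  am <- ref_mask; bm <- mov_mask
  nr <- nrow(am); nc <- ncol(am)
  er <- nr - nr %% 2L; ec <- nc - nc %% 2L    # even crop for downsampling
  a2 <- downsample2_cpp(am[seq_len(er), seq_len(ec), drop = FALSE])
  b2 <- downsample2_cpp(bm[seq_len(er), seq_len(ec), drop = FALSE])
  a2 <- a2 - mean(a2); b2 <- b2 - mean(b2)
  cc <- Re(fft(Conj(fft(a2)) * fft(b2), inverse = TRUE))
  r2 <- min(ceiling(search_radius / 2) + 1L,
            floor((min(dim(cc)) - 1L) / 2))
  shifts_r <- (-r2):r2; shifts_c <- (-r2):r2    # contiguous shift grid
  sub <- cc[(shifts_r %% nrow(cc)) + 1L, (shifts_c %% ncol(cc)) + 1L,
            drop = FALSE]
  best <- arrayInd(which.max(sub), dim(sub))
  peak_y <- shifts_r[best[1]] + parabolic_offset(sub, best, 1L)
  peak_x <- shifts_c[best[2]] + parabolic_offset(sub, best, 2L)
  cand <- expand.grid(dy = round(2 * peak_y) + (-2:2),
                      dx = round(2 * peak_x) + (-2:2))
  cand <- cand[abs(cand$dy) <= search_radius & abs(cand$dx) <= search_radius, ,
               drop = FALSE]
  ma <- mean(am); mb <- mean(bm)
  corr <- shift_corr_cpp(am, bm, as.integer(cand$dy), as.integer(cand$dx),
                         ma, mb)
  k <- which.max(corr)
  dy <- cand$dy[k]; dx <- cand$dx[k]
  denom <- sqrt(sum((am - ma)^2) * sum((bm - mb)^2))
  score <- max(0, min(1, corr[k] / denom))
  if (score < score_floor) {
    warning(sprintf(
      "registration score %.3f below floor %.3f; returning identity", score,
      score_floor))
    return(structure(list(dy = 0L, dx = 0L, score = score,
                          search_radius = search_radius),
                     class = "rigid_transform"))
  }
  structure(list(dy = as.integer(dy), dx = as.integer(dx), score = score,
                 search_radius = search_radius),
            class = "rigid_transform")
}

# Sub-bin peak refinement: fit a parabola through the correlation peak and
# its two neighbors along one margin; returns the fractional offset in
# [-0.5, 0.5] (0 at the grid borders).
parabolic_offset <- function(m, best, margin) {
  i <- best[margin]
  n <- dim(m)[margin]
  if (i <= 1L || i >= n) return(0)
  v <- if (margin == 1L) m[(i - 1L):(i + 1L), best[2]]
  else m[best[1], (i - 1L):(i + 1L)]
  den <- v[1] - 2 * v[2] + v[3]
  if (den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (v[1] - v[3]) / den))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: dy = %d, dx = %d (score %.3f)\n",
              x$dy, x$dx, x$score))
  invisible(x)
}

#' Quantify marker intensity by trophoblast density band
#'
#' Aligns the marker scan onto the CK7 grid frame using the rigid transform,
#' converts to gray with the standard Rec. 601 luma weighting, and averages
#' gray levels over the included tissue pixels of every included patch. Band
#' means are patch-count-weighted averages of patch means; the overall mean
#' averages all included patches. Gray level runs 0 (black, maximal staining)
#' to 255 (white, none): lower gray means higher expression, and the
#' convention is never inverted internally. A band with no patches is
#' reported as `NA`, not 0.
#'
#' @param marker_scan the marker `slide_scan` (NRF2 or KEAP1).
#' @param transform `rigid_transform` mapping the marker scan onto the grid
#'   frame (from [register_sections()]); `NULL` for identity.
#' @param grid a `patch_grid` built on the CK7 reference section.
#' @param subject_id optional subject identifier carried into the summary.
#' @param trophoblast_count,trophoblast_density,tissue_area_mm2 optional
#'   slide-level quantities carried into the summary.
#' @return object of class `band_intensity_summary`.
#' @export
quantify_intensity <- function(marker_scan, transform = NULL, grid,
                               subject_id = NA_character_,
                               trophoblast_count = NA_integer_,
                               trophoblast_density = NA_real_,
                               tissue_area_mm2 = NA_real_) {
  stopifnot(inherits(marker_scan, "slide_scan"), inherits(grid, "patch_grid"))
  img <- marker_scan$image
  if (!identical(dim(img)[1:2], as.integer(grid$shape)))
    stop("marker scan shape does not match the patch grid", call. = FALSE)
  gray <- rgb_to_gray(img)
  if (!is.null(transform)) {
    stopifnot(inherits(transform, "rigid_transform"))
    # luma commutes with translation, so align the gray raster directly
    gray <- translate_image(gray, -transform$dy, -transform$dx, fill = 255)
  }
  nr <- grid$shape[1]; nc <- grid$shape[2]; ps <- grid$patch_size
  sums <- patch_sums_cpp(gray, grid$included_mask, as.integer(ps))
  p <- grid$patches
  # look patches up by (row, col) so results do not depend on row order
  idx <- cbind(p$row, p$col)
  cnt <- sums$count[idx]
  patch_mean <- ifelse(cnt > 0, sums$sum[idx] / cnt, NA_real_)
  keep <- p$included & !is.na(patch_mean)
  bands <- c("maternal", "low", "high")
  band_mean <- setNames(rep(NA_real_, 3), bands)
  n_patches <- setNames(integer(3), bands)
  for (b in bands) {
    sel <- keep & !is.na(p$band) & p$band == b
    n_patches[b] <- sum(sel)
    if (n_patches[b] > 0) band_mean[b] <- mean(patch_mean[sel])
  }
  overall <- if (any(keep)) mean(patch_mean[keep]) else NA_real_
  structure(list(subject_id = subject_id, marker = marker_scan$marker,
                 mean_gray = band_mean, n_patches = n_patches,
                 overall_mean_gray = overall,
                 trophoblast_count = trophoblast_count,
                 trophoblast_density = trophoblast_density,
                 tissue_area_mm2 = tissue_area_mm2,
                 patch_means = data.frame(p[c("row", "col", "band")],
                                          mean_gray = patch_mean,
                                          included = keep)),
            class = "band_intensity_summary")
}

#' @export
print.band_intensity_summary <- function(x, ...) {
  cat(sprintf("Band intensity summary [%s%s]\n", x$marker,
              if (is.na(x$subject_id)) "" else paste0(", subject ", x$subject_id)))
  df <- data.frame(band = names(x$mean_gray),
                   mean_gray = round(unname(x$mean_gray), 2),
                   n_patches = unname(x$n_patches))
  print(df, row.names = FALSE)
  cat(sprintf("  overall mean gray: %.2f over %d patches\n",
              x$overall_mean_gray, sum(x$n_patches)))
  if (!is.na(x$trophoblast_count))
    cat(sprintf("  trophoblasts: %d (%.1f cells/mm^2 over %.3f mm^2)\n",
                x$trophoblast_count, x$trophoblast_density, x$tissue_area_mm2))
  invisible(x)
}

#' @export
as.data.frame.band_intensity_summary <- function(x, ...) {
  data.frame(subject_id = x$subject_id, marker = x$marker,
             maternal = x$mean_gray[["maternal"]],
             low = x$mean_gray[["low"]], high = x$mean_gray[["high"]],
             n_maternal = x$n_patches[["maternal"]],
             n_low = x$n_patches[["low"]], n_high = x$n_patches[["high"]],
             overall_mean_gray = x$overall_mean_gray,
             trophoblast_count = x$trophoblast_count,
             trophoblast_density = x$trophoblast_density,
             tissue_area_mm2 = x$tissue_area_mm2)
}

#' Run the whole slide pipeline on one subject's serial sections
#'
#' Flat-field corrects and stitches each section, detects tissue and applies
#' regions of disinterest on the CK7 reference, separates H-DAB, builds the
#' trophoblast patch grid, counts trophoblasts, registers each marker section
#' onto the CK7 frame and quantifies its density-banded intensity.
#'
#' @param tilesets named list of `tile_set`s; must contain `CK7` plus one or
#'   more marker sections (e.g. `NRF2`, `KEAP1`).
#' @param roi optional `roi_mask` in the stitched CK7 frame.
#' @param flatfield apply flat-field correction before stitching.
#' @param patch_size analysis patch edge, px.
#' @param od_threshold CK7 DAB positivity threshold (OD units).
#' @param white_threshold tissue detection threshold (gray level).
#' @param search_radius registration search radius, px.
#' @param subject_id carried into the summaries.
#' @param ... further arguments passed to [count_trophoblasts()].
#' @return list with the stitched `scans`, `grid`, `transforms`, per-marker
#'   `summaries`, `count`, `density`, `area_mm2` and a `table` (one row per
#'   marker, via [as.data.frame.band_intensity_summary()]).
#' @export
quantify_slide <- function(tilesets, roi = NULL, flatfield = TRUE,
                           patch_size = 50L, od_threshold = 0.15,
                           white_threshold = 240, search_radius = 100L,
                           subject_id = NA_character_, ...) {
  stopifnot("CK7" %in% names(tilesets))
  scans <- lapply(tilesets, function(ts) {
    if (flatfield) ts <- correct_tiles(ts, estimate_flatfield(ts))
    stitch(ts)
  })
  ck7 <- scans$CK7
  tis <- tissue_mask(ck7, white_threshold = white_threshold)
  inc <- apply_roi(tis, roi, ck7$pixel_size)
  dab <- dab_od_fast(ck7)
  ck7_pos <- ck7_positive_mask(dab, od_threshold = od_threshold)
  grid <- build_patch_grid(dim(ck7$image)[1:2], patch_size,
                           ck7_pos & inc$included, inc$included)
  cnt <- count_trophoblasts(ck7_pos & inc$included, area_mm2 = inc$area_mm2, ...)
  markers <- setdiff(names(scans), "CK7")
  transforms <- list(); summaries <- list()
  for (m in markers) {
    # same mask treatment on both sides keeps the correlation peak unbiased
    mov_mask <- tissue_mask(scans[[m]], white_threshold = white_threshold)
    transforms[[m]] <- register_sections(ck7, scans[[m]],
                                         search_radius = search_radius,
                                         white_threshold = white_threshold,
                                         ref_mask = tis, mov_mask = mov_mask)
    summaries[[m]] <- quantify_intensity(scans[[m]], transforms[[m]], grid,
                                         subject_id = subject_id,
                                         trophoblast_count = cnt$count,
                                         trophoblast_density = cnt$density,
                                         tissue_area_mm2 = inc$area_mm2)
  }
  list(scans = scans, grid = grid, transforms = transforms,
       summaries = summaries, count = cnt$count, density = cnt$density,
       area_mm2 = inc$area_mm2,
       table = do.call(rbind, lapply(summaries, as.data.frame)))
}
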