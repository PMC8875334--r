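# Phantom generator: counts, determinism, packing errors, rendering physics.

test_that("phantom cell counts and cluster labels follow the request", {
  ph0 <- generate_phantom(canvas_size = c(256L, 256L), n_clusters = 0L,
                          n_singles = 0L, seed = 1)
  expect_equal(nrow(ph0$trophoblast_cells), 0L)

  ph <- generate_phantom(canvas_size = c(512L, 512L), n_clusters = 2L,
                         cells_per_cluster = 5L, n_singles = 3L, seed = 1)
  expect_equal(nrow(ph$trophoblast_cells), 13L)
  expect_setequal(unique(ph$trophoblast_cells$cluster_id),
                  c("1", "2", "single"))
  # cells inside the canvas, radii positive
  expect_true(all(ph$trophoblast_cells$y > 0 &
                    ph$trophoblast_cells$y < ph$canvas_size[1]))
  expect_true(all(ph$trophoblast_cells$radius > 0))
})

test_that("phantom generation is a pure function of the seed", {
  a <- small_phantom(seed = 11)
  b <- small_phantom(seed = 11)
  expect_identical(a, b)
  c <- small_phantom(seed = 12)
  expect_false(identical(a$trophoblast_cells, c$trophoblast_cells))
})

test_that("no cell pair overlaps (count truth is unambiguous)", {
  ph <- generate_phantom(canvas_size = c(768L, 768L), n_clusters = 2L,
                         cells_per_cluster = 19L, n_singles = 10L, seed = 3)
  cells <- ph$trophoblast_cells
  d <- as.matrix(dist(cells[, c("y", "x")]))
  diag(d) <- Inf
  expect_true(min(d) > 2 * ph$cell_radius)
})

test_that("impossible packing requests raise errors, never truncate", {
  expect_error(generate_phantom(canvas_size = c(64L, 64L), n_clusters = 0L,
                                n_singles = 500L, seed = 1),
               "impossible packing")
  expect_error(generate_phantom(canvas_size = c(512L, 512L), n_clusters = 1L,
                                cells_per_cluster = 100L, cluster_spread = 20,
                                seed = 1),
               "impossible packing")
})

test_that("marker strengths outside [0,1] and bad offsets are rejected", {
  expect_error(generate_phantom(canvas_size = c(256L, 256L), seed = 1,
                                n_clusters = 0L, n_singles = 0L,
                                marker_strengths = list(CK7 = c(trophoblast = 1.2,
                                                                maternal = 0))),
               "\\[0, 1\\]")
  expect_error(generate_phantom(canvas_size = c(256L, 256L), seed = 1,
                                n_clusters = 0L, n_singles = 0L,
                                section_offsets = list(CK7 = c(dy = 90L, dx = 0L)),
                                max_offset = 50L),
               "max_offset")
})

test_that("an empty phantom renders as a uniform white slide", {
  ph <- generate_phantom(canvas_size = c(256L, 256L), n_clusters = 0L,
                         n_singles = 0L, stroma_fill = 0, n_exclusions = 0L,
                         seed = 2)
  ts <- render_section(ph, "CK7", vignette_strength = 0, noise_sd = 0,
                       tile_shape = c(128L, 128L))
  for (t in ts$tiles) expect_true(all(abs(t - 255) <= 1))
})

test_that("rendered gray level decreases strictly with DAB strength", {
  ph1 <- small_phantom(seed = 4)
  ph2 <- ph1
  ph1$marker_strengths$NRF2 <- c(trophoblast = 0.3, maternal = 0.1)
  ph2$marker_strengths$NRF2 <- c(trophoblast = 0.8, maternal = 0.1)
  g1 <- luma_oracle(stitch(render_section(ph1, "NRF2", 0, 0))$image)
  g2 <- luma_oracle(stitch(render_section(ph2, "NRF2", 0, 0))$image)
  off <- ph1$section_offsets$NRF2
  centers <- cbind(round(ph1$trophoblast_cells$y + off[1]),
                   round(ph1$trophoblast_cells$x + off[2]))
  ok <- centers[, 1] >= 1 & centers[, 1] <= 512 &
    centers[, 2] >= 1 & centers[, 2] <= 512
  centers <- centers[ok, , drop = FALSE]
  expect_gt(nrow(centers), 0)
  expect_true(all(g2[centers] < g1[centers]))
})

test_that("rendering is deterministic and tiling arithmetic is exact", {
  ph <- small_phantom(seed = 5)
  a <- render_section(ph, "CK7", 0.2, 0.05)
  b <- render_section(ph, "CK7", 0.2, 0.05)
  expect_identical(a, b)

  ph2 <- generate_phantom(canvas_size = c(512L, 576L), n_clusters = 0L,
                          n_singles = 0L, seed = 1)
  ts <- render_section(ph2, "CK7", 0, 0, tile_shape = c(256L, 192L))
  expect_equal(ts$grid_layout, c(2L, 3L))
  expect_length(ts$tiles, 6L)
  expect_error(render_section(ph2, "CK7", 0, 0, tile_shape = c(200L, 200L)),
               "not compatible")
  expect_error(render_section(ph2, "XYZ"), "unknown marker")
})

test_that("patch truth matches a brute-force disk rasterization", {
  ph <- generate_phantom(canvas_size = c(256L, 256L), n_clusters = 1L,
                         cells_per_cluster = 7L, n_singles = 4L,
                         cluster_spread = 45, seed = 7)
  truth <- phantom_patch_truth(ph, patch_size = 50L)
  # independent oracle: per-pixel distance test against every disk
  cells <- ph$trophoblast_cells
  for (k in sample(nrow(truth), 12L)) {
    p <- truth[k, ]
    ys <- (p$y0 + 1):p$y1; xs <- (p$x0 + 1):p$x1
    cnt <- 0L
    for (yy in ys) for (xx in xs) {
      inside <- any((cells$y - (yy - 0.5))^2 + (cells$x - (xx - 0.5))^2 <=
                      cells$radius^2)
      cnt <- cnt + inside
    }
    expect_equal(p$fraction, cnt / p$area_px, tolerance = 1e-12)
    expect_equal(as.character(p$band), band_oracle(p$fraction))
  }
})

test_that("patch truth covers the degenerate and saturated cases", {
  ph0 <- generate_phantom(canvas_size = c(200L, 200L), n_clusters = 0L,
                          n_singles = 0L, n_exclusions = 0L, seed = 1)
  t0 <- phantom_patch_truth(ph0, 50L)
  expect_true(all(t0$fraction == 0))
  expect_true(all(t0$band == "maternal"))
  expect_true(all(!t0$excluded))

  # a patch fully inside one giant cell has fraction 1 and band "high"
  ph1 <- ph0
  ph1$trophoblast_cells <- data.frame(y = 100, x = 100, radius = 75,
                                      cluster_id = "single")
  t1 <- phantom_patch_truth(ph1, 50L)
  center <- t1[t1$row == 2 & t1$col == 2, ]
  expect_equal(center$fraction, 1)
  expect_equal(as.character(center$band), "high")
})

test_that("expression phantom nulls are balanced and effects implant cleanly", {
  genes <- sprintf("g%04d", 1:1000)
  sets <- list(s1 = genes[1:40], s2 = genes[41:80])
  ep0 <- generate_expression(1000L, 10L, gene_sets = sets, seed = 3)
  m <- ep0$matrix
  for (nm in names(sets)) {
    idx <- match(sets[[nm]], rownames(m))
    d <- mean(m[idx, ep0$phenotype == 1]) - mean(m[idx, ep0$phenotype == 0])
    se <- sqrt(2 / (length(idx) * 10))
    expect_lt(abs(d), 4 * se)
  }

  ep2 <- generate_expression(1000L, 20L, gene_sets = sets,
                             implanted_set = "s1", implanted_effect = 2,
                             seed = 4)
  idx <- match(sets$s1, rownames(ep2$matrix))
  d <- mean(ep2$matrix[idx, ep2$phenotype == 1]) -
    mean(ep2$matrix[idx, ep2$phenotype == 0])
  expect_equal(d, 2, tolerance = 0.15)

  expect_identical(generate_expression(100L, 5L, seed = 9)$matrix,
                   generate_expression(100L, 5L, seed = 9)$matrix)
  expect_error(generate_expression(100L, 5L, gene_sets = list(bad = "nope"),
                                   seed = 1), "unknown genes")
  overlapping <- list(a = genes[1:10], b = genes[5:15])
  expect_error(generate_expression(1000L, 5L, gene_sets = overlapping, seed = 1),
               "overlap")
  expect_silent(generate_expression(1000L, 5L, gene_sets = overlapping,
                                    allow_overlap = TRUE, seed = 1))
})
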