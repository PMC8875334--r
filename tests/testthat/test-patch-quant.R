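# Stain separation, CK7 masking, patch grid, counting, registration,
# density-banded intensity.

test_that("H-DAB separation inverts the forward color model", {
  white <- scan_from_gray(matrix(255, 8, 8))
  od <- separate_hdab(white)
  expect_true(all(od$hematoxylin == 0))
  expect_true(all(od$dab == 0))

  # recovered DAB OD increases strictly with rendered DAB strength
  strengths <- c(0.1, 0.3, 0.5, 0.7)
  rec <- vapply(strengths, function(s) {
    ph <- generate_phantom(canvas_size = c(128L, 128L), n_clusters = 0L,
                           n_singles = 0L, stroma_fill = 1, n_exclusions = 0L,
                           marker_strengths = list(NRF2 = c(trophoblast = 0,
                                                            maternal = s)),
                           section_offsets = list(NRF2 = c(dy = 0L, dx = 0L)),
                           seed = 1)
    sc <- stitch(render_section(ph, "NRF2", 0, 0, tile_shape = c(128L, 128L)))
    mean(separate_hdab(sc)$dab)
  }, 0)
  expect_true(all(diff(rec) > 0))

  # hematoxylin-only phantom shows no DAB positivity (cross-talk bound)
  ph <- generate_phantom(canvas_size = c(128L, 128L), n_clusters = 0L,
                         n_singles = 0L, stroma_fill = 1, n_exclusions = 0L,
                         marker_strengths = list(CK7 = c(trophoblast = 0,
                                                         maternal = 0)),
                         section_offsets = list(CK7 = c(dy = 0L, dx = 0L)),
                         seed = 2)
  sc <- stitch(render_section(ph, "CK7", 0, 0, tile_shape = c(128L, 128L)))
  expect_true(all(separate_hdab(sc)$dab < 0.15))

  # the one-pass pipeline kernel agrees with the reference implementation
  ph2 <- small_phantom(seed = 3)
  sc2 <- stitch(render_section(ph2, "CK7", 0, 0.02, tile_shape = c(256L, 256L)))
  expect_equal(trophoquant:::dab_od_fast(sc2), separate_hdab(sc2)$dab,
               tolerance = 1e-10)
})

test_that("CK7 positivity masks behave at both extremes", {
  zeros <- matrix(0, 50, 50)
  expect_false(any(ck7_positive_mask(zeros)))

  ph <- small_phantom(seed = 4)
  sc <- stitch(render_section(ph, "CK7", 0, 0, tile_shape = c(256L, 256L)))
  dab <- separate_hdab(sc)$dab
  m <- ck7_positive_mask(dab)
  truth <- trophoquant:::rasterize_cells(ph$trophoblast_cells, 512L, 512L)
  expect_gte(sum(m & truth) / sum(m | truth), 0.9)
  expect_false(any(ck7_positive_mask(dab, min_object_px = sum(truth) * 10)))
})

test_that("patch grid fractions match brute-force pixel counting", {
  set.seed(51)
  ck7 <- matrix(runif(200 * 200) < 0.3, 200, 200)
  inc <- matrix(runif(200 * 200) < 0.9, 200, 200)
  grid <- build_patch_grid(c(200L, 200L), 50L, ck7, inc)
  p <- grid$patches
  for (k in seq_len(nrow(p))) {
    ys <- (p$y0[k] + 1):p$y1[k]; xs <- (p$x0[k] + 1):p$x1[k]
    tis <- sum(inc[ys, xs])
    pos <- sum(ck7[ys, xs] & inc[ys, xs])
    if (tis == 0) expect_false(p$included[k])
    else expect_equal(p$trophoblast_fraction[k], pos / tis)
  }
  # every included patch is in exactly one band and the counts partition
  expect_true(all(!is.na(p$band[p$included])))
  expect_equal(sum(table(p$band[p$included])), sum(p$included))
})

test_that("band boundary semantics: exactly half CK7-positive is low", {
  inc <- matrix(TRUE, 50, 50)
  ck7 <- matrix(FALSE, 50, 50); ck7[, 1:25] <- TRUE
  g <- build_patch_grid(c(50L, 50L), 50L, ck7, inc)
  expect_equal(g$patches$trophoblast_fraction, 0.5)
  expect_equal(as.character(g$patches$band), "low")

  empty <- build_patch_grid(c(100L, 100L), 50L, matrix(FALSE, 100, 100),
                            matrix(TRUE, 100, 100))
  expect_true(all(empty$patches$band == "maternal"))
})

test_that("trophoblast counting is exact for disjoint cells and splits clusters", {
  expect_equal(count_trophoblasts(matrix(FALSE, 50, 50), area_mm2 = 1)$count, 0L)

  ph <- generate_phantom(canvas_size = c(512L, 512L), n_clusters = 2L,
                         cells_per_cluster = 5L, n_singles = 3L, seed = 6,
                         n_exclusions = 0L)
  m <- trophoquant:::rasterize_cells(ph$trophoblast_cells, 512L, 512L)
  res <- count_trophoblasts(m, area_mm2 = 0.1)
  expect_equal(res$count, 13L)
  expect_equal(res$density, 130)

  # five equal touching disks in a row, plus two singles to anchor the
  # single-cell area estimate
  mk <- matrix(FALSE, 120, 220)
  for (cx in c(30 + 0:4 * 15)) mk <- mk | trophoquant:::rasterize_cells(
    data.frame(y = 30, x = cx, radius = 8, cluster_id = "c"), 120L, 220L)
  mk <- mk | trophoquant:::rasterize_cells(
    data.frame(y = c(80, 80), x = c(40, 120), radius = 8, cluster_id = "s"),
    120L, 220L)
  res2 <- count_trophoblasts(mk, max_cell_px = 320, area_mm2 = 1)
  expect_gte(res2$count, 6 + 1)   # 5 +/- 1 in the cluster plus 2 singles
  expect_lte(res2$count, 6 + 3)

  expect_error(count_trophoblasts(m, area_mm2 = 0), "area is zero")
})

test_that("registration recovers identity, known offsets, and fails loudly", {
  ph <- generate_phantom(canvas_size = c(512L, 512L), seed = 7,
                         n_clusters = 2L, n_exclusions = 0L,
                         section_offsets = list(CK7 = c(dy = 0L, dx = 0L),
                                                NRF2 = c(dy = 17L, dx = -23L),
                                                KEAP1 = c(dy = 0L, dx = 0L)))
  ck7 <- stitch(render_section(ph, "CK7", 0, 0, tile_shape = c(256L, 256L)))
  self <- register_sections(ck7, ck7)
  expect_equal(c(self$dy, self$dx), c(0L, 0L))

  nrf <- stitch(render_section(ph, "NRF2", 0, 0.02, tile_shape = c(256L, 256L)))
  tr <- register_sections(ck7, nrf, search_radius = 50L)
  expect_lte(abs(tr$dy - 17L), 1L)
  expect_lte(abs(tr$dx + 23L), 1L)
  expect_gt(tr$score, 0.5)

  # content displaced far beyond the search radius: the in-window correlation
  # is poor, so the low-score warning path returns the identity
  g1 <- matrix(255, 512, 512); g1[1:120, 1:120] <- 40
  g2 <- matrix(255, 512, 512); g2[350:470, 350:470] <- 40
  s1 <- scan_from_gray(g1); s2 <- scan_from_gray(g2)
  expect_warning(far <- register_sections(s1, s2, search_radius = 20L),
                 "below floor")
  expect_equal(c(far$dy, far$dx), c(0L, 0L))

  blank <- scan_from_gray(matrix(255, 512, 512), pixel_size = ph$pixel_size)
  expect_error(register_sections(ck7, blank), "empty")
  small <- scan_from_gray(matrix(100, 64, 64), pixel_size = ph$pixel_size)
  expect_error(register_sections(ck7, small), "dimensions")
})

test_that("band intensity means equal hand-computed averages exactly", {
  set.seed(61)
  gray <- matrix(round(runif(100 * 100, 0, 255)), 100, 100)
  sc <- scan_from_gray(gray)
  inc <- matrix(runif(100 * 100) < 0.8, 100, 100)
  ck7 <- matrix(FALSE, 100, 100); ck7[1:50, 1:50] <- TRUE      # patch (1,1) high
  ck7[51:100, 1:50] <- matrix(runif(2500) < 0.2, 50, 50)       # patch (2,1) low-ish
  grid <- build_patch_grid(c(100L, 100L), 50L, ck7 & inc, inc)
  s <- quantify_intensity(sc, NULL, grid)
  p <- grid$patches
  hand <- vapply(seq_len(nrow(p)), function(k) {
    ys <- (p$y0[k] + 1):p$y1[k]; xs <- (p$x0[k] + 1):p$x1[k]
    mean(gray[ys, xs][inc[ys, xs]])
  }, 0)
  for (b in c("maternal", "low", "high")) {
    sel <- p$included & !is.na(p$band) & p$band == b
    if (any(sel)) expect_equal(s$mean_gray[[b]], mean(hand[sel]))
    else expect_true(is.na(s$mean_gray[[b]]))
  }
  expect_equal(s$overall_mean_gray, mean(hand[p$included]))
  expect_equal(sum(s$n_patches), sum(p$included))

  # all-white marker scan: every observed band mean is 255
  sw <- quantify_intensity(scan_from_gray(matrix(255, 100, 100)), NULL, grid)
  expect_true(all(sw$mean_gray[!is.na(sw$mean_gray)] == 255))
})

test_that("stronger marker staining lowers the high-band gray mean", {
  ph1 <- generate_phantom(canvas_size = c(512L, 512L), n_clusters = 1L,
                          cells_per_cluster = 19L, n_singles = 5L,
                          n_exclusions = 1L, seed = 8)
  ph2 <- ph1
  ph1$marker_strengths$NRF2 <- c(trophoblast = 0.3, maternal = 0.1)
  ph2$marker_strengths$NRF2 <- c(trophoblast = 0.7, maternal = 0.1)
  run <- function(ph) {
    ts <- lapply(setNames(nm = c("CK7", "NRF2")), function(m)
      render_section(ph, m, 0, 0, tile_shape = c(256L, 256L)))
    quantify_slide(ts, flatfield = FALSE)$summaries$NRF2$mean_gray
  }
  m1 <- run(ph1); m2 <- run(ph2)
  expect_lt(m2[["high"]], m1[["high"]])
})

test_that("quantification is invariant to patch bookkeeping order", {
  set.seed(62)
  gray <- matrix(round(runif(150 * 150, 0, 255)), 150, 150)
  inc <- matrix(runif(150 * 150) < 0.7, 150, 150)
  ck7 <- matrix(runif(150 * 150) < 0.3, 150, 150)
  grid <- build_patch_grid(c(150L, 150L), 50L, ck7 & inc, inc)
  g2 <- grid
  perm <- sample(nrow(g2$patches))
  g2$patches <- g2$patches[perm, ]
  a <- quantify_intensity(scan_from_gray(gray), NULL, grid)
  b <- quantify_intensity(scan_from_gray(gray), NULL, g2)
  expect_equal(a$mean_gray, b$mean_gray)
  expect_equal(a$overall_mean_gray, b$overall_mean_gray)
})
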