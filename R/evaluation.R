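# Seeded validation studies on synthetic phantoms. These are the package's
# own benchmarks: each runs the real pipeline on generated data with known
# truth and reports recovery / calibration summaries.

#' End-to-end phantom recovery study
#'
#' For each seeded phantom (three serial sections: CK7 reference plus NRF2
#' and KEAP1 with injected rigid offsets up to the phantom's `max_offset`),
#' runs flat-field correction, stitching, tissue masking, H-DAB separation,
#' patch-grid construction, registration, trophoblast counting and
#' density-banded intensity quantification, then scores the result against
#' ground truth: was the NRF2 band gray-mean ordering (high < low < maternal)
#' recovered; the registration error per marker; and the relative error of
#' the trophoblast density (phantoms use non-touching cells, so the count
#' truth is unambiguous).
#'
#' @param n_phantoms number of phantoms.
#' @param seed integer master seed.
#' @param canvas_size phantom canvas, px.
#' @param vignette_strength,noise_sd rendering conditions.
#' @param flatfield apply flat-field correction in the pipeline.
#' @param white_threshold tissue threshold; the default tolerates the
#'   residual shading left when `flatfield = FALSE`.
#' @return data.frame, one row per phantom: `ordering_ok`,
#'   `offset_err_nrf2`, `offset_err_keap1` (Chebyshev px), `density_rel_err`,
#'   plus a `summary` attribute with the aggregate rates.
#' @export
phantom_recovery_study <- function(n_phantoms = 100L, seed = 1L,
                                   canvas_size = c(1536L, 1536L),
                                   vignette_strength = 0.1, noise_sd = 0.02,
                                   flatfield = FALSE, white_threshold = 215) {
  seeds <- with_seed(seed, sample.int(2^30, n_phantoms))
  rows <- vector("list", n_phantoms)
  for (i in seq_len(n_phantoms)) {
    ph <- generate_phantom(canvas_size = canvas_size, seed = seeds[i])
    tilesets <- lapply(setNames(nm = names(ph$marker_strengths)), function(m)
      render_section(ph, m, vignette_strength = vignette_strength,
                     noise_sd = noise_sd))
    res <- quantify_slide(tilesets, flatfield = flatfield,
                          white_threshold = white_threshold,
                          subject_id = sprintf("ph%03d", i))
    s <- res$summaries$NRF2$mean_gray
    ordering_ok <- !anyNA(s) && s[["high"]] < s[["low"]] &&
      s[["low"]] < s[["maternal"]]
    err <- function(m) max(abs(c(
      res$transforms[[m]]$dy - ph$section_offsets[[m]][1],
      res$transforms[[m]]$dx - ph$section_offsets[[m]][2])))
    truth_area <- sum(phantom_tissue_truth(ph)) * (ph$pixel_size / 1000)^2
    truth_density <- nrow(ph$trophoblast_cells) / truth_area
    rows[[i]] <- data.frame(
      phantom = i, ordering_ok = ordering_ok,
      offset_err_nrf2 = err("NRF2"), offset_err_keap1 = err("KEAP1"),
      density_rel_err = abs(res$density - truth_density) / truth_density)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(
    ordering_rate = mean(out$ordering_ok),
    offset_max_err = max(out$offset_err_nrf2, out$offset_err_keap1),
    density_max_rel_err = max(out$density_rel_err))
  out
}

#' Type-I error of the group-comparison pipelines under the null
#'
#' Simulates `n_sims` null datasets (`k` groups of `n_per_group` standard
#' normals) and reports the rejection rate at `alpha` of the Kruskal-Wallis
#' and one-way ANOVA omnibus tests.
#'
#' @param n_sims number of simulated datasets.
#' @param n_per_group group size.
#' @param k number of groups.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return named vector with `kruskal_rate` and `anova_rate`.
#' @export
null_calibration_study <- function(n_sims = 1000L, n_per_group = 10L, k = 3L,
                                   alpha = 0.05, seed = 1L) {
  with_seed(seed, {
    g <- rep(seq_len(k), each = n_per_group)
    kw <- logical(n_sims); av <- logical(n_sims)
    for (i in seq_len(n_sims)) {
      y <- rnorm(k * n_per_group)
      kw[i] <- kruskal_dunn(y, g, method = "asymptotic")$p_value <= alpha
      av[i] <- anova_tukey(y, g)$p_value <= alpha
    }
    c(kruskal_rate = mean(kw), anova_rate = mean(av))
  })
}

#' Fixed-effect recovery of the density-band mixed model
#'
#' Simulates subjects in two diagnostic groups, each contributing one
#' low-band and one high-band observation, with a subject random intercept,
#' a band effect and a group effect; fits the mixed model and records the
#' group fixed-effect estimate per simulation.
#'
#' @param n_sims simulations.
#' @param n_per_group subjects per group.
#' @param effect true group effect on band means (gray levels).
#' @param subject_sd,resid_sd random-intercept and residual SDs.
#' @param band_effect true band effect (high minus low).
#' @param seed integer seed.
#' @return numeric vector of group-effect estimates (length `n_sims`);
#'   its mean minus `effect` is the recovery bias.
#' @export
mixed_recovery_study <- function(n_sims = 200L, n_per_group = 25L, effect = 8,
                                 subject_sd = 5, resid_sd = 5,
                                 band_effect = -10, seed = 1L) {
  with_seed(seed, {
    est <- numeric(n_sims)
    for (i in seq_len(n_sims)) {
      n <- 2L * n_per_group
      subj <- factor(rep(seq_len(n), each = 2L))
      grp <- factor(rep(c("A", "B"), each = 2L * n_per_group))
      site <- factor(sample(c("site_A", "site_B"), 2L * n, replace = TRUE))[
        rep(seq_len(n), each = 2L)]
      band <- factor(rep(c("low", "high"), times = n),
                     levels = c("low", "high"))
      u <- rnorm(n, sd = subject_sd)[rep(seq_len(n), each = 2L)]
      y <- 150 + (grp == "B") * effect + (band == "high") * band_effect +
        u + rnorm(2L * n, sd = resid_sd)
      fit <- fit_density_band_mixed(
        data.frame(value = y, subject = subj, group = grp,
                   site = site, band = band), interaction = FALSE)
      est[i] <- fit$fixed_effects$estimate[fit$fixed_effects$term == "groupB"]
    }
    est
  })
}

#' Calibration of the robust outlier procedure
#'
#' Reports (a) the fraction of clean standard-normal points flagged at the
#' given `Q` over replicate null samples, and (b) the detection rate of a
#' single gross outlier placed `outlier_mads` robust SDs from the median.
#'
#' @param n_reps replicate samples.
#' @param n sample size per replicate.
#' @param Q false-discovery rate.
#' @param outlier_mads distance of the planted outlier in MAD units.
#' @param seed integer seed.
#' @return named vector `null_flag_rate`, `outlier_detection_rate`.
#' @export
rout_calibration_study <- function(n_reps = 200L, n = 100L, Q = 0.01,
                                   outlier_mads = 50, seed = 1L) {
  with_seed(seed, {
    flags <- numeric(n_reps); hits <- logical(n_reps)
    for (i in seq_len(n_reps)) {
      x <- rnorm(n)
      flags[i] <- length(rout_outliers(x, Q)$flagged) / n
      x2 <- c(x, median(x) + outlier_mads * mad(x))
      hits[i] <- (n + 1L) %in% rout_outliers(x2, Q)$flagged
    }
    c(null_flag_rate = mean(flags), outlier_detection_rate = mean(hits))
  })
}

#' Calibration and power of the permutation enrichment p-value
#'
#' Null calibration: datasets with no implanted effect; reports the fraction
#' with `p <= alpha` for a random 40-gene set (should be close to `alpha`).
#' Power: datasets with an implanted shift on the set; reports the fraction
#' with `p <= alpha` and `NES > 1`.
#'
#' @param n_null,n_power number of datasets per arm.
#' @param n_genes genes per matrix.
#' @param set_size implanted set size.
#' @param n_samples_per_class samples per phenotype class.
#' @param effect implanted shift (within-group SD units) for the power arm.
#' @param n_permutations label permutations per dataset.
#' @param alpha nominal level.
#' @param seed integer master seed.
#' @return named vector `null_rejection_rate`, `power`.
#' @export
enrichment_calibration_study <- function(n_null = 200L, n_power = 50L,
                                         n_genes = 500L, set_size = 40L,
                                         n_samples_per_class = 20L, effect = 2,
                                         n_permutations = 100L, alpha = 0.05,
                                         seed = 1L) {
  seeds <- with_seed(seed, sample.int(2^30, n_null + n_power))
  one <- function(s, eff) {
    genes <- sprintf("g%04d", seq_len(n_genes))
    gs <- list(target = genes[seq_len(set_size)])
    ep <- generate_expression(n_genes, n_samples_per_class, gene_sets = gs,
                              implanted_set = if (eff != 0) "target",
                              implanted_effect = eff, seed = s)
    ranked <- rank_by_phenotype(ep$matrix, ep$phenotype)
    nes_and_p(ranked, gs$target, n_permutations, seed = s + 1L,
              set_name = "target")
  }
  null_res <- lapply(seeds[seq_len(n_null)], one, eff = 0)
  pow_res <- lapply(seeds[n_null + seq_len(n_power)], one, eff = effect)
  null_rej <- mean(vapply(null_res, function(r) r$p_value <= alpha, TRUE))
  pow <- mean(vapply(pow_res, function(r)
    r$p_value <= alpha && !is.na(r$nes) && r$nes > 1, TRUE))
  c(null_rejection_rate = null_rej, power = pow)
}

#' Flat-field correction benchmark
#'
#' Renders a vignetted, noiseless phantom section, estimates and applies the
#' flat field, and reports the coefficient of variation of true background
#' pixels before and after correction.
#'
#' @param vignette_strength vignette amplitude.
#' @param seed integer seed.
#' @param canvas_size phantom canvas.
#' @return named vector `cv_before`, `cv_after`, `reduction_factor`.
#' @export
flatfield_benchmark <- function(vignette_strength = 0.3, seed = 1L,
                                canvas_size = c(1024L, 1024L)) {
  ph <- generate_phantom(canvas_size = canvas_size, stroma_fill = 0.6,
                         n_exclusions = 0L, seed = seed)
  ts <- render_section(ph, "CK7", vignette_strength = vignette_strength,
                       noise_sd = 0)
  truth_bg <- !phantom_tissue_truth(ph)   # CK7 reference has zero offset
  corrected <- correct_tiles(ts, estimate_flatfield(ts))
  cv_of <- function(tiles) {
    v <- unlist(lapply(seq_along(tiles$tiles), function(i) {
      sub <- tile_region(truth_bg, tiles, i)
      g <- rgb_to_gray(tiles$tiles[[i]])
      g[sub]
    }))
    sd(v) / mean(v)
  }
  cvb <- cv_of(ts); cva <- cv_of(corrected)
  c(cv_before = cvb, cv_after = cva, reduction_factor = cvb / cva)
}

# Logical submatrix of a canvas-shaped mask corresponding to tile i.
tile_region <- function(mask, tiles, i) {
  rows <- tiles$grid_layout[1]; cols <- tiles$grid_layout[2]
  th <- tiles$tile_shape[1]; tw <- tiles$tile_shape[2]; ov <- tiles$overlap
  r <- (i - 1L) %/% cols + 1L; c <- (i - 1L) %% cols + 1L
  y <- (r - 1L) * (th - ov) + seq_len(th)
  x <- (c - 1L) * (tw - ov) + seq_len(tw)
  mask[y, x]
}
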