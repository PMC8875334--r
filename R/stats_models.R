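# Regression layer for intensity outcomes: a site-adjusted linear model for
# maternal-tissue / overall means and a linear mixed model with a subject
# random intercept for the density-banded repeated measures.

ihc_model <- function(kind, fit, fixed_effects, estimated_means, pairwise,
                      n_used, note = NULL) {
  structure(list(kind = kind, fit = fit, fixed_effects = fixed_effects,
                 estimated_means = estimated_means, pairwise = pairwise,
                 n_used = n_used, note = note),
            class = "ihc_model")
}

#' @export
print.ihc_model <- function(x, digits = 4, ...) {
  cat(sprintf("%s (n = %d observations)\n", x$kind, x$n_used))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  cat("  fixed effects:\n")
  print(x$fixed_effects, row.names = FALSE, digits = digits)
  cat("  estimated means (+/- SEM):\n")
  print(x$estimated_means, row.names = FALSE, digits = digits)
  cat("  pairwise group contrasts:\n")
  print(x$pairwise, row.names = FALSE, digits = digits)
  invisible(x)
}

#' @export
summary.ihc_model <- function(object, ...) summary(object$fit, ...)

#' @export
coef.ihc_model <- function(object, ...) {
  setNames(object$fixed_effects$estimate, object$fixed_effects$term)
}

emm_to_df <- function(emm) {
  s <- as.data.frame(emm)
  names(s)[names(s) == "emmean"] <- "estimate"
  names(s)[names(s) == "SE"] <- "sem"
  s[!(names(s) %in% c("df", "lower.CL", "upper.CL", "asymp.LCL", "asymp.UCL"))]
}

#' Site-adjusted linear model for slide-level intensities
#'
#' Least-squares fit of a slide-level outcome (e.g. maternal-tissue mean gray
#' or overall mean gray) on diagnostic group with recruitment site as a
#' covariate. Reports group coefficients against the reference group,
#' estimated marginal means with standard errors, and pairwise group
#' contrasts both unadjusted and Tukey-adjusted. A site factor with a single
#' observed level is dropped (with a message), which leaves all other
#' estimates unchanged.
#'
#' @param values numeric outcome per subject.
#' @param group diagnostic group factor; its first level is the reference
#'   (conventionally the normal pregnancies).
#' @param site recruitment-site factor.
#' @return an `ihc_model`.
#' @export
fit_site_adjusted_linear <- function(values, group, site) {
  group <- droplevels(as.factor(group))
  site <- droplevels(as.factor(site))
  stopifnot(length(values) == length(group), length(values) == length(site))
  use_site <- nlevels(site) >= 2L
  use_group <- nlevels(group) >= 2L
  if (!use_site) message("site has a single level; fitting without it")
  df <- data.frame(y = values, group = group, site = site)
  rhs <- paste(c(if (use_group) "group", if (use_site) "site", "1"),
               collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cs <- summary(fit)$coefficients
  fe <- data.frame(term = rownames(cs), estimate = cs[, 1], se = cs[, 2],
                   p_value = cs[, 4], row.names = NULL)
  if (use_group) {
    emm <- emmeans::emmeans(fit, ~ group)
    prs_raw <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
    prs_adj <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
    means <- emm_to_df(emm)
    pw <- data.frame(comparison = prs_raw$contrast, estimate = prs_raw$estimate,
                     se = prs_raw$SE, p_raw = prs_raw$p.value,
                     p_adjusted = prs_adj$p.value)
  } else {
    means <- data.frame(group = levels(group), estimate = cs["(Intercept)", 1],
                        sem = cs["(Intercept)", 2])
    pw <- data.frame(comparison = character(), estimate = numeric(),
                     se = numeric(), p_raw = numeric(), p_adjusted = numeric())
  }
  ihc_model("Site-adjusted linear model", fit, fe, means, pw,
            n_used = nrow(df),
            note = if (!use_site) "site dropped (single level)" else NULL)
}

#' Linear mixed model for density-banded intensities
#'
#' REML fit of band-level mean gray values on diagnostic group, trophoblast
#' density band and recruitment site, with a subject-specific random
#' intercept absorbing within-subject correlation across bands. Only the
#' trophoblast-containing bands (`low`, `high`) enter the model; a
#' group-by-band interaction is included by default so that within-band group
#' contrasts are free to differ. Estimated group-by-band means with standard
#' errors and within-band pairwise group contrasts (raw and Tukey-adjusted,
#' Wald z) are reported. The observational unit is subject by band: duplicate
#' rows for the same subject and band are averaged (with a message) before
#' fitting. When no subject contributes two bands the random
#' intercept is inestimable and the fit falls back to fixed effects only,
#' with a warning.
#'
#' @param data data.frame with one row per subject-by-band observation.
#' @param value,subject,group,site,band column names in `data`.
#' @param bands bands retained (default the trophoblast-containing two).
#' @param interaction include group-by-band interaction.
#' @return an `ihc_model`; the lme4 fit (or the fallback `lm`) is in `$fit`.
#' @export
fit_density_band_mixed <- function(data, value = "value", subject = "subject",
                                   group = "group", site = "site",
                                   band = "band", bands = c("low", "high"),
                                   interaction = TRUE) {
  df <- data.frame(y = data[[value]],
                   subject = as.factor(data[[subject]]),
                   group = droplevels(as.factor(data[[group]])),
                   site = droplevels(as.factor(data[[site]])),
                   band = as.factor(data[[band]]))
  df <- df[df$band %in% bands & !is.na(df$y), ]
  df$band <- factor(as.character(df$band), levels = bands)
  df <- droplevels(df)
  if (!nrow(df)) stop("no usable band-level observations", call. = FALSE)
  # the observational unit is subject x band: collapse accidental duplicates
  if (anyDuplicated(df[c("subject", "band")])) {
    message("averaging duplicate subject-by-band observations before fitting")
    df <- stats::aggregate(y ~ subject + group + site + band, data = df,
                           FUN = mean)
  }
  use_site <- nlevels(df$site) >= 2L
  use_band <- nlevels(df$band) >= 2L
  rhs <- if (use_band && interaction) "group * band"
  else if (use_band) "group + band" else "group"
  if (use_site) rhs <- paste(rhs, "+ site")
  repeated <- any(table(df$subject) >= 2L)
  fallback <- FALSE
  if (repeated) {
    form <- stats::as.formula(paste("y ~", rhs, "+ (1 | subject)"))
    fit <- suppressMessages(lme4::lmer(form, data = df, REML = TRUE))
    fe_mat <- coef(summary(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranvar <- vc$vcov[vc$grp == "subject"]
  } else {
    warning("no subject contributes >= 2 bands; falling back to a fixed-effects-only fit")
    fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = df)
    fe_mat <- summary(fit)$coefficients
    ranvar <- NA_real_
    fallback <- TRUE
  }
  fe <- data.frame(term = rownames(fe_mat), estimate = fe_mat[, 1],
                   se = fe_mat[, 2], row.names = NULL)
  emm_formula <- if (use_band) ~ group | band else ~ group
  emm <- emmeans::emmeans(fit, emm_formula, lmer.df = "asymptotic")
  prs_raw <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
  prs_adj <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
  pw <- data.frame(comparison = prs_raw$contrast,
                   band = if (use_band) prs_raw$band else NA,
                   estimate = prs_raw$estimate, se = prs_raw$SE,
                   p_raw = prs_raw$p.value, p_adjusted = prs_adj$p.value)
  out <- ihc_model(
    if (fallback) "Density-band model (fixed effects only)"
    else "Density-band linear mixed model (REML, subject random intercept)",
    fit, fe, emm_to_df(emm), pw, n_used = nrow(df),
    note = if (fallback) "random intercept inestimable" else
      sprintf("random intercept variance %.4g", ranvar))
  out$random_intercept_var <- ranvar
  out
}
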