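# Group-comparison layer: robust outlier removal, Kruskal-Wallis with Dunn
# post hoc, one-way ANOVA with Tukey post hoc.

#' Robust outlier flagging (ROUT-style)
#'
#' Approximation of GraphPad's ROUT procedure for the one-sample (constant
#' model) case: a robust location/scale fit (median and MAD) yields t-like
#' standardized residuals whose two-sided normal p-values are screened by
#' Benjamini-Hochberg FDR at rate `Q`. Only points rejected at that rate are
#' flagged. This is a documented approximation of the published method, not a
#' bit-level clone of the GraphPad implementation.
#'
#' @param values numeric vector, `n >= 5`.
#' @param Q maximum false-discovery rate for flagged outliers, in `(0, 0.1]`.
#' @return list with `kept` (values minus flagged), `flagged` (indices into
#'   `values`), `center`, `scale`.
#' @export
rout_outliers <- function(values, Q = 0.01) {
  if (length(values) < 5L)
    stop("need at least 5 values for robust scale estimation", call. = FALSE)
  if (Q <= 0 || Q > 0.1) stop("Q must be in (0, 0.1]", call. = FALSE)
  center <- median(values)
  scale <- mad(values, center = center)
  if (scale == 0) scale <- diff(quantile(values, c(0.25, 0.75))) / 1.349
  if (scale == 0) {
    # zero spread: nothing can be an outlier
    return(list(kept = values, flagged = integer(0),
                center = center, scale = 0))
  }
  z <- (values - center) / scale
  p <- 2 * stats::pnorm(-abs(z))
  flagged <- which(stats::p.adjust(p, method = "BH") <= Q)
  list(kept = if (length(flagged)) values[-flagged] else values,
       flagged = flagged, center = center, scale = scale)
}

# Tie-robust Kruskal-Wallis statistic: (N-1) * SSbetween(ranks) / SStotal(ranks).
kw_statistic <- function(values, g) {
  r <- rank(values)
  N <- length(r)
  rbar <- mean(r)
  num <- sum(tapply(r, g, function(x) length(x) * (mean(x) - rbar)^2))
  den <- sum((r - rbar)^2)
  if (den == 0) return(0)
  (N - 1) * num / den
}

# All distinct assignments of n indices to groups of given sizes (recursive
# over combinations); used for the exact permutation p at small n.
label_arrangements <- function(sizes) {
  n <- sum(sizes)
  rec <- function(avail, sizes) {
    if (length(sizes) == 1L) return(list(list(avail)))
    first <- utils::combn(avail, sizes[1], simplify = FALSE)
    out <- list()
    for (f in first) {
      rest <- rec(setdiff(avail, f), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(list(f), r)))
    }
    out
  }
  rec(seq_len(n), sizes)
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Rank-based omnibus comparison of two or more groups followed by Dunn's
#' pairwise z-tests on mean ranks with tie correction. The omnibus p-value is
#' the asymptotic chi-square by default; with `method = "exact"` (the default
#' when total n is at most `exact_n_max`) it is the exhaustive permutation
#' p-value over all distinct label assignments, so small-sample results do
#' not rely on the asymptotic approximation.
#'
#' @param values numeric vector of observations.
#' @param groups group labels (coerced to factor), each group `n >= 2`.
#' @param method `"auto"`, `"asymptotic"` or `"exact"`.
#' @param p_adjust multiplicity adjustment for the Dunn p-values
#'   (`"bonferroni"` is the classical Dunn adjustment; any
#'   [stats::p.adjust()] method or `"none"`).
#' @param exact_n_max largest total n for which `"auto"` picks the exact test.
#' @return object of class `group_test` with `statistic`, `p_value`,
#'   `method`, and a `pairwise` data.frame (`comparison`, `z`, `p_raw`,
#'   `p_adjusted`).
#' @export
kruskal_dunn <- function(values, groups, method = c("auto", "asymptotic", "exact"),
                         p_adjust = "bonferroni", exact_n_max = 9L) {
  method <- match.arg(method)
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2L)) stop("every group needs n >= 2", call. = FALSE)
  N <- length(values)
  H <- kw_statistic(values, g)
  k <- nlevels(g)
  if (method == "auto") method <- if (N <= exact_n_max) "exact" else "asymptotic"
  if (method == "exact") {
    arr <- label_arrangements(as.integer(sizes))
    perm_H <- vapply(arr, function(a) {
      gl <- integer(N)
      for (i in seq_along(a)) gl[a[[i]]] <- i
      kw_statistic(values, factor(gl))
    }, 0)
    p <- mean(perm_H >= H - 1e-12)
  } else {
    p <- stats::pchisq(H, df = k - 1L, lower.tail = FALSE)
  }
  # Dunn pairwise z on mean ranks with tie correction
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    ni <- sizes[[pr[1]]]; nj <- sizes[[pr[2]]]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni + 1 / nj))
    z <- if (se > 0) (rbar[[pr[1]]] - rbar[[pr[2]]]) / se else 0
    data.frame(comparison = paste(pr[1], "-", pr[2]), z = z,
               p_raw = 2 * stats::pnorm(-abs(z)))
  }))
  pw$p_adjusted <- if (identical(p_adjust, "none")) pw$p_raw
  else stats::p.adjust(pw$p_raw, method = p_adjust)
  structure(list(test = "Kruskal-Wallis + Dunn", statistic = H, df = k - 1L,
                 p_value = p, method = method, pairwise = pw,
                 n = as.integer(N)),
            class = "group_test")
}

#' One-way ANOVA with Tukey's honestly-significant-difference post hoc test
#'
#' @param values numeric vector.
#' @param groups group labels (coerced to factor), each group `n >= 2`.
#' @return object of class `group_test` with the F statistic, omnibus p and a
#'   `pairwise` data.frame of Tukey comparisons (`estimate`, `p_adjusted`).
#' @export
anova_tukey <- function(values, groups) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("every group needs n >= 2", call. = FALSE)
  if (all(tapply(values, g, stats::var) == 0))
    stop("zero within-group variance in every group", call. = FALSE)
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pw <- data.frame(comparison = rownames(tk), estimate = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adjusted = tk[, "p adj"], row.names = NULL)
  structure(list(test = "one-way ANOVA + Tukey",
                 statistic = tab[["F value"]][1], df = tab[["Df"]][1:2],
                 p_value = tab[["Pr(>F)"]][1], method = "F",
                 pairwise = pw, n = length(values)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, digits = 4, ...) {
  cat(sprintf("%s (n = %d)\n", x$test, x$n))
  cat(sprintf("  omnibus statistic %.3f, p = %s (%s)\n", x$statistic,
              format.pval(x$p_value, digits = digits), x$method))
  cat("  pairwise:\n")
  print(x$pairwise, row.names = FALSE, digits = digits)
  invisible(x)
}
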