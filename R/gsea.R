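# Gene-set enrichment stage: weighted Kolmogorov-Smirnov enrichment score
# with phenotype-permutation NES and p-value, producing a per-set results
# table (set, n transcripts, ES, NES, p).

#' Rank genes by association with a binary phenotype
#'
#' Default metric is the signal-to-noise ratio, `(mean1 - mean0) / (sd1 +
#' sd0)`, computed class-wise per gene; `metric = "t"` uses Welch's
#' t-statistic instead. Class SDs are floored at `sd_floor` (with a warning
#' when the floor binds) so constant genes do not produce infinite scores.
#' Genes are ordered by decreasing metric; ties break by gene identifier so
#' the ordering is deterministic.
#'
#' @param matrix genes x samples numeric matrix with rownames.
#' @param phenotype binary labels (0/1 or two-level factor) per column.
#' @param metric `"s2n"` (signal-to-noise) or `"t"` (Welch t).
#' @param sd_floor minimum class SD.
#' @return object of class `ranked_expression` with `gene_order`,
#'   `metric_values` (named, in ranked order), `phenotype`, `metric`; the
#'   matrix is retained so phenotype permutations can re-rank.
#' @export
rank_by_phenotype <- function(matrix, phenotype, metric = c("s2n", "t"),
                              sd_floor = 1e-3) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            ncol(matrix) == length(phenotype))
  phen <- as.integer(as.factor(phenotype)) - 1L
  if (!all(phen %in% c(0L, 1L)) || length(unique(phen)) != 2L)
    stop("phenotype must have exactly two classes", call. = FALSE)
  if (min(table(phen)) < 3L)
    stop("each phenotype class needs >= 3 samples", call. = FALSE)
  mv <- ranking_metric(matrix, phen, metric, sd_floor, warn = TRUE)
  ord <- order(-mv, rownames(matrix))
  structure(list(gene_order = rownames(matrix)[ord],
                 metric_values = setNames(mv[ord], rownames(matrix)[ord]),
                 phenotype = phen, metric = metric, sd_floor = sd_floor,
                 matrix = matrix),
            class = "ranked_expression")
}

ranking_metric <- function(m, phen, metric, sd_floor, warn = FALSE) {
  i1 <- phen == 1L; i0 <- !i1
  m1 <- rowMeans(m[, i1, drop = FALSE]); m0 <- rowMeans(m[, i0, drop = FALSE])
  v1 <- rowSums((m[, i1, drop = FALSE] - m1)^2) / (sum(i1) - 1L)
  v0 <- rowSums((m[, i0, drop = FALSE] - m0)^2) / (sum(i0) - 1L)
  s1 <- sqrt(v1); s0 <- sqrt(v0)
  if (any(s1 < sd_floor) || any(s0 < sd_floor)) {
    if (warn) warning("class SD below floor for some genes; floored")
    s1 <- pmax(s1, sd_floor); s0 <- pmax(s0, sd_floor)
  }
  if (metric == "s2n") (m1 - m0) / (s1 + s0)
  else (m1 - m0) / sqrt(s1^2 / sum(phen == 1L) + s0^2 / sum(phen == 0L))
}

# Weighted KS running sum for hit positions `hit_idx` in a ranking of N
# genes with metric values `metric_sorted` (descending order). Hits increment
# proportionally to |metric|^weight_p (normalized to total 1; uniform if all
# weights vanish); every rank decrements uniformly by 1/N, so the sum starts
# and ends at zero and a single hit at rank 1 peaks at 1 - 1/N, the classical
# KS deviation against the uniform rank distribution.
running_sum <- function(metric_sorted, hit_idx, weight_p) {
  N <- length(metric_sorted)
  hit_w <- numeric(N)
  w <- abs(metric_sorted[hit_idx])^weight_p
  if (sum(w) <= 0) w <- rep(1, length(hit_idx))
  hit_w[hit_idx] <- w / sum(w)
  cumsum(hit_w) - seq_len(N) / N
}

es_value <- function(rs) rs[which.max(abs(rs))]

#' Enrichment score of a gene set in a ranked list
#'
#' Signed maximum deviation of the weighted Kolmogorov-Smirnov running sum:
#' walking down the ranking, hits increment proportionally to
#' `|metric|^weight_p` (normalized to sum 1) and every rank decrements
#' uniformly by `1/N`, so the sum starts and ends at zero and the ES is
#' bounded in `[-1, 1]`. With `weight_p = 0` this is the classical KS
#' deviation of the set's rank distribution from uniform (a single-gene set
#' at rank 1 scores `1 - 1/N`).
#'
#' @param ranked a `ranked_expression`.
#' @param gene_set character vector of genes; must be a nonempty proper
#'   subset of the ranked genes.
#' @param weight_p hit-weight exponent (default 1).
#' @return list with `es` and the `running` profile (length = genes).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_expression"), length(gene_set) >= 1L)
  hit_idx <- match(unique(gene_set), ranked$gene_order)
  if (anyNA(hit_idx))
    stop("gene set contains genes absent from the ranking", call. = FALSE)
  if (length(hit_idx) == length(ranked$gene_order))
    stop("gene set equals the whole ranking; running sum degenerate",
         call. = FALSE)
  rs <- running_sum(unname(ranked$metric_values), hit_idx, weight_p)
  list(es = es_value(rs), running = rs)
}

# Permuted rankings shared by all sets of one analysis: for each permutation,
# the descending order (as indices into rownames) and sorted metric values.
permuted_rankings <- function(matrix, phen, metric, sd_floor, n_permutations) {
  lapply(seq_len(n_permutations), function(i) {
    pp <- sample(phen)
    mv <- ranking_metric(matrix, pp, metric, sd_floor)
    ord <- order(-mv, rownames(matrix))
    list(order = rownames(matrix)[ord], metric = unname(mv[ord]))
  })
}

perm_es <- function(perms, gene_set, weight_p) {
  vapply(perms, function(p) {
    hit <- match(unique(gene_set), p$order)
    es_value(running_sum(p$metric, hit, weight_p))
  }, 0)
}

nes_p_from_perms <- function(es, pes, n_permutations) {
  if (es == 0) return(list(nes = 0, p = 1, floored = FALSE))
  same <- pes[sign(pes) == sign(es)]
  if (!length(same))
    return(list(nes = NA_real_, p = 1 / (n_permutations + 1), floored = TRUE))
  nes <- es / mean(abs(same))
  cnt <- sum(abs(same) >= abs(es))
  if (cnt == 0) list(nes = nes, p = 1 / (n_permutations + 1), floored = TRUE)
  else list(nes = nes, p = cnt / length(same), floored = FALSE)
}

#' Normalized enrichment score and permutation p-value
#'
#' Permutes the phenotype labels `n_permutations` times (preserving the
#' inter-gene correlation structure, unlike gene permutation), re-ranks and
#' recomputes the ES each time. NES is the observed ES divided by the mean
#' |permuted ES| of matching sign; the p-value is the fraction of
#' matching-sign permuted ES at least as extreme, floored at
#' `1 / (n_permutations + 1)` so it is never exactly zero (the `p_floored`
#' flag records when the floor binds, including the degenerate case of no
#' matching-sign permutation).
#'
#' @param ranked a `ranked_expression`.
#' @param gene_set character vector of genes.
#' @param n_permutations number of label permutations (>= 10).
#' @param seed integer seed; results are deterministic given the seed.
#' @param weight_p hit-weight exponent.
#' @param set_name label for the output row.
#' @return data.frame row: `set_name`, `n_transcripts`, `es`, `nes`,
#'   `p_value`, `p_floored`.
#' @export
nes_and_p <- function(ranked, gene_set, n_permutations = 100L, seed,
                      weight_p = 1, set_name = "gene_set") {
  stopifnot(inherits(ranked, "ranked_expression"), n_permutations >= 10L)
  es <- enrichment_score(ranked, gene_set, weight_p)$es
  with_seed(seed, {
    perms <- permuted_rankings(ranked$matrix, ranked$phenotype, ranked$metric,
                               ranked$sd_floor, n_permutations)
    pes <- perm_es(perms, gene_set, weight_p)
    np <- nes_p_from_perms(es, pes, n_permutations)
    data.frame(set_name = set_name,
               n_transcripts = length(unique(gene_set)),
               es = es, nes = np$nes, p_value = np$p, p_floored = np$floored)
  })
}

#' Enrichment table for a collection of gene sets plus a pooled row
#'
#' Ranks the matrix once, draws one shared block of phenotype permutations
#' (so per-set results are invariant to the order sets are supplied), scores
#' every set and a pooled union-of-all-sets row, and returns the results in
#' the standard table shape: set, number of transcripts, ES, NES, p.
#' Overlapping sets are deduplicated in the pooled row with a warning.
#'
#' @param matrix genes x samples expression matrix with rownames.
#' @param phenotype binary labels per column.
#' @param gene_sets named list of gene sets.
#' @param n_permutations label permutations (default 100).
#' @param seed integer seed.
#' @param weight_p hit-weight exponent.
#' @param metric ranking metric, see [rank_by_phenotype()].
#' @param pooled_name row name of the pooled set.
#' @return data.frame with one row per set plus the pooled row.
#' @export
run_table <- function(matrix, phenotype, gene_sets, n_permutations = 100L,
                      seed, weight_p = 1, metric = "s2n",
                      pooled_name = "all sets (pooled)") {
  if (!length(gene_sets))
    return(data.frame(set_name = character(), n_transcripts = integer(),
                      es = numeric(), nes = numeric(), p_value = numeric(),
                      p_floored = logical()))
  ranked <- rank_by_phenotype(matrix, phenotype, metric = metric)
  all_members <- unlist(gene_sets, use.names = FALSE)
  pooled <- unique(all_members)
  if (length(pooled) < length(all_members))
    warning("gene sets overlap; pooled row deduplicated")
  sets <- c(gene_sets, setNames(list(pooled), pooled_name))
  with_seed(seed, {
    perms <- permuted_rankings(ranked$matrix, ranked$phenotype, ranked$metric,
                               ranked$sd_floor, n_permutations)
    do.call(rbind, lapply(names(sets), function(nm) {
      gs <- unique(sets[[nm]])
      es <- enrichment_score(ranked, gs, weight_p)$es
      np <- nes_p_from_perms(es, perm_es(perms, gs, weight_p), n_permutations)
      data.frame(set_name = nm, n_transcripts = length(gs), es = es,
                 nes = np$nes, p_value = np$p, p_floored = np$floored)
    }))
  })
}
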