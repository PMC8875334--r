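#' Generate a synthetic expression matrix with an implanted gene-set effect
#'
#' Null genes are i.i.d. standard normal across all samples. Genes belonging
#' to the implanted set are shifted by `implanted_effect` (in units of the
#' within-group SD, which is 1 by construction) in phenotype class 1. With
#' `implanted_effect = 0` the matrix is exchangeable across phenotype labels,
#' which is what the permutation null of the enrichment stage assumes.
#'
#' @param n_genes total number of genes (rows).
#' @param n_samples_per_class samples per phenotype class (columns are
#'   class 0 then class 1).
#' @param gene_sets named list of character vectors of gene identifiers; all
#'   members must exist among the generated gene names `g0001, g0002, ...`
#'   (or among `rownames` supplied via `gene_names`).
#' @param implanted_set name of the set receiving the shift (`NULL` for none).
#' @param implanted_effect shift in within-group SD units applied to the
#'   implanted set in class 1.
#' @param allow_overlap if `FALSE` (default) overlapping gene sets are an
#'   error, making set effects unambiguous.
#' @param gene_names optional explicit gene identifiers.
#' @param seed integer seed.
#' @return object of class `expression_phantom` with fields `matrix`
#'   (genes x samples), `phenotype` (0/1 per sample), `gene_sets`,
#'   `implanted_set`, `implanted_effect`, `seed`.
#' @export
generate_expression <- function(n_genes = 1000L, n_samples_per_class = 20L,
                                gene_sets = list(), implanted_set = NULL,
                                implanted_effect = 0, allow_overlap = FALSE,
                                gene_names = NULL, seed) {
  stopifnot(n_genes >= 1L, n_samples_per_class >= 1L)
  if (is.null(gene_names))
    gene_names <- sprintf("g%04d", seq_len(n_genes))
  stopifnot(length(gene_names) == n_genes)
  for (nm in names(gene_sets)) {
    unknown <- setdiff(gene_sets[[nm]], gene_names)
    if (length(unknown))
      stop(sprintf("gene set '%s' references unknown genes: %s", nm,
                   paste(head(unknown, 3), collapse = ", ")), call. = FALSE)
  }
  if (!allow_overlap && length(gene_sets) > 1L) {
    all_members <- unlist(gene_sets)
    if (anyDuplicated(all_members))
      stop("gene sets overlap; pass allow_overlap = TRUE to permit this",
           call. = FALSE)
  }
  if (!is.null(implanted_set) && !implanted_set %in% names(gene_sets))
    stop("implanted_set is not among the supplied gene sets", call. = FALSE)

  n_s <- 2L * n_samples_per_class
  with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_s), n_genes, n_s,
                dimnames = list(gene_names,
                                sprintf("s%03d", seq_len(n_s))))
    phen <- rep(c(0L, 1L), each = n_samples_per_class)
    if (!is.null(implanted_set) && implanted_effect != 0) {
      idx <- match(gene_sets[[implanted_set]], gene_names)
      m[idx, phen == 1L] <- m[idx, phen == 1L] + implanted_effect
    }
    structure(list(matrix = m, phenotype = phen, gene_sets = gene_sets,
                   implanted_set = implanted_set,
                   implanted_effect = implanted_effect, seed = seed),
              class = "expression_phantom")
  })
}

#' Five synthetic NRF2 functional gene sets
#'
#' Disjoint placeholder sets named after the five NRF2 functional categories,
#' with the published per-set transcript counts (18, 48, 43, 4 and 5; 118
#' pooled). Membership is synthetic: real set contents are configuration to
#' be supplied by the user, e.g. via [read_gmt()].
#'
#' @param gene_names pool of gene identifiers to draw members from.
#' @param seed integer seed for the draw.
#' @return named list of five character vectors.
#' @export
synthetic_nrf2_sets <- function(gene_names, seed = 1L) {
  sizes <- c("antioxidant proteins" = 18L,
             "phase I and II metabolizing enzymes" = 48L,
             "chaperone and stress response proteins" = 43L,
             "phase III detoxifying proteins" = 4L,
             "ubiquitination and proteasomal degradation" = 5L)
  stopifnot(length(gene_names) >= sum(sizes))
  with_seed(seed, {
    pool <- sample(gene_names, sum(sizes))
    out <- vector("list", length(sizes)); names(out) <- names(sizes)
    at <- 0L
    for (i in seq_along(sizes)) {
      out[[i]] <- pool[at + seq_len(sizes[i])]
      at <- at + sizes[i]
    }
    out
  })
}

#' Read gene sets in GMT format
#'
#' One set per line: `name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(ln, 1, 40),
                             call. = FALSE)
    out[[f[1]]] <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
  }
  out
}

#' Write gene sets in GMT format
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description column.
#' @export
write_gmt <- function(gene_sets, path, description = "synthetic") {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
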