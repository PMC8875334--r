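# Delimited outputs with a provenance header: every table the pipeline
# emits records the parameters that produced it as leading comment lines
# ("# key: value"), so a result file is self-describing.

write_with_header <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(provenance[[nm]]), collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_skip_header <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a patch grid as a delimited table with provenance header
#' @param grid a `patch_grid`.
#' @param path output path (tab-separated; `#`-prefixed provenance lines).
#' @export
write_patch_table <- function(grid, path) {
  stopifnot(inherits(grid, "patch_grid"))
  write_with_header(grid$patches, path,
                    list(patch_size_px = grid$patch_size,
                         scan_shape = grid$shape,
                         band_rule = "0=maternal; (0,0.5]=low; (0.5,1]=high"))
}

#' Write band intensity summaries (one row per subject x marker)
#' @param summaries a `band_intensity_summary` or a list of them.
#' @param path output path (tab-separated; `#`-prefixed provenance lines).
#' @param provenance optional named list of extra parameters to record.
#' @export
write_band_summaries <- function(summaries, path, provenance = list()) {
  if (inherits(summaries, "band_intensity_summary"))
    summaries <- list(summaries)
  df <- do.call(rbind, lapply(summaries, as.data.frame))
  write_with_header(df, path, c(
    list(gray_convention = "0=black=max staining; 255=white=none",
         luma_weights = LUMA_WEIGHTS), provenance))
}

#' Write a fitted model's results as a tidy delimited table
#'
#' Emits the fixed effects, estimated means and pairwise contrasts of an
#' `ihc_model` stacked into one tidy table (`section` column distinguishes
#' them); the printed form of the object is the human-readable report.
#' @param x an `ihc_model`.
#' @param path output path.
#' @export
write_model_result <- function(x, path) {
  stopifnot(inherits(x, "ihc_model"))
  as_chunk <- function(df, section) {
    if (!nrow(df)) return(NULL)
    cbind(data.frame(section = rep(section, nrow(df))), df)
  }
  chunks <- list(as_chunk(x$fixed_effects, "fixed_effect"),
                 as_chunk(x$estimated_means, "estimated_mean"),
                 as_chunk(x$pairwise, "pairwise"))
  chunks <- Filter(Negate(is.null), chunks)
  all_cols <- unique(unlist(lapply(chunks, names)))
  chunks <- lapply(chunks, function(ch) {
    for (nm in setdiff(all_cols, names(ch))) ch[[nm]] <- NA
    ch[all_cols]
  })
  write_with_header(do.call(rbind, chunks), path,
                    list(model = x$kind, n_used = x$n_used))
}

#' Write an enrichment results table
#' @param tab data.frame from [run_table()].
#' @param path output path.
#' @param provenance optional named list (e.g. permutation count, seed).
#' @export
write_enrichment_table <- function(tab, path, provenance = list()) {
  write_with_header(tab, path, provenance)
}
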