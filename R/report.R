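# Report writing: per-gene rates table, selection-test table, association
# JSON.  Numeric columns are written with 17 significant digits so a re-read
# reproduces the doubles exactly.

fmt_num_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), NA_character_,
                        sprintf("%.17g", df[[j]]))
    }
  }
  df
}

#' Write the analysis report bundle
#'
#' Produces three files in `dir`:
#' \describe{
#'   \item{per_gene.tsv}{one row per gene: `gene_id`, `omega`, `dN`, `dS`,
#'     `tree_length`, `degree`, `closeness`, `betweenness`, `component`,
#'     `cell_type`, `process`, `fun`, `protein_length`.  Genes outside the
#'     network have empty centrality fields.}
#'   \item{selection_tests.tsv}{one row per test: `gene_id`, `test`,
#'     `branch`, `lnL_alt`, `lnL_null`, `statistic`, `df`, `p_raw`,
#'     `p_adjusted`.}
#'   \item{associations.json}{the Spearman/Kruskal-Wallis/neighbor battery
#'     with metadata.}
#' }
#'
#' @param results List with `per_gene` (data frame), `selection_tests`
#'   (data frame or NULL) and `associations` (`association_report` or NULL).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  paths <- character(0)
  pg <- file.path(dir, "per_gene.tsv")
  utils::write.table(fmt_num_cols(results$per_gene), pg, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  paths <- c(paths, pg)
  if (!is.null(results$selection_tests)) {
    st <- file.path(dir, "selection_tests.tsv")
    utils::write.table(fmt_num_cols(results$selection_tests), st, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    paths <- c(paths, st)
  }
  if (!is.null(results$associations)) {
    aj <- file.path(dir, "associations.json")
    a <- results$associations
    payload <- list(
      metadata = list(
        n_genes = nrow(results$per_gene),
        note = "association p-values are reported uncorrected"),
      spearman = a$spearman_results,
      kruskal_wallis = a$kruskal_results,
      neighbor = a$neighbor_results)
    jsonlite::write_json(payload, aj, auto_unbox = TRUE, digits = NA,
                         na = "null")
    paths <- c(paths, aj)
  }
  if (!is.null(results$site_posteriors)) {
    sp <- file.path(dir, "site_posteriors.tsv")
    utils::write.table(fmt_num_cols(results$site_posteriors), sp, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    paths <- c(paths, sp)
  }
  invisible(paths)
}


#' Read back a per-gene or selection-test TSV
#'
#' @param path File written by [write_report()].
#' @return Data frame with numeric columns restored.
#' @export
read_report_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "", stringsAsFactors = FALSE)
}
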