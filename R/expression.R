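#' Transcripts per kilobase million (TPM)
#'
#' `rate_g = count_g / (length_g / 1000)`; `tpm_g = 1e6 * rate_g / sum(rate)`.
#' TPM sums to one million over the genes of a sample by construction.
#'
#' @param counts Named non-negative count vector.
#' @param lengths Named positive gene lengths (bp), covering every gene in
#'   `counts`.
#' @return Named TPM vector; all-`NA` when the total rate is zero.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  lengths <- lengths[names(counts)]
  if (anyNA(lengths) || any(lengths <= 0)) {
    stop("every gene needs a positive length")
  }
  rate <- counts / (lengths / 1000)
  tot <- sum(rate)
  if (tot == 0) {
    return(stats::setNames(rep(NA_real_, length(counts)), names(counts)))
  }
  1e6 * rate / tot
}

#' Flag differentially expressed genes
#'
#' A gene is `up` when `log2fc > lfc_min` and `padj < padj_max`, `down` when
#' `log2fc < -lfc_min` and `padj < padj_max`, otherwise `ns`. All
#' inequalities are strict (defaults: |log2FC| > 1, FDR < 0.05). Records with
#' missing `padj` are flagged `ns` and counted in the `n_missing_padj`
#' attribute, with a warning.
#'
#' @param records `data.frame` with columns `log2fc` and `padj`.
#' @param lfc_min Absolute log2 fold-change threshold (exclusive).
#' @param padj_max Adjusted p-value threshold (exclusive).
#' @return `records` with a `deg` column added (values `up`/`down`/`ns`).
#' @export
flag_degs <- function(records, lfc_min = 1, padj_max = 0.05) {
  stopifnot(all(c("log2fc", "padj") %in% names(records)))
  miss <- is.na(records$padj)
  if (any(miss)) {
    warning(sum(miss), " record(s) lack padj; flagged ns")
  }
  deg <- rep("ns", nrow(records))
  ok <- !miss & records$padj < padj_max
  deg[ok & records$log2fc > lfc_min] <- "up"
  deg[ok & records$log2fc < -lfc_min] <- "down"
  records$deg <- deg
  attr(records, "n_missing_padj") <- sum(miss)
  records
}

#' Summarize expression by gene category
#'
#' For each category, reports the gene count, the up-regulated count and its
#' percentage, the number of genes in the genome-wide top expression decile
#' per condition, and the fold ratio between the top- and second-ranked gene
#' of the category per condition. The top decile is defined over a
#' genome-wide TPM table (`ceiling(0.1 * N)` highest genes, TPM ties broken
#' by gene id); when no genome-wide table is available the decile membership
#' is reported as `NA` rather than approximated from the summary rows alone.
#'
#' @param records `data.frame` with `gene_id`, `category`, a `deg` column
#'   (see [flag_degs()]) and one TPM column per condition.
#' @param tpm_cols Named character vector mapping condition names to TPM
#'   column names, e.g. `c(mucin = "tpm_mucin", glucose = "tpm_glucose")`.
#' @param genome_tpm Optional genome-wide `data.frame` with `gene_id` plus
#'   the same TPM columns, defining the decile cutoffs.
#' @return A list of class `expression_summary` with elements `categories`
#'   (per-category counts data.frame) and `fold_ratios` (per category and
#'   condition: top gene, second gene, ratio).
#' @export
summarize_expression <- function(records, tpm_cols, genome_tpm = NULL) {
  stopifnot(all(c("gene_id", "category", "deg") %in% names(records)),
            all(tpm_cols %in% names(records)))
  top_sets <- NULL
  if (!is.null(genome_tpm)) {
    stopifnot("gene_id" %in% names(genome_tpm),
              all(tpm_cols %in% names(genome_tpm)))
    k <- ceiling(0.1 * nrow(genome_tpm))
    top_sets <- lapply(tpm_cols, function(col) {
      ord <- order(-genome_tpm[[col]], genome_tpm$gene_id)
      genome_tpm$gene_id[ord[seq_len(k)]]
    })
  }
  cats <- split(records, records$category)
  cat_rows <- lapply(cats, function(d) {
    row <- data.frame(category = d$category[1], n = nrow(d),
                      n_up = sum(d$deg == "up"),
                      pct_up = 100 * sum(d$deg == "up") / nrow(d),
                      stringsAsFactors = FALSE)
    for (cond in names(tpm_cols)) {
      row[[paste0("n_top_decile_", cond)]] <- if (is.null(top_sets)) {
        NA_integer_
      } else {
        sum(d$gene_id %in% top_sets[[cond]])
      }
    }
    row
  })
  fr_rows <- list()
  for (cn in names(cats)) {
    d <- cats[[cn]]
    for (cond in names(tpm_cols)) {
      v <- d[[tpm_cols[[cond]]]]
      ord <- order(-v, d$gene_id)
      if (nrow(d) >= 2L && v[ord[2]] > 0) {
        fr_rows[[length(fr_rows) + 1L]] <- data.frame(
          category = cn, condition = cond,
          top_gene = d$gene_id[ord[1]], second_gene = d$gene_id[ord[2]],
          top_tpm = v[ord[1]], second_tpm = v[ord[2]],
          ratio = v[ord[1]] / v[ord[2]], stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    categories = do.call(rbind, c(cat_rows, list(make.row.names = FALSE))),
    fold_ratios = if (length(fr_rows)) {
      do.call(rbind, c(fr_rows, list(make.row.names = FALSE)))
    } else NULL
  ), class = "expression_summary")
}

#' @export
print.expression_summary <- function(x, ...) {
  cat("Expression summary by category:\n")
  print(x$categories, row.names = FALSE)
  if (!is.null(x$fold_ratios)) {
    cat("\nTop-vs-second fold ratios:\n")
    print(x$fold_ratios, row.names = FALSE)
  }
  invisible(x)
}

#' ET540 mucin-vs-glucose expression of mucinolysome-related genes
#'
#' Published expression summary statistics for the *Limousia pullorum* ET540
#' genes encoding mucinolysome components (scaffoldins, dockerin-bearing
#' CAZymes and peptidases) and the non-mucinolysome mucin-degrading CAZymes,
#' from growth on mucin versus glucose: per-condition TPM, log2 fold change
#' (mucin over glucose) and FDR-adjusted p-value. Gene categories:
#' `mucinolysome` (scaffoldins and dockerin-bearing CAZymes, 26 genes),
#' `mucinolysome_peptidase` (standalone dockerin-bearing peptidases, 5),
#' `non_mucinolysome_mucin_cazyme` (10).
#'
#' @return `data.frame` with columns `gene_id`, `gene_name`, `category`,
#'   `tpm_mucin`, `tpm_glucose`, `log2fc`, `padj`.
#' @export
et540_expression <- function() {
  path <- system.file("extdata", "et540_mucinolysome_expression.tsv",
                      package = "mucikit")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$category <- ifelse(
    tab$mucinolysome == "No", "non_mucinolysome_mucin_cazyme",
    ifelse(grepl("^cP[0-9]+$", tab$gene_name),
           "mucinolysome_peptidase", "mucinolysome"))
  tab$mucinolysome <- NULL
  tab
}
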