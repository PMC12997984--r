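#' Read per-domain hits from a HMMER3 domain table
#'
#' Parses the whitespace-delimited per-domain tabular output of `hmmsearch
#' --domtblout` (profile HMMs searched against a protein database). One row is
#' returned per domain record. The per-domain independent E-value (`i-Evalue`)
#' is used as the hit E-value, the convention for domain-level filtering.
#'
#' @param path Path to a domtblout file. Lines starting with `#` are ignored.
#' @param source_db Database label attached to every hit, one of
#'   `"pfam"`, `"cazyme"`, `"peptidase"`, `"sulfatase"`.
#' @return A `data.frame` of class `domain_hits` with columns `protein_id`,
#'   `model_name`, `source_db`, `e_value`, `ali_from`, `ali_to`, `hmm_from`,
#'   `hmm_to`, `hmm_length` and `protein_length`.
#' @seealso [filter_hits()], [resolve_overlaps()], [write_domtblout()]
#' @export
parse_domtblout <- function(path, source_db = "pfam") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_hits())
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(f) < 22L) {
      stop("malformed domtblout record at data line ", i,
           ": expected >= 22 fields, got ", length(f))
    }
    num <- suppressWarnings(as.numeric(f[c(3, 6, 13, 16, 17, 18, 19)]))
    if (anyNA(num)) {
      stop("malformed domtblout record at data line ", i,
           ": non-numeric coordinate or E-value field")
    }
    data.frame(
      protein_id = f[1], model_name = f[4],
      e_value = num[3],
      ali_from = as.integer(num[6]), ali_to = as.integer(num[7]),
      hmm_from = as.integer(num[4]), hmm_to = as.integer(num[5]),
      hmm_length = as.integer(num[2]), protein_length = as.integer(num[1]),
      stringsAsFactors = FALSE
    )
  })
  hits <- do.call(rbind, rows)
  hits$source_db <- source_db
  as_domain_hits(hits)
}

#' Write hits as a HMMER3-style domain table
#'
#' Emits the 23-column per-domain tabular dialect accepted by
#' [parse_domtblout()]. Only the columns the parser consumes carry real
#' values; score and envelope columns are filled with placeholders.
#'
#' @param hits A `domain_hits` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  hits <- as_domain_hits(hits)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# generated by mucikit", con)
  if (nrow(hits)) {
    plen <- if ("protein_length" %in% names(hits) && !anyNA(hits$protein_length)) {
      hits$protein_length
    } else {
      hits$ali_to
    }
    # i-Evalue (field 13) is printed at full double precision so written
    # tables parse back to exactly the hits they came from
    lines <- sprintf(
      "%s - %d %s - %d %.3g 0.0 0.0 1 1 %.3g %.17g 0.0 0.0 %d %d %d %d %d %d 0.90 -",
      hits$protein_id, plen, hits$model_name, hits$hmm_length,
      hits$e_value, hits$e_value, hits$e_value,
      hits$hmm_from, hits$hmm_to, hits$ali_from, hits$ali_to,
      hits$ali_from, hits$ali_to
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read domain hits from a plain tab-separated table
#'
#' Reads dbCAN-style CAZyme calls and generic peptidase/sulfatase hit tables.
#' Required columns: `protein_id`, `model_name`, `e_value`, `ali_from`,
#' `ali_to`. `hmm_from`, `hmm_to`, `hmm_length` are optional; when absent the
#' model span is taken as fully aligned so that no HMM-coverage filter can
#' reject the hit.
#'
#' @param path Path to a TSV file with a header row.
#' @param source_db Database label, one of `"cazyme"`, `"peptidase"`,
#'   `"sulfatase"`, `"pfam"`.
#' @return A `domain_hits` data.frame.
#' @export
read_hits_tsv <- function(path, source_db) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "model_name", "e_value", "ali_from", "ali_to")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("hit table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!"hmm_length" %in% names(tab)) tab$hmm_length <- 1L
  if (!"hmm_from" %in% names(tab)) tab$hmm_from <- 1L
  if (!"hmm_to" %in% names(tab)) tab$hmm_to <- tab$hmm_length
  tab$source_db <- source_db
  if (!"protein_length" %in% names(tab)) tab$protein_length <- NA_integer_
  as_domain_hits(tab)
}

#' Read per-protein signal-peptide flags
#'
#' Signal peptides are consumed as a precomputed column (the output of an
#' external predictor), never predicted internally.
#'
#' @param path TSV with header columns `protein_id` and `signal_peptide`
#'   (logical, 0/1, or Y/N).
#' @return Named logical vector keyed by protein id.
#' @export
read_signalp_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "signal_peptide") %in% names(tab))) {
    stop("signal-peptide table needs columns protein_id, signal_peptide")
  }
  v <- tab$signal_peptide
  flag <- if (is.logical(v)) v else toupper(as.character(v)) %in% c("1", "Y", "YES", "TRUE")
  stats::setNames(flag, tab$protein_id)
}

empty_hits <- function() {
  as_domain_hits(data.frame(
    protein_id = character(), model_name = character(),
    source_db = character(), e_value = numeric(),
    ali_from = integer(), ali_to = integer(),
    hmm_from = integer(), hmm_to = integer(), hmm_length = integer(),
    protein_length = integer(), stringsAsFactors = FALSE
  ))
}

as_domain_hits <- function(x) {
  cols <- c("protein_id", "model_name", "source_db", "e_value",
            "ali_from", "ali_to", "hmm_from", "hmm_to", "hmm_length")
  stopifnot(is.data.frame(x), all(cols %in% names(x)))
  if (!"protein_length" %in% names(x)) x$protein_length <- NA_integer_
  x <- x[, c(cols, "protein_length")]
  if (nrow(x)) {
    bad <- x$e_value <= 0 | x$ali_from > x$ali_to | x$hmm_from > x$hmm_to |
      x$hmm_to > x$hmm_length
    if (any(bad)) {
      stop("invalid hit record(s) at row(s): ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    }
  }
  rownames(x) <- NULL
  class(x) <- c("domain_hits", "data.frame")
  x
}
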