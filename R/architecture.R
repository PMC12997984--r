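#' HMM-side coverage of domain hits
#'
#' Coverage is the fraction of the profile HMM spanned by the alignment,
#' `(hmm_to - hmm_from + 1) / hmm_length` — the convention used by
#' dbCAN-style filtering.
#'
#' @param hits A `domain_hits` data.frame.
#' @return Numeric vector of coverages in `[0, 1]`.
#' @export
hit_coverage <- function(hits) {
  if (nrow(hits) == 0L) return(numeric())
  (hits$hmm_to - hits$hmm_from + 1) / hits$hmm_length
}

#' Filter domain hits by E-value and HMM coverage
#'
#' Keeps exactly the hits with `e_value < e_max` and coverage `> cov_min`
#' (both strict, matching the screen's "E-value <1e-4 and coverage >60%"
#' rule for cohesin/dockerin profiles). Input order is preserved.
#'
#' @param hits A `domain_hits` data.frame.
#' @param e_max Maximum E-value (exclusive); must be positive.
#' @param cov_min Minimum HMM coverage (exclusive), in `[0, 1]`.
#' @return The retained rows, same class.
#' @export
filter_hits <- function(hits, e_max = 1e-4, cov_min = 0.6) {
  stopifnot(e_max > 0, cov_min >= 0, cov_min <= 1)
  if (nrow(hits) == 0L) return(hits)
  keep <- hits$e_value < e_max & hit_coverage(hits) > cov_min
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping domain hits on one protein
#'
#' Greedy acceptance by ascending E-value: a candidate is rejected when it
#' overlaps an already-accepted hit by more than 50% of the shorter hit's
#' aligned length. Ties are broken deterministically by
#' `(e_value, ali_from, model_name)`.
#'
#' @param hits A `domain_hits` data.frame, all rows on one protein.
#' @param max_overlap Overlap tolerance as a fraction of the shorter hit
#'   (default 0.5; rejection requires strictly more overlap than this).
#' @return Accepted hits sorted by `ali_from`.
#' @export
resolve_overlaps <- function(hits, max_overlap = 0.5) {
  if (nrow(hits) == 0L) return(hits)
  if (length(unique(hits$protein_id)) != 1L) {
    stop("resolve_overlaps expects hits on a single protein")
  }
  ord <- order(hits$e_value, hits$ali_from, hits$model_name)
  cand <- hits[ord, , drop = FALSE]
  acc <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in which(acc)) {
      ov <- min(cand$ali_to[i], cand$ali_to[j]) -
        max(cand$ali_from[i], cand$ali_from[j]) + 1L
      if (ov > 0L) {
        shorter <- min(cand$ali_to[i] - cand$ali_from[i] + 1L,
                       cand$ali_to[j] - cand$ali_from[j] + 1L)
        if (ov > max_overlap * shorter) {
          ok <- FALSE
          break
        }
      }
    }
    acc[i] <- ok
  }
  out <- cand[acc, , drop = FALSE]
  out <- out[order(out$ali_from, out$e_value, out$model_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_cazyme_hit <- function(hits) hits$source_db == "cazyme"
is_peptidase_hit <- function(hits) hits$source_db == "peptidase"
is_cohesin_hit <- function(hits) {
  hits$source_db == "pfam" & grepl("^cohesin$", hits$model_name, ignore.case = TRUE)
}
is_dockerin_hit <- function(hits) {
  hits$source_db == "pfam" & grepl("^dockerin$", hits$model_name, ignore.case = TRUE)
}

#' Classify a protein from its accepted domain content
#'
#' The functional classes mirror how cellulosome-like systems are annotated:
#' * `scaffoldin` — at least one cohesin and no catalytic (CAZyme or
#'   peptidase) domain; the structural backbone of the complex.
#' * `coh_enzyme` — cohesin plus a catalytic domain (the architecture seen in
#'   *C. perfringens*-type systems); takes precedence over dockerin classes.
#' * `doc_cazyme` — dockerin plus at least one CAZyme domain; a protein also
#'   carrying a peptidase domain keeps this class with `dual_role = TRUE`.
#' * `doc_peptidase` — dockerin plus peptidase, no CAZyme.
#' * `doc_other` — dockerin only.
#' * `other` — none of the above.
#'
#' @param domains Accepted `domain_hits` for one protein (post-filter,
#'   post-overlap-resolution).
#' @return A list with `protein_class`, `n_coh`, `n_doc`, `dual_role`.
#' @export
classify_protein <- function(domains) {
  n_coh <- sum(is_cohesin_hit(domains))
  n_doc <- sum(is_dockerin_hit(domains))
  n_caz <- sum(is_cazyme_hit(domains))
  n_pep <- sum(is_peptidase_hit(domains))
  cls <- if (n_coh >= 1L && n_caz == 0L && n_pep == 0L) {
    "scaffoldin"
  } else if (n_coh >= 1L) {
    "coh_enzyme"
  } else if (n_doc >= 1L && n_caz >= 1L) {
    "doc_cazyme"
  } else if (n_doc >= 1L && n_pep >= 1L) {
    "doc_peptidase"
  } else if (n_doc >= 1L) {
    "doc_other"
  } else {
    "other"
  }
  list(protein_class = cls, n_coh = n_coh, n_doc = n_doc,
       dual_role = cls == "doc_cazyme" && n_pep >= 1L)
}

#' Assemble per-protein domain architectures
#'
#' Applies per-database hit filters (E-value for all; HMM coverage for the
#' Pfam cohesin/dockerin profiles), resolves overlapping hits per protein,
#' and classifies every protein. Proteins present in `protein_lengths` but
#' without accepted domains are reported with class `other`.
#'
#' @param hits A `domain_hits` data.frame pooling all source databases.
#' @param protein_lengths Named integer vector of protein lengths (aa).
#' @param signal_peptide Named logical vector of signal-peptide flags;
#'   missing proteins default to `FALSE`.
#' @param e_max,cov_min Thresholds for Pfam cohesin/dockerin hits.
#' @param cazy_e_max,cazy_cov_min Thresholds for CAZyme hits.
#' @param pept_e_max E-value threshold for peptidase hits.
#' @param sulf_e_max E-value threshold for sulfatase hits.
#' @return A `data.frame` of class `protein_architectures`, one row per
#'   protein: `protein_id`, `length`, `protein_class`, `n_coh`, `n_doc`,
#'   `domain_string` (e.g. `"Doc+GH33"`), `has_signal_peptide`, `dual_role`.
#'   The accepted per-protein hits are attached as attribute `"domains"`
#'   (a list keyed by protein id, each sorted by `ali_from`).
#' @export
build_architectures <- function(hits, protein_lengths,
                                signal_peptide = NULL,
                                e_max = 1e-4, cov_min = 0.6,
                                cazy_e_max = 1e-15, cazy_cov_min = 0.35,
                                pept_e_max = 1e-10, sulf_e_max = 1e-3) {
  stopifnot(!is.null(names(protein_lengths)))
  kept <- rbind(
    filter_hits(hits[hits$source_db == "pfam", , drop = FALSE], e_max, cov_min),
    filter_hits(hits[hits$source_db == "cazyme", , drop = FALSE],
                cazy_e_max, cazy_cov_min),
    filter_hits(hits[hits$source_db == "peptidase", , drop = FALSE],
                pept_e_max, 0),
    filter_hits(hits[hits$source_db == "sulfatase", , drop = FALSE],
                sulf_e_max, 0)
  )
  ids <- names(protein_lengths)
  dom_list <- stats::setNames(vector("list", length(ids)), ids)
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    pid <- ids[k]
    ph <- kept[kept$protein_id == pid, , drop = FALSE]
    if (nrow(ph) && any(ph$ali_to > protein_lengths[[pid]], na.rm = TRUE)) {
      stop("hit extends past protein length for ", pid)
    }
    ph <- resolve_overlaps(ph)
    dom_list[[pid]] <- ph
    cl <- classify_protein(ph)
    rows[[k]] <- data.frame(
      protein_id = pid,
      length = as.integer(protein_lengths[[pid]]),
      protein_class = cl$protein_class,
      n_coh = cl$n_coh, n_doc = cl$n_doc,
      domain_string = domain_string(ph),
      has_signal_peptide = isTRUE(unname(signal_peptide[pid])),
      dual_role = cl$dual_role,
      stringsAsFactors = FALSE
    )
  }
  arch <- do.call(rbind, rows)
  rownames(arch) <- NULL
  attr(arch, "domains") <- dom_list
  class(arch) <- c("protein_architectures", "data.frame")
  arch
}

domain_string <- function(domains) {
  if (nrow(domains) == 0L) return("")
  lab <- domains$model_name
  lab[is_cohesin_hit(domains)] <- "Coh"
  lab[is_dockerin_hit(domains)] <- "Doc"
  paste(lab, collapse = "+")
}

#' Extract padded cohesin/dockerin regions for structure prediction
#'
#' Each accepted cohesin or dockerin domain is extended by `pad` residues on
#' both sides, clamped to the protein bounds, and the corresponding sequence
#' is sliced from the protein FASTA. These regions are the unit submitted to
#' complex-structure prediction.
#'
#' @param arch A `protein_architectures` object.
#' @param fasta An [Biostrings::AAStringSet] (or named character vector) of
#'   protein sequences.
#' @param pad Extension in residues on each side (default 10).
#' @return A `data.frame` with `region_id`, `protein_id`, `module`
#'   (`"cohesin"`/`"dockerin"`), `start`, `end`, `sequence`.
#' @export
extract_domain_regions <- function(arch, fasta, pad = 10L) {
  stopifnot(pad >= 0)
  seqs <- if (methods::is(fasta, "XStringSet")) {
    # XStringSet from Biostrings::readAAStringSet
    stats::setNames(as.character(fasta), names(fasta))
  } else {
    fasta
  }
  doms <- attr(arch, "domains")
  out <- list()
  for (pid in names(doms)) {
    d <- doms[[pid]]
    if (nrow(d) == 0L) next
    cohdoc <- d[is_cohesin_hit(d) | is_dockerin_hit(d), , drop = FALSE]
    if (nrow(cohdoc) == 0L) next
    if (!pid %in% names(seqs)) {
      stop("protein ", pid, " absent from the supplied FASTA")
    }
    len <- arch$length[match(pid, arch$protein_id)]
    s <- seqs[[pid]]
    for (i in seq_len(nrow(cohdoc))) {
      start <- max(1L, cohdoc$ali_from[i] - as.integer(pad))
      end <- min(len, cohdoc$ali_to[i] + as.integer(pad))
      module <- if (is_cohesin_hit(cohdoc)[i]) "cohesin" else "dockerin"
      out[[length(out) + 1L]] <- data.frame(
        region_id = sprintf("%s_%s_%d_%d", pid, module, start, end),
        protein_id = pid, module = module,
        start = start, end = end,
        sequence = substr(s, start, end),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(region_id = character(), protein_id = character(),
                      module = character(), start = integer(), end = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write extracted regions as FASTA
#'
#' @param regions Output of [extract_domain_regions()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_regions_fasta <- function(regions, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(regions$sequence,
                                                regions$region_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
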