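#' Bundle protein architectures into a genome annotation
#'
#' @param genome_id Genome identifier.
#' @param proteins A `protein_architectures` object for this genome.
#' @param total_gene_count Total genes in the genome (used as the denominator
#'   of repertoire percentages); defaults to the number of proteins supplied.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, proteins, total_gene_count = nrow(proteins)) {
  stopifnot(inherits(proteins, "protein_architectures"),
            !anyDuplicated(proteins$protein_id),
            total_gene_count >= nrow(proteins))
  structure(list(genome_id = genome_id, proteins = proteins,
                 total_gene_count = as.integer(total_gene_count)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("Genome annotation:", x$genome_id, "\n")
  cat(" ", nrow(x$proteins), "annotated proteins of",
      x$total_gene_count, "genes\n")
  tb <- table(x$proteins$protein_class)
  for (cl in names(tb)) cat(sprintf("  %-14s %d\n", cl, tb[[cl]]))
  invisible(x)
}

#' Mucin-glycan-degrading glycoside hydrolase families
#'
#' The default family set covers GH families experimentally characterized for
#' mucin glycan degradation in gut bacteria (sialidases, fucosidases,
#' N-acetyl-glucosaminidases/-galactosaminidases, galactosidases and related
#' activities). It ships as an editable table in
#' `system.file("extdata", "mucin_gh_families.tsv", package = "mucikit")`;
#' one family (`GH43_24`) is configured at subfamily resolution.
#'
#' @param path Optional path to an alternative TSV with columns `family` and
#'   `note`.
#' @return Character vector of family labels.
#' @export
mucin_gh_families <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mucin_gh_families.tsv", package = "mucikit")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("family" %in% names(tab), nrow(tab) > 0)
  bad <- !grepl("^[A-Za-z]+[0-9]+(_[0-9]+)?$", tab$family)
  if (any(bad)) stop("invalid family label(s): ",
                     paste(tab$family[bad], collapse = ", "))
  tab$family
}

#' Match CAZyme family labels against a configured family set
#'
#' Matching is asymmetric: a configured subfamily (`"GH43_24"`) matches only
#' itself, while a configured parent family (`"GH43"`) matches the family and
#' all of its subfamilies (`"GH43_11"`, ...).
#'
#' @param labels Character vector of observed family labels.
#' @param families Configured family set.
#' @return Logical vector parallel to `labels`.
#' @export
match_gh_family <- function(labels, families) {
  parent <- sub("_.*$", "", labels)
  labels %in% families | parent %in% families
}

is_gh_label <- function(labels) grepl("^GH[0-9]+(_[0-9]+)?$", labels)

protein_cazy_families <- function(domains) {
  unique(domains$model_name[is_cazyme_hit(domains)])
}

#' Genomes with cohesin and dockerin co-presence
#'
#' The first stage of the screen: only genomes encoding at least one accepted
#' cohesin domain and at least one accepted dockerin domain can assemble a
#' cohesin-dockerin complex.
#'
#' @param genomes List of `genome_annotation` objects.
#' @return Character vector of genome ids passing the co-presence filter.
#' @export
copresence_filter <- function(genomes) {
  keep <- vapply(genomes, function(g) {
    sum(g$proteins$n_coh) >= 1L && sum(g$proteins$n_doc) >= 1L
  }, logical(1))
  vapply(genomes[keep], function(g) g$genome_id, character(1))
}

#' Screen one genome for a mucinolysome architecture
#'
#' A genome is called mucinolysome-positive when it encodes both
#' (i) a scaffoldin bearing multiple (>= 2) cohesin domains and
#' (ii) a dockerin-bearing CAZyme whose family set intersects the configured
#' mucin-glycan-degrading GH families. Dockerin-bearing peptidases are
#' inventoried but not required for a positive verdict; signal peptides are
#' reported, not required.
#'
#' @param genome A `genome_annotation`.
#' @param families Mucin-GH family labels (default [mucin_gh_families()]).
#' @return An object of class `mucinolysome_call`: `genome_id`, `has_coh`,
#'   `has_doc`, `scaffoldins` (data.frame with `n_coh`),
#'   `multi_coh_scaffoldin`, `doc_mucin_cazymes`, `doc_peptidases`,
#'   `mucin_gh_families_present`, `verdict`.
#' @export
screen_genome <- function(genome, families = mucin_gh_families()) {
  p <- genome$proteins
  doms <- attr(p, "domains")
  has_coh <- sum(p$n_coh) >= 1L
  has_doc <- sum(p$n_doc) >= 1L
  sca <- p[p$protein_class == "scaffoldin", c("protein_id", "n_coh"), drop = FALSE]
  multi <- nrow(sca) > 0L && any(sca$n_coh >= 2L)
  dc <- p$protein_id[p$protein_class == "doc_cazyme"]
  fam_present <- character()
  doc_mucin <- character()
  for (pid in dc) {
    fams <- protein_cazy_families(doms[[pid]])
    hit <- match_gh_family(fams, families)
    if (any(hit)) {
      doc_mucin <- c(doc_mucin, pid)
      fam_present <- union(fam_present, fams[hit])
    }
  }
  doc_pept <- p$protein_id[p$protein_class == "doc_peptidase"]
  structure(list(
    genome_id = genome$genome_id,
    has_coh = has_coh, has_doc = has_doc,
    scaffoldins = sca, multi_coh_scaffoldin = multi,
    doc_mucin_cazymes = doc_mucin, doc_peptidases = doc_pept,
    mucin_gh_families_present = sort(fam_present),
    verdict = has_coh && has_doc && multi && length(doc_mucin) >= 1L
  ), class = "mucinolysome_call")
}

#' @export
print.mucinolysome_call <- function(x, ...) {
  cat("Mucinolysome screen:", x$genome_id, "->",
      if (x$verdict) "POSITIVE" else "negative", "\n")
  cat("  scaffoldins:", nrow(x$scaffoldins),
      "(multi-Coh:", x$multi_coh_scaffoldin, ")\n")
  cat("  Doc + mucin-GH CAZymes:", length(x$doc_mucin_cazymes), "\n")
  cat("  Doc peptidases:", length(x$doc_peptidases), "\n")
  if (length(x$mucin_gh_families_present)) {
    cat("  mucin-GH families:",
        paste(x$mucin_gh_families_present, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Screen a cohort of genomes
#'
#' @param genomes List of `genome_annotation` objects.
#' @param families Mucin-GH family labels.
#' @return A `data.frame` with one row per genome (`genome_id`, `verdict`,
#'   component counts) and the full calls as attribute `"calls"`.
#' @export
screen_genomes <- function(genomes, families = mucin_gh_families()) {
  calls <- lapply(genomes, screen_genome, families = families)
  out <- do.call(rbind, lapply(calls, function(cl) data.frame(
    genome_id = cl$genome_id, verdict = cl$verdict,
    n_scaffoldins = nrow(cl$scaffoldins),
    multi_coh_scaffoldin = cl$multi_coh_scaffoldin,
    n_doc_mucin_cazymes = length(cl$doc_mucin_cazymes),
    n_doc_peptidases = length(cl$doc_peptidases),
    stringsAsFactors = FALSE
  )))
  rownames(out) <- NULL
  attr(out, "calls") <- calls
  out
}

#' Expand the screen by scaffoldin homology matches
#'
#' Consumes a precomputed alignment table (MMseqs2/BLAST tabular dialect) of
#' scaffoldin queries against candidate genome proteomes and returns the
#' genomes retaining at least one match at `identity >= id_min`,
#' `coverage >= cov_min` and `e_value < e_max`.
#'
#' @param alignments `data.frame` with columns `qseqid`, `sseqid`, `pident`,
#'   `qcovs`, `evalue` and `genome_id` (when absent, `sseqid` is used as the
#'   genome id).
#' @param id_min Minimum percent identity (inclusive), default 50.
#' @param cov_min Minimum percent coverage (inclusive), default 85.
#' @param e_max Maximum E-value (exclusive), default 1e-5.
#' @return Character vector of unique genome ids, in first-match order.
#' @export
homology_expand <- function(alignments, id_min = 50, cov_min = 85, e_max = 1e-5) {
  need <- c("qseqid", "sseqid", "pident", "qcovs", "evalue")
  miss <- setdiff(need, names(alignments))
  if (length(miss)) {
    stop("alignment table lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  gid <- if ("genome_id" %in% names(alignments)) {
    alignments$genome_id
  } else {
    alignments$sseqid
  }
  pass <- alignments$pident >= id_min & alignments$qcovs >= cov_min &
    alignments$evalue < e_max
  unique(gid[pass])
}

#' Summarize a genome's glycoside-hydrolase repertoire
#'
#' Counts GH-carrying proteins, mucin-glycan-degrading GH proteins and their
#' secreted (signal-peptide-bearing) subsets, and reports the two repertoire
#' percentages: mucin-GH proteins over all genes in the genome, and mucin-GH
#' proteins over all GH proteins. A protein carrying several GH domains
#' counts once overall and once per distinct family; with zero GH proteins
#' the GH-denominator percentages are `NA`, not 0.
#'
#' @param genome A `genome_annotation`.
#' @param families Mucin-GH family labels.
#' @return A one-row `data.frame` with counts and percentages.
#' @export
repertoire_summary <- function(genome, families = mucin_gh_families()) {
  p <- genome$proteins
  doms <- attr(p, "domains")
  fam_by_protein <- lapply(p$protein_id, function(pid) {
    fams <- protein_cazy_families(doms[[pid]])
    fams[is_gh_label(fams)]
  })
  has_gh <- lengths(fam_by_protein) > 0L
  is_mucin <- vapply(fam_by_protein,
                     function(f) any(match_gh_family(f, families)),
                     logical(1))
  secreted <- p$has_signal_peptide
  gh_protein_count <- sum(has_gh)
  mucin_gh_protein_count <- sum(is_mucin)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  data.frame(
    genome_id = genome$genome_id,
    gh_family_count = length(unique(unlist(fam_by_protein))),
    gh_protein_count = gh_protein_count,
    secreted_gh_count = sum(has_gh & secreted),
    mucin_gh_protein_count = mucin_gh_protein_count,
    secreted_mucin_gh_count = sum(is_mucin & secreted),
    pct_mucin_gh_over_genes = pct(mucin_gh_protein_count, genome$total_gene_count),
    pct_mucin_gh_over_ghs = pct(mucin_gh_protein_count, gh_protein_count),
    pct_secreted_gh = pct(sum(has_gh & secreted), gh_protein_count),
    pct_secreted_mucin_gh = if (mucin_gh_protein_count > 0) {
      100 * sum(is_mucin & secreted) / mucin_gh_protein_count
    } else NA_real_,
    stringsAsFactors = FALSE
  )
}
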