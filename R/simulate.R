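#' Derive a child seed from a global seed
#'
#' Each generator draws from its own deterministically derived stream, so
#' adding a generator never perturbs the fixtures of another. Children stay
#' below 2^31 - 1.
#'
#' @param seed Integer global seed.
#' @param stream Stream name (a string).
#' @return Integer child seed.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + h * 1000003) %% 2147483629)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

rand_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# E-values/coordinates guaranteed to pass (E < 1e-4, HMM coverage > 0.6)
passing_pfam_hit <- function(protein_id, model, ali_from, hmm_length, plen) {
  hmm_to <- sample(seq(ceiling(0.75 * hmm_length), hmm_length), 1L)
  span <- hmm_to  # hmm_from = 1
  data.frame(protein_id = protein_id, model_name = model, source_db = "pfam",
             e_value = 10^stats::runif(1, -30, -6),
             ali_from = ali_from, ali_to = ali_from + span - 1L,
             hmm_from = 1L, hmm_to = hmm_to, hmm_length = hmm_length,
             protein_length = plen, stringsAsFactors = FALSE)
}

failing_pfam_hit <- function(protein_id, model, ali_from, hmm_length, plen) {
  # fails the coverage rule (span < 60% of the model)
  hmm_to <- sample(seq(ceiling(0.2 * hmm_length), floor(0.55 * hmm_length)), 1L)
  data.frame(protein_id = protein_id, model_name = model, source_db = "pfam",
             e_value = 10^stats::runif(1, -30, -6),
             ali_from = ali_from, ali_to = ali_from + hmm_to - 1L,
             hmm_from = 1L, hmm_to = hmm_to, hmm_length = hmm_length,
             protein_length = plen, stringsAsFactors = FALSE)
}

cazyme_hit <- function(protein_id, family, ali_from, plen) {
  data.frame(protein_id = protein_id, model_name = family,
             source_db = "cazyme", e_value = 10^stats::runif(1, -60, -20),
             ali_from = ali_from, ali_to = ali_from + 249L,
             hmm_from = 1L, hmm_to = 250L, hmm_length = 250L,
             protein_length = plen, stringsAsFactors = FALSE)
}

peptidase_hit <- function(protein_id, family, ali_from, plen) {
  data.frame(protein_id = protein_id, model_name = family,
             source_db = "peptidase", e_value = 10^stats::runif(1, -40, -12),
             ali_from = ali_from, ali_to = ali_from + 199L,
             hmm_from = 1L, hmm_to = 200L, hmm_length = 200L,
             protein_length = plen, stringsAsFactors = FALSE)
}

COH_HMM_LEN <- 139L
DOC_HMM_LEN <- 58L
NON_MUCIN_GH <- c("GH5", "GH9", "GH13", "GH26", "GH48", "GH77")

#' Simulate genomes with and without planted mucinolysome architectures
#'
#' Positive genomes carry at least one multi-cohesin scaffoldin and at least
#' one dockerin-bearing CAZyme of a configured mucin-GH family, with all
#' cohesin/dockerin hits passing the screen thresholds (E < 1e-4, HMM
#' coverage > 60%). Negative genomes violate exactly one recorded criterion:
#' `no_coh`, `no_doc`, `single_coh_scaffoldin`, or `non_mucin_gh`. Decoy
#' sub-threshold cohesin/dockerin hits are sprinkled on both classes to
#' exercise the filters. Byte-identical across reruns at a fixed seed.
#'
#' @param n_genomes Number of genomes.
#' @param fraction_positive Planted positive fraction; the positive count is
#'   exactly `round(fraction_positive * n_genomes)`.
#' @param seed Integer seed.
#' @param proteins_per_genome Range of background protein counts per genome.
#' @param families Mucin-GH family labels used for planting.
#' @param sequences Generate random protein sequences (needed for
#'   region-extraction round trips)? Default `TRUE`.
#' @return A list: `hits` (pooled `domain_hits`), `protein_lengths` (named
#'   vector), `protein_genome` (named genome id per protein),
#'   `signal_peptide` (named logical), `sequences` (named character or
#'   `NULL`), `truth` (`data.frame` of `genome_id`, `positive`,
#'   `failure_mode`), `seed`.
#' @export
sim_genomes <- function(n_genomes = 200, fraction_positive = 0.5, seed = 1L,
                        proteins_per_genome = c(6L, 12L),
                        families = mucin_gh_families(),
                        sequences = TRUE) {
  stopifnot(fraction_positive >= 0, fraction_positive <= 1)
  parent_fams <- unique(sub("_.*$", "", families))
  with_local_seed(derive_seed(seed, "genomes"), {
    n_pos <- round(fraction_positive * n_genomes)
    pos <- rep(FALSE, n_genomes)
    pos[sample.int(n_genomes, n_pos)] <- TRUE
    modes <- c("no_coh", "no_doc", "single_coh_scaffoldin", "non_mucin_gh")
    hit_list <- list()
    plen <- integer()
    pg <- character()
    sp <- logical()
    truth <- data.frame(genome_id = sprintf("g%03d", seq_len(n_genomes)),
                        positive = pos, failure_mode = NA_character_,
                        stringsAsFactors = FALSE)
    for (g in seq_len(n_genomes)) {
      gid <- truth$genome_id[g]
      pidx <- 0L
      new_pid <- function() {
        pidx <<- pidx + 1L
        sprintf("%s_p%02d", gid, pidx)
      }
      add_protein <- function(len, hits = NULL, signal = FALSE) {
        pid <- new_pid()
        if (!is.null(hits)) {
          hits$protein_id <- pid
          hits$protein_length <- len
          hit_list[[length(hit_list) + 1L]] <<- hits
        }
        plen[pid] <<- len
        pg[pid] <<- gid
        sp[pid] <<- signal
        pid
      }
      scaffoldin <- function(n_coh) {
        len <- 200L * n_coh + sample(100:400, 1L)
        h <- do.call(rbind, lapply(seq_len(n_coh), function(i) {
          passing_pfam_hit(".", "Cohesin", 40L + (i - 1L) * 180L,
                           COH_HMM_LEN, len)
        }))
        add_protein(len, h, signal = TRUE)
      }
      doc_enzyme <- function(fam, source = "cazyme") {
        len <- sample(400:900, 1L)
        mk <- if (source == "cazyme") cazyme_hit else peptidase_hit
        h <- rbind(mk(".", fam, 30L, len),
                   passing_pfam_hit(".", "Dockerin", len - 80L, DOC_HMM_LEN, len))
        add_protein(len, h, signal = stats::runif(1) < 0.8)
      }
      background <- function() {
        len <- sample(300:800, 1L)
        h <- if (stats::runif(1) < 0.5) {
          cazyme_hit(".", sample(NON_MUCIN_GH, 1L), 20L, len)
        } else NULL
        add_protein(len, h, signal = stats::runif(1) < 0.2)
      }
      decoy <- function() {
        # sub-threshold Coh/Doc signal that the filter must drop
        len <- sample(200:600, 1L)
        model <- sample(c("Cohesin", "Dockerin"), 1L)
        hlen <- if (model == "Cohesin") COH_HMM_LEN else DOC_HMM_LEN
        add_protein(len, failing_pfam_hit(".", model, 30L, hlen, len))
      }
      if (pos[g]) {
        scaffoldin(sample(2:5, 1L))
        fam <- sample(families, 1L)
        doc_enzyme(fam)
        if (stats::runif(1) < 0.5) doc_enzyme("M60", source = "peptidase")
      } else {
        mode <- sample(modes, 1L)
        truth$failure_mode[g] <- mode
        if (mode == "no_coh") {
          doc_enzyme(sample(families, 1L))
        } else if (mode == "no_doc") {
          scaffoldin(sample(2:5, 1L))
        } else if (mode == "single_coh_scaffoldin") {
          scaffoldin(1L)
          doc_enzyme(sample(families, 1L))
        } else { # non_mucin_gh
          scaffoldin(sample(2:5, 1L))
          doc_enzyme(sample(setdiff(NON_MUCIN_GH, parent_fams), 1L))
        }
        if (stats::runif(1) < 0.5) decoy()
      }
      for (k in seq_len(sample(proteins_per_genome[1]:proteins_per_genome[2], 1L))) {
        background()
      }
    }
    hits <- as_domain_hits(do.call(rbind, hit_list))
    seqs <- NULL
    if (sequences) {
      seqs <- vapply(plen, rand_aa_seq, character(1))
      names(seqs) <- names(plen)
    }
    list(hits = hits, protein_lengths = plen, protein_genome = pg,
         signal_peptide = sp, sequences = seqs, truth = truth, seed = seed)
  })
}

#' Assemble genome annotations for a simulated (or real) cohort
#'
#' Runs [build_architectures()] on the pooled hit table and splits the result
#' by genome.
#'
#' @param hits Pooled `domain_hits`.
#' @param protein_lengths Named lengths.
#' @param protein_genome Named genome id per protein.
#' @param signal_peptide Named logical flags.
#' @param ... Passed to [build_architectures()] (thresholds).
#' @return Named list of `genome_annotation` objects.
#' @export
build_genome_set <- function(hits, protein_lengths, protein_genome,
                             signal_peptide = NULL, ...) {
  arch <- build_architectures(hits, protein_lengths, signal_peptide, ...)
  doms <- attr(arch, "domains")
  gids <- unique(protein_genome)
  out <- lapply(gids, function(gid) {
    pids <- names(protein_genome)[protein_genome == gid]
    sub <- arch[arch$protein_id %in% pids, , drop = FALSE]
    rownames(sub) <- NULL
    attr(sub, "domains") <- doms[pids]
    class(sub) <- c("protein_architectures", "data.frame")
    genome_annotation(gid, sub)
  })
  stats::setNames(out, gids)
}

#' Simulate a two-chain complex with a planted interface
#'
#' Builds a CA/CB pseudo-structure with exactly `k` inter-chain CB contact
#' pairs within 8 angstroms (contact pairs are spaced 30 angstroms apart so
#' no incidental cross-pair contacts arise) plus non-interface residues far
#' from the interface. Interface residues carry the supplied plDDT values in
#' the B-factor slot.
#'
#' @param k Number of planted contact pairs.
#' @param interface_plddt plDDT for interface residues: a scalar or a vector
#'   of length `2 * k` (chain A residues then chain B residues).
#' @param n_extra Non-interface residues added per chain.
#' @param noninterface_plddt plDDT for non-interface residues.
#' @param pair_id Identifier.
#' @return List with `model` (a `complex_model`) and `truth`
#'   (`if_contacts`, `if_plddt`, `pdockq`).
#' @export
sim_complex <- function(k, interface_plddt = 90, n_extra = 5L,
                        noninterface_plddt = 50, pair_id = "coh__doc") {
  stopifnot(k >= 0)
  ipl <- rep_len(interface_plddt, max(2L * k, 1L))
  mk_chain <- function(n_if, y, base_resno, if_plddts) {
    ifr <- if (n_if > 0) {
      data.frame(resno = base_resno + seq_len(n_if),
                 x = 30 * seq_len(n_if), y = y, z = 0,
                 plddt = if_plddts, stringsAsFactors = FALSE)
    } else NULL
    ext <- if (n_extra > 0) {
      data.frame(resno = base_resno + n_if + seq_len(n_extra),
                 x = 30 * seq_len(n_extra),
                 y = y, z = ifelse(y == 0, 500, -500),
                 plddt = noninterface_plddt, stringsAsFactors = FALSE)
    } else NULL
    rbind(ifr, ext)
  }
  a <- mk_chain(k, 0, 0L, ipl[seq_len(k)])
  b <- mk_chain(k, 4, 1000L, ipl[k + seq_len(k)])
  if (is.null(a)) a <- mk_chain(0, 0, 0L, numeric())
  if (is.null(b)) b <- mk_chain(0, 4, 1000L, numeric())
  model <- complex_model(pair_id, a, b)
  if_plddt <- if (k > 0) mean(ipl[seq_len(2L * k)]) else NA_real_
  list(model = model,
       truth = list(if_contacts = as.integer(k), if_plddt = if_plddt,
                    pdockq = if (k == 0) 0 else pdockq(if_plddt, k)))
}

#' Simulate a batch of complexes with random planted interfaces
#'
#' @param n Number of complexes.
#' @param seed Integer seed.
#' @param contacts_range Range of planted contact counts.
#' @param plddt_mean,plddt_sd Normal parameters for interface plDDT values,
#'   truncated to `[0, 100]`.
#' @return List of [sim_complex()] results.
#' @export
sim_complexes <- function(n = 100, seed = 1L, contacts_range = c(1L, 80L),
                          plddt_mean = 85, plddt_sd = 8) {
  with_local_seed(derive_seed(seed, "complexes"), {
    lapply(seq_len(n), function(i) {
      k <- sample(contacts_range[1]:contacts_range[2], 1L)
      pl <- pmin(100, pmax(0, stats::rnorm(2L * k, plddt_mean, plddt_sd)))
      sim_complex(k, pl, n_extra = sample(0:10, 1L),
                  pair_id = sprintf("coh%03d__doc%03d", i, i))
    })
  })
}

#' Write a complex model as a PDB file
#'
#' Minimal fixed-width ATOM-record writer for the CA/CB pseudo-structures the
#' simulator produces (per-residue plDDT in the B-factor column; residues are
#' alanines so the CB atom is the contact atom). Files round-trip through
#' [read_complex()].
#'
#' @param model A `complex_model`.
#' @param path Output `.pdb` path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  chains <- c("A", "B")
  for (ci in 1:2) {
    ch <- model$chains[[ci]]
    for (i in seq_len(nrow(ch))) {
      for (atom in c("CA", "CB")) {
        serial <- serial + 1L
        # CA is offset so contact geometry lives on CB
        dz <- if (atom == "CA") 1.5 else 0
        writeLines(sprintf(
          "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
          serial, atom, "ALA", chains[ci], ch$resno[i],
          ch$x[i], ch$y[i], ch$z[i] + dz, 1.00, ch$plddt[i],
          "C"), con)
      }
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Simulate a cohort of depth profiles with planted presence labels
#'
#' Samples are assigned hosts; each host gets an exact planted count of
#' positive samples. A positive sample carries at least one target profile
#' satisfying the presence rule (BC >= 0.6, ARD >= 1); negative samples carry
#' only failing profiles, split between low-breadth and low-depth failure
#' modes. Recorded truth holds the exact BC/ARD of every generated profile.
#'
#' @param hosts Named integer vector: samples per host.
#' @param positives Named integer vector: planted positive samples per host
#'   (same names as `hosts`).
#' @param targets Target ids.
#' @param target_length Reference length in bp.
#' @param seed Integer seed.
#' @return List: `profiles` (list of `depth_profile` keyed
#'   `"<sample>|<target>"`), `truth` (`sample_id`, `target_id`, `bc`, `ard`,
#'   `present`), `manifest` (`sample_id`, `host`, `total_reads`),
#'   `host_truth` (planted per-host prevalence in percent).
#' @export
sim_depth <- function(hosts = c(chicken = 40L, pig = 40L, human = 20L),
                      positives = c(chicken = 8L, pig = 12L, human = 0L),
                      targets = sprintf("MAG%02d", 1:5),
                      target_length = 2000L, seed = 1L) {
  stopifnot(identical(sort(names(hosts)), sort(names(positives))),
            all(positives <= hosts))
  with_local_seed(derive_seed(seed, "depth"), {
    L <- target_length
    gen_present <- function() {
      f <- stats::runif(1, 0.65, 1.0)
      covered <- sort(sample.int(L, ceiling(f * L)))
      d <- numeric(L)
      d[covered] <- 1 + stats::rpois(length(covered), 2)
      if (sum(d) < L) d[covered[1]] <- d[covered[1]] + (L - sum(d)) + 1
      d
    }
    gen_absent <- function() {
      d <- numeric(L)
      if (stats::runif(1) < 0.5) {
        f <- stats::runif(1, 0.05, 0.55)   # fails breadth
        covered <- sample.int(L, floor(f * L))
        d[covered] <- 1 + stats::rpois(length(covered), 2)
      } else {
        f <- stats::runif(1, 0.62, 0.95)   # passes breadth, fails depth
        covered <- sample.int(L, floor(f * L))
        d[covered] <- 1
      }
      d
    }
    profiles <- list()
    truth <- list()
    manifest <- list()
    si <- 0L
    for (h in names(hosts)) {
      pos_flags <- rep(FALSE, hosts[[h]])
      if (positives[[h]] > 0) {
        pos_flags[sample.int(hosts[[h]], positives[[h]])] <- TRUE
      }
      for (s in seq_len(hosts[[h]])) {
        si <- si + 1L
        sid <- sprintf("S%04d", si)
        manifest[[si]] <- data.frame(sample_id = sid, host = h,
                                     total_reads = 1e7,
                                     stringsAsFactors = FALSE)
        pos_targets <- if (pos_flags[s]) {
          sample(targets, sample.int(length(targets), 1L))
        } else character()
        for (tg in targets) {
          d <- if (tg %in% pos_targets) gen_present() else gen_absent()
          p <- depth_profile(tg, d,
                             mapped_read_count = round(sum(d) / 150))
          key <- paste(sid, tg, sep = "|")
          profiles[[key]] <- p
          truth[[key]] <- data.frame(
            sample_id = sid, target_id = tg,
            bc = sum(d >= 1) / L, ard = sum(d) / L,
            present = tg %in% pos_targets, stringsAsFactors = FALSE)
        }
      }
    }
    list(profiles = profiles,
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))),
         host_truth = data.frame(host = names(hosts),
                                 positive_count = as.integer(positives[names(hosts)]),
                                 total_count = as.integer(hosts),
                                 prevalence = 100 * as.numeric(positives[names(hosts)]) /
                                   as.numeric(hosts),
                                 stringsAsFactors = FALSE))
  })
}

#' Write depth profiles as a per-base depth table
#'
#' @param profiles Named list of `depth_profile` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(profiles, path) {
  tabs <- lapply(profiles, function(p) {
    data.frame(target = p$target_id, pos = seq_len(p$length),
               depth = p$depth, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a differential-expression table with planted DEG labels
#'
#' Planted counts are exact; log2 fold changes and adjusted p-values respect
#' the strict DEG thresholds (|log2FC| > 1, FDR < 0.05) with margin on both
#' sides, including non-significant genes that fail only one of the two
#' conditions. TPM columns are generated consistently with the fold changes.
#'
#' @param n_genes Number of genes.
#' @param n_up,n_down Planted up-/down-regulated counts.
#' @param seed Integer seed.
#' @param n_mucinolysome,n_mucin_cazyme Genes assigned to the
#'   `mucinolysome` / `non_mucinolysome_mucin_cazyme` categories (the rest
#'   are `other`).
#' @return List: `records` (`gene_id`, `category`, `tpm_a`, `tpm_b`,
#'   `log2fc`, `padj`), `truth` (`gene_id`, `deg`).
#' @export
sim_expression <- function(n_genes = 2527, n_up = 324, n_down = 302,
                           seed = 1L, n_mucinolysome = 26,
                           n_mucin_cazyme = 10) {
  stopifnot(n_up + n_down <= n_genes,
            n_mucinolysome + n_mucin_cazyme <= n_genes)
  with_local_seed(derive_seed(seed, "expression"), {
    gene_id <- sprintf("gene%05d", seq_len(n_genes))
    deg <- rep("ns", n_genes)
    idx <- sample.int(n_genes, n_up + n_down)
    deg[idx[seq_len(n_up)]] <- "up"
    deg[idx[n_up + seq_len(n_down)]] <- "down"
    log2fc <- numeric(n_genes)
    padj <- numeric(n_genes)
    up <- deg == "up"; down <- deg == "down"; ns <- deg == "ns"
    log2fc[up] <- stats::runif(sum(up), 1.2, 6)
    log2fc[down] <- -stats::runif(sum(down), 1.2, 6)
    padj[up | down] <- 10^stats::runif(sum(up | down), -60, -2.5)
    # ns genes fail one condition or both
    kind <- sample(1:3, sum(ns), replace = TRUE)
    fc_ns <- stats::runif(sum(ns), -0.8, 0.8)
    fc_big <- sample(c(-1, 1), sum(ns), TRUE) * stats::runif(sum(ns), 1.2, 4)
    log2fc[ns] <- ifelse(kind == 2, fc_big, fc_ns)
    padj[ns] <- ifelse(kind == 1, 10^stats::runif(sum(ns), -20, -2.5),
                       stats::runif(sum(ns), 0.06, 1))
    base <- stats::rlnorm(n_genes, 4, 1.5)
    tpm_b <- 1e6 * base / sum(base)
    raw_a <- base * 2^log2fc
    tpm_a <- 1e6 * raw_a / sum(raw_a)
    category <- rep("other", n_genes)
    cat_idx <- sample.int(n_genes, n_mucinolysome + n_mucin_cazyme)
    category[cat_idx[seq_len(n_mucinolysome)]] <- "mucinolysome"
    category[cat_idx[n_mucinolysome + seq_len(n_mucin_cazyme)]] <-
      "non_mucinolysome_mucin_cazyme"
    list(records = data.frame(gene_id = gene_id, category = category,
                              tpm_a = tpm_a, tpm_b = tpm_b,
                              log2fc = log2fc, padj = padj,
                              stringsAsFactors = FALSE),
         truth = data.frame(gene_id = gene_id, deg = deg,
                            stringsAsFactors = FALSE))
  })
}
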