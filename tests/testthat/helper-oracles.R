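# Independent brute-force oracles kept deliberately naive: plain loops and
# direct arithmetic, no shared code with the implementation paths they check.

bf_filter <- function(hits, e_max, cov_min) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    cov <- (hits$hmm_to[i] - hits$hmm_from[i] + 1) / hits$hmm_length[i]
    keep[i] <- hits$e_value[i] < e_max && cov > cov_min
  }
  hits[keep, , drop = FALSE]
}

bf_resolve <- function(hits, max_overlap = 0.5) {
  ord <- order(hits$e_value, hits$ali_from, hits$model_name)
  accepted <- list()
  for (i in ord) {
    clash <- FALSE
    for (j in seq_along(accepted)) {
      a <- accepted[[j]]
      lo <- max(hits$ali_from[i], a$from)
      hi <- min(hits$ali_to[i], a$to)
      if (hi - lo + 1 > 0) {
        short <- min(hits$ali_to[i] - hits$ali_from[i] + 1, a$to - a$from + 1)
        if (hi - lo + 1 > max_overlap * short) clash <- TRUE
      }
    }
    if (!clash) {
      accepted[[length(accepted) + 1]] <- list(
        row = i, from = hits$ali_from[i], to = hits$ali_to[i])
    }
  }
  sort(vapply(accepted, function(a) a$row, numeric(1)))
}

bf_interface <- function(model, cutoff = 8.0) {
  a <- model$chains[[1]]
  b <- model$chains[[2]]
  n <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d <= cutoff) n <- n + 1L
    }
  }
  n
}

random_hits <- function(n, protein_id = NULL) {
  hmm_length <- sample(50:300, n, replace = TRUE)
  hmm_from <- mapply(function(L) sample.int(L, 1L), hmm_length)
  hmm_to <- mapply(function(f, L) sample(f:L, 1L), hmm_from, hmm_length)
  ali_from <- sample(1:500, n, replace = TRUE)
  ali_to <- ali_from + (hmm_to - hmm_from) + sample(0:20, n, replace = TRUE)
  df <- data.frame(
    protein_id = if (is.null(protein_id)) sprintf("p%04d", seq_len(n)) else protein_id,
    model_name = sample(c("Cohesin", "Dockerin", "GH33", "GH2"), n, TRUE),
    source_db = "pfam",
    e_value = 10^runif(n, -30, 0),
    ali_from = as.integer(ali_from), ali_to = as.integer(ali_to),
    hmm_from = as.integer(hmm_from), hmm_to = as.integer(hmm_to),
    hmm_length = as.integer(hmm_length),
    protein_length = as.integer(ali_to + 50L),
    stringsAsFactors = FALSE
  )
  class(df) <- c("domain_hits", "data.frame")
  df
}

# one-protein architecture from a plain list of planted domain labels,
# bypassing the hit filters (for classification unit tests)
arch_from_domains <- function(labels, sources, length = 1000L,
                              protein_id = "p1", signal = FALSE) {
  n <- length(labels)
  hits <- data.frame(
    protein_id = protein_id, model_name = labels, source_db = sources,
    e_value = 1e-20,
    ali_from = as.integer(seq(1, by = 150, length.out = n)),
    ali_to = as.integer(seq(1, by = 150, length.out = n) + 100L),
    hmm_from = 1L, hmm_to = 100L, hmm_length = 100L,
    protein_length = length, stringsAsFactors = FALSE)
  class(hits) <- c("domain_hits", "data.frame")
  lens <- stats::setNames(length, protein_id)
  sp <- stats::setNames(signal, protein_id)
  build_architectures(hits, lens, sp, cov_min = 0, cazy_cov_min = 0)
}

# genome with planted protein architectures given as list(labels=, sources=)
genome_from_proteins <- function(genome_id, proteins, total_gene_count = NULL) {
  hits <- list()
  lens <- integer()
  sp <- logical()
  for (i in seq_along(proteins)) {
    p <- proteins[[i]]
    pid <- sprintf("%s_p%02d", genome_id, i)
    n <- length(p$labels)
    if (n > 0) {
      hits[[length(hits) + 1]] <- data.frame(
        protein_id = pid, model_name = p$labels, source_db = p$sources,
        e_value = 1e-20,
        ali_from = as.integer(seq(1, by = 150, length.out = n)),
        ali_to = as.integer(seq(1, by = 150, length.out = n) + 100L),
        hmm_from = 1L, hmm_to = 100L, hmm_length = 100L,
        protein_length = 150L * n + 200L, stringsAsFactors = FALSE)
    }
    lens[pid] <- 150L * n + 200L
    sp[pid] <- isTRUE(p$signal)
  }
  hdf <- if (length(hits)) do.call(rbind, hits) else {
    mucikit:::empty_hits()
  }
  class(hdf) <- c("domain_hits", "data.frame")
  arch <- build_architectures(hdf, lens, sp, cov_min = 0, cazy_cov_min = 0)
  genome_annotation(genome_id, arch,
                    total_gene_count = if (is.null(total_gene_count)) {
                      nrow(arch)
                    } else total_gene_count)
}
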