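mucin_positive_genome <- function(id = "gpos") {
  genome_from_proteins(id, list(
    list(labels = rep("Cohesin", 5), sources = rep("pfam", 5), signal = TRUE),
    list(labels = c("Dockerin", "GH33"), sources = c("pfam", "cazyme"),
         signal = TRUE),
    list(labels = "GH13", sources = "cazyme")
  ))
}

test_that("co-presence requires both cohesin and dockerin in the genome", {
  coh_only <- genome_from_proteins("g_coh", list(
    list(labels = rep("Cohesin", 3), sources = rep("pfam", 3))))
  both <- genome_from_proteins("g_both", list(
    list(labels = "Cohesin", sources = "pfam"),
    list(labels = "Dockerin", sources = "pfam")))
  expect_identical(copresence_filter(list(coh_only, both)), "g_both")
})

test_that("a multi-cohesin scaffoldin plus a Doc mucin-GH yields a positive call", {
  call <- screen_genome(mucin_positive_genome())
  expect_true(call$verdict)
  expect_true(call$multi_coh_scaffoldin)
  expect_identical(call$mucin_gh_families_present, "GH33")
})

test_that("cohesin-bearing enzymes without a catalytic-free scaffoldin stay negative", {
  # the architecture seen in C. perfringens-type systems: every cohesin
  # protein also carries a GH domain, so no scaffoldin exists
  g <- genome_from_proteins("g_cpe", list(
    list(labels = c("Cohesin", "GH84"), sources = c("pfam", "cazyme")),
    list(labels = c("Cohesin", "GH33"), sources = c("pfam", "cazyme")),
    list(labels = c("Dockerin", "GH2"), sources = c("pfam", "cazyme"))
  ))
  call <- screen_genome(g)
  expect_false(call$verdict)
  expect_false(call$multi_coh_scaffoldin)
  expect_true(call$has_coh && call$has_doc)
  expect_length(call$doc_mucin_cazymes, 1L)
})

test_that("a single-cohesin scaffoldin does not satisfy the multi-Coh rule", {
  g <- genome_from_proteins("g1coh", list(
    list(labels = "Cohesin", sources = "pfam"),
    list(labels = c("Dockerin", "GH33"), sources = c("pfam", "cazyme"))))
  expect_false(screen_genome(g)$verdict)
})

test_that("subfamily matching is asymmetric", {
  expect_true(match_gh_family("GH43_24", c("GH43_24")))
  expect_false(match_gh_family("GH43_11", c("GH43_24")))
  expect_true(all(match_gh_family(c("GH43", "GH43_11", "GH43_24"), "GH43")))
  expect_false(match_gh_family("GH33", c("GH43_24")))
})

test_that("the verdict is monotone in the configured family set", {
  g <- genome_from_proteins("gmono", list(
    list(labels = rep("Cohesin", 2), sources = rep("pfam", 2)),
    list(labels = c("Dockerin", "GH13"), sources = c("pfam", "cazyme"))))
  small <- c("GH33")
  big <- c("GH33", "GH13")
  expect_false(screen_genome(g, small)$verdict)
  expect_true(screen_genome(g, big)$verdict)
  # enlarging the set never flips a positive to negative
  pos <- mucin_positive_genome()
  expect_true(screen_genome(pos, c("GH33", "GH13"))$verdict)
})

test_that("screening is invariant under protein reordering", {
  g <- mucin_positive_genome()
  rev_g <- g
  perm <- rev(seq_len(nrow(g$proteins)))
  rev_g$proteins <- g$proteins[perm, , drop = FALSE]
  attr(rev_g$proteins, "domains") <- attr(g$proteins, "domains")[
    rev_g$proteins$protein_id]
  class(rev_g$proteins) <- class(g$proteins)
  a <- screen_genome(g)
  b <- screen_genome(rev_g)
  expect_identical(a$verdict, b$verdict)
  expect_identical(sort(a$doc_mucin_cazymes), sort(b$doc_mucin_cazymes))
})

test_that("screen positives recover planted labels on a synthetic cohort", {
  sim <- sim_genomes(60, 0.5, seed = 11, sequences = FALSE)
  genomes <- build_genome_set(sim$hits, sim$protein_lengths,
                              sim$protein_genome, sim$signal_peptide)
  verdicts <- screen_genomes(genomes[sim$truth$genome_id])
  expect_identical(verdicts$verdict, sim$truth$positive)
  # screen-positive genomes are a subset of the co-presence set
  cop <- copresence_filter(genomes)
  expect_true(all(verdicts$genome_id[verdicts$verdict] %in% cop))
})

test_that("homology expansion applies identity, coverage and E-value rules", {
  aln <- data.frame(
    qseqid = "hSca1", sseqid = c("m1", "m2", "m3"),
    pident = c(98.94, 49.9, 60), qcovs = c(100, 100, 84),
    evalue = c(0, 1e-30, 1e-30),
    genome_id = c("G1", "G2", "G3"), stringsAsFactors = FALSE)
  expect_identical(homology_expand(aln), "G1")
  expect_error(homology_expand(aln[, -3]), "pident")
})

test_that("homology expansion equals a brute-force row filter on random tables", {
  set.seed(4)
  aln <- data.frame(
    qseqid = "q", sseqid = sprintf("s%03d", 1:300),
    pident = runif(300, 0, 100), qcovs = runif(300, 0, 100),
    evalue = 10^runif(300, -40, 0),
    genome_id = sample(sprintf("G%02d", 1:40), 300, TRUE),
    stringsAsFactors = FALSE)
  got <- homology_expand(aln)
  want <- character()
  for (i in seq_len(nrow(aln))) {
    if (aln$pident[i] >= 50 && aln$qcovs[i] >= 85 && aln$evalue[i] < 1e-5) {
      want <- union(want, aln$genome_id[i])
    }
  }
  expect_setequal(got, want)
})

test_that("repertoire percentages use the documented denominators", {
  # 45 GH proteins, 31 of mucin-degrading families
  prot <- c(
    lapply(1:31, function(i) list(labels = "GH33", sources = "cazyme",
                                  signal = i <= 20)),
    lapply(1:14, function(i) list(labels = "GH13", sources = "cazyme")))
  g <- genome_from_proteins("grep", prot, total_gene_count = 2000L)
  rs <- repertoire_summary(g)
  expect_identical(rs$gh_protein_count, 45L)
  expect_identical(rs$mucin_gh_protein_count, 31L)
  expect_equal(round(rs$pct_mucin_gh_over_ghs, 1), 68.9)
  expect_equal(rs$pct_mucin_gh_over_genes, 100 * 31 / 2000)
  expect_identical(rs$secreted_mucin_gh_count, 20L)
  expect_equal(rs$pct_secreted_gh, 100 * 20 / 45)
})

test_that("a genome without GH proteins reports missing GH percentages", {
  g <- genome_from_proteins("gno", list(
    list(labels = "M60", sources = "peptidase")))
  rs <- repertoire_summary(g)
  expect_identical(rs$gh_protein_count, 0L)
  expect_true(is.na(rs$pct_mucin_gh_over_ghs))
  expect_true(is.na(rs$pct_secreted_gh))
  expect_equal(rs$pct_mucin_gh_over_genes, 0)
})

test_that("planted repertoire counts match closed-form percentages", {
  sim <- sim_genomes(10, 1, seed = 21, sequences = FALSE)
  genomes <- build_genome_set(sim$hits, sim$protein_lengths,
                              sim$protein_genome, sim$signal_peptide)
  for (g in genomes) {
    rs <- repertoire_summary(g)
    if (rs$gh_protein_count > 0) {
      expect_equal(rs$pct_mucin_gh_over_ghs,
                   100 * rs$mucin_gh_protein_count / rs$gh_protein_count)
    }
    expect_equal(rs$pct_mucin_gh_over_genes,
                 100 * rs$mucin_gh_protein_count / g$total_gene_count)
  }
})
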