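test_that("pDockQ reproduces the published worked examples", {
  expect_equal(round(pdockq(96.4, 57), 2), 0.53)
  expect_equal(round(pdockq(94.7, 53), 2), 0.48)
  expect_identical(pdockq(85, 0), 0)
})

test_that("pDockQ is bounded, monotone, and hits its sigmoid midpoint", {
  # midpoint: x = 152.611 gives 0.724/2 + 0.018 = 0.38
  expect_equal(pdockq(152.611 / 2, 100), 0.380)
  grid_pl <- seq(10, 100, by = 10)
  grid_ct <- c(1, 2, 5, 10, 20, 50, 100, 500)
  vals <- outer(grid_pl, grid_ct, pdockq)
  expect_true(all(vals >= 0 & vals <= 0.742))
  # increasing in contacts at fixed plDDT > 0
  for (i in seq_along(grid_pl)) expect_true(all(diff(vals[i, ]) > 0))
  # increasing in plDDT at fixed contacts >= 2 (log10(1) = 0 makes the
  # single-contact score independent of plDDT)
  for (j in which(grid_ct >= 2)) expect_true(all(diff(vals[, j]) > 0))
  expect_equal(diff(range(vals[, grid_ct == 1])), 0)
  expect_equal(pdockq(100, 1e12), 0.742, tolerance = 1e-3)
})

test_that("chains far apart have no interface", {
  far <- complex_model("far",
    data.frame(resno = 1:3, x = 0, y = 0, z = c(0, 4, 8), plddt = 90),
    data.frame(resno = 1:3, x = 100, y = 0, z = c(0, 4, 8), plddt = 90))
  iface <- find_interface(far)
  expect_identical(iface$if_contacts, 0L)
  expect_identical(score_complex(far)$pdockq, 0)
})

test_that("a constructed grid has exactly the contacts the geometry implies", {
  # chain A at x = 0, 10, 20; chain B at x = 5, 15, 100 (y = z = 0):
  # pairs within 8 A: (0,5), (10,5), (10,15), (20,15) -> 4 contacts
  a <- data.frame(resno = 1:3, x = c(0, 10, 20), y = 0, z = 0, plddt = 90)
  b <- data.frame(resno = 1:3, x = c(5, 15, 100), y = 0, z = 0, plddt = 80)
  m <- complex_model("grid", a, b)
  iface <- find_interface(m)
  expect_identical(iface$if_contacts, 4L)
  expect_identical(iface$if_contacts, bf_interface(m))
  # interface residues: all of A, B residues 1-2
  expect_setequal(iface$interface_residues$A, 1:3)
  expect_setequal(iface$interface_residues$B, 1:2)
})

test_that("interface detection equals all-pairs brute force on random chains", {
  set.seed(5)
  for (i in 1:10) {
    na <- sample(5:50, 1); nb <- sample(5:50, 1)
    m <- complex_model(
      "rnd",
      data.frame(resno = seq_len(na), x = runif(na, 0, 40),
                 y = runif(na, 0, 40), z = runif(na, 0, 40), plddt = 90),
      data.frame(resno = seq_len(nb), x = runif(nb, 0, 40),
                 y = runif(nb, 0, 40), z = runif(nb, 0, 40), plddt = 90))
    expect_identical(find_interface(m)$if_contacts, bf_interface(m))
  }
})

test_that("IF_pLDDT averages interface residues only", {
  a <- data.frame(resno = 1:3, x = c(0, 0, 500), y = 0, z = 0,
                  plddt = c(90, 90, 10))
  b <- data.frame(resno = 1:2, x = c(4, 900), y = 0, z = 0,
                  plddt = c(90, 5))
  m <- complex_model("loc", a, b)
  sc <- score_complex(m)
  expect_equal(sc$if_plddt, 90)
  # perturbing non-interface plDDT leaves the score unchanged
  a2 <- a; a2$plddt[3] <- 99
  sc2 <- score_complex(complex_model("loc2", a2, b))
  expect_equal(sc2$if_plddt, sc$if_plddt)
  expect_equal(sc2$pdockq, sc$pdockq)
})

test_that("scores are symmetric under chain swap", {
  sim <- sim_complex(12, interface_plddt = c(seq(80, 91, 1), seq(70, 81, 1)))
  m <- sim$model
  swapped <- complex_model(m$pair_id, m$chains[[2]], m$chains[[1]])
  s1 <- score_complex(m); s2 <- score_complex(swapped)
  expect_identical(s1$if_contacts, s2$if_contacts)
  expect_equal(s1$if_plddt, s2$if_plddt)
  expect_equal(s1$pdockq, s2$pdockq)
})

test_that("PDB round trip preserves contacts, plDDT and pDockQ", {
  sim <- sim_complex(57, 96.4, n_extra = 6L)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(sim$model, f)
  sc <- score_complex(read_complex(f))
  expect_identical(sc$if_contacts, 57L)
  expect_equal(sc$if_plddt, 96.4)
  expect_equal(round(sc$pdockq, 2), 0.53)
})

test_that("the matrix threshold is strictly greater-than", {
  scores <- data.frame(coh = c("c1", "c1", "c2"), doc = c("d1", "d2", "d1"),
                       pdockq = c(0.3, 0.53, 0.29))
  m <- build_ppi_matrix(scores, threshold = 0.3)
  expect_false(m$predicted["c1", "d1"])  # exactly 0.3 is not predicted
  expect_true(m$predicted["c1", "d2"])
  expect_false(m$predicted["c2", "d1"])
  expect_error(build_ppi_matrix(rbind(scores, scores[1, ])), "duplicate")
})

test_that("matrix thresholding equals brute-force row thresholding", {
  set.seed(6)
  scores <- expand.grid(coh = sprintf("c%02d", 1:8),
                        doc = sprintf("d%02d", 1:6),
                        stringsAsFactors = FALSE)
  scores$pdockq <- runif(nrow(scores), 0, 0.742)
  m <- build_ppi_matrix(scores, threshold = 0.3)
  for (i in seq_len(nrow(scores))) {
    expect_identical(m$predicted[scores$coh[i], scores$doc[i]],
                     scores$pdockq[i] > 0.3)
  }
})

test_that("evaluation counts only ground-truth cells and satisfies the F1 identity", {
  scores <- expand.grid(coh = c("c1", "c2"), doc = c("d1", "d2", "dnew"),
                        stringsAsFactors = FALSE)
  scores$pdockq <- c(0.5, 0.1, 0.5, 0.5, 0.6, 0.6)  # dnew column unannotated
  m <- build_ppi_matrix(scores)
  truth <- data.frame(coh = c("c1", "c2", "c1", "c2"),
                      doc = c("d1", "d1", "d2", "d2"),
                      label = c("+", "-", "+", "-"))
  ev <- evaluate_ppi(m, truth)
  expect_identical(c(ev$tp, ev$fp, ev$fn, ev$tn), c(2L, 1L, 0L, 1L))
  expect_equal(ev$f1, 2 * ev$precision * ev$recall / (ev$precision + ev$recall))
  # perfect prediction
  truth2 <- data.frame(coh = c("c1", "c1"), doc = c("d1", "d2"),
                       label = c("+", "+"))
  scores2 <- data.frame(coh = "c1", doc = c("d1", "d2"), pdockq = 0.6)
  ev2 <- evaluate_ppi(build_ppi_matrix(scores2), truth2)
  expect_equal(c(ev2$recall, ev2$precision, ev2$f1), c(1, 1, 1))
})

test_that("F1 equals the harmonic mean on random confusion tables", {
  set.seed(8)
  for (i in 1:20) {
    n <- 30
    scores <- data.frame(coh = "c1", doc = sprintf("d%02d", 1:n),
                         pdockq = runif(n, 0, 0.742))
    truth <- data.frame(coh = "c1", doc = sprintf("d%02d", 1:n),
                        label = sample(c("+", "-"), n, TRUE))
    ev <- evaluate_ppi(build_ppi_matrix(scores), truth)
    if (!is.na(ev$f1)) {
      expect_equal(ev$f1,
                   2 * ev$precision * ev$recall / (ev$precision + ev$recall))
    }
    expect_identical(ev$tp + ev$fn, sum(truth$label == "+"))
  }
})

test_that("undefined precision or recall is reported as missing", {
  scores <- data.frame(coh = "c1", doc = c("d1", "d2"), pdockq = c(0.1, 0.1))
  truth <- data.frame(coh = "c1", doc = c("d1", "d2"), label = c("+", "-"))
  ev <- evaluate_ppi(build_ppi_matrix(scores), truth)
  expect_true(is.na(ev$precision))
  expect_equal(ev$recall, 0)
})

test_that("synthetic complexes score exactly their planted truth", {
  sims <- sim_complexes(40, seed = 13)
  for (s in sims) {
    sc <- score_complex(s$model)
    expect_identical(sc$if_contacts, s$truth$if_contacts)
    expect_equal(sc$if_plddt, s$truth$if_plddt, tolerance = 1e-9)
    expect_equal(sc$pdockq, s$truth$pdockq, tolerance = 1e-9)
  }
})
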