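#' Read a two-chain complex model from PDB or mmCIF
#'
#' Loads a predicted cohesin-dockerin complex and reduces it to the per-residue
#' geometry the interface scorer needs: one contact atom per residue (CB, or
#' CA for glycine) plus the per-residue predicted confidence (plDDT) stored in
#' the B-factor column, as structure predictors write it.
#'
#' @param path Path to a `.pdb` or `.cif` file with exactly two chains.
#' @param pair_id Identifier for the complex; defaults to the file name.
#' @return An object of class `complex_model`: `pair_id` and `chains`, a
#'   2-element named list of data.frames (`resno`, `resid`, `x`, `y`, `z`,
#'   `plddt`).
#' @export
read_complex <- function(path, pair_id = NULL) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  at <- pdb$atom
  chains <- unique(at$chain)
  if (length(chains) != 2L) {
    stop("expected exactly two chains, found ", length(chains), " in ", path)
  }
  id <- if (is.null(pair_id)) sub("\\.[^.]+$", "", basename(path)) else pair_id
  chain_tab <- lapply(chains, function(ch) {
    a <- at[at$chain == ch, , drop = FALSE]
    res <- unique(a$resno)
    rows <- lapply(res, function(r) {
      ar <- a[a$resno == r, , drop = FALSE]
      cb <- ar[ar$elety == "CB", , drop = FALSE]
      ca <- ar[ar$elety == "CA", , drop = FALSE]
      resid <- ar$resid[1]
      use <- if (nrow(cb) && resid != "GLY") cb[1, ] else ca[1, ]
      if (!nrow(ca)) stop("residue ", r, " chain ", ch, " lacks a CA atom")
      if (is.na(use$x)) stop("residue ", r, " chain ", ch,
                             " lacks CB and CA coordinates")
      data.frame(resno = r, resid = resid, x = use$x, y = use$y, z = use$z,
                 plddt = ca$b[1], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(chain_tab) <- chains
  if (any(vapply(chain_tab, nrow, integer(1)) == 0L)) {
    stop("empty chain in ", path)
  }
  complex_model(id, chain_tab[[1]], chain_tab[[2]],
                chain_ids = chains)
}

#' Construct a complex model from per-residue tables
#'
#' @param pair_id Identifier.
#' @param chain_a,chain_b data.frames with columns `resno`, `x`, `y`, `z`,
#'   `plddt` (and optionally `resid`).
#' @param chain_ids Chain labels, default `c("A", "B")`.
#' @return A `complex_model` object.
#' @export
complex_model <- function(pair_id, chain_a, chain_b, chain_ids = c("A", "B")) {
  chk <- function(ch) {
    stopifnot(is.data.frame(ch), nrow(ch) > 0,
              all(c("resno", "x", "y", "z", "plddt") %in% names(ch)))
    if (any(ch$plddt < 0 | ch$plddt > 100)) {
      stop("plDDT values must lie in [0, 100]")
    }
    ch
  }
  structure(list(pair_id = pair_id,
                 chains = stats::setNames(list(chk(chain_a), chk(chain_b)),
                                          chain_ids)),
            class = "complex_model")
}

#' Detect the inter-chain interface of a complex model
#'
#' A contact is an inter-chain residue pair whose contact atoms (CB, CA for
#' glycine) lie within `dist_cutoff` angstroms — the FoldDock convention.
#' Interface residues are the residues participating in at least one contact.
#'
#' @param model A `complex_model`.
#' @param dist_cutoff Distance cutoff in angstroms (default 8).
#' @return List with `if_contacts` (count of contacting residue pairs) and
#'   `interface_residues` (list of residue numbers per chain).
#' @export
find_interface <- function(model, dist_cutoff = 8.0) {
  a <- model$chains[[1]]
  b <- model$chains[[2]]
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  d2 <- dx * dx + dy * dy + dz * dz
  contact <- d2 <= dist_cutoff^2
  list(
    if_contacts = sum(contact),
    interface_residues = stats::setNames(
      list(a$resno[rowSums(contact) > 0], b$resno[colSums(contact) > 0]),
      names(model$chains)
    )
  )
}

#' pDockQ interface confidence score
#'
#' Sigmoid transform of the product of mean interface plDDT and the log10 of
#' the interface contact count:
#' \deqn{pDockQ = \frac{0.724}{1 + e^{-0.052 (x - 152.611)}} + 0.018, \quad
#'   x = \mathrm{IF\_pLDDT} \cdot \log_{10}(\mathrm{IF\_contacts})}
#' A complex with no interface contacts scores 0 (not the sigmoid baseline).
#' The score is bounded by 0.742.
#'
#' @param if_plddt Mean plDDT over interface residues, in `[0, 100]`.
#' @param if_contacts Number of interface contacts (non-negative integer).
#' @return Numeric pDockQ value(s) in `[0, 0.742]`; vectorized.
#' @export
pdockq <- function(if_plddt, if_contacts) {
  stopifnot(all(if_plddt >= 0 & if_plddt <= 100), all(if_contacts >= 0))
  x <- if_plddt * log10(pmax(if_contacts, 1))
  s <- 0.724 / (1 + exp(-0.052 * (x - 152.611))) + 0.018
  ifelse(if_contacts == 0, 0, s)
}

#' Score a complex model's interface
#'
#' Detects the interface, averages plDDT over the union of interface residues
#' of both chains (each residue counted once), and computes pDockQ.
#'
#' @param model A `complex_model`.
#' @param dist_cutoff Contact distance cutoff in angstroms.
#' @return An object of class `interface_score`: `pair_id`, `if_contacts`,
#'   `if_plddt`, `pdockq`, `interface_residues`.
#' @export
score_complex <- function(model, dist_cutoff = 8.0) {
  iface <- find_interface(model, dist_cutoff)
  res <- iface$interface_residues
  pl <- c(
    model$chains[[1]]$plddt[model$chains[[1]]$resno %in% res[[1]]],
    model$chains[[2]]$plddt[model$chains[[2]]$resno %in% res[[2]]]
  )
  if_plddt <- if (length(pl)) mean(pl) else NA_real_
  structure(list(
    pair_id = model$pair_id,
    if_contacts = iface$if_contacts,
    if_plddt = if_plddt,
    pdockq = if (iface$if_contacts == 0) 0 else pdockq(if_plddt, iface$if_contacts),
    interface_residues = res
  ), class = "interface_score")
}

#' @export
print.interface_score <- function(x, ...) {
  cat(sprintf("%s: IF_contacts = %d, IF_pLDDT = %s, pDockQ = %s\n",
              x$pair_id, x$if_contacts,
              format(round(x$if_plddt, 1)), format(round(x$pdockq, 2))))
  invisible(x)
}

#' Build a cohesin x dockerin interaction matrix
#'
#' @param scores data.frame with columns `coh`, `doc`, `pdockq` (one row per
#'   scored pair; duplicated pairs are an error), or a list of
#'   `interface_score` objects whose `pair_id` is `"<coh>__<doc>"`.
#' @param threshold Prediction threshold; a pair is predicted interacting when
#'   `pdockq > threshold` (strict), default 0.3.
#' @return An object of class `ppi_matrix`: numeric matrix `pdockq`
#'   (rows cohesins, cols dockerins, `NA` where unscored), logical matrix
#'   `predicted`, and `threshold`.
#' @export
build_ppi_matrix <- function(scores, threshold = 0.3) {
  if (!is.data.frame(scores)) {
    scores <- do.call(rbind, lapply(scores, function(s) {
      parts <- strsplit(s$pair_id, "__", fixed = TRUE)[[1]]
      if (length(parts) != 2L) {
        stop("pair_id '", s$pair_id, "' does not decompose as <coh>__<doc>")
      }
      data.frame(coh = parts[1], doc = parts[2], pdockq = s$pdockq,
                 stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("coh", "doc", "pdockq") %in% names(scores)))
  if (anyDuplicated(scores[, c("coh", "doc")])) {
    stop("duplicate cohesin-dockerin pair(s) in scores")
  }
  rows <- unique(scores$coh)
  cols <- unique(scores$doc)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(scores$coh, scores$doc)] <- scores$pdockq
  structure(list(pdockq = m, predicted = !is.na(m) & m > threshold,
                 threshold = threshold),
            class = "ppi_matrix")
}

#' Evaluate a predicted interaction matrix against ground truth
#'
#' Ground truth is partial: only cells labelled `+` or `-` enter the counts;
#' unannotated cells (e.g. a newly discovered dockerin with no binding assay)
#' are excluded from all metrics.
#'
#' @param matrix A `ppi_matrix`.
#' @param truth data.frame with columns `coh`, `doc`, `label` (`"+"`/`"-"`, or
#'   logical).
#' @return A list of class `ppi_eval`: `tp`, `fp`, `fn`, `tn`, `recall`,
#'   `precision`, `f1` (undefined metrics reported as `NA`).
#' @export
evaluate_ppi <- function(matrix, truth) {
  stopifnot(inherits(matrix, "ppi_matrix"),
            all(c("coh", "doc", "label") %in% names(truth)))
  lab <- truth$label
  pos <- if (is.logical(lab)) lab else lab == "+"
  idx <- cbind(match(truth$coh, rownames(matrix$pdockq)),
               match(truth$doc, colnames(matrix$pdockq)))
  if (anyNA(idx)) {
    stop("truth refers to cohesin/dockerin absent from the matrix")
  }
  pred <- matrix$predicted[idx]
  tp <- sum(pred & pos)
  fp <- sum(pred & !pos)
  fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 recall = recall, precision = precision, f1 = f1),
            class = "ppi_eval")
}

#' @export
print.ppi_eval <- function(x, ...) {
  cat(sprintf("PPI evaluation: TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  recall %.2f  precision %.2f  F1 %.2f\n",
              x$recall, x$precision, x$f1))
  invisible(x)
}
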