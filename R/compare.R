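## Polymorph-vs-polymorph comparison: range-restricted superposition RMSD
## and circular torsion-angle differences.

selection_atoms <- function(selection) {
  switch(selection,
         heavy = NULL,                 # all non-hydrogen
         backbone = c("N", "CA", "C", "O"),
         ca = "CA")
}

#' Range-restricted superposition RMSD between two molecules
#'
#' Optimal least-squares rigid superposition (proper rotation, Kabsch) of
#' one molecule onto another over the atoms of `fit_range`, scored as RMSD
#' over the atoms of `score_range`. The two ranges are independent because
#' published comparisons sometimes align over one residue window and
#' report RMSD over a slightly different one. Atoms are paired by residue
#' number and atom name; mismatched residue types are reported and the
#' computation proceeds on the intersection.
#'
#' @param a,b [fibril_model()] objects.
#' @param fit_range length-2 residue range used for the superposition.
#' @param score_range residue range scored (default: `fit_range`).
#' @param selection `"heavy"` (all non-hydrogen, default), `"backbone"`,
#'   or `"ca"`.
#' @param chain_a,chain_b chains compared (default: first chain of each).
#' @param bundle `"first"` uses the first bundle model of each input;
#'   `"all"` averages the RMSD over all bundle-model pairs.
#' @return list of class `superposition_rmsd` with `rmsd` (Angstrom),
#'   `n_fit`, `n_score`, `coverage` (matched fraction of the score range),
#'   `mismatches` (residues whose names differ), and the fitted transform.
#' @export
superpose_rmsd <- function(a, b, fit_range, score_range = fit_range,
                           selection = c("heavy", "backbone", "ca"),
                           chain_a = NULL, chain_b = NULL,
                           bundle = c("first", "all")) {
  selection <- match.arg(selection)
  bundle <- match.arg(bundle)
  if (is.null(chain_a)) chain_a <- chains_of(a)[1]
  if (is.null(chain_b)) chain_b <- chains_of(b)[1]
  ety <- selection_atoms(selection)
  in_range <- function(x, r) x$resno >= min(r) & x$resno <= max(r)

  pair_one <- function(ma, mb) {
    A <- a$atoms[a$atoms$model == ma & a$atoms$chain == chain_a &
                 a$atoms$elesy != "H", , drop = FALSE]
    B <- b$atoms[b$atoms$model == mb & b$atoms$chain == chain_b &
                 b$atoms$elesy != "H", , drop = FALSE]
    if (!is.null(ety)) {
      A <- A[A$elety %in% ety, , drop = FALSE]
      B <- B[B$elety %in% ety, , drop = FALSE]
    }
    keyA <- paste(A$resno, A$elety, sep = "|")
    keyB <- paste(B$resno, B$elety, sep = "|")
    ## report residue-type mismatches over the union of the two ranges
    ra <- unique(A[in_range(A, range(c(fit_range, score_range))), c("resno", "resid")])
    rb <- unique(B[in_range(B, range(c(fit_range, score_range))), c("resno", "resid")])
    mm <- merge(ra, rb, by = "resno", suffixes = c("_a", "_b"))
    mismatches <- mm$resno[mm$resid_a != mm$resid_b]
    common <- intersect(keyA, keyB)
    ia <- match(common, keyA); ib <- match(common, keyB)
    Af <- A[ia, , drop = FALSE]; Bf <- B[ib, , drop = FALSE]
    fit_i <- in_range(Af, fit_range)
    sc_i <- in_range(Af, score_range)
    if (sum(fit_i) < 3) stop("insufficient data: fewer than 3 matched atoms in the fit range",
                             call. = FALSE)
    P <- as.matrix(Af[fit_i, c("x", "y", "z")])
    Q <- as.matrix(Bf[fit_i, c("x", "y", "z")])
    f <- kabsch(P, Q)
    Ps <- as.matrix(Af[sc_i, c("x", "y", "z")])
    Qs <- as.matrix(Bf[sc_i, c("x", "y", "z")])
    Pm <- sweep(Ps %*% t(f$R), 2, f$t, "+")
    n_possible <- length(unique(B$resno[in_range(B, score_range)]))
    list(rmsd = sqrt(mean(rowSums((Pm - Qs)^2))),
         n_fit = sum(fit_i), n_score = sum(sc_i),
         coverage = length(unique(Af$resno[sc_i])) / max(1, n_possible),
         mismatches = mismatches, transform = f)
  }

  if (bundle == "first") {
    res <- pair_one(sort(unique(a$atoms$model))[1], sort(unique(b$atoms$model))[1])
  } else {
    mas <- sort(unique(a$atoms$model)); mbs <- sort(unique(b$atoms$model))
    all <- list()
    for (ma in mas) for (mb in mbs) all[[length(all) + 1L]] <- pair_one(ma, mb)
    res <- all[[1]]
    res$rmsd <- mean(vapply(all, `[[`, numeric(1), "rmsd"))
    res$rmsd_sd <- stats::sd(vapply(all, `[[`, numeric(1), "rmsd"))
  }
  if (length(res$mismatches)) {
    warning("residue types differ at position(s) ",
            paste(res$mismatches, collapse = ", "),
            "; computed on the matched-atom intersection")
  }
  class(res) <- "superposition_rmsd"
  res
}

#' @export
print.superposition_rmsd <- function(x, ...) {
  cat(sprintf("Superposition RMSD: %.3f A over %d atoms (fit on %d atoms, coverage %.0f%%)\n",
              x$rmsd, x$n_score, x$n_fit, 100 * x$coverage))
  invisible(x)
}

#' Per-residue circular torsion differences between two models
#'
#' Bundle-averaged phi/psi angles of each input (circular mean over chains
#' and bundle models per residue) are differenced circularly, so a phi of
#' 179 vs -179 degrees gives 2 degrees, not 358. Residues where the
#' absolute difference exceeds the combined bundle SDs (root sum of
#' squares) are flagged -- the operational meaning of "similar but not
#' identical" torsion angles.
#'
#' @param a,b [fibril_model()] objects.
#' @param range optional residue range restriction.
#' @param min_diff numerical floor (degrees) below which a difference is
#'   never flagged, so that machine-precision wiggle in otherwise identical
#'   zero-SD bundles does not raise flags (default 0.01).
#' @return data.frame with `resno`, `resid`, `dphi`, `dpsi` (degrees in
#'   (-180, 180]), `phi_sd`, `psi_sd` (combined), `phi_flag`, `psi_flag`.
#'   Zero rows when the resolved ranges are disjoint.
#' @export
torsion_difference <- function(a, b, range = NULL, min_diff = 0.01) {
  sa <- torsion_summary(compute_torsions(a), by = "residue")
  sb <- torsion_summary(compute_torsions(b), by = "residue")
  m <- merge(sa, sb, by = "resno", suffixes = c("_a", "_b"))
  if (!is.null(range)) m <- m[m$resno >= min(range) & m$resno <= max(range), ]
  if (!nrow(m)) {
    return(data.frame(resno = integer(), resid = character(),
                      dphi = numeric(), dpsi = numeric(),
                      phi_sd = numeric(), psi_sd = numeric(),
                      phi_flag = logical(), psi_flag = logical()))
  }
  out <- data.frame(
    resno = m$resno, resid = m$resid_a,
    dphi = circular_diff(m$phi_mean_a, m$phi_mean_b),
    dpsi = circular_diff(m$psi_mean_a, m$psi_mean_b),
    phi_sd = sqrt(m$phi_sd_a^2 + m$phi_sd_b^2),
    psi_sd = sqrt(m$psi_sd_a^2 + m$psi_sd_b^2),
    stringsAsFactors = FALSE)
  out$phi_flag <- !is.na(out$dphi) & abs(out$dphi) > pmax(out$phi_sd, min_diff)
  out$psi_flag <- !is.na(out$dpsi) & abs(out$dpsi) > pmax(out$psi_sd, min_diff)
  out[order(out$resno), , drop = FALSE]
}
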