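## Conformational annotation: backbone torsions, beta-strand segments by
## the alternating-sides hydrogen-bond rule, molecular-axis angles,
## inter-subunit contacts and salt bridges.

HYDROPHOBIC_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")
ACIDIC_O_ATOMS <- c("OD1", "OD2", "OE1", "OE2")
BASIC_N_ATOMS <- c("NZ", "NH1", "NH2", "NE")

#' Backbone phi/psi torsion angles of a fibril model
#'
#' Computes standard phi (C-, N, CA, C) and psi (N, CA, C, N+) dihedrals
#' for every residue of every chain and bundle model. Phi is undefined for
#' the first residue of a chain and psi for the last; undefined values are
#' `NA`, never 0. Residues with missing backbone atoms, sequence gaps, or
#' degenerate (collinear) geometry also yield `NA`.
#'
#' @param m a [fibril_model()].
#' @return data.frame of class `torsion_table` with columns `model`,
#'   `chain`, `subunit` (if assigned), `resno`, `resid`, `phi`, `psi`
#'   (degrees in (-180, 180]).
#' @export
compute_torsions <- function(m) {
  out <- list()
  for (k in sort(unique(m$atoms$model))) {
    for (ch in chains_of(m)) {
      a <- m$atoms[m$atoms$model == k & m$atoms$chain == ch, , drop = FALSE]
      res <- sort(unique(a$resno))
      get <- function(rn, ty) {
        r <- a[a$resno == rn & a$elety == ty, , drop = FALSE]
        if (nrow(r) != 1) NULL else as.numeric(r[1, c("x", "y", "z")])
      }
      phi <- psi <- rep(NA_real_, length(res))
      resid <- vapply(res, function(rn) a$resid[a$resno == rn][1], character(1))
      for (ii in seq_along(res)) {
        rn <- res[ii]
        N <- get(rn, "N"); CA <- get(rn, "CA"); C <- get(rn, "C")
        if (is.null(N) || is.null(CA) || is.null(C)) next
        if ((rn - 1) %in% res) {
          Cp <- get(rn - 1, "C")
          if (!is.null(Cp)) phi[ii] <- dihedral(Cp, N, CA, C)
        }
        if ((rn + 1) %in% res) {
          Nn <- get(rn + 1, "N")
          if (!is.null(Nn)) psi[ii] <- dihedral(N, CA, C, Nn)
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        model = k, chain = ch,
        subunit = if (!is.null(m$subunit)) unname(m$subunit[ch]) else NA_character_,
        resno = res, resid = resid, phi = phi, psi = psi,
        stringsAsFactors = FALSE)
    }
  }
  tt <- do.call(rbind, out)
  class(tt) <- c("torsion_table", "data.frame")
  tt
}

#' Bundle summary of a torsion table
#'
#' Circular mean and circular SD of phi and psi per residue, aggregated
#' over bundle models and (by default) over the chains of each subunit.
#'
#' @param tt a `torsion_table` from [compute_torsions()].
#' @param by `"subunit"` (default; falls back to chain when no subunits are
#'   assigned), `"chain"`, or `"residue"` (pool everything per residue).
#' @return data.frame with `group`, `resno`, `resid`, `phi_mean`, `phi_sd`,
#'   `psi_mean`, `psi_sd`, `n`.
#' @export
torsion_summary <- function(tt, by = c("subunit", "chain", "residue")) {
  by <- match.arg(by)
  grp <- switch(by,
                subunit = if (all(is.na(tt$subunit))) tt$chain else tt$subunit,
                chain = tt$chain,
                residue = "all")
  key <- paste(grp, tt$resno, sep = "\r")
  rows <- lapply(split(seq_len(nrow(tt)), key), function(idx) {
    x <- tt[idx, , drop = FALSE]
    data.frame(group = grp[idx[1]], resno = x$resno[1], resid = x$resid[1],
               phi_mean = circular_mean(x$phi), phi_sd = circular_sd(x$phi),
               psi_mean = circular_mean(x$psi), psi_sd = circular_sd(x$psi),
               n = sum(!is.na(x$phi) | !is.na(x$psi)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residues deviating from typical beta-strand torsion angles
#'
#' Flags residues whose bundle-mean phi or psi falls outside the
#' beta-strand windows phi0 +/- halfwidth, psi0 +/- halfwidth (defaults
#' -130 +/- 30 and 130 +/- 30 degrees). Distances are circular so angles
#' near +/-180 are handled correctly, and the window boundary is inclusive
#' (a residue exactly at the edge does not deviate). Residues with
#' undefined torsions are excluded (`NA` in the deviation columns).
#'
#' @param tt a `torsion_table` from [compute_torsions()].
#' @param phi0,psi0 window centers in degrees.
#' @param halfwidth window half-width in degrees.
#' @param by grouping passed to [torsion_summary()].
#' @return the summary table with logical columns `phi_dev`, `psi_dev`,
#'   `deviates`.
#' @export
beta_deviation <- function(tt, phi0 = -130, psi0 = 130, halfwidth = 30,
                           by = "subunit") {
  s <- torsion_summary(tt, by = by)
  s$phi_dev <- abs(circular_diff(s$phi_mean, phi0)) > halfwidth
  s$psi_dev <- abs(circular_diff(s$psi_mean, psi0)) > halfwidth
  s$deviates <- s$phi_dev | s$psi_dev
  s
}

## infer amide H positions for one chain: H on N, 1.01 A along the reversed
## carbonyl direction of the previous residue (trans peptide plane).
infer_amide_h <- function(a) {
  res <- sort(unique(a$resno))
  pos <- function(rn, ty) {
    r <- a[a$resno == rn & a$elety == ty, , drop = FALSE]
    if (nrow(r) != 1) NULL else as.numeric(r[1, c("x", "y", "z")])
  }
  out <- list()
  for (rn in res) {
    if (!((rn - 1) %in% res)) next
    N <- pos(rn, "N"); Cp <- pos(rn - 1, "C"); Op <- pos(rn - 1, "O")
    if (is.null(N) || is.null(Cp) || is.null(Op)) next
    d <- Cp - Op
    if (sqrt(sum(d^2)) < 1e-6) next
    out[[length(out) + 1L]] <- c(rn, N + 1.01 * unit3(d))
  }
  if (!length(out)) return(NULL)
  h <- do.call(rbind, out)
  colnames(h) <- c("resno", "hx", "hy", "hz")
  h
}

#' Inter-chain backbone hydrogen bonds
#'
#' Detects backbone N-H...O=C hydrogen bonds between residues of different
#' chains. Deposited fibril models carry no hydrogens, so the amide H is
#' inferred from backbone geometry (1.01 Angstrom from N, antiparallel to
#' the previous residue's carbonyl). Two criteria are available:
#' \describe{
#'   \item{geometric}{donor N to acceptor O distance <= `dist_cutoff` and
#'     N-H...O angle >= `angle_cutoff` (defaults 3.5 Angstrom, 120 deg).}
#'   \item{dssp}{Kabsch-Sander electrostatic energy below `energy_cutoff`
#'     (default -0.5 kcal/mol), computed from the same inferred H.}
#' }
#' Each bond is labelled with the axial side of the partner chain relative
#' to the donor's chain (+1 above, -1 below along the growth axis).
#'
#' @param m a [fibril_model()]; growth axis is inferred if absent.
#' @param mode `"geometric"` or `"dssp"`.
#' @param dist_cutoff,angle_cutoff geometric-mode cutoffs.
#' @param energy_cutoff dssp-mode cutoff in kcal/mol.
#' @return data.frame with columns `model`, `donor_chain`, `donor_resno`,
#'   `acceptor_chain`, `acceptor_resno`, `dist_NO`, `side`. Empty (zero
#'   rows) for single-chain or pulled-apart models.
#' @export
detect_hbonds <- function(m, mode = c("geometric", "dssp"),
                          dist_cutoff = 3.5, angle_cutoff = 120,
                          energy_cutoff = -0.5) {
  mode <- match.arg(mode)
  if (is.null(m$axis)) m <- infer_layers_and_subunits(m)
  v <- m$axis$v
  ch <- chains_of(m)
  empty <- data.frame(model = integer(), donor_chain = character(),
                      donor_resno = integer(), acceptor_chain = character(),
                      acceptor_resno = integer(), dist_NO = numeric(),
                      side = integer(), stringsAsFactors = FALSE)
  if (length(ch) < 2) return(empty)
  out <- list()
  for (k in sort(unique(m$atoms$model))) {
    ak <- m$atoms[m$atoms$model == k, , drop = FALSE]
    per <- lapply(ch, function(c1) ak[ak$chain == c1, , drop = FALSE])
    names(per) <- ch
    hs <- lapply(per, infer_amide_h)
    cz <- vapply(per, function(a) mean(as.matrix(a[, c("x", "y", "z")]) %*% v), numeric(1))
    for (dc in ch) {
      H <- hs[[dc]]
      if (is.null(H)) next
      ad <- per[[dc]]
      Nxyz <- ad[ad$elety == "N", , drop = FALSE]
      for (ac in ch) {
        if (ac == dc) next
        aa <- per[[ac]]
        O <- aa[aa$elety == "O", , drop = FALSE]
        C <- aa[aa$elety == "C", , drop = FALSE]
        if (!nrow(O)) next
        side <- sign(cz[ac] - cz[dc])
        for (r in seq_len(nrow(H))) {
          rn <- H[r, 1]
          Np <- Nxyz[Nxyz$resno == rn, c("x", "y", "z")]
          if (nrow(Np) != 1) next
          Np <- as.numeric(Np)
          Hp <- H[r, 2:4]
          dno <- sqrt((O$x - Np[1])^2 + (O$y - Np[2])^2 + (O$z - Np[3])^2)
          cand <- which(dno <= max(dist_cutoff, 5.2))
          for (j in cand) {
            Op <- as.numeric(O[j, c("x", "y", "z")])
            keep <- FALSE
            if (mode == "geometric") {
              if (dno[j] <= dist_cutoff) {
                u1 <- Np - Hp; u2 <- Op - Hp
                angle <- acos(min(1, max(-1, sum(u1 * u2) /
                                  (sqrt(sum(u1^2)) * sqrt(sum(u2^2)))))) * 180 / pi
                keep <- angle >= angle_cutoff
              }
            } else {
              Cp <- C[C$resno == O$resno[j], c("x", "y", "z")]
              if (nrow(Cp) == 1) {
                Cp <- as.numeric(Cp)
                rON <- dno[j]
                rOH <- sqrt(sum((Op - Hp)^2))
                rCN <- sqrt(sum((Cp - Np)^2))
                rCH <- sqrt(sum((Cp - Hp)^2))
                E <- 0.084 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN) * 332
                keep <- E < energy_cutoff
              }
            }
            if (keep) {
              out[[length(out) + 1L]] <- data.frame(
                model = k, donor_chain = dc, donor_resno = as.integer(rn),
                acceptor_chain = ac, acceptor_resno = as.integer(O$resno[j]),
                dist_NO = dno[j], side = as.integer(side),
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

## axial side of each residue's carbonyl: sign of (O - C) . axis
carbonyl_sides <- function(m, model = 1) {
  v <- m$axis$v
  a <- m$atoms[m$atoms$model == model, , drop = FALSE]
  out <- list()
  for (ch in unique(a$chain)) {
    ac <- a[a$chain == ch, , drop = FALSE]
    O <- ac[ac$elety == "O", , drop = FALSE]
    C <- ac[ac$elety == "C", , drop = FALSE]
    res <- intersect(O$resno, C$resno)
    if (!length(res)) next
    io <- match(res, O$resno); ic <- match(res, C$resno)
    s <- (O$x[io] - C$x[ic]) * v[1] + (O$y[io] - C$y[ic]) * v[2] +
         (O$z[io] - C$z[ic]) * v[3]
    out[[length(out) + 1L]] <- data.frame(chain = ch, resno = res,
                                          axial = s, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Beta-strand segments by the alternating-sides hydrogen-bond rule
#'
#' A beta-strand segment is a run of at least `min_len` consecutive
#' residues whose backbone amide and carbonyl groups both hydrogen-bond to
#' neighboring chains, with the axial side of the engagement alternating
#' from residue to residue. The side of a residue is the sign of the axial
#' component of its C=O vector, which in a cross-beta sheet points
#' alternately up and down the growth axis.
#'
#' Segments are reported per subunit as the consensus (majority vote) over
#' bundle models and over interior chains -- chains with stacking neighbors
#' on both sides within their subunit -- since boundary chains necessarily
#' lack half of their hydrogen bonds.
#'
#' @param m a [fibril_model()] with (or able to infer) organization.
#' @param hbonds optional precomputed result of [detect_hbonds()].
#' @param min_len minimum segment length in residues (default 3).
#' @param ... further arguments to [detect_hbonds()].
#' @return data.frame of class `strand_segments` with columns `subunit`,
#'   `start`, `end`, `length`; zero rows when no segment qualifies.
#' @export
beta_strand_segments <- function(m, hbonds = NULL, min_len = 3, ...) {
  if (is.null(m$subunit) || is.null(m$axis)) m <- infer_layers_and_subunits(m)
  if (is.null(hbonds)) hbonds <- detect_hbonds(m, ...)
  empty <- data.frame(subunit = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("strand_segments", "data.frame")
  if (!nrow(hbonds)) return(empty)
  models <- sort(unique(m$atoms$model))
  subs <- sort(unique(m$subunit))
  segs <- list()
  for (s in subs) {
    sc <- names(m$subunit)[m$subunit == s]
    lay <- m$layer[sc]
    interior <- sc[lay > min(lay) & lay < max(lay)]
    use <- if (length(interior)) interior else sc
    res_all <- sort(unique(m$atoms$resno[m$atoms$chain %in% sc]))
    nvote <- length(use) * length(models)
    qual <- side <- stats::setNames(numeric(length(res_all)), res_all)
    for (k in models) {
      hb <- hbonds[hbonds$model == k, , drop = FALSE]
      cs <- carbonyl_sides(m, model = k)
      for (ch in use) {
        don <- unique(hb$donor_resno[hb$donor_chain == ch])
        acc <- unique(hb$acceptor_resno[hb$acceptor_chain == ch])
        ok <- intersect(don, acc)
        qual[as.character(ok)] <- qual[as.character(ok)] + 1
        csc <- cs[cs$chain == ch, , drop = FALSE]
        i <- match(csc$resno, res_all)
        side[i[!is.na(i)]] <- side[i[!is.na(i)]] + sign(csc$axial[!is.na(i)])
      }
    }
    is_q <- qual > nvote / 2
    sgn <- sign(side)
    ## maximal runs of consecutive, qualifying, side-alternating residues
    run_start <- NA
    flush <- function(a, b) {
      if (!is.na(a) && (b - a + 1) >= min_len) {
        segs[[length(segs) + 1L]] <<- data.frame(subunit = s, start = a, end = b,
                                                 length = b - a + 1L,
                                                 stringsAsFactors = FALSE)
      }
    }
    prev <- NA
    for (ii in seq_along(res_all)) {
      rn <- res_all[ii]
      ok <- is_q[ii] && sgn[ii] != 0 &&
        (is.na(run_start) ||
           (rn == prev + 1 && sgn[ii] == -sgn[match(prev, res_all)]))
      if (ok && is.na(run_start)) {
        run_start <- rn
      } else if (!ok) {
        flush(run_start, prev)
        run_start <- if (is_q[ii] && sgn[ii] != 0) rn else NA
      }
      prev <- rn
    }
    flush(run_start, prev)
  }
  if (!length(segs)) return(empty)
  out <- do.call(rbind, segs)
  out <- out[order(out$subunit, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("strand_segments", "data.frame")
  out
}

#' Major molecular axis of a subunit
#'
#' The major molecular axis is the direction from the Calpha of the
#' N-terminal residue of the conformationally ordered segment to the
#' Calpha of its C-terminal residue. It is computed per chain and bundle
#' model and averaged over the subunit; the tilt is the angle between the
#' axis vector and the plane perpendicular to the fibril growth axis.
#'
#' @param m a [fibril_model()].
#' @param subunit subunit label (default: first).
#' @param ordered_range length-2 integer vector, first and last ordered
#'   residues (author numbering).
#' @return list with `vector` (mean unit vector), `tilt_deg` (mean absolute
#'   tilt), `length_nm` (mean Calpha-Calpha distance), `n` (chains x models
#'   used).
#' @export
major_axis <- function(m, subunit = NULL, ordered_range) {
  if (is.null(m$subunit)) m <- infer_layers_and_subunits(m)
  if (is.null(subunit)) subunit <- sort(unique(m$subunit))[1]
  v <- m$axis$v
  sc <- names(m$subunit)[m$subunit == subunit]
  vecs <- list(); tilts <- c(); lens <- c()
  for (k in sort(unique(m$atoms$model))) {
    for (ch in sc) {
      a <- m$atoms[m$atoms$model == k & m$atoms$chain == ch & m$atoms$elety == "CA", ]
      p1 <- a[a$resno == ordered_range[1], c("x", "y", "z")]
      p2 <- a[a$resno == ordered_range[2], c("x", "y", "z")]
      if (nrow(p1) != 1 || nrow(p2) != 1) {
        stop("insufficient data: boundary residue ",
             ordered_range[if (nrow(p1) != 1) 1 else 2],
             " missing in chain ", ch, call. = FALSE)
      }
      d <- as.numeric(p2) - as.numeric(p1)
      u <- unit3(d)
      vecs[[length(vecs) + 1L]] <- u
      tilts <- c(tilts, abs(asin(min(1, max(-1, sum(u * v)))) * 180 / pi))
      lens <- c(lens, sqrt(sum(d^2)))
    }
  }
  V <- do.call(rbind, vecs)
  ref <- V[1, ]
  V <- V * ifelse(as.numeric(V %*% ref) < 0, -1, 1)
  list(vector = unit3(colMeans(V)), tilt_deg = mean(tilts),
       length_nm = mean(lens) / 10, n = nrow(V))
}

#' Herringbone angle between the two subunits' major molecular axes
#'
#' Angle between the major molecular axes of the two cross-beta subunits,
#' folded into \[0, 90\] degrees (the axes of symmetry-related subunits are
#' antiparallel up to twice the per-subunit tilt, so the acute
#' representation is reported).
#'
#' @param m a [fibril_model()] with two subunits.
#' @param ordered_range passed to [major_axis()].
#' @return angle in degrees.
#' @export
herringbone_angle <- function(m, ordered_range) {
  if (is.null(m$subunit)) m <- infer_layers_and_subunits(m)
  subs <- sort(unique(m$subunit))
  if (length(subs) < 2) stop("insufficient data: need two subunits", call. = FALSE)
  a <- major_axis(m, subs[1], ordered_range)$vector
  b <- major_axis(m, subs[2], ordered_range)$vector
  ang <- acos(min(1, max(-1, abs(sum(a * b))))) * 180 / pi
  ang
}

#' Inter-subunit residue contact map
#'
#' Residue pairs from the two cross-beta subunits whose minimum sidechain
#' heavy-atom distance (bundle mean of per-model minima) is at most
#' `cutoff`. Pairs are classified `"salt_bridge"` when acidic sidechain
#' oxygens and basic sidechain nitrogens approach within `salt_cutoff`,
#' `"hydrophobic"` when both sidechains are apolar, and `"polar"`
#' otherwise. The map is symmetric in the two subunits.
#'
#' @param m a [fibril_model()] with two subunits assigned or inferable.
#' @param cutoff sidechain heavy-atom distance cutoff in Angstrom
#'   (default 5.0).
#' @param salt_cutoff N-O distance for salt-bridge classification
#'   (default 4.0).
#' @param hydrophobic residue names counted as apolar.
#' @return data.frame of class `contact_map` with columns `resno_a`,
#'   `resid_a`, `resno_b`, `resid_b`, `dist` and `class`; attribute
#'   `cutoff`.
#' @export
contact_map <- function(m, cutoff = 5.0, salt_cutoff = 4.0,
                        hydrophobic = HYDROPHOBIC_RESIDUES) {
  if (is.null(m$subunit)) m <- infer_layers_and_subunits(m)
  subs <- sort(unique(m$subunit))
  if (length(subs) < 2) stop("need two subunits for an inter-subunit contact map", call. = FALSE)
  sc_a <- names(m$subunit)[m$subunit == subs[1]]
  sc_b <- names(m$subunit)[m$subunit == subs[2]]
  side_atoms <- function(k, chs) {
    a <- m$atoms[m$atoms$model == k & m$atoms$chain %in% chs &
                 !(m$atoms$elety %in% BACKBONE_ATOMS) & m$atoms$elesy != "H", ]
    a
  }
  models <- sort(unique(m$atoms$model))
  acc <- list()
  for (k in models) {
    A <- side_atoms(k, sc_a); B <- side_atoms(k, sc_b)
    if (!nrow(A) || !nrow(B)) next
    D <- sqrt(outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2 +
              outer(A$z, B$z, "-")^2)
    near <- which(D <= cutoff + 3, arr.ind = TRUE)   # margin for salt-bridge scan
    if (!nrow(near)) next
    df <- data.frame(resno_a = A$resno[near[, 1]], resid_a = A$resid[near[, 1]],
                     elety_a = A$elety[near[, 1]],
                     resno_b = B$resno[near[, 2]], resid_b = B$resid[near[, 2]],
                     elety_b = B$elety[near[, 2]],
                     d = D[near], model = k, stringsAsFactors = FALSE)
    acc[[length(acc) + 1L]] <- df
  }
  empty <- data.frame(resno_a = integer(), resid_a = character(),
                      resno_b = integer(), resid_b = character(),
                      dist = numeric(), class = character(),
                      stringsAsFactors = FALSE)
  attr(empty, "cutoff") <- cutoff
  class(empty) <- c("contact_map", "data.frame")
  if (!length(acc)) return(empty)
  all <- do.call(rbind, acc)
  key <- paste(all$resno_a, all$resno_b, sep = "-")
  rows <- lapply(split(seq_len(nrow(all)), key), function(idx) {
    x <- all[idx, , drop = FALSE]
    per_model <- tapply(x$d, x$model, min)
    mind <- mean(per_model)
    sb <- x$elety_a %in% ACIDIC_O_ATOMS & x$elety_b %in% BASIC_N_ATOMS |
          x$elety_a %in% BASIC_N_ATOMS & x$elety_b %in% ACIDIC_O_ATOMS
    salt <- any(sb & x$d <= salt_cutoff)
    data.frame(resno_a = x$resno_a[1], resid_a = x$resid_a[1],
               resno_b = x$resno_b[1], resid_b = x$resid_b[1],
               dist = mind,
               class = if (salt) "salt_bridge"
                       else if (x$resid_a[1] %in% hydrophobic &&
                                x$resid_b[1] %in% hydrophobic) "hydrophobic"
                       else "polar",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$dist <= cutoff, , drop = FALSE]
  out <- out[order(out$resno_a, out$resno_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_map", "data.frame")
  out
}

#' Intramolecular salt bridge between two sidechains
#'
#' Minimum distance between the basic sidechain nitrogens of `donor_resno`
#' (default K28, atom NZ) and the acidic sidechain oxygens of
#' `acceptor_resno` (default D23, atoms OD1/OD2) within each chain,
#' averaged over chains and bundle models. The bridge is called present
#' when the bundle-mean minimum distance is at most `cutoff`.
#'
#' @param m a [fibril_model()].
#' @param donor_resno,acceptor_resno author residue numbers.
#' @param cutoff N-O distance cutoff in Angstrom (default 4.0).
#' @return list with `present` (logical, `NA` if sidechain atoms are
#'   missing), `dist` (bundle-mean minimum N-O distance), `per_chain`
#'   (data.frame of per-chain/model minima).
#' @export
salt_bridge <- function(m, donor_resno = 28, acceptor_resno = 23, cutoff = 4.0) {
  rows <- list()
  for (k in sort(unique(m$atoms$model))) {
    for (ch in chains_of(m)) {
      a <- m$atoms[m$atoms$model == k & m$atoms$chain == ch, , drop = FALSE]
      Nn <- a[a$resno == donor_resno & a$elety %in% BASIC_N_ATOMS, , drop = FALSE]
      Oo <- a[a$resno == acceptor_resno & a$elety %in% ACIDIC_O_ATOMS, , drop = FALSE]
      if (!nrow(Nn) || !nrow(Oo)) next
      d <- min(sqrt(outer(Nn$x, Oo$x, "-")^2 + outer(Nn$y, Oo$y, "-")^2 +
                    outer(Nn$z, Oo$z, "-")^2))
      rows[[length(rows) + 1L]] <- data.frame(model = k, chain = ch, dist = d,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("sidechain atoms for the salt bridge are missing; indeterminate")
    return(list(present = NA, dist = NA_real_,
                per_chain = data.frame(model = integer(), chain = character(),
                                       dist = numeric())))
  }
  per <- do.call(rbind, rows)
  md <- mean(per$dist)
  list(present = md <= cutoff, dist = md, per_chain = per)
}
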