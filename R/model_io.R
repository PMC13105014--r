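## Atomic fibril models: reading/writing PDB and mmCIF, organizing chains
## into cross-beta subunits and layers, and recovering helical parameters
## from coordinates.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Fibril model container
#'
#' Holds the atoms of a (possibly multi-model bundle) fibril structure plus
#' the structural organization used throughout the package: which chain
#' belongs to which cross-beta subunit, the layer index of each chain along
#' the growth axis, and the fitted growth axis itself.
#'
#' @param atoms data.frame with columns `model` (integer), `chain`,
#'   `resno` (author numbering), `resid` (3-letter residue name), `elety`
#'   (atom name), `elesy` (element), `x`, `y`, `z` (Angstrom).
#' @param subunit optional named character vector mapping chain id to
#'   subunit label.
#' @param layer optional named integer vector mapping chain id to layer
#'   index (increasing along the growth axis).
#' @param axis optional list with unit vector `v` and point `origin`.
#' @param source optional provenance string.
#' @return object of class `fibril_model`.
#' @export
fibril_model <- function(atoms, subunit = NULL, layer = NULL, axis = NULL,
                         source = NULL) {
  need <- c("model", "chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(atoms)) stop("empty model: no atoms", call. = FALSE)
  structure(list(atoms = atoms, subunit = subunit, layer = layer, axis = axis,
                 bundle_size = length(unique(atoms$model)),
                 source = source),
            class = "fibril_model")
}

#' @export
print.fibril_model <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("Fibril model: %d atoms, %d chain(s), %d bundle model(s)\n",
              sum(x$atoms$model == x$atoms$model[1]), length(ch), x$bundle_size))
  if (!is.null(x$subunit)) {
    cat("  subunits:", paste(sprintf("%s=%s", names(x$subunit), x$subunit),
                             collapse = " "), "\n")
  }
  if (!is.null(x$axis)) {
    cat(sprintf("  growth axis: (%.3f, %.3f, %.3f)\n",
                x$axis$v[1], x$axis$v[2], x$axis$v[3]))
  }
  invisible(x)
}

chains_of <- function(m) unique(m$atoms$chain)

## coordinates of one chain in one bundle model, keyed "resno|elety"
chain_xyz <- function(m, chain, model = 1, elety = NULL, heavy = TRUE) {
  a <- m$atoms[m$atoms$chain == chain & m$atoms$model == model, , drop = FALSE]
  if (heavy) a <- a[a$elesy != "H", , drop = FALSE]
  if (!is.null(elety)) a <- a[a$elety %in% elety, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rownames(xyz) <- paste(a$resno, a$elety, sep = "|")
  xyz
}

## paired coordinates of two chains on their common (resno, elety) keys
matched_xyz <- function(m, chain_a, chain_b, model_a = 1, model_b = model_a,
                        elety = NULL) {
  A <- chain_xyz(m, chain_a, model_a, elety)
  B <- chain_xyz(m, chain_b, model_b, elety)
  keys <- intersect(rownames(A), rownames(B))
  list(A = A[keys, , drop = FALSE], B = B[keys, , drop = FALSE], keys = keys)
}

#' Read an atomic fibril model from PDB or mmCIF
#'
#' Parses the file with bio3d, retaining every model of a multi-model
#' bundle, and returns a [fibril_model()]. Subunit/layer organization and
#' the growth axis are not assumed from the file; call
#' [infer_layers_and_subunits()] next.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @param drop_hydrogens drop hydrogen atoms on input (deposited fibril
#'   models list non-hydrogen atoms only; default TRUE).
#' @return a [fibril_model()].
#' @export
read_fibril_model <- function(path, format = c("auto", "pdb", "cif"),
                              drop_hydrogens = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path) else
      bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", toupper(format),
                             ": ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!nrow(at)) stop("empty model: file contains no ATOM records", call. = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  n_atoms <- nrow(pdb$atom)
  keep <- pdb$atom$type %in% c("ATOM", "HETATM")
  one <- function(k) {
    co <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
    data.frame(model = k, chain = at$chain, resno = at$resno, resid = at$resid,
               elety = at$elety,
               elesy = ifelse(is.na(at$elesy) | at$elesy == "",
                              substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy),
               x = co[, 1], y = co[, 2], z = co[, 3],
               stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, lapply(seq_len(n_models), one))
  if (drop_hydrogens) atoms <- atoms[atoms$elesy != "H", , drop = FALSE]
  if (!nrow(atoms)) stop("empty model after hydrogen removal", call. = FALSE)
  fibril_model(atoms, source = path)
}

#' Write a fibril model to PDB
#'
#' Writes all bundle models (MODEL/ENDMDL records for bundles) through
#' bio3d. Coordinates round-trip at PDB precision (1e-3 Angstrom).
#'
#' @param m a [fibril_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fibril_model <- function(m, path) {
  a1 <- m$atoms[m$atoms$model == sort(unique(m$atoms$model))[1], , drop = FALSE]
  models <- sort(unique(m$atoms$model))
  xyz <- t(vapply(models, function(k) {
    ak <- m$atoms[m$atoms$model == k, , drop = FALSE]
    as.numeric(t(as.matrix(ak[, c("x", "y", "z")])))
  }, numeric(3 * nrow(a1))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a1$resno, resid = a1$resid,
                   eleno = seq_len(nrow(a1)), elety = a1$elety,
                   chain = a1$chain, elesy = a1$elesy)
  invisible(path)
}

## ---- organization ------------------------------------------------------

## union-find components over an adjacency (logical) matrix
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

#' Infer growth axis, layers, and subunits of a fibril model
#'
#' Estimates the fibril growth axis from the screw transforms between
#' equivalent chains (rotation-axis extraction from optimal rigid
#' superpositions), groups chains into cross-beta subunits, and indexes
#' layers by the axial coordinate of chain centroids within each subunit.
#'
#' Chains are assigned to the same subunit when they superpose within
#' `same_rmsd` *and* the rotation relating them is less than 90 degrees --
#' successive layers of one subunit are related by a small screw rotation,
#' whereas the companion subunit is related by a (pseudo-)two-fold.
#' Conformationally inequivalent subunits (C1 polymorphs) fail the RMSD
#' test and separate as well.
#'
#' @param m a [fibril_model()].
#' @param same_rmsd RMSD threshold (Angstrom) under which two chains count
#'   as copies of the same subunit (default 1.0).
#' @return `m` with `subunit`, `layer` and `axis` filled in.
#' @export
infer_layers_and_subunits <- function(m, same_rmsd = 1.0) {
  ch <- chains_of(m)
  if (length(ch) < 2) {
    warning("single-chain model: cannot infer organization; using trivial assignment")
    m$subunit <- stats::setNames("A", ch)
    m$layer <- stats::setNames(1L, ch)
    m$axis <- list(v = c(0, 0, 1), origin = c(0, 0, 0))
    return(m)
  }
  n <- length(ch)
  cent <- t(vapply(ch, function(c1) colMeans(chain_xyz(m, c1)), numeric(3)))
  fits <- vector("list", n * n); dim(fits) <- c(n, n)
  rms <- ang <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    mm <- matched_xyz(m, ch[i], ch[j])
    if (length(mm$keys) < 3) next
    f <- kabsch(mm$A, mm$B)
    sd <- screw_decompose(f$R, f$t)
    fits[[i, j]] <- c(f, sd)
    rms[i, j] <- rms[j, i] <- f$rmsd
    ang[i, j] <- ang[j, i] <- abs(sd$angle_deg)
  }
  adj <- !is.na(rms) & rms < same_rmsd & ang < 90
  diag(adj) <- TRUE
  comp <- graph_components(adj)
  ## stable subunit labels, ordered by first chain id
  first_chain <- vapply(sort(unique(comp)), function(k) min(ch[comp == k]), character(1))
  lab <- LETTERS[order(order(first_chain))]
  subunit <- stats::setNames(lab[comp], ch)

  ## growth axis from within-subunit screw transforms between nearest copies
  axes <- list(); points <- list(); trans <- list()
  for (i in seq_len(n)) {
    same <- which(comp == comp[i] & seq_len(n) != i)
    if (!length(same)) next
    j <- same[which.min(sqrt(rowSums((cent[same, , drop = FALSE] -
                                      matrix(cent[i, ], length(same), 3, byrow = TRUE))^2)))]
    f <- fits[[min(i, j), max(i, j)]]
    if (is.null(f)) next
    if (abs(f$angle_deg) > 0.2) {
      axes[[length(axes) + 1L]] <- f$axis
      points[[length(points) + 1L]] <- f$point
    } else {
      dv <- cent[j, ] - cent[i, ]
      if (sqrt(sum(dv^2)) > 1e-6) trans[[length(trans) + 1L]] <- unit3(dv)
    }
  }
  cand <- if (length(axes)) axes else trans
  if (!length(cand)) {
    v <- c(0, 0, 1)
    origin <- colMeans(cent)
  } else {
    ref <- cand[[1]]
    vs <- t(vapply(cand, function(a) if (sum(a * ref) < 0) -a else a, numeric(3)))
    v <- unit3(colMeans(vs))
    origin <- if (length(points)) colMeans(do.call(rbind, points)) else colMeans(cent)
  }
  ## deterministic orientation
  key <- if (abs(v[3]) > 1e-6) v[3] else if (abs(v[1]) > 1e-6) v[1] else v[2]
  if (key < 0) v <- -v
  m$axis <- list(v = unname(v), origin = unname(origin))

  ## layer index: rank of axial centroid within each subunit
  proj <- as.numeric(cent %*% v)
  layer <- integer(n)
  for (s in unique(subunit)) {
    idx <- which(subunit == s)
    layer[idx] <- rank(proj[idx], ties.method = "first")
  }
  m$subunit <- subunit
  m$layer <- stats::setNames(as.integer(layer), ch)
  m
}

#' Fit helical parameters from a fibril model's coordinates
#'
#' Recovers the helical twist and rise of the best-fit screw transform
#' between successive layers, averaged over layer pairs and bundle models,
#' and classifies the symmetry relating the two cross-beta subunits:
#' \describe{
#'   \item{C2}{subunits superpose and are related by a two-fold about the
#'     axis with no axial offset; twist/rise are the per-layer values.}
#'   \item{pseudo-2_1}{subunits superpose and are related by a ~180-degree
#'     screw with a half-rise offset; the reported twist is the
#'     near-180-degree screw representative whose sign matches the folded
#'     net rotation, and the rise is per screw step.}
#'   \item{C1}{the subunits do not superpose within `c1_rmsd` (ordered-core
#'     RMSD after optimal superposition), or no two-fold relates them; the
#'     repeat contains the inequivalent molecules.}
#' }
#'
#' @param m a [fibril_model()]; organization is inferred if absent.
#' @param c1_rmsd Calpha/heavy-atom RMSD threshold (Angstrom) above which
#'   the two subunits are declared conformationally inequivalent
#'   (default 1.5).
#' @param same_rmsd forwarded to [infer_layers_and_subunits()] when the
#'   organization has to be inferred; raise it for noisy coordinates
#'   (chain copies with independent noise sigma superpose at about
#'   sigma * sqrt(6)).
#' @return a [helical_params()] with attribute `"details"` (per-subunit
#'   twists/rises, inter-subunit transform, RMSD).
#' @export
fit_helical_params <- function(m, c1_rmsd = 1.5, same_rmsd = 1.0) {
  if (is.null(m$subunit) || is.null(m$axis)) {
    m <- infer_layers_and_subunits(m, same_rmsd = same_rmsd)
  }
  v <- m$axis$v
  ch <- chains_of(m)
  models <- sort(unique(m$atoms$model))
  subs <- sort(unique(m$subunit))
  twists <- c(); rises <- c()
  per_sub <- list()
  for (s in subs) {
    sc <- names(m$subunit)[m$subunit == s]
    sc <- sc[order(m$layer[sc])]
    if (length(sc) < 2) next
    tw_s <- c(); ri_s <- c()
    for (k in models) {
      for (i in seq_len(length(sc) - 1)) {
        mm <- matched_xyz(m, sc[i], sc[i + 1], model_a = k)
        if (length(mm$keys) < 3) next
        f <- kabsch(mm$A, mm$B)
        tw_s <- c(tw_s, signed_angle_about(f$R, v))
        ri_s <- c(ri_s, sum(f$t * v))
      }
    }
    twists <- c(twists, tw_s); rises <- c(rises, ri_s)
    per_sub[[s]] <- list(twist = circular_mean(tw_s), rise = mean(ri_s))
  }
  if (!length(twists)) {
    stop("insufficient data: need at least 2 layers in one subunit", call. = FALSE)
  }
  twist_sub <- circular_mean(twists)
  rise_sub <- mean(rises)

  details <- list(per_subunit = per_sub, axis = m$axis)
  if (length(subs) < 2) {
    hp <- helical_params(twist_sub, rise_sub, "C1", molecules_per_repeat = 1L)
    attr(hp, "details") <- details
    return(hp)
  }

  ## inter-subunit transform between layer-matched chains (bundle model 1)
  a_ch <- names(m$subunit)[m$subunit == subs[1]]
  b_ch <- names(m$subunit)[m$subunit == subs[2]]
  a1 <- a_ch[which.min(m$layer[a_ch])]
  b1 <- b_ch[which.min(m$layer[b_ch])]
  mm <- matched_xyz(m, a1, b1)
  ab <- if (length(mm$keys) >= 3) kabsch(mm$A, mm$B) else NULL
  if (is.null(ab) || ab$rmsd > c1_rmsd) {
    details$inter_subunit_rmsd <- if (is.null(ab)) NA_real_ else ab$rmsd
    hp <- helical_params(twist_sub, rise_sub, "C1", molecules_per_repeat = 2L)
    attr(hp, "details") <- details
    return(hp)
  }
  theta <- signed_angle_about(ab$R, v)
  delta <- sum(ab$t * v)
  details$inter_subunit_rmsd <- ab$rmsd
  details$inter_subunit_angle <- theta
  details$inter_subunit_offset <- delta
  twofold <- min(abs(theta - 180), abs(theta + 180)) < 30
  if (twofold && abs(delta) < 0.25 * abs(rise_sub)) {
    hp <- helical_params(twist_sub, rise_sub, "C2", molecules_per_repeat = 2L)
  } else if (twofold && abs(abs(delta) - abs(rise_sub) / 2) < 0.25 * abs(rise_sub)) {
    f <- fold_twist(theta)                      # net rotation per screw step
    screw_twist <- if (f > 0) f + 180 else f - 180
    hp <- helical_params(screw_twist, (abs(delta) + abs(rise_sub) / 2) / 2,
                         "pseudo-21", molecules_per_repeat = 1L)
  } else {
    hp <- helical_params(twist_sub, rise_sub, "C1", molecules_per_repeat = 2L)
  }
  attr(hp, "details") <- details
  hp
}
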