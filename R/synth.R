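## Synthetic cross-beta fibril generator: idealized in-register stacks with
## known twist, rise, symmetry, tilt, strand layout and noise, plus
## projected width profiles for cross-over measurement.

AB40_SEQ3 <- c("ASP", "ALA", "GLU", "PHE", "ARG", "HIS", "ASP", "SER", "GLY",
               "TYR", "GLU", "VAL", "HIS", "HIS", "GLN", "LYS", "LEU", "VAL",
               "PHE", "PHE", "ALA", "GLU", "ASP", "VAL", "GLY", "SER", "ASN",
               "LYS", "GLY", "ALA", "ILE", "ILE", "GLY", "LEU", "MET", "VAL",
               "GLY", "GLY", "VAL", "VAL")

#' Built-in U-shaped 40-residue trace
#'
#' Calpha trace of a planar, U-shaped 40-residue peptide layer: an extended
#' strand (residues 1-22), a turn at residues 23-29, and a returning strand
#' (30-40) facing the first across ~9.6 Angstrom, mimicking the U-shaped
#' in-register folds of amyloid-beta fibril cores. Purely synthetic
#' idealized coordinates.
#'
#' @return list with `trace` (40 x 2 matrix of in-plane Calpha positions,
#'   Angstrom) and `sequence` (3-letter residue names of Abeta40).
#' @export
template_u40 <- function() {
  n <- 40
  q <- matrix(NA_real_, n, 2)
  for (i in 1:22) q[i, ] <- c((i - 1) * 3.8, 0)
  ctr <- c(21 * 3.8, 4.8)
  for (i in 23:29) {
    th <- (-90 + (i - 22) * 22.5) * pi / 180
    q[i, ] <- ctr + 4.8 * c(cos(th), sin(th))
  }
  for (i in 30:40) q[i, ] <- c(21 * 3.8 - (i - 30) * 3.8, 9.6)
  list(trace = q, sequence = AB40_SEQ3)
}

#' Specification of a synthetic fibril
#'
#' Declares the geometry of an idealized in-register cross-beta fibril:
#' the per-layer template (built-in U-shaped 40-residue trace, or a
#' user-supplied n x 2 Calpha trace), the helical twist and rise per
#' repeat, the symmetry class, the number of layers per subunit, a
#' per-subunit tilt of the molecular plane, the residue intervals designed
#' as hydrogen-bonded strands, and Gaussian coordinate noise.
#'
#' @param twist degrees per helical repeat (signed; use a near +/-180 value
#'   for pseudo-2_1 screws).
#' @param rise Angstrom per helical repeat.
#' @param symmetry `"C1"`, `"C2"`, or `"pseudo-21"`.
#' @param n_layers layers per subunit (>= 1; total chains are `2*n_layers`
#'   for two-subunit fibrils).
#' @param tilt_deg tilt of the molecular plane so that the major molecular
#'   axis makes this angle with the plane perpendicular to the growth axis.
#' @param strand_plan list of length-2 integer vectors: residue intervals
#'   designed as cross-beta strands (each of length >= 3). Residues outside
#'   the plan get in-plane carbonyls and do not hydrogen bond axially.
#' @param noise_sigma Gaussian coordinate noise SD in Angstrom.
#' @param seed integer seed controlling the noise draws.
#' @param template `"u40"` or an n x 2 matrix of Calpha positions.
#' @param offset lateral offset (Angstrom) of the template centroid from
#'   the fibril axis (default 7; use 0 to center the molecule on the axis).
#' @param atoms `"full"` (backbone + CB + K28/D23 charged tips),
#'   `"backbone"` (N, CA, C, O), or `"ca"`.
#' @param n_subunits 2 (default) or 1 (single protofilament stack; C1 only).
#' @param salt_dist designed K28 NZ to D23 OD1 distance in Angstrom
#'   (default 3.3; only with the built-in template and `atoms = "full"`).
#' @param c1_perturb_deg conformational perturbation (rotation of the
#'   C-terminal strand, degrees) applied to the second subunit of C1
#'   fibrils to make the subunits inequivalent.
#' @return object of class `fibril_spec`.
#' @export
fibril_spec <- function(twist, rise, symmetry = "C2", n_layers = 3,
                        tilt_deg = 0,
                        strand_plan = list(c(14, 22), c(30, 36)),
                        noise_sigma = 0, seed = 1L,
                        template = "u40", offset = 7,
                        atoms = c("full", "backbone", "ca"),
                        n_subunits = 2L, salt_dist = 3.3,
                        c1_perturb_deg = 18) {
  atoms <- match.arg(atoms)
  symmetry <- normalize_symmetry(symmetry)
  if (!is.finite(twist) || !is.finite(rise) || rise <= 0) {
    stop("twist must be finite and rise positive", call. = FALSE)
  }
  n_subunits <- as.integer(n_subunits)
  if (!n_subunits %in% c(1L, 2L)) stop("n_subunits must be 1 or 2", call. = FALSE)
  if (n_subunits == 1L && symmetry != "C1") {
    stop("a single-subunit stack is only meaningful with C1 symmetry", call. = FALSE)
  }
  if (is.character(template)) {
    template <- match.arg(template, "u40")
    tpl <- template_u40()
  } else {
    template <- as.matrix(template)
    if (ncol(template) != 2) stop("a custom template must be an n x 2 Calpha trace", call. = FALSE)
    tpl <- list(trace = template,
                sequence = rep("ALA", nrow(template)))
  }
  n_res <- nrow(tpl$trace)
  for (iv in strand_plan) {
    if (length(iv) != 2 || iv[2] - iv[1] + 1 < 3) {
      stop("each designed strand interval needs length >= 3", call. = FALSE)
    }
    if (iv[1] < 2 || iv[2] > n_res) {
      stop("strand intervals must lie within residues 2..", n_res,
           " (the first residue has no amide hydrogen to donate)", call. = FALSE)
    }
  }
  structure(list(twist = twist, rise = rise, symmetry = symmetry,
                 n_layers = as.integer(n_layers), tilt_deg = tilt_deg,
                 strand_plan = strand_plan, noise_sigma = noise_sigma,
                 seed = as.integer(seed), template = tpl, offset = offset,
                 atoms = atoms, n_subunits = n_subunits,
                 salt_dist = salt_dist, c1_perturb_deg = c1_perturb_deg),
            class = "fibril_spec")
}

## Build one flat reference layer (z ~ 0) from a Calpha trace.
## Strand residues get axially alternating carbonyls and a pleated amide
## nitrogen so that stacked copies at ~4.7 A rise hydrogen bond with the
## cross-beta up/down alternation; non-strand residues get in-plane
## carbonyls and stay out of axial H-bond register.
build_layer <- function(spec) {
  q <- spec$template$trace
  sq <- spec$template$sequence
  n <- nrow(q)
  ## the amide pucker extends one residue past the strand end so that the
  ## last strand carbonyl still finds a donor in the adjacent layer
  in_plan <- function(i) any(vapply(spec$strand_plan,
                                    function(iv) i >= iv[1] && i <= iv[2] + 1, logical(1)))
  axial_o <- function(i) any(vapply(spec$strand_plan,
                                    function(iv) i >= iv[1] - 1 && i <= iv[2], logical(1)))
  rows <- list()
  add <- function(i, ty, el, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      resno = as.integer(i), resid = sq[i], elety = ty, elesy = el,
      x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    tfw <- if (i < n) q[i + 1, ] - q[i, ] else q[i, ] - q[i - 1, ]
    tbk <- if (i > 1) q[i, ] - q[i - 1, ] else tfw
    th <- tfw / sqrt(sum(tfw^2))
    tb <- tbk / sqrt(sum(tbk^2))
    nh <- c(-th[2], th[1])
    s <- if (i %% 2 == 0) 1 else -1
    ca <- c(q[i, ] + 0.45 * s * nh, 0)
    add(i, "CA", "C", ca)
    if (spec$atoms == "ca") next
    npos <- c(q[i, ] - 1.45 * tb, if (in_plan(i)) 0.5 * s else 0)
    add(i, "N", "N", npos)
    cpos <- c(q[i, ] + 1.52 * th, 0)
    add(i, "C", "C", cpos)
    o <- if (axial_o(i)) cpos + c(0, 0, 1.23 * s) else c(cpos[1:2] + 1.23 * nh, 0)
    add(i, "O", "O", o)
    if (spec$atoms == "full" && sq[i] != "GLY") {
      add(i, "CB", "C", c(q[i, ] - 1.1 * s * nh, -0.9 * s))
    }
  }
  ## designed K28-D23 salt bridge across the turn (built-in template only)
  if (spec$atoms == "full" && n >= 28 && sq[23] == "ASP" && sq[28] == "LYS") {
    u <- q[28, ] - q[23, ]; u <- u / sqrt(sum(u^2))
    od1 <- c(q[23, ] + 2.0 * u, 0.3)
    add(23, "OD1", "O", od1)
    add(23, "OD2", "O", od1 + c(1.1 * c(-u[2], u[1]), 0))
    add(28, "NZ", "N", od1 + c(spec$salt_dist * u, 0))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$resno), , drop = FALSE]
  df
}

## rotate the layer so the major molecular axis tilts out of the xy plane
apply_tilt <- function(xyz, tilt_deg, trace) {
  if (abs(tilt_deg) < 1e-12) return(xyz)
  mdir <- c(trace[nrow(trace), ] - trace[1, ], 0)
  u <- cross3(c(0, 0, 1), unit3(mdir))      # in-plane axis perpendicular to m
  ctr <- c(colMeans(trace), 0)
  R <- rot_about_axis(u, tilt_deg)
  sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
}

chain_ids <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else sprintf("c%03d", seq_len(n))
}

#' Generate a synthetic cross-beta fibril model
#'
#' Places copies of the reference layer with the screw/rotation operators
#' implied by the spec's symmetry: successive near-180-degree screw steps
#' for pseudo-2_1, per-layer screws plus the exact two-fold for C2, and
#' two (optionally conformationally inequivalent) stacks for C1. Designed
#' strand residues carry axially alternating carbonyls whose inter-layer
#' N...O distances support backbone hydrogen bonds; turn residues are out
#' of axial register. Deterministic for a fixed seed.
#'
#' @param spec a [fibril_spec()].
#' @return a [fibril_model()] with subunit, layer and axis assignments from
#'   the construction (ground truth); attribute `"spec"` holds the spec.
#' @export
generate_fibril <- function(spec) {
  stopifnot(inherits(spec, "fibril_spec"))
  layer0 <- build_layer(spec)
  xyz0 <- as.matrix(layer0[, c("x", "y", "z")])
  xyz0 <- apply_tilt(xyz0, spec$tilt_deg, spec$template$trace)
  ## center the trace and offset from the axis along +y
  ctr <- c(colMeans(spec$template$trace), 0)
  xyz0 <- sweep(xyz0, 2, ctr)
  xyz0 <- sweep(xyz0, 2, c(0, spec$offset, 0), "+")

  place <- list()  # list of (xyz, subunit, layer)
  if (spec$symmetry == "pseudo-21") {
    for (j in seq_len(2L * spec$n_layers) - 1L) {
      R <- rot_z(j * spec$twist)
      place[[length(place) + 1L]] <- list(
        xyz = sweep(xyz0 %*% t(R), 2, c(0, 0, j * spec$rise), "+"),
        subunit = if (j %% 2L == 0L) "A" else "B",
        layer = j %/% 2L + 1L)
    }
  } else if (spec$symmetry == "C2") {
    for (k in seq_len(spec$n_layers) - 1L) {
      for (su in c("A", "B")) {
        ang <- k * spec$twist + if (su == "B") 180 else 0
        R <- rot_z(ang)
        place[[length(place) + 1L]] <- list(
          xyz = sweep(xyz0 %*% t(R), 2, c(0, 0, k * spec$rise), "+"),
          subunit = su, layer = k + 1L)
      }
    }
  } else { # C1
    xyzB <- NULL
    if (spec$n_subunits == 2L) {
      ## inequivalent companion subunit: same trace with the returning
      ## strand rotated in-plane, then the pseudo two-fold placement
      trB <- spec$template$trace
      mid <- 0.5 * (trB[min(28, nrow(trB)), ] + trB[max(1, nrow(trB) - 10), ])
      Rp <- matrix(c(cos(spec$c1_perturb_deg * pi / 180),
                     -sin(spec$c1_perturb_deg * pi / 180),
                     sin(spec$c1_perturb_deg * pi / 180),
                     cos(spec$c1_perturb_deg * pi / 180)), 2, 2, byrow = TRUE)
      half <- seq_len(nrow(trB)) > ceiling(nrow(trB) * 0.6)
      trB[half, ] <- sweep(sweep(trB[half, , drop = FALSE], 2, mid) %*% t(Rp), 2, mid, "+")
      specB <- spec; specB$template$trace <- trB
      layerB <- build_layer(specB)
      xyzB <- as.matrix(layerB[, c("x", "y", "z")])
      xyzB <- apply_tilt(xyzB, spec$tilt_deg, trB)
      xyzB <- sweep(xyzB, 2, c(colMeans(trB), 0))
      xyzB <- sweep(xyzB, 2, c(0, spec$offset, 0), "+")
      xyzB <- xyzB %*% t(rot_z(180))
    }
    for (k in seq_len(spec$n_layers) - 1L) {
      R <- rot_z(k * spec$twist)
      place[[length(place) + 1L]] <- list(
        xyz = sweep(xyz0 %*% t(R), 2, c(0, 0, k * spec$rise), "+"),
        subunit = "A", layer = k + 1L)
      if (!is.null(xyzB)) {
        place[[length(place) + 1L]] <- list(
          xyz = sweep(xyzB %*% t(rot_z(k * spec$twist + spec$twist / 2)), 2,
                      c(0, 0, (k + 0.5) * spec$rise), "+"),
          subunit = "B", layer = k + 1L)
      }
    }
  }

  ids <- chain_ids(length(place))
  atoms <- do.call(rbind, lapply(seq_along(place), function(i) {
    df <- layer0[, c("resno", "resid", "elety", "elesy")]
    if (spec$symmetry == "C1" && place[[i]]$subunit == "B") {
      ## subunit B of C1 fibrils shares atom composition with the template
      df <- df
    }
    cbind(data.frame(model = 1L, chain = ids[i], stringsAsFactors = FALSE),
          df,
          as.data.frame(place[[i]]$xyz) |> stats::setNames(c("x", "y", "z")))
  }))
  if (spec$noise_sigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, spec$noise_sigma)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, spec$noise_sigma)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, spec$noise_sigma)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  subunit <- stats::setNames(vapply(place, `[[`, character(1), "subunit"), ids)
  layer <- stats::setNames(vapply(place, function(p) as.integer(p$layer), integer(1)), ids)
  m <- fibril_model(atoms, subunit = subunit, layer = layer,
                    axis = list(v = c(0, 0, 1), origin = c(0, 0, 0)),
                    source = "synthetic")
  attr(m, "spec") <- spec
  m
}

#' Projected width profile and cross-over measurement
#'
#' Projects the model onto a plane containing the growth axis and measures
#' the apparent width (transverse extent) as a function of axial position,
#' the analogue of the width modulation of twisted fibrils in electron
#' microscope images. Local minima of the smoothed profile are detected
#' and their mean spacing is the measured cross-over distance.
#'
#' @param m a [fibril_model()] (axis inferred if absent).
#' @param bin_A axial bin width in Angstrom (default 4).
#' @param smooth_bins running-mean window in bins (odd; default 9).
#' @param min_prominence minimum depth of a minimum relative to the
#'   profile's full modulation range (default 0.1) -- suppresses noise
#'   minima on untwisted profiles.
#' @param direction optional transverse unit vector along which width is
#'   measured; default: a fixed direction perpendicular to the axis.
#' @return list of class `width_profile` with `profile` (data.frame
#'   `z_A`, `width_A`, `smooth_A`), `minima_z_A`, `spacing_nm` (`NA` and
#'   `untwisted = TRUE` when no modulation is found).
#' @export
width_profile <- function(m, bin_A = 4, smooth_bins = 9,
                          min_prominence = 0.1, direction = NULL) {
  if (is.null(m$axis)) m <- infer_layers_and_subunits(m)
  v <- m$axis$v
  if (is.null(direction)) {
    ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- unit3(cross3(v, ref))
  } else {
    u <- unit3(direction)
  }
  a1 <- m$atoms[m$atoms$model == sort(unique(m$atoms$model))[1], , drop = FALSE]
  xyz <- as.matrix(a1[, c("x", "y", "z")])
  z <- as.numeric(xyz %*% v); z <- z - min(z)
  w <- as.numeric(xyz %*% u)
  nb <- max(3L, ceiling(max(z) / bin_A))
  bin <- factor(pmin(nb, floor(z / bin_A) + 1L), levels = seq_len(nb))
  wmax <- tapply(w, bin, max); wmin <- tapply(w, bin, min)
  zc <- (seq_len(nb) - 0.5) * bin_A
  width <- as.numeric(wmax - wmin)
  keep <- is.finite(width)
  zc <- zc[keep]; width <- width[keep]
  ## centered running mean
  k <- max(1L, smooth_bins %/% 2L)
  sm <- vapply(seq_along(width), function(i) {
    mean(width[max(1, i - k):min(length(width), i + k)], na.rm = TRUE)
  }, numeric(1))
  prof <- data.frame(z_A = zc, width_A = width, smooth_A = sm)
  rng <- max(sm, na.rm = TRUE) - min(sm, na.rm = TRUE)
  minima <- c()
  if (rng > 1e-9) {
    for (i in seq(2, length(sm) - 1)) {
      if (sm[i] <= sm[i - 1] && sm[i] < sm[i + 1]) {
        ## prominence: rise to the lower of the two flanking maxima
        lmax <- max(sm[1:i]); rmax <- max(sm[i:length(sm)])
        if (min(lmax, rmax) - sm[i] >= min_prominence * rng) {
          minima <- c(minima, zc[i])
        }
      }
    }
  }
  spacing <- if (length(minima) >= 2) mean(diff(minima)) / 10 else NA_real_
  out <- list(profile = prof, minima_z_A = minima, spacing_nm = spacing,
              untwisted = length(minima) < 2)
  class(out) <- "width_profile"
  out
}

#' @export
print.width_profile <- function(x, ...) {
  if (x$untwisted) {
    cat("Width profile: no periodic width minima (apparently untwisted)\n")
  } else {
    cat(sprintf("Width profile: %d minima, mean spacing %.1f nm\n",
                length(x$minima_z_A), x$spacing_nm))
  }
  invisible(x)
}

#' Build a peptide backbone from torsion angles
#'
#' Constructs N-CA-C(-O) backbone coordinates for a chain with specified
#' phi/psi (and omega) torsions and ideal bond geometry, by sequential
#' internal-to-Cartesian placement. Useful as ground truth for torsion
#' computations: the recomputed dihedrals equal the inputs to machine
#' precision.
#'
#' @param phi,psi torsion angles in degrees, one per residue; `phi[1]` and
#'   `psi[n]` are unused (undefined at chain ends).
#' @param omega peptide-bond torsions (degrees), recycled (default 180).
#' @param chain chain id for the output.
#' @return a [fibril_model()] with one chain of poly-alanine backbone.
#' @export
build_chain_from_torsions <- function(phi, psi, omega = 180, chain = "A") {
  n <- length(phi)
  stopifnot(length(psi) == n)
  omega <- rep_len(omega, n)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329
  a_NCAC <- 111.0; a_CACN <- 116.6; a_CNCA <- 121.7
  place <- function(p1, p2, p3, bond, angle, tors) {
    ## NeRF: position a 4th atom given bond length, bond angle, torsion
    th <- angle * pi / 180; ph <- tors * pi / 180
    d <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
    bc <- unit3(p3 - p2)
    nv <- unit3(cross3(p2 - p1, bc))
    M <- cbind(bc, cross3(nv, bc), nv)
    as.numeric(M %*% d + p3)
  }
  coords <- list()
  ## seed residue 1
  N1 <- c(0, 0, 0)
  CA1 <- c(b_NCA, 0, 0)
  C1 <- CA1 + b_CAC * c(cos((180 - a_NCAC) * pi / 180),
                        sin((180 - a_NCAC) * pi / 180), 0)
  coords[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n - 1)) {
    prev <- coords[[i]]
    Np <- place(prev$N, prev$CA, prev$C, b_CN, a_CACN, psi[i])
    CAp <- place(prev$CA, prev$C, Np, b_NCA, a_CNCA, omega[i])
    Cp <- place(prev$C, Np, CAp, b_CAC, a_NCAC, phi[i + 1])
    coords[[i + 1]] <- list(N = Np, CA = CAp, C = Cp)
  }
  rows <- list()
  for (i in seq_len(n)) {
    for (ty in c("N", "CA", "C")) {
      p <- coords[[i]][[ty]]
      rows[[length(rows) + 1L]] <- data.frame(
        model = 1L, chain = chain, resno = i, resid = "ALA",
        elety = ty, elesy = substr(ty, 1, 1),
        x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
    }
  }
  fibril_model(do.call(rbind, rows), source = "torsion-built")
}
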