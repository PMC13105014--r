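## Helical-symmetry algebra: twist/rise <-> cross-over distance, symmetry
## operators, and polymorph parameter tables.

.sym_levels <- c("C1", "C2", "pseudo-21")

normalize_symmetry <- function(x) {
  s <- tolower(gsub("[ _]", "", as.character(x)))
  out <- ifelse(s %in% c("c1"), "C1",
         ifelse(s %in% c("c2"), "C2",
         ifelse(s %in% c("pseudo-21", "pseudo21", "quasi-21", "quasi21",
                         "pseudo-2-1", "21screw", "p21"), "pseudo-21",
                NA_character_)))
  if (anyNA(out)) {
    stop("unknown symmetry label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected C1, C2 or pseudo-21)", call. = FALSE)
  }
  out
}

#' Helical parameters of a fibril polymorph
#'
#' Container for the refined helical symmetry of one cross-beta fibril
#' polymorph: the signed twist and rise per helical repeat, the symmetry
#' class relating the two cross-beta subunits, and the twist handedness.
#' The sign of `twist` is stored verbatim from the deposition and never
#' used to infer handedness (depositions mix sign conventions for
#' near-180-degree screws); all morphology math uses the folded net twist,
#' see [fold_twist()].
#'
#' @param twist signed helical twist in degrees per repeat.
#' @param rise helical rise in Angstrom per repeat (> 0).
#' @param symmetry one of `"C1"`, `"C2"`, `"pseudo-21"` (synonyms such as
#'   `"quasi-21"` are accepted).
#' @param molecules_per_repeat positive integer; 1 for a single molecule per
#'   screw repeat (pseudo-2_1), 2 for C2 pairs or for a C1 repeat containing
#'   two inequivalent molecules.
#' @param handedness `"left"`, `"right"` or `"undetermined"`; metadata only.
#' @param crossover_nm optional observed cross-over distance in nm.
#' @return an object of class `helical_params`.
#' @examples
#' hp <- helical_params(-181.75, 2.34, "pseudo-21", handedness = "right")
#' crossover_distance(hp)
#' @export
helical_params <- function(twist, rise, symmetry,
                           molecules_per_repeat = NULL,
                           handedness = c("undetermined", "left", "right"),
                           crossover_nm = NULL) {
  if (!is.finite(twist)) stop("twist must be finite", call. = FALSE)
  if (!is.finite(rise) || rise <= 0) stop("rise must be a positive length in Angstrom", call. = FALSE)
  symmetry <- normalize_symmetry(symmetry)
  handedness <- match.arg(handedness)
  if (is.null(molecules_per_repeat)) {
    molecules_per_repeat <- switch(symmetry, C1 = 1L, C2 = 2L, `pseudo-21` = 1L)
  }
  molecules_per_repeat <- as.integer(molecules_per_repeat)
  if (molecules_per_repeat < 1L) stop("molecules_per_repeat must be >= 1", call. = FALSE)
  structure(list(twist = twist, rise = rise, symmetry = symmetry,
                 molecules_per_repeat = molecules_per_repeat,
                 handedness = handedness, crossover_nm = crossover_nm),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  d <- crossover_distance(x)
  cat(sprintf("Helical parameters: twist %.4g deg / rise %.4g A, %s, %s-handed\n",
              x$twist, x$rise, x$symmetry, x$handedness))
  cat(sprintf("  net cross-section rotation %.4g deg/repeat; cross-over %s\n",
              fold_twist(x$twist),
              if (is.infinite(d)) "infinite (untwisted)" else sprintf("%.2f nm (~%d nm)", d, round(d))))
  invisible(x)
}

#' Fold a helical twist to its net cross-section rotation
#'
#' Reduces a per-repeat twist modulo 180 degrees into the half-open interval
#' (-90, 90]. A pseudo-2_1 screw twist near +/-180 degrees thereby maps to
#' the small net rotation of the fibril cross-section per repeat (e.g.
#' -181.75 -> -1.75), and a pure 2_1 screw (+/-180) maps to exactly 0.
#' Idempotent; the result drives all cross-over morphology math.
#'
#' @param twist signed twist in degrees (vectorized).
#' @return folded twist in degrees, in (-90, 90].
#' @examples
#' fold_twist(c(-181.75, 179.53, 180))
#' @export
fold_twist <- function(twist) {
  if (!is.numeric(twist) || !all(is.finite(twist))) {
    stop("twist must be finite numeric", call. = FALSE)
  }
  r <- ((twist + 90) %% 180) - 90
  r[r == -90] <- 90
  r
}

#' Cross-over distance from helical parameters
#'
#' The cross-over distance is the axial distance over which the fibril
#' cross-section rotates by 180 degrees -- the spacing between apparent
#' width minima of a twisted fibril in projection. It equals
#' `rise * 180 / |fold_twist(twist)|`, converted from Angstrom to nm.
#' An untwisted fibril (folded twist exactly 0) has an infinite cross-over
#' and returns `Inf` rather than an error.
#'
#' @param twist signed twist in degrees per repeat, or a [helical_params()]
#'   object (then `rise` is ignored).
#' @param rise rise in Angstrom per repeat.
#' @return cross-over distance in nm (vectorized); `Inf` where untwisted.
#' @examples
#' crossover_distance(-181.75, 2.34)  # ~24.07 nm
#' crossover_distance(-5.24, 9.40)    # ~32.3 nm
#' @export
crossover_distance <- function(twist, rise = NULL) {
  if (inherits(twist, "helical_params")) {
    rise <- twist$rise
    twist <- twist$twist
  }
  if (is.null(rise)) stop("rise is required", call. = FALSE)
  if (!all(is.finite(rise)) || any(rise <= 0)) {
    stop("rise must be positive and finite", call. = FALSE)
  }
  f <- abs(fold_twist(twist))
  ifelse(f == 0, Inf, rise * 180 / f / 10)
}

#' Twist implied by a cross-over distance
#'
#' Inverse of [crossover_distance()]: the per-repeat twist whose folded
#' magnitude is `rise * 180 / (10 d)`. With `screw = TRUE` the returned
#' twist is offset by -180 degrees, i.e. a pseudo-2_1 screw representative.
#' Infinite `d` returns 0 (or -180 for a screw).
#'
#' @param d cross-over distance in nm (> 0, may be `Inf`).
#' @param rise rise in Angstrom per repeat (> 0).
#' @param screw logical; return a near-180-degree screw representative.
#' @param sign sign of the folded net rotation (+1 or -1; default -1, the
#'   convention of most left-handed depositions).
#' @return twist in degrees.
#' @examples
#' twist_from_crossover(24.07, 2.34, screw = TRUE)   # ~ -181.75
#' twist_from_crossover(23.78, 4.69)                 # ~ -3.55
#' @export
twist_from_crossover <- function(d, rise, screw = FALSE, sign = -1) {
  if (!all(is.finite(rise)) || any(rise <= 0)) stop("rise must be positive", call. = FALSE)
  if (any(is.na(d)) || any(d <= 0)) stop("cross-over distance must be positive", call. = FALSE)
  sign <- ifelse(sign >= 0, 1, -1)
  mag <- ifelse(is.infinite(d), 0, rise * 180 / (10 * d))
  if (any(mag > 90)) stop("cross-over shorter than one repeat allows; no folded twist exists", call. = FALSE)
  tw <- sign * mag
  if (screw) tw <- tw - 180 else tw
}

#' Rigid symmetry operators of a helical fibril segment
#'
#' Generates the rigid transforms (rotation about the growth axis, taken as
#' z, plus axial translation) mapping a reference molecule onto every
#' molecule of an `n_layers` segment, according to the symmetry class:
#' \describe{
#'   \item{C1}{one screw operator per repeat: `k = 0 .. n_layers-1` steps of
#'     (twist, rise).}
#'   \item{C2}{screw steps combined with the exact 2-fold rotation about the
#'     axis (zero translation).}
#'   \item{pseudo-21}{successive applications of the near-180-degree screw,
#'     two molecules (one per subunit) per repeat pair.}
#' }
#' The identity is included. Operators are closed under composition with
#' the generating screw.
#'
#' @param p a [helical_params()] object.
#' @param n_layers number of layers (repeats) in the segment, >= 1.
#' @return list of transforms, each a list with `R` (3x3), `t` (length 3),
#'   `angle_deg`, `translation`, `subunit` ("A"/"B").
#' @export
symmetry_operators <- function(p, n_layers) {
  stopifnot(inherits(p, "helical_params"))
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L) stop("n_layers must be >= 1", call. = FALSE)
  mk <- function(angle, dz, subunit) {
    list(R = rot_z(angle), t = c(0, 0, dz),
         angle_deg = angle, translation = dz, subunit = subunit)
  }
  ops <- list()
  if (p$symmetry == "C1") {
    for (k in seq_len(n_layers) - 1L) {
      ops[[length(ops) + 1L]] <- mk(k * p$twist, k * p$rise, "A")
    }
  } else if (p$symmetry == "C2") {
    for (k in seq_len(n_layers) - 1L) {
      ops[[length(ops) + 1L]] <- mk(k * p$twist, k * p$rise, "A")
      ops[[length(ops) + 1L]] <- mk(k * p$twist + 180, k * p$rise, "B")
    }
  } else { # pseudo-21: each screw application alternates subunit
    for (j in seq_len(2L * n_layers) - 1L) {
      ops[[length(ops) + 1L]] <- mk(j * p$twist, j * p$rise,
                                    if (j %% 2L == 0L) "A" else "B")
    }
  }
  ops
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `a` first, then `b`.
#' @param a,b transforms as returned by [symmetry_operators()] (fields `R`, `t`).
#' @return composed transform with net `angle_deg` (sum of components, not
#'   folded) and `translation`.
#' @export
compose_transforms <- function(b, a) {
  R <- b$R %*% a$R
  t <- as.vector(b$R %*% a$t) + b$t
  ang <- (a$angle_deg %||% NA_real_) + (b$angle_deg %||% NA_real_)
  list(R = R, t = t, angle_deg = ang, translation = t[3])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

apply_transform <- function(op, xyz) {
  sweep(as.matrix(xyz) %*% t(op$R), 2, op$t, "+")
}

#' Published helical parameters of Abeta40 fibril polymorphs
#'
#' Curated table of refined helical twist, rise, symmetry, handedness and
#' reported integer cross-over distances for the three rapidly twisting
#' Abeta40 polymorphs (plus the related C1-prime class) and ten previously
#' described Abeta40 polymorphs identified by their PDB codes. Twists are
#' stored with the depositions' sign conventions, which are not mutually
#' consistent for near-180-degree screws.
#'
#' @return data.frame with columns `name`, `pdb`, `set` ("rapid" for the
#'   rapidly twisting polymorphs, "previous" otherwise), `twist_deg`,
#'   `rise_A`, `symmetry`, `handedness`, `crossover_nm` (reported integer).
#' @examples
#' tab <- ab40_polymorphs()
#' all(round(crossover_distance(tab$twist_deg, tab$rise_A)) == tab$crossover_nm)
#' @export
ab40_polymorphs <- function() {
  data.frame(
    name = c("RT-Ab40(21)", "RT-Ab40(C2)", "RT-Ab40(C1)", "RT-Ab40(C1)'",
             "8OT4", "9IIO", "8QN6", "8QN7", "8FF2", "6SHS",
             "8OT1", "8OT3", "8FF3", "6W0O"),
    pdb = c("11EN", "11EO", "11EP", NA,
            "8OT4", "9IIO", "8QN6", "8QN7", "8FF2", "6SHS",
            "8OT1", "8OT3", "8FF3", "6W0O"),
    set = c(rep("rapid", 4), rep("previous", 10)),
    twist_deg = c(-181.75, -3.55, -5.24, -1.96,
                  181.18, 179.2, -0.79, 179.53, 181.17, 181.0,
                  -0.782, 179.526, 179.75, -180.34),
    rise_A = c(2.34, 4.69, 9.40, 4.76,
               2.38, 2.45, 4.87, 2.44, 2.44, 2.41,
               4.763, 2.372, 2.44, 2.45),
    symmetry = c("pseudo-21", "C2", "C1", "C1",
                 "pseudo-21", "pseudo-21", "C2", "pseudo-21", "pseudo-21",
                 "pseudo-21", "C2", "pseudo-21", "pseudo-21", "pseudo-21"),
    handedness = c("right", "left", "right", "undetermined",
                   "right", "left", "right", "right", "right", "right",
                   "left", "left", "undetermined", "left"),
    crossover_nm = c(24, 24, 32, 44,
                     36, 55, 111, 93, 38, 43,
                     110, 90, 176, 130),
    stringsAsFactors = FALSE
  )
}

#' Read / write polymorph parameter tables
#'
#' Plain-text interchange for polymorph helical-parameter sets. TSV files
#' need columns `name`, `twist_deg`, `rise_A`, `symmetry`; optional
#' `handedness` and `crossover_nm`. JSON files hold an array of objects
#' with the same fields. The format is chosen by file extension.
#'
#' @param path file path (`.tsv`/`.txt` or `.json`).
#' @return data.frame of polymorph parameters.
#' @export
read_polymorph_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("name", "twist_deg", "rise_A", "symmetry")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("polymorph table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tab$symmetry <- normalize_symmetry(tab$symmetry)
  tab
}

#' @rdname read_polymorph_table
#' @param tab data.frame of polymorph parameters.
#' @export
write_polymorph_table <- function(tab, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Cross-over report for a polymorph table
#'
#' Computes the cross-over distance implied by each row's twist and rise,
#' alongside the nearest-integer value used in printed tables, and (when a
#' reported `crossover_nm` column is present) whether the computed integer
#' agrees with it.
#'
#' @param tab data.frame as from [ab40_polymorphs()] or
#'   [read_polymorph_table()].
#' @return the table with added columns `net_twist_deg`,
#'   `crossover_calc_nm`, `crossover_round_nm`, and `consistent` if a
#'   reported value is available.
#' @export
crossover_report <- function(tab) {
  tab$net_twist_deg <- fold_twist(tab$twist_deg)
  tab$crossover_calc_nm <- crossover_distance(tab$twist_deg, tab$rise_A)
  tab$crossover_round_nm <- ifelse(is.infinite(tab$crossover_calc_nm),
                                   NA_integer_, round(tab$crossover_calc_nm))
  if ("crossover_nm" %in% names(tab)) {
    tab$consistent <- tab$crossover_round_nm == tab$crossover_nm
  }
  tab
}
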