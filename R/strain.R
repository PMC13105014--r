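## Geometric twist-strain model: how ordered-segment length and cross-over
## distance set the intermolecular spacing at segment ends.
## All lengths here are nm (reporting scale), unlike the Angstrom used for
## atomic coordinates elsewhere.

#' Inter-molecular rotation angle of a twisting cross-beta stack
#'
#' A cross-beta structure spaces successive molecules by `b` (default
#' 0.48 nm) along the growth axis, so a cross-over distance `d` (180-degree
#' rotation of the cross-section) requires a rotation `rho = b * pi / d`
#' radians between successive molecules.
#'
#' @param d cross-over distance in nm (> 0; `Inf` allowed, giving 0).
#' @param b cross-beta stacking distance in nm (default 0.48).
#' @return rho in radians (vectorized).
#' @examples
#' inter_molecular_angle(25)          # ~0.0603 rad
#' inter_molecular_angle(24) * 180/pi # ~3.6 deg
#' @export
inter_molecular_angle <- function(d, b = 0.48) {
  if (any(is.na(d)) || any(d <= 0)) stop("cross-over distance d must be positive", call. = FALSE)
  if (any(b <= 0)) stop("stacking distance b must be positive", call. = FALSE)
  ifelse(is.infinite(d), 0, b * pi / d)
}

#' Intermolecular spacing at the ends of the ordered segment
#'
#' For molecules with extended ordered segments of length `L` centered on
#' the fibril axis, rotation by `rho` between successive molecules moves the
#' segment ends apart: the intermolecular distance at the N- and C-terminal
#' ends becomes `s = sqrt(b^2 + L^2 sin^2(rho/2))` with `rho = b*pi/d`.
#' `s` is monotone increasing in `L` and decreasing in `d`, and equals `b`
#' exactly for `L = 0` or an untwisted fibril. Spacings well above `b`
#' strain the backbone hydrogen bonds that hold the stack together, which
#' is the proposed geometric limit on how rapidly a long ordered segment
#' can twist.
#'
#' @param L ordered-segment length in nm (>= 0).
#' @param d cross-over distance in nm (> 0; `Inf` allowed).
#' @param b cross-beta stacking distance in nm (default 0.48, with a
#'   reported uncertainty of about +/-0.01 nm).
#' @return end spacing s in nm (vectorized over `L` and `d`).
#' @examples
#' end_spacing(7.3, 25)  # 0.528 nm
#' end_spacing(5.3, 25)  # 0.506 nm
#' @export
end_spacing <- function(L, d, b = 0.48) {
  if (any(is.na(L)) || any(L < 0)) stop("ordered length L must be >= 0", call. = FALSE)
  rho <- inter_molecular_angle(d, b)
  sqrt(b^2 + L^2 * sin(rho / 2)^2)
}

#' Longest ordered segment compatible with an end-spacing bound
#'
#' Inverse of [end_spacing()] in `L`: the segment length `L*` at which the
#' end spacing reaches `s_max` for a given cross-over distance, i.e.
#' `L* = sqrt(s_max^2 - b^2) / sin(rho/2)`. Lengths above `L*` would
#' require intermolecular distances beyond `s_max` at the segment ends.
#'
#' @param d cross-over distance in nm (> 0, finite).
#' @param s_max maximum tolerated end spacing in nm; must be >= `b`
#'   (`s_max = b` returns 0; `s_max < b` is infeasible and errors).
#' @param b cross-beta stacking distance in nm (default 0.48).
#' @return L* in nm.
#' @examples
#' max_ordered_length(25, 0.528)  # ~7.3 nm
#' @export
max_ordered_length <- function(d, s_max, b = 0.48) {
  if (any(is.na(d)) || any(d <= 0) || any(is.infinite(d))) {
    stop("cross-over distance d must be positive and finite", call. = FALSE)
  }
  if (any(s_max < b)) {
    stop("infeasible: s_max is below the stacking distance b; no length satisfies it",
         call. = FALSE)
  }
  rho <- inter_molecular_angle(d, b)
  sqrt(pmax(s_max^2 - b^2, 0)) / sin(rho / 2)
}

#' Strain-profile sweep over (L, d) grids
#'
#' Evaluates the twist-strain model on the outer product of ordered lengths
#' and cross-over distances, for export or plotting.
#'
#' @param L ordered-segment lengths in nm.
#' @param d cross-over distances in nm.
#' @param b stacking distance in nm (default 0.48).
#' @return data.frame of class `strain_profile` with columns `L_nm`, `d_nm`,
#'   `b_nm`, `rho_rad`, `s_nm`.
#' @export
strain_profile <- function(L, d, b = 0.48) {
  g <- expand.grid(L_nm = L, d_nm = d, KEEP.OUT.ATTRS = FALSE)
  g$b_nm <- b
  g$rho_rad <- inter_molecular_angle(g$d_nm, b)
  g$s_nm <- end_spacing(g$L_nm, g$d_nm, b)
  class(g) <- c("strain_profile", "data.frame")
  g
}
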