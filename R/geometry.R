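#' Nuclear geometry of the model yeast nucleus
#'
#' Builds the full sphere/shell geometry used by the simulator and all
#' structural statistics: the spherical nuclear envelope (NE), the
#' spindle-pole-body (SPB) restraint sphere tangent to the NE, the nucleolar
#' restraint sphere centred on the NE point opposite the SPB and sized so its
#' intersection with the nucleus encloses a given fraction of the nuclear
#' volume, and the radii bounding three concentric shells of equal volume.
#'
#' All lengths are nanometres. With the defaults (`r_nuc = 1000`,
#' `nucleolar_volume_fraction = 0.10`) the solved nucleolar radius is
#' 640.92 nm and the peripheral shell is the outermost 126 nm.
#'
#' @param r_nuc Nuclear radius in nm.
#' @param r_spb Radius of the SPB restraint sphere in nm.
#' @param nucleolar_volume_fraction Fraction of the nuclear volume occupied by
#'   the nucleolar region (intersection lens).
#' @param indent_k Stiffness of the indent restraint force, in reduced force
#'   per squared reduced length (applied as `K * (r - R)^2`).
#'
#' @return An object of class `nuc_geometry`: a list with elements `r_nuc`,
#'   `c_spb`, `r_spb`, `c_nucl`, `r_nucl`, `nucleolar_volume_fraction`,
#'   `shell_r1`, `shell_r2`, `r_per` (peripheral shell thickness) and
#'   `indent_k`.
#' @examples
#' geom <- nuclear_geometry()
#' geom$r_nucl   # 640.92
#' geom$r_per    # ~126
#' @export
nuclear_geometry <- function(r_nuc = 1000,
                             r_spb = 150,
                             nucleolar_volume_fraction = 0.10,
                             indent_k = 10) {
  stopifnot(r_nuc > 0, r_spb > 0, r_spb < r_nuc,
            nucleolar_volume_fraction > 0, nucleolar_volume_fraction < 1)
  shells <- equal_volume_shell_radii(r_nuc)
  geom <- structure(list(
    r_nuc = r_nuc,
    c_spb = c(-(r_nuc - r_spb), 0, 0),
    r_spb = r_spb,
    c_nucl = c(r_nuc, 0, 0),
    r_nucl = solve_nucleolus_radius(nucleolar_volume_fraction, r_nuc),
    nucleolar_volume_fraction = nucleolar_volume_fraction,
    shell_r1 = shells$r1,
    shell_r2 = shells$r2,
    r_per = shells$thickness,
    indent_k = indent_k
  ), class = "nuc_geometry")
  geom
}

#' @export
print.nuc_geometry <- function(x, ...) {
  cat("<nuc_geometry>\n")
  cat(sprintf("  nucleus:   R = %.1f nm, centred at origin\n", x$r_nuc))
  cat(sprintf("  SPB:       R = %.1f nm at (%.0f, 0, 0)\n", x$r_spb, x$c_spb[1]))
  cat(sprintf("  nucleolus: R = %.2f nm at (%.0f, 0, 0)  [%.0f%% of nuclear volume]\n",
              x$r_nucl, x$c_nucl[1], 100 * x$nucleolar_volume_fraction))
  cat(sprintf("  shells:    r1 = %.2f, r2 = %.2f nm; peripheral thickness %.2f nm\n",
              x$shell_r1, x$shell_r2, x$r_per))
  invisible(x)
}

#' Volume of the intersection of two spheres
#'
#' Closed-form lens volume for spheres of radii `r` and `R` whose centres are
#' `d` apart: zero when disjoint, the smaller sphere's volume when contained,
#' and the classical spherical-lens formula otherwise.
#'
#' @param r,R Sphere radii (nm), both positive.
#' @param d Centre-to-centre distance (nm), non-negative.
#' @return Intersection volume in nm^3. Vectorised over `r`.
#' @examples
#' lens_volume(640.92, 1000, 1000) / (4 / 3 * pi * 1000^3)  # ~0.10
#' @export
lens_volume <- function(r, R, d) {
  if (any(r <= 0) || R <= 0) stop("sphere radii must be positive")
  if (any(d < 0)) stop("centre distance must be non-negative")
  vapply(seq_along(r), function(i) .lens_volume1(r[i], R, d), numeric(1))
}

.lens_volume1 <- function(r, R, d) {
  if (d >= r + R) return(0)
  if (d <= abs(R - r)) {
    rmin <- min(r, R)
    return(4 / 3 * pi * rmin^3)
  }
  # standard two-sphere lens
  pi * (r + R - d)^2 *
    (d^2 + 2 * d * (r + R) - 3 * (r - R)^2) / (12 * d)
}

#' Solve for the nucleolar sphere radius
#'
#' Finds the radius `r` of a sphere centred on the nuclear envelope
#' (centre distance `d = r_nuc`) whose intersection with the nucleus encloses
#' `volume_fraction` of the nuclear volume, by bracketed root finding on the
#' lens-volume equation.
#'
#' @param volume_fraction Target fraction in (0, 1).
#' @param r_nuc Nuclear radius in nm.
#' @param tol Root tolerance in nm (default 1e-4, well below 0.005 nm).
#' @return Radius in nm.
#' @examples
#' solve_nucleolus_radius(0.10, 1000)  # 640.92
#' @export
solve_nucleolus_radius <- function(volume_fraction, r_nuc, tol = 1e-4) {
  stopifnot(volume_fraction > 0, volume_fraction < 1, r_nuc > 0)
  target <- volume_fraction * 4 / 3 * pi * r_nuc^3
  f <- function(r) .lens_volume1(r, r_nuc, r_nuc) - target
  lo <- r_nuc * 1e-9
  hi <- 2 * r_nuc
  if (f(lo) > 0 || f(hi) < 0) stop("no root in (0, 2 * r_nuc)")
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Radii bounding three equal-volume concentric shells
#'
#' Splits a sphere of radius `r_nuc` into three concentric shells each holding
#' one-third of the volume: `r1 = (1/3)^(1/3) r_nuc`, `r2 = (2/3)^(1/3) r_nuc`.
#' The peripheral shell thickness `r_nuc - r2` is 126 nm for a 1000-nm nucleus.
#'
#' @param r_nuc Nuclear radius in nm.
#' @return A list with `r1`, `r2` and `thickness` (all nm).
#' @export
equal_volume_shell_radii <- function(r_nuc) {
  stopifnot(r_nuc > 0)
  r1 <- (1 / 3)^(1 / 3) * r_nuc
  r2 <- (2 / 3)^(1 / 3) * r_nuc
  list(r1 = r1, r2 = r2, thickness = r_nuc - r2)
}

#' Classify points into the three equal-volume nuclear shells
#'
#' @param points Numeric matrix (n x 3) of coordinates in nm, or a length-3
#'   vector for a single point.
#' @param geometry A [nuclear_geometry()] object.
#' @return Character vector in `{"central","middle","peripheral","outside"}`.
#'   Boundary radii are assigned to the inner shell.
#' @export
classify_shell <- function(points, geometry = nuclear_geometry()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  r <- sqrt(rowSums(points^2))
  out <- character(length(r))
  out[r <= geometry$shell_r1] <- "central"
  out[r > geometry$shell_r1 & r <= geometry$shell_r2] <- "middle"
  out[r > geometry$shell_r2 & r <= geometry$r_nuc] <- "peripheral"
  out[r > geometry$r_nuc] <- "outside"
  out
}

#' Restraint sphere
#'
#' A spherical restraint region with a confinement mode. Particles violating
#' the condition feel a force of magnitude `K (r - R)^2` directed radially
#' back toward compliance.
#'
#' @param center Length-3 numeric centre (nm).
#' @param radius Sphere radius (nm), positive.
#' @param mode `"keep_inside"` or `"keep_outside"`.
#' @param stiffness Force constant K (reduced units, default 10).
#' @return A `restraint_sphere` list.
#' @export
restraint_sphere <- function(center, radius,
                             mode = c("keep_inside", "keep_outside"),
                             stiffness = 10) {
  mode <- match.arg(mode)
  stopifnot(length(center) == 3, radius > 0, stiffness >= 0)
  structure(list(center = as.numeric(center), radius = radius,
                 mode = mode, stiffness = stiffness),
            class = "restraint_sphere")
}

#' Indent restraint force on a point
#'
#' Implements the one-sided harmonic-squared confinement force
#' `F(r) = K (r - R)^2` acting only when the point violates the sphere's
#' confinement condition: inward for `keep_inside` violations (point outside
#' the sphere), outward for `keep_outside` violations (point inside it).
#' A point exactly at the sphere centre under `keep_outside` has no defined
#' radial direction; it is pushed along +x deterministically.
#'
#' @param point Length-3 numeric position (same length units as the sphere).
#' @param sphere A [restraint_sphere()].
#' @return Length-3 force vector (reduced force units).
#' @export
indent_force <- function(point, sphere) {
  stopifnot(inherits(sphere, "restraint_sphere"))
  v <- as.numeric(point) - sphere$center
  r <- sqrt(sum(v^2))
  K <- sphere$stiffness
  R <- sphere$radius
  if (sphere$mode == "keep_inside") {
    if (r <= R) return(c(0, 0, 0))
    mag <- K * (r - R)^2
    return(-mag * v / r)
  }
  # keep_outside
  if (r >= R) return(c(0, 0, 0))
  if (r == 0) return(c(K * R^2, 0, 0))
  mag <- K * (R - r)^2
  mag * v / r
}
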