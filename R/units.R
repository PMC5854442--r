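#' @title Unit conventions and conversions
#'
#' @description
#' All internal computation uses a single canonical unit system: lengths in
#' micrometres (um), 3D number densities in um^-3, 2D number densities in
#' um^-2, 3D association constants in um^3 (per molecule), 2D association
#' constants in um^2, and time in seconds. Molar quantities are accepted and
#' emitted only at I/O boundaries; this avoids carrying Avogadro factors
#' inside every equation.
#'
#' The molar bridge is exact: 1 M corresponds to 6.02214076e8 molecules per
#' um^3, so 1 uM = 602.214076 um^-3, and the two directions are exact
#' inverses of one another.
#'
#' @name units
NULL

# molecules per um^3 at 1 mol/L (Avogadro / 1e15 um^3 per L); exact by the
# SI definition of the mole
.PER_UM3_PER_MOLAR <- 6.02214076e8

#' Convert molar concentration to number density
#'
#' @param x concentration in mol/L.
#' @return Number density in um^-3.
#' @examples
#' molar_to_um3(1e-6)  # 1 uM = 602.214076 um^-3
#' @export
molar_to_um3 <- function(x) x * .PER_UM3_PER_MOLAR

#' Convert number density to molar concentration
#'
#' @param x number density in um^-3.
#' @return Concentration in mol/L.
#' @export
um3_to_molar <- function(x) x / .PER_UM3_PER_MOLAR

#' Convert a per-molar association constant to per-molecule volume units
#'
#' @param ka association constant in 1/M.
#' @return Association constant in um^3 (per molecule).
#' @examples
#' ka_molar_to_um3(1e6)  # 10^6 M^-1 = 1.6606e-3 um^3
#' @export
ka_molar_to_um3 <- function(ka) ka / .PER_UM3_PER_MOLAR

#' Convert a per-molecule association constant back to 1/M
#'
#' @param ka association constant in um^3.
#' @return Association constant in 1/M.
#' @export
ka_um3_to_molar <- function(ka) ka * .PER_UM3_PER_MOLAR

#' Convert nanometres to micrometres (and back)
#'
#' @param x length in nm (or um for `um_to_nm`).
#' @return Length in um (or nm).
#' @export
nm_to_um <- function(x) x / 1e3

#' @rdname nm_to_um
#' @export
um_to_nm <- function(x) x * 1e3

#' Cell/compartment geometry
#'
#' A solution volume paired with a membrane surface area. Equilibrium
#' results of the theory depend only on the ratio V/A, not the absolute
#' size, but kinetics and stochastic simulations use both.
#'
#' @param V solution volume in um^3.
#' @param A membrane surface area in um^2.
#' @return A `kaeff_geometry` list with elements `V`, `A`, and the derived
#'   length `V_over_A` (um).
#' @examples
#' geometry(V = 1200, A = 767)  # human cell plasma-membrane geometry
#' @export
geometry <- function(V, A) {
  stopifnot(is.numeric(V), is.numeric(A), length(V) == 1, length(A) == 1)
  if (!is.finite(V) || !is.finite(A) || V <= 0 || A <= 0) {
    stop("geometry: V and A must be finite and positive", call. = FALSE)
  }
  structure(list(V = V, A = A, V_over_A = V / A), class = "kaeff_geometry")
}

#' @export
print.kaeff_geometry <- function(x, ...) {
  cat(sprintf("<geometry> V = %g um^3, A = %g um^2, V/A = %g um\n",
              x$V, x$A, x$V_over_A))
  invisible(x)
}

#' The dimensionless geometry factor gamma = V / (2 A sigma)
#'
#' gamma is the ceiling on the binding enhancement: when every protein is
#' membrane-bound the effective association constant equals gamma times the
#' solution constant. gamma = 1 (V/A = 2 sigma) is the boundary at which the
#' membrane neither enhances nor reduces binding; gamma < 1 reduces it.
#'
#' @param geom a [geometry()] object.
#' @param sigma_um the length scale relating 3D and 2D association
#'   constants, in um.
#' @return Dimensionless gamma.
#' @examples
#' gamma_factor(geometry(1200, 767), nm_to_um(1))  # 782.27
#' @export
gamma_factor <- function(geom, sigma_um) {
  stopifnot(inherits(geom, "kaeff_geometry"))
  if (!is.numeric(sigma_um) || any(!is.finite(sigma_um)) || any(sigma_um <= 0)) {
    stop("gamma_factor: sigma must be finite and positive", call. = FALSE)
  }
  geom$V / (2 * geom$A * sigma_um)
}

#' Convert a 3D association constant to its 2D counterpart
#'
#' K_a^2D = K_a^3D / (2 sigma). sigma is a thermodynamic property of each
#' binding pair (nanometre scale), capturing the free-energy change of
#' restricting the pair to a surface.
#'
#' @param ka3d association constant in um^3.
#' @param sigma_um sigma in um.
#' @return Association constant in um^2.
#' @export
ka2d_from_3d <- function(ka3d, sigma_um) {
  if (!is.numeric(sigma_um) || any(!is.finite(sigma_um)) || any(sigma_um <= 0)) {
    stop("ka2d_from_3d: sigma must be finite and positive", call. = FALSE)
  }
  if (any(ka3d < 0)) stop("ka2d_from_3d: Ka must be >= 0", call. = FALSE)
  ka3d / (2 * sigma_um)
}

#' @rdname ka2d_from_3d
#' @param ka2d association constant in um^2.
#' @export
ka3d_from_2d <- function(ka2d, sigma_um) {
  if (!is.numeric(sigma_um) || any(!is.finite(sigma_um)) || any(sigma_um <= 0)) {
    stop("ka3d_from_2d: sigma must be finite and positive", call. = FALSE)
  }
  if (any(ka2d < 0)) stop("ka3d_from_2d: Ka must be >= 0", call. = FALSE)
  ka2d * 2 * sigma_um
}

#' Convert a surface density to an equivalent volume density
#'
#' A species held at d um^-2 on an area A inside a volume V contributes
#' d * A / V um^-3 when all species are solved in consistent volume units.
#'
#' @param d surface density in um^-2.
#' @param geom a [geometry()] object.
#' @return Volume density in um^-3.
#' @export
to_volume_density <- function(d, geom) {
  stopifnot(inherits(geom, "kaeff_geometry"))
  if (any(d < 0)) stop("to_volume_density: density must be >= 0", call. = FALSE)
  d * geom$A / geom$V
}

#' @rdname to_volume_density
#' @export
to_surface_density <- function(d, geom) {
  stopifnot(inherits(geom, "kaeff_geometry"))
  if (any(d < 0)) stop("to_surface_density: density must be >= 0", call. = FALSE)
  d * geom$V / geom$A
}
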