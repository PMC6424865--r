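#' Solute species for a square-well fluid
#'
#' Describes a single spherical macromolecular solute: its hard-core radius
#' (in reduced units; the hard-core diameter \eqn{\sigma = 2r} is the natural
#' length unit of the model) and, optionally, the molar mass and specific
#' exclusion volume needed to convert between molar concentration and volume
#' fraction.
#'
#' @param radius Hard-core radius \eqn{r > 0} (reduced length units). The
#'   default 0.5 makes the hard-core diameter \eqn{\sigma = 1}.
#' @param molar_mass Molar mass \eqn{M} in g/mol (required only for
#'   concentration conversion).
#' @param v_bar Specific exclusion volume \eqn{\bar v} in cm^3/g (required
#'   only for concentration conversion).
#' @return An object of class `sw_species`.
#' @examples
#' sp <- sw_species(radius = 0.5, molar_mass = 65500, v_bar = 1.0)
#' phi_from_molar(2e-3, sp)
#' @export
sw_species <- function(radius = 0.5, molar_mass = NULL, v_bar = NULL) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius))
  if (radius <= 0) stop("radius must be > 0")
  if (!is.null(molar_mass)) {
    stopifnot(is.numeric(molar_mass), length(molar_mass) == 1L)
    if (!is.finite(molar_mass) || molar_mass <= 0) stop("molar_mass must be > 0")
  }
  if (!is.null(v_bar)) {
    stopifnot(is.numeric(v_bar), length(v_bar) == 1L)
    if (!is.finite(v_bar) || v_bar <= 0) stop("v_bar must be > 0")
  }
  structure(list(radius = radius, molar_mass = molar_mass, v_bar = v_bar),
            class = "sw_species")
}

#' @export
print.sw_species <- function(x, ...) {
  cat("Square-well solute species\n")
  cat("  hard-core radius:", x$radius, "(sigma =", 2 * x$radius, ")\n")
  if (!is.null(x$molar_mass)) cat("  molar mass:", x$molar_mass, "g/mol\n")
  if (!is.null(x$v_bar)) cat("  specific exclusion volume:", x$v_bar, "cm^3/g\n")
  invisible(x)
}

#' Square-well pair interaction parameters
#'
#' The square-well potential of mean force is parameterized by the reduced
#' well range `L` (ratio of the outer well radius to the contact distance,
#' `L >= 1`) and the reduced well depth `eps_star` = \eqn{\epsilon/kT}.
#' Negative `eps_star` is attraction; `eps_star = 0` (or `L = 1`) recovers
#' the pure hard-sphere fluid. Positive `eps_star` (a repulsive shoulder) is
#' accepted by all analytic routines as an extension beyond the attractive
#' regime the model was designed for.
#'
#' @param L Well range, dimensionless, `>= 1`.
#' @param eps_star Well depth in units of kT; finite.
#' @return An object of class `sw_interaction`.
#' @examples
#' sw_interaction(L = 1.25, eps_star = -1.0)
#' @export
sw_interaction <- function(L, eps_star) {
  stopifnot(is.numeric(L), length(L) == 1L, is.numeric(eps_star),
            length(eps_star) == 1L)
  if (!is.finite(L) || L < 1) stop("well range L must be finite and >= 1")
  if (!is.finite(eps_star)) stop("eps_star must be finite")
  structure(list(L = L, eps_star = eps_star), class = "sw_interaction")
}

#' @export
print.sw_interaction <- function(x, ...) {
  cat("Square-well interaction: L =", x$L, ", eps* =", x$eps_star, "kT\n")
  invisible(x)
}

#' Convert molar concentration to volume fraction
#'
#' \eqn{\phi = c M \bar v / 1000}, with `c` in mol/L, `M` in g/mol and
#' \eqn{\bar v} in cm^3/g.
#'
#' @param c Molar concentration (mol/L), non-negative; vectorized.
#' @param species An [sw_species()] with `molar_mass` and `v_bar` set.
#' @return Volume fraction(s) \eqn{\phi}.
#' @seealso [molar_from_phi()] for the exact inverse.
#' @export
phi_from_molar <- function(c, species) {
  stopifnot(inherits(species, "sw_species"))
  if (is.null(species$molar_mass) || is.null(species$v_bar))
    stop("species needs molar_mass and v_bar for concentration conversion")
  if (any(!is.finite(c)) || any(c < 0)) stop("molar concentration must be >= 0")
  phi <- c * species$molar_mass * species$v_bar / 1000
  if (any(phi >= 1)) stop("conversion yields volume fraction >= 1")
  phi
}

#' Convert volume fraction to molar concentration
#'
#' Exact inverse of [phi_from_molar()].
#'
#' @param phi Volume fraction(s) in `[0, 1)`.
#' @param species An [sw_species()] with `molar_mass` and `v_bar` set.
#' @return Molar concentration(s) in mol/L.
#' @export
molar_from_phi <- function(phi, species) {
  stopifnot(inherits(species, "sw_species"))
  if (is.null(species$molar_mass) || is.null(species$v_bar))
    stop("species needs molar_mass and v_bar for concentration conversion")
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi >= 1))
    stop("volume fraction must lie in [0, 1)")
  phi * 1000 / (species$molar_mass * species$v_bar)
}

#' Square-well pair potential
#'
#' Three-branch potential of mean force between two spheres of radii `r_i`
#' and `r_j` at center-to-center distance `distance`:
#' infinite (hard-core overlap) below the contact distance
#' \eqn{r_i + r_j}; `eps_star` inside the well,
#' \eqn{r_i + r_j \le d < L (r_i + r_j)}; zero at and beyond the outer well
#' boundary. The branch boundaries are half-open: contact is inside the
#' well, the outer boundary is outside it.
#'
#' Hard-core overlap is reported as the sentinel `Inf`; it never enters
#' arithmetic except through [boltzmann_factor()], which maps it to exactly 0.
#'
#' @param distance Center-to-center distance(s), `>= 0`; vectorized.
#' @param r_i,r_j Hard-core radii of the two particles.
#' @param params An [sw_interaction()].
#' @return Energy in kT units (`Inf` marks overlap).
#' @examples
#' p <- sw_interaction(1.25, -1)
#' pair_potential(c(0.4, 1.1, 1.25), r_i = 0.5, r_j = 0.5, params = p)
#' @export
pair_potential <- function(distance, r_i, r_j, params) {
  stopifnot(inherits(params, "sw_interaction"), r_i > 0, r_j > 0)
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("distance must be >= 0")
  contact <- r_i + r_j
  outer <- params$L * contact
  ifelse(distance < contact, Inf,
         ifelse(distance < outer, params$eps_star, 0))
}

#' Boltzmann factor of a reduced pair energy
#'
#' `exp(-u)` with the hard-core overlap sentinel (`Inf`) mapped to exactly 0.
#'
#' @param u Reduced energy (kT units), possibly `Inf`.
#' @return `exp(-u)`, with `exp(-Inf)` exactly 0.
#' @export
boltzmann_factor <- function(u) {
  out <- exp(-u)
  out[is.infinite(u) & u > 0] <- 0
  out
}

#' Read a model configuration file
#'
#' Reads a JSON (or YAML, if the `yaml` package is installed) configuration
#' with blocks `species` (`radius`, `molar_mass`, `v_bar`), `interaction`
#' (`L`, `eps_star`) and optionally `grids` (`phi_min`, `phi_max`,
#' `phi_step`, `eps_grid`).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `species` ([sw_species()]),
#'   `interaction` ([sw_interaction()]) and `grids` (list, possibly empty).
#' @export
read_sw_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw$interaction))
    stop("config must contain an 'interaction' block with L and eps_star")
  sp <- raw$species
  species <- sw_species(radius = if (is.null(sp$radius)) 0.5 else sp$radius,
                        molar_mass = sp$molar_mass, v_bar = sp$v_bar)
  interaction <- sw_interaction(L = raw$interaction$L,
                                eps_star = raw$interaction$eps_star)
  list(species = species, interaction = interaction,
       grids = if (is.null(raw$grids)) list() else raw$grids)
}
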