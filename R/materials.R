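#' Bundled material data
#'
#' The transport engine's physics data layer: mass collision stopping powers
#' (MeV cm^2/g), radiative-loss fractions and radiation lengths for the
#' materials the package needs (phantom media, machine-head metals, air).
#' Values are smooth reference tabulations on a 0.1--15 MeV grid; the
#' engine interpolates them log-log in energy and scales linearly with
#' density. The radiative fraction is the ratio of radiative to collision
#' loss, tabulated from the complete-screening form S_rad ~ (E + m_e c^2)/X0
#' with an empirical 0.7 efficiency factor.
#'
#' @return Named list of material objects (class `ioert_material`), each with
#'   fields `name`, `density` (g/cm^3), `energies` (MeV), `stopping_power`
#'   (MeV cm^2/g), `radfrac` (unitless) and `x0` (radiation length, g/cm^2).
#' @export
#' @examples
#' mats <- ioert_materials()
#' names(mats)
#' mats$water$density
ioert_materials <- function() {
  e <- c(0.1, 0.2, 0.3, 0.5, 0.7, 1, 1.5, 2, 3, 5, 7, 10, 15)

  # collision mass stopping powers, MeV cm^2/g
  sp_water <- c(4.115, 2.793, 2.355, 2.034, 1.931, 1.849, 1.816, 1.824,
                1.846, 1.892, 1.926, 1.968, 2.005)
  sp_air   <- c(3.633, 2.470, 2.084, 1.802, 1.713, 1.661, 1.653, 1.684,
                1.740, 1.833, 1.901, 1.979, 2.069)
  sp_al    <- sp_water * c(0.845, 0.843, 0.840, 0.836, 0.833, 0.829, 0.825,
                           0.822, 0.818, 0.813, 0.810, 0.806, 0.802)
  sp_ti    <- sp_water * 0.79
  sp_ta    <- sp_water * 0.615
  sp_cu    <- sp_water * 0.675
  sp_tis   <- sp_water * 0.992
  sp_bone  <- sp_water * 0.931

  mk <- function(name, density, sp, x0) {
    radfrac <- 0.7 * (e + 0.511) / x0 / sp
    structure(list(name = name, density = density, energies = e,
                   stopping_power = sp, radfrac = radfrac, x0 = x0),
              class = "ioert_material")
  }

  list(
    water       = mk("water",       1.0,      sp_water, 36.08),
    air         = mk("air",         0.0012041, sp_air,  36.62),
    aluminum    = mk("aluminum",    2.699,    sp_al,    24.01),
    titanium    = mk("titanium",    4.506,    sp_ti,    16.16),
    tantalum    = mk("tantalum",    16.654,   sp_ta,     6.82),
    copper      = mk("copper",      8.96,     sp_cu,    12.86),
    soft_tissue = mk("soft_tissue", 0.9869,   sp_tis,   36.2),
    lung        = mk("lung",        0.2958,   sp_tis,   36.2),
    bone        = mk("bone",        1.4862,   sp_bone,  26.5)
  )
}

#' @export
print.ioert_material <- function(x, ...) {
  cat(sprintf("<ioert_material> %s: density %.4g g/cm^3, X0 %.4g g/cm^2, %d-node stopping-power table\n",
              x$name, x$density, x$x0, length(x$energies)))
  invisible(x)
}

#' Clone a material at a different bulk density
#'
#' Linear stopping power scales linearly with density; the mass stopping power
#' table is shared. Used e.g. for lung-like low-density media or for tuning
#' the secondary-scattering-foil alloy density.
#'
#' @param material An `ioert_material`.
#' @param density New density in g/cm^3 (> 0).
#' @export
material_with_density <- function(material, density) {
  stopifnot(inherits(material, "ioert_material"), density > 0)
  material$density <- density
  material
}

#' Collision stopping power of a material
#'
#' Log-log interpolation of the bundled mass stopping-power table, scaled by
#' the material density to a linear stopping power. Queries outside the
#' tabulated 0.1--15 MeV range are an error: the tables are not extrapolated.
#'
#' @param material An `ioert_material`.
#' @param energy Kinetic energy in MeV (vectorized).
#' @return Linear collision stopping power in MeV/cm.
#' @export
#' @examples
#' w <- ioert_materials()$water
#' collision_stopping_power(w, c(1, 5, 10))
collision_stopping_power <- function(material, energy) {
  stopifnot(inherits(material, "ioert_material"))
  rng <- range(material$energies)
  if (any(energy < rng[1] | energy > rng[2])) {
    stop(sprintf("energy outside tabulated range [%g, %g] MeV; no extrapolation",
                 rng[1], rng[2]))
  }
  le <- log(material$energies)
  ls <- log(material$stopping_power)
  exp(stats::approx(le, ls, xout = log(energy))$y) * material$density
}

#' Highland multiple-scattering angle
#'
#' Standard deviation of the projected Gaussian scattering angle after a path
#' through a material, per the Highland parameterization
#' sigma = (13.6 MeV / beta c p) sqrt(t/X0) (1 + 0.038 ln(t/X0)), floored at
#' zero. `path_length` is geometric, in mm; it is converted to areal density
#' with the material density.
#'
#' @param material An `ioert_material`.
#' @param energy Electron kinetic energy in MeV; must exceed `cutoff`.
#' @param path_length Path length in mm (>= 0).
#' @param cutoff Transport cutoff in MeV below which the query is an error.
#' @return Scattering-angle sigma in radians.
#' @export
scatter_sigma <- function(material, energy, path_length, cutoff = 0.2) {
  stopifnot(inherits(material, "ioert_material"), path_length >= 0)
  if (any(energy <= cutoff)) stop("energy at or below transport cutoff")
  if (path_length == 0) return(0)
  me <- 0.511
  pc <- sqrt(energy * (energy + 2 * me))
  betapc <- pc^2 / (energy + me)
  tr <- (path_length / 10) * material$density / material$x0
  pmax(0, (13.6 / betapc) * sqrt(tr) * (1 + 0.038 * log(tr)))
}

# internal: pack materials for the C++ engine
materials_for_engine <- function(mats) {
  lapply(mats, function(m) {
    list(log_e = log(m$energies), log_sp = log(m$stopping_power),
         radfrac = m$radfrac, density = m$density, x0 = m$x0)
  })
}
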