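#' Material constants for iron-oxide tracer calculations
#'
#' Bundles the physical constants used throughout the package to convert
#' between mass-, molar- and volume-referenced magnetizations and between
#' magnetic moments and equivalent sphere diameters. Defaults describe
#' maghemite (gamma-Fe2O3), the dominant phase of the multicore tracers this
#' package models.
#'
#' @param fe_molar_mass Molar mass of iron in kg/mol.
#' @param maghemite_fe_mass_fraction Mass fraction of iron in maghemite
#'   (2*M_Fe / M_Fe2O3), dimensionless, in (0, 1).
#' @param maghemite_density Density of maghemite in kg/m^3.
#' @param boltzmann Boltzmann constant in J/K.
#'
#' @return An object of class `material_constants` (a named list).
#' @examples
#' mc <- material_constants()
#' mc$fe_molar_mass
#' @export
material_constants <- function(fe_molar_mass = 0.055845,
                               maghemite_fe_mass_fraction = 0.6994,
                               maghemite_density = 4860,
                               boltzmann = 1.380649e-23) {
  stopifnot(fe_molar_mass > 0, maghemite_density > 0, boltzmann > 0,
            maghemite_fe_mass_fraction > 0, maghemite_fe_mass_fraction < 1)
  structure(list(fe_molar_mass = fe_molar_mass,
                 maghemite_fe_mass_fraction = maghemite_fe_mass_fraction,
                 maghemite_density = maghemite_density,
                 boltzmann = boltzmann),
            class = "material_constants")
}

#' Convert mass magnetization to molar magnetization
#'
#' Iron-normalized magnetizations are quoted either per kilogram of iron
#' (Am^2/kg(Fe)) or per mole of iron (Am^2/mol(Fe)); the two differ by the
#' molar mass of iron.
#'
#' @param m_mass Magnetization in Am^2/kg(Fe). Must be non-negative.
#' @param constants A [material_constants()] object.
#' @return Magnetization in Am^2/mol(Fe).
#' @examples
#' mass_to_molar_magnetization(104) # ~5.8 Am^2/mol(Fe)
#' @export
mass_to_molar_magnetization <- function(m_mass, constants = material_constants()) {
  if (any(m_mass < 0)) stop("mass magnetization must be non-negative")
  m_mass * constants$fe_molar_mass
}

#' @rdname mass_to_molar_magnetization
#' @param m_molar Magnetization in Am^2/mol(Fe). Must be non-negative.
#' @export
molar_to_mass_magnetization <- function(m_molar, constants = material_constants()) {
  if (any(m_molar < 0)) stop("molar magnetization must be non-negative")
  m_molar / constants$fe_molar_mass
}

#' Ferrous iron fraction of an iron-oxide mineral
#'
#' Fraction of total iron present as Fe(2+). Magnetite (Fe3O4) carries one
#' ferrous iron per three irons (33.3%); maghemite (gamma-Fe2O3) is fully
#' ferric. A magnetite/maghemite mixed phase scales linearly with the molar
#' fraction of iron residing in the magnetite phase.
#'
#' @param stoichiometry `"magnetite"` or `"maghemite"`.
#' @param magnetite_iron_fraction For mixed phases: molar fraction of total
#'   iron in the magnetite phase (default 1 for pure magnetite).
#' @return Percent of total iron that is ferrous.
#' @examples
#' fe2plus_fraction("magnetite") # 33.33
#' fe2plus_fraction("maghemite") # 0
#' @export
fe2plus_fraction <- function(stoichiometry = c("magnetite", "maghemite"),
                             magnetite_iron_fraction = 1) {
  stoichiometry <- match.arg(stoichiometry)
  stopifnot(magnetite_iron_fraction >= 0, magnetite_iron_fraction <= 1)
  if (stoichiometry == "maghemite") return(0)
  100 / 3 * magnetite_iron_fraction
}

#' Convert between magnetic moment and equivalent sphere diameter
#'
#' Assuming spherical particles of identical volumetric saturation
#' magnetization `M_vol` (A/m), a particle of moment `mu` (Am^2) has volume
#' `mu / M_vol` and diameter `d = (6 mu / (pi M_vol))^(1/3)`. The volumetric
#' magnetization is derived from the iron-mass magnetization via the mineral's
#' iron mass fraction and density: `M_vol = m_mass * w_Fe * rho`.
#'
#' @param mu Magnetic moment in Am^2 (strictly positive).
#' @param ms_molar Saturation magnetization in Am^2/mol(Fe).
#' @param constants A [material_constants()] object.
#' @return `moment_to_diameter`: diameter in nm. `diameter_to_moment`:
#'   moment in Am^2.
#' @examples
#' mc <- material_constants()
#' moment_to_diameter(3.9e-18, mass_to_molar_magnetization(104, mc), mc)
#' @export
moment_to_diameter <- function(mu, ms_molar, constants = material_constants()) {
  if (any(mu <= 0)) stop("magnetic moment must be strictly positive")
  m_vol <- volumetric_magnetization(ms_molar, constants)
  (6 * mu / (pi * m_vol))^(1 / 3) * 1e9
}

#' @rdname moment_to_diameter
#' @param d_nm Equivalent sphere diameter in nm (strictly positive).
#' @export
diameter_to_moment <- function(d_nm, ms_molar, constants = material_constants()) {
  if (any(d_nm <= 0)) stop("diameter must be strictly positive")
  m_vol <- volumetric_magnetization(ms_molar, constants)
  pi / 6 * (d_nm * 1e-9)^3 * m_vol
}

# Volumetric saturation magnetization (A/m) from molar magnetization,
# via mass magnetization x iron mass fraction x mineral density.
volumetric_magnetization <- function(ms_molar, constants = material_constants()) {
  molar_to_mass_magnetization(ms_molar, constants) *
    constants$maghemite_fe_mass_fraction * constants$maghemite_density
}

#' @export
print.material_constants <- function(x, ...) {
  cat("Material constants:\n")
  cat(sprintf("  Fe molar mass        : %g kg/mol\n", x$fe_molar_mass))
  cat(sprintf("  maghemite Fe fraction: %g\n", x$maghemite_fe_mass_fraction))
  cat(sprintf("  maghemite density    : %g kg/m^3\n", x$maghemite_density))
  cat(sprintf("  Boltzmann constant   : %g J/K\n", x$boltzmann))
  invisible(x)
}
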