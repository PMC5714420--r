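# Material physics: HU->density calibration, density->material binning,
# mass attenuation coefficient components, mean free path, collision stopping
# powers and water/medium stopping-power ratios.
#
# The Compton (incoherent) component is computed from the exact Klein-Nishina
# total cross-section times the electron density Z/A (electron binding
# ignored, as in the transport model). Collision stopping powers come from
# the Moller/Bethe formula with ICRU mean excitation energies; the density
# effect is neglected (< ~1% below 1.25 MeV). Photoelectric and Rayleigh
# components are interpolated from embedded anchor curves that follow the
# standard photon cross-section compilations to within a few percent at low
# energy; above 100 keV both channels contribute < 1% of the total in tissue.
# Lead is tabulated without K/L-edge structure: under the single-scatter
# filter rule lead only ever sees photons of 0.212 MeV or more.

# ---- material catalogue ----------------------------------------------------

.MATERIALS <- data.frame(
  id       = 1:6,
  name     = c("air", "lung", "soft_tissue", "bone", "aluminum", "lead"),
  za       = c(0.49919, 0.55048, 0.55509, 0.51478, 0.48181, 0.39575),
  i_ev     = c(85.7, 75.3, 75.0, 106.4, 166.0, 823.0),
  zeff     = c(7.64, 7.42, 7.42, 13.80, 13.00, 82.0),
  density  = c(0.0012, 0.26, 1.00, 1.92, 2.70, 11.35),
  stringsAsFactors = FALSE
)

# photoelectric mass attenuation anchors for water [cm^2/g]
.PE_WATER <- list(
  energy = c(0.01, 0.015, 0.02, 0.03, 0.04, 0.05, 0.06, 0.08, 0.10,
             0.15, 0.20, 0.30, 0.50, 0.80, 1.00, 1.33),
  value  = c(4.98, 1.39, 0.550, 0.155, 0.0630, 0.0305, 0.0170, 0.00669,
             0.00311, 8.4e-4, 3.3e-4, 9.0e-5, 2.0e-5, 6.0e-6, 3.5e-6, 1.7e-6)
)

# Rayleigh (coherent) mass attenuation anchors for water [cm^2/g]
.RAY_WATER <- list(
  energy = c(0.01, 0.015, 0.02, 0.03, 0.04, 0.05, 0.06, 0.08, 0.10,
             0.15, 0.20, 0.30, 0.50, 0.80, 1.00, 1.33),
  value  = c(0.200, 0.115, 0.075, 0.038, 0.0235, 0.0157, 0.0113, 0.0066,
             0.0043, 2.02e-3, 1.18e-3, 5.5e-4, 2.05e-4, 8.3e-5, 5.4e-5, 3.1e-5)
)

# lead photoelectric / coherent anchors [cm^2/g] (edge structure smoothed)
.PE_LEAD <- list(
  energy = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.08, 0.10, 0.15, 0.20,
             0.30, 0.40, 0.50, 0.60, 0.80, 1.00, 1.25, 1.33),
  value  = c(125, 84.0, 28.9, 13.4, 7.39, 4.55, 2.16, 5.21, 1.79, 0.829,
             0.278, 0.128, 0.0695, 0.0417, 0.0181, 0.0172, 0.0119, 0.0105)
)
.RAY_LEAD <- list(
  energy = c(0.01, 0.02, 0.03, 0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50,
             0.60, 0.80, 1.00, 1.25, 1.33),
  value  = c(3.5, 1.9, 1.2, 0.65, 0.221, 0.112, 0.0648, 0.0317, 0.0187,
             0.0124, 0.00886, 0.00514, 0.00336, 0.00220, 0.00196)
)

.ENERGY_GRID <- seq(0.01, 1.33, by = 0.01)

.material_row <- function(material) {
  if (is.numeric(material)) {
    i <- match(as.integer(material), .MATERIALS$id)
  } else {
    i <- match(as.character(material), .MATERIALS$name)
  }
  if (any(is.na(i))) stop("unknown material: ", paste(material, collapse = ", "))
  i
}

.loglog_interp <- function(xout, x, y) {
  exp(approx(log(x), log(y), xout = log(xout), rule = 2)$y)
}

# exact Klein-Nishina total cross-section per electron [cm^2]
.kn_total <- function(energy) {
  k <- energy / MEC2
  2 * pi * R0_CM^2 * (
    (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
      log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2
  )
}

.AVOGADRO <- 6.02214076e23

# Moller/Bethe mass collision stopping power [MeV cm^2/g]
.bethe_collision <- function(energy, za, i_ev) {
  tau <- energy / MEC2
  gamma <- tau + 1
  beta2 <- 1 - 1 / gamma^2
  i_ratio2 <- (i_ev * 1e-6 / MEC2)^2
  f_tau <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / gamma^2
  brack <- log(tau^2 * (tau + 2) / (2 * i_ratio2)) + f_tau
  0.1535363 / beta2 * za * brack
}

.build_material_tables <- function() {
  grids <- lapply(seq_len(nrow(.MATERIALS)), function(i) {
    m <- .MATERIALS[i, ]
    e <- .ENERGY_GRID
    compton <- .kn_total(e) * .AVOGADRO * m$za
    if (m$name == "lead") {
      pe  <- .loglog_interp(e, .PE_LEAD$energy, .PE_LEAD$value)
      ray <- .loglog_interp(e, .RAY_LEAD$energy, .RAY_LEAD$value)
    } else {
      # effective-atomic-number scaling of the water anchor curves
      w <- .MATERIALS[.MATERIALS$name == "soft_tissue", ]
      pe_scale  <- (m$zeff / w$zeff)^3.62 * (m$za / w$za)
      ray_scale <- (m$zeff / w$zeff)^1.90 * (m$za / w$za)
      pe  <- .loglog_interp(e, .PE_WATER$energy, .PE_WATER$value) * pe_scale
      ray <- .loglog_interp(e, .RAY_WATER$energy, .RAY_WATER$value) * ray_scale
    }
    spow <- .bethe_collision(e, m$za, m$i_ev)
    data.frame(energy = e, pe = pe, compton = compton, rayleigh = ray,
               total = pe + compton + ray, stopping_power = spow)
  })
  names(grids) <- .MATERIALS$name
  grids
}

.material_tables <- function() {
  if (is.null(.tbimc$tables)) .tbimc$tables <- .build_material_tables()
  .tbimc$tables
}

#' Material coefficient table
#'
#' Returns the embedded physics table for one material: mass attenuation
#' coefficient components (photoelectric, Compton, Rayleigh) and the mass
#' collision stopping power, on a 10 keV energy grid from 10 keV to 1.33 MeV.
#'
#' @param material material name (`"air"`, `"lung"`, `"soft_tissue"`,
#'   `"bone"`, `"aluminum"`, `"lead"`) or id (1-6).
#' @return a data.frame with columns `energy` (MeV), `pe`, `compton`,
#'   `rayleigh`, `total` (cm^2/g) and `stopping_power` (MeV cm^2/g).
#' @export
#' @examples
#' head(material_table("soft_tissue"))
material_table <- function(material = "soft_tissue") {
  .material_tables()[[.material_row(material)]]
}

#' List of supported materials
#' @return data.frame of material ids, names and reference properties.
#' @export
materials <- function() .MATERIALS

#' Write material tables as plain-text files
#'
#' Serializes every material table to `<dir>/<name>.csv` with a schema
#' `energy, pe, compton, rayleigh, total, stopping_power` per row.
#'
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_material_tables <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(.MATERIALS$name, function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(material_table(nm), p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

# ---- HU -> density -> material ---------------------------------------------

#' CT number to density calibration model
#'
#' Bilinear calibration: density = slope * HU + intercept with separate
#' slopes below and above HU = 0, continuous at 0, clamped to a small
#' positive floor. Material ids are assigned from density bands.
#'
#' @param slope_neg slope for HU <= 0 \[g/cm^3 per HU\].
#' @param slope_pos slope for HU > 0 \[g/cm^3 per HU\].
#' @param intercept density at HU = 0 \[g/cm^3\].
#' @param floor minimum density returned \[g/cm^3\].
#' @param bin_edges increasing density edges \[g/cm^3\] separating
#'   air | lung | soft tissue | bone | metal (aluminum).
#' @return an object of class `density_model`.
#' @export
density_model <- function(slope_neg = 0.001, slope_pos = 0.0006,
                          intercept = 1.034, floor = 0.001,
                          bin_edges = c(0.05, 0.6, 1.1, 2.0)) {
  stopifnot(length(bin_edges) == 4, !is.unsorted(bin_edges), floor > 0)
  structure(list(slope_neg = slope_neg, slope_pos = slope_pos,
                 intercept = intercept, floor = floor, bin_edges = bin_edges),
            class = "density_model")
}

#' Convert Hounsfield units to mass density
#'
#' @param hu numeric vector of CT numbers (finite).
#' @param model a [density_model()].
#' @return densities \[g/cm^3\], clamped to `model$floor`.
#' @export
#' @examples
#' hu_to_density(c(-1000, 0, 1000))
hu_to_density <- function(hu, model = density_model()) {
  if (!all(is.finite(hu))) stop("non-finite HU value")
  d <- ifelse(hu <= 0, model$slope_neg * hu, model$slope_pos * hu) +
    model$intercept
  pmax(d, model$floor)
}

#' Assign a material id from mass density
#'
#' Bands (defaults): density < 0.05 air; 0.05-0.6 lung; 0.6-1.1 soft
#' tissue; 1.1-2.0 bone; above 2.0 metal (aluminum). The patient material
#' set excludes lead.
#'
#' @param density numeric vector, g/cm^3, positive.
#' @param model a [density_model()].
#' @return integer material ids (named by material).
#' @export
density_to_material <- function(density, model = density_model()) {
  stopifnot(all(density > 0))
  id <- findInterval(density, model$bin_edges) + 1L
  names(id) <- .MATERIALS$name[id]
  id
}

# ---- lookups ----------------------------------------------------------------

.check_energy <- function(energy, lo = 0.01, hi = 1.33) {
  if (any(!is.finite(energy)) || any(energy < lo) || any(energy > hi))
    stop(sprintf("energy outside table range [%g, %g] MeV", lo, hi))
}

#' Mass attenuation coefficient components
#'
#' Log-log interpolation of the embedded component tables.
#'
#' @param material material name or id.
#' @param energy photon energy in MeV, within \[0.01, 1.33\].
#' @return data.frame with columns `pe`, `compton`, `rayleigh` \[cm^2/g\].
#' @export
#' @examples
#' mass_attenuation("soft_tissue", 1.25)
mass_attenuation <- function(material, energy) {
  .check_energy(energy)
  tab <- material_table(material)
  data.frame(
    pe       = .loglog_interp(energy, tab$energy, tab$pe),
    compton  = .loglog_interp(energy, tab$energy, tab$compton),
    rayleigh = .loglog_interp(energy, tab$energy, tab$rayleigh)
  )
}

#' Photon mean free path
#'
#' lambda = 1 / (mass attenuation x density). Inside the patient the
#' Rayleigh component is excluded from transport; set
#' `include_rayleigh = FALSE` to match that convention.
#'
#' @param material material name or id.
#' @param density g/cm^3, positive.
#' @param energy MeV.
#' @param include_rayleigh include the coherent component (default TRUE,
#'   as in the filter; the in-patient engine uses FALSE).
#' @return mean free path in cm.
#' @export
#' @examples
#' mean_free_path("soft_tissue", 1.0, 1.25)
mean_free_path <- function(material, density, energy, include_rayleigh = TRUE) {
  stopifnot(all(density > 0))
  mu <- mass_attenuation(material, energy)
  tot <- mu$pe + mu$compton + if (include_rayleigh) mu$rayleigh else 0
  1 / (tot * density)
}

#' Electron mass collision stopping power
#'
#' @param material material name or id.
#' @param energy electron kinetic energy in MeV, within \[0.01, 1.33\].
#' @return stopping power \[MeV cm^2/g\].
#' @export
#' @examples
#' collision_stopping_power("soft_tissue", 0.3)
collision_stopping_power <- function(material, energy) {
  .check_energy(energy)
  m <- .MATERIALS[.material_row(material), ]
  .bethe_collision(energy, m$za, m$i_ev)
}

#' Water/medium stopping-power ratio
#'
#' Bragg-Gray conversion factor evaluated at an average electron energy of
#' 0.3 MeV: `S_col(water) / S_col(material)`.
#'
#' @param material material name or id.
#' @return dimensionless ratio (exactly 1 for soft tissue/water).
#' @export
water_spr <- function(material) {
  collision_stopping_power("soft_tissue", 0.3) /
    collision_stopping_power(material, 0.3)
}
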