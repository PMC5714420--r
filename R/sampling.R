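# Discretized inverse-CDF angle sampling, Compton kinematics and direction
# rotation.
#
# Both scattering processes are sampled from pre-built tables: the
# differential cross-section is discretized at 1 degree resolution, summed
# cumulatively, normalized, and 1001 equal-probability slots on [0,1] are
# filled with the angle whose cumulative probability first reaches the slot
# value. Sampling is then a single table lookup: round(u * 1000) indexes the
# slot -- no per-event comparison. Tables exist for every 10 keV energy from
# 10 keV to 1.25 MeV; photon energies snap to the nearest row.

#' Klein-Nishina differential cross-section
#'
#' Differential Compton cross-section per unit solid angle, in units of the
#' squared classical electron radius (r0^2/sr): at `theta = 0` the value is
#' exactly 1 (i.e. r0^2).
#'
#' @param hv incident photon energy \[MeV\], positive.
#' @param theta polar scattering angle \[radians\], in \[0, pi\].
#' @return cross-section in units of r0^2 per steradian.
#' @export
#' @examples
#' klein_nishina_dcs(1.25, 0)      # exactly 1
#' klein_nishina_dcs(1.25, pi)
klein_nishina_dcs <- function(hv, theta) {
  stopifnot(all(hv > 0), all(theta >= 0), all(theta <= pi + 1e-12))
  hvp <- compton_scattered_energy(hv, theta)
  r <- hvp / hv
  0.5 * r^2 * (1 / r + r - sin(theta)^2)
}

#' Compton scattered photon energy
#'
#' `hv' = hv / (1 + hv/m0c^2 (1 - cos theta))` with `m0c^2 = 0.511` MeV.
#'
#' @inheritParams klein_nishina_dcs
#' @return scattered photon energy \[MeV\]; never exceeds `hv`, bounded
#'   below by the backscatter energy `hv / (1 + 2 hv / m0c^2)`.
#' @export
#' @examples
#' compton_scattered_energy(1.25, pi)  # 0.2122 MeV
compton_scattered_energy <- function(hv, theta) {
  stopifnot(all(hv > 0))
  hv / (1 + hv / MEC2 * (1 - cos(theta)))
}

# tabulated atomic form factor for lead, F(x) vs momentum transfer
# x = E[keV] sin(theta/2) / 12.39842 in inverse Angstrom; interpolated from
# standard coherent-scattering tabulations (F(0) = Z = 82).
.PB_FF <- list(
  x = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 1.0, 1.5, 2, 3, 4, 5, 6,
        8, 10, 15, 20, 40, 80, 200),
  f = c(82, 74.8, 62.9, 53.1, 45.6, 40.1, 35.8, 29.9, 25.5, 18.2, 14.1,
        9.9, 7.5, 6.0, 5.0, 3.7, 2.9, 1.8, 1.3, 0.5, 0.18, 0.04)
)

.lead_form_factor <- function(x) {
  exp(approx(.PB_FF$x, log(.PB_FF$f), xout = pmin(x, 200), rule = 2)$y)
}

#' Rayleigh angular sampling density
#'
#' Unnormalized polar-angle density for coherent scattering,
#' `(1 + cos^2 theta) sin(theta) F^2(q)` with the atomic form factor F and
#' momentum transfer `q = 2 hv sin(theta/2)`. The density already contains
#' the solid-angle Jacobian `sin(theta)` and vanishes at both 0 and pi.
#' `literal = TRUE` switches the angular factor to `(1 - cos^2 theta)`.
#'
#' @inheritParams klein_nishina_dcs
#' @param material only `"lead"` is supported (filter use).
#' @param literal use the alternative `(1 - cos^2)` angular factor.
#' @return unnormalized density values.
#' @export
rayleigh_dcs <- function(hv, theta, material = "lead", literal = FALSE) {
  if (!identical(.MATERIALS$name[.material_row(material)], "lead"))
    stop("Rayleigh sampling tables are built for the lead filter only")
  x <- hv * 1000 * sin(theta / 2) / 12.39842
  ang <- if (literal) (1 - cos(theta)^2) else (1 + cos(theta)^2)
  ang * sin(theta) * .lead_form_factor(x)^2
}

#' Build a discretized inverse-CDF angle table
#'
#' @param process `"compton"` or `"rayleigh"`.
#' @param material material for the Rayleigh form factor (lead); ignored
#'   for Compton, whose per-electron cross-section is material independent.
#' @param energies table rows \[MeV\]; default every 10 keV from 10 keV to
#'   1.25 MeV.
#' @param n_bins number of uniform-deviate slots minus one (default 1000,
#'   giving slots `round(u * 1000)` for u in \[0,1\]).
#' @param literal for Rayleigh, use the `(1 - cos^2)` angular factor.
#' @param cache_dir optional directory; the built table is stored to /
#'   re-read from an `.rds` keyed by process, material and grid so repeated
#'   runs skip the rebuild.
#' @return an object of class `angle_table`: list with `process`,
#'   `energies` and `slots`, a `(n_bins + 1) x length(energies)` integer
#'   matrix of polar angles in degrees.
#' @export
build_angle_table <- function(process = c("compton", "rayleigh"),
                              material = "lead",
                              energies = seq(0.01, 1.25, by = 0.01),
                              n_bins = 1000, literal = FALSE,
                              cache_dir = NULL) {
  process <- match.arg(process)
  if (!is.null(cache_dir)) {
    key <- sprintf("angle-%s-%s-%d-%d-%s.rds", process,
                   if (process == "rayleigh") material else "any",
                   length(energies), n_bins, if (literal) "lit" else "std")
    path <- file.path(cache_dir, key)
    if (file.exists(path)) return(readRDS(path))
  }
  deg <- 0:180
  th <- deg * pi / 180
  slots <- matrix(0L, nrow = n_bins + 1L, ncol = length(energies))
  u <- (0:n_bins) / n_bins
  for (j in seq_along(energies)) {
    pdf <- if (process == "compton") {
      klein_nishina_dcs(energies[j], th) * sin(th)
    } else {
      rayleigh_dcs(energies[j], th, material, literal = literal)
    }
    cdf <- cumsum(pdf) / sum(pdf)
    idx <- findInterval(u - 1e-12, cdf) + 1L
    slots[, j] <- deg[pmin(idx, length(deg))]
  }
  tab <- structure(list(process = process,
                        material = if (process == "rayleigh") material else NA,
                        energies = energies, n_bins = n_bins, slots = slots),
                   class = "angle_table")
  if (!is.null(cache_dir)) {
    if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
    saveRDS(tab, path)
  }
  tab
}

.energy_row <- function(table, energy) {
  if (any(energy < min(table$energies) - 0.005))
    stop("energy below cutoff: particle should have been absorbed")
  vapply(energy, function(e) which.min(abs(table$energies - e)), integer(1))
}

#' Sample polar scattering angles from an angle table
#'
#' Draws `round(u * 1000)` as the slot index for uniform deviates u; the
#' photon energy snaps to the nearest 10 keV table row.
#'
#' @param table an [build_angle_table()] result.
#' @param energy photon energy \[MeV\] (single value).
#' @param n number of draws.
#' @return polar angles in radians, in \[0, pi\].
#' @export
sample_angle <- function(table, energy, n = 1) {
  j <- .energy_row(table, energy)
  m <- round(runif(n) * table$n_bins)
  table$slots[m + 1L, j] * pi / 180
}

#' Sample an azimuthal angle uniformly on \[0, 2 pi)
#'
#' @param n number of draws.
#' @return angles in radians.
#' @export
sample_azimuth <- function(n = 1) runif(n, 0, 2 * pi)

#' Rotate a direction vector by scattering angles
#'
#' Deflects the unit vector `u` by polar angle `theta` (relative to `u`)
#' and azimuth `psi`, using a local orthonormal frame tied to the global
#' z-axis (the standard well-posed form of the scattering rotation; a
#' dedicated branch handles near-vertical `u`).
#'
#' @param u numeric length-3 unit vector, or an n x 3 matrix of unit rows.
#' @param theta polar angle(s) \[radians\].
#' @param psi azimuthal angle(s) \[radians\].
#' @return rotated unit vector(s), same shape as `u`.
#' @export
rotate_direction <- function(u, theta, psi) {
  vec <- is.null(dim(u))
  if (vec) u <- matrix(u, nrow = 1)
  if (any(abs(sqrt(rowSums(u^2)) - 1) > 1e-6))
    stop("direction must be a unit vector")
  theta <- rep_len(theta, nrow(u))
  psi <- rep_len(psi, nrow(u))
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(psi);   sp <- sin(psi)
  uz <- u[, 3]
  s2 <- sqrt(pmax(1 - uz^2, 0))
  ok <- s2 > 1e-10
  out <- u
  # general case
  out[ok, 1] <- u[ok, 1] * ct[ok] +
    st[ok] * (u[ok, 1] * uz[ok] * cp[ok] - u[ok, 2] * sp[ok]) / s2[ok]
  out[ok, 2] <- u[ok, 2] * ct[ok] +
    st[ok] * (u[ok, 2] * uz[ok] * cp[ok] + u[ok, 1] * sp[ok]) / s2[ok]
  out[ok, 3] <- uz[ok] * ct[ok] - s2[ok] * st[ok] * cp[ok]
  # near-vertical: polar axis frame
  nk <- !ok
  if (any(nk)) {
    sgn <- sign(uz[nk] + (uz[nk] == 0))
    out[nk, 1] <- st[nk] * cp[nk] * sgn
    out[nk, 2] <- st[nk] * sp[nk] * sgn
    out[nk, 3] <- ct[nk] * sgn
  }
  out <- out / sqrt(rowSums(out^2))
  if (vec) out[1, ] else out
}

#' Compton recoil electron direction
#'
#' Polar angle of the recoil electron from the standard kinematic relation
#' `cot(phi) = (1 + hv/m0c^2) tan(theta/2)`; its azimuth is opposite the
#' photon's (`psi + 180` degrees). `literal = TRUE` uses the
#' `(1 - hv/m0c^2)` variant instead (kept as a switch; it produces
#' backward-directed recoils, which momentum conservation forbids).
#'
#' @param hv incident photon energy \[MeV\].
#' @param theta_photon photon polar scattering angle \[radians\], in
#'   (0, pi\]; at exactly 0 there is no energy transfer and no recoil
#'   electron (returns `NA` angles).
#' @param psi_photon photon azimuthal angle \[radians\].
#' @param literal use the alternative sign.
#' @return list with `phi` (polar, radians, in \[0, pi/2\]) and `psi`
#'   (azimuth, radians).
#' @export
recoil_electron_direction <- function(hv, theta_photon, psi_photon,
                                      literal = FALSE) {
  fac <- if (literal) (1 - hv / MEC2) else (1 + hv / MEC2)
  cotphi <- fac * tan(theta_photon / 2)
  phi <- ifelse(theta_photon <= 0, NA_real_, atan2(1, cotphi))
  list(phi = phi, psi = (psi_photon + pi) %% (2 * pi))
}

#' Reproducible random stream
#'
#' Thin wrapper over R's Mersenne-Twister generator: seeds the global RNG
#' and records the seed, so identical seeds give identical deviate
#' sequences across the package's sampling functions.
#'
#' @param seed integer seed.
#' @return an object of class `random_stream`.
#' @export
random_stream <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister")
  structure(list(seed = seed), class = "random_stream")
}
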