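# In-patient voxel Monte Carlo: grid and config containers, the
# run_simulation() driver over the compiled transport core, dose-to-water
# conversion, and plain-R single-particle reference implementations of the
# transport steps (used by the test-suite to cross-check the compiled
# engine and as an executable description of the algorithm).

#' Voxelized phantom / patient grid
#'
#' @param hu 3-D array of Hounsfield units (x, y, z); z is the vertical
#'   (beam) axis, increasing upward.
#' @param voxel_size voxel edge lengths `c(dx, dy, dz)` \[cm\].
#' @param origin world position of the corner of voxel (1,1,1) \[cm\];
#'   default centers the grid laterally on the beam axis and puts its base
#'   at `table_height` above the floor.
#' @param model [density_model()] used for HU to density conversion and
#'   material binning.
#' @param table_height height of the phantom support above the floor
#'   \[cm\] (treatment table convention).
#' @return object of class `voxel_grid` with `hu`, `density`, `material`
#'   arrays and placement metadata. Voxel `(i,j,k)` spans the half-open box
#'   `origin + (i-1..i) * voxel_size` etc.
#' @export
voxel_grid <- function(hu, voxel_size, origin = NULL,
                       model = density_model(), table_height = 6.0) {
  stopifnot(length(dim(hu)) == 3, length(voxel_size) == 3,
            all(voxel_size > 0))
  shape <- dim(hu)
  if (is.null(origin)) {
    origin <- c(-shape[1] * voxel_size[1] / 2,
                -shape[2] * voxel_size[2] / 2,
                table_height)
  }
  density <- array(hu_to_density(hu, model), dim = shape)
  material <- array(unname(density_to_material(density, model)), dim = shape)
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin,
                 hu = hu, density = density, material = material,
                 model = model, table_height = table_height),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels of %.3g x %.3g x %.3g cm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  extent: %.1f x %.1f x %.1f cm, base at z = %.1f cm\n",
              x$shape[1] * x$voxel_size[1], x$shape[2] * x$voxel_size[2],
              x$shape[3] * x$voxel_size[3], x$origin[3]))
  tb <- table(.MATERIALS$name[x$material])
  cat("  materials:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Transport configuration
#'
#' @param n_histories number of source photons to simulate.
#' @param step photon step size h \[cm\] (1 mm).
#' @param electron_step electron CSDA sub-step \[cm\]; defaults to `step/5`
#'   because Compton-electron ranges at this beam energy (up to ~0.44 cm)
#'   are comparable to one photon step.
#' @param cutoff transport cutoff for photons and electrons \[MeV\]; below
#'   it a particle's remaining energy is deposited in the local voxel.
#' @param seed integer seed for the engine's Mersenne twister.
#' @return object of class `transport_config`.
#' @export
transport_config <- function(n_histories = 1e6, step = 0.1,
                             electron_step = step / 5, cutoff = 0.01,
                             seed = 1) {
  stopifnot(step > 0, electron_step > 0, cutoff > 0, n_histories >= 1)
  structure(list(n_histories = n_histories, step = step,
                 electron_step = electron_step, cutoff = cutoff, seed = seed),
            class = "transport_config")
}

# engine lookup tables on the 10 keV grid up to 1.25 MeV, patient material
# set (air, lung, soft tissue, bone, aluminum -- no lead)
.engine_physics <- function() {
  if (!is.null(.tbimc$engine)) return(.tbimc$engine)
  rows <- which(.ENERGY_GRID <= 1.25 + 1e-9)
  mats <- .MATERIALS$name[1:5]
  att <- pefrac <- spow <- matrix(0, length(rows), length(mats))
  for (m in seq_along(mats)) {
    tab <- material_table(mats[m])
    att[, m] <- tab$pe[rows] + tab$compton[rows] # Rayleigh excluded in patient
    pefrac[, m] <- tab$pe[rows] / att[, m]
    spow[, m] <- tab$stopping_power[rows]
  }
  ct <- build_angle_table("compton")
  rt <- build_angle_table("rayleigh", "lead")
  lead_tab <- material_table("lead")
  rho_pb <- .MATERIALS$density[.MATERIALS$name == "lead"]
  i125 <- which.min(abs(lead_tab$energy - 1.25))
  .tbimc$engine <- list(
    att = att, pefrac = pefrac, spow = spow,
    cang = ct$slots * pi / 180,
    ray125 = rt$slots[, .energy_row(rt, 1.25)] * pi / 180,
    lead = list(mu125 = lead_tab$total[i125] * rho_pb,
                wpe = lead_tab$pe[i125], wc = lead_tab$compton[i125],
                wr = lead_tab$rayleigh[i125],
                mu_total = lead_tab$total[rows] * rho_pb),
    spr = vapply(1:5, water_spr, numeric(1))
  )
  .tbimc$engine
}

.engine_grid_args <- function(grid) {
  list(dims = as.integer(grid$shape),
       vox = as.numeric(grid$voxel_size),
       origin = as.numeric(grid$origin),
       density = as.numeric(grid$density),
       material = as.integer(grid$material))
}

.as_dose_grid <- function(res, grid, config) {
  vol <- prod(grid$voxel_size)
  dose_medium <- res$edep / (vol * grid$density)
  ep <- .engine_physics()
  spr <- array(ep$spr[grid$material], dim = grid$shape)
  counters <- res[setdiff(names(res), "edep")]
  structure(list(energy_deposited = res$edep, dose_medium = dose_medium,
                 dose_water = dose_medium * spr,
                 histories = config$n_histories, config = config,
                 grid = grid[c("shape", "voxel_size", "origin")],
                 material = grid$material, counters = counters),
            class = "dose_grid")
}

#' Run the full TBI dose simulation
#'
#' Per history: emit a collimated 1.25 MeV photon, transport it through the
#' flattening filter (zero/single scatter), project it to the phantom entry
#' window, then run the in-patient cascade (survival-probability photon
#' stepping, Compton/photoelectric interactions, straight-line CSDA
#' electrons) until every descendant is absorbed, cut off, or leaves the
#' grid. Deterministic for a fixed `config$seed`.
#'
#' @param grid a [voxel_grid()].
#' @param source a [co60_source()].
#' @param filt a [flattening_filter()].
#' @param config a [transport_config()].
#' @return object of class `dose_grid`: per-voxel deposited energy \[MeV\],
#'   `dose_medium` and `dose_water` \[MeV/g\] (per run, not per history),
#'   plus transport counters (`n_entered`, `energy_entered`,
#'   `energy_exited`, `energy_deposited`, ...).
#' @export
run_simulation <- function(grid, source = co60_source(),
                           filt = flattening_filter(),
                           config = transport_config()) {
  stopifnot(inherits(grid, "voxel_grid"), config$n_histories >= 1,
            prod(grid$shape) > 0)
  if (grid$origin[3] < 0 ||
      grid$origin[3] + grid$shape[3] * grid$voxel_size[3] >= source$height)
    stop("grid must lie between the floor and the source")
  ep <- .engine_physics()
  ga <- .engine_grid_args(grid)
  res <- cpp_simulate(ga$dims, ga$vox, ga$origin, ga$density, ga$material,
                      ep$att, ep$pefrac, ep$spow, ep$cang, ep$ray125,
                      list(radius = source$radius, height = source$height,
                           energy = source$energy, field = source$field),
                      list(radii = filt$diameters / 2,
                           plate_thickness = filt$plate_thickness,
                           clip_halfwidth = filt$envelope[2] / 2,
                           zmid = .filter_midplane_z(filt, source)),
                      ep$lead, unclass(config))
  .as_dose_grid(res, grid, config)
}

#' Transport a prepared set of photons through a grid
#'
#' Lower-level driver used for beam experiments and validation: takes
#' photons already positioned on (or in) the grid and runs only the
#' in-patient transport.
#'
#' @param photons data.frame as produced by [emit_photons()] /
#'   [project_to_entry_window()].
#' @inheritParams run_simulation
#' @return a `dose_grid`.
#' @export
transport_photons <- function(photons, grid, config = transport_config()) {
  ep <- .engine_physics()
  ga <- .engine_grid_args(grid)
  ph <- as.matrix(photons[, c("x", "y", "z", "ux", "uy", "uz", "energy")])
  res <- cpp_transport_photons(ph, ga$dims, ga$vox, ga$origin, ga$density,
                               ga$material, ep$att, ep$pefrac, ep$spow,
                               ep$cang, unclass(config))
  config$n_histories <- nrow(ph)
  .as_dose_grid(res, grid, config)
}

#' Convert a dose grid to dose-to-water
#'
#' Multiplies the per-voxel dose-to-medium by the water/medium stopping
#' power ratio at 0.3 MeV (Bragg-Gray). Idempotent: water voxels are
#' unchanged, and `dose_water` is recomputed from `dose_medium`.
#'
#' @param dose a `dose_grid`.
#' @return the `dose_grid` with `dose_water` (re)computed.
#' @export
dose_to_water <- function(dose) {
  ep <- .engine_physics()
  spr <- array(ep$spr[dose$material], dim = dose$grid$shape)
  dose$dose_water <- dose$dose_medium * spr
  dose
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels, %g histories\n",
              paste(x$grid$shape, collapse = " x "), x$histories))
  cat(sprintf("  entered: %g photons, %.4g MeV\n",
              x$counters$n_entered, x$counters$energy_entered))
  cat(sprintf("  deposited %.4g MeV, exited %.4g MeV\n",
              x$counters$energy_deposited, x$counters$energy_exited))
  invisible(x)
}

#' @export
summary.dose_grid <- function(object, ...) {
  pdd <- extract_pdd(object)
  cat(sprintf("Dose grid: %s voxels, %g histories\n",
              paste(object$grid$shape, collapse = " x "), object$histories))
  cat(sprintf("  max dose-to-water: %.4g MeV/g\n",
              max(object$dose_water)))
  cat(sprintf("  central-axis depth of maximum: %.2f cm\n",
              depth_of_maximum(pdd, method = "argmax")))
  cat(sprintf("  energy balance: entered %.6g = deposited %.6g + exited %.6g MeV\n",
              object$counters$energy_entered,
              object$counters$energy_deposited, object$counters$energy_exited))
  invisible(object)
}

#' @param x a `dose_grid`.
#' @param what which dose array to display.
#' @param ... passed to [graphics::image()].
#' @describeIn run_simulation display the central longitudinal dose slice.
#' @export
plot.dose_grid <- function(x, what = c("dose_water", "dose_medium"), ...) {
  what <- match.arg(what)
  sl <- x[[what]][, , ]
  i <- ceiling(x$grid$shape[1] / 2)
  img <- sl[i, , ]
  yy <- x$grid$origin[2] + (seq_len(x$grid$shape[2]) - 0.5) * x$grid$voxel_size[2]
  zz <- x$grid$origin[3] + (seq_len(x$grid$shape[3]) - 0.5) * x$grid$voxel_size[3]
  graphics::image(yy, zz, img, xlab = "y [cm]", ylab = "z [cm]",
                  main = paste("central slice,", what), ...)
  invisible(x)
}

# ---- plain-R reference transport steps -------------------------------------

.voxel_index <- function(grid, pos) {
  i <- floor((pos - grid$origin) / grid$voxel_size) + 1
  if (any(i < 1) || any(i > grid$shape)) NULL else as.integer(i)
}

#' Step a photon to its next interaction site (reference implementation)
#'
#' Survival-probability stepping: one uniform survival threshold is drawn
#' for the whole flight, then the photon advances in steps of `config$step`
#' while the accumulated transmission `exp(-sum h / lambda_j)` (lambda from
#' the voxel at each step midpoint, Rayleigh excluded) is above the
#' threshold. Single-photon R version of the compiled engine, for testing
#' and illustration.
#'
#' @param photon list or one-row data.frame with `x, y, z, ux, uy, uz,
#'   energy`.
#' @param grid a [voxel_grid()].
#' @param config a [transport_config()].
#' @return list with `exited` (logical), and when `exited` is `FALSE`:
#'   `position` (site), `voxel` (ijk index), `depth` (path length \[cm\]).
#' @export
step_photon_to_interaction <- function(photon, grid,
                                       config = transport_config()) {
  ep <- .engine_physics()
  row <- max(1L, min(nrow(ep$att), as.integer(round(photon$energy / 0.01))))
  tau_th <- -log(runif(1))
  pos <- c(photon$x, photon$y, photon$z)
  dir <- c(photon$ux, photon$uy, photon$uz)
  h <- config$step
  tau <- 0; len <- 0
  repeat {
    mid <- pos + 0.5 * h * dir
    v <- .voxel_index(grid, mid)
    if (is.null(v)) return(list(exited = TRUE))
    rho <- grid$density[v[1], v[2], v[3]]
    mat <- grid$material[v[1], v[2], v[3]]
    tau <- tau + h * rho * ep$att[row, mat]
    pos <- pos + h * dir
    len <- len + h
    if (tau >= tau_th)
      return(list(exited = FALSE, position = pos, voxel = v, depth = len))
  }
}

#' Choose the interaction process in a voxel (reference implementation)
#'
#' Photoelectric vs Compton, drawn proportional to the two mass attenuation
#' components at the photon energy in the voxel material (Rayleigh is
#' excluded in the patient).
#'
#' @param energy photon energy \[MeV\].
#' @param material material name or id.
#' @param n number of draws.
#' @return character vector of `"photoelectric"` / `"compton"`.
#' @export
choose_interaction <- function(energy, material, n = 1) {
  mu <- mass_attenuation(material, energy)
  p_pe <- mu$pe / (mu$pe + mu$compton)
  ifelse(runif(n) < p_pe, "photoelectric", "compton")
}

#' Photoelectric absorption (reference implementation)
#'
#' The photon is absorbed and its entire energy is deposited in the
#' interaction voxel: the photo-electron's angular distribution is ignored
#' and its range assumed sub-voxel; binding energy is ignored.
#'
#' @param energy photon energy \[MeV\].
#' @param voxel ijk index.
#' @param dose 3-D array of deposited energy \[MeV\].
#' @return the updated dose array.
#' @export
do_photoelectric <- function(energy, voxel, dose) {
  dose[voxel[1], voxel[2], voxel[3]] <- dose[voxel[1], voxel[2], voxel[3]] +
    energy
  dose
}

#' Compton scattering event (reference implementation)
#'
#' Samples the photon polar angle from the discretized inverse-CDF table at
#' the snapped energy, the azimuth uniformly; computes the scattered energy,
#' rotates the photon, and constructs the recoil electron (energy
#' `hv - hv'`, kinematic polar angle, opposite azimuth).
#'
#' @param photon list with `ux, uy, uz, energy`.
#' @param table a Compton [build_angle_table()].
#' @return list with updated `photon` (direction, energy) and `electron`
#'   (`direction`, `energy`).
#' @export
do_compton <- function(photon, table = build_angle_table("compton")) {
  th <- sample_angle(table, photon$energy, 1)
  psi <- sample_azimuth(1)
  hvp <- compton_scattered_energy(photon$energy, th)
  te <- photon$energy - hvp
  dir0 <- c(photon$ux, photon$uy, photon$uz)
  rec <- recoil_electron_direction(photon$energy, th, psi)
  electron <- list(
    direction = if (th > 0) rotate_direction(dir0, rec$phi, rec$psi) else
      c(NA, NA, NA),
    energy = te)
  newdir <- rotate_direction(dir0, th, psi)
  photon$ux <- newdir[1]; photon$uy <- newdir[2]; photon$uz <- newdir[3]
  photon$energy <- hvp
  list(photon = photon, electron = electron)
}

#' CSDA electron transport (reference implementation)
#'
#' Advances the electron along a straight line in sub-steps, depositing
#' `S_col(E) * rho * h_e` per sub-step (capped at the remaining energy, in
#' which case the final sub-step is shortened accordingly); terminates when
#' the energy falls below the cutoff (remainder deposited locally) or the
#' electron leaves the grid.
#'
#' @param electron list with `x, y, z`, `ux, uy, uz`, `energy` \[MeV\].
#' @param grid a [voxel_grid()].
#' @param dose 3-D array of deposited energy \[MeV\].
#' @param config a [transport_config()].
#' @return list with the updated `dose` array, `exited_energy` \[MeV\] and
#'   `track_length` \[cm\].
#' @export
transport_electron_csda <- function(electron, grid, dose,
                                    config = transport_config()) {
  pos <- c(electron$x, electron$y, electron$z)
  dir <- c(electron$ux, electron$uy, electron$uz)
  e <- electron$energy
  he <- config$electron_step
  len <- 0
  while (e >= config$cutoff) {
    mid <- pos + 0.5 * he * dir
    v <- .voxel_index(grid, mid)
    if (is.null(v))
      return(list(dose = dose, exited_energy = e, track_length = len))
    rho <- grid$density[v[1], v[2], v[3]]
    s <- collision_stopping_power(grid$material[v[1], v[2], v[3]],
                                  max(e, 0.01)) * rho
    de <- s * he
    if (de >= e) {
      step_len <- e / s
      mid2 <- pos + 0.5 * step_len * dir
      v2 <- .voxel_index(grid, mid2)
      if (is.null(v2)) v2 <- v
      dose[v2[1], v2[2], v2[3]] <- dose[v2[1], v2[2], v2[3]] + e
      return(list(dose = dose, exited_energy = 0,
                  track_length = len + step_len))
    }
    dose[v[1], v[2], v[3]] <- dose[v[1], v[2], v[3]] + de
    e <- e - de
    pos <- pos + he * dir
    len <- len + he
  }
  v <- .voxel_index(grid, pos)
  if (!is.null(v)) {
    dose[v[1], v[2], v[3]] <- dose[v[1], v[2], v[3]] + e
    e <- 0
  }
  list(dose = dose, exited_energy = e, track_length = len)
}
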