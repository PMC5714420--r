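# Photon generation from the finite Co-60 source, collimation to the TBI
# field, and zero/single-scatter transport through the stacked lead
# flattening filter.
#
# World frame: floor at z = 0, beam axis vertical (x = y = 0), source disk
# at z = 195.4 cm. Emission targets a point drawn uniformly on the
# 50 x 200 cm field rectangle at floor level ("aperture-target" emission):
# this samples only directions within the collimation limits instead of
# wasting > 99% of isotropic histories. Photons are represented as a
# data.frame, one row per photon, so the filter operations vectorize.

#' Co-60 source model
#'
#' @param radius source disk radius \[cm\].
#' @param height source height above the floor \[cm\].
#' @param energy emission energy \[MeV\]; single effective line, the mean
#'   of the 1.17 and 1.33 MeV emission lines.
#' @param field field size at floor level, `c(width_x, length_y)` \[cm\].
#' @return object of class `co60_source`.
#' @export
co60_source <- function(radius = 2.0, height = 195.4, energy = 1.25,
                        field = c(50, 200)) {
  structure(list(radius = radius, height = height, energy = energy,
                 field = field), class = "co60_source")
}

#' Stacked-plate flattening filter geometry
#'
#' Six concentric round lead plates, 0.3175 cm thick each, clipped to a
#' 33.0 x 14.0 cm envelope (the larger plates are truncated circles in the
#' narrow direction, taken along x, the 50 cm field axis).
#'
#' @param diameters plate diameters \[cm\].
#' @param plate_thickness per-plate thickness \[cm\].
#' @param source_to_bottom distance from source to filter bottom \[cm\].
#' @param envelope filter footprint `c(length_y, width_x)` \[cm\].
#' @return object of class `flattening_filter`.
#' @export
flattening_filter <- function(diameters = c(7.62, 12.7, 17.8, 22.9, 27.9, 33.0),
                              plate_thickness = 0.3175,
                              source_to_bottom = 25.4,
                              envelope = c(33.0, 14.0)) {
  structure(list(diameters = diameters, plate_thickness = plate_thickness,
                 source_to_bottom = source_to_bottom, envelope = envelope),
            class = "flattening_filter")
}

#' Emit collimated photons from the source
#'
#' Origins are sampled uniformly on the source disk; each direction points
#' from its origin to a point drawn uniformly on the field rectangle at
#' floor level. All photons carry the single line energy.
#'
#' @param n number of photons.
#' @param source a [co60_source()].
#' @return data.frame with columns `x, y, z` \[cm\], unit direction
#'   `ux, uy, uz`, `energy` \[MeV\] and `scatter_count`.
#' @export
emit_photons <- function(n, source = co60_source()) {
  r <- source$radius * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  x0 <- r * cos(a); y0 <- r * sin(a); z0 <- rep(source$height, n)
  tx <- (runif(n) - 0.5) * source$field[1]
  ty <- (runif(n) - 0.5) * source$field[2]
  dx <- tx - x0; dy <- ty - y0; dz <- -z0
  nrm <- sqrt(dx^2 + dy^2 + dz^2)
  data.frame(x = x0, y = y0, z = z0,
             ux = dx / nrm, uy = dy / nrm, uz = dz / nrm,
             energy = source$energy, scatter_count = 0L)
}

.filter_midplane_z <- function(filt, source) {
  source$height - filt$source_to_bottom + 3 * filt$plate_thickness
}

#' Lead thickness along a photon ray
#'
#' Thin-stack model: the ray's lateral position is evaluated once at the
#' filter mid-plane and the thickness is 0.3175 cm times the number of
#' plates whose clipped disk covers that position.
#'
#' @param photons photon data.frame (see [emit_photons()]), heading down.
#' @param filt a [flattening_filter()].
#' @param source a [co60_source()] (fixes the filter plane height).
#' @return numeric vector of thicknesses \[cm\].
#' @export
filter_path_thickness <- function(photons, filt = flattening_filter(),
                                  source = co60_source()) {
  zf <- .filter_midplane_z(filt, source)
  s <- (zf - photons$z) / photons$uz
  px <- photons$x + s * photons$ux
  py <- photons$y + s * photons$uy
  rr <- sqrt(px^2 + py^2)
  radii <- filt$diameters / 2
  counts <- rowSums(outer(rr, radii, `<=`))
  counts[abs(px) > filt$envelope[2] / 2] <- 0
  counts * filt$plate_thickness
}

# lead data needed by the filter: linear attenuation and process weights at
# 1.25 MeV, total linear attenuation vs energy for scattered-photon escape,
# plus the two angle-sampling tables
.filter_tables <- function(literal = FALSE) {
  key <- if (literal) "filter_literal" else "filter_std"
  if (is.null(.tbimc[[key]])) {
    tab <- material_table("lead")
    rho <- .MATERIALS$density[.MATERIALS$name == "lead"]
    i125 <- which.min(abs(tab$energy - 1.25))
    .tbimc[[key]] <- list(
      rho = rho,
      mu_total_125 = tab$total[i125] * rho,
      weights = c(pe = tab$pe[i125], compton = tab$compton[i125],
                  rayleigh = tab$rayleigh[i125]),
      energies = tab$energy, mu_total = tab$total * rho,
      compton_table = build_angle_table("compton"),
      rayleigh_table = build_angle_table("rayleigh", "lead",
                                         literal = literal)
    )
  }
  .tbimc[[key]]
}

#' Transport photons through the flattening filter
#'
#' Zero/single-scatter model: each photon survives unscattered with
#' probability `exp(-mu t)`; otherwise exactly one interaction is drawn
#' with probabilities proportional to the photoelectric / Compton /
#' Rayleigh shares of the lead attenuation coefficient at 1.25 MeV.
#' Photoelectric absorbs the photon (the electron is dismissed). Compton
#' redirects and degrades the photon (recoil electron dismissed); Rayleigh
#' redirects it at full energy. A scattered photon must then escape the
#' remaining filter thickness without further interaction, or it is
#' dismissed; upward-scattered photons are dismissed. No electrons leave
#' the filter.
#'
#' @param photons photon data.frame at the line energy.
#' @param filt a [flattening_filter()].
#' @param source a [co60_source()].
#' @param literal use the literal Rayleigh angular factor (see
#'   [rayleigh_dcs()]).
#' @return the surviving photons (rows of `photons`, directions/energies
#'   updated, `scatter_count` at most 1), positioned at the filter plane.
#' @export
transport_through_filter <- function(photons, filt = flattening_filter(),
                                     source = co60_source(),
                                     literal = FALSE) {
  ft <- .filter_tables(literal)
  t_pb <- filter_path_thickness(photons, filt, source)
  zf <- .filter_midplane_z(filt, source)
  s <- (zf - photons$z) / photons$uz
  photons$x <- photons$x + s * photons$ux
  photons$y <- photons$y + s * photons$uy
  photons$z <- zf

  mu <- ft$mu_total_125
  u <- runif(nrow(photons))
  pass <- u < exp(-mu * t_pb)
  hit <- which(!pass)
  if (length(hit)) {
    w <- ft$weights / sum(ft$weights)
    proc <- sample.int(3L, length(hit), replace = TRUE, prob = w)
    keep <- logical(length(hit))
    th <- numeric(length(hit))
    en <- photons$energy[hit]
    cs <- proc == 2L
    rs <- proc == 3L
    if (any(cs)) {
      th[cs] <- sample_angle(ft$compton_table, 1.25, sum(cs))
      en[cs] <- compton_scattered_energy(1.25, th[cs])
    }
    if (any(rs)) th[rs] <- sample_angle(ft$rayleigh_table, 1.25, sum(rs))
    sc <- cs | rs
    if (any(sc)) {
      i <- hit[sc]
      psi <- sample_azimuth(sum(sc))
      newdir <- rotate_direction(as.matrix(photons[i, c("ux", "uy", "uz")]),
                                 th[sc], psi)
      # interaction depth within t, then escape through the remainder
      tt <- t_pb[i]
      v <- runif(sum(sc))
      depth <- -log(1 - v * (1 - exp(-mu * tt))) / mu
      downward <- newdir[, 3] < 0
      mu_e <- approx(ft$energies, ft$mu_total, xout = en[sc], rule = 2)$y
      esc <- runif(sum(sc)) <
        exp(-mu_e * (tt - depth) / pmax(abs(newdir[, 3]), 1e-9))
      ok <- downward & esc
      keep[sc] <- ok
      ii <- i[ok]
      photons[ii, c("ux", "uy", "uz")] <- newdir[ok, , drop = FALSE]
      photons$energy[ii] <- en[sc][ok]
      photons$scatter_count[ii] <- 1L
    }
    drop_rows <- hit[!keep]
    if (length(drop_rows)) photons <- photons[-drop_rows, , drop = FALSE]
  }
  photons
}

#' Project photons to the phantom entry window
#'
#' Straight-line (vacuum) advance to the top plane of the voxel grid;
#' photons whose intersection lies outside the grid's lateral extent are
#' dismissed, as are photons not heading downward.
#'
#' @param photons photon data.frame below the filter.
#' @param grid a [voxel_grid()].
#' @return the accepted photons positioned on the entry plane.
#' @export
project_to_entry_window <- function(photons, grid) {
  ztop <- grid$origin[3] + grid$shape[3] * grid$voxel_size[3]
  down <- photons$uz < 0
  s <- (ztop - photons$z) / photons$uz
  px <- photons$x + s * photons$ux
  py <- photons$y + s * photons$uy
  inside <- down & s >= 0 &
    px >= grid$origin[1] & px < grid$origin[1] + grid$shape[1] * grid$voxel_size[1] &
    py >= grid$origin[2] & py < grid$origin[2] + grid$shape[2] * grid$voxel_size[2]
  photons <- photons[inside, , drop = FALSE]
  photons$x <- px[inside]; photons$y <- py[inside]
  photons$z <- rep(ztop, nrow(photons))
  photons
}
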