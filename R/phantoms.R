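# Validation geometries generated in code: the water tank (with optional
# aluminum insert) and a layered heterogeneous slab phantom. All generators
# are deterministic functions of their arguments.

#' Water tank phantom
#'
#' Uniform water tank, 31.8 x 48.4 x 30 cm by default, HU = 0 everywhere
#' (density 1.034 under the CT calibration), base 6.0 cm above the floor,
#' centred on the beam axis.
#'
#' @param voxel_size voxel edges `c(dx, dy, dz)` \[cm\].
#' @param dimensions tank size `c(x, y, z)` \[cm\]; the voxel count per
#'   axis is `round(dimensions / voxel_size)`.
#' @param model a [density_model()].
#' @return a [voxel_grid()].
#' @export
#' @examples
#' ph <- make_water_phantom(voxel_size = c(1, 1, 1))
make_water_phantom <- function(voxel_size = c(0.254, 0.254, 0.5),
                               dimensions = c(31.8, 48.4, 30),
                               model = density_model()) {
  stopifnot(all(voxel_size > 0), all(dimensions > 0))
  shape <- pmax(1, round(dimensions / voxel_size))
  voxel_grid(array(0, dim = shape), voxel_size, model = model)
}

#' Add a two-bar aluminum insert to a phantom
#'
#' Places two parallel aluminum bars flanking a horizontal measurement
#' plane at the given depth below the phantom surface (the film position in
#' the physical insert). The voxels covered by the bars get aluminum
#' density and material by direct override (the insert is physical
#' aluminum, not a CT artifact).
#'
#' @param grid a [voxel_grid()].
#' @param bar_thickness thickness of each bar along the beam \[cm\].
#' @param depth depth of the measurement plane below the surface \[cm\].
#' @param gap separation between the bars around the plane \[cm\].
#' @param lateral_size bar extent `c(x, y)` \[cm\], centred laterally.
#' @param density aluminum bulk density \[g/cm^3\].
#' @return the modified `voxel_grid`.
#' @export
add_aluminum_insert <- function(grid, bar_thickness = 0.95, depth = 3.0,
                                gap = 0.3, lateral_size = c(10, 10),
                                density = 2.70) {
  ztop <- grid$origin[3] + grid$shape[3] * grid$voxel_size[3]
  zc <- ztop - depth
  zlim <- list(upper = c(zc + gap / 2, zc + gap / 2 + bar_thickness),
               lower = c(zc - gap / 2 - bar_thickness, zc - gap / 2))
  if (zlim$lower[1] < grid$origin[3] || zlim$upper[2] > ztop)
    stop("insert extends outside the grid")
  cx <- grid$origin[1] + (seq_len(grid$shape[1]) - 0.5) * grid$voxel_size[1]
  cy <- grid$origin[2] + (seq_len(grid$shape[2]) - 0.5) * grid$voxel_size[2]
  cz <- grid$origin[3] + (seq_len(grid$shape[3]) - 0.5) * grid$voxel_size[3]
  inx <- abs(cx) <= lateral_size[1] / 2
  iny <- abs(cy) <= lateral_size[2] / 2
  if (!any(inx) || !any(iny)) stop("insert outside the grid laterally")
  al <- .MATERIALS$id[.MATERIALS$name == "aluminum"]
  for (b in zlim) {
    inz <- cz >= b[1] & cz < b[2]
    grid$density[inx, iny, inz] <- density
    grid$material[inx, iny, inz] <- al
  }
  grid
}

#' Layered heterogeneous slab phantom
#'
#' A body-like slab built from horizontal layers of given thickness and
#' Hounsfield value (top layer first, i.e. the layer the beam enters
#' first), with optional embedded box regions (e.g. two low-HU lung blocks
#' and a high-HU spine rod) for heterogeneity studies. This is an
#' anthropomorphic-phantom stand-in by material class only, not a replica
#' of any physical phantom.
#'
#' @param layers data.frame with columns `thickness` \[cm\] and `hu`,
#'   ordered from the beam-entry side down.
#' @param lateral lateral size `c(x, y)` \[cm\].
#' @param voxel_size voxel edges \[cm\].
#' @param regions optional list of box regions, each a list with `center`
#'   `c(x, y, depth)` (depth below the surface, cm), `size` `c(x, y, z)`
#'   \[cm\] and `hu`.
#' @param model a [density_model()].
#' @return a [voxel_grid()].
#' @export
#' @examples
#' slab <- make_layered_body(
#'   layers = data.frame(thickness = c(2, 8, 10), hu = c(0, -700, 0)),
#'   lateral = c(20, 30), voxel_size = c(1, 1, 0.5))
make_layered_body <- function(layers, lateral = c(30, 48),
                              voxel_size = c(0.254, 0.254, 0.5),
                              regions = NULL, model = density_model()) {
  stopifnot(is.data.frame(layers), all(layers$thickness > 0))
  height <- sum(layers$thickness)
  shape <- pmax(1, round(c(lateral, height) / voxel_size))
  hu <- array(0, dim = shape)
  cz_depth <- height - (seq_len(shape[3]) - 0.5) * voxel_size[3]
  bounds <- cumsum(layers$thickness)
  layer_of <- findInterval(cz_depth, c(0, bounds), rightmost.closed = TRUE)
  layer_of <- pmin(pmax(layer_of, 1L), nrow(layers))
  for (k in seq_len(shape[3])) hu[, , k] <- layers$hu[layer_of[k]]
  if (!is.null(regions)) {
    cx <- (seq_len(shape[1]) - 0.5) * voxel_size[1] - lateral[1] / 2
    cy <- (seq_len(shape[2]) - 0.5) * voxel_size[2] - lateral[2] / 2
    for (rg in regions) {
      inx <- abs(cx - rg$center[1]) <= rg$size[1] / 2
      iny <- abs(cy - rg$center[2]) <= rg$size[2] / 2
      inz <- abs(cz_depth - rg$center[3]) <= rg$size[3] / 2
      hu[inx, iny, inz] <- rg$hu
    }
  }
  voxel_grid(hu, voxel_size, model = model)
}
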