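# Dose grid persistence: flat binary array + JSON sidecar, and CSV dose
# planes (the stand-in for film scans) for the gamma tools.

#' Write a dose grid to a flat binary file with a JSON sidecar
#'
#' Writes `<prefix>.bin` (the `energy_deposited`, `dose_medium` and
#' `dose_water` arrays concatenated as little-endian doubles, x fastest)
#' and `<prefix>.json` (shape, voxel size, origin, histories, counters).
#'
#' @param dose a `dose_grid`.
#' @param prefix output path prefix.
#' @return invisibly, the two paths.
#' @export
write_dose <- function(dose, prefix) {
  bin <- paste0(prefix, ".bin")
  con <- file(bin, "wb")
  writeBin(c(as.numeric(dose$energy_deposited),
             as.numeric(dose$dose_medium),
             as.numeric(dose$dose_water)), con, size = 8, endian = "little")
  close(con)
  meta <- list(shape = dose$grid$shape, voxel_size = dose$grid$voxel_size,
               origin = dose$grid$origin, histories = dose$histories,
               arrays = c("energy_deposited", "dose_medium", "dose_water"),
               counters = dose$counters)
  json <- paste0(prefix, ".json")
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(bin, json))
}

#' Read a dose grid written by [write_dose()]
#'
#' @param prefix path prefix used when writing.
#' @return a `dose_grid` (without material information).
#' @export
read_dose <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(paste0(prefix, ".bin"), "rb")
  v <- readBin(con, "numeric", n = 3 * n, size = 8, endian = "little")
  close(con)
  arr <- function(i) array(v[(i - 1) * n + seq_len(n)], dim = meta$shape)
  structure(list(energy_deposited = arr(1), dose_medium = arr(2),
                 dose_water = arr(3), histories = meta$histories,
                 grid = list(shape = meta$shape,
                             voxel_size = meta$voxel_size,
                             origin = meta$origin),
                 counters = meta$counters),
            class = "dose_grid")
}

#' Read a dose plane from a plain CSV matrix
#'
#' @param path CSV file of dose values (no header).
#' @return numeric matrix.
#' @export
read_dose_plane_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}
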