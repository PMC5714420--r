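# Minimal DICOM Part 10 CT reader. Supports the implicit and explicit VR
# little endian transfer syntaxes and the handful of tags a voxelized CT
# import needs; written in-package because no DICOM reader is available in
# the R dependency set. Not a general DICOM implementation: encapsulated
# (compressed) pixel data and undefined-length sequences are rejected.

.dcm_uint <- function(raw) sum(as.integer(raw) * 256^(seq_along(raw) - 1))

.dcm_read_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM Part 10 file: ", path)
  pos <- 133L
  elems <- list()
  explicit <- TRUE
  meta_end <- Inf
  ts <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  repeat {
    if (pos + 7L > length(raw)) break
    group <- .dcm_uint(raw[pos:(pos + 1L)])
    elem <- .dcm_uint(raw[(pos + 2L):(pos + 3L)])
    in_meta <- group == 2L
    expl <- if (in_meta) TRUE else explicit
    if (expl) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- .dcm_uint(raw[(pos + 8L):(pos + 11L)])
        hdr <- 12L
      } else {
        len <- .dcm_uint(raw[(pos + 6L):(pos + 7L)])
        hdr <- 8L
      }
    } else {
      vr <- NA
      len <- .dcm_uint(raw[(pos + 4L):(pos + 7L)])
      hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length element not supported")
    body <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    elems[[key]] <- body
    if (key == "0002,0000") meta_end <- pos + hdr + len + .dcm_uint(body)
    if (key == "0002,0010") {
      ts <- sub("\\0+$", "", rawToChar(body))
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        stop("unsupported transfer syntax: ", ts)
    }
    pos <- pos + hdr + len
  }
  elems
}

.dcm_str <- function(elems, key, default = NULL) {
  b <- elems[[key]]
  if (is.null(b)) return(default)
  trimws(sub("\\0+$", "", rawToChar(b)))
}

.dcm_ds <- function(elems, key, default = NULL) {
  s <- .dcm_str(elems, key)
  if (is.null(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dcm_us <- function(elems, key) {
  b <- elems[[key]]
  if (is.null(b)) stop("missing required tag (", key, ")")
  .dcm_uint(b[1:2])
}

#' Read a DICOM CT series into a voxel grid
#'
#' Reads every DICOM file in a directory, orders the slices by table
#' position, and assembles the Hounsfield volume (rescale slope/intercept
#' applied). Voxel size is taken as (row spacing, column spacing, slice
#' spacing), converted from mm to cm. Densities and materials follow the
#' CT calibration; the grid base is placed at the 6 cm table-top height.
#'
#' @param path directory containing one axial CT series.
#' @param model a [density_model()].
#' @return a [voxel_grid()].
#' @export
read_ct_series <- function(path, model = density_model()) {
  files <- sort(list.files(path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in ", path)
  slices <- lapply(files, .dcm_read_file)
  uid <- unique(vapply(slices, .dcm_str, "", key = "0020,000e"))
  if (length(uid) > 1) stop("mixed series in ", path)
  zs <- vapply(slices, function(e) .dcm_ds(e, "0020,0032", c(0, 0, NA))[3],
               numeric(1))
  if (any(is.na(zs))) stop("missing image position tag")
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  rows <- .dcm_us(slices[[1]], "0028,0010")
  cols <- .dcm_us(slices[[1]], "0028,0011")
  spacing <- .dcm_ds(slices[[1]], "0028,0030")
  if (is.null(spacing)) stop("missing pixel spacing tag")
  thick <- .dcm_ds(slices[[1]], "0018,0050", NA)[1]
  dz <- if (length(zs) > 1) {
    gaps <- diff(zs)
    if (max(gaps) - min(gaps) > 0.01 * mean(gaps))
      stop("non-uniform slice spacing")
    mean(gaps)
  } else thick
  if (!is.finite(dz)) stop("cannot determine slice spacing")
  bits <- .dcm_us(slices[[1]], "0028,0100")
  if (bits != 16) stop("only 16-bit pixel data supported")
  signed <- .dcm_us(slices[[1]], "0028,0103") == 1
  hu <- array(0, dim = c(rows, cols, length(slices)))
  for (k in seq_along(slices)) {
    e <- slices[[k]]
    px <- e[["7fe0,0010"]]
    if (is.null(px)) stop("missing pixel data")
    v <- readBin(px, "integer", n = rows * cols, size = 2,
                 signed = signed, endian = "little")
    slope <- .dcm_ds(e, "0028,1053", 1)[1]
    inter <- .dcm_ds(e, "0028,1052", 0)[1]
    # pixel data is row-major: fill columns first, then transpose to [row, col]
    hu[, , k] <- t(matrix(v * slope + inter, nrow = cols, ncol = rows))
  }
  voxel_grid(hu, voxel_size = c(spacing[1], spacing[2], dz) / 10,
             model = model)
}
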