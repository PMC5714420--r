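# Shared fixtures: small grids, parallel beams, synthetic dose objects and
# the pydicom-based DICOM fixture writer.

# uniform water grid, world-centred, base at 6 cm
water_grid <- function(shape = c(20, 20, 60), voxel = c(1, 1, 0.5)) {
  voxel_grid(array(0, dim = shape), voxel)
}

# parallel vertical beam entering the top of a grid over a centred square
parallel_beam <- function(n, grid, half = 5, energy = 1.25) {
  ztop <- grid$origin[3] + grid$shape[3] * grid$voxel_size[3]
  data.frame(x = runif(n, -half, half), y = runif(n, -half, half),
             z = ztop, ux = 0, uy = 0, uz = -1, energy = energy,
             scatter_count = 0L)
}

# a dose_grid wrapper around a given dose array (for the analysis tools)
synthetic_dose <- function(arr, voxel = c(1, 1, 1)) {
  shape <- dim(arr)
  structure(list(
    energy_deposited = arr, dose_medium = arr, dose_water = arr,
    histories = 1,
    grid = list(shape = shape, voxel_size = voxel,
                origin = c(-shape[1] * voxel[1] / 2,
                           -shape[2] * voxel[2] / 2, 6)),
    counters = list()), class = "dose_grid")
}

# brute-force gamma oracle: exhaustive search over all evaluated points
gamma_brute <- function(reference, evaluated, dta, dd, spacing = 1,
                        spacing_eval = spacing) {
  dmax <- max(reference)
  ex <- (seq_len(nrow(evaluated)) - 1) * spacing_eval
  ey <- (seq_len(ncol(evaluated)) - 1) * spacing_eval
  g <- matrix(NA_real_, nrow(reference), ncol(reference))
  for (i in seq_len(nrow(reference))) {
    for (j in seq_len(ncol(reference))) {
      d2 <- outer((ex - (i - 1) * spacing)^2, (ey - (j - 1) * spacing)^2, `+`)
      dd2 <- ((evaluated - reference[i, j]) / (dd / 100 * dmax))^2
      g[i, j] <- sqrt(min(d2 / dta^2 + dd2))
    }
  }
  g
}

# write a 4-slice synthetic CT series with pydicom (independent writer for
# the DICOM reader round-trip); returns the HU array it encoded
write_dicom_fixture <- function(dir) {
  script <- '
import sys, numpy as np
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid, CTImageStorage
outdir = sys.argv[1]
series = generate_uid()
study = generate_uid()
for k in range(4):
    ds = Dataset()
    ds.SOPClassUID = CTImageStorage
    ds.SOPInstanceUID = generate_uid()
    ds.SeriesInstanceUID = series
    ds.StudyInstanceUID = study
    ds.Modality = "CT"
    ds.Rows = 32
    ds.Columns = 32
    ds.PixelSpacing = ["2.0", "1.5"]
    ds.SliceThickness = "5.0"
    ds.ImagePositionPatient = ["0", "0", str(5.0 * k)]
    ds.ImageOrientationPatient = ["1", "0", "0", "0", "1", "0"]
    ds.RescaleIntercept = "-1024"
    ds.RescaleSlope = "1"
    ds.BitsAllocated = 16
    ds.BitsStored = 16
    ds.HighBit = 15
    ds.PixelRepresentation = 1
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    hu = np.add.outer(np.arange(32) * 7, np.arange(32)) + 50 * k - 200
    ds.PixelData = (hu + 1024).astype(np.int16).tobytes()
    fm = FileMetaDataset()
    fm.TransferSyntaxUID = ExplicitVRLittleEndian
    fm.MediaStorageSOPClassUID = CTImageStorage
    fm.MediaStorageSOPInstanceUID = ds.SOPInstanceUID
    ds.file_meta = fm
    pydicom.dcmwrite(outdir + "/ct%d.dcm" % k, ds, enforce_file_format=True)
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, dir), stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")))
    stop("pydicom fixture writer failed: ", paste(status, collapse = "\n"))
  hu <- array(0, dim = c(32, 32, 4))
  base <- outer((0:31) * 7, 0:31, `+`) - 200
  for (k in 1:4) hu[, , k] <- base + 50 * (k - 1)
  hu
}
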