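# Writes a tiny synthetic axial DICOM series with pydicom (the independent
# oracle for the package's DICOM reader). Returns the directory, or NULL if
# no python with pydicom is available on the PATH.

write_test_dicom_series <- function(dir, n_slices = 4, rows = 6, cols = 5,
                                    series = "1.2.3.4.5", flip = FALSE,
                                    extra_series = NULL) {
  script <- sprintf('
import numpy as np, pydicom, os, sys
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

outdir, n, rows, cols, series, flip = sys.argv[1], %d, %d, %d, "%s", %s
extra = %s

def write_slice(i, series_uid, z):
    ds = Dataset()
    ds.SOPClassUID = "1.2.840.10008.5.1.4.1.1.2"
    ds.SOPInstanceUID = generate_uid(entropy_srcs=[series_uid, str(i)])
    ds.SeriesInstanceUID = series_uid
    ds.StudyInstanceUID = "9.8.7"
    ds.Modality = "CT"
    ds.Rows, ds.Columns = rows, cols
    ds.BitsAllocated, ds.BitsStored, ds.HighBit = 16, 16, 15
    ds.PixelRepresentation = 1
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.ImagePositionPatient = [0.0, 0.0, z]
    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]
    ds.PixelSpacing = [0.7, 0.9]
    ds.RescaleSlope, ds.RescaleIntercept = 1.0, -1024.0
    arr = (np.arange(rows * cols).reshape(rows, cols) + 100 * i).astype(np.int16)
    ds.PixelData = arr.tobytes()
    meta = FileMetaDataset()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    meta.MediaStorageSOPClassUID = ds.SOPClassUID
    meta.MediaStorageSOPInstanceUID = ds.SOPInstanceUID
    ds.file_meta = meta
    ds.save_as(os.path.join(outdir, "slice_%%03d_%%s.dcm" %% (i, series_uid[-1])),
               enforce_file_format=True)

zs = [2.5 * i for i in range(n)]
if flip:
    zs = zs[::-1]
for i in range(n):
    write_slice(i, series, zs[i])
if extra:
    write_slice(n, extra, 0.0)
', n_slices, rows, cols, series, if (flip) "True" else "False",
    if (is.null(extra_series)) "None" else sprintf('"%s"', extra_series))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- suppressWarnings(system2("python", c(sf, shQuote(dir)),
                                     stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0) {
    message(paste(status, collapse = "\n"))
    return(NULL)
  }
  dir
}

has_pydicom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- suppressWarnings(try(system2("python", c("-c", shQuote("import pydicom")),
                                         stdout = FALSE, stderr = FALSE), silent = TRUE))
      cache <<- !inherits(st, "try-error") && identical(st, 0L)
    }
    cache
  }
})
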