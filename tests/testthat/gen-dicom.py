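"""Generate tiny synthetic CT DICOM series for reader tests.

Usage: python gen-dicom.py OUTDIR MODE
  MODE = "series"  : 3-slice CT series, slope 1 / intercept -1024,
                     identity orientation, origin (10, 20, 30), written in
                     shuffled instance order to exercise spatial sorting
  MODE = "onepix"  : 1-slice series whose stored value 1024 rescales to 0 HU
  MODE = "mixed"   : two slices from different SeriesInstanceUIDs
  MODE = "noslope" : one slice missing RescaleSlope/Intercept
"""
import sys

import numpy as np
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

OUT, MODE = sys.argv[1], sys.argv[2]

ROWS, COLS = 6, 8


def make_slice(series_uid, k, values, with_rescale=True):
    ds = Dataset()
    meta = FileMetaDataset()
    meta.MediaStorageSOPClassUID = pydicom.uid.CTImageStorage
    meta.MediaStorageSOPInstanceUID = generate_uid()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds.file_meta = meta
    ds.SOPClassUID = pydicom.uid.CTImageStorage
    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
    ds.Modality = "CT"
    ds.SeriesInstanceUID = series_uid
    ds.InstanceNumber = 100 - k  # deliberately anti-correlated with position
    ds.Rows, ds.Columns = ROWS, COLS
    ds.PixelSpacing = [0.7, 0.5]  # row spacing, column spacing
    ds.ImagePositionPatient = [10.0, 20.0, 30.0 + 2.5 * k]
    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]
    ds.BitsAllocated = 16
    ds.BitsStored = 16
    ds.HighBit = 15
    ds.PixelRepresentation = 0
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    if with_rescale:
        ds.RescaleSlope = 1.0
        ds.RescaleIntercept = -1024.0
    ds.PixelData = values.astype(np.uint16).tobytes()
    ds.save_as(f"{OUT}/slice_{k:02d}.dcm", enforce_file_format=True)


base = np.arange(ROWS * COLS, dtype=np.uint16).reshape(ROWS, COLS)

if MODE == "series":
    uid = generate_uid()
    for k in [2, 0, 1]:  # shuffled write order
        make_slice(uid, k, base + 100 * k)
elif MODE == "onepix":
    uid = generate_uid()
    make_slice(uid, 0, np.full((ROWS, COLS), 1024, dtype=np.uint16))
elif MODE == "mixed":
    make_slice(generate_uid(), 0, base)
    make_slice(generate_uid(), 1, base)
elif MODE == "noslope":
    make_slice(generate_uid(), 0, base, with_rescale=False)
else:
    raise SystemExit(f"unknown mode {MODE}")
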