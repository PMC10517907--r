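# Table-published group means on internal scales (mm^2/s, fractions),
# used throughout the fit-recovery tests.
adverse_truth <- list(f = 0.2356, D = 1.55e-3, Dstar = 161.13e-3,
                      DDC = 2.40e-3, Alpha = 0.70, ADC = 2.34e-3)
non_adverse_truth <- list(f = 0.2844, D = 1.62e-3, Dstar = 138.80e-3,
                          DDC = 2.94e-3, Alpha = 0.69, ADC = 2.75e-3)

protocol_b <- c(0, 50, 100, 150, 200, 500, 800)

make_series <- function(dims = c(3L, 3L, 2L), bvalues = protocol_b,
                        fill = function(b) mono_signal(1e-3, 100, b)) {
  curve <- fill(bvalues)
  signal <- array(rep(curve, each = prod(dims)), c(dims, length(bvalues)))
  dwi_series(signal, bvalues)
}

write_temp_dwi <- function(series, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  img <- file.path(dir, "dwi.nii.gz")
  bval <- file.path(dir, "dwi.bval")
  write_dwi(series, img, bval)
  list(image = img, bval = bval, dir = dir)
}

write_temp_mask <- function(mask_array, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(mask_array * 1), path)
  path
}

rel_err <- function(x, truth) abs(x - truth) / abs(truth)
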