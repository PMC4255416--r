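# NIfTI-1 and CSV input/output.

#' Write a 3D array as a NIfTI-1 volume
#'
#' @param x 3D array (intensities or integer labels)
#' @param file output path (`.nii` or `.nii.gz`)
#' @param voxelSize numeric(3), mm
#' @return the path, invisibly
#' @export
writeVolume <- function(x, file, voxelSize) {
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a NIfTI-1 volume
#'
#' @param file path to a `.nii`/`.nii.gz` file
#' @return list: `data` (3D array), `voxelSize` (numeric(3), mm)
#' @export
readVolume <- function(file) {
  img <- RNifti::readNifti(file)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxelSize = RNifti::pixdim(img)[1:3])
}

#' Write a phantom to disk as NIfTI volumes
#'
#' One file per modality (`t1.nii`, `pd.nii`, `t2.nii`) plus the
#' ground-truth label volume (`labels.nii`).
#'
#' @param phantom list from [generatePhantom()]
#' @param dir output directory (created if absent)
#' @return character vector of paths, invisibly
#' @export
writePhantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vox <- phantom$volume@voxelSize
  paths <- c(
    writeVolume(phantom$volume@t1, file.path(dir, "t1.nii"), vox),
    writeVolume(phantom$volume@pd, file.path(dir, "pd.nii"), vox),
    writeVolume(phantom$volume@t2, file.path(dir, "t2.nii"), vox),
    writeVolume(phantom$truth@labels, file.path(dir, "labels.nii"), vox))
  invisible(paths)
}
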