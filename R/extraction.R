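#' Extract the supratentorial intracranial mask from a T1 volume
#'
#' Deterministic threshold-plus-morphology extraction: a four-component
#' Gaussian mixture fitted to the whole-scene T1 histogram separates the
#' background mode from the lowest in-head intensity class (CSF under the
#' dura), and the head/background threshold is placed midway between those
#' two component means — robust where a single two-class histogram split
#' would cut between CSF and parenchyma instead. The largest 26-connected
#' foreground component is kept, a binary closing smooths the surface, and
#' fully enclosed cavities (ventricles, cystic cores) are filled so the mask
#' covers parenchyma plus all interior CSF. ST-TIV is the mask volume in cc.
#'
#' @param volume a [MultiModalVolume-class] (or a bare 3D T1 array with
#'   `voxelSize` supplied).
#' @param voxelSize numeric(3), required when `volume` is a bare array.
#' @param threshold foreground threshold; `NULL` (default) derives it from
#'   the whole-scene mixture fit.
#' @param closingRadius radius (voxels) of the binary closing.
#' @param exclusionMask optional logical array of voxels to remove before
#'   the volume is measured (stands in for cerebellum/subtentorial removal;
#'   phantoms have no subtentorial compartment so the default is none).
#' @return an [IntracranialMask-class]
#' @export
extractBrain <- function(volume, voxelSize = NULL, threshold = NULL,
                         closingRadius = 1L, exclusionMask = NULL) {
  if (is(volume, "MultiModalVolume")) {
    t1 <- volume@t1
    voxelSize <- volume@voxelSize
  } else {
    t1 <- volume
    if (is.null(voxelSize)) stop("voxelSize required for a bare array")
  }
  if (any(!is.finite(t1))) stop("T1 intensities must be finite")
  if (is.null(threshold)) threshold <- foregroundThreshold(t1)
  fg <- t1 > threshold
  if (!any(fg)) stop("empty scene: no voxel exceeds the foreground threshold")
  lab <- labelComponents(fg, 26L)
  keep <- which.max(tabulate(lab[lab > 0]))
  mask <- lab == keep
  if (closingRadius > 0)
    mask <- erodeMask(dilateMask(mask, closingRadius, 26L), closingRadius, 26L)
  mask <- fillHoles(mask)
  if (!is.null(exclusionMask)) mask <- mask & !exclusionMask
  if (!any(mask)) stop("empty scene: mask empty after exclusion")
  new("IntracranialMask", mask = mask, voxelSize = voxelSize,
      stTIV = computeSTTIV(mask, voxelSize))
}

#' Supratentorial total intracranial volume from a mask
#'
#' @param mask logical 3D array or an [IntracranialMask-class]
#' @param voxelSize numeric(3) voxel edge lengths, mm
#' @return volume in cc (voxel count x voxel volume / 1000)
#' @export
computeSTTIV <- function(mask, voxelSize) {
  if (is(mask, "IntracranialMask")) {
    voxelSize <- mask@voxelSize
    mask <- mask@mask
  }
  if (any(voxelSize <= 0) || length(voxelSize) != 3L)
    stop("voxel dimensions must be three positive lengths")
  n <- sum(mask)
  if (n == 0) stop("mask is empty")
  n * prod(voxelSize) / 1000
}

# Head/background threshold: fit four Gaussian components to a subsample of
# the whole scene and cut midway between the lowest (background) and second
# component means. A scene with a single intensity population has no
# foreground above the threshold, which extractBrain reports as empty.
foregroundThreshold <- function(x) {
  v <- as.numeric(x)
  if (length(v) > 20000L) v <- v[seq(1L, length(v), length.out = 20000L)]
  # a coarse fit suffices: only the air/CSF gap matters for the cut
  fit <- mergeCloseComponents(emFitGaussians(v, 4L, tol = 1e-4, maxit = 60L),
                              diff(range(v)))
  if (fit$k < 2L) return(max(v))   # single population: nothing above
  (fit$mean[1] + fit$mean[2]) / 2
}
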