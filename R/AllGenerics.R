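#' Voxel edge lengths in mm
#' @param x an object carrying a voxel grid
#' @return numeric(3)
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Label or region array
#' @param x an object carrying a per-voxel labeling
#' @return integer 3D array
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' Supratentorial total intracranial volume (cc)
#' @param x an [IntracranialMask-class] or [VolumetricProfile-class]
#' @return numeric scalar, cc
#' @export
setGeneric("stTIV", function(x) standardGeneric("stTIV"))

#' Connected-component table of a lesion segmentation
#' @param x a [LesionSegmentation-class]
#' @return data.frame with one row per component
#' @export
setGeneric("componentTable", function(x) standardGeneric("componentTable"))

#' @rdname voxelSize
setMethod("voxelSize", "MultiModalVolume", function(x) x@voxelSize)
#' @rdname voxelSize
setMethod("voxelSize", "GroundTruth", function(x) x@voxelSize)
#' @rdname voxelSize
setMethod("voxelSize", "IntracranialMask", function(x) x@voxelSize)
#' @rdname voxelSize
setMethod("voxelSize", "TissueSegmentation", function(x) x@voxelSize)
#' @rdname voxelSize
setMethod("voxelSize", "LesionSegmentation", function(x) x@voxelSize)
#' @rdname voxelSize
setMethod("voxelSize", "VOIAtlas", function(x) x@voxelSize)

#' @rdname labelArray
setMethod("labelArray", "GroundTruth", function(x) x@labels)
#' @rdname labelArray
setMethod("labelArray", "TissueSegmentation", function(x) x@labels)
#' @rdname labelArray
setMethod("labelArray", "LesionSegmentation", function(x) x@labels)
#' @rdname labelArray
setMethod("labelArray", "VOIAtlas", function(x) x@regions)

#' @rdname stTIV
setMethod("stTIV", "IntracranialMask", function(x) x@stTIV)
#' @rdname stTIV
setMethod("stTIV", "VolumetricProfile", function(x) x@stTIV)

#' @rdname componentTable
setMethod("componentTable", "LesionSegmentation", function(x) x@components)

#' Accessors for MultiModalVolume channels
#' @param x a [MultiModalVolume-class]
#' @return 3D numeric array
#' @export
t1Volume <- function(x) x@t1
#' @rdname t1Volume
#' @export
pdVolume <- function(x) x@pd
#' @rdname t1Volume
#' @export
t2Volume <- function(x) x@t2

#' Region lookup table of an atlas
#' @param x a [VOIAtlas-class]
#' @return data.frame: id, name, hemisphere, lobe
#' @export
regionTable <- function(x) x@regionTable

#' Brain parenchymal fraction of a profile (percent)
#' @param x a [VolumetricProfile-class]
#' @export
bpf <- function(x) x@bpf

#' Whole-brain class volumes of a profile (cc)
#' @param x a [VolumetricProfile-class]
#' @export
wholeBrainVolumes <- function(x) x@wholeBrain

#' Regional class volumes of a profile
#' @param x a [VolumetricProfile-class]
#' @return data.frame: region, class, raw_cc
#' @export
regionalVolumes <- function(x) x@regional

setMethod("show", "MultiModalVolume", function(object) {
  d <- dim(object@t1)
  cat(sprintf("MultiModalVolume: %d x %d x %d voxels at %.3g x %.3g x %.3g mm (T1/PD/T2)\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3]))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth phantom labels; class volumes (cc):\n")
  print(round(object@trueVolumes, 3))
})

setMethod("show", "IntracranialMask", function(object) {
  cat(sprintf("IntracranialMask: %d voxels, ST-TIV = %.1f cc\n",
              sum(object@mask), object@stTIV))
})

setMethod("show", "TissueSegmentation", function(object) {
  n <- tabulate(object@labels + 1L, nbins = 5L)
  cat(sprintf("TissueSegmentation: sCSF %d, vCSF %d, GM %d, WM %d voxels\n",
              n[2], n[3], n[4], n[5]))
})

setMethod("show", "LesionSegmentation", function(object) {
  cat(sprintf("LesionSegmentation: %d components (%d pvSH, %d dwSH, %d lacune)\n",
              nrow(object@components),
              sum(object@components$class == "pvSH"),
              sum(object@components$class == "dwSH"),
              sum(object@components$class == "lacune")))
})

setMethod("show", "VOIAtlas", function(object) {
  cat(sprintf("VOIAtlas: 26 regions over %d voxels\n", sum(object@regions > 0)))
})

setMethod("show", "VolumetricProfile", function(object) {
  cat(sprintf("VolumetricProfile '%s': ST-TIV %.1f cc, BPF %.1f%%, vCSF/ST-TIV %.4f\n",
              object@subject, object@stTIV, object@bpf, object@vcsfRatio))
})
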