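#' @useDynLib lesionvol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats dnorm lm lm.fit pnorm quantile rnorm rbinom runif sd
#'   coef resid qnorm var complete.cases
#' @importFrom utils head write.csv read.csv
NULL

#' Co-registered multimodal MR volume
#'
#' Container for a co-registered triple of T1-weighted, proton-density and
#' T2-weighted intensity grids sharing one voxel geometry. All downstream
#' stages (brain extraction, tissue segmentation, hyperintensity detection)
#' operate on this object.
#'
#' @slot t1,pd,t2 3D numeric arrays of identical dimension.
#' @slot voxelSize numeric(3), voxel edge lengths in mm (x, y, z).
#' @export
setClass("MultiModalVolume",
  representation(t1 = "array", pd = "array", t2 = "array",
                 voxelSize = "numeric"))

setValidity("MultiModalVolume", function(object) {
  d <- dim(object@t1)
  if (length(d) != 3L) return("t1 must be a 3D array")
  if (!identical(d, dim(object@pd)) || !identical(d, dim(object@t2)))
    return("t1, pd, t2 must share dimensions")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive lengths (mm)")
  if (any(!is.finite(object@t1)) || any(!is.finite(object@pd)) ||
      any(!is.finite(object@t2)))
    return("intensities must be finite")
  TRUE
})

#' Ground-truth labels for a synthetic phantom
#'
#' @slot labels integer 3D array of class codes (see [phantomClasses()]).
#' @slot voxelSize numeric(3) voxel size in mm.
#' @slot trueVolumes named numeric, per-class volume in cc.
#' @slot ventricleSeeds integer matrix, one row per ventricle, 1-based voxel
#'   indices of a voxel inside each ventricle.
#' @export
setClass("GroundTruth",
  representation(labels = "array", voxelSize = "numeric",
                 trueVolumes = "numeric", ventricleSeeds = "matrix"))

setValidity("GroundTruth", function(object) {
  vv <- prod(object@voxelSize) / 1000
  counts <- tabulate(object@labels + 1L, nbins = 8L)[-1L]
  expect <- counts * vv
  got <- object@trueVolumes[names(phantomClasses())]
  if (any(abs(got - expect) > 1e-9)) return("trueVolumes must equal label counts x voxel volume")
  TRUE
})

#' Supratentorial intracranial mask with ST-TIV
#'
#' @slot mask logical 3D array; TRUE inside the intracranial cavity.
#' @slot voxelSize numeric(3) mm.
#' @slot stTIV total supratentorial intracranial volume in cc.
#' @export
setClass("IntracranialMask",
  representation(mask = "array", voxelSize = "numeric", stTIV = "numeric"))

setValidity("IntracranialMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  vv <- prod(object@voxelSize) / 1000
  if (abs(object@stTIV - sum(object@mask) * vv) > 1e-8)
    return("stTIV must equal voxel count x voxel volume")
  TRUE
})

#' Localized four-Gaussian T1 intensity model
#'
#' Fitted by [fitLocalGaussians()]: a grid of overlapping cubic windows, each
#' carrying up to four Gaussian components on T1 intensity, plus a global
#' whole-mask fit used as fallback and as the class anchor.
#'
#' @slot windows list of per-window fits (origin, size, mean/sd/weight
#'   vectors, classOf mapping, fallback flag).
#' @slot global list with the whole-mask fit and its component-to-class map.
#' @slot windowSize,stride integer, window geometry in voxels.
#' @slot dims integer(3) grid dimension the model was fitted on.
#' @export
setClass("GaussianFieldModel",
  representation(windows = "list", global = "list", windowSize = "integer",
                 stride = "integer", dims = "integer"))

#' Tissue segmentation result
#'
#' Per-voxel tissue labels inside the intracranial mask with blended class
#' posteriors. Label codes: 0 background, 1 sCSF, 2 vCSF, 3 GM, 4 WM
#' (CSF is labeled 1 before [splitCSF()] assigns compartments).
#'
#' @slot labels integer 3D array.
#' @slot posteriors 4D array (x, y, z, class) with classes CSF, GM, WM;
#'   rows inside the mask sum to 1.
#' @slot voxelSize numeric(3) mm.
#' @export
setClass("TissueSegmentation",
  representation(labels = "array", posteriors = "array",
                 voxelSize = "numeric"))

setValidity("TissueSegmentation", function(object) {
  if (!identical(dim(object@labels), dim(object@posteriors)[1:3]))
    return("labels and posteriors must share grid dimensions")
  if (dim(object@posteriors)[4] != 3L)
    return("posteriors must have 3 class planes (CSF, GM, WM)")
  TRUE
})

#' Lesion segmentation result
#'
#' Subcortical-hyperintensity labels and the per-component table. Label
#' codes: 0 none, 1 pvSH, 2 dwSH, 3 lacune.
#'
#' @slot labels integer 3D array.
#' @slot components data.frame: id, class, voxels, volume_cc, cx, cy, cz
#'   (centroid, 1-based voxel coordinates). Lacune components carry the id of
#'   their parent SH component in `parent`.
#' @slot componentIds integer 3D array: id of the originally detected SH
#'   component covering each voxel (0 outside), preserved through lacune
#'   carving so lacunes stay linked to their parents.
#' @slot voxelSize numeric(3) mm.
#' @export
setClass("LesionSegmentation",
  representation(labels = "array", components = "data.frame",
                 componentIds = "array", voxelSize = "numeric"))

setValidity("LesionSegmentation", function(object) {
  if (nrow(object@components)) {
    need <- c("id", "class", "voxels", "volume_cc", "cx", "cy", "cz", "parent")
    if (!all(need %in% names(object@components)))
      return("components table missing required columns")
    vv <- prod(object@voxelSize) / 1000
    if (any(abs(object@components$volume_cc -
                object@components$voxels * vv) > 1e-9))
      return("component volumes must equal voxel counts x voxel volume")
  }
  TRUE
})

#' Geometric 26-region volume-of-interest atlas
#'
#' A plane-based partition of the intracranial mask into 26 named regions
#' (13 per hemisphere), exposing the standard regionalized-volumetrics
#' interface (lateral/medial frontal subdivisions, parietal, occipital,
#' anterior/posterior temporal).
#'
#' @slot regions integer 3D array with region ids 1..26 inside the mask,
#'   0 outside.
#' @slot regionTable data.frame: id, name, hemisphere, lobe.
#' @slot voxelSize numeric(3) mm.
#' @export
setClass("VOIAtlas",
  representation(regions = "array", regionTable = "data.frame",
                 voxelSize = "numeric"))

setValidity("VOIAtlas", function(object) {
  if (nrow(object@regionTable) != 26L) return("atlas must define exactly 26 regions")
  ids <- sort(unique(as.integer(object@regions[object@regions > 0])))
  if (length(ids) && !all(ids %in% object@regionTable$id))
    return("region grid contains ids absent from the region table")
  TRUE
})

#' Per-subject volumetric profile
#'
#' Raw volumes (cc) per tissue/lesion class, whole-brain and per VOI, with
#' ST-TIV, brain parenchymal fraction and the vCSF/ST-TIV atrophy ratio.
#'
#' @slot subject character scalar id.
#' @slot stTIV numeric, cc.
#' @slot bpf numeric, percent: 100 * (GM + WM) / ST-TIV.
#' @slot vcsfRatio numeric: vCSF / ST-TIV.
#' @slot wholeBrain named numeric, per-class cc.
#' @slot regional data.frame: region, class, raw_cc.
#' @export
setClass("VolumetricProfile",
  representation(subject = "character", stTIV = "numeric", bpf = "numeric",
                 vcsfRatio = "numeric", wholeBrain = "numeric",
                 regional = "data.frame"))

setValidity("VolumetricProfile", function(object) {
  if (object@bpf < 0 || object@bpf > 100 + 1e-9)
    return("bpf must lie in (0, 100]")
  if (any(object@wholeBrain < 0)) return("class volumes must be nonnegative")
  agg <- tapply(object@regional$raw_cc, object@regional$class, sum)
  for (cl in names(agg))
    if (abs(agg[[cl]] - object@wholeBrain[[cl]]) > 1e-6)
      return(sprintf("regional volumes for %s do not sum to whole-brain value", cl))
  TRUE
})
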