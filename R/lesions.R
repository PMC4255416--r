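#' Detection parameters for subcortical hyperintensities
#'
#' @param zThreshold SDs above the fitted white-matter mean required jointly
#'   on PD and on T2.
#' @param minComponentVoxels smallest retained connected component.
#' @param connectivity neighborhood order for component labeling (6, 18, 26).
#' @param pvDistanceVoxels maximum Chebyshev gap to ventricular CSF for
#'   periventricular status.
#' @param gmNeighborMajority exclude candidate voxels whose 26-neighborhood
#'   holds more than this many non-candidate GM voxels (cortical
#'   false-positive control).
#' @return list of class `SHDetectionParams`
#' @export
shDetectionParams <- function(zThreshold = 3, minComponentVoxels = 5L,
                              connectivity = 26L, pvDistanceVoxels = 1L,
                              gmNeighborMajority = 13L) {
  if (zThreshold <= 0) stop("zThreshold must be positive")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  structure(list(zThreshold = zThreshold,
                 minComponentVoxels = as.integer(minComponentVoxels),
                 connectivity = as.integer(connectivity),
                 pvDistanceVoxels = as.integer(pvDistanceVoxels),
                 gmNeighborMajority = as.integer(gmNeighborMajority)),
            class = "SHDetectionParams")
}

# Mean/SD of a modality's intensities over voxels carrying a tissue label.
labelStats <- function(grid, labels, code, what) {
  v <- grid[labels %in% code]
  if (!length(v)) stop(sprintf("%s class is empty; cannot calibrate", what))
  s <- if (length(v) > 1L) sd(v) else 0
  c(mean = mean(v), sd = max(s, 1e-6))
}

#' Segment subcortical hyperintensities from PD and T2
#'
#' A voxel enters the SH mask iff it lies inside the intracranial mask, is
#' not ventricular CSF nor exterior (surface-connected) sulcal CSF, and its
#' PD and T2 intensities both exceed the fitted white-matter mean by
#' `zThreshold` SDs on that modality. WM statistics are estimated over
#' WM-labeled voxels per modality. Candidate voxels whose 26-neighborhood is
#' dominated by non-candidate gray matter are excluded (cortical
#' false-positive control), and components below `minComponentVoxels` are
#' removed. CSF-labeled voxels carrying the lacune signature — CSF-dark on
#' T1 yet above both hyperintensity thresholds — keep their candidacy, so
#' lacunar cores contiguous with the ventricles or embedded in SH are not
#' masked away; interior CSF-intensity pockets also remain candidates.
#'
#' @param pd,t2 co-registered 3D arrays.
#' @param tissue a [TissueSegmentation-class] (after [splitCSF()]).
#' @param mask logical array or [IntracranialMask-class].
#' @param params an `SHDetectionParams` list.
#' @param t1 optional co-registered T1 array for the lacune-signature test;
#'   without it, the CSF exclusions apply unconditionally.
#' @return logical 3D array (the binary SH mask)
#' @export
segmentSH <- function(pd, t2, tissue, mask, params = shDetectionParams(),
                      t1 = NULL) {
  if (is(mask, "IntracranialMask")) mask <- mask@mask
  labels <- tissue@labels
  wmPD <- labelStats(pd, labels, 4L, "WM")
  wmT2 <- labelStats(t2, labels, 4L, "WM")
  hot <- mask &
    pd > wmPD["mean"] + params$zThreshold * wmPD["sd"] &
    t2 > wmT2["mean"] + params$zThreshold * wmT2["sd"]
  # exclude ventricular CSF and exterior sulcal CSF (components touching
  # the mask boundary); interior CSF pockets remain candidates
  vcsf <- labels == 2L
  dim(vcsf) <- dim(labels)
  scsf <- labels == 1L
  dim(scsf) <- dim(labels)
  if (any(scsf)) {
    border <- dilateMask(!mask, 1L, 26L) & mask
    comp <- labelComponents(scsf, 26L)
    exterior <- unique(comp[border & scsf])
    exterior <- exterior[exterior > 0]
    scsfExterior <- scsf & (comp %in% exterior)
    dim(scsfExterior) <- dim(labels)
  } else scsfExterior <- scsf
  lacuneLike <- if (!is.null(t1) && any(labels %in% c(1L, 2L))) {
    csfT1 <- labelStats(t1, labels, c(1L, 2L), "CSF")
    ll <- t1 < csfT1["mean"] + 2 * csfT1["sd"]
    dim(ll) <- dim(labels)
    ll
  } else array(FALSE, dim(labels))
  hot <- hot & !((vcsf | scsfExterior) & !lacuneLike)
  if (any(hot)) {
    gmOutside <- (labels == 3L) & !hot
    dim(gmOutside) <- dim(labels)
    nGM <- neighborCount26(gmOutside, dim(labels))
    hot <- hot & nGM <= params$gmNeighborMajority
  }
  if (any(hot)) {
    comp <- labelComponents(hot, params$connectivity)
    sizes <- tabulate(comp[comp > 0])
    small <- which(sizes < params$minComponentVoxels)
    hot[comp %in% small] <- FALSE
    dim(hot) <- dim(labels)
  }
  hot
}

#' Classify SH components as periventricular or deep white
#'
#' Connected components of the SH mask are labeled at the configured
#' connectivity; a component is periventricular iff any of its voxels lies
#' within `pvDistanceVoxels` (Chebyshev) of a ventricular-CSF voxel,
#' otherwise deep white.
#'
#' @param shMask logical 3D SH mask (from [segmentSH()]).
#' @param vcsfMask logical 3D ventricular-CSF mask.
#' @param voxelSize numeric(3), mm.
#' @param params an `SHDetectionParams` list.
#' @return a [LesionSegmentation-class]
#' @export
classifyPvDw <- function(shMask, vcsfMask, voxelSize,
                         params = shDetectionParams()) {
  dims <- dim(shMask)
  vv <- voxelVolumeCC(voxelSize)
  labels <- array(0L, dims)
  if (!any(shMask)) {
    return(new("LesionSegmentation", labels = labels,
               components = emptyComponentTable(),
               componentIds = array(0L, dims), voxelSize = voxelSize))
  }
  comp <- labelComponents(shMask, params$connectivity)
  near <- if (any(vcsfMask)) dilateMask(vcsfMask, params$pvDistanceVoxels, 26L)
          else array(FALSE, dims)
  ncomp <- max(comp)
  rows <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    vox <- which(comp == k)
    isPV <- any(near[vox])
    cls <- if (isPV) "pvSH" else "dwSH"
    labels[vox] <- if (isPV) 1L else 2L
    ai <- arrayInd(vox, dims)
    rows[[k]] <- data.frame(id = k, class = cls, voxels = length(vox),
                            volume_cc = length(vox) * vv,
                            cx = mean(ai[, 1]), cy = mean(ai[, 2]),
                            cz = mean(ai[, 3]), parent = NA_integer_)
  }
  new("LesionSegmentation", labels = labels,
      components = do.call(rbind, rows), componentIds = comp,
      voxelSize = voxelSize)
}

emptyComponentTable <- function() {
  data.frame(id = integer(), class = character(), voxels = integer(),
             volume_cc = numeric(), cx = numeric(), cy = numeric(),
             cz = numeric(), parent = integer())
}

#' Extract lacunes inside segmented hyperintensities
#'
#' Relabels SH voxels whose T1 intensity is CSF-like — below the fitted CSF
#' mean plus twice the CSF SD on T1 — as lacune. CSF statistics come from
#' CSF-labeled voxels of the tissue segmentation. Lacune components record
#' the id of the SH component they were carved from.
#'
#' @param lesions a [LesionSegmentation-class] from [classifyPvDw()].
#' @param t1 the co-registered T1 array.
#' @param tissue the [TissueSegmentation-class] supplying CSF statistics.
#' @return the updated [LesionSegmentation-class]
#' @export
extractLacunes <- function(lesions, t1, tissue) {
  labels <- lesions@labels
  comps <- lesions@components
  if (!any(labels > 0)) return(lesions)
  csfStats <- labelStats(t1, tissue@labels, c(1L, 2L), "CSF")
  cut <- csfStats["mean"] + 2 * csfStats["sd"]
  sh <- labels > 0
  dim(sh) <- dim(labels)
  lac <- sh & t1 < cut
  if (!any(lac)) return(lesions)
  dims <- dim(labels)
  vv <- voxelVolumeCC(lesions@voxelSize)
  lacComp <- labelComponents(lac, 26L)
  nextId <- max(comps$id) + 1L
  parentOf <- lesions@componentIds
  for (k in seq_len(max(lacComp))) {
    vox <- which(lacComp == k)
    labels[vox] <- 3L
    ai <- arrayInd(vox, dims)
    par <- parentOf[vox[1]]
    comps <- rbind(comps, data.frame(
      id = nextId, class = "lacune", voxels = length(vox),
      volume_cc = length(vox) * vv, cx = mean(ai[, 1]), cy = mean(ai[, 2]),
      cz = mean(ai[, 3]), parent = if (par > 0) par else NA_integer_))
    nextId <- nextId + 1L
  }
  # shrink parent component records to the voxels they retain
  for (r in seq_len(nrow(comps)))
    if (comps$class[r] %in% c("pvSH", "dwSH")) {
      kept <- sum(parentOf == comps$id[r] & labels != 3L)
      comps$voxels[r] <- kept
      comps$volume_cc[r] <- kept * vv
    }
  lesions@labels <- labels
  lesions@components <- comps
  validObject(lesions)
  lesions
}
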