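#' Tissue/lesion class codes used by phantom ground truth
#'
#' Integer codes for the combined label map: sCSF 1, vCSF 2, GM 3, WM 4,
#' pvSH 5, dwSH 6, lacune 7 (0 = background).
#'
#' @return named integer vector
#' @export
phantomClasses <- function() {
  c(sCSF = 1L, vCSF = 2L, GM = 3L, WM = 4L, pvSH = 5L, dwSH = 6L, lacune = 7L)
}

#' Specification of a synthetic multimodal brain phantom
#'
#' The phantom is an analytic nested-ellipsoid brain: an outer sulcal-CSF
#' shell under the dura, a cortical gray-matter shell, a white-matter
#' interior, and two mirrored ventricular-CSF ellipsoids. Periventricular
#' hyperintense lesions are grown into white matter from a seed on the
#' ventricle surface; deep-white lesions are compact blobs kept a
#' configurable gap away from the ventricles; lacune cores are CSF-intensity
#' voxels placed at lesion centroids. Each class has modality-specific
#' Gaussian intensities, plus global additive noise.
#'
#' @param gridShape integer(3) voxel counts.
#' @param voxelSize numeric(3) voxel edge lengths in mm.
#' @param brainSemiaxes numeric(3) brain-ellipsoid semiaxes, mm.
#' @param csfShell sulcal-CSF shell thickness under the dura, mm.
#' @param gmThickness cortical GM shell thickness, mm.
#' @param ventricleSemiaxes numeric(3) semiaxes of each ventricle, mm.
#' @param ventricleOffset numeric(3) center of the right ventricle relative
#'   to the brain center, mm; the left ventricle mirrors it in x.
#' @param pvLesions list of periventricular lesion requests:
#'   `list(volume_cc=, ventricle=, direction=)` with `direction` a 3-vector
#'   pointing from the ventricle center toward the seed on its surface.
#' @param dwLesions list of deep-white lesion requests:
#'   `list(volume_cc=, center=)` with `center` mm relative to brain center.
#' @param lacunes list of `list(parent=, volume_cc=)`; `parent` indexes the
#'   concatenated pv-then-dw lesion list.
#' @param dwGapVoxels minimum Chebyshev gap (voxels) between deep-white
#'   lesions and the ventricular mask.
#' @param intensityModel 5 x 3 mean matrix and 5 x 3 sd matrix (rows CSF,
#'   GM, WM, SH, lacune; columns t1, pd, t2) as a list `mean`, `sd`.
#' @param noiseSD global additive Gaussian noise SD (intensity units).
#' @param seed integer master seed.
#' @return object of class `PhantomSpec` (a validated list).
#' @seealso [defaultPhantomSpec()], [generatePhantom()]
#' @export
phantomSpec <- function(gridShape, voxelSize, brainSemiaxes, csfShell = 3,
                        gmThickness = 4, ventricleSemiaxes,
                        ventricleOffset = c(14, 5, 8),
                        pvLesions = list(), dwLesions = list(),
                        lacunes = list(), dwGapVoxels = 3L,
                        intensityModel = defaultIntensityModel(),
                        noiseSD = 0, seed = 1L) {
  spec <- list(gridShape = as.integer(gridShape), voxelSize = voxelSize,
               brainSemiaxes = brainSemiaxes, csfShell = csfShell,
               gmThickness = gmThickness,
               ventricleSemiaxes = ventricleSemiaxes,
               ventricleOffset = ventricleOffset, pvLesions = pvLesions,
               dwLesions = dwLesions, lacunes = lacunes,
               dwGapVoxels = as.integer(dwGapVoxels),
               intensityModel = intensityModel, noiseSD = noiseSD,
               seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  validatePhantomSpec(spec)
  spec
}

validatePhantomSpec <- function(spec) {
  stopifnot(length(spec$gridShape) == 3L, all(spec$gridShape > 0),
            all(spec$voxelSize > 0), all(spec$brainSemiaxes > 0),
            all(spec$ventricleSemiaxes > 0), spec$noiseSD >= 0)
  # ventricles strictly inside the WM interior of the brain ellipsoid
  inner <- spec$brainSemiaxes - spec$csfShell - spec$gmThickness
  if (any(inner <= 0)) stop("CSF+GM shells thicker than the brain semiaxes")
  ext <- abs(spec$ventricleOffset) + spec$ventricleSemiaxes
  if (any(ext >= inner))
    stop("ventricle ellipsoids must lie strictly inside the white matter")
  for (l in c(spec$pvLesions, spec$dwLesions))
    if (l$volume_cc <= 0) stop("lesion volumes must be positive")
  for (l in spec$lacunes) {
    if (l$volume_cc <= 0) stop("lacune volumes must be positive")
    nles <- length(spec$pvLesions) + length(spec$dwLesions)
    if (l$parent < 1 || l$parent > nles)
      stop("lacune parent index out of range")
  }
  im <- spec$intensityModel
  if (any(im$sd < 0)) stop("intensity SDs must be nonnegative")
  m <- im$mean
  if (!(m["CSF", "t1"] < m["GM", "t1"] && m["GM", "t1"] < m["WM", "t1"]))
    stop("T1 class means must satisfy CSF < GM < WM")
  if (!(m["SH", "pd"] > m["WM", "pd"] && m["SH", "t2"] > m["WM", "t2"]))
    stop("SH must be hyperintense to WM on PD and T2")
  invisible(TRUE)
}

#' Default class-conditional intensity model
#'
#' Means chosen so that the discriminative contrasts mirror the real
#' acquisition: on T1, CSF < GM < WM with hyperintensities isointense to WM
#' and lacune cores CSF-like; on PD and T2 the hyperintensity and lacune
#' classes sit well above white matter. The minimum discriminative
#' inter-class gap (T1 CSF/GM, T1 GM/WM, PD WM/SH, T2 WM/SH) is 30 units.
#'
#' @return list with `mean` and `sd` matrices (class x modality)
#' @export
defaultIntensityModel <- function() {
  classes <- c("CSF", "GM", "WM", "SH", "lacune")
  mods <- c("t1", "pd", "t2")
  mean <- matrix(c(
    # t1, pd, t2
    30,  55, 120,   # CSF
    70,  85,  75,   # GM
    100, 90,  60,   # WM
    100, 120, 105,  # SH (isointense to WM on T1)
    30,  120, 115   # lacune core (CSF-like on T1, bright on PD/T2)
  ), nrow = 5, byrow = TRUE, dimnames = list(classes, mods))
  sd <- matrix(0, 5, 3, dimnames = list(classes, mods))
  list(mean = mean, sd = sd)
}

#' Default desk-scale phantom
#'
#' A 72 x 88 x 64 grid at 2 mm isotropic voxels with a brain of semiaxes
#' 63 x 78 x 55 mm (analytic volume ~1.13 litre, in the range of adult
#' supratentorial intracranial volumes), two ventricles, two periventricular
#' lesions (4.5 and 1.5 cc), one deep-white lesion (0.6 cc) and one 0.05 cc
#' lacune core inside the large periventricular lesion. Volumes echo typical
#' AD-range hyperintensity loads.
#'
#' @param noiseSD additive noise SD; 0 gives a noise-free phantom.
#' @param seed integer master seed.
#' @param pvLesions,dwLesions,lacunes override the default lesion load.
#' @return a `PhantomSpec`
#' @export
defaultPhantomSpec <- function(noiseSD = 0, seed = 1L,
                               pvLesions = list(
                                 list(volume_cc = 4.5, ventricle = 1L,
                                      direction = c(1, -0.3, 0.2)),
                                 list(volume_cc = 1.5, ventricle = 2L,
                                      direction = c(-1, 0.5, 0))),
                               dwLesions = list(
                                 list(volume_cc = 0.6, center = c(32, -20, 5))),
                               lacunes = list(
                                 list(parent = 1L, volume_cc = 0.05))) {
  phantomSpec(gridShape = c(72L, 88L, 64L), voxelSize = c(2, 2, 2),
              brainSemiaxes = c(63, 78, 55), csfShell = 4, gmThickness = 5,
              ventricleSemiaxes = c(8, 22, 9),
              ventricleOffset = c(13, 6, 6),
              pvLesions = pvLesions, dwLesions = dwLesions,
              lacunes = lacunes, noiseSD = noiseSD, seed = seed)
}

#' Minimum discriminative inter-class intensity gap of a phantom spec
#'
#' The smallest of the contrasts the pipeline must resolve: T1 CSF-GM,
#' T1 GM-WM, PD WM-SH, T2 WM-SH. Noise conditions expressed as a fraction
#' of "the inter-class gap" refer to this value.
#'
#' @param spec a `PhantomSpec`
#' @return numeric scalar, intensity units
#' @export
interClassGap <- function(spec) {
  m <- spec$intensityModel$mean
  min(m["GM", "t1"] - m["CSF", "t1"], m["WM", "t1"] - m["GM", "t1"],
      m["SH", "pd"] - m["WM", "pd"], m["SH", "t2"] - m["WM", "t2"])
}

# Grow a lesion of `nvox` voxels from the eligible mask, taking the voxels
# nearest (Euclidean, mm) to the seed point.
growLesion <- function(eligible, seedPoint, nvox, co, labels, code,
                       lesionName) {
  idx <- which(eligible)
  if (length(idx) < nvox)
    stop(sprintf("lesion %s cannot be placed: only %d eligible white-matter voxels for %d requested",
                 lesionName, length(idx), nvox))
  dims <- dim(eligible)
  ai <- arrayInd(idx, dims)
  dx <- co$x[ai[, 1]] - seedPoint[1]
  dy <- co$y[ai[, 2]] - seedPoint[2]
  dz <- co$z[ai[, 3]] - seedPoint[3]
  d2 <- dx * dx + dy * dy + dz * dz
  take <- idx[order(d2)[seq_len(nvox)]]
  labels[take] <- code
  labels
}

#' Generate a multimodal phantom with ground truth
#'
#' Builds the analytic label geometry from `spec`, places the requested
#' lesions and lacune cores, then samples class-conditional intensities for
#' T1, PD and T2 plus additive Gaussian noise. Identical spec and seed give
#' bit-identical output. Each lesion's realized volume differs from its
#' request by at most one voxel volume (count = rounded target / voxel
#' volume).
#'
#' @param spec a `PhantomSpec` from [phantomSpec()]
#' @return list with `volume` ([MultiModalVolume-class]) and `truth`
#'   ([GroundTruth-class])
#' @export
generatePhantom <- function(spec) {
  validatePhantomSpec(spec)
  dims <- spec$gridShape
  vox <- spec$voxelSize
  vv <- voxelVolumeCC(vox)
  co <- gridCoords(dims, vox)
  K <- phantomClasses()

  brain <- ellipsoidMask(dims, vox, spec$brainSemiaxes)
  gmOuter <- ellipsoidMask(dims, vox, spec$brainSemiaxes - spec$csfShell)
  wmOuter <- ellipsoidMask(dims, vox,
                           spec$brainSemiaxes - spec$csfShell - spec$gmThickness)
  labels <- array(0L, dims)
  labels[brain] <- K[["sCSF"]]
  labels[gmOuter] <- K[["GM"]]
  labels[wmOuter] <- K[["WM"]]

  ventOffsets <- list(spec$ventricleOffset,
                      spec$ventricleOffset * c(-1, 1, 1))
  ventSeeds <- matrix(0L, nrow = 2, ncol = 3)
  for (v in 1:2) {
    vm <- ellipsoidMask(dims, vox, spec$ventricleSemiaxes, ventOffsets[[v]])
    if (any(labels[vm] != K[["WM"]]))
      stop("ventricle ellipsoid leaves the white-matter interior")
    labels[vm] <- K[["vCSF"]]
    ctr <- dims * vox / 2 + ventOffsets[[v]]
    ventSeeds[v, ] <- pmin(pmax(round(ctr / vox + 0.5), 1L), dims)
  }

  # periventricular lesions: seed = first WM voxel along a ray from the
  # ventricle center, then nearest-WM growth (guarantees ventricle contact)
  lesionVox <- list()
  for (i in seq_along(spec$pvLesions)) {
    l <- spec$pvLesions[[i]]
    off <- ventOffsets[[l$ventricle]]
    dir <- l$direction / sqrt(sum(l$direction^2))
    seedPoint <- NULL
    for (t in seq(0, max(spec$brainSemiaxes), by = min(vox) / 4)) {
      p <- off + t * dir
      iv <- pmin(pmax(ceiling((p + dims * vox / 2) / vox), 1L), dims)
      if (labels[iv[1], iv[2], iv[3]] == K[["WM"]]) {
        seedPoint <- p
        break
      }
    }
    if (is.null(seedPoint))
      stop(sprintf("pv lesion %d: no white matter found along its direction", i))
    nvox <- max(1L, round(l$volume_cc / vv))
    before <- labels
    labels <- growLesion(labels == K[["WM"]], seedPoint, nvox, co,
                         labels, K[["pvSH"]], sprintf("pv%d", i))
    lesionVox[[length(lesionVox) + 1L]] <-
      which(labels == K[["pvSH"]] & before != K[["pvSH"]])
  }

  # deep-white lesions: eligible WM kept >= dwGapVoxels (Chebyshev) away
  # from ventricular CSF so connectivity-based classification is unambiguous
  ventMask <- labels == K[["vCSF"]]
  forbidden <- dilateMask(ventMask, spec$dwGapVoxels, 26L)
  for (i in seq_along(spec$dwLesions)) {
    l <- spec$dwLesions[[i]]
    nvox <- max(1L, round(l$volume_cc / vv))
    before <- labels
    labels <- growLesion(labels == K[["WM"]] & !forbidden, l$center, nvox,
                         co, labels, K[["dwSH"]], sprintf("dw%d", i))
    lesionVox[[length(lesionVox) + 1L]] <-
      which(labels == K[["dwSH"]] & before != K[["dwSH"]])
  }

  # lacune cores at parent-lesion centroids, strictly interior by taking
  # the parent voxels nearest its centroid
  for (i in seq_along(spec$lacunes)) {
    l <- spec$lacunes[[i]]
    parent <- lesionVox[[l$parent]]
    parent <- parent[labels[parent] %in% c(K[["pvSH"]], K[["dwSH"]])]
    nvox <- max(1L, round(l$volume_cc / vv))
    if (length(parent) < nvox)
      stop(sprintf("lacune %d larger than its parent lesion", i))
    ai <- arrayInd(parent, dims)
    ctr <- c(mean(co$x[ai[, 1]]), mean(co$y[ai[, 2]]), mean(co$z[ai[, 3]]))
    d2 <- (co$x[ai[, 1]] - ctr[1])^2 + (co$y[ai[, 2]] - ctr[2])^2 +
      (co$z[ai[, 3]] - ctr[3])^2
    labels[parent[order(d2)[seq_len(nvox)]]] <- K[["lacune"]]
  }

  # intensity synthesis
  im <- spec$intensityModel
  classOfLabel <- c(sCSF = "CSF", vCSF = "CSF", GM = "GM", WM = "WM",
                    pvSH = "SH", dwSH = "SH", lacune = "lacune")
  grids <- withStream(spec$seed, "phantom-intensity", {
    out <- list()
    for (mod in c("t1", "pd", "t2")) {
      g <- array(0, dims)
      for (lab in names(K)) {
        sel <- labels == K[[lab]]
        n <- sum(sel)
        if (!n) next
        cls <- classOfLabel[[lab]]
        g[sel] <- im$mean[cls, mod] +
          (if (im$sd[cls, mod] > 0) rnorm(n, 0, im$sd[cls, mod]) else 0)
      }
      if (spec$noiseSD > 0)
        g <- g + array(rnorm(prod(dims), 0, spec$noiseSD), dims)
      out[[mod]] <- g
    }
    out
  })

  counts <- tabulate(labels + 1L, nbins = 8L)[-1L]
  trueVolumes <- counts * vv
  names(trueVolumes) <- names(K)

  vol <- new("MultiModalVolume", t1 = grids$t1, pd = grids$pd, t2 = grids$t2,
             voxelSize = vox)
  truth <- new("GroundTruth", labels = labels, voxelSize = vox,
               trueVolumes = trueVolumes, ventricleSeeds = ventSeeds)
  list(volume = vol, truth = truth)
}
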