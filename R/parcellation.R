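# Plane-based geometric 26-region parcellation exposing the standard
# regionalized-volumetrics interface (13 regions per hemisphere).

#' Default landmark/boundary configuration for the geometric atlas
#'
#' Fractions are measured along the mask's bounding extent: `coronal` split
#' the anterior-posterior axis into frontal / parietal / occipital bands;
#' `frontalAxial` split the frontal band into superior / middle / inferior
#' thirds; `temporalAxial` is the axial height (fraction of the z extent)
#' below which the temporal carve-out applies; `temporalSplit` separates
#' anterior from posterior temporal along y; `temporalAnterior` is where the
#' temporal carve-out begins along y; `medialFraction` is the half-width
#' (fraction of each hemisphere's lateral extent from the midline) of the
#' medial frontal and parietal strips.
#'
#' @param coronal numeric(2), strictly increasing in (0, 1).
#' @param frontalAxial numeric(2), strictly increasing in (0, 1).
#' @param temporalAxial,temporalSplit,temporalAnterior,medialFraction scalars
#'   in (0, 1).
#' @param parietalAxial scalar in (0, 1), superior/inferior parietal split.
#' @return list of class `AtlasLandmarks`
#' @export
atlasLandmarks <- function(coronal = c(0.40, 0.75),
                           frontalAxial = c(1 / 3, 2 / 3),
                           temporalAxial = 0.35, temporalSplit = 0.50,
                           temporalAnterior = 0.15, medialFraction = 0.30,
                           parietalAxial = 0.5) {
  stopifnot(length(coronal) == 2, all(diff(coronal) > 0),
            all(coronal > 0 & coronal < 1),
            length(frontalAxial) == 2, all(diff(frontalAxial) > 0))
  structure(list(coronal = coronal, frontalAxial = frontalAxial,
                 temporalAxial = temporalAxial,
                 temporalSplit = temporalSplit,
                 temporalAnterior = temporalAnterior,
                 medialFraction = medialFraction,
                 parietalAxial = parietalAxial),
            class = "AtlasLandmarks")
}

voiRegionNames <- function() {
  per <- c("medial superior frontal", "lateral superior frontal",
           "medial middle frontal", "lateral middle frontal",
           "medial inferior frontal", "lateral inferior frontal",
           "medial superior parietal", "lateral superior parietal",
           "medial inferior parietal", "lateral inferior parietal",
           "occipital", "anterior temporal", "posterior temporal")
  data.frame(
    id = 1:26,
    name = c(paste("L", per), paste("R", per)),
    hemisphere = rep(c("L", "R"), each = 13),
    lobe = rep(c(rep("frontal", 6), rep("parietal", 4), "occipital",
                 "temporal", "temporal"), 2),
    stringsAsFactors = FALSE)
}

#' Build the geometric 26-region VOI atlas over an intracranial mask
#'
#' Deterministic partition by cutting planes: a sagittal midline splits the
#' hemispheres; coronal cuts at the configured fractions of the
#' anterior-posterior extent define frontal, parietal and occipital bands;
#' an axial cut and an anterior/posterior split carve the temporal regions
#' out of the inferior parietal/posterior-frontal territory; medial-lateral
#' and axial cuts subdivide the frontal band into six regions and the
#' parietal band into four, giving 13 regions per hemisphere.
#'
#' @param mask logical 3D array or [IntracranialMask-class].
#' @param voxelSize numeric(3), mm.
#' @param landmarks an `AtlasLandmarks` configuration; the sagittal midline
#'   defaults to the mask centroid and may be overridden with `midlineX`.
#' @param midlineX optional x coordinate (1-based voxel units, may be
#'   fractional) of the midline plane.
#' @return a [VOIAtlas-class]
#' @export
buildAtlas <- function(mask, voxelSize = NULL, landmarks = atlasLandmarks(),
                       midlineX = NULL) {
  if (is(mask, "IntracranialMask")) {
    voxelSize <- mask@voxelSize
    mask <- mask@mask
  }
  if (is.null(voxelSize)) stop("voxelSize required for a bare mask array")
  if (!any(mask)) stop("mask is empty")
  dims <- dim(mask)
  idx <- which(mask)
  ai <- arrayInd(idx, dims)
  xr <- range(ai[, 1]); yr <- range(ai[, 2]); zr <- range(ai[, 3])
  if (diff(yr) < 2 || diff(zr) < 2)
    stop("degenerate landmarks: mask extent too small to parcellate")
  if (is.null(midlineX)) midlineX <- mean(ai[, 1])
  lm <- landmarks
  yf <- (ai[, 2] - yr[1]) / diff(yr)        # 0 anterior .. 1 posterior
  zf <- (ai[, 3] - zr[1]) / diff(zr)        # 0 inferior .. 1 superior
  leftSide <- ai[, 1] <= midlineX
  latExtent <- ifelse(leftSide, midlineX - xr[1], xr[2] - midlineX)
  latFrac <- abs(ai[, 1] - midlineX) / pmax(latExtent, 1e-9)
  medial <- latFrac <= lm$medialFraction

  band <- ifelse(yf < lm$coronal[1], "frontal",
                 ifelse(yf < lm$coronal[2], "parietal", "occipital"))
  temporal <- zf < lm$temporalAxial & yf >= lm$temporalAnterior &
    yf < lm$coronal[2]
  regional <- character(length(idx))
  regional[band == "occipital"] <- "occipital"
  ft <- band == "frontal" & !temporal
  fa <- ifelse(zf >= lm$frontalAxial[2], "superior",
               ifelse(zf >= lm$frontalAxial[1], "middle", "inferior"))
  regional[ft] <- paste(ifelse(medial[ft], "medial", "lateral"),
                        fa[ft], "frontal")
  pt <- band == "parietal" & !temporal
  pa <- ifelse(zf >= lm$parietalAxial, "superior", "inferior")
  regional[pt] <- paste(ifelse(medial[pt], "medial", "lateral"),
                        pa[pt], "parietal")
  regional[temporal] <- ifelse(yf[temporal] < lm$temporalSplit,
                               "anterior temporal", "posterior temporal")
  full <- paste(ifelse(leftSide, "L", "R"), regional)

  tab <- voiRegionNames()
  regionId <- tab$id[match(full, tab$name)]
  if (any(is.na(regionId))) stop("internal: unnamed region produced")
  regions <- array(0L, dims)
  regions[idx] <- regionId
  new("VOIAtlas", regions = regions, regionTable = tab,
      voxelSize = voxelSize)
}

#' Cross-tabulate label classes by atlas region
#'
#' @param labels integer 3D label array (any labeling co-registered with the
#'   atlas), or an object with a [labelArray()] method.
#' @param atlas a [VOIAtlas-class].
#' @param classNames optional named integer vector mapping class names to
#'   label codes (defaults to the nonzero codes present).
#' @return matrix of voxel counts, regions (26 rows, named) x classes;
#'   column sums reproduce whole-brain class counts over the atlas mask.
#' @export
regionalize <- function(labels, atlas, classNames = NULL) {
  if (!is.array(labels)) labels <- labelArray(labels)
  if (!identical(dim(labels), dim(atlas@regions)))
    stop("geometry mismatch: labels and atlas differ in grid dimensions")
  if (is.null(classNames)) {
    codes <- sort(unique(labels[labels > 0]))
    classNames <- structure(as.integer(codes), names = paste0("class", codes))
  }
  tab <- atlas@regionTable
  out <- matrix(0L, nrow = 26, ncol = length(classNames),
                dimnames = list(tab$name, names(classNames)))
  reg <- atlas@regions
  for (ci in seq_along(classNames)) {
    sel <- labels == classNames[ci] & reg > 0
    counts <- tabulate(reg[sel], nbins = 26L)
    out[, ci] <- counts
  }
  out
}
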