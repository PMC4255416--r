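# Internal helpers: named RNG streams, voxel geometry, shared small utilities.

# Derive a per-stage seed from the user's master seed and a stream name, so
# modules draw from independent reproducible streams. Stays below 2^31.
streamSeed <- function(seed, stream) {
  ch <- utf8ToInt(stream)
  h <- sum(ch * seq_along(ch)) %% 1000003L
  ((as.integer(seed) %% 1000003L) * 2011L + h) %% 2147483629L
}

withStream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(streamSeed(seed, stream))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

voxelVolumeCC <- function(voxelSize) prod(voxelSize) / 1000

# 1-based voxel-center world coordinates (mm) for each axis of a grid.
axisCoords <- function(n, vox) (seq_len(n) - 0.5) * vox

# Coordinate arrays for a full grid, centered at `center` (mm).
gridCoords <- function(dims, voxelSize, center = dims * voxelSize / 2) {
  list(
    x = axisCoords(dims[1], voxelSize[1]) - center[1],
    y = axisCoords(dims[2], voxelSize[2]) - center[2],
    z = axisCoords(dims[3], voxelSize[3]) - center[3]
  )
}

# Logical array of voxels inside an ellipsoid (semiaxes mm, center mm
# relative to grid center).
ellipsoidMask <- function(dims, voxelSize, semiaxes, offset = c(0, 0, 0)) {
  co <- gridCoords(dims, voxelSize)
  x2 <- ((co$x - offset[1]) / semiaxes[1])^2
  y2 <- ((co$y - offset[2]) / semiaxes[2])^2
  z2 <- ((co$z - offset[3]) / semiaxes[3])^2
  q <- outer(outer(x2, y2, `+`), z2, `+`)
  q <= 1
}

asLogicalArray <- function(v, dims) array(as.logical(v), dim = dims)

labelComponents <- function(mask, connectivity = 26L) {
  array(.cc_label(as.logical(mask), dim(mask), as.integer(connectivity)),
        dim = dim(mask))
}

dilateMask <- function(mask, radius = 1L, connectivity = 26L) {
  asLogicalArray(.dilate(as.logical(mask), dim(mask), as.integer(radius),
                         as.integer(connectivity)), dim(mask))
}

erodeMask <- function(mask, radius = 1L, connectivity = 26L) {
  asLogicalArray(.erode(as.logical(mask), dim(mask), as.integer(radius),
                        as.integer(connectivity)), dim(mask))
}

fillHoles <- function(mask) {
  asLogicalArray(.fill_holes(as.logical(mask), dim(mask)), dim(mask))
}

neighborCount26 <- function(flag, dims) {
  array(.neighbor_count(as.logical(flag), as.integer(dims)), dim = dims)
}

# Dice coefficient between two binary masks.
diceCoefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Adjusted Fisher-Pearson sample skewness.
sampleSkewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(0)
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  sqrt(n * (n - 1)) / (n - 2) * (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^1.5
}
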