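# Synthetic phantom generator: geometry, volumes, determinism, noise model.

test_that("lesion-free spec yields zero lesion volumes and a clean partition", {
  spec <- smallPhantomSpec(pvLesions = list(), dwLesions = list(),
                           lacunes = list())
  ph <- generatePhantom(spec)
  tv <- ph$truth@trueVolumes
  expect_equal(unname(tv[c("pvSH", "dwSH", "lacune")]), c(0, 0, 0))
  # every in-brain voxel carries exactly one class; volumes sum to the brain
  labels <- labelArray(ph$truth)
  vv <- prod(spec$voxelSize) / 1000
  expect_equal(sum(tv), sum(labels > 0) * vv)
})

test_that("requested lesion volumes are realized to voxel quantization", {
  # 1 mm^3 voxels: a 2.0 cc deep lesion must land within 0.001 cc
  spec <- phantomSpec(gridShape = c(44L, 52L, 44L), voxelSize = c(1, 1, 1),
                      brainSemiaxes = c(20, 24, 20), csfShell = 2,
                      gmThickness = 2, ventricleSemiaxes = c(3, 7, 3),
                      ventricleOffset = c(5, 2, 2),
                      dwLesions = list(list(volume_cc = 2.0,
                                            center = c(-9, -6, 2))),
                      seed = 3L)
  ph <- generatePhantom(spec)
  expect_lt(abs(ph$truth@trueVolumes[["dwSH"]] - 2.0), 0.001)
  # at coarser voxels the bound is one voxel volume
  spec2 <- smallPhantomSpec()
  ph2 <- generatePhantom(spec2)
  vv <- prod(spec2$voxelSize) / 1000
  tv <- ph2$truth@trueVolumes
  expect_lte(abs((tv[["pvSH"]] + tv[["lacune"]]) - 2.0), vv)
  expect_lte(abs(tv[["dwSH"]] - 0.5), vv)
})

test_that("same spec and seed give bit-identical volumes", {
  spec <- smallPhantomSpec(noiseSD = 4)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(t1Volume(a$volume), t1Volume(b$volume))
  expect_identical(pdVolume(a$volume), pdVolume(b$volume))
  expect_identical(labelArray(a$truth), labelArray(b$truth))
  c <- generatePhantom(smallPhantomSpec(noiseSD = 4, seed = 2L))
  expect_false(identical(t1Volume(a$volume), t1Volume(c$volume)))
})

test_that("sampled intensities respect the configured class ordering", {
  spec <- smallPhantomSpec(noiseSD = 5)
  ph <- generatePhantom(spec)
  labels <- labelArray(ph$truth)
  t1 <- t1Volume(ph$volume)
  mCSF <- mean(t1[labels %in% c(1, 2)])
  mGM <- mean(t1[labels == 3])
  mWM <- mean(t1[labels == 4])
  expect_lt(mCSF, mGM)
  expect_lt(mGM, mWM)
  pd <- pdVolume(ph$volume); t2 <- t2Volume(ph$volume)
  sh <- labels %in% c(5, 6)
  expect_gt(mean(pd[sh]), mean(pd[labels == 4]))
  expect_gt(mean(t2[sh]), mean(t2[labels == 4]))
})

test_that("geometric and lesion invariants are validated", {
  expect_error(
    phantomSpec(gridShape = c(40L, 40L, 40L), voxelSize = c(2, 2, 2),
                brainSemiaxes = c(30, 30, 30),
                ventricleSemiaxes = c(15, 25, 15)),
    "inside")
  expect_error(
    smallPhantomSpec(pvLesions = list(list(volume_cc = -1, ventricle = 1L,
                                           direction = c(1, 0, 0)))),
    "positive")
  expect_error(
    smallPhantomSpec(lacunes = list(list(parent = 9L, volume_cc = 0.1))),
    "parent")
  # lesion larger than the available white matter is a placement error
  expect_error(
    generatePhantom(smallPhantomSpec(
      dwLesions = list(list(volume_cc = 5000, center = c(26, -14, 4))))),
    "cannot be placed")
})

test_that("lacune cores are carved from their parent lesion at its centroid", {
  spec <- smallPhantomSpec()
  ph <- generatePhantom(spec)
  labels <- labelArray(ph$truth)
  lac <- which(labels == 7L)
  expect_gt(length(lac), 0)
  # carving conserves the parent's requested volume
  vv <- prod(spec$voxelSize) / 1000
  tv <- ph$truth@trueVolumes
  expect_lte(abs(tv[["pvSH"]] + tv[["lacune"]] - 2.0), vv)
  # every core voxel stays attached to hyperintense lesion tissue
  dims <- dim(labels)
  for (v in lac) {
    ai <- arrayInd(v, dims)
    xs <- max(ai[1] - 1, 1):min(ai[1] + 1, dims[1])
    ys <- max(ai[2] - 1, 1):min(ai[2] + 1, dims[2])
    zs <- max(ai[3] - 1, 1):min(ai[3] + 1, dims[3])
    expect_true(any(labels[xs, ys, zs] %in% c(5L, 6L)))
  }
})
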