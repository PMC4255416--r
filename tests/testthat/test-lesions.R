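# SH detection, periventricular/deep-white split, lacune extraction.

test_that("a lesion-free phantom yields an empty SH mask", {
  res <- cachedPipeline("nolesion", smallPhantomSpec(
    pvLesions = list(), dwLesions = list(), lacunes = list()))
  expect_false(any(res$lesions@labels > 0))
  expect_equal(nrow(componentTable(res$lesions)), 0L)
})

test_that("implanted hyperintense lesions are detected nearly completely", {
  res <- smallZeroNoiseRun()
  truth <- labelArray(res$phantom$truth)
  sh <- res$lesions@labels > 0
  truthSH <- truth %in% c(5L, 6L, 7L)
  expect_gte(sum(sh & truthSH) / sum(truthSH), 0.95)
})

test_that("hyperintensity outside the intracranial mask is ignored", {
  res <- smallZeroNoiseRun()
  vol <- res$phantom$volume
  pd <- pdVolume(vol); t2 <- t2Volume(vol)
  out <- which(!res$mask@mask)[1:50]
  pd[out] <- 200; t2[out] <- 200
  shMask <- segmentSH(pd, t2, res$tissue, res$mask)
  expect_false(any(shMask[out]))
})

test_that("an empty white-matter class is a calibration error", {
  res <- smallZeroNoiseRun()
  tissue <- res$tissue
  tissue@labels[tissue@labels == 4L] <- 3L
  expect_error(segmentSH(pdVolume(res$phantom$volume),
                         t2Volume(res$phantom$volume), tissue, res$mask),
               "WM class is empty")
})

test_that("ventricle-touching components are periventricular, distant ones deep", {
  dims <- c(24L, 24L, 24L)
  vcsf <- array(FALSE, dims); vcsf[10:14, 10:14, 10:14] <- TRUE
  sh <- array(FALSE, dims)
  sh[15:17, 10:12, 10:12] <- TRUE    # face contact with the ventricle
  sh[20:22, 20:22, 20:22] <- TRUE    # >= 3 voxels away
  les <- classifyPvDw(sh, vcsf, c(1, 1, 1))
  tab <- componentTable(les)
  expect_equal(nrow(tab), 2L)
  near <- tab[tab$cx < 19, ]
  far <- tab[tab$cx > 19, ]
  expect_equal(near$class, "pvSH")
  expect_equal(far$class, "dwSH")
  # empty mask is a valid empty result, not an error
  e <- classifyPvDw(array(FALSE, dims), vcsf, c(1, 1, 1))
  expect_equal(nrow(componentTable(e)), 0L)
})

test_that("pv/dw split matches the dilate-and-intersect oracle on random scenes", {
  dims <- c(30L, 34L, 30L)
  for (s in 1:4) {
    set.seed(100 + s)
    vcsf <- array(FALSE, dims)
    vcsf[12:18, 14:20, 12:18] <- TRUE
    sh <- array(FALSE, dims)
    for (i in 1:25) {
      c0 <- sapply(dims, function(d) sample(2:(d - 2), 1))
      r <- sample(0:1, 1)
      xs <- max(c0[1] - r, 1):min(c0[1] + r, dims[1])
      ys <- max(c0[2] - r, 1):min(c0[2] + r, dims[2])
      zs <- max(c0[3] - r, 1):min(c0[3] + r, dims[3])
      sh[xs, ys, zs] <- TRUE
    }
    sh <- sh & !vcsf
    params <- shDetectionParams(pvDistanceVoxels = 1L,
                                minComponentVoxels = 1L)
    les <- classifyPvDw(sh, vcsf, c(1, 1, 1), params)
    oracle <- oraclePvDw(sh, vcsf, 1L)
    for (k in seq_len(max(oracle$labels))) {
      vox <- which(oracle$labels == k)
      predClass <- unique(les@labels[vox])
      expect_length(predClass, 1L)
      expect_equal(c("pvSH", "dwSH")[predClass], oracle$classes[k])
    }
  }
})

test_that("T1 intensity decides lacune membership voxelwise", {
  res <- smallZeroNoiseRun()
  t1 <- t1Volume(res$phantom$volume)
  tissueLabels <- res$tissue@labels
  csfMean <- mean(t1[tissueLabels %in% c(1L, 2L)])
  wmMean <- mean(t1[tissueLabels == 4L])
  lac <- res$lesions@labels == 3L
  shOnly <- res$lesions@labels %in% c(1L, 2L)
  # CSF-intensity SH voxels became lacune; WM-intensity SH voxels stayed SH
  expect_true(all(abs(t1[lac] - csfMean) < 1))
  expect_true(all(abs(t1[shOnly] - wmMean) < 1))
})

test_that("implanted lacune components are recovered exactly at zero noise", {
  spec <- smallPhantomSpec(
    pvLesions = list(list(volume_cc = 2.0, ventricle = 1L,
                          direction = c(1, -0.3, 0.2)),
                     list(volume_cc = 1.2, ventricle = 2L,
                          direction = c(-1, 0.4, 0.1))),
    dwLesions = list(list(volume_cc = 0.5, center = c(26, -14, 4)),
                     list(volume_cc = 0.4, center = c(-26, -16, -2))),
    lacunes = list(list(parent = 1L, volume_cc = 0.06),
                   list(parent = 2L, volume_cc = 0.05),
                   list(parent = 3L, volume_cc = 0.05),
                   list(parent = 4L, volume_cc = 0.05)))
  res <- cachedPipeline("lacune4", spec)
  tab <- componentTable(res$lesions)
  expect_equal(sum(tab$class == "lacune"), 4L)
  expect_true(all(!is.na(tab$parent[tab$class == "lacune"])))
})

test_that("lacune reassignment conserves total detected SH volume", {
  res <- smallZeroNoiseRun()
  vcsf <- res$tissue@labels == 2L
  dim(vcsf) <- dim(res$tissue@labels)
  shMask <- segmentSH(pdVolume(res$phantom$volume),
                      t2Volume(res$phantom$volume), res$tissue, res$mask,
                      t1 = t1Volume(res$phantom$volume))
  pre <- classifyPvDw(shMask, vcsf, voxelSize(res$phantom$volume))
  post <- extractLacunes(pre, t1Volume(res$phantom$volume), res$tissue)
  vv <- prod(voxelSize(res$phantom$volume)) / 1000
  expect_equal(sum(post@labels > 0), sum(shMask))
  tab <- componentTable(post)
  expect_equal(sum(tab$volume_cc), sum(shMask) * vv)
})

test_that("raising the detection threshold never increases SH volume", {
  res <- cachedPipeline("noisy2", smallPhantomSpec(noiseSD = 3, seed = 2L))
  vols <- sapply(c(2, 3, 4, 5), function(z) {
    m <- segmentSH(pdVolume(res$phantom$volume),
                   t2Volume(res$phantom$volume), res$tissue, res$mask,
                   shDetectionParams(zThreshold = z))
    sum(m)
  })
  expect_true(all(diff(vols) <= 0))
})
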