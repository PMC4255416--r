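# Volumetric profiles: identities, additivity, normalization, z-scores.

test_that("BPF and vCSF ratio follow their defining identities", {
  res <- smallZeroNoiseRun()
  p <- res$profile
  w <- wholeBrainVolumes(p)
  expect_equal(bpf(p), 100 * (w[["GM"]] + w[["WM"]]) / stTIV(p))
  expect_equal(p@vcsfRatio, w[["vCSF"]] / stTIV(p))
  expect_error(computeProfile(res$tissue, res$lesions, res$atlas, 0),
               "positive")
})

test_that("zero-noise profile reproduces ground-truth volumes exactly", {
  res <- smallZeroNoiseRun()
  w <- wholeBrainVolumes(res$profile)
  tv <- res$phantom$truth@trueVolumes
  for (cl in names(tv)) expect_equal(w[[cl]], tv[[cl]], tolerance = 1e-12)
})

test_that("regional volumes are additive to whole-brain volumes", {
  res <- smallZeroNoiseRun()
  reg <- regionalVolumes(res$profile)
  agg <- tapply(reg$raw_cc, reg$class, sum)
  w <- wholeBrainVolumes(res$profile)
  for (cl in names(agg)) expect_equal(agg[[cl]], w[[cl]])
})

test_that("volumes scale with voxel volume while ratios are invariant", {
  spec1 <- smallPhantomSpec()
  spec2 <- smallPhantomSpec()
  spec2$voxelSize <- spec1$voxelSize * 2
  spec2$brainSemiaxes <- spec1$brainSemiaxes * 2
  spec2$ventricleSemiaxes <- spec1$ventricleSemiaxes * 2
  spec2$ventricleOffset <- spec1$ventricleOffset * 2
  spec2$csfShell <- spec1$csfShell * 2
  spec2$gmThickness <- spec1$gmThickness * 2
  spec2$pvLesions[[1]]$volume_cc <- spec1$pvLesions[[1]]$volume_cc * 8
  spec2$dwLesions[[1]]$center <- spec1$dwLesions[[1]]$center * 2
  spec2$dwLesions[[1]]$volume_cc <- spec1$dwLesions[[1]]$volume_cc * 8
  spec2$lacunes[[1]]$volume_cc <- spec1$lacunes[[1]]$volume_cc * 8
  t1 <- generatePhantom(spec1)$truth
  t2 <- generatePhantom(spec2)$truth
  expect_equal(unname(t2@trueVolumes), unname(t1@trueVolumes * 8))
  # BPF-style ratios are scale-free
  r1 <- (t1@trueVolumes[["GM"]] + t1@trueVolumes[["WM"]]) / sum(t1@trueVolumes)
  r2 <- (t2@trueVolumes[["GM"]] + t2@trueVolumes[["WM"]]) / sum(t2@trueVolumes)
  expect_equal(r1, r2)
})

test_that("reference z-scores are centered and scaled on the reference", {
  set.seed(9)
  n <- 120
  df <- data.frame(st_tiv = rnorm(n, 1200, 100),
                   gm_cc = rnorm(n, 520, 50))
  ref <- rep(c(TRUE, FALSE), length.out = n)
  out <- normalizeAndZscore(df, "gm_cc", ref)
  z <- out$data$gm_cc_z
  expect_equal(mean(z[ref]), 0, tolerance = 1e-10)
  expect_equal(sd(z[ref]), 1, tolerance = 1e-10)
  expect_false(out$log$log_applied)
  # subject exactly at the reference mean has z = 0
  x <- df$gm_cc / df$st_tiv
  iMid <- which.min(abs(x - mean(x[ref])))
  expect_lt(abs(z[iMid]), 0.1)
})

test_that("right-skewed variables trigger the log branch and de-skew", {
  set.seed(21)
  n <- 150
  df <- data.frame(st_tiv = rep(1, n),
                   sh_cc = c(rlnorm(n - 10, 1, 1), rep(0, 10)))
  out <- normalizeAndZscore(df, "sh_cc", rep(TRUE, n))
  expect_true(out$log$log_applied)
  expect_gt(out$log$skew_before, 1)
  expect_lt(out$log$skew_after, out$log$skew_before)
  # zero lesion loads survive via the smallest-positive offset
  expect_true(all(is.finite(out$data$sh_cc_z)))
})

test_that("zero reference variance flags the variable instead of failing", {
  df <- data.frame(st_tiv = rep(1, 10), v = rep(3, 10))
  expect_warning(out <- normalizeAndZscore(df, "v", rep(TRUE, 10)),
                 "zero reference variance")
  expect_true(all(is.na(out$data$v_z)))
})
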