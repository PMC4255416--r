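# Composite scores, effect sizes, ANCOVA, backwards elimination, stepwise
# VOI modeling, partial regression.

mkBattery <- function(n, refN = 40) {
  set.seed(31)
  tests <- names(defaultDomainMap()$orientation)
  df <- as.data.frame(setNames(lapply(tests, function(t) rnorm(n + refN, 50, 10)),
                               tests))
  df$group <- c(rep("AD", n), rep("NC", refN))
  df
}

test_that("composites are NC-referenced, oriented and averaged", {
  dm <- defaultDomainMap()
  df <- mkBattery(30)
  ref <- df$group == "NC"
  comp <- compositeScore(df, ref, dm)
  # reference rows average to composite 0
  expect_equal(unname(colMeans(comp[ref, ])), c(0, 0, 0), tolerance = 1e-10)
  # a subject at the NC mean on all tests scores 0 in every domain
  probe <- df
  for (t in names(dm$orientation)) probe[1, t] <- mean(df[[t]][ref])
  c0 <- compositeScore(probe, ref, dm)
  expect_equal(unname(unlist(c0[1, ])), c(0, 0, 0), tolerance = 1e-10)
  # one NC-SD better on every executive test gives composite +1
  probe <- df
  for (t in dm$domains$executive) {
    o <- dm$orientation[[t]]
    probe[1, t] <- mean(df[[t]][ref]) + o * sd(df[[t]][ref])
  }
  c1 <- compositeScore(probe, ref, dm)
  expect_equal(c1$executive[1], 1, tolerance = 1e-10)
  # slower Trails A (1 SD above the NC mean) maps to speed composite -1
  probe <- df
  probe[1, "trails_a_seconds"] <- mean(df$trails_a_seconds[ref]) +
    sd(df$trails_a_seconds[ref])
  cs <- compositeScore(probe, ref, dm)
  expect_equal(cs$speed[1], -1, tolerance = 1e-10)
})

test_that("pooled-SD Cohen's d matches hand calculation and edge cases", {
  # equal means give d = 0
  expect_equal(cohensDPooled(5, 1, 10, 5, 2, 12)$d, 0)
  # hand-checked pooled SD
  e <- cohensDPooled(10, 2, 5, 8, 2, 5)
  expect_equal(e$pooled_sd, 2)
  expect_equal(e$d, 1)
  expect_error(cohensDPooled(1, 0, 5, 1, 0, 5), "pooled SD is zero")
  expect_error(cohensDPooled(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("ANCOVA recovers a planted adjusted group difference", {
  set.seed(77)
  n <- 400
  df <- data.frame(group = factor(rep(c("AD", "NC"), each = n / 2)),
                   age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5),
                   education = rnorm(n, 14, 3))
  df$y <- 0.5 * (df$group == "NC") + 0.02 * df$age + rnorm(n, 0, 1)
  a <- ancovaGroupDifference(df, "y")
  expect_lt(abs(a$estimate - 0.5), 2 * a$se)
  expect_equal(a$n, n)
  # constant covariate triggers a collinearity error
  df$education <- 5
  expect_error(ancovaGroupDifference(df, "y"), "collinearity")
})

test_that("strong signals are retained and pure noise eliminated", {
  set.seed(12)
  n <- 200
  df <- data.frame(x = rnorm(n))
  df$y <- 0.5 * df$x + rnorm(n, 0, 0.1)
  r <- backwardsElimination(df, "y", "x")
  expect_equal(r$retained$term, "x")
  expect_lt(r$retained$p, 0.05)
  # pure-noise predictors at n = 500 are eliminated in most replicates
  reps <- 100
  kept <- 0
  set.seed(13)
  for (i in seq_len(reps)) {
    d2 <- data.frame(y = rnorm(500), x = rnorm(500))
    r2 <- backwardsElimination(d2, "y", "x")
    if (nrow(r2$retained)) kept <- kept + 1
  }
  expect_lt(kept / reps, 0.10)
})

test_that("elimination path matches the explicit refit oracle", {
  set.seed(55)
  for (i in 1:30) {
    n <- 60
    p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n)
    beta <- runif(p, -0.4, 0.4) * rbinom(p, 1, 0.5)
    y <- X %*% beta + rnorm(n)
    df <- data.frame(y = y, X)
    cand <- colnames(df)[-1]
    mine <- backwardsElimination(df, "y", cand)
    oracle <- oracleBackwardsElimination(df, "y", cand, character())
    expect_equal(sort(mine$retained$term), oracle)
  }
})

test_that("forced covariates survive elimination and an empty model is legal", {
  set.seed(8)
  n <- 100
  df <- data.frame(y = rnorm(n), x = rnorm(n), age = rnorm(n))
  r <- backwardsElimination(df, "y", "x", forced = "age")
  expect_true("age" %in% r$retained$term)
  expect_true(all(r$retained$forced[r$retained$term == "age"]))
  r2 <- backwardsElimination(df, "y", "x")
  if (!nrow(r2$retained)) expect_equal(r2$eliminated$term, "x")
})

test_that("stepwise modeling localizes lobar signal and respects the VOI cap", {
  lobarMap <- list(frontal = paste0("f", 1:6), parietal = paste0("p", 1:4),
                   temporal = c("t1", "t2"), occipital = "o1")
  gen <- function(seed, beta) {
    set.seed(seed)
    n <- 250
    df <- as.data.frame(setNames(
      lapply(unlist(lobarMap), function(v) rnorm(n)), unlist(lobarMap)))
    df$age <- rnorm(n); df$sex <- rbinom(n, 1, 0.5)
    df$education <- rnorm(n); df$bpf_percent <- rnorm(n)
    df$y <- beta * df$t2 + rnorm(n, 0, sqrt(1 - beta^2))
    df
  }
  hits <- 0
  for (s in 1:20) {
    df <- gen(400 + s, 0.35)
    r <- stepwiseVOIAnalysis(df, "y", lobarMap)
    if ("temporal" %in% r$localizedLobes &&
        "t2" %in% r$retainedSubregions) hits <- hits + 1
  }
  expect_gte(hits, 14)
  # covariate-only signal retains no VOI
  df <- gen(999, 0)
  df$y <- 0.6 * df$bpf_percent + rnorm(250, 0, 0.8)
  r0 <- stepwiseVOIAnalysis(df, "y", lobarMap)
  expect_length(r0$retainedSubregions, 0)
  # more than six subregions per lobe is rejected
  bad <- c(lobarMap, list(huge = paste0("h", 1:7)))
  expect_error(stepwiseVOIAnalysis(df, "y", bad), "six")
})

test_that("partial regression residuals obey the Frisch-Waugh identity", {
  set.seed(3)
  n <- 150
  df <- data.frame(x = rnorm(n), age = rnorm(n), edu = rnorm(n))
  df$y <- -0.14 * df$x + 0.2 * df$age + rnorm(n, 0, 0.9)
  pr <- partialRegressionData(df, "y", "x", c("age", "edu"))
  expect_equal(attr(pr, "slope"), attr(pr, "joint_coefficient"),
               tolerance = 1e-10)
  # with no covariates the residuals are the centered variables
  pr0 <- partialRegressionData(df, "y", "x")
  expect_equal(pr0$x_resid, df$x - mean(df$x))
  expect_equal(pr0$y_resid, df$y - mean(df$y))
})
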