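# T1 tissue segmentation: localized four-Gaussian mixture fitting over
# overlapping cubic windows, posterior blending, and CSF compartment split.

# ---- 1D Gaussian mixture EM ------------------------------------------------

# Fit up to k Gaussian components to intensities x by EM. Deterministic:
# initialized from intensity quantiles (evenly re-spread if degenerate),
# log-space E-step, SD floored at a small fraction of the intensity range,
# vanishing components pruned. Returns list(mean, sd, weight, loglik, k).
emFitGaussians <- function(x, k = 4L, tol = 1e-6, maxit = 200L,
                           initQuantiles = c(0.05, 0.35, 0.65, 0.95)) {
  n <- length(x)
  rng <- range(x)
  span <- diff(rng)
  if (span <= 0)
    return(list(mean = rng[1], sd = 1e-6, weight = 1, loglik = NA_real_, k = 1L))
  sdFloor <- max(1e-8, 1e-3 * span)
  m <- as.numeric(quantile(x, initQuantiles[seq_len(k)], names = FALSE))
  if (any(diff(sort(m)) < 1e-6 * span))
    m <- seq(rng[1], rng[2], length.out = k)
  s <- rep(span / 4, k)
  w <- rep(1 / k, k)
  prev <- -Inf
  for (it in seq_len(maxit)) {
    logd <- vapply(seq_along(m), function(j)
      log(w[j]) + dnorm(x, m[j], s[j], log = TRUE), numeric(n))
    mx <- do.call(pmax, lapply(seq_along(m), function(j) logd[, j]))
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    keep <- nk / n > 1e-8
    if (!all(keep)) {          # prune vanished components and continue
      m <- m[keep]; s <- s[keep]; w <- w[keep]; nk <- nk[keep]
      resp <- resp[, keep, drop = FALSE]
      prev <- -Inf
      if (length(m) == 1L) {
        m <- mean(x); s <- max(sd(x), sdFloor); w <- 1
        break
      }
    }
    w <- nk / sum(nk)
    m <- colSums(resp * x) / nk
    s <- pmax(sqrt(colSums(resp * (outer(x, m, `-`))^2) / nk), sdFloor)
    if (is.finite(prev) && abs(ll - prev) <= tol * abs(prev)) break
    prev <- ll
  }
  o <- order(m)
  list(mean = m[o], sd = pmax(s, sdFloor)[o], weight = w[o],
       loglik = prev, k = length(m))
}

# Merge components whose means are closer than their pooled spread (or a
# small absolute fraction of the range): duplicated components fitted to one
# intensity population otherwise split a tissue class across two labels.
mergeCloseComponents <- function(fit, span) {
  m <- fit$mean; s <- fit$sd; w <- fit$weight
  repeat {
    if (length(m) == 1L) break
    gaps <- diff(m)
    lim <- pmax(1e-3 * span, (s[-length(s)] + s[-1]))
    j <- which(gaps < lim)
    if (!length(j)) break
    j <- j[which.min(gaps[j])]
    wj <- w[j] + w[j + 1]
    mj <- (w[j] * m[j] + w[j + 1] * m[j + 1]) / wj
    vj <- (w[j] * (s[j]^2 + m[j]^2) + w[j + 1] * (s[j + 1]^2 + m[j + 1]^2)) / wj - mj^2
    m <- c(m[seq_len(j - 1)], mj, m[-seq_len(j + 1)])
    s <- c(s[seq_len(j - 1)], sqrt(max(vj, 1e-16)), s[-seq_len(j + 1)])
    w <- c(w[seq_len(j - 1)], wj, w[-seq_len(j + 1)])
  }
  list(mean = m, sd = s, weight = w, k = length(m))
}

# Ascending-mean class semantics for the global model: with four distinct
# components the second is the CSF/GM partial-volume shoulder; with three,
# the plain CSF/GM/WM triplet; fewer cover degenerate scenes.
globalClassMap <- function(k) {
  switch(as.character(k),
         "4" = c("CSF", "partial", "GM", "WM"),
         "3" = c("CSF", "GM", "WM"),
         "2" = c("CSF", "WM"),
         "1" = "GM",
         stop("unsupported component count"))
}

#' Fit the localized four-Gaussian T1 intensity model
#'
#' Fits a four-component Gaussian mixture to T1 intensities globally over
#' the intracranial mask, then refits it inside overlapping cubic windows.
#' Windows with fewer in-mask voxels than `minVoxels` inherit the global
#' fit. Components that collapse onto one another (duplicated fits to a
#' single intensity population) are merged; window components are matched to
#' global tissue classes by nearest mean.
#'
#' @param t1 3D T1 array.
#' @param mask logical 3D array or [IntracranialMask-class].
#' @param windowSize cubic window edge, voxels (>= 8).
#' @param stride window spacing, voxels (default half the window: 50%
#'   overlap).
#' @param minVoxels smallest in-mask voxel count for a private window fit.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxit maximum EM iterations.
#' @param fitSubsample cap on voxels used per window fit (deterministic
#'   stride subsample); classification always uses every voxel.
#' @return a [GaussianFieldModel-class]
#' @export
fitLocalGaussians <- function(t1, mask, windowSize = 32L,
                              stride = windowSize %/% 2L, minVoxels = 500L,
                              tol = 1e-6, maxit = 200L, fitSubsample = 8000L) {
  if (is(mask, "IntracranialMask")) mask <- mask@mask
  if (!any(mask)) stop("mask is empty")
  if (windowSize < 8L) stop("window size must be at least 8 voxels per side")
  dims <- dim(t1)
  xg <- t1[mask]
  if (length(xg) > 30000L)
    xg <- xg[seq(1L, length(xg), length.out = 30000L)]
  span <- diff(range(xg))
  gfit <- mergeCloseComponents(emFitGaussians(xg, 4L, tol, maxit), span)
  gfit$classOf <- globalClassMap(gfit$k)

  starts <- function(d) {
    if (d <= windowSize) return(1L)
    unique(c(seq(1L, d - windowSize + 1L, by = stride), d - windowSize + 1L))
  }
  windows <- list()
  for (ox in starts(dims[1])) for (oy in starts(dims[2])) for (oz in starts(dims[3])) {
    xi <- ox:min(ox + windowSize - 1L, dims[1])
    yi <- oy:min(oy + windowSize - 1L, dims[2])
    zi <- oz:min(oz + windowSize - 1L, dims[3])
    sub <- mask[xi, yi, zi]
    nvox <- sum(sub)
    win <- list(origin = c(ox, oy, oz),
                size = c(length(xi), length(yi), length(zi)))
    if (nvox < minVoxels) {
      win$fit <- gfit
      win$fallback <- TRUE
    } else {
      xv <- t1[xi, yi, zi][sub]
      if (length(xv) > fitSubsample)
        xv <- xv[seq(1L, length(xv), length.out = fitSubsample)]
      f <- mergeCloseComponents(emFitGaussians(xv, 4L, tol, maxit), span)
      # match window components to global classes by nearest global mean
      f$classOf <- gfit$classOf[vapply(f$mean, function(mm)
        which.min(abs(gfit$mean - mm)), integer(1))]
      win$fit <- f
      win$fallback <- FALSE
    }
    windows[[length(windows) + 1L]] <- win
  }
  new("GaussianFieldModel", windows = windows, global = gfit,
      windowSize = as.integer(windowSize), stride = as.integer(stride),
      dims = as.integer(dims))
}

# Per-voxel CSF/GM/WM posterior matrix (n x 3) under one component fit.
# The partial-volume component's mass is reassigned per voxel to CSF or GM,
# whichever has higher posterior odds at that intensity (falling back to the
# global CSF/GM components when the window lacks one).
classPosteriors <- function(x, fit, globalFit) {
  n <- length(x)
  logd <- vapply(seq_len(fit$k), function(j)
    log(fit$weight[j]) + dnorm(x, fit$mean[j], fit$sd[j], log = TRUE),
    numeric(n))
  if (n == 1L) logd <- matrix(logd, nrow = 1L)
  mx <- do.call(pmax, lapply(seq_len(fit$k), function(j) logd[, j]))
  p <- exp(logd - mx)
  p <- p / rowSums(p)
  out <- matrix(0, n, 3, dimnames = list(NULL, c("CSF", "GM", "WM")))
  for (j in seq_len(fit$k)) {
    cl <- fit$classOf[j]
    if (cl %in% colnames(out)) out[, cl] <- out[, cl] + p[, j]
  }
  pj <- which(fit$classOf == "partial")
  if (length(pj)) {
    partialMass <- rowSums(p[, pj, drop = FALSE])
    refFor <- function(cl) {
      jj <- which(fit$classOf == cl)
      if (!length(jj)) jj <- which(globalFit$classOf == cl)
      f <- if (length(which(fit$classOf == cl))) fit else globalFit
      dnorm(x, f$mean[jj[1]], f$sd[jj[1]], log = TRUE)
    }
    toGM <- refFor("GM") >= refFor("CSF")
    out[, "GM"] <- out[, "GM"] + partialMass * toGM
    out[, "CSF"] <- out[, "CSF"] + partialMass * !toGM
  }
  out
}

#' Classify tissue from the fitted local Gaussian model
#'
#' Computes CSF/GM/WM posteriors per voxel within every window covering it,
#' blends them with trilinear (tent) weights centered on the windows, and
#' assigns the maximum-posterior class. CSF is labeled sulcal (code 1) until
#' [splitCSF()] separates the ventricular compartment.
#'
#' @param model a [GaussianFieldModel-class] fitted on the same grid.
#' @param t1 the T1 array used for fitting.
#' @param mask logical array or [IntracranialMask-class].
#' @param voxelSize numeric(3), mm.
#' @return a [TissueSegmentation-class]
#' @export
classifyTissue <- function(model, t1, mask, voxelSize) {
  if (is(mask, "IntracranialMask")) {
    voxelSize <- mask@voxelSize
    mask <- mask@mask
  }
  dims <- dim(t1)
  if (!identical(as.integer(dims), model@dims))
    stop("model was fitted on a different grid geometry")
  post <- array(0, c(dims, 3L))
  wsum <- array(0, dims)
  tent <- function(idx, origin, size) {
    c0 <- origin + (size - 1) / 2
    pmax(1 - abs(idx - c0) / (size / 2 + 0.5), 1e-3)
  }
  for (win in model@windows) {
    o <- win$origin; sz <- win$size
    xi <- o[1]:(o[1] + sz[1] - 1L)
    yi <- o[2]:(o[2] + sz[2] - 1L)
    zi <- o[3]:(o[3] + sz[3] - 1L)
    sub <- mask[xi, yi, zi]
    if (!any(sub)) next
    xv <- t1[xi, yi, zi][sub]
    cp <- classPosteriors(xv, win$fit, model@global)
    w3 <- outer(outer(tent(xi, o[1], sz[1]), tent(yi, o[2], sz[2])),
                tent(zi, o[3], sz[3]))
    wv <- w3[sub]
    ai <- arrayInd(which(sub), sz)
    gi <- cbind(xi[ai[, 1]], yi[ai[, 2]], zi[ai[, 3]])
    flat <- gi[, 1] + dims[1] * (gi[, 2] - 1L + dims[2] * (gi[, 3] - 1L))
    nvol <- prod(dims)
    for (cl in 1:3)
      post[flat + (cl - 1L) * nvol] <- post[flat + (cl - 1L) * nvol] + wv * cp[, cl]
    wsum[flat] <- wsum[flat] + wv
  }
  inm <- which(mask)
  uncovered <- inm[wsum[inm] == 0]
  if (length(uncovered)) {   # outside all windows: global fallback
    cp <- classPosteriors(t1[uncovered], model@global, model@global)
    nvol <- prod(dims)
    for (cl in 1:3) post[uncovered + (cl - 1L) * nvol] <- cp[, cl]
    wsum[uncovered] <- 1
  }
  nvol <- prod(dims)
  pm <- cbind(post[inm], post[inm + nvol], post[inm + 2L * nvol]) / wsum[inm]
  for (cl in 1:3) post[inm + (cl - 1L) * nvol] <- pm[, cl]
  cls <- max.col(pm, ties.method = "first")
  labels <- array(0L, dims)
  labels[inm] <- c(1L, 3L, 4L)[cls]   # CSF -> sCSF code until split
  new("TissueSegmentation", labels = labels, posteriors = post,
      voxelSize = voxelSize)
}

#' Split CSF into ventricular and sulcal compartments
#'
#' Ventricular CSF is the union of 26-connected CSF components containing a
#' supplied seed voxel; all remaining CSF is sulcal.
#'
#' @param tissue a [TissueSegmentation-class]
#' @param seeds integer matrix, one row per seed, 1-based voxel indices
#'   (e.g. `GroundTruth@ventricleSeeds` on phantoms). `NULL` labels all CSF
#'   sulcal with a warning.
#' @return the updated [TissueSegmentation-class]
#' @export
splitCSF <- function(tissue, seeds) {
  labels <- tissue@labels
  csf <- labels %in% c(1L, 2L)
  dim(csf) <- dim(labels)
  labels[csf] <- 1L
  if (is.null(seeds) || (is.matrix(seeds) && nrow(seeds) == 0)) {
    warning("no ventricle seeds supplied; all CSF labeled sulcal")
    tissue@labels <- labels
    return(tissue)
  }
  seeds <- matrix(as.integer(seeds), ncol = 3)
  comp <- labelComponents(csf, 26L)
  vcomp <- integer(0)
  for (r in seq_len(nrow(seeds))) {
    v <- comp[seeds[r, 1], seeds[r, 2], seeds[r, 3]]
    if (v == 0)
      stop(sprintf("seed (%d, %d, %d) is not in a CSF-labeled voxel",
                   seeds[r, 1], seeds[r, 2], seeds[r, 3]))
    vcomp <- union(vcomp, v)
  }
  labels[comp %in% vcomp] <- 2L
  tissue@labels <- labels
  tissue
}
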