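# Independent brute-force oracles, deliberately written without the
# package's C++ morphology or its elimination loop.

# Chebyshev dilation by repeated 26-neighborhood shifts in plain R.
oracleDilate <- function(mask, radius) {
  dims <- dim(mask)
  cur <- mask
  shift1 <- function(m, d) {
    out <- array(FALSE, dims)
    src <- lapply(seq_along(dims), function(a) {
      i <- seq_len(dims[a]) + d[a]
      i[i < 1 | i > dims[a]] <- NA
      i
    })
    xs <- which(!is.na(src[[1]])); ys <- which(!is.na(src[[2]]))
    zs <- which(!is.na(src[[3]]))
    out[xs, ys, zs] <- m[src[[1]][xs], src[[2]][ys], src[[3]][zs]]
    out
  }
  for (r in seq_len(radius)) {
    nxt <- cur
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nxt <- nxt | shift1(cur, c(dx, dy, dz))
    }
    cur <- nxt
  }
  cur
}

# BFS component labeling in plain R (26-connectivity), queue-based.
oracleLabel <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  ncomp <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] > 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ai <- arrayInd(v, dims)
      for (k in seq_len(nrow(nb))) {
        p <- ai + nb[k, ]
        if (any(p < 1) || any(p > dims)) next
        if (mask[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- ncomp
          queue <- c(queue, (p[3] - 1L) * dims[1] * dims[2] +
                       (p[2] - 1L) * dims[1] + p[1])
        }
      }
    }
  }
  lab
}

# Dilate-and-intersect periventricular classification oracle: label SH
# components by BFS, dilate the ventricular mask, call a component
# periventricular iff it intersects the dilated mask.
oraclePvDw <- function(shMask, vcsfMask, pvDistance) {
  lab <- oracleLabel(shMask)
  near <- if (any(vcsfMask)) oracleDilate(vcsfMask, pvDistance)
          else array(FALSE, dim(vcsfMask))
  n <- max(lab)
  out <- character(n)
  for (k in seq_len(n)) out[k] <- if (any(near[lab == k])) "pvSH" else "dwSH"
  list(labels = lab, classes = out)
}

# Explicit iterative-refit backwards-elimination oracle: plain lm() loop,
# z-scoring first, dropping the worst candidate (ties by smaller |beta|).
oracleBackwardsElimination <- function(data, outcome, candidates, forced,
                                       alpha = 0.05) {
  vars <- c(outcome, candidates, forced)
  data <- data[stats::complete.cases(data[, vars]), ]
  for (v in vars) data[[v]] <- as.numeric(scale(data[[v]]))
  pool <- candidates
  repeat {
    terms <- c(forced, pool)
    fml <- stats::reformulate(if (length(terms)) terms else "1",
                              response = outcome)
    fit <- stats::lm(fml, data = data)
    if (!length(pool)) break
    sm <- summary(fit)$coefficients
    pv <- sm[pool, "Pr(>|t|)", drop = TRUE]
    if (length(pool) == 1L) names(pv) <- pool
    if (max(pv) <= alpha) break
    worst <- names(pv)[pv >= max(pv) - 1e-12]
    if (length(worst) > 1L) {
      bv <- abs(sm[worst, "Estimate"])
      worst <- worst[which.min(bv)]
    }
    pool <- setdiff(pool, worst)
  }
  sort(pool)
}

# Dice coefficient computed independently of the package helper.
diceCoef2 <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Nested-loop region-by-class counting oracle.
oracleRegionalize <- function(labels, regions, classCodes) {
  out <- matrix(0L, nrow = 26, ncol = length(classCodes))
  for (v in which(labels > 0 & regions > 0)) {
    ci <- match(labels[v], classCodes)
    if (!is.na(ci)) out[regions[v], ci] <- out[regions[v], ci] + 1L
  }
  out
}
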