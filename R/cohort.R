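# Synthetic AD/NC cohort generation with configurable linear-Gaussian
# structure, for calibration and parameter-recovery studies.

#' Specification of a synthetic two-group cohort
#'
#' Base variables are drawn per group from Gaussian (or Bernoulli, for
#' binary variables) distributions; derived outcomes follow a linear model
#' on within-group z-scored predictors plus Gaussian noise, so planted
#' coefficients are standardized effect sizes.
#'
#' @param nPerGroup named integer, subjects per group, e.g.
#'   `c(AD = 265, NC = 100)`.
#' @param meanSD named list: for each base variable a 2 x nGroup matrix of
#'   means (row 1) and SDs (row 2) with group columns; SD `NA` with a mean
#'   in (0, 1) denotes a Bernoulli proportion (e.g. sex = proportion
#'   female). A `lognormal` attribute on a variable switches to a
#'   log-normal with the given median and IQR.
#' @param effectStructure data.frame with columns outcome, predictor, beta:
#'   linear generative relationships. Predictors must be base variables or
#'   previously defined outcomes.
#' @param noiseSD named numeric, residual SD per outcome (on the outcome's
#'   z scale when predictors are z-scored).
#' @param bounds named list of `c(lower, upper)` clamps (e.g. MMSE 0..30).
#' @param seed integer master seed.
#' @return list of class `CohortSpec`
#' @export
cohortSpec <- function(nPerGroup, meanSD, effectStructure = NULL,
                       noiseSD = numeric(), bounds = list(), seed = 1L) {
  stopifnot(all(nPerGroup > 0), length(names(nPerGroup)) == length(nPerGroup))
  for (v in names(meanSD)) {
    m <- meanSD[[v]]
    if (!is.matrix(m) || nrow(m) != 2)
      stop(sprintf("meanSD entry '%s' must be a 2 x nGroup matrix", v))
    sds <- m[2, ]
    if (any(!is.na(sds) & sds < 0)) stop("SDs must be nonnegative")
  }
  if (!is.null(effectStructure)) {
    stopifnot(all(c("outcome", "predictor", "beta") %in%
                    names(effectStructure)))
    known <- names(meanSD)
    for (i in seq_len(nrow(effectStructure))) {
      o <- effectStructure$outcome[i]
      p <- effectStructure$predictor[i]
      if (!p %in% known)
        stop(sprintf("effect structure references undefined variable '%s'", p))
      known <- union(known, o)
    }
  }
  structure(list(nPerGroup = nPerGroup, meanSD = meanSD,
                 effectStructure = effectStructure, noiseSD = noiseSD,
                 bounds = bounds, seed = as.integer(seed)),
            class = "CohortSpec")
}

# Solve a log-normal's (meanlog, sdlog) from a target median and IQR.
lognormalFromMedianIQR <- function(med, iqr) {
  mu <- log(med)
  f <- function(s) exp(mu + 0.6744898 * s) - exp(mu - 0.6744898 * s) - iqr
  s <- tryCatch(stats::uniroot(f, c(1e-6, 10))$root, error = function(e) 0.5)
  c(meanlog = mu, sdlog = s)
}

#' Default AD/NC cohort specification
#'
#' Two groups (AD n = 265, NC n = 100) with demographic, global volumetric
#' and cognitive-test distributions matching a typical dementia-clinic
#' case-control sample: AD older, less educated, lower MMSE, smaller
#' parenchymal fraction, larger CSF spaces, and right-skewed
#' hyperintensity/lacune loads (log-normal, matched on median and IQR).
#'
#' @param seed integer master seed
#' @return a `CohortSpec`
#' @export
defaultCohortSpec <- function(seed = 1L) {
  g <- function(adMean, adSD, ncMean, ncSD)
    matrix(c(adMean, adSD, ncMean, ncSD), nrow = 2,
           dimnames = list(c("mean", "sd"), c("AD", "NC")))
  ln <- function(adMed, adIQR, ncMed, ncIQR) {
    m <- g(adMed, adIQR, ncMed, ncIQR)
    attr(m, "lognormal") <- TRUE
    m
  }
  meanSD <- list(
    age = g(72.8, 9.0, 69.5, 8.0),
    sex = g(0.57, NA, 0.55, NA),          # proportion female
    education = g(13.8, 3.8, 15.5, 3.0),
    mmse = g(23.2, 4.5, 29.0, 1.1),
    st_tiv = g(1211.8, 140.1, 1227.7, 112.5),
    bpf_percent = g(73.1, 4.6, 79.0, 3.7),
    gm_cc = g(509.9, 55.7, 560.8, 45.0),
    wm_cc = g(363.6, 55.1, 403.1, 52.3),
    scsf_cc = g(274.8, 62.5, 224.2, 48.1),
    vcsf_cc = g(52.9, 27.1, 34.1, 16.2),
    sh_cc = ln(5.4, 11.0, 2.5, 3.3),
    pvsh_cc = ln(4.5, 9.9, 1.8, 3.0),
    dwsh_cc = ln(0.6, 1.1, 0.3, 0.6),
    lacune_mm3 = ln(32.8, 155.9, 10.3, 45.0),
    # raw cognitive battery (test-score scales; NC-referenced z-scores are
    # derived downstream)
    fas_total = g(27, 11, 40, 11),
    wcst_correct = g(55, 18, 70, 12),
    wcst_persev_response = g(28, 16, 14, 9),
    wcst_persev_category = g(18, 12, 8, 6),
    trails_a_seconds = g(78, 40, 38, 13),
    cvlt_total = g(25, 9, 45, 10),
    wms_visual_repro = g(18, 9, 32, 6),
    drs_memory = g(17, 4, 24, 1.2)
  )
  cohortSpec(nPerGroup = c(AD = 265L, NC = 100L), meanSD = meanSD,
             bounds = list(mmse = c(0, 30), education = c(0, 25),
                           drs_memory = c(0, 25)),
             seed = seed)
}

#' Generate a synthetic cohort table
#'
#' One row per subject: group label, base variables drawn from their group
#' distributions, then derived outcomes computed in declaration order as
#' `sum(beta * z(predictor)) + noise`, where `z()` standardizes with the
#' group's specified (not sample) mean and SD for base variables, and with
#' the realized group sample statistics for derived predictors.
#' Reproducible under the spec seed.
#'
#' @param spec a `CohortSpec`
#' @return data.frame with a `group` factor and one column per variable
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  groups <- names(spec$nPerGroup)
  withStream(spec$seed, "cohort", {
    rows <- lapply(groups, function(gname) {
      n <- spec$nPerGroup[[gname]]
      df <- data.frame(group = rep(gname, n), stringsAsFactors = FALSE)
      for (v in names(spec$meanSD)) {
        m <- spec$meanSD[[v]]
        mu <- m["mean", gname]; sdv <- m["sd", gname]
        if (isTRUE(attr(m, "lognormal"))) {
          p <- lognormalFromMedianIQR(mu, sdv)
          df[[v]] <- stats::rlnorm(n, p["meanlog"], p["sdlog"])
        } else if (is.na(sdv)) {
          df[[v]] <- rbinom(n, 1L, mu)
        } else {
          df[[v]] <- rnorm(n, mu, sdv)
        }
      }
      df
    })
    out <- do.call(rbind, rows)
    es <- spec$effectStructure
    if (!is.null(es) && nrow(es)) {
      for (o in unique(es$outcome)) {
        terms <- es[es$outcome == o, ]
        y <- numeric(nrow(out))
        for (gname in groups) {
          sel <- out$group == gname
          # intercept: the outcome's own group mean when one is specified
          contrib <- if (!is.null(spec$meanSD[[o]]))
            spec$meanSD[[o]]["mean", gname] else 0
          for (i in seq_len(nrow(terms))) {
            p <- terms$predictor[i]
            m <- spec$meanSD[[p]]
            if (!is.null(m) && !isTRUE(attr(m, "lognormal")) &&
                !is.na(m["sd", gname]) && m["sd", gname] > 0) {
              zp <- (out[[p]][sel] - m["mean", gname]) / m["sd", gname]
            } else {
              zp <- as.numeric(scale(out[[p]][sel]))
            }
            contrib <- contrib + terms$beta[i] * zp
          }
          nsd <- if (o %in% names(spec$noiseSD)) spec$noiseSD[[o]] else
            sqrt(max(1 - sum(terms$beta^2), 0.05))
          y[sel] <- contrib + rnorm(sum(sel), 0, nsd)
        }
        out[[o]] <- y
      }
    }
    for (v in names(spec$bounds)) {
      b <- spec$bounds[[v]]
      if (!is.null(out[[v]])) out[[v]] <- pmin(pmax(out[[v]], b[1]), b[2])
    }
    out$group <- factor(out$group, levels = groups)
    rownames(out) <- NULL
    out
  })
}
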