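# The statistical stage: cognitive composites, pooled-SD effect sizes,
# covariate-adjusted group contrasts, backwards-elimination regression and
# the lobar-then-subregion stepwise VOI strategy.

#' Default cognitive domain battery and score orientations
#'
#' Domains and measures of the standard battery: executive function (FAS
#' verbal fluency, WCST total correct, two WCST perseverative-error counts),
#' mental processing speed (Trail Making A completion time) and memory
#' (CVLT acquisition total, WMS-R immediate Visual Reproduction, DRS memory
#' subscore). Orientation -1 marks measures where a higher raw score is
#' worse (times, error counts); composites are oriented higher = better.
#'
#' @return list with `domains` (named list of test columns) and
#'   `orientation` (named numeric of +-1)
#' @export
defaultDomainMap <- function() {
  list(
    domains = list(
      executive = c("fas_total", "wcst_correct", "wcst_persev_response",
                    "wcst_persev_category"),
      speed = c("trails_a_seconds"),
      memory = c("cvlt_total", "wms_visual_repro", "drs_memory")
    ),
    orientation = c(fas_total = 1, wcst_correct = 1,
                    wcst_persev_response = -1, wcst_persev_category = -1,
                    trails_a_seconds = -1, cvlt_total = 1,
                    wms_visual_repro = 1, drs_memory = 1)
  )
}

#' Cognitive composite scores from raw test scores
#'
#' Each test is z-scored against the reference (normal-control) rows'
#' mean and SD, sign-flipped where a higher raw score means worse
#' performance, and averaged within domain over the subject's available
#' tests (at least one required; otherwise the composite is missing).
#'
#' @param data data.frame of raw test scores (one row per subject).
#' @param reference logical or integer index of the normal-control rows.
#' @param domainMap list as returned by [defaultDomainMap()].
#' @return data.frame of per-subject composites, one column per domain
#' @export
compositeScore <- function(data, reference, domainMap = defaultDomainMap()) {
  refIdx <- if (is.logical(reference)) which(reference) else reference
  if (!length(refIdx)) stop("reference subset is empty")
  orient <- domainMap$orientation
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (dom in names(domainMap$domains)) {
    tests <- domainMap$domains[[dom]]
    zs <- sapply(tests, function(tt) {
      x <- data[[tt]]
      if (is.null(x)) stop(sprintf("test column '%s' missing", tt))
      m <- mean(x[refIdx], na.rm = TRUE)
      s <- sd(x[refIdx], na.rm = TRUE)
      if (!is.finite(s) || s == 0)
        stop(sprintf("test '%s' has no reference variance", tt))
      o <- if (tt %in% names(orient)) orient[[tt]] else 1
      o * (x - m) / s
    })
    zs <- matrix(zs, nrow = nrow(data))
    out[[dom]] <- rowMeans(zs, na.rm = TRUE)
    out[[dom]][rowSums(!is.na(zs)) == 0] <- NA_real_
  }
  out
}

#' Cohen's d by the pooled standard deviation method
#'
#' `pooled_sd = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))`,
#' `d = (mean1 - mean2) / pooled_sd`. The magnitude `abs(d)` is what effect
#' size tables report.
#'
#' @param mean1,sd1,n1 first group summary statistics
#' @param mean2,sd2,n2 second group summary statistics
#' @return list of class `effectSize`: d, abs_d, pooled_sd, and the inputs
#' @export
cohensDPooled <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be nonnegative")
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (pooled == 0) stop("pooled SD is zero; effect size undefined")
  d <- (mean1 - mean2) / pooled
  structure(list(d = d, abs_d = abs(d), pooled_sd = pooled,
                 mean1 = mean1, sd1 = sd1, n1 = n1,
                 mean2 = mean2, sd2 = sd2, n2 = n2),
            class = "effectSize")
}

#' @export
print.effectSize <- function(x, ...) {
  cat(sprintf("Cohen's d (pooled SD): d = %.3f (|d| = %.2f), pooled SD = %.3f\n",
              x$d, x$abs_d, x$pooled_sd))
  invisible(x)
}

# Build a full-rank check and a fitted lm, with informative collinearity
# errors naming the offending columns.
fitCheckedLM <- function(data, outcome, predictors) {
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- lm(fml, data = data)
  al <- stats::alias(fit)$Complete
  if (!is.null(al))
    stop(sprintf("collinearity: columns {%s} are aliased",
                 paste(rownames(al), collapse = ", ")))
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop(sprintf("collinearity: columns {%s} are aliased",
                 paste(bad, collapse = ", ")))
  }
  fit
}

#' Covariate-adjusted group contrast (ANCOVA)
#'
#' Ordinary least squares of the outcome on a group indicator plus
#' covariates; reports the adjusted group coefficient with its t and F
#' statistics and p-value.
#'
#' @param data data.frame with a two-level `group` column.
#' @param outcome outcome column name.
#' @param covariates covariate column names (default age, sex, education).
#' @param group name of the group column.
#' @return list: estimate, se, t, F, p, n, fit
#' @export
ancovaGroupDifference <- function(data, outcome,
                                  covariates = c("age", "sex", "education"),
                                  group = "group") {
  g <- data[[group]]
  if (length(unique(g[!is.na(g)])) != 2)
    stop("group must have exactly two levels present")
  fit <- fitCheckedLM(data, outcome, c(group, covariates))
  sm <- summary(fit)
  rn <- rownames(sm$coefficients)
  gi <- grep(paste0("^", group), rn)[1]
  est <- sm$coefficients[gi, ]
  list(estimate = unname(est["Estimate"]), se = unname(est["Std. Error"]),
       t = unname(est["t value"]), F = unname(est["t value"]^2),
       p = unname(est["Pr(>|t|)"]), n = length(resid(fit)), fit = fit)
}

# z-score numeric columns in place (returns transformed copy).
standardizeColumns <- function(data, cols) {
  for (cc in cols) {
    x <- data[[cc]]
    if (is.factor(x)) x <- as.numeric(x) - 1
    s <- sd(x, na.rm = TRUE)
    data[[cc]] <- if (is.finite(s) && s > 0) (x - mean(x, na.rm = TRUE)) / s
                  else x - mean(x, na.rm = TRUE)
  }
  data
}

#' Linear regression with backwards elimination
#'
#' Iteratively refits OLS, removing the least significant candidate
#' predictor (highest p-value above `alpha`; ties broken by smaller
#' absolute coefficient) until every remaining candidate is significant.
#' Forced covariates are always kept in the model; by default they are not
#' eligible for elimination. Outcome and predictors are z-scored before
#' fitting so reported coefficients are standardized betas; per-predictor
#' R-squared is the squared partial correlation t^2 / (t^2 + df).
#'
#' @param data data.frame.
#' @param outcome outcome column.
#' @param candidates candidate predictor columns (eliminable).
#' @param forced covariate columns never eliminated.
#' @param alpha retention threshold on the candidate p-value.
#' @param eliminateForced if `TRUE` forced covariates join the candidate
#'   pool after the first pass.
#' @param standardize z-score outcome and predictors first (standardized
#'   betas).
#' @return list of class `regressionResult`: outcome, retained (data.frame
#'   term/beta/partial_r2/p), eliminated (term/order/p_at_removal), n,
#'   alpha, fit (final lm), trace (character log of steps)
#' @export
backwardsElimination <- function(data, outcome, candidates,
                                 forced = character(), alpha = 0.05,
                                 eliminateForced = FALSE,
                                 standardize = TRUE) {
  vars <- c(outcome, candidates, forced)
  data <- data[complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  n <- nrow(data)
  if (n <= length(candidates) + length(forced) + 1)
    stop("too few observations for the full model")
  if (standardize) data <- standardizeColumns(data, vars)
  pool <- candidates
  if (eliminateForced) { pool <- c(pool, forced); forced <- character() }
  eliminated <- data.frame(term = character(), order = integer(),
                           p_at_removal = numeric(), stringsAsFactors = FALSE)
  trace <- character()
  step <- 0L
  repeat {
    terms <- c(forced, pool)
    if (!length(terms)) {
      fit <- lm(stats::reformulate("1", response = outcome), data = data)
      trace <- c(trace, "final model: intercept only")
      break
    }
    fit <- fitCheckedLM(data, outcome, terms)
    sm <- summary(fit)$coefficients
    if (!length(pool)) break
    rows <- match(pool, rownames(sm))
    pv <- sm[rows, "Pr(>|t|)"]
    bv <- abs(sm[rows, "Estimate"])
    worst <- which(pv > alpha)
    if (!length(worst)) break
    pmax <- max(pv[worst])
    cand <- worst[pv[worst] >= pmax - 1e-12]
    drop <- cand[which.min(bv[cand])]
    step <- step + 1L
    eliminated <- rbind(eliminated, data.frame(
      term = pool[drop], order = step, p_at_removal = pv[drop],
      stringsAsFactors = FALSE))
    trace <- c(trace, sprintf("step %d: removed %s (p = %.4g)", step,
                              pool[drop], pv[drop]))
    pool <- pool[-drop]
  }
  sm <- summary(fit)$coefficients
  dfres <- fit$df.residual
  keepTerms <- c(forced, pool)
  retained <- if (length(keepTerms)) {
    rows <- match(keepTerms, rownames(sm))
    data.frame(term = keepTerms,
               beta = sm[rows, "Estimate"],
               partial_r2 = sm[rows, "t value"]^2 /
                 (sm[rows, "t value"]^2 + dfres),
               p = sm[rows, "Pr(>|t|)"],
               forced = keepTerms %in% forced,
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(term = character(), beta = numeric(),
                    partial_r2 = numeric(), p = numeric(),
                    forced = logical())
  structure(list(outcome = outcome, retained = retained,
                 eliminated = eliminated, n = n, alpha = alpha, fit = fit,
                 trace = trace),
            class = "regressionResult")
}

#' @export
print.regressionResult <- function(x, ...) {
  cat(sprintf("Backwards elimination for '%s' (n = %d, alpha = %.2g)\n",
              x$outcome, x$n, x$alpha))
  if (nrow(x$retained)) {
    cat("Retained:\n")
    print(transform(x$retained, beta = round(beta, 3),
                    partial_r2 = round(partial_r2, 3),
                    p = signif(p, 3)), row.names = FALSE)
  } else cat("No predictors retained (intercept-only model)\n")
  if (nrow(x$eliminated))
    cat("Eliminated (in order):",
        paste(x$eliminated$term, collapse = ", "), "\n")
  invisible(x)
}

#' Stepwise lobar-then-subregion VOI analysis
#'
#' Stage 1 aggregates regional lesion z-scores into four lobar sums
#' (frontal, parietal, temporal, occipital) and runs backwards elimination
#' with the forced covariates. For each lobe retained at `p <= alpha`,
#' stage 2 runs backwards elimination on that lobe's subregions (at most
#' six per model) plus covariates. Returns the stage-2 result(s), or the
#' stage-1 result when no lobe localizes.
#'
#' @param data data.frame with subregion z-score columns and covariates.
#' @param outcome outcome column.
#' @param lobarMap named list: lobe name -> character vector of its
#'   subregion columns.
#' @param covariates forced covariate columns.
#' @param alpha elimination threshold.
#' @return list of class `stepwiseVOIResult`: stage1 (regressionResult),
#'   stage2 (named list of regressionResult per localized lobe),
#'   localizedLobes, retainedSubregions
#' @export
stepwiseVOIAnalysis <- function(data, outcome, lobarMap,
                                covariates = c("age", "sex", "education",
                                               "bpf_percent"),
                                alpha = 0.05) {
  for (lobe in names(lobarMap))
    if (length(lobarMap[[lobe]]) > 6)
      stop(sprintf("lobe '%s' has more than six subregion VOIs", lobe))
  lobeCols <- paste0("lobar_", names(lobarMap))
  for (i in seq_along(lobarMap)) {
    cols <- lobarMap[[i]]
    data[[lobeCols[i]]] <- rowSums(data[, cols, drop = FALSE])
  }
  stage1 <- backwardsElimination(data, outcome, candidates = lobeCols,
                                 forced = covariates, alpha = alpha)
  kept <- stage1$retained
  keptLobes <- sub("^lobar_", "",
                   kept$term[!kept$forced & kept$p <= alpha])
  stage2 <- list()
  for (lobe in keptLobes) {
    stage2[[lobe]] <- backwardsElimination(
      data, outcome, candidates = lobarMap[[lobe]], forced = covariates,
      alpha = alpha)
  }
  retainedSub <- unlist(lapply(stage2, function(r)
    r$retained$term[!r$retained$forced]), use.names = FALSE)
  structure(list(stage1 = stage1, stage2 = stage2,
                 localizedLobes = keptLobes,
                 retainedSubregions = retainedSub),
            class = "stepwiseVOIResult")
}

#' Paired residual series for a partial regression plot
#'
#' Residuals of the outcome on the covariates against residuals of the
#' focal predictor on the covariates. By the Frisch-Waugh-Lovell identity
#' the OLS slope of the residual series equals the focal coefficient in the
#' joint model, which is returned alongside for verification.
#'
#' @param data data.frame.
#' @param outcome,focal,covariates column names.
#' @return data.frame (x_resid, y_resid) with attributes `slope` (residual
#'   regression) and `joint_coefficient` (focal coefficient in the joint
#'   fit)
#' @export
partialRegressionData <- function(data, outcome, focal,
                                  covariates = character()) {
  vars <- c(outcome, focal, covariates)
  data <- data[complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  if (length(covariates)) {
    ry <- resid(fitCheckedLM(data, outcome, covariates))
    rx <- resid(fitCheckedLM(data, focal, covariates))
  } else {
    ry <- data[[outcome]] - mean(data[[outcome]])
    rx <- data[[focal]] - mean(data[[focal]])
  }
  slope <- sum(rx * ry) / sum(rx^2)
  joint <- coef(fitCheckedLM(data, outcome, c(focal, covariates)))[[focal]]
  out <- data.frame(x_resid = rx, y_resid = ry)
  attr(out, "slope") <- slope
  attr(out, "joint_coefficient") <- joint
  out
}
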