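# Per-subject volumetric profiles: class volumes per VOI, ST-TIV, BPF,
# head-size normalization and reference z-scores.

#' Combine tissue and lesion segmentations into one label map
#'
#' Lesion labels override tissue labels (the PD/T2 stage corrects the
#' T1-only segmentation where hyperintensities are isointense to normal
#' tissue on T1). Codes follow [phantomClasses()].
#'
#' @param tissue a [TissueSegmentation-class]
#' @param lesions a [LesionSegmentation-class]
#' @return integer 3D array
#' @export
combinedLabelMap <- function(tissue, lesions) {
  labels <- tissue@labels          # 1 sCSF, 2 vCSF, 3 GM, 4 WM
  les <- lesions@labels            # 1 pvSH, 2 dwSH, 3 lacune
  labels[les == 1L] <- 5L
  labels[les == 2L] <- 6L
  labels[les == 3L] <- 7L
  labels
}

#' Assemble a per-subject volumetric profile
#'
#' Every cell is a voxel count times the voxel volume. BPF is
#' 100 * (GM + WM) / ST-TIV; the ventricular-atrophy ratio is
#' vCSF / ST-TIV. Regional volumes are additive: a lesion splitting across
#' regions contributes each voxel to the region containing it.
#'
#' @param tissue a [TissueSegmentation-class] (after [splitCSF()])
#' @param lesions a [LesionSegmentation-class]
#' @param atlas a [VOIAtlas-class]
#' @param stTIVcc supratentorial total intracranial volume, cc (from
#'   [computeSTTIV()]); must be positive.
#' @param subject subject identifier.
#' @return a [VolumetricProfile-class]
#' @export
computeProfile <- function(tissue, lesions, atlas, stTIVcc,
                           subject = "subject") {
  if (stTIVcc <= 0) stop("ST-TIV must be positive")
  labels <- combinedLabelMap(tissue, lesions)
  if (!identical(dim(labels), dim(atlas@regions)))
    stop("geometry mismatch between segmentations and atlas")
  vv <- voxelVolumeCC(tissue@voxelSize)
  K <- phantomClasses()
  counts <- tabulate(labels + 1L, nbins = 8L)[-1L]
  whole <- counts * vv
  names(whole) <- names(K)
  whole <- c(whole, SH = unname(whole[["pvSH"]] + whole[["dwSH"]] +
                                  whole[["lacune"]]))
  regCounts <- regionalize(labels, atlas, classNames = K)
  regional <- data.frame(
    region = rep(rownames(regCounts), times = ncol(regCounts)),
    class = rep(colnames(regCounts), each = nrow(regCounts)),
    raw_cc = as.vector(regCounts) * vv,
    stringsAsFactors = FALSE)
  sh <- regional[regional$class %in% c("pvSH", "dwSH", "lacune"), ]
  shAgg <- tapply(sh$raw_cc, sh$region, sum)
  regional <- rbind(regional, data.frame(
    region = names(shAgg), class = "SH", raw_cc = as.numeric(shAgg),
    stringsAsFactors = FALSE))
  bpfPct <- 100 * (whole[["GM"]] + whole[["WM"]]) / stTIVcc
  new("VolumetricProfile", subject = subject, stTIV = stTIVcc,
      bpf = bpfPct, vcsfRatio = whole[["vCSF"]] / stTIVcc,
      wholeBrain = whole, regional = regional)
}

#' Flatten profiles into a tidy per-subject table
#'
#' @param profiles list of [VolumetricProfile-class]
#' @return data.frame: subject, region ("whole brain" included), class,
#'   raw_cc, plus st_tiv, bpf_percent and vcsf_ratio repeated per subject
#' @export
profileTable <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    reg <- p@regional
    whole <- data.frame(region = "whole brain", class = names(p@wholeBrain),
                        raw_cc = as.numeric(p@wholeBrain),
                        stringsAsFactors = FALSE)
    out <- rbind(whole, reg)
    out$subject <- p@subject
    out$st_tiv <- p@stTIV
    out$bpf_percent <- p@bpf
    out$vcsf_ratio <- p@vcsfRatio
    out[, c("subject", "region", "class", "raw_cc", "st_tiv", "bpf_percent",
            "vcsf_ratio")]
  })
  do.call(rbind, rows)
}

#' Head-size normalization and reference z-scoring of volumetric variables
#'
#' Each variable is first divided by the subject's ST-TIV (proportion of
#' head size), then, if its reference-sample skewness exceeds
#' `skewThreshold`, log-transformed as `log(value + offset)` with offset the
#' smallest positive observed value (this keeps zero lesion loads, common
#' for lacunes, in the sample); finally converted to a z-score against the
#' reference subset's mean and SD.
#'
#' @param data data.frame with one row per subject, containing `st_tiv` and
#'   the columns named in `variables`.
#' @param variables character, volumetric columns to normalize.
#' @param reference logical or integer index of reference rows (typically
#'   the normal-control group); must be nonempty.
#' @param skewThreshold sample-skewness cutoff triggering the log branch.
#' @param normalize if `FALSE` variables are assumed already head-size
#'   corrected.
#' @return list: `data` (input plus `<var>_z` columns), `log` (data.frame
#'   per variable: skewness before/after, whether log was applied, offset,
#'   reference mean/sd)
#' @export
normalizeAndZscore <- function(data, variables, reference,
                               skewThreshold = 1, normalize = TRUE) {
  refIdx <- if (is.logical(reference)) which(reference) else reference
  if (!length(refIdx)) stop("reference subset is empty")
  logRows <- list()
  for (v in variables) {
    x <- data[[v]]
    if (is.null(x)) stop(sprintf("variable '%s' not found", v))
    if (normalize) x <- x / data$st_tiv
    skewBefore <- sampleSkewness(x[refIdx])
    useLog <- is.finite(skewBefore) && skewBefore > skewThreshold
    offset <- NA_real_
    if (useLog) {
      pos <- x[x > 0]
      offset <- if (length(pos)) min(pos) else 1
      x <- log(x + offset)
    }
    skewAfter <- sampleSkewness(x[refIdx])
    m <- mean(x[refIdx]); s <- sd(x[refIdx])
    if (!is.finite(s) || s == 0) {
      warning(sprintf("variable '%s' has zero reference variance; z undefined", v))
      data[[paste0(v, "_z")]] <- NA_real_
    } else {
      data[[paste0(v, "_z")]] <- (x - m) / s
    }
    logRows[[v]] <- data.frame(variable = v, skew_before = skewBefore,
                               log_applied = useLog, offset = offset,
                               skew_after = skewAfter, ref_mean = m,
                               ref_sd = s, stringsAsFactors = FALSE)
  }
  list(data = data, log = do.call(rbind, logRows))
}
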