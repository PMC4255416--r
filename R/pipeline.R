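#' Run the full phantom segmentation pipeline
#'
#' Phantom synthesis, brain extraction, localized-Gaussian tissue
#' segmentation, CSF compartment split, PD/T2 hyperintensity detection with
#' the periventricular/deep-white connectivity split, lacune extraction,
#' geometric 26-region parcellation and volumetric profiling — the same
#' stages a clinical tri-feature lesion pipeline chains, run end to end on
#' synthetic ground truth. Ventricle seeds come from the phantom's ground
#' truth.
#'
#' @param spec a `PhantomSpec`
#' @param subject subject id recorded in the profile
#' @param params an `SHDetectionParams` list
#' @param landmarks an `AtlasLandmarks` configuration
#' @return list: phantom, mask, tissue, lesions, atlas, profile, labels
#'   (combined predicted label map)
#' @export
runPhantomPipeline <- function(spec, subject = "phantom",
                               params = shDetectionParams(),
                               landmarks = atlasLandmarks()) {
  phantom <- generatePhantom(spec)
  vol <- phantom$volume
  mask <- extractBrain(vol)
  model <- fitLocalGaussians(vol@t1, mask)
  tissue <- classifyTissue(model, vol@t1, mask)
  tissue <- splitCSF(tissue, phantom$truth@ventricleSeeds)
  shMask <- segmentSH(vol@pd, vol@t2, tissue, mask, params, t1 = vol@t1)
  vcsf <- tissue@labels == 2L
  dim(vcsf) <- dim(tissue@labels)
  lesions <- classifyPvDw(shMask, vcsf, vol@voxelSize, params)
  lesions <- extractLacunes(lesions, vol@t1, tissue)
  atlas <- buildAtlas(mask, landmarks = landmarks)
  profile <- computeProfile(tissue, lesions, atlas, stTIV(mask),
                            subject = subject)
  list(phantom = phantom, mask = mask, model = model, tissue = tissue,
       lesions = lesions, atlas = atlas, profile = profile,
       labels = combinedLabelMap(tissue, lesions))
}

#' Write pipeline outputs as CSV
#'
#' Writes the tidy volumetric profile (`profiles.csv`) and the lesion
#' component table (`components.csv`); numbers are formatted with full
#' precision so identical runs produce byte-identical files.
#'
#' @param result list from [runPhantomPipeline()]
#' @param dir output directory (created if absent)
#' @return character vector of the two paths, invisibly
#' @export
writePipelineOutputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pf <- file.path(dir, "profiles.csv")
  cf <- file.path(dir, "components.csv")
  write.csv(profileTable(list(result$profile)), pf, row.names = FALSE)
  write.csv(componentTable(result$lesions), cf, row.names = FALSE)
  invisible(c(pf, cf))
}

#' Per-class Dice agreement with phantom ground truth
#'
#' @param labels predicted combined label array (see [combinedLabelMap()])
#' @param truth a [GroundTruth-class]
#' @return named numeric of Dice coefficients per class present in truth
#' @export
diceByClass <- function(labels, truth) {
  K <- phantomClasses()
  present <- K[tabulate(truth@labels + 1L, nbins = 8L)[-1L] > 0]
  vapply(present, function(code)
    diceCoefficient(labels == code, truth@labels == code), numeric(1))
}
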