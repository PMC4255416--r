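# Shared fixtures: a compact phantom for unit tests and a lazily computed,
# cached pipeline run so several test files can share one segmentation.

smallPhantomSpec <- function(noiseSD = 0, seed = 1L,
                             pvLesions = list(
                               list(volume_cc = 2.0, ventricle = 1L,
                                    direction = c(1, -0.3, 0.2))),
                             dwLesions = list(
                               list(volume_cc = 0.5, center = c(26, -14, 4))),
                             lacunes = list(
                               list(parent = 1L, volume_cc = 0.06))) {
  phantomSpec(gridShape = c(48L, 56L, 44L), voxelSize = c(2.5, 2.5, 2.5),
              brainSemiaxes = c(52, 62, 46), csfShell = 4, gmThickness = 5,
              ventricleSemiaxes = c(7, 18, 8), ventricleOffset = c(11, 5, 5),
              pvLesions = pvLesions, dwLesions = dwLesions,
              lacunes = lacunes, noiseSD = noiseSD, seed = seed)
}

# Lean lesion-free phantom for multi-seed tissue-classification studies.
tinyPhantomSpec <- function(noiseSD = 0, seed = 1L) {
  phantomSpec(gridShape = c(40L, 48L, 36L), voxelSize = c(3, 3, 3),
              brainSemiaxes = c(52, 64, 46), csfShell = 4, gmThickness = 6,
              ventricleSemiaxes = c(7, 16, 8), ventricleOffset = c(11, 5, 4),
              pvLesions = list(), dwLesions = list(), lacunes = list(),
              noiseSD = noiseSD, seed = seed)
}

.pipelineCache <- new.env(parent = emptyenv())

cachedPipeline <- function(key, spec) {
  if (!exists(key, envir = .pipelineCache))
    assign(key, runPhantomPipeline(spec), envir = .pipelineCache)
  get(key, envir = .pipelineCache)
}

# Zero-noise run of the small phantom, shared across test files.
smallZeroNoiseRun <- function() cachedPipeline("small0", smallPhantomSpec())
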