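# Shared test-scale study condition: 20 components allocated to the 7
# networks in proportion to the 53-component layout, default affected
# blocks (CC-DM for subtype 1; SM-VI and VI-CB for subtype 2), 200
# controls + 400 patients, per-edge effect 0.8 against noise SD 0.1.

tstPartition <- function() scaledPartition(20)

tstSpec <- function(seed, effectSize = 0.8, noiseSd = 0.1,
                    nHC = 200L, nPatients = 400L) {
  cohortSpec(nHC = nHC, nPatients = nPatients, partition = tstPartition(),
             effectSize = effectSize, noiseSd = noiseSd, seed = seed)
}

tstConfig <- function(seed, ...) {
  trainingConfig(hiddenDim = 64L, embeddingDim = 16L,
                 pretrainEpochs = 100L, jointEpochs = 100L, seed = seed, ...)
}

tstTruth <- function(cohort) {
  st <- subjectTable(cohort)
  st$trueSubtype[st$diagnosis == "patient"]
}

# small cohorts for cheap unit tests
tinySpec <- function(seed, nHC = 30L, nPatients = 60L, ...) {
  tstSpec(seed, nHC = nHC, nPatients = nPatients, ...)
}
tinyConfig <- function(seed, hiddenDim = 16L, embeddingDim = 4L,
                       pretrainEpochs = 15L, jointEpochs = 15L, ...) {
  trainingConfig(hiddenDim = hiddenDim, embeddingDim = embeddingDim,
                 pretrainEpochs = pretrainEpochs, jointEpochs = jointEpochs,
                 seed = seed, ...)
}

# reference trained models at the test-scale condition, shared across
# test files (5 cohort seeds x 5 training seeds)
.tstCache <- new.env(parent = emptyenv())

tstModelSet <- function() {
  if (!is.null(.tstCache$models)) return(.tstCache$models)
  .tstCache$models <- lapply(1:5, function(s) {
    co <- generateCohort(tstSpec(100 + s))
    g <- cohortGraph(co)
    list(cohort = co, graph = g, truth = tstTruth(co),
         model = trainBiotypeModel(g, tstConfig(s)))
  })
  .tstCache$models
}

# best label-permutation accuracy for two-cluster assignments
matchAccuracy <- function(labels, truth) {
  max(mean(labels == truth), mean(labels == (3 - truth)))
}
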