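# small fixture builders shared across test files

smallCounts <- function(shared = 10L, aOnly = 5L, bOnly = 5L, null = 40L,
                        sexLinked = 10L) {
  c(shared_age = shared, tissueA_only = aOnly, tissueB_only = bOnly,
    null = null, sex_linked = sexLinked)
}

smallStudy <- function(seed = 1, n = 60, noiseSd = 0.005, batchSd = 0.01,
                       counts = smallCounts(), ...) {
  generateCohort(simulationConfig(nSubjects = n, seed = seed,
                                  noiseSd = noiseSd, batchSd = batchSd,
                                  cpgCounts = counts, ...))
}

# paired-tissue config for slope-recovery scenarios: shared CpGs only, a
# configurable B/A effect ratio and tissue-A baseline deficit
rateScenarioConfig <- function(seed, k = 2, deltaA = 0, n = 400,
                               noiseSd = 0.005, nShared = 201L) {
  cfg <- simulationConfig(
    nSubjects = n, seed = seed, noiseSd = noiseSd, batchSd = 0,
    cpgCounts = c(shared_age = nShared, tissueA_only = 0L,
                  tissueB_only = 0L, null = 100L, sex_linked = 0L))
  cfg@effectModel$effectRatio <- k
  cfg@baselineModel$deltaA <- deltaA
  cfg
}

sharedTruthSet <- function(study) {
  tr <- simTruth(study)
  rownames(tr)[tr$class == "shared_age"]
}

# deterministic beta matrix with named dims for unit fixtures
namedMatrix <- function(values, nr, nc) {
  matrix(values, nr, nc,
         dimnames = list(sprintf("cg%03d", seq_len(nr)),
                         sprintf("s%02d", seq_len(nc))))
}

table1Path <- function() {
  system.file("extdata", "cohort_table1.tsv", package = "methylRate")
}
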