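#' SimulationConfig: parameters of the paired-tissue cohort generator
#'
#' Describes the statistical structure of a simulated two-tissue methylation
#' cohort: subject ages, dataset batches, per-class CpG counts, effect-size
#' and baseline models, and noise levels. Defaults emulate the study design
#' the analysis is built for: two brain tissues measured on the same elderly
#' subjects (truncated-normal ages, mean 80, sd 10, range 15-114), six
#' dataset batches of unequal size, a small mostly methylation-gaining
#' island/shore-enriched set of CpGs age-associated in both tissues with
#' smaller effects and lower island/shore baselines in tissue A, larger
#' tissue-specific sets, a null majority, and sex-linked probes.
#'
#' @name SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nSubjects = "integer", nDatasets = "integer",
                 datasetWeights = "numeric", ageModel = "list",
                 cpgCounts = "integer", effectModel = "list",
                 baselineModel = "list", noiseSd = "numeric",
                 batchSd = "numeric", diseaseEffect = "numeric",
                 diseaseCpgFraction = "numeric", pDisease = "numeric",
                 pFemale = "numeric", crosshybFraction = "numeric",
                 tissueLabels = "character", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@nDatasets < 1L) msg <- c(msg, "nDatasets must be >= 1")
  if (length(object@datasetWeights) != object@nDatasets ||
      any(object@datasetWeights <= 0))
    msg <- c(msg, "datasetWeights must be positive, one per dataset")
  am <- object@ageModel
  if (!am$name %in% c("uniform", "truncated-normal"))
    msg <- c(msg, "age model must be 'uniform' or 'truncated-normal'")
  if (am$min <= 0 || am$max <= am$min)
    msg <- c(msg, "age range must satisfy 0 < min < max")
  cc <- object@cpgCounts
  if (!all(c("shared_age", "tissueA_only", "tissueB_only", "null",
             "sex_linked") %in% names(cc)))
    msg <- c(msg, "cpgCounts must name shared_age, tissueA_only, tissueB_only, null, sex_linked")
  if (any(cc < 0L)) msg <- c(msg, "all CpG counts must be >= 0")
  if (sum(cc) < 1L) msg <- c(msg, "at least one CpG is required")
  if (object@noiseSd < 0 || object@noiseSd >= 0.5)
    msg <- c(msg, "noiseSd must satisfy 0 <= noiseSd < 0.5")
  if (object@effectModel$effectRatio <= 0)
    msg <- c(msg, "effect ratio k must be > 0")
  if (object@batchSd < 0) msg <- c(msg, "batchSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param nSubjects number of subjects (each measured in both tissues);
#'   default 404.
#' @param nDatasets number of dataset batches; default 6.
#' @param datasetWeights relative dataset sizes (default mirrors a six-cohort
#'   collection dominated by one large dataset).
#' @param ageModel list with `name` (`"truncated-normal"` or `"uniform"`),
#'   `min`, `max`, `mean`, `sd`. Default truncated-normal mean 80, sd 10 on
#'   \[15, 114\] (an elderly-skewed postmortem cohort).
#' @param cpgCounts named integer vector of CpG counts per class:
#'   `shared_age` (age-associated in both tissues), `tissueA_only`,
#'   `tissueB_only`, `null`, `sex_linked`.
#' @param effectModel list: `magRange` (per-year slope magnitude range, beta
#'   units/year), `fracPositive` (named per class), `effectRatio` k with
#'   tissue-B slope = k x tissue-A slope for shared CpGs, `constantRatio`.
#' @param baselineModel list: `ranges` (per genomic category baseline beta
#'   range), `deltaA` (tissue-A island/shore baseline deficit),
#'   `categoryProbs` (category mix for the shared class and for all others).
#' @param noiseSd residual Gaussian sd on the beta scale.
#' @param batchSd sd of per-CpG dataset-level additive offsets.
#' @param diseaseEffect additive beta shift in diseased subjects on a
#'   designated CpG subset (default 0).
#' @param diseaseCpgFraction fraction of null CpGs carrying the disease shift.
#' @param pDisease probability a subject carries the disease label.
#' @param pFemale probability a subject is female.
#' @param crosshybFraction fraction of null CpGs flagged cross-hybridizing.
#' @param tissueLabels character(2) tissue labels.
#' @param seed integer seed (mandatory; the generator is a pure function of
#'   the configuration including this seed).
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nSubjects = 40, seed = 1,
#'                         cpgCounts = c(shared_age = 20, tissueA_only = 10,
#'                                       tissueB_only = 10, null = 50,
#'                                       sex_linked = 10))
#' @export
simulationConfig <- function(
    nSubjects = 404,
    nDatasets = 6,
    datasetWeights = c(404, 111, 95, 66, 44, 32)[seq_len(nDatasets)],
    ageModel = list(name = "truncated-normal", min = 15, max = 114,
                    mean = 80, sd = 10),
    cpgCounts = c(shared_age = 201L, tissueA_only = 412L,
                  tissueB_only = 4012L, null = 5000L, sex_linked = 200L),
    effectModel = list(magRange = c(5e-4, 2.5e-3),
                       fracPositive = c(shared_age = 0.94,
                                        tissueA_only = 0.5,
                                        tissueB_only = 0.76),
                       effectRatio = 2, constantRatio = TRUE),
    baselineModel = list(
      ranges = list(island = c(0.05, 0.20), shore = c(0.15, 0.40),
                    shelf = c(0.60, 0.90), open_sea = c(0.65, 0.90)),
      deltaA = 0.05,
      categoryProbs = list(
        shared = c(island = 0.70, shore = 0.24, shelf = 0.02, open_sea = 0.04),
        other = c(island = 0.30, shore = 0.23, shelf = 0.10, open_sea = 0.37))),
    noiseSd = 0.02, batchSd = 0.01,
    diseaseEffect = 0, diseaseCpgFraction = 0.05,
    pDisease = 225 / 404, pFemale = 200 / 404,
    crosshybFraction = 0.01,
    tissueLabels = c("CBL", "MTG"), seed) {
  .stopIf(missing(seed), "a seed is mandatory in the simulation config")
  if (is.na(datasetWeights[1]) || length(datasetWeights) != nDatasets)
    datasetWeights <- rep(1, nDatasets)
  cc <- cpgCounts
  storage.mode(cc) <- "integer"
  new("SimulationConfig", nSubjects = as.integer(nSubjects),
      nDatasets = as.integer(nDatasets), datasetWeights = datasetWeights,
      ageModel = ageModel, cpgCounts = cc, effectModel = effectModel,
      baselineModel = baselineModel, noiseSd = noiseSd, batchSd = batchSd,
      diseaseEffect = diseaseEffect, diseaseCpgFraction = diseaseCpgFraction,
      pDisease = pDisease, pFemale = pFemale,
      crosshybFraction = crosshybFraction, tissueLabels = tissueLabels,
      seed = as.integer(seed))
}

.sampleAges <- function(n, am) {
  if (am$name == "uniform") return(stats::runif(n, am$min, am$max))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, am$mean, am$sd)
    out <- c(out, draw[draw >= am$min & draw <= am$max])
  }
  out[seq_len(n)]
}

#' Generate a paired-tissue methylation cohort with ground truth
#'
#' Simulates beta values for two tissues measured on the same subjects as
#' `beta = clip(baseline + slope * age + batch + disease + sex term + noise,
#' 0, 1)`. Per-CpG true slopes, baselines, classes and genomic categories are
#' returned as ground truth. Baselines are drawn once per CpG (tissue B) and
#' tissue A receives a configurable island/shore deficit; baselines are then
#' nudged, per tissue, into the feasible band so that the linear trend does
#' not systematically clip over the age range (slopes are never altered, so
#' effect-ratio oracles remain exact). A warning is raised if more than 5% of
#' generated values were clipped.
#'
#' @param config a [SimulationConfig-class] from [simulationConfig()].
#' @return A [PairedTissueStudy-class] with `simTruth()` attached.
#' @examples
#' study <- generateCohort(simulationConfig(
#'   nSubjects = 30, seed = 7,
#'   cpgCounts = c(shared_age = 10, tissueA_only = 5, tissueB_only = 5,
#'                 null = 30, sex_linked = 5)))
#' study
#' @export
generateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nSubjects
  cc <- config@cpgCounts
  nCpg <- sum(cc)
  .stopIf(n < 1L || nCpg < 1L, "invalid config: zero subjects or zero CpGs")

  ## subjects
  nd <- config@nDatasets
  w <- config@datasetWeights
  sizes <- diff(round(cumsum(c(0, w)) / sum(w) * n))
  sizes[nd] <- n - sum(sizes[-nd])
  dataset <- rep(sprintf("ds%d", seq_len(nd)), times = sizes)
  age <- .sampleAges(n, config@ageModel)
  sex <- ifelse(stats::runif(n) < config@pFemale, "F", "M")
  disease <- ifelse(stats::runif(n) < config@pDisease, "case", "control")
  sid <- sprintf("S%04d", seq_len(n))

  ## CpG panel
  classes <- rep(names(cc), times = cc)
  cpg <- sprintf("cg%06d", seq_len(nCpg))
  cats <- character(nCpg)
  catNames <- c("island", "shore", "shelf", "open_sea")
  pShared <- config@baselineModel$categoryProbs$shared[catNames]
  pOther <- config@baselineModel$categoryProbs$other[catNames]
  isShared <- classes == "shared_age"
  cats[isShared] <- sample(catNames, sum(isShared), TRUE, prob = pShared)
  cats[!isShared] <- sample(catNames, sum(!isShared), TRUE, prob = pOther)
  chrom <- sample(paste0("chr", 1:22), nCpg, TRUE)
  chrom[classes == "sex_linked"] <- "chrX"
  xhyb <- rep(FALSE, nCpg)
  idxNull <- which(classes == "null")
  nx <- round(config@crosshybFraction * length(idxNull))
  if (nx > 0) xhyb[idxNull[seq_len(nx)]] <- TRUE
  design <- sample(c("I", "II"), nCpg, TRUE, prob = c(0.3, 0.7))

  ## true slopes (beta units per year)
  em <- config@effectModel
  mag <- stats::runif(nCpg, em$magRange[1], em$magRange[2])
  sgn <- numeric(nCpg)
  for (cl in c("shared_age", "tissueA_only", "tissueB_only")) {
    i <- classes == cl
    sgn[i] <- ifelse(stats::runif(sum(i)) < em$fracPositive[[cl]], 1, -1)
  }
  slopeA <- slopeB <- numeric(nCpg)
  i <- classes == "shared_age"
  slopeA[i] <- sgn[i] * mag[i]
  slopeB[i] <- if (isTRUE(em$constantRatio)) em$effectRatio * slopeA[i] else
    sgn[i] * mag[i] * em$effectRatio
  i <- classes == "tissueA_only"
  slopeA[i] <- sgn[i] * mag[i]
  i <- classes == "tissueB_only"
  slopeB[i] <- sgn[i] * mag[i]

  ## baselines: one draw per CpG (tissue B), tissue A island/shore deficit
  bm <- config@baselineModel
  baseB <- numeric(nCpg)
  for (ct in catNames) {
    i <- cats == ct
    baseB[i] <- stats::runif(sum(i), bm$ranges[[ct]][1], bm$ranges[[ct]][2])
  }
  baseA <- baseB - ifelse(cats %in% c("island", "shore"), bm$deltaA, 0)
  maxAge <- config@ageModel$max
  feas <- function(b, s) {
    b <- ifelse(s > 0, pmin(b, 0.98 - s * maxAge), b)
    b <- ifelse(s < 0, pmax(b, 0.02 - s * maxAge), b)
    pmin(0.99, pmax(0.01, b))
  }
  baseA <- feas(baseA, slopeA)
  baseB <- feas(baseB, slopeB)

  ## sex-linked probe levels (X-inactivation surrogate, identical per tissue)
  sexIdx <- which(classes == "sex_linked")
  fLevel <- stats::runif(length(sexIdx), 0.45, 0.55)
  mPole <- sample(c(0.08, 0.92), length(sexIdx), TRUE)
  mLevel <- mPole + stats::runif(length(sexIdx), -0.02, 0.02)

  ## disease-carrying subset of the null class (disjoint from cross-hyb flags)
  nDis <- round(config@diseaseCpgFraction * length(idxNull))
  disIdx <- if (nDis > 0) utils::tail(idxNull, nDis) else integer(0)
  diseased <- disease == "case"

  buildTissue <- function(base, slope, label) {
    m <- base + outer(slope, age)
    if (length(sexIdx)) {
      lv <- ifelse(matrix(sex == "F", length(sexIdx), n, byrow = TRUE),
                   fLevel, mLevel)
      m[sexIdx, ] <- lv
    }
    if (config@batchSd > 0) {
      batch <- matrix(stats::rnorm(nCpg * nd, 0, config@batchSd), nCpg, nd)
      m <- m + batch[, match(dataset, sprintf("ds%d", seq_len(nd)))]
    }
    if (config@diseaseEffect != 0 && length(disIdx))
      m[disIdx, diseased] <- m[disIdx, diseased] + config@diseaseEffect
    if (config@noiseSd > 0)
      m <- m + matrix(stats::rnorm(nCpg * n, 0, config@noiseSd), nCpg, n)
    clipped <- mean(m < 0 | m > 1)
    m <- .clip01(m)
    dimnames(m) <- list(cpg, sid)
    list(beta = m, clipped = clipped)
  }
  tA <- buildTissue(baseA, slopeA, config@tissueLabels[1])
  tB <- buildTissue(baseB, slopeB, config@tissueLabels[2])
  mA <- tA$beta; mB <- tB$beta
  clipped <- max(tA$clipped, tB$clipped)
  if (clipped > 0.05)
    warning(sprintf(
      "systematic clipping: %.1f%% of generated beta values fell outside [0,1]",
      100 * clipped))

  probes <- DataFrame(cpg_id = cpg, chrom = chrom, category = cats,
                      cross_hybridizing = xhyb, design = design,
                      row.names = cpg)
  truth <- DataFrame(cpg_id = cpg, class = classes, category = cats,
                     slopeA = slopeA, slopeB = slopeB,
                     baselineA = baseA, baselineB = baseB,
                     disease_cpg = seq_len(nCpg) %in% disIdx,
                     row.names = cpg)
  metadata(truth) <- list(
    config = list(cpgCounts = as.list(cc),
                  fracPositive = as.list(em$fracPositive),
                  effectRatio = em$effectRatio, noiseSd = config@noiseSd,
                  batchSd = config@batchSd, seed = config@seed))
  mkSample <- function(tissue) DataFrame(
    sample_id = sid, age = age, sex = sex, tissue = tissue,
    dataset_id = dataset, disease = disease, row.names = sid)
  PairedTissueStudy(
    BetaSet(mA, mkSample(config@tissueLabels[1]), probes),
    BetaSet(mB, mkSample(config@tissueLabels[2]), probes),
    truth = truth, labels = config@tissueLabels)
}

#' Invert beta values to methylated/unmethylated intensities
#'
#' Produces an intensity pair such that `beta = M / (M + U + 100)` recovers
#' the input exactly: `M = beta * (total + 100)`, `U = total - M`.
#'
#' @param beta a [BetaSet-class] or beta matrix.
#' @param totalIntensity total signal `M + U` per probe (scalar). The default
#'   `2^20 - 100` makes `total + 100` a power of two, so `beta * (total+100)`
#'   is an exact binary scaling and the round trip through [computeBeta()] is
#'   bit-exact.
#' @return A list of class `"IntensityPair"` with matrices `M` and `U`.
#' @examples
#' p <- generateIntensities(matrix(0.5, 1, 1, dimnames = list("cg1", "s1")),
#'                          totalIntensity = 5000)
#' p$M  # 2550
#' @export
generateIntensities <- function(beta, totalIntensity = 2^20 - 100) {
  b <- if (is(beta, "BetaSet")) betaValues(beta) else as.matrix(beta)
  .stopIf(totalIntensity <= 0, "totalIntensity must be positive")
  lim <- totalIntensity / (totalIntensity + 100)
  .stopIf(any(b > lim),
          sprintf("infeasible intensity: beta values above %g cannot be represented at total %g",
                  lim, totalIntensity))
  M <- b * (totalIntensity + 100)
  U <- totalIntensity - M
  structure(list(M = M, U = U), class = "IntensityPair")
}

#' Summarize the ground truth of a simulated study
#'
#' Tabulates per-class CpG counts, expected and observed direction fractions,
#' and the expected and observed tissue-B/tissue-A effect ratio. This table is
#' the oracle input for parameter-recovery tests.
#'
#' @param study a [PairedTissueStudy-class] produced by [generateCohort()].
#' @return A data.frame with one row per CpG class, with attributes
#'   `expectedEffectRatio` and `observedEffectRatio`.
#' @export
truthReport <- function(study) {
  truth <- simTruth(study)
  .stopIf(nrow(truth) == 0, "not a simulation: study carries no ground truth")
  cfg <- metadata(truth)$config
  cls <- names(cfg$cpgCounts)
  rows <- lapply(cls, function(cl) {
    i <- truth$class == cl
    slope <- ifelse(truth$slopeA[i] != 0, truth$slopeA[i], truth$slopeB[i])
    informative <- cl %in% c("shared_age", "tissueA_only", "tissueB_only")
    data.frame(class = cl, n = sum(i),
               expected_frac_positive =
                 if (informative) cfg$fracPositive[[cl]] else NA_real_,
               observed_frac_positive =
                 if (informative && any(i)) mean(slope > 0) else NA_real_)
  })
  out <- do.call(rbind, rows)
  sh <- truth$class == "shared_age" & truth$slopeA != 0
  attr(out, "expectedEffectRatio") <- cfg$effectRatio
  attr(out, "observedEffectRatio") <-
    if (any(sh)) stats::median(truth$slopeB[sh] / truth$slopeA[sh]) else NA_real_
  out
}

#' Write a paired-tissue study as plain TSV files
#'
#' Writes one beta matrix per tissue (rows = CpG IDs, columns = sample IDs),
#' a shared sample sheet, the probe annotation, and the truth table when the
#' study is a simulation.
#'
#' @param study a [PairedTissueStudy-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (side in c("A", "B")) {
    bs <- if (side == "A") tissueA(study) else tissueB(study)
    lab <- tissueLabels(study)[if (side == "A") 1 else 2]
    p <- file.path(dir, sprintf("beta_%s.tsv", lab))
    b <- betaValues(bs)
    .writeTsv(data.frame(cpg_id = rownames(b), b, check.names = FALSE), p)
    paths <- c(paths, p)
  }
  ss <- sampleData(tissueA(study))
  ss$tissue <- NULL
  p <- file.path(dir, "sample_sheet.tsv"); .writeTsv(ss, p); paths <- c(paths, p)
  p <- file.path(dir, "probe_annotation.tsv")
  .writeTsv(probeData(tissueA(study)), p); paths <- c(paths, p)
  if (nrow(simTruth(study)) > 0) {
    p <- file.path(dir, "truth.tsv")
    .writeTsv(as.data.frame(simTruth(study)), p); paths <- c(paths, p)
  }
  invisible(paths)
}
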