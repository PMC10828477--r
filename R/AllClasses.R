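#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom Rcpp sourceCpp
#' @useDynLib methylRate, .registration = TRUE
NULL

#' BetaSet: methylation beta values with aligned sample and probe metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"beta"` assay of methylation fractions (CpGs in rows, samples in
#' columns). `colData` carries the sample sheet (`sample_id`, `age`, `sex`,
#' `tissue`, `dataset_id`, `disease`) and `rowData` the probe annotation
#' (`chrom`, `category`, `cross_hybridizing`, `design`).
#'
#' Validity requires every beta value in \[0, 1\] (NAs allowed) and unique,
#' non-empty row and column names.
#'
#' @name BetaSet-class
#' @aliases BetaSet-class
#' @exportClass BetaSet
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
  msg <- character()
  if (!"beta" %in% names(assays(object)))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- assay(object, "beta")
    rng <- suppressWarnings(range(b, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
      msg <- c(msg, "beta values must lie in [0, 1]")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique CpG row names are required")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "unique sample column names are required")
  if (length(msg)) msg else TRUE
})

#' Construct a BetaSet
#'
#' @param beta numeric matrix of beta fractions, CpGs x samples, with row and
#'   column names.
#' @param sampleData data.frame or DataFrame of per-sample metadata, one row
#'   per column of `beta` (matched by `sample_id` column or row names).
#' @param probeData data.frame or DataFrame of per-probe annotation, one row
#'   per row of `beta` (matched by `cpg_id` column or row names).
#' @return A [BetaSet-class] object.
#' @examples
#' b <- matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' bs <- BetaSet(b)
#' dim(bs)
#' @export
BetaSet <- function(beta, sampleData = NULL, probeData = NULL) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("'beta' must have CpG row names and sample column names")
  if (is.null(sampleData)) {
    sampleData <- DataFrame(sample_id = colnames(beta), row.names = colnames(beta))
  } else {
    sampleData <- DataFrame(sampleData)
    if ("sample_id" %in% colnames(sampleData))
      rownames(sampleData) <- sampleData$sample_id
    sampleData <- sampleData[colnames(beta), , drop = FALSE]
  }
  if (is.null(probeData)) {
    probeData <- DataFrame(cpg_id = rownames(beta), row.names = rownames(beta))
  } else {
    probeData <- DataFrame(probeData)
    if ("cpg_id" %in% colnames(probeData))
      rownames(probeData) <- probeData$cpg_id
    probeData <- probeData[rownames(beta), , drop = FALSE]
  }
  new("BetaSet", SummarizedExperiment(
    assays = list(beta = beta), colData = sampleData, rowData = probeData))
}

#' PairedTissueStudy: two tissues measured on the same subjects
#'
#' Holds one [BetaSet-class] per tissue over an identical CpG panel and an
#' identically ordered sample set, together with optional simulation ground
#' truth (per-CpG class labels, true slopes and baselines) when the study was
#' produced by [generateCohort()].
#'
#' @name PairedTissueStudy-class
#' @exportClass PairedTissueStudy
setClass("PairedTissueStudy",
  representation(tissueA = "BetaSet", tissueB = "BetaSet",
                 truth = "DataFrame", labels = "character"))

setValidity("PairedTissueStudy", function(object) {
  msg <- character()
  a <- object@tissueA; b <- object@tissueB
  if (!identical(rownames(a), rownames(b)))
    msg <- c(msg, "CpG panels must be identical and identically ordered")
  if (!identical(colnames(a), colnames(b)))
    msg <- c(msg, "sample IDs must be identical and identically ordered")
  if (length(object@labels) != 2L || anyDuplicated(object@labels))
    msg <- c(msg, "exactly two distinct tissue labels are required")
  if (nrow(object@truth) > 0 && !identical(rownames(object@truth), rownames(a)))
    msg <- c(msg, "truth rows must match the CpG panel")
  if (length(msg)) msg else TRUE
})

#' Construct a PairedTissueStudy
#'
#' @param tissueA,tissueB [BetaSet-class] objects sharing CpG panel and samples.
#' @param truth optional DataFrame of per-CpG ground truth (simulations only).
#' @param labels character(2), tissue labels, default `c("CBL", "MTG")`.
#' @return A [PairedTissueStudy-class] object.
#' @export
PairedTissueStudy <- function(tissueA, tissueB, truth = NULL,
                              labels = c("CBL", "MTG")) {
  if (is.null(truth)) truth <- DataFrame()
  new("PairedTissueStudy", tissueA = tissueA, tissueB = tissueB,
      truth = DataFrame(truth), labels = labels)
}

#' ClockModel: a sparse linear epigenetic age predictor
#'
#' Stores the nonzero CpG coefficients, intercept, age transform, per-CpG
#' training means (for optional missing-probe imputation) and training
#' provenance of a methylation clock. Predicted age is
#' `inverse_transform(intercept + sum(coef * beta))`.
#'
#' @name ClockModel-class
#' @exportClass ClockModel
setClass("ClockModel",
  representation(name = "character", coefficients = "numeric",
                 intercept = "numeric", transform = "character",
                 adultAge = "numeric", trainingMeans = "numeric",
                 provenance = "list"))

setValidity("ClockModel", function(object) {
  msg <- character()
  cf <- object@coefficients
  if (length(cf) && (is.null(names(cf)) || anyDuplicated(names(cf))))
    msg <- c(msg, "coefficients must have unique CpG names")
  if (any(cf == 0))
    msg <- c(msg, "zero coefficients must not be stored")
  if (!object@transform %in% c("identity", "log1p", "horvath"))
    msg <- c(msg, "transform must be identity, log1p or horvath")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a ClockModel
#'
#' @param name clock name.
#' @param coefficients named numeric vector of nonzero CpG coefficients.
#' @param intercept model intercept on the transformed-age scale.
#' @param transform age transform, one of `"identity"`, `"log1p"`, `"horvath"`.
#' @param adultAge adult age parameter of the horvath transform (years).
#' @param trainingMeans named numeric vector of training-set mean betas for the
#'   model CpGs (used by `missingPolicy = "impute_training_mean"`).
#' @param provenance list describing the training run (tissues, CpG-set name,
#'   alpha, chosen lambda, seed, n).
#' @return A [ClockModel-class] object.
#' @export
ClockModel <- function(name, coefficients, intercept,
                       transform = "log1p", adultAge = 20,
                       trainingMeans = numeric(), provenance = list()) {
  coefficients <- coefficients[coefficients != 0]
  new("ClockModel", name = name, coefficients = coefficients,
      intercept = as.numeric(intercept), transform = transform,
      adultAge = as.numeric(adultAge), trainingMeans = trainingMeans,
      provenance = provenance)
}

#' EwasResult: per-CpG age-association statistics
#'
#' One row per CpG with the age effect size (beta units per year), its t
#' statistic, raw and Bonferroni-adjusted p-value and a significance flag at
#' the stored threshold.
#'
#' @name EwasResult-class
#' @exportClass EwasResult
setClass("EwasResult",
  representation(table = "data.frame", tissue = "character",
                 covariates = "character", threshold = "numeric"))

setValidity("EwasResult", function(object) {
  tb <- object@table
  need <- c("cpg_id", "effect", "t", "p", "p_adj", "significant")
  msg <- character()
  if (!all(need %in% colnames(tb)))
    msg <- c(msg, paste("table must contain columns:", paste(need, collapse = ", ")))
  else {
    ok <- !is.na(tb$p) & !is.na(tb$p_adj)
    if (any(tb$p_adj[ok] + 1e-12 < tb$p[ok]))
      msg <- c(msg, "adjusted p must be >= raw p")
    if (any(tb$p_adj[ok] > 1))
      msg <- c(msg, "adjusted p must be <= 1")
    if (!identical(tb$significant, !is.na(tb$p_adj) & tb$p_adj <= object@threshold))
      msg <- c(msg, "significance flag inconsistent with threshold")
  }
  if (length(msg)) msg else TRUE
})

#' PredictionReport: per-sample DNAm ages with accuracy summaries
#'
#' Per-sample chronological age, DNAm age, age acceleration and missing-probe
#' count, plus summary metrics (RMSD, MAD, Pearson r, slope and intercept of
#' DNAm age regressed on chronological age, n).
#'
#' @name PredictionReport-class
#' @exportClass PredictionReport
setClass("PredictionReport",
  representation(table = "data.frame", metrics = "list", accelMode = "character"))

setValidity("PredictionReport", function(object) {
  m <- object@metrics
  msg <- character()
  if (!all(c("rmsd", "mad", "r", "slope", "intercept", "n") %in% names(m)))
    msg <- c(msg, "metrics must contain rmsd, mad, r, slope, intercept, n")
  else if (is.finite(m$rmsd) && is.finite(m$mad) && m$rmsd + 1e-12 < m$mad)
    msg <- c(msg, "RMSD must be >= MAD")
  if (!object@accelMode %in% c("difference", "residual"))
    msg <- c(msg, "accelMode must be 'difference' or 'residual'")
  if (length(msg)) msg else TRUE
})
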