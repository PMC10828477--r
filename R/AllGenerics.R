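#' Accessors for methylRate classes
#'
#' `betaValues()` returns the beta matrix of a [BetaSet-class];
#' `sampleData()`/`probeData()` return its sample sheet and probe annotation as
#' data.frames. `tissueA()`/`tissueB()` extract the per-tissue [BetaSet-class]
#' of a [PairedTissueStudy-class], `tissueLabels()` its labels and
#' `simTruth()` its simulation ground truth. `clockName()`, `clockCoef()`,
#' `clockIntercept()`, `ageTransformSpec()` and `clockProvenance()` read
#' [ClockModel-class] slots; `ewasTable()` and `significantCpgs()` read
#' [EwasResult-class]; `reportTable()` and `reportMetrics()` read
#' [PredictionReport-class].
#'
#' @param object an object of the documented class.
#' @return The slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("betaValues", function(object) standardGeneric("betaValues"))
#' @rdname accessors
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))
#' @rdname accessors
#' @export
setGeneric("probeData", function(object) standardGeneric("probeData"))
#' @rdname accessors
#' @export
setGeneric("tissueA", function(object) standardGeneric("tissueA"))
#' @rdname accessors
#' @export
setGeneric("tissueB", function(object) standardGeneric("tissueB"))
#' @rdname accessors
#' @export
setGeneric("tissueLabels", function(object) standardGeneric("tissueLabels"))
#' @rdname accessors
#' @export
setGeneric("simTruth", function(object) standardGeneric("simTruth"))
#' @rdname accessors
#' @export
setGeneric("clockName", function(object) standardGeneric("clockName"))
#' @rdname accessors
#' @export
setGeneric("clockCoef", function(object) standardGeneric("clockCoef"))
#' @rdname accessors
#' @export
setGeneric("clockIntercept", function(object) standardGeneric("clockIntercept"))
#' @rdname accessors
#' @export
setGeneric("ageTransformSpec", function(object) standardGeneric("ageTransformSpec"))
#' @rdname accessors
#' @export
setGeneric("clockProvenance", function(object) standardGeneric("clockProvenance"))
#' @rdname accessors
#' @export
setGeneric("ewasTable", function(object) standardGeneric("ewasTable"))
#' @rdname accessors
#' @export
setGeneric("significantCpgs", function(object) standardGeneric("significantCpgs"))
#' @rdname accessors
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))
#' @rdname accessors
#' @export
setGeneric("reportMetrics", function(object) standardGeneric("reportMetrics"))

#' @rdname accessors
setMethod("betaValues", "BetaSet", function(object) assay(object, "beta"))
#' @rdname accessors
setMethod("sampleData", "BetaSet",
          function(object) as.data.frame(colData(object)))
#' @rdname accessors
setMethod("probeData", "BetaSet",
          function(object) as.data.frame(rowData(object)))
#' @rdname accessors
setMethod("tissueA", "PairedTissueStudy", function(object) object@tissueA)
#' @rdname accessors
setMethod("tissueB", "PairedTissueStudy", function(object) object@tissueB)
#' @rdname accessors
setMethod("tissueLabels", "PairedTissueStudy", function(object) object@labels)
#' @rdname accessors
setMethod("simTruth", "PairedTissueStudy", function(object) object@truth)
#' @rdname accessors
setMethod("clockName", "ClockModel", function(object) object@name)
#' @rdname accessors
setMethod("clockCoef", "ClockModel", function(object) object@coefficients)
#' @rdname accessors
setMethod("clockIntercept", "ClockModel", function(object) object@intercept)
#' @rdname accessors
setMethod("ageTransformSpec", "ClockModel",
          function(object) list(kind = object@transform, adultAge = object@adultAge))
#' @rdname accessors
setMethod("clockProvenance", "ClockModel", function(object) object@provenance)
#' @rdname accessors
setMethod("ewasTable", "EwasResult", function(object) object@table)
#' @rdname accessors
setMethod("significantCpgs", "EwasResult",
          function(object) object@table$cpg_id[object@table$significant])
#' @rdname accessors
setMethod("reportTable", "PredictionReport", function(object) object@table)
#' @rdname accessors
setMethod("reportMetrics", "PredictionReport", function(object) object@metrics)

setMethod("show", "BetaSet", function(object) {
  cat("BetaSet:", nrow(object), "CpGs x", ncol(object), "samples\n")
  callNextMethod()
})

setMethod("show", "PairedTissueStudy", function(object) {
  cat("PairedTissueStudy [", paste(object@labels, collapse = " / "), "]\n",
      "  ", nrow(object@tissueA), " CpGs x ", ncol(object@tissueA),
      " paired samples\n", sep = "")
  if (nrow(object@truth) > 0)
    cat("  simulation ground truth attached (",
        paste(names(table(object@truth$class)), table(object@truth$class),
              sep = "=", collapse = ", "), ")\n", sep = "")
})

setMethod("show", "ClockModel", function(object) {
  cat("ClockModel '", object@name, "': ", length(object@coefficients),
      " CpGs, intercept ", signif(object@intercept, 5),
      ", transform ", object@transform, "\n", sep = "")
  pr <- object@provenance
  if (length(pr))
    cat("  trained:", paste(names(pr), vapply(pr, function(x)
      paste(format(x), collapse = ","), ""), sep = "=", collapse = "; "), "\n")
})

setMethod("show", "EwasResult", function(object) {
  cat("EwasResult [", object@tissue, "]: ", nrow(object@table), " CpGs, ",
      sum(object@table$significant), " significant at adjusted p <= ",
      object@threshold, "\n  covariates: age",
      if (length(object@covariates))
        paste0(" + ", paste(object@covariates, collapse = " + ")),
      "\n", sep = "")
})

setMethod("show", "PredictionReport", function(object) {
  m <- object@metrics
  cat("PredictionReport: n=", m$n, ", r=", signif(m$r, 4),
      ", RMSD=", signif(m$rmsd, 4), ", MAD=", signif(m$mad, 4),
      ", slope=", signif(m$slope, 4), ", intercept=", signif(m$intercept, 4),
      " (acceleration: ", object@accelMode, ")\n", sep = "")
})
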