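#' Convert methylated/unmethylated intensities to beta values
#'
#' Computes `beta = M / (M + U + 100)` elementwise; the +100 offset keeps the
#' ratio defined (and below 1) even at zero total signal.
#'
#' @param intensities an `"IntensityPair"` (list with matrices `M` and `U`)
#'   as produced by [generateIntensities()], or any list with those elements.
#' @param sampleData,probeData optional metadata forwarded to [BetaSet()].
#' @return A [BetaSet-class].
#' @examples
#' p <- list(M = matrix(900, 1, 1, dimnames = list("cg1", "s1")),
#'           U = matrix(0, 1, 1, dimnames = list("cg1", "s1")))
#' betaValues(computeBeta(p))  # 0.9
#' @export
computeBeta <- function(intensities, sampleData = NULL, probeData = NULL) {
  M <- as.matrix(intensities$M); U <- as.matrix(intensities$U)
  .stopIf(!identical(dim(M), dim(U)), "M and U must have identical shapes")
  .stopIf(any(M < 0) || any(U < 0), "invalid input: negative intensities")
  BetaSet(M / (M + U + 100), sampleData = sampleData, probeData = probeData)
}

#' Estimate sample sex from X-chromosome methylation
#'
#' A deterministic surrogate sex caller: for each sample the score is the
#' fraction of X-chromosome betas in the intermediate band (0.2, 0.8). Due to
#' X inactivation, female samples show intermediate X methylation while male
#' samples are bimodal (near 0 or 1). Samples are split by the midpoint of a
#' one-dimensional 2-means on the scores (initialized at the score extremes);
#' the high-score group is called female.
#'
#' @param beta a [BetaSet-class] or beta matrix.
#' @param annotation probe annotation data.frame with `cpg_id` and `chrom`
#'   (defaults to the `rowData` of `beta`).
#' @return data.frame with `sample_id`, `score`, `estimated_sex`; the 2-means
#'   threshold is attached as attribute `"threshold"`.
#' @export
estimateSex <- function(beta, annotation = NULL) {
  b <- if (is(beta, "BetaSet")) betaValues(beta) else as.matrix(beta)
  if (is.null(annotation) && is(beta, "BetaSet")) annotation <- probeData(beta)
  annotation <- as.data.frame(annotation)
  xIds <- annotation$cpg_id[annotation$chrom %in% c("chrX", "X")]
  xIds <- intersect(xIds, rownames(b))
  .stopIf(length(xIds) < 10,
          "cannot estimate sex: fewer than 10 X-chromosome probes present")
  xb <- b[xIds, , drop = FALSE]
  score <- colMeans(xb > 0.2 & xb < 0.8)
  if (diff(range(score)) == 0) {
    thr <- score[1]
    call <- rep(if (score[1] >= 0.5) "F" else "M", length(score))
  } else {
    km <- stats::kmeans(score, centers = range(score))
    thr <- mean(km$centers)
    call <- ifelse(score > thr, "F", "M")
  }
  structure(data.frame(sample_id = colnames(b), score = as.numeric(score),
                       estimated_sex = call, stringsAsFactors = FALSE),
            threshold = thr)
}

#' Sample-level quality control
#'
#' Applies two deterministic sample filters: (1) samples whose estimated sex
#' (via [estimateSex()]) contradicts the reported sex are removed; (2) samples
#' with an abnormal beta density are removed, where abnormality is scored as
#' the fraction of autosomal betas in the mid-range \[0.25, 0.75\] (a healthy
#' methylome is bimodal, so this mass is low) and samples above
#' `densityThreshold` fail. Samples with reported sex `"unknown"` skip the
#' sex check.
#'
#' @param beta a [BetaSet-class] with sample sheet and probe annotation, or a
#'   matrix with `samples`/`annotation` supplied.
#' @param samples sample sheet with `sample_id` and `reported_sex` or `sex`.
#' @param annotation probe annotation with `cpg_id` and `chrom`.
#' @param densityThreshold mid-beta mass above which a sample is abnormal
#'   (default 0.5).
#' @return list with the filtered `beta` ([BetaSet-class] when the input was
#'   one, matrix otherwise) and `report`, a list of class `"QCReport"` with
#'   per-sample scores/flags and per-rule exclusion counts.
#' @export
qcFilter <- function(beta, samples = NULL, annotation = NULL,
                     densityThreshold = 0.5) {
  isSet <- is(beta, "BetaSet")
  b <- if (isSet) betaValues(beta) else as.matrix(beta)
  if (is.null(samples) && isSet) samples <- sampleData(beta)
  if (is.null(annotation) && isSet) annotation <- probeData(beta)
  samples <- as.data.frame(samples)
  annotation <- as.data.frame(annotation)
  .stopIf(!all(colnames(b) %in% samples$sample_id),
          "inputs not aligned: samples missing from the sample sheet")
  samples <- samples[match(colnames(b), samples$sample_id), ]
  reported <- if ("reported_sex" %in% colnames(samples))
    samples$reported_sex else samples$sex
  if (is.null(reported)) reported <- rep("unknown", ncol(b))

  sexEst <- estimateSex(b, annotation)
  mismatch <- !is.na(reported) & reported %in% c("F", "M") &
    sexEst$estimated_sex != reported

  autoIds <- annotation$cpg_id[!annotation$chrom %in% c("chrX", "chrY", "X", "Y")]
  ab <- b[intersect(autoIds, rownames(b)), , drop = FALSE]
  density <- colMeans(ab >= 0.25 & ab <= 0.75)
  abnormal <- density > densityThreshold

  fail <- mismatch | abnormal
  reason <- ifelse(mismatch, "sex_mismatch",
                   ifelse(abnormal, "abnormal_density", ""))
  report <- structure(list(
    perSample = data.frame(sample_id = colnames(b),
                           estimated_sex = sexEst$estimated_sex,
                           reported_sex = reported,
                           sex_mismatch = mismatch,
                           density_score = as.numeric(density),
                           pass = !fail, reason = reason,
                           stringsAsFactors = FALSE),
    excluded = c(sex_mismatch = sum(mismatch),
                 abnormal_density = sum(abnormal & !mismatch)),
    retained = sum(!fail), input = ncol(b),
    densityThreshold = densityThreshold), class = "QCReport")
  .stopIf(all(fail), "empty cohort: all samples excluded by QC")
  keep <- colnames(b)[!fail]
  out <- if (isSet) beta[, keep] else b[, keep, drop = FALSE]
  list(beta = out, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QC report:", x$input, "samples in,", x$retained, "retained\n")
  cat("  excluded:", paste(names(x$excluded), x$excluded, sep = "=",
                           collapse = ", "),
      sprintf("(density threshold %.2f)\n", x$densityThreshold))
  invisible(x)
}

#' Remove sex-chromosome and cross-hybridizing probes
#'
#' Drops rows mapped to chrX/chrY or flagged as cross-hybridizing, preserving
#' the order (and values) of all surviving rows.
#'
#' @param beta a [BetaSet-class] or beta matrix.
#' @param annotation probe annotation with `cpg_id`, `chrom` and
#'   `cross_hybridizing` (defaults to the `rowData` of `beta`).
#' @return The filtered object, same type as the input.
#' @export
filterProbes <- function(beta, annotation = NULL) {
  isSet <- is(beta, "BetaSet")
  b <- if (isSet) betaValues(beta) else as.matrix(beta)
  if (is.null(annotation) && isSet) annotation <- probeData(beta)
  annotation <- as.data.frame(annotation)
  missing <- setdiff(rownames(b), annotation$cpg_id)
  .stopIf(length(missing) > 0,
          "missing annotation for probes: ", paste(missing, collapse = ", "))
  ann <- annotation[match(rownames(b), annotation$cpg_id), ]
  xh <- if ("cross_hybridizing" %in% colnames(ann))
    ann$cross_hybridizing %in% c(TRUE, "TRUE", 1) else FALSE
  drop <- ann$chrom %in% c("chrX", "chrY", "X", "Y") | xh
  keep <- rownames(b)[!drop]
  if (isSet) beta[keep, ] else b[keep, , drop = FALSE]
}

#' Build a fixed quantile-normalization reference
#'
#' Pools the betas of all samples within each probe design type and records
#' their empirical quantiles at `nQuantiles` plotting positions. Serializing
#' this reference with a run lets later cohorts be normalized against the
#' same distribution, reducing between-dataset variance.
#'
#' @param beta a [BetaSet-class] or beta matrix of the reference cohort.
#' @param annotation probe annotation with `cpg_id` and `design`.
#' @param nQuantiles number of quantile anchors per design type (default 500).
#' @return list of class `"QuantileReference"`: per design type, `probs` and
#'   `values`.
#' @export
buildQuantileReference <- function(beta, annotation = NULL, nQuantiles = 500) {
  b <- if (is(beta, "BetaSet")) betaValues(beta) else as.matrix(beta)
  if (is.null(annotation) && is(beta, "BetaSet")) annotation <- probeData(beta)
  annotation <- as.data.frame(annotation)
  ann <- annotation[match(rownames(b), annotation$cpg_id), ]
  ref <- list()
  for (d in unique(ann$design)) {
    v <- as.numeric(b[ann$design == d, , drop = FALSE])
    probs <- (seq_len(nQuantiles) - 0.5) / nQuantiles
    ref[[d]] <- list(probs = probs,
                     values = as.numeric(stats::quantile(v, probs, names = FALSE)))
  }
  structure(ref, class = "QuantileReference")
}

#' Quantile-normalize samples onto a fixed reference
#'
#' Within each probe design type, each sample's betas are rank-mapped onto
#' the fixed reference distribution: value at mid-rank plotting position
#' `(rank - 0.5) / m` is linearly interpolated between the reference
#' quantiles. The map preserves within-sample ranks and is idempotent on a
#' sample already distributed like the reference.
#'
#' @param beta a [BetaSet-class] or beta matrix.
#' @param reference a `"QuantileReference"` from [buildQuantileReference()],
#'   covering every design type present.
#' @param annotation probe annotation with `cpg_id` and `design`.
#' @return The normalized object, same type as the input.
#' @export
normalizeFixedQuantiles <- function(beta, reference, annotation = NULL) {
  isSet <- is(beta, "BetaSet")
  b <- if (isSet) betaValues(beta) else as.matrix(beta)
  if (is.null(annotation) && isSet) annotation <- probeData(beta)
  annotation <- as.data.frame(annotation)
  ann <- annotation[match(rownames(b), annotation$cpg_id), ]
  designs <- unique(ann$design)
  .stopIf(!all(designs %in% names(reference)),
          "reference does not cover all probe design types")
  out <- b
  for (d in designs) {
    ref <- reference[[d]]
    .stopIf(length(ref$values) < 2, "invalid reference: fewer than 2 quantiles")
    rows <- which(ann$design == d)
    m <- length(rows)
    for (j in seq_len(ncol(b))) {
      r <- rank(b[rows, j], ties.method = "average")
      p <- (r - 0.5) / m
      out[rows, j] <- stats::approx(ref$probs, ref$values, xout = p,
                                    rule = 2)$y
    }
  }
  if (isSet) {
    res <- beta
    SummarizedExperiment::assay(res, "beta") <- out
    res
  } else out
}

#' Z-score standardize each sample
#'
#' Centers and scales each column (sample) of the beta matrix to mean 0 and
#' sd 1, the per-sample normalization used before applying clocks trained on
#' standardized methylation values.
#'
#' @param beta a [BetaSet-class] or beta matrix with at least 2 probes.
#' @return A numeric matrix of standardized values.
#' @export
zscoreSamples <- function(beta) {
  b <- if (is(beta, "BetaSet")) betaValues(beta) else as.matrix(beta)
  .stopIf(nrow(b) < 2, "at least 2 probes per sample are required")
  s <- apply(b, 2, stats::sd)
  .stopIf(any(s == 0), "degenerate sample: zero variance in ",
          paste(colnames(b)[s == 0], collapse = ", "))
  scale(b, center = TRUE, scale = TRUE)[, , drop = FALSE]
}
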