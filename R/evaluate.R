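#' Apply a clock to a beta matrix
#'
#' Computes, per sample, `dnam_age = inverse_transform(intercept +
#' sum(coef * beta))`, aligning model CpGs to the panel by name (row order is
#' irrelevant). Model CpGs absent from the panel are handled by
#' `missingPolicy`: `"error"` (default) aborts listing the IDs;
#' `"impute_training_mean"` substitutes the training-set mean beta stored in
#' the clock and counts the imputations per sample.
#'
#' @param model a [ClockModel-class].
#' @param beta a [BetaSet-class] or beta matrix.
#' @param missingPolicy `"error"` or `"impute_training_mean"`.
#' @return data.frame `(sample_id, dnam_age, missing_probes)`.
#' @examples
#' m <- ClockModel("toy", c(cg1 = 1), 2, transform = "identity")
#' predictAge(m, matrix(0.5, 1, 1, dimnames = list("cg1", "s1")))  # 2.5
#' @export
predictAge <- function(model, beta,
                       missingPolicy = c("error", "impute_training_mean")) {
  missingPolicy <- match.arg(missingPolicy)
  b <- if (is(beta, "BetaSet")) betaValues(beta) else as.matrix(beta)
  cf <- clockCoef(model)
  present <- names(cf) %in% rownames(b)
  .stopIf(!any(present), "no usable probes: the panel shares no CpGs with the clock")
  if (!all(present)) {
    miss <- names(cf)[!present]
    if (missingPolicy == "error")
      stop("missing model probes: ", paste(miss, collapse = ", "),
           call. = FALSE)
    tm <- model@trainingMeans[miss]
    .stopIf(anyNA(tm) || length(tm) < length(miss),
            "cannot impute: training means unavailable for missing probes")
    baseShift <- sum(cf[miss] * tm)
  } else baseShift <- 0
  use <- names(cf)[present]
  lin <- as.numeric(crossprod(b[use, , drop = FALSE], cf[use])) +
    clockIntercept(model) + baseShift
  tr <- ageTransformSpec(model)
  data.frame(sample_id = colnames(b),
             dnam_age = inverseTransformAge(lin, tr$kind, tr$adultAge),
             missing_probes = sum(!present), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Accuracy metrics of DNAm age predictions
#'
#' Root mean squared deviation `RMSD = sqrt(mean((y - yhat)^2))`, mean
#' absolute deviation `MAD = mean(|y - yhat|)`, Pearson correlation, and the
#' slope and intercept of the OLS regression of DNAm age on chronological
#' age (the regression-line convention used throughout for rate reading).
#'
#' @param y chronological ages (years).
#' @param yhat predicted DNAm ages (years), same length.
#' @return list `(rmsd, mad, r, slope, intercept, n)`; `r`/`slope` are NA for
#'   constant `y`.
#' @examples
#' accuracyMetrics(c(50, 60), c(53, 64))  # MAD 3.5, RMSD sqrt(12.5)
#' @export
accuracyMetrics <- function(y, yhat) {
  .stopIf(length(y) != length(yhat), "y and yhat must have equal length")
  .stopIf(length(y) < 2, "insufficient data: need at least 2 samples")
  d <- y - yhat
  out <- list(rmsd = sqrt(mean(d^2)), mad = mean(abs(d)))
  if (stats::var(y) > 0) {
    slope <- stats::cov(y, yhat) / stats::var(y)
    out$r <- if (stats::var(yhat) > 0) stats::cor(y, yhat) else NA_real_
    out$slope <- slope
    out$intercept <- mean(yhat) - slope * mean(y)
  } else {
    out$r <- NA_real_; out$slope <- NA_real_; out$intercept <- NA_real_
  }
  out$n <- length(y)
  out
}

#' Age acceleration
#'
#' `"difference"` is the classical definition `dnam_age - age`;
#' `"residual"` returns the residuals of the OLS regression of DNAm age on
#' chronological age (mean exactly 0), which removes calibration slope
#' artefacts and is the default for cross-tissue comparisons.
#'
#' @inheritParams accuracyMetrics
#' @param mode `"difference"` or `"residual"`.
#' @return numeric vector of per-sample accelerations.
#' @export
ageAcceleration <- function(y, yhat, mode = c("residual", "difference")) {
  mode <- match.arg(mode)
  .stopIf(length(y) != length(yhat), "y and yhat must have equal length")
  .stopIf(length(y) < 2, "insufficient data: need at least 2 samples")
  if (mode == "difference") return(yhat - y)
  .stopIf(stats::var(y) == 0, "residual mode needs nonconstant ages")
  stats::residuals(stats::lm(yhat ~ y))
}

#' Build a full prediction report
#'
#' Combines [predictAge()] output (or any `(y, yhat)` pair) with
#' [accuracyMetrics()] and [ageAcceleration()] into a
#' [PredictionReport-class].
#'
#' @param sampleIds sample identifiers.
#' @param y chronological ages.
#' @param yhat DNAm ages.
#' @param accelMode acceleration definition recorded in the report.
#' @param missingProbes per-sample missing-probe counts (default 0).
#' @return A [PredictionReport-class].
#' @export
predictionReport <- function(sampleIds, y, yhat,
                             accelMode = c("residual", "difference"),
                             missingProbes = 0L) {
  accelMode <- match.arg(accelMode)
  m <- accuracyMetrics(y, yhat)
  acc <- ageAcceleration(y, yhat, accelMode)
  new("PredictionReport",
      table = data.frame(sample_id = sampleIds, age = y, dnam_age = yhat,
                         acceleration = as.numeric(acc),
                         missing_probes = missingProbes,
                         stringsAsFactors = FALSE, row.names = NULL),
      metrics = m, accelMode = accelMode)
}

#' Cross-tissue ageing-rate comparison via reciprocal clock application
#'
#' The core rate inference: a clock is trained on tissue A restricted to a
#' shared CpG set and applied to tissue B (and vice versa); the slope of the
#' regression of predicted DNAm age on chronological age in the foreign
#' tissue reads off the relative ageing tick rate on those CpGs. A slope
#' above 1 for the A-trained clock on B, together with a slope below 1 for
#' the B-trained clock on A, consistently identifies tissue A as the slower
#' tissue. Supporting tallies over the shared set (fraction gaining
#' methylation in both tissues, fraction with lower methylation in A,
#' fraction with smaller absolute effect in A) and optional per-tissue
#' self cross-validation metrics are reported alongside.
#'
#' @param study a [PairedTissueStudy-class].
#' @param sharedSet nonempty character vector of CpG IDs age-associated in
#'   both tissues.
#' @param transform age transform for clock training (identity recommended
#'   for quantitative slope reading; log transforms bend the slope and are
#'   interpreted qualitatively).
#' @param config an [enetConfig()] (shared-CpG clock convention: alpha 0.2).
#' @param selfCV `"loco"`, `"kfold"` or `"none"`: scheme for the per-tissue
#'   self cross-validation metrics.
#' @return list of class `"RateComparison"`: `slopes` and `intercepts` for
#'   both directions, `selfCV` metrics, `tallies`, `verdict` (which tissue is
#'   slower under each direction, and whether the two directions agree).
#' @export
compareRates <- function(study, sharedSet, transform = "identity",
                         config = enetConfig(alpha = 0.2),
                         selfCV = c("loco", "kfold", "none")) {
  selfCV <- match.arg(selfCV)
  .stopIf(length(sharedSet) == 0, "sharedSet must be nonempty")
  labs <- tissueLabels(study)
  bsA <- tissueA(study); bsB <- tissueB(study)
  age <- sampleData(bsA)$age
  cross <- function(trainSet, testSet, dirName) {
    tryCatch({
      clk <- trainClock(trainSet, sharedSet, name = dirName,
                        transform = transform, config = config)
      pred <- predictAge(clk, testSet)
      m <- accuracyMetrics(age, pred$dnam_age)
      list(slope = m$slope, intercept = m$intercept, r = m$r, clock = clk)
    }, error = function(e) {
      warning(sprintf("direction %s failed to train: %s", dirName,
                      conditionMessage(e)))
      list(slope = NA_real_, intercept = NA_real_, r = NA_real_, clock = NULL)
    })
  }
  ab <- cross(bsA, bsB, paste0(labs[1], "->", labs[2]))
  ba <- cross(bsB, bsA, paste0(labs[2], "->", labs[1]))

  self <- NULL
  if (selfCV != "none") {
    cvFun <- function(bs) {
      ds <- sampleData(bs)$dataset_id
      preds <- if (selfCV == "loco" && length(unique(ds)) >= 2)
        leaveOneDatasetOutCV(bs, sharedSet, transform = transform,
                             config = config)
      else kFoldCV(bs, sharedSet, transform = transform, config = config,
                   k = min(10, ncol(bs)))
      accuracyMetrics(sampleData(bs)$age[match(preds$sample_id,
                                               sampleData(bs)$sample_id)],
                      preds$dnam_age)
    }
    self <- list(cvFun(bsA), cvFun(bsB))
    names(self) <- labs
  }

  cs <- categorySummary(study, cpgSet = sharedSet)
  tallies <- cs$setTallies[c("frac_positive_in_both",
                             "frac_lower_median_in_A",
                             "frac_larger_abs_effect_in_A")]
  tallies["frac_smaller_abs_effect_in_A"] <-
    1 - tallies[["frac_larger_abs_effect_in_A"]]

  verdictAB <- if (is.na(ab$slope)) NA_character_ else
    if (ab$slope > 1) labs[1] else if (ab$slope < 1) labs[2] else NA_character_
  verdictBA <- if (is.na(ba$slope)) NA_character_ else
    if (ba$slope < 1) labs[1] else if (ba$slope > 1) labs[2] else NA_character_
  consistent <- !is.na(verdictAB) && !is.na(verdictBA) &&
    verdictAB == verdictBA
  structure(list(
    tissues = labs, sharedSetSize = length(sharedSet),
    slopes = c(A_to_B = ab$slope, B_to_A = ba$slope),
    intercepts = c(A_to_B = ab$intercept, B_to_A = ba$intercept),
    r = c(A_to_B = ab$r, B_to_A = ba$r),
    clocks = list(A = ab$clock, B = ba$clock),
    selfCV = self, tallies = tallies,
    verdict = list(by_A_clock = verdictAB, by_B_clock = verdictBA,
                   consistent = consistent,
                   slower = if (consistent) verdictAB else NA_character_)),
    class = "RateComparison")
}

#' @export
print.RateComparison <- function(x, ...) {
  cat(sprintf("Ageing-rate comparison [%s vs %s], %d shared CpGs\n",
              x$tissues[1], x$tissues[2], x$sharedSetSize))
  cat(sprintf("  %s-trained clock on %s: slope %.3f, intercept %.2f\n",
              x$tissues[1], x$tissues[2], x$slopes["A_to_B"],
              x$intercepts["A_to_B"]))
  cat(sprintf("  %s-trained clock on %s: slope %.3f, intercept %.2f\n",
              x$tissues[2], x$tissues[1], x$slopes["B_to_A"],
              x$intercepts["B_to_A"]))
  if (x$verdict$consistent)
    cat(sprintf("  verdict: %s has the smaller ageing tick rate (both directions agree)\n",
                x$verdict$slower))
  else cat("  verdict: directions do not agree\n")
  invisible(x)
}

#' Cross-tissue age-acceleration correlations
#'
#' Pearson correlations of residual-mode age accelerations between every
#' pair of tissues over their shared subjects, plus paired Wilcoxon
#' signed-rank tests on the acceleration levels. Pairs with fewer than 3
#' shared subjects are reported NA.
#'
#' @param reports named list of [PredictionReport-class], one per tissue.
#' @param pairing optional named list mapping each tissue's sample IDs to
#'   subject IDs; by default sample IDs are taken as subject IDs.
#' @return list of class `"AccelCorrelation"` with symmetric matrices `cor`
#'   and `wilcoxP`, and `nShared`.
#' @export
accelerationCorrelation <- function(reports, pairing = NULL) {
  .stopIf(length(reports) < 2, "need at least 2 tissues")
  nm <- names(reports)
  .stopIf(is.null(nm) || any(nm == ""), "reports must be a named list")
  getAcc <- function(i) {
    tb <- reportTable(reports[[i]])
    subj <- if (!is.null(pairing)) pairing[[nm[i]]][tb$sample_id] else
      tb$sample_id
    stats::setNames(tb$acceleration, subj)
  }
  accs <- lapply(seq_along(reports), getAcc)
  k <- length(accs)
  cm <- pm <- ns <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(cm) <- 1; diag(pm) <- NA
  for (i in seq_len(k)) ns[i, i] <- length(accs[[i]])
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    shared <- intersect(names(accs[[i]]), names(accs[[j]]))
    ns[i, j] <- ns[j, i] <- length(shared)
    if (length(shared) < 3) next
    a <- accs[[i]][shared]; bb <- accs[[j]][shared]
    cm[i, j] <- cm[j, i] <- stats::cor(a, bb)
    d <- a - bb
    pm[i, j] <- pm[j, i] <- if (all(d == 0)) 1 else
      suppressWarnings(stats::wilcox.test(a, bb, paired = TRUE)$p.value)
  }
  structure(list(cor = cm, wilcoxP = pm, nShared = ns),
            class = "AccelCorrelation")
}

#' @export
print.AccelCorrelation <- function(x, ...) {
  cat("Age-acceleration correlations (residual mode):\n")
  print(round(x$cor, 3))
  invisible(x)
}
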