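#' Age transforms for clock training
#'
#' `transformAge()` maps chronological age (years) onto the training scale;
#' `inverseTransformAge()` maps predictions back to years. Supported kinds:
#' `"identity"`; `"log1p"` (`log(age + 1)`, inverse `expm1`), the default
#' log transform for clock training; `"horvath"`, the piecewise transform
#' `log(age + 1) - log(adult + 1)` below the adult age and
#' `(age - adult) / (adult + 1)` above it, continuous at `adult` and provided
#' for interoperability with published clocks.
#'
#' @param age numeric vector of ages in years (must be > -1).
#' @param value numeric vector on the transformed scale.
#' @param kind one of `"identity"`, `"log1p"`, `"horvath"`.
#' @param adultAge adult-age knot of the horvath transform (default 20).
#' @return Numeric vector, transformed (or back-transformed) values.
#' @examples
#' transformAge(20, "log1p")                      # log(21)
#' inverseTransformAge(transformAge(80), )        # 80
#' transformAge(20, "horvath", adultAge = 20)     # 0
#' @export
transformAge <- function(age, kind = c("log1p", "identity", "horvath"),
                         adultAge = 20) {
  kind <- match.arg(kind)
  .stopIf(any(age <= -1), "domain error: age must be > -1")
  switch(kind,
         identity = age,
         log1p = log1p(age),
         horvath = ifelse(age <= adultAge,
                          log1p(age) - log1p(adultAge),
                          (age - adultAge) / (adultAge + 1)))
}

#' @rdname transformAge
#' @export
inverseTransformAge <- function(value, kind = c("log1p", "identity", "horvath"),
                                adultAge = 20) {
  kind <- match.arg(kind)
  switch(kind,
         identity = value,
         log1p = expm1(value),
         horvath = ifelse(value <= 0,
                          expm1(value + log1p(adultAge)),
                          value * (adultAge + 1) + adultAge))
}

#' Train an elastic-net epigenetic clock
#'
#' Restricts the beta matrix to `cpgSet`, regresses transformed chronological
#' age on the CpG betas with [fitElasticNet()], and packages the nonzero
#' coefficients, intercept, transform, per-CpG training means and provenance
#' as a [ClockModel-class]. Training samples are internally ordered by sample
#' ID so the fit does not depend on input column order.
#'
#' @param beta a [BetaSet-class] (or beta matrix with `samples` given).
#' @param cpgSet character vector of candidate CpG IDs (must intersect the
#'   panel).
#' @param name clock name recorded in the model.
#' @param samples sample sheet with `age` (defaults to `colData`).
#' @param transform age transform kind (see [transformAge()]).
#' @param adultAge horvath transform knot.
#' @param config an [enetConfig()]; the study's conventions are alpha 0.5
#'   for tissue-specific clocks and alpha 0.2 (more retained CpGs) for
#'   shared-CpG clocks, with lambda chosen by 10-fold CV.
#' @return A [ClockModel-class].
#' @export
trainClock <- function(beta, cpgSet, name = "clock", samples = NULL,
                       transform = "log1p", adultAge = 20,
                       config = enetConfig(alpha = 0.5)) {
  isSet <- is(beta, "BetaSet")
  b <- if (isSet) betaValues(beta) else as.matrix(beta)
  if (is.null(samples) && isSet) samples <- sampleData(beta)
  samples <- as.data.frame(samples)
  cpgSet <- intersect(cpgSet, rownames(b))
  .stopIf(length(cpgSet) == 0, "empty feature set after intersecting the panel")
  ord <- order(colnames(b))
  X <- t(b[cpgSet, ord, drop = FALSE])
  age <- samples$age[match(colnames(b), samples$sample_id)][ord]
  y <- transformAge(age, transform, adultAge)
  fit <- fitElasticNet(X, y, config)
  cf <- fit$coef[fit$coef != 0]
  ClockModel(name = name, coefficients = cf, intercept = fit$intercept,
             transform = transform, adultAge = adultAge,
             trainingMeans = colMeans(X)[names(cf)],
             provenance = list(
               tissues = paste(unique(samples$tissue), collapse = "+"),
               cpg_set_size = length(cpgSet), alpha = fit$alpha,
               lambda = fit$lambda, seed = config$seed, n = nrow(X)))
}

# internal: out-of-fold prediction engine shared by both CV schemes
.cvPredict <- function(b, samples, cpgSet, transform, adultAge, config,
                       foldOf, foldLabels) {
  preds <- rep(NA_real_, ncol(b))
  names(preds) <- colnames(b)
  models <- list()
  for (f in foldLabels) {
    holdout <- foldOf == f
    .stopIf(all(holdout), "insufficient folds: a fold holds every sample")
    trainIds <- colnames(b)[!holdout]
    cfgF <- config
    cfgF$seed <- .deriveSeed(config$seed, paste0("fold_", f))
    cfgF$nFolds <- min(cfgF$nFolds, length(trainIds))  # small training folds
    model <- trainClock(b[, trainIds, drop = FALSE], cpgSet,
                        name = paste0("fold_", f),
                        samples = samples[samples$sample_id %in% trainIds, ],
                        transform = transform, adultAge = adultAge,
                        config = cfgF)
    ph <- predictAge(model, b[, holdout, drop = FALSE])
    preds[ph$sample_id] <- ph$dnam_age
    models[[as.character(f)]] <- model
  }
  structure(data.frame(sample_id = colnames(b), dnam_age = as.numeric(preds),
                       fold = as.character(foldOf), stringsAsFactors = FALSE),
            models = models)
}

#' Leave-one-dataset-out cross-validated DNAm ages
#'
#' Every sample receives exactly one out-of-fold prediction, from a clock
#' whose training set excluded that sample's entire dataset — the scheme
#' used to measure cross-batch generalization of a clock. Fold seeds are
#' derived from the dataset label, so predictions do not depend on dataset
#' processing order.
#'
#' @inheritParams trainClock
#' @return data.frame `(sample_id, dnam_age, fold)` in input sample order,
#'   with the per-fold [ClockModel-class]s attached as attribute `"models"`.
#' @export
leaveOneDatasetOutCV <- function(beta, cpgSet, samples = NULL,
                                 transform = "log1p", adultAge = 20,
                                 config = enetConfig(alpha = 0.5)) {
  isSet <- is(beta, "BetaSet")
  b <- if (isSet) betaValues(beta) else as.matrix(beta)
  if (is.null(samples) && isSet) samples <- sampleData(beta)
  samples <- as.data.frame(samples)
  ds <- samples$dataset_id[match(colnames(b), samples$sample_id)]
  .stopIf(length(unique(ds)) < 2,
          "leave-one-dataset-out requires at least 2 distinct datasets")
  .cvPredict(b, samples, cpgSet, transform, adultAge, config,
             foldOf = ds, foldLabels = sort(unique(ds)))
}

#' k-fold cross-validated DNAm ages
#'
#' Randomly partitions samples (seeded, near-equal fold sizes) into `k`
#' folds; each sample's DNAm age comes from a clock trained with its fold
#' held out.
#'
#' @inheritParams trainClock
#' @param k number of folds (default 10; must not exceed the sample count).
#' @return As [leaveOneDatasetOutCV()].
#' @export
kFoldCV <- function(beta, cpgSet, samples = NULL, transform = "log1p",
                    adultAge = 20, config = enetConfig(alpha = 0.5), k = 10) {
  isSet <- is(beta, "BetaSet")
  b <- if (isSet) betaValues(beta) else as.matrix(beta)
  if (is.null(samples) && isSet) samples <- sampleData(beta)
  samples <- as.data.frame(samples)
  n <- ncol(b)
  .stopIf(k > n, "invalid k: more folds than samples")
  .stopIf(k < 2, "invalid k: need at least 2 folds")
  set.seed(.deriveSeed(config$seed, "kfold_assignment"))
  ids <- sort(colnames(b))           # assignment tied to sorted sample ids
  f <- sample(rep(seq_len(k), length.out = n))
  foldOf <- f[match(colnames(b), ids)]
  .cvPredict(b, samples, cpgSet, transform, adultAge, config,
             foldOf = foldOf, foldLabels = seq_len(k))
}

#' Serialize / deserialize a clock as a plain-text coefficient table
#'
#' `saveClock()` writes a header block (name, intercept, transform, adult
#' age, provenance) followed by tab-separated `cpg_id`, `coefficient` and
#' `training_mean` rows at full double precision, so that a round trip
#' preserves predictions bit for bit. `loadClock()` reads that format; it
#' also accepts foreign two-column coefficient tables provided the header
#' declares at least `intercept` (and optionally `transform`).
#'
#' @param model a [ClockModel-class].
#' @param path file path for the coefficient table.
#' @return `saveClock()` the path, invisibly; `loadClock()` a
#'   [ClockModel-class].
#' @export
saveClock <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pr <- clockProvenance(model)
  writeLines(c(
    sprintf("# name\t%s", clockName(model)),
    sprintf("# intercept\t%s", sprintf("%.17g", clockIntercept(model))),
    sprintf("# transform\t%s", ageTransformSpec(model)$kind),
    sprintf("# adult_age\t%s", sprintf("%.17g", ageTransformSpec(model)$adultAge)),
    sprintf("# provenance\t%s",
            jsonlite::toJSON(pr, auto_unbox = TRUE, digits = NA))), con)
  cf <- clockCoef(model)
  tm <- model@trainingMeans[names(cf)]
  writeLines("cpg_id\tcoefficient\ttraining_mean", con)
  writeLines(sprintf("%s\t%.17g\t%.17g", names(cf), cf,
                     ifelse(is.na(tm), NaN, tm)), con)
  invisible(path)
}

#' @rdname saveClock
#' @export
loadClock <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^# ", lines)
  kv <- do.call(rbind, strsplit(sub("^# ", "", lines[hdr]), "\t"))
  header <- stats::setNames(as.list(kv[, 2]), kv[, 1])
  .stopIf(is.null(header$intercept),
          "malformed clock: header is missing the intercept")
  body <- lines[!hdr]
  tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  .stopIf(!all(c("cpg_id", "coefficient") %in% colnames(tab)),
          "malformed clock: cpg_id and coefficient columns are required")
  .stopIf(anyDuplicated(tab$cpg_id) > 0,
          "malformed clock: duplicate cpg_id rows")
  tm <- if ("training_mean" %in% colnames(tab))
    stats::setNames(tab$training_mean, tab$cpg_id) else numeric()
  prov <- if (!is.null(header$provenance))
    jsonlite::fromJSON(header$provenance) else list()
  ClockModel(name = header$name %||% basename(path),
             coefficients = stats::setNames(tab$coefficient, tab$cpg_id),
             intercept = as.numeric(header$intercept),
             transform = header$transform %||% "identity",
             adultAge = as.numeric(header$adult_age %||% 20),
             trainingMeans = tm, provenance = as.list(prov))
}
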