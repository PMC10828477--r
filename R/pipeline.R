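#' Summarize a cohort sample sheet
#'
#' Produces a dataset-by-dataset characteristics table (n, sex counts, mean
#' age, age range, per-disease-group counts) with a final `Total` row equal
#' to the column sums / pooled statistics — the conventional cohort table of
#' a multi-dataset methylation study. Samples with missing age are counted
#' and flagged; their rows contribute NA to the mean.
#'
#' @param samples data.frame with `sample_id`, `age`, `sex`, `dataset_id`,
#'   `disease`.
#' @return data.frame of class `c("cohortSummary", "data.frame")` with one
#'   row per dataset plus `Total`.
#' @export
summarizeCohort <- function(samples) {
  samples <- as.data.frame(samples)
  if (nrow(samples) == 0)
    return(structure(data.frame(), class = c("cohortSummary", "data.frame")))
  diseases <- sort(unique(as.character(samples$disease)))
  one <- function(df, id) {
    ageOk <- !is.na(df$age)
    row <- data.frame(
      dataset_id = id, n = nrow(df),
      n_female = sum(df$sex == "F"), n_male = sum(df$sex == "M"),
      age_mean = if (all(ageOk)) mean(df$age) else
        if (any(ageOk)) NA_real_ else NA_real_,
      age_min = if (any(ageOk)) min(df$age, na.rm = TRUE) else NA_real_,
      age_max = if (any(ageOk)) max(df$age, na.rm = TRUE) else NA_real_,
      n_missing_age = sum(!ageOk), stringsAsFactors = FALSE)
    for (d in diseases) row[[d]] <- sum(df$disease == d)
    row
  }
  ids <- unique(as.character(samples$dataset_id))
  rows <- lapply(ids, function(id) one(samples[samples$dataset_id == id, ], id))
  tot <- one(samples, "Total")
  tot$age_mean <- mean(samples$age, na.rm = TRUE)
  out <- do.call(rbind, c(rows, list(tot)))
  structure(out, class = c("cohortSummary", "data.frame"))
}

#' Expand a dataset-level cohort characteristics table to per-sample rows
#'
#' Utility for working with published dataset-level cohort tables (columns
#' `dataset_id`, `n_female`, `n_male` and one count column per disease
#' group). Each dataset's rows are expanded into synthetic per-sample
#' entries: sex and disease labels exactly reproduce the printed counts,
#' while every sample is assigned the dataset's mean age (individual ages
#' are not published, so per-sample ages are placeholders — counts and
#' totals are exact, age ranges are not).
#'
#' @param counts data.frame with columns `dataset_id`, `n_female`, `n_male`,
#'   `age_mean` and disease count columns (any column not otherwise named).
#' @return per-sample data.frame `(sample_id, age, sex, dataset_id, disease)`.
#' @export
expandCohortCounts <- function(counts) {
  fixed <- c("dataset_id", "n", "n_female", "n_male", "age_mean", "age_min",
             "age_max")
  diseaseCols <- setdiff(colnames(counts), fixed)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    n <- r$n_female + r$n_male
    dis <- unlist(lapply(diseaseCols, function(d)
      rep(d, as.integer(r[[d]]))))
    .stopIf(length(dis) != n,
            "disease counts do not sum to the sample count in ", r$dataset_id)
    data.frame(sample_id = sprintf("%s_%03d", r$dataset_id, seq_len(n)),
               age = r$age_mean,
               sex = rep(c("F", "M"), c(r$n_female, r$n_male)),
               dataset_id = r$dataset_id, disease = dis,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.knownConfigKeys <- list(
  top = c("seed", "outdir", "stages", "simulation", "qc", "ewas", "clocks",
          "rates"),
  simulation = c("nSubjects", "nDatasets", "noiseSd", "batchSd",
                 "diseaseEffect", "cpgCounts", "effectRatio", "deltaA",
                 "fracPositiveShared"),
  qc = c("densityThreshold"),
  ewas = c("threshold", "covariates"),
  clocks = c("alphaSpecific", "alphaCommon", "transform", "nFolds"),
  rates = c("transform", "selfCV"))

#' Read and validate a pipeline run configuration
#'
#' Accepts a YAML/JSON file path or an R list. Unknown keys are rejected by
#' name; omitted keys fall back to the documented defaults. `seed` is
#' mandatory: every random stage derives its own seed deterministically from
#' it.
#'
#' @param config list or path to a YAML (or JSON) config file.
#' @return validated config list with defaults filled in.
#' @export
readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  .stopIf(!is.list(config), "config must be a list or a YAML file path")
  checkKeys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    .stopIf(length(bad) > 0,
            sprintf("unknown config key%s in %s: %s",
                    if (length(bad) > 1) "s" else "", where,
                    paste(bad, collapse = ", ")))
  }
  checkKeys(config, .knownConfigKeys$top, "top level")
  for (sec in c("simulation", "qc", "ewas", "clocks", "rates"))
    if (!is.null(config[[sec]]))
      checkKeys(config[[sec]], .knownConfigKeys[[sec]], sec)
  .stopIf(is.null(config$seed), "config must provide a seed")
  defaults <- list(
    stages = c("simulate", "qc", "ewas", "partition", "train", "rates"),
    qc = list(densityThreshold = 0.5),
    ewas = list(threshold = 0.01, covariates = c("sex", "dataset_id", "disease")),
    clocks = list(alphaSpecific = 0.5, alphaCommon = 0.2,
                  transform = "log1p", nFolds = 10),
    rates = list(transform = "identity", selfCV = "loco"),
    simulation = list())
  for (k in setdiff(names(defaults), "stages"))
    config[[k]] <- utils::modifyList(defaults[[k]],
                                     as.list(config[[k]] %||% list()))
  if (is.null(config$stages) || length(config$stages) == 0)
    config$stages <- defaults$stages
  config$stages <- unlist(config$stages)
  config$ewas$covariates <- unlist(config$ewas$covariates)
  config
}

#' Run the full simulate-to-rates workflow
#'
#' Executes the study workflow end to end on a simulated paired-tissue
#' cohort: simulate, sample QC and probe filtering, per-tissue age EWAS,
#' partition of significant CpGs, clock training (a tissue-specific clock on
#' tissue A's significant CpGs at alpha 0.5, and shared-CpG clocks at alpha
#' 0.2), and the reciprocal ageing-rate comparison. All tables are written as
#' deterministic TSVs plus a JSON manifest (package version, seed, config
#' echo, output checksums); re-running the same config reproduces the output
#' byte for byte.
#'
#' @param config list or YAML path, see [readRunConfig()].
#' @return the output directory path, invisibly; the run's key objects are
#'   attached as attribute `"results"`.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  outdir <- cfg$outdir %||% tempfile("methylRate_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(outdir, "run.log")
  logmsg <- function(...) cat(sprintf(...), "\n", sep = "", file = log,
                              append = TRUE)
  cat("", file = log)
  stage <- function(name, expr) {
    logmsg("[stage %s] start", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  res <- list()

  sim <- cfg$simulation
  simArgs <- list(seed = .deriveSeed(cfg$seed, "simulate"))
  for (k in c("nSubjects", "nDatasets", "noiseSd", "batchSd", "diseaseEffect"))
    if (!is.null(sim[[k]])) simArgs[[k]] <- sim[[k]]
  if (!is.null(sim$cpgCounts)) {
    cc <- unlist(sim$cpgCounts)
    simArgs$cpgCounts <- stats::setNames(as.integer(cc), names(cc))
  }
  scfg <- do.call(simulationConfig, simArgs)
  if (!is.null(sim$effectRatio))
    scfg@effectModel$effectRatio <- sim$effectRatio
  if (!is.null(sim$fracPositiveShared))
    scfg@effectModel$fracPositive[["shared_age"]] <- sim$fracPositiveShared
  if (!is.null(sim$deltaA)) scfg@baselineModel$deltaA <- sim$deltaA
  study <- stage("simulate", generateCohort(scfg))
  res$study <- study
  writeStudy(study, file.path(outdir, "study"))
  .writeTsv(summarizeCohort(sampleData(tissueA(study))),
            file.path(outdir, "cohort_summary.tsv"))

  if ("qc" %in% cfg$stages) {
    study <- stage("qc", {
      qa <- qcFilter(tissueA(study), densityThreshold = cfg$qc$densityThreshold)
      qb <- qcFilter(tissueB(study), densityThreshold = cfg$qc$densityThreshold)
      keep <- intersect(colnames(qa$beta), colnames(qb$beta))
      .writeTsv(qa$report$perSample, file.path(outdir, "qc_report.tsv"))
      logmsg("QC: retained %d of %d samples", length(keep),
             ncol(tissueA(study)))
      fa <- filterProbes(qa$beta[, keep])
      fb <- filterProbes(qb$beta[, keep])
      tr <- simTruth(study)
      PairedTissueStudy(fa, fb,
                        truth = if (nrow(tr)) tr[rownames(fa), ] else NULL,
                        labels = tissueLabels(study))
    })
    res$study <- study
  }

  resA <- resB <- NULL
  if ("ewas" %in% cfg$stages) {
    resA <- stage("ewas", fitAgeEwas(tissueA(study),
                                     covariates = cfg$ewas$covariates,
                                     threshold = cfg$ewas$threshold))
    resB <- fitAgeEwas(tissueB(study), covariates = cfg$ewas$covariates,
                       threshold = cfg$ewas$threshold)
    .writeTsv(ewasTable(resA), file.path(outdir, "ewas_A.tsv"))
    .writeTsv(ewasTable(resB), file.path(outdir, "ewas_B.tsv"))
    res$ewas <- list(A = resA, B = resB)
    logmsg("EWAS: %d significant in %s, %d in %s",
           length(significantCpgs(resA)), tissueLabels(study)[1],
           length(significantCpgs(resB)), tissueLabels(study)[2])
  }

  part <- NULL
  if ("partition" %in% cfg$stages && !is.null(resA)) {
    part <- stage("partition", partitionCpgs(resA, resB))
    res$partition <- part
    writeLines(part$A_only, file.path(outdir, "cpgs_A_only.txt"))
    writeLines(part$shared, file.path(outdir, "cpgs_shared.txt"))
    writeLines(part$B_only, file.path(outdir, "cpgs_B_only.txt"))
    .writeTsv(data.frame(set = c("A_only", "shared", "B_only"),
                         n = c(length(part$A_only), length(part$shared),
                               length(part$B_only))),
              file.path(outdir, "partition_summary.tsv"))
  }

  if ("train" %in% cfg$stages && !is.null(resA)) {
    clocks <- stage("train", {
      sigA <- significantCpgs(resA)
      specific <- if (length(sigA) >= 2)
        trainClock(tissueA(study), sigA, name = "tissueA_specific",
                   transform = cfg$clocks$transform,
                   config = enetConfig(alpha = cfg$clocks$alphaSpecific,
                                       nFolds = cfg$clocks$nFolds,
                                       seed = .deriveSeed(cfg$seed, "train_specific")))
      else NULL
      common <- if (!is.null(part) && length(part$shared) >= 2)
        trainClock(tissueA(study), part$shared, name = "tissueA_common",
                   transform = cfg$clocks$transform,
                   config = enetConfig(alpha = cfg$clocks$alphaCommon,
                                       nFolds = cfg$clocks$nFolds,
                                       seed = .deriveSeed(cfg$seed, "train_common")))
      else NULL
      list(specific = specific, common = common)
    })
    res$clocks <- clocks
    if (!is.null(clocks$specific))
      saveClock(clocks$specific, file.path(outdir, "clock_specific.tsv"))
    if (!is.null(clocks$common))
      saveClock(clocks$common, file.path(outdir, "clock_common.tsv"))
  }

  if ("rates" %in% cfg$stages && !is.null(part) && length(part$shared) >= 2) {
    rc <- stage("rates", compareRates(
      study, part$shared, transform = cfg$rates$transform,
      config = enetConfig(alpha = cfg$clocks$alphaCommon,
                          nFolds = cfg$clocks$nFolds,
                          seed = .deriveSeed(cfg$seed, "rates")),
      selfCV = cfg$rates$selfCV))
    res$rates <- rc
    .writeTsv(data.frame(direction = c("A_to_B", "B_to_A"),
                         slope = as.numeric(rc$slopes),
                         intercept = as.numeric(rc$intercepts),
                         r = as.numeric(rc$r)),
              file.path(outdir, "rate_comparison.tsv"))
    logmsg("rates: slope A->B %.3f, B->A %.3f, slower=%s",
           rc$slopes["A_to_B"], rc$slopes["B_to_A"],
           rc$verdict$slower %||% "inconsistent")
  }

  cfgPath <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  outs <- setdiff(list.files(outdir, recursive = TRUE, full.names = TRUE),
                  file.path(outdir, "manifest.json"))
  manifest <- list(
    package = "methylRate",
    version = as.character(utils::packageVersion("methylRate")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfgPath)),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outs)),
                                      basename(outs))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(outdir, "results") <- res
  invisible(outdir)
}
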