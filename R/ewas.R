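#' Per-CpG covariate-adjusted age regression
#'
#' Fits, for every CpG, the ordinary least squares model
#' `beta ~ age + covariates` (categorical covariates dummy-coded with the
#' first observed level as reference), and tests the age coefficient with a
#' two-sided Student's t test on `n - p` residual degrees of freedom.
#' P-values are Bonferroni-adjusted via [adjustPvalues()]; a CpG is called
#' significant when its adjusted p-value is at or below `threshold`.
#' CpGs with zero residual variance have undefined t statistics and are
#' reported with `p = NA`, excluded from the significance count.
#'
#' @param beta a [BetaSet-class] or beta matrix (CpGs x samples).
#' @param samples sample sheet (defaults to the `colData` of `beta`); must
#'   contain `age` and any requested covariate columns.
#' @param covariates character vector of covariate column names (default
#'   `c("sex", "dataset_id", "disease")`; use `character()` for age only).
#' @param threshold adjusted-p significance cutoff (default 0.01).
#' @param tissue tissue label recorded in the result.
#' @return An [EwasResult-class].
#' @examples
#' study <- generateCohort(simulationConfig(
#'   nSubjects = 60, seed = 3,
#'   cpgCounts = c(shared_age = 5, tissueA_only = 5, tissueB_only = 5,
#'                 null = 30, sex_linked = 0)))
#' res <- fitAgeEwas(tissueA(study))
#' res
#' @export
fitAgeEwas <- function(beta, samples = NULL,
                       covariates = c("sex", "dataset_id", "disease"),
                       threshold = 0.01, tissue = NULL) {
  isSet <- is(beta, "BetaSet")
  b <- if (isSet) betaValues(beta) else as.matrix(beta)
  if (is.null(samples) && isSet) samples <- sampleData(beta)
  samples <- as.data.frame(samples)
  .stopIf(!"age" %in% colnames(samples), "sample sheet must contain 'age'")
  if (is.null(tissue))
    tissue <- if ("tissue" %in% colnames(samples))
      as.character(samples$tissue[1]) else "unknown"
  covariates <- covariates[covariates %in% colnames(samples)]
  covariates <- covariates[vapply(covariates, function(cv)
    length(unique(samples[[cv]])) > 1, TRUE)]
  fml <- stats::as.formula(paste(
    "~ age", if (length(covariates))
      paste("+", paste(covariates, collapse = " + ")) else ""))
  df0 <- samples
  for (cv in covariates)
    if (!is.numeric(df0[[cv]])) df0[[cv]] <- factor(df0[[cv]],
                                                    levels = unique(df0[[cv]]))
  X <- stats::model.matrix(fml, df0)
  n <- nrow(X); p <- ncol(X)
  .stopIf(n < p + 2, "need at least (model columns + 2) samples")
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  Y <- t(b)                     # samples x CpGs
  fit <- stats::lm.fit(X, Y)
  coefs <- fit$coefficients     # p x nCpG
  if (is.null(dim(coefs)))
    coefs <- matrix(coefs, ncol = 1, dimnames = list(names(coefs), NULL))
  res <- Y - X %*% coefs
  dfres <- n - p
  rss <- colSums(res^2)
  sigma2 <- rss / dfres
  xtxinv <- chol2inv(qr.R(qrX))[2, 2]   # variance factor of the age column
  w1 <- coefs["age", ]
  se <- sqrt(sigma2 * xtxinv)
  # residual sd below 1e-10 on the beta scale means an exact linear fit;
  # the t statistic is undefined there, not astronomically significant
  degenerate <- sqrt(sigma2) < 1e-10
  tstat <- ifelse(!degenerate & se > 0, w1 / se, NA_real_)
  pval <- 2 * stats::pt(-abs(tstat), dfres)
  padj <- adjustPvalues(pval)
  sig <- !is.na(padj) & padj <= threshold
  tb <- data.frame(cpg_id = rownames(b), effect = as.numeric(w1),
                   t = as.numeric(tstat), p = as.numeric(pval),
                   p_adj = as.numeric(padj), significant = sig,
                   stringsAsFactors = FALSE, row.names = NULL)
  new("EwasResult", table = tb, tissue = tissue,
      covariates = covariates, threshold = threshold)
}

#' Bonferroni adjustment of p-values
#'
#' `adjusted = min(1, m * p)` with `m` the number of non-NA tests; NAs
#' propagate and do not count toward `m`.
#'
#' @param p numeric vector of raw p-values in \[0, 1\] (NA allowed).
#' @param method only `"bonferroni"` is supported.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjustPvalues(c(0.001, NA, 0.5), )  # m = 2
#' @export
adjustPvalues <- function(p, method = "bonferroni") {
  method <- match.arg(method)
  ok <- !is.na(p)
  .stopIf(any(p[ok] < 0 | p[ok] > 1), "invalid input: p-values outside [0, 1]")
  m <- sum(ok)
  out <- pmin(1, m * p)
  out[!ok] <- NA_real_
  out
}

#' Partition two tissues' significant CpGs into unique and shared sets
#'
#' Set algebra on the significant CpG sets of two [EwasResult-class] objects
#' computed on a common panel. Direction tallies (gains vs. loses methylation
#' with age) come from the sign of the age effect in the tissue where the CpG
#' is significant; shared CpGs record both tissues' signs.
#'
#' @param resA,resB [EwasResult-class] objects for the two tissues.
#' @return list of class `"CpgPartition"`: sets `A_only`, `shared`, `B_only`;
#'   per-set direction tallies; `fractions` with the shared percentage of each
#'   tissue's significant set (one decimal).
#' @export
partitionCpgs <- function(resA, resB) {
  panelA <- ewasTable(resA)$cpg_id; panelB <- ewasTable(resB)$cpg_id
  .stopIf(length(intersect(panelA, panelB)) == 0,
          "panel mismatch: the two results share no CpGs")
  sigA <- significantCpgs(resA); sigB <- significantCpgs(resB)
  shared <- intersect(sigA, sigB)
  aOnly <- setdiff(sigA, shared); bOnly <- setdiff(sigB, shared)
  effA <- stats::setNames(ewasTable(resA)$effect, panelA)
  effB <- stats::setNames(ewasTable(resB)$effect, panelB)
  tally <- function(e) c(positive = sum(e > 0), negative = sum(e < 0))
  structure(list(
    A_only = aOnly, shared = shared, B_only = bOnly,
    tissues = c(resA@tissue, resB@tissue),
    direction = list(A_only = tally(effA[aOnly]),
                     B_only = tally(effB[bOnly]),
                     shared_in_A = tally(effA[shared]),
                     shared_in_B = tally(effB[shared])),
    fractions = c(
      shared_pct_of_A = round(100 * length(shared) / max(1, length(sigA)), 1),
      shared_pct_of_B = round(100 * length(shared) / max(1, length(sigB)), 1)),
    nSignificant = c(A = length(sigA), B = length(sigB))),
    class = "CpgPartition")
}

#' @export
print.CpgPartition <- function(x, ...) {
  cat(sprintf("CpG partition [%s vs %s]: %d | %d shared | %d\n",
              x$tissues[1], x$tissues[2], length(x$A_only),
              length(x$shared), length(x$B_only)))
  cat(sprintf("  shared = %.1f%% of %s significant, %.1f%% of %s significant\n",
              x$fractions["shared_pct_of_A"], x$tissues[1],
              x$fractions["shared_pct_of_B"], x$tissues[2]))
  invisible(x)
}

#' Compare age effect sizes between tissues
#'
#' Three contrasts with Bonferroni correction across them: unpaired Wilcoxon
#' rank-sum tests comparing effect sizes between the tissues' own positive
#' and (separately) negative significant CpGs, and a paired Wilcoxon
#' signed-rank test of `|effect_A|` vs `|effect_B|` over the shared CpGs.
#' Contrasts with fewer than 3 CpGs on a side are skipped with a warning.
#'
#' @param resA,resB [EwasResult-class] objects.
#' @param partition the [partitionCpgs()] output derived from the same pair.
#' @return list of class `"EffectComparison"`: per-contrast test name, raw and
#'   adjusted p, group medians; plus the per-CpG `(|w_A|, |w_B|)` pairs for
#'   the shared set.
#' @export
compareEffectSizes <- function(resA, resB, partition) {
  effA <- stats::setNames(ewasTable(resA)$effect, ewasTable(resA)$cpg_id)
  effB <- stats::setNames(ewasTable(resB)$effect, ewasTable(resB)$cpg_id)
  sigA <- significantCpgs(resA); sigB <- significantCpgs(resB)
  contrasts <- list()
  runTest <- function(name, test, x, y, paired) {
    if (length(x) < 3 || length(y) < 3) {
      warning(sprintf("contrast '%s' skipped: fewer than 3 CpGs", name))
      return(NULL)
    }
    ht <- if (paired)
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = NULL))
    else
      suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
    list(name = name, test = test, p = ht$p.value, statistic = ht$statistic,
         medians = c(A = stats::median(x), B = stats::median(y)))
  }
  posA <- effA[intersect(sigA, names(effA)[effA > 0])]
  posB <- effB[intersect(sigB, names(effB)[effB > 0])]
  negA <- effA[intersect(sigA, names(effA)[effA < 0])]
  negB <- effB[intersect(sigB, names(effB)[effB < 0])]
  contrasts$positive <- runTest("positive", "rank-sum", posA, posB, FALSE)
  contrasts$negative <- runTest("negative", "rank-sum", negA, negB, FALSE)
  sh <- partition$shared
  contrasts$shared_abs <- runTest("shared_abs", "signed-rank",
                                  abs(effA[sh]), abs(effB[sh]), TRUE)
  contrasts <- Filter(Negate(is.null), contrasts)
  praw <- vapply(contrasts, `[[`, 0, "p")
  padj <- adjustPvalues(praw)
  for (i in seq_along(contrasts)) contrasts[[i]]$p_adj <- padj[i]
  structure(list(contrasts = contrasts,
                 sharedPairs = data.frame(cpg_id = sh,
                                          abs_w_A = abs(effA[sh]),
                                          abs_w_B = abs(effB[sh]),
                                          row.names = NULL)),
            class = "EffectComparison")
}

#' @export
print.EffectComparison <- function(x, ...) {
  for (ct in x$contrasts)
    cat(sprintf("  %-11s %-11s p=%.3g  p_adj=%.3g  medians A=%.3g B=%.3g\n",
                ct$name, ct$test, ct$p, ct$p_adj,
                ct$medians["A"], ct$medians["B"]))
  invisible(x)
}

#' Summarize methylation by genomic category
#'
#' Per tissue and genomic category (island, shore, shelf, open sea): mean and
#' median beta. For a supplied CpG set, additionally reports the category
#' composition (counts and fractions), per-CpG tallies of which tissue has
#' the lower median methylation and which the larger absolute age effect
#' (simple per-CpG OLS slope of beta on age), and, as a negative control, the
#' per-category correlation between per-sample mean beta and age.
#'
#' @param study a [PairedTissueStudy-class].
#' @param cpgSet optional character vector of CpG IDs to profile.
#' @return list of class `"CategorySummary"` with elements `byCategory`,
#'   `meanBetaAgeCor`, and (when `cpgSet` is given) `composition` and
#'   `setTallies`.
#' @export
categorySummary <- function(study, cpgSet = NULL) {
  ann <- probeData(tissueA(study))
  labs <- tissueLabels(study)
  cats <- c("island", "shore", "shelf", "open_sea")
  bA <- betaValues(tissueA(study)); bB <- betaValues(tissueB(study))
  age <- sampleData(tissueA(study))$age
  byCat <- do.call(rbind, lapply(cats, function(ct) {
    i <- ann$category == ct
    do.call(rbind, lapply(list(c(labs[1], "A"), c(labs[2], "B")), function(tl) {
      b <- if (tl[2] == "A") bA else bB
      v <- b[i, , drop = FALSE]
      data.frame(tissue = tl[1], category = ct,
                 n = sum(i),
                 mean_beta = if (any(i)) mean(v) else NA_real_,
                 median_beta = if (any(i)) stats::median(v) else NA_real_)
    }))
  }))
  corTab <- do.call(rbind, lapply(cats, function(ct) {
    i <- ann$category == ct
    do.call(rbind, lapply(list(c(labs[1], "A"), c(labs[2], "B")), function(tl) {
      b <- if (tl[2] == "A") bA else bB
      if (!any(i) || length(unique(age)) < 3)
        return(data.frame(tissue = tl[1], category = ct, cor = NA_real_,
                          p = NA_real_))
      mb <- colMeans(b[i, , drop = FALSE])
      if (stats::sd(mb) == 0)
        return(data.frame(tissue = tl[1], category = ct, cor = NA_real_,
                          p = NA_real_))
      ht <- stats::cor.test(mb, age)
      data.frame(tissue = tl[1], category = ct, cor = unname(ht$estimate),
                 p = ht$p.value)
    }))
  }))
  out <- list(byCategory = byCat, meanBetaAgeCor = corTab, tissues = labs)
  if (!is.null(cpgSet)) {
    idx <- match(cpgSet, rownames(bA))
    .stopIf(anyNA(idx), "cpgSet contains CpGs absent from the panel")
    comp <- table(factor(ann$category[idx], levels = cats))
    slope1 <- function(b) {
      ac <- age - mean(age)
      as.numeric((b %*% ac) / sum(ac^2))
    }
    sA <- slope1(bA[idx, , drop = FALSE]); sB <- slope1(bB[idx, , drop = FALSE])
    medA <- apply(bA[idx, , drop = FALSE], 1, stats::median)
    medB <- apply(bB[idx, , drop = FALSE], 1, stats::median)
    out$composition <- data.frame(category = cats, n = as.integer(comp),
                                  fraction = as.numeric(comp) / length(idx))
    out$setTallies <- c(
      frac_lower_median_in_A = mean(medA < medB),
      frac_larger_abs_effect_in_A = mean(abs(sA) > abs(sB)),
      frac_positive_in_both = mean(sA > 0 & sB > 0),
      island_shore_pct = round(100 * sum(comp[c("island", "shore")]) /
                                 length(idx), 1))
  }
  structure(out, class = "CategorySummary")
}

#' @export
print.CategorySummary <- function(x, ...) {
  print(x$byCategory, row.names = FALSE)
  if (!is.null(x$setTallies)) {
    cat("CpG-set tallies:\n")
    print(round(x$setTallies, 3))
  }
  invisible(x)
}
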