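#' Elastic-net training configuration
#'
#' @param alpha L1/L2 mixing weight in \[0, 1\] (1 = lasso, 0 = ridge).
#' @param lambda penalty strength: a nonnegative number, or `"cv"` to choose
#'   it by internal cross-validation.
#' @param nFolds folds for the internal CV (default 10).
#' @param lambdaRule `"min"` (MSE-minimizing lambda, default) or `"1se"`.
#' @param weights optional nonnegative observation weights (default all 1).
#' @param penaltyFactors optional nonnegative per-predictor penalty factors
#'   (default all 1; a factor of 0 leaves that predictor unpenalized).
#' @param standardize standardize predictors internally (coefficients are
#'   always returned on the original scale); default TRUE.
#' @param nLambda,lambdaMinRatio path resolution for the CV search.
#' @param seed integer seed governing fold assignment.
#' @return list of class `"ElasticNetConfig"`.
#' @export
enetConfig <- function(alpha = 0.5, lambda = "cv", nFolds = 10,
                       lambdaRule = c("min", "1se"), weights = NULL,
                       penaltyFactors = NULL, standardize = TRUE,
                       nLambda = 60, lambdaMinRatio = NULL, seed = 1) {
  .stopIf(alpha < 0 || alpha > 1, "alpha must lie in [0, 1]")
  .stopIf(is.numeric(lambda) && any(lambda < 0), "lambda must be >= 0")
  .stopIf(!is.null(weights) && any(weights < 0), "weights must be nonnegative")
  .stopIf(!is.null(penaltyFactors) && any(penaltyFactors < 0),
          "penalty factors must be nonnegative")
  structure(list(alpha = alpha, lambda = lambda, nFolds = nFolds,
                 lambdaRule = match.arg(lambdaRule), weights = weights,
                 penaltyFactors = penaltyFactors, standardize = standardize,
                 nLambda = nLambda, lambdaMinRatio = lambdaMinRatio,
                 seed = as.integer(seed)),
            class = "ElasticNetConfig")
}

# core path solver on one (X, y); returns coefficients on the original scale.
# tol is relative to sd(y); init (original-scale coefficients) warm-starts.
.enetPath <- function(X, y, lambda, alpha, w, pf, standardize,
                      tol = 1e-10, maxit = 100000L, devStop = FALSE,
                      init = NULL) {
  n <- nrow(X); p <- ncol(X)
  W <- sum(w)
  xm <- colSums(X * w) / W
  Xc <- sweep(X, 2, xm)
  xv <- colSums(Xc^2 * w) / W
  xs <- if (standardize) ifelse(xv > 0, sqrt(xv), 1) else rep(1, p)
  Xs <- sweep(Xc, 2, xs, "/")
  ym <- sum(y * w) / W
  yc <- y - ym
  Xw <- Xs * w
  G <- crossprod(Xw, Xs) / W
  bvec <- as.numeric(crossprod(Xw, yc)) / W
  zeroVar <- xv <= 0
  if (any(zeroVar)) { G[zeroVar, ] <- 0; G[, zeroVar] <- 0; bvec[zeroVar] <- 0 }
  yvar <- sum(w * yc^2) / W
  tolAbs <- tol * max(sqrt(yvar), .Machine$double.eps)
  cinit <- if (is.null(init)) numeric(0) else as.numeric(init) * xs
  sol <- cd_enet_path(G, bvec, as.numeric(lambda), alpha, pf, tolAbs,
                      as.integer(maxit), yvar, isTRUE(devStop), cinit)
  keep <- seq_len(sol$nlam)
  cmat <- sol$coef[, keep, drop = FALSE]
  corig <- cmat / xs
  icpt <- ym - as.numeric(xm %*% corig)
  list(coef = corig, intercept = icpt, lambda = as.numeric(lambda)[keep],
       devRatio = sol$devRatio[keep], xm = xm, xs = xs)
}

.lambdaPath <- function(X, y, alpha, w, pf, standardize, nLambda,
                        lambdaMinRatio) {
  n <- nrow(X); W <- sum(w)
  xm <- colSums(X * w) / W
  Xc <- sweep(X, 2, xm)
  xv <- colSums(Xc^2 * w) / W
  xs <- if (standardize) ifelse(xv > 0, sqrt(xv), 1) else rep(1, ncol(X))
  Xs <- sweep(Xc, 2, xs, "/")
  yc <- y - sum(y * w) / W
  b <- abs(as.numeric(crossprod(Xs * w, yc))) / W
  pf1 <- ifelse(pf > 0, pf, Inf)
  lmax <- max(b / (max(alpha, 1e-3) * pf1), na.rm = TRUE)
  if (!is.finite(lmax) || lmax <= 0) return(c(1e-4, 0))
  if (is.null(lambdaMinRatio))
    lambdaMinRatio <- if (nrow(X) < ncol(X)) 1e-2 else 1e-4
  exp(seq(log(lmax), log(lmax * lambdaMinRatio), length.out = nLambda))
}

#' Fit a weighted elastic-net linear model
#'
#' Minimizes the standard weighted elastic-net objective
#' \deqn{\frac{1}{2W}\sum_i w_i (y_i - c_0 - x_i^\top c)^2 +
#'       \lambda \sum_j \gamma_j \left[\frac{(1-\alpha)}{2} c_j^2 +
#'       \alpha |c_j|\right]}
#' (with `W = sum(w)`, so unit weights give the usual `1/(2n)` scaling) by
#' cyclic coordinate descent with covariance updates and warm starts on a
#' decreasing lambda path. When `lambda = "cv"` the penalty is chosen to
#' minimize the cross-validated mean squared error over seeded folds
#' (`lambdaRule = "1se"` picks the largest lambda within one standard error
#' of the minimum). Constant predictors receive a coefficient of exactly 0.
#'
#' @param X numeric predictor matrix (observations x predictors, no NAs).
#' @param y numeric response vector.
#' @param config an [enetConfig()] list.
#' @return list of class `"enetFit"`: named `coef`, `intercept`, `alpha`,
#'   chosen `lambda`, `lambdaPath`, `coefPath` (original scale), `df`
#'   (nonzero count per path point), and for CV fits `cv` (cvm, cvsd,
#'   lambdaMin, lambda1se, foldid).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 50, 4); y <- X[, 1] - 2 * X[, 2] + rnorm(50, 0, .1)
#' fit <- fitElasticNet(X, y, enetConfig(alpha = 1, lambda = 0.05))
#' fit$coef
#' @export
fitElasticNet <- function(X, y, config = enetConfig()) {
  X <- as.matrix(X)
  .stopIf(anyNA(X) || anyNA(y), "missing values are not allowed")
  n <- nrow(X); p <- ncol(X)
  .stopIf(n < 2 || p < 1, "need n >= 2 observations and p >= 1 predictors")
  .stopIf(length(y) != n, "length(y) must equal nrow(X)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  w <- config$weights %||% rep(1, n)
  pf <- config$penaltyFactors %||% rep(1, p)
  .stopIf(length(w) != n, "weights must have one entry per observation")
  .stopIf(length(pf) != p, "penaltyFactors must have one entry per predictor")
  std <- isTRUE(config$standardize)
  alpha <- config$alpha

  if (identical(config$lambda, "cv")) {
    path0 <- .lambdaPath(X, y, alpha, w, pf, std, config$nLambda,
                         config$lambdaMinRatio)
    # full-data fit first; the deviance-saturation stop truncates the path
    # before the flat small-lambda tail (where CV cannot discriminate anyway).
    # Path and fold fits run at a light tolerance -- they only rank lambdas;
    # the chosen lambda is then polished to full precision from a warm start.
    full <- .enetPath(X, y, path0, alpha, w, pf, std, tol = 1e-5,
                      devStop = TRUE)
    path <- full$lambda
    k <- config$nFolds
    .stopIf(k < 2 || k > n, "invalid number of CV folds")
    set.seed(config$seed)
    foldid <- sample(rep(seq_len(k), length.out = n))
    errs <- matrix(NA_real_, k, length(path))
    for (f in seq_len(k)) {
      tr <- foldid != f
      # fold fits only rank lambdas by out-of-fold MSE; a lighter tolerance
      # than the final fit is ample for that
      fitf <- .enetPath(X[tr, , drop = FALSE], y[tr], path, alpha, w[tr], pf,
                        std, tol = 1e-5)
      pred <- sweep(X[!tr, , drop = FALSE] %*% fitf$coef, 2,
                    fitf$intercept, "+")
      errs[f, ] <- colMeans((pred - y[!tr])^2)
    }
    cvm <- colMeans(errs)
    cvsd <- apply(errs, 2, stats::sd) / sqrt(k)
    iMin <- which.min(cvm)
    i1se <- min(which(cvm <= cvm[iMin] + cvsd[iMin]))
    chosen <- if (config$lambdaRule == "1se") path[i1se] else path[iMin]
    iPick <- if (config$lambdaRule == "1se") i1se else iMin
    fine <- .enetPath(X, y, chosen, alpha, w, pf, std, tol = 1e-10,
                      init = full$coef[, iPick])
    cf <- stats::setNames(fine$coef[, 1], colnames(X))
    out <- list(coef = cf, intercept = fine$intercept[1], alpha = alpha,
                lambda = chosen, lambdaPath = path, coefPath = full$coef,
                df = colSums(full$coef != 0),
                cv = list(cvm = cvm, cvsd = cvsd, lambdaMin = path[iMin],
                          lambda1se = path[i1se], foldid = foldid))
  } else {
    lam <- config$lambda
    warm <- .lambdaPath(X, y, alpha, w, pf, std, 20, NULL)
    path <- c(warm[warm > lam], lam)
    rough <- .enetPath(X, y, path, alpha, w, pf, std, tol = 1e-5)
    fine <- .enetPath(X, y, lam, alpha, w, pf, std, tol = 1e-10,
                      init = rough$coef[, length(path)])
    cf <- stats::setNames(fine$coef[, 1], colnames(X))
    out <- list(coef = cf, intercept = fine$intercept[1], alpha = alpha,
                lambda = lam, lambdaPath = path, coefPath = rough$coef,
                df = colSums(rough$coef != 0), cv = NULL)
  }
  out$pf <- pf; out$weights <- w; out$standardize <- std
  class(out) <- "enetFit"
  out
}

#' @export
print.enetFit <- function(x, ...) {
  cat(sprintf("elastic-net fit: alpha=%.2f, lambda=%.4g, %d/%d nonzero\n",
              x$alpha, x$lambda, sum(x$coef != 0), length(x$coef)))
  invisible(x)
}

#' @export
predict.enetFit <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata)[, names(object$coef), drop = FALSE] %*%
               object$coef + object$intercept)
}

#' KKT residuals of an elastic-net solution
#'
#' Verifies the stationarity (subgradient) conditions of the elastic-net
#' objective at a fitted solution, on the same internally standardized scale
#' the solver works on. For active coefficients the condition is
#' `gradient + lambda*alpha*gamma*sign(c) = 0`; for zero coefficients
#' `|gradient| <= lambda*alpha*gamma`. Returns the largest violation, which
#' is ~0 at an exact solution.
#'
#' @param fit an `"enetFit"` object.
#' @param X,y the training data the fit was produced from.
#' @return Maximum KKT violation (a nonnegative scalar).
#' @export
enetKKT <- function(fit, X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  w <- fit$weights; pf <- fit$pf; W <- sum(w)
  xm <- colSums(X * w) / W
  Xc <- sweep(X, 2, xm)
  xv <- colSums(Xc^2 * w) / W
  xs <- if (fit$standardize) ifelse(xv > 0, sqrt(xv), 1) else rep(1, p)
  Xs <- sweep(Xc, 2, xs, "/")
  ym <- sum(y * w) / W
  yc <- y - ym
  cstd <- fit$coef * xs
  r <- yc - as.numeric(Xs %*% cstd)
  grad <- -as.numeric(crossprod(Xs * w, r)) / W +
    fit$lambda * (1 - fit$alpha) * pf * cstd
  lamA <- fit$lambda * fit$alpha * pf
  active <- cstd != 0 & xv > 0
  viol <- numeric(p)
  viol[active] <- abs(grad[active] + lamA[active] * sign(cstd[active]))
  viol[!active] <- pmax(0, abs(grad[!active]) - lamA[!active])
  viol[xv <= 0] <- 0
  max(c(0, viol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
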