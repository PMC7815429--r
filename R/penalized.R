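#' Penalized-GLM configuration
#'
#' Settings for the shared elastic-net fitting engine: the candidate alpha
#' grid searched by cross-validation, the lambda path, fold count and
#' family. Penalty factors are supplied per fit (0 = unpenalized, 1 =
#' penalized).
#'
#' @param family "gaussian", "binomial" or "poisson"
#' @param alphaGrid elastic-net mixing values searched by [cvSelect()]
#' @param nLambda number of lambda path points
#' @param lambdaMinRatio smallest lambda as a fraction of the
#'   all-coefficients-zero lambda
#' @param nFolds cross-validation folds (default 20)
#' @param intercept fit an intercept (default TRUE)
#' @return list of class "PenaltyConfig"
#' @export
penaltyConfig <- function(family = c("gaussian", "binomial", "poisson"),
                          alphaGrid = c(0.1, 0.25, 0.5, 0.75, 0.95, 1.0),
                          nLambda = 100, lambdaMinRatio = 1e-4,
                          nFolds = 20, intercept = TRUE) {
  family <- match.arg(family)
  stopifnot(all(alphaGrid >= 0 & alphaGrid <= 1), nLambda >= 2,
            lambdaMinRatio > 0, lambdaMinRatio < 1, nFolds >= 2)
  structure(list(family = family, alphaGrid = alphaGrid, nLambda = nLambda,
                 lambdaMinRatio = lambdaMinRatio,
                 nFolds = as.integer(nFolds), intercept = intercept),
            class = "PenaltyConfig")
}

# Standardize predictors: centre (when an intercept is fitted) and scale to
# unit population SD so the penalty treats coefficients comparably.
# Constant columns keep scale 1.
standardizeDesign <- function(X, center = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  ctr <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2L, ctr)
  scl <- sqrt(colMeans(Xc^2))
  scl[scl <= 0 | !is.finite(scl)] <- 1
  list(X = sweep(Xc, 2L, scl, "/"),
       center = stats::setNames(ctr, colnames(X)),
       scale = stats::setNames(scl, colnames(X)))
}

# glmnet rescales penalty factors to sum to nvars; apply the same rescaling
# so stored factors match the objective actually minimized.
effectivePenaltyFactors <- function(pf) {
  pf * length(pf) / sum(pf)
}

# glmnet's fast "gaussian" code path rescales the ridge component of the
# penalty by sd(y) (a side effect of its internal response
# standardization), so the minimized objective is not the stated one when
# alpha < 1. The family-object route solves the exact objective; gaussian
# fits go through it.
glmnetFamily <- function(family) {
  if (family == "gaussian") stats::gaussian() else family
}

# A response with no variation carries no information about any
# coefficient: every penalized and unpenalized slope is 0 and the intercept
# is the (clamped) mean link.
constantResponseFit <- function(X, y, family, alpha, lambda, pf, std,
                                intercept) {
  mu <- mean(y)
  a0 <- if (!intercept) 0
        else switch(family,
                    gaussian = mu,
                    binomial = stats::qlogis(min(max(mu, 1e-10), 1 - 1e-10)),
                    poisson = log(max(mu, 1e-10)))
  zero <- stats::setNames(numeric(ncol(X)), colnames(std$X))
  new("PenalizedFit", family = family, alpha = alpha, lambda = lambda,
      coefficients = zero, intercept = a0,
      penaltyFactors = stats::setNames(pf, colnames(std$X)),
      betaStd = zero, interceptStd = a0,
      center = std$center, scale = std$scale, cv = list(),
      converged = TRUE)
}

buildPenalizedFit <- function(glmnetFit, s, std, pf, family, alpha,
                              intercept, cv = list()) {
  beta <- as.numeric(glmnet::coef.glmnet(glmnetFit, s = s, exact = FALSE))
  nms <- rownames(glmnet::coef.glmnet(glmnetFit, s = s))
  a0Std <- beta[1L]
  betaStd <- stats::setNames(beta[-1L], nms[-1L])
  betaOrig <- betaStd / std$scale
  a0Orig <- a0Std - sum(betaStd * std$center / std$scale)
  new("PenalizedFit",
      family = family, alpha = alpha, lambda = s,
      coefficients = betaOrig, intercept = if (intercept) a0Orig else 0,
      penaltyFactors = stats::setNames(pf, names(betaStd)),
      betaStd = betaStd, interceptStd = a0Std,
      center = std$center, scale = std$scale,
      cv = cv, converged = TRUE)
}

#' Fit an elastic-net penalized GLM at a fixed (alpha, lambda)
#'
#' Minimizes \code{(negative log-likelihood)/n +
#' lambda * sum_j pf_j (alpha |b_j| + (1-alpha) b_j^2 / 2)} over
#' coefficients on internally standardized predictors; coefficients are
#' reported back on the original scale. Coefficients with penalty factor 0
#' (and the intercept) are never shrunk. Deterministic given its inputs.
#'
#' @param X numeric design matrix (finite)
#' @param y response: numeric for gaussian, 0/1 for binomial, non-negative
#'   counts for poisson
#' @param family model family
#' @param alpha elastic-net mixing in [0, 1] (1 = lasso)
#' @param lambda regularization strength (0 = unpenalized fit)
#' @param penaltyFactors per-column factors, typically 0/1; default all 1
#' @param offset optional per-observation offset on the linear-predictor
#'   scale
#' @param intercept fit an intercept (default TRUE; set FALSE for models
#'   defined without one, in which case predictors are scaled but not
#'   centred)
#' @return a [PenalizedFit-class]
#' @export
fitPenalizedGLM <- function(X, y,
                            family = c("gaussian", "binomial", "poisson"),
                            alpha = 1, lambda,
                            penaltyFactors = rep(1, ncol(X)),
                            offset = NULL, intercept = TRUE) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("design matrix must be finite")
  stopifnot(length(y) == nrow(X), lambda >= 0, alpha >= 0, alpha <= 1,
            length(penaltyFactors) == ncol(X))
  if (sum(penaltyFactors) <= 0) stop("at least one penalized coefficient")
  std <- standardizeDesign(X, center = intercept)
  if (stats::var(y) == 0)
    return(constantResponseFit(X, y, family, alpha, lambda,
                               penaltyFactors, std, intercept))
  pfEff <- effectivePenaltyFactors(penaltyFactors)

  probe <- glmnet::glmnet(std$X, y, family = glmnetFamily(family),
                          alpha = max(alpha, 0.01),
                          penalty.factor = pfEff, offset = offset,
                          standardize = FALSE, intercept = intercept,
                          nlambda = 5)
  lambdaMax <- probe$lambda[1L]
  hi <- max(lambdaMax, lambda * 2, 1e-3)
  lo <- max(lambda, hi * 1e-6)
  path <- hi * (lo / hi)^(seq(0, 1, length.out = 30))
  # keep the exact requested lambda and drop near-duplicate knots, which
  # destabilize glmnet's warm starts
  path <- sort(c(path[abs(path - lambda) > 1e-6 * max(lambda, 1e-12)],
                 lambda), decreasing = TRUE)
  if (lambda == 0) path <- c(path[path > 0], 0)

  # disable glmnet's early path stopping so the requested lambda is always
  # an exact knot (coef(s = .) would otherwise extrapolate)
  oldFdev <- glmnet::glmnet.control()$fdev
  glmnet::glmnet.control(fdev = 0)
  on.exit(glmnet::glmnet.control(fdev = oldFdev), add = TRUE)

  fit <- glmnet::glmnet(std$X, y, family = glmnetFamily(family),
                        alpha = alpha,
                        lambda = path, penalty.factor = pfEff,
                        offset = offset, standardize = FALSE,
                        intercept = intercept, thresh = 1e-12,
                        maxit = 10^6)
  idx <- which.min(abs(fit$lambda - lambda))
  if (abs(fit$lambda[idx] - lambda) > 1e-9 * max(1, lambda))
    stop("requested lambda missing from the fitted path")
  buildPenalizedFit(fit, fit$lambda[idx], std, penaltyFactors, family,
                    alpha, intercept)
}

#' Select (alpha, lambda_1SE) by cross-validation and refit
#'
#' Grid search over the configured alpha values with a common seeded fold
#' assignment (stratified by class for binomial responses). For each alpha
#' the CV deviance curve is computed along that alpha's lambda path; the
#' winning alpha minimizes the CV deviance (ties resolved toward the larger,
#' sparser alpha), and lambda_1SE is the largest lambda whose CV deviance
#' lies within one standard error of the minimum. The returned fit is on
#' the full data at (alpha*, lambda_1SE). Fold assignment draws from the
#' session RNG: call [set.seed()] beforehand for reproducibility.
#'
#' @param X,y design and response, as in [fitPenalizedGLM()]
#' @param config a [penaltyConfig()]
#' @param penaltyFactors per-column factors (0 = unpenalized)
#' @param offset optional linear-predictor offset
#' @param foldid optional explicit fold assignment (overrides the seeded
#'   draw)
#' @return a [PenalizedFit-class] with CV diagnostics in its \code{cv} slot
#' @export
cvSelect <- function(X, y, config, penaltyFactors = rep(1, ncol(X)),
                     offset = NULL, foldid = NULL) {
  stopifnot(inherits(config, "PenaltyConfig"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("design matrix must be finite")
  n <- nrow(X)
  if (n < config$nFolds)
    stop("fewer observations (", n, ") than folds (", config$nFolds, ")")
  if (sum(penaltyFactors) <= 0)
    stop("lambda selection requires at least one penalized coefficient")
  if (stats::var(y) == 0) {
    std0 <- standardizeDesign(X, center = config$intercept)
    return(constantResponseFit(X, y, config$family, config$alphaGrid[1],
                               Inf, penaltyFactors, std0,
                               config$intercept))
  }
  if (is.null(foldid)) {
    foldid <- integer(n)
    if (config$family == "binomial") {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        foldid[idx] <- sample(rep_len(seq_len(config$nFolds), length(idx)))
      }
    } else {
      foldid <- sample(rep_len(seq_len(config$nFolds), n))
    }
  }
  std <- standardizeDesign(X, center = config$intercept)
  pfEff <- effectivePenaltyFactors(penaltyFactors)

  # selection runs on glmnet's fast family code paths; the returned model
  # is then refit at (alpha*, lambda_1SE) through the exact-objective route
  cvFits <- lapply(config$alphaGrid, function(a) {
    glmnet::cv.glmnet(std$X, y, family = config$family, alpha = a,
                      foldid = foldid, penalty.factor = pfEff,
                      offset = offset, standardize = FALSE,
                      intercept = config$intercept,
                      nlambda = config$nLambda,
                      lambda.min.ratio = config$lambdaMinRatio,
                      thresh = 1e-10, maxit = 10^6)
  })
  cvmMin <- vapply(cvFits, function(f) min(f$cvm), numeric(1))
  best <- which(cvmMin <= min(cvmMin) + 0)
  best <- best[which.max(config$alphaGrid[best])]
  cvBest <- cvFits[[best]]
  alphaStar <- config$alphaGrid[best]
  lambda1se <- cvBest$lambda.1se

  cv <- list(alphaGrid = config$alphaGrid, cvmMinByAlpha = cvmMin,
             alpha = alphaStar, lambda = cvBest$lambda, cvm = cvBest$cvm,
             cvsd = cvBest$cvsd, lambda1se = lambda1se,
             lambdaMin = cvBest$lambda.min, nFolds = config$nFolds)
  if (lambda1se >= max(cvBest$lambda)) {
    # the 1SE rule picked the head of the path: the model with every
    # penalized coefficient exactly zero. glmnet's own path head carries
    # that solution exactly (and with no active penalized coefficients the
    # penalty plays no role in the remaining IRLS problem).
    return(buildPenalizedFit(cvBest$glmnet.fit, lambda1se, std,
                             penaltyFactors, config$family, alphaStar,
                             config$intercept, cv = cv))
  }
  # otherwise refit on the full data along the CV fit's own lambda path
  # truncated at lambda_1SE, with a tight threshold; the gaussian case goes
  # through the exact-objective family-object route
  path <- cvBest$lambda[cvBest$lambda >= lambda1se]
  oldFdev <- glmnet::glmnet.control()$fdev
  glmnet::glmnet.control(fdev = 0)
  on.exit(glmnet::glmnet.control(fdev = oldFdev), add = TRUE)
  refit <- glmnet::glmnet(std$X, y, family = glmnetFamily(config$family),
                          alpha = alphaStar, lambda = path,
                          penalty.factor = pfEff, offset = offset,
                          standardize = FALSE, intercept = config$intercept,
                          thresh = 1e-12, maxit = 10^6)
  idx <- which.min(abs(refit$lambda - lambda1se))
  buildPenalizedFit(refit, refit$lambda[idx], std, penaltyFactors,
                    config$family, alphaStar, config$intercept, cv = cv)
}

#' Verify Karush-Kuhn-Tucker conditions of a penalized fit
#'
#' Checks the subgradient optimality conditions of the elastic-net
#' objective at the returned solution, on the standardized scale on which
#' the penalty applies: unpenalized coefficients (and the intercept) must
#' have zero gradient; zero penalized coefficients must have gradient
#' magnitude at most lambda * alpha * pf; nonzero penalized coefficients
#' must satisfy gradient + lambda * pf * (alpha * sign(b) + (1 - alpha) b)
#' = 0.
#'
#' @param fit a [PenalizedFit-class]
#' @param X,y the data the fit was computed from
#' @param offset the offset used in the fit, if any
#' @return maximum absolute KKT violation across coefficients
#' @export
kktCheck <- function(fit, X, y, offset = NULL) {
  stopifnot(is(fit, "PenalizedFit"))
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2L, fit@center), 2L, fit@scale, "/")
  n <- nrow(Xs)
  eta <- drop(Xs %*% fit@betaStd) + fit@interceptStd
  if (!is.null(offset)) eta <- eta + offset
  mu <- switch(fit@family,
               gaussian = eta,
               binomial = stats::plogis(eta),
               poisson = exp(eta))
  g <- -drop(crossprod(Xs, y - mu)) / n
  lam <- fit@lambda
  pfEff <- effectivePenaltyFactors(fit@penaltyFactors)
  b <- fit@betaStd
  viol <- numeric(length(b))
  pen <- pfEff > 0
  zero <- pen & b == 0
  viol[zero] <- pmax(abs(g[zero]) - lam * fit@alpha * pfEff[zero], 0)
  nz <- pen & b != 0
  viol[nz] <- abs(g[nz] + lam * pfEff[nz] *
                    (fit@alpha * sign(b[nz]) + (1 - fit@alpha) * b[nz]))
  viol[!pen] <- abs(g[!pen])
  v <- max(0, viol)
  if (fit@interceptStd != 0)
    v <- max(v, abs(mean(y - mu)))
  v
}

#' Permutation false-discovery check for a penalized model
#'
#' Re-fits the cross-validated model after randomly permuting the rows of
#' the penalized columns of the design (breaking their alignment with the
#' response while preserving the unpenalized structure and any offset), and
#' counts nonzero penalized coefficients per permutation. On data with no
#' real structure the one-standard-error rule should select the empty
#' model, so discoveries under permutation estimate the false-discovery
#' behaviour of the full procedure.
#'
#' @param X,y design and response
#' @param config a [penaltyConfig()]
#' @param penaltyFactors per-column factors (0 = unpenalized)
#' @param nPerms number of permutations (>= 1)
#' @param offset optional linear-predictor offset (preserved, not permuted)
#' @return list: \code{counts} (nonzero penalized coefficients per
#'   permutation), \code{anyDiscovery} (fraction of permutations with any)
#' @export
permutationNullFit <- function(X, y, config,
                               penaltyFactors = rep(1, ncol(X)),
                               nPerms = 20, offset = NULL) {
  if (nPerms < 1) stop("nPerms must be at least 1")
  X <- as.matrix(X)
  pen <- which(penaltyFactors > 0)
  counts <- integer(nPerms)
  for (p in seq_len(nPerms)) {
    perm <- sample.int(nrow(X))
    Xp <- X
    Xp[, pen] <- X[perm, pen, drop = FALSE]
    fit <- cvSelect(Xp, y, config, penaltyFactors, offset = offset)
    counts[p] <- length(nonzeroCoefficients(fit))
  }
  list(counts = counts, anyDiscovery = mean(counts > 0))
}
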