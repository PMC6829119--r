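#' Fit the fast Laplace model by coordinate descent
#'
#' Whole-genome regression \code{y = 1 mu + M beta + eps} with one phenotype
#' per individual. Each marker effect carries its own regularizer
#' \code{tau_j^-2 = sqrt(lambda2 sigma2_eps / sigma2_beta_j)}, the
#' inverse-Gaussian conditional expectation that collectively shapes the
#' effects into a Laplace distribution; the scale \code{lambda2} is the sum
#' of marker variances, so the model has no tuning parameter. One sweep
#' updates, in order: the intercept, every polymorphic marker (effect, then
#' its full-conditional variance, then its regularizer), and the residual
#' variance \code{y' eps / (n - 1)}. Sweeps repeat until the sum of squared
#' effect changes falls below \code{tol} or \code{maxIter} sweeps are done.
#'
#' With \code{prior = "gaussian"} a single pooled regularizer shared by all
#' markers is used instead (ridge/SNP-BLUP behaviour), updated once per
#' sweep from the pooled full-conditional marker variance. Freezing the
#' regularizer via \code{fixedTauInv2} turns the solver into plain penalized
#' least squares, which is how the implementation is cross-checked against
#' dense normal-equations solutions.
#'
#' @param y numeric phenotypes, length n, no missing values.
#' @param M a \code{\link{GenotypeMatrix}} (or coercible matrix of codes in
#'   \{-1,0,1\}) with n rows.
#' @param tol convergence threshold on the per-sweep sum of squared changes
#'   in beta (default 1e-8).
#' @param maxIter maximum number of full sweeps (default 300).
#' @param prior \code{"laplace"} (default) or \code{"gaussian"}.
#' @param weights optional positive observation weights (length n); the
#'   marker cross-products and all variance updates use the weighted forms.
#' @param fixedTauInv2 optional scalar or length-p vector freezing the
#'   regularizer(s); implies no regularizer adaptation (test/oracle mode).
#'   A value of 0 gives unpenalized coordinate descent.
#' @param updateVariances logical; set \code{FALSE} to freeze the residual
#'   variance as well (only meaningful together with \code{fixedTauInv2}).
#' @param includeIntercept logical; the single-stage marker step sets this
#'   \code{FALSE} because its fixed effects absorb the mean.
#' @return an \code{\link{FLMFit}}.
#' @examples
#' set.seed(1)
#' M <- genotypeMatrix(matrix(sample(c(-1, 0, 1), 200, TRUE), 20, 10))
#' y <- markerCodes(M)[, 1] * 0.8 + rnorm(20, sd = 0.3)
#' fit <- fitFLM(y, M)
#' head(markerEffects(fit))
#' @seealso \code{\link{predictFLM}}, \code{\link{fitSingleStage}}
#' @export
fitFLM <- function(y, M, tol = 1e-8, maxIter = 300L,
                   prior = c("laplace", "gaussian"),
                   weights = NULL, fixedTauInv2 = NULL,
                   updateVariances = TRUE, includeIntercept = TRUE) {
    prior <- match.arg(prior)
    if (!is(M, "GenotypeMatrix"))
        M <- genotypeMatrix(M)
    y <- as.numeric(y)
    n <- length(y)
    if (n != nrow(M@codes))
        stop("length(y) must equal the number of individuals in M")
    if (n < 2L)
        stop("need at least 2 observations")
    if (anyNA(y))
        stop("missing phenotype values are not supported; filter first")
    if (!(tol > 0) || maxIter < 1L)
        stop("tol must be > 0 and maxIter >= 1")
    if (is.null(weights)) {
        weights <- rep(1, n)
    } else {
        weights <- as.numeric(weights)
        if (length(weights) != n || any(weights <= 0))
            stop("weights must be length n and strictly positive")
    }

    st <- .flmEngine(y, M, weights = weights, tol = tol, maxIter = maxIter,
                     prior = prior, fixedTauInv2 = fixedTauInv2,
                     updateVariances = updateVariances,
                     includeIntercept = includeIntercept)
    new("FLMFit", mu = st$mu, beta = st$beta, betaVar = st$beta_var,
        tauInv2 = st$tau_inv2, residVar = st$resid_var, resid = st$resid,
        lambda2 = st$lambda2, prior = st$prior, nIter = as.integer(st$n_iter),
        converged = st$converged, markerIds = M@markerIds)
}

# Shared state setup + C++ engine call; also used by the single-stage
# marker step (warm starts, no intercept, genotype weights).
.flmEngine <- function(y, M, weights, tol, maxIter, prior,
                       fixedTauInv2 = NULL, updateVariances = TRUE,
                       includeIntercept = TRUE, warm = NULL,
                       residIn = NULL) {
    n <- length(y)
    p <- ncol(M@codes)
    lambda2 <- sum(M@colVar)
    poly <- M@colVar > 0
    colSqW <- if (all(weights == weights[1L]) && weights[1L] == 1)
        M@colSq
    else
        colSums(weights * M@codes * M@codes)
    colSqW[!poly] <- 0        # exclude monomorphic markers from the sweep

    sw <- sum(weights)
    ybar <- sum(weights * y) / sw
    vy <- sum(weights * (y - ybar)^2) / max(sw - 1, 1)
    varFloor <- 1e-10 * max(vy, .Machine$double.eps)
    tauCap <- 1e12

    priorCode <- switch(prior, laplace = 0L, gaussian = 1L, fixed = 2L)
    if (!is.null(fixedTauInv2)) {
        priorCode <- 2L
        prior <- "fixed"
        tauInit <- rep_len(as.numeric(fixedTauInv2), p)
        if (any(tauInit < 0))
            stop("fixedTauInv2 must be nonnegative")
    } else if (!any(poly)) {
        tauInit <- rep(tauCap, p)
    } else {
        tauInit <- rep(lambda2, p)
    }

    if (!any(poly) && is.null(fixedTauInv2)) {
        warning("all markers are monomorphic; returning intercept-only fit")
        mu <- if (includeIntercept) ybar else 0
        return(list(mu = mu, beta = numeric(p), beta_var = rep(NA_real_, p),
                    tau_inv2 = tauInit, resid_var = max(vy, varFloor),
                    resid = y - mu, lambda2 = lambda2, n_iter = 1L,
                    converged = TRUE, prior = prior))
    }

    if (is.null(warm)) {
        mu <- 0
        beta <- numeric(p)
        residVar <- max(vy, varFloor)
        resid <- y
    } else {
        mu <- warm$mu
        beta <- warm$beta
        residVar <- warm$resid_var
        if (is.null(fixedTauInv2))
            tauInit <- warm$tau_inv2
        resid <- if (is.null(residIn)) y - mu - drop(M@codes %*% beta)
                 else residIn
    }

    out <- flm_engine_cpp(y, M@codes, weights, mu, beta, tauInit, residVar,
                          resid, lambda2, colSqW, priorCode,
                          includeIntercept, updateVariances,
                          as.integer(maxIter), tol, varFloor, tauCap)
    out$lambda2 <- lambda2
    out$prior <- prior
    out
}

#' Predict phenotypic/genetic values from a fitted FLM
#'
#' Evaluates \code{mu + M_new beta} for new individuals genotyped at the
#' same p markers, in the same order.
#'
#' @param fit an \code{\link{FLMFit}}.
#' @param Mnew a \code{\link{GenotypeMatrix}} or code matrix with the same
#'   markers as the training data.
#' @return numeric vector of predictions, one per row of \code{Mnew}.
#' @export
predictFLM <- function(fit, Mnew) {
    stopifnot(is(fit, "FLMFit"))
    codes <- if (is(Mnew, "GenotypeMatrix")) Mnew@codes else as.matrix(Mnew)
    if (ncol(codes) != length(fit@beta))
        stop(sprintf("Mnew has %d markers but the fit has %d",
                     ncol(codes), length(fit@beta)))
    drop(fit@mu + codes %*% fit@beta)
}

#' @describeIn predictFLM predict method for FLMFit objects.
#' @param object an \code{FLMFit}.
#' @param ... unused.
#' @export
setMethod("predict", "FLMFit", function(object, Mnew, ...)
    predictFLM(object, Mnew))

## ---- Reference step operations (pure R) ------------------------------------
## These are the literal one-at-a-time updates of the algorithm, exposed for
## transparency and used as the independent route in the test suite. The
## production path is the compiled engine above; both must agree.

#' Intercept update of the fast Laplace model
#'
#' \code{mu <- mu + mean(resid)}; the residuals are decremented by the
#' change so they stay current. After the update the residuals sum to zero
#' up to round-off.
#'
#' @param fit an \code{\link{FLMFit}} whose residuals are current.
#' @param n number of observations (must match \code{length(fit@resid)}).
#' @return the updated \code{FLMFit}.
#' @export
updateIntercept <- function(fit, n = length(fit@resid)) {
    stopifnot(is(fit, "FLMFit"))
    if (n == 0L)
        stop("n must be positive")
    if (n != length(fit@resid))
        stop("n must match the residual length")
    dmu <- sum(fit@resid) / n
    fit@mu <- fit@mu + dmu
    fit@resid <- fit@resid - dmu
    fit
}

#' Single-marker update of the fast Laplace model
#'
#' Applies, in order: the effect update
#' \code{beta_j <- (m_j' eps + beta_j m_j'm_j) / (m_j'm_j + tau_j^-2)}, the
#' residual correction, the full-conditional variance
#' \code{sigma2_beta_j <- beta_j^2 + sigma2_eps / (m_j'm_j + tau_j^-2)}, and
#' the regularizer
#' \code{tau_j^-2 <- sqrt(lambda2 sigma2_eps / sigma2_beta_j)} (the
#' inverse-Gaussian conditional expectation under the Laplace prior).
#'
#' @param fit an \code{\link{FLMFit}} with current residuals.
#' @param j marker index (must be polymorphic: \code{colSq > 0}).
#' @param M the training \code{\link{GenotypeMatrix}}.
#' @param updateVariances if \code{FALSE}, only the effect and residuals are
#'   updated (test mode; permits a frozen or zero regularizer, in which case
#'   the update is the ordinary least-squares conditional slope).
#' @return the updated \code{FLMFit}.
#' @export
updateMarker <- function(fit, j, M, updateVariances = TRUE) {
    stopifnot(is(fit, "FLMFit"), is(M, "GenotypeMatrix"))
    mm <- M@colSq[j]
    if (mm <= 0)
        stop("updateMarker called on a monomorphic marker (colSq == 0)")
    tau <- fit@tauInv2[j]
    if (tau < 0 || (tau == 0 && updateVariances))
        stop("tau_j^-2 must be strictly positive")
    mj <- unname(M@codes[, j])
    denom <- mm + tau
    bNew <- (sum(mj * fit@resid) + fit@beta[j] * mm) / denom
    fit@resid <- fit@resid - mj * (bNew - fit@beta[j])
    fit@beta[j] <- bNew
    if (updateVariances) {
        s2b <- bNew^2 + fit@residVar / denom
        fit@betaVar[j] <- s2b
        fit@tauInv2[j] <- sqrt(fit@lambda2 * fit@residVar / s2b)
    }
    fit
}

#' Residual-variance update of the fast Laplace model
#'
#' Maximum-likelihood style update \code{sigma2_eps <- y' eps / (n - 1)},
#' floored at a small positive multiple of \code{var(y)} so degenerate
#' perfect fits cannot collapse the variance to zero.
#'
#' @param fit an \code{\link{FLMFit}} with current residuals.
#' @param y the phenotype vector the model is being fitted to.
#' @param n number of observations (> 1).
#' @return the updated \code{FLMFit}.
#' @export
updateResidVariance <- function(fit, y, n = length(y)) {
    stopifnot(is(fit, "FLMFit"))
    if (n <= 1L)
        stop("n must exceed 1")
    floorVal <- 1e-10 * max(var(y), .Machine$double.eps)
    fit@residVar <- max(sum(y * fit@resid) / (n - 1), floorVal)
    fit
}

# Fresh coordinate-descent state for the reference R path.
.newFLMState <- function(y, M) {
    stopifnot(is(M, "GenotypeMatrix"))
    p <- ncol(M@codes)
    l2 <- sum(M@colVar)
    new("FLMFit", mu = 0, beta = numeric(p), betaVar = rep(NA_real_, p),
        tauInv2 = rep(if (l2 > 0) l2 else 1e12, p),
        residVar = max(var(y), .Machine$double.eps), resid = as.numeric(y),
        lambda2 = l2, prior = "laplace", nIter = 0L, converged = FALSE,
        markerIds = M@markerIds)
}

# Pure-R fit composed from the exported step operations: the independent
# route used to validate the compiled engine.
.fitFLMR <- function(y, M, tol = 1e-8, maxIter = 300L) {
    if (!is(M, "GenotypeMatrix"))
        M <- genotypeMatrix(M)
    fit <- .newFLMState(y, M)
    n <- length(y)
    active <- which(M@colVar > 0)
    for (it in seq_len(maxIter)) {
        betaOld <- fit@beta
        fit <- updateIntercept(fit, n)
        for (j in active)
            fit <- updateMarker(fit, j, M)
        fit <- updateResidVariance(fit, y, n)
        fit@nIter <- it
        if (sum((fit@beta - betaOld)^2) < tol) {
            fit@converged <- TRUE
            break
        }
    }
    fit
}
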