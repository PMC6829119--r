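#' Build a TrialData object from observation-level records
#'
#' Assembles replicated multi-environment phenotypes into the containers the
#' single-stage solver uses: the fixed-effect design X (intercept plus
#' treatment contrasts for environment, first environment dropped for
#' identifiability), the genotype incidence encoded as an index vector, and
#' the per-genotype replicate counts. Genotypes with no observation are
#' never part of the fit; their breeding values are predicted afterwards
#' from the marker effects.
#'
#' @param genotype character/factor genotype id per observation.
#' @param environment character/factor environment id per observation.
#' @param y numeric phenotype per observation.
#' @param RDiag optional positive residual weight diagonal (default all 1).
#' @return a \code{\link{TrialData}}.
#' @examples
#' td <- trialData(c("g1", "g2", "g1"), c("e1", "e1", "e2"), c(10, 11, 12))
#' td
#' @export
trialData <- function(genotype, environment, y, RDiag = NULL) {
    y <- as.numeric(y)
    N <- length(y)
    if (length(genotype) != N || length(environment) != N)
        stop("genotype, environment and y must have equal length")
    if (anyNA(y) || anyNA(genotype) || anyNA(environment))
        stop("missing values are not supported in trial data")
    gf <- factor(as.character(genotype),
                 levels = unique(as.character(genotype)))
    ef <- factor(as.character(environment))
    X <- if (nlevels(ef) > 1L) model.matrix(~ ef)
         else matrix(1, N, 1L)
    colnames(X) <- c("(Intercept)",
                     paste0("env", levels(ef)[-1L]))[seq_len(ncol(X))]
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("fixed-effect design is rank deficient; collinear columns: ",
             paste(colnames(X)[-seq_len(qrX$rank)], collapse = ", "))
    if (is.null(RDiag))
        RDiag <- rep(1, N)
    new("TrialData", y = y, X = X, genoIndex = as.integer(gf),
        genoIds = levels(gf), env = ef, RDiag = as.numeric(RDiag),
        obsCounts = as.numeric(tabulate(as.integer(gf), nlevels(gf))))
}

#' Generalized-least-squares update of the fixed effects
#'
#' Solves \code{b = (X'R^-1 X)^-1 X'R^-1 (y - Za)} on the response
#' conditioned on the current breeding values; the f x f system is dense but
#' small (environments plus intercept).
#'
#' @param y phenotypes, length N.
#' @param X fixed-effect design, N x f, full rank.
#' @param genoIndex integer genotype index per observation (the incidence Z
#'   in index form).
#' @param a current breeding values per fitted genotype (0 at start-up).
#' @param RDiag residual weight diagonal.
#' @return numeric coefficient vector b.
#' @export
solveFixedEffects <- function(y, X, genoIndex, a, RDiag = rep(1, length(y))) {
    yc <- y - a[genoIndex]
    w <- 1 / RDiag
    XtWX <- crossprod(X, X * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch))
        stop("rank-deficient fixed-effect design: ",
             paste(colnames(X), collapse = ", "))
    drop(backsolve(ch, backsolve(ch, crossprod(X, w * yc),
                                 transpose = TRUE)))
}

#' Least-squares genetic values per genotype
#'
#' Solves \code{u0 = (Z'R^-1 Z)^-1 Z'R^-1 (y - Xb)}. Because Z is an
#' incidence matrix this is the per-genotype weighted mean of the
#' fixed-effect-adjusted phenotypes; no matrix is built or inverted. These
#' are intermediary values: the marker regression shrinks them into
#' breeding values.
#'
#' @inheritParams solveFixedEffects
#' @param b current fixed-effect coefficients.
#' @param nGeno number of fitted genotypes.
#' @return numeric vector u0, length nGeno.
#' @export
solveGeneticValues <- function(y, X, genoIndex, b, nGeno,
                               RDiag = rep(1, length(y))) {
    cnt <- tabulate(genoIndex, nGeno)
    if (any(cnt == 0))
        stop("every fitted genotype needs >= 1 observation; drop empty ones")
    w <- 1 / RDiag
    r <- w * (y - drop(X %*% b))
    num <- rowsum(r, genoIndex, reorder = FALSE)
    den <- rowsum(w, genoIndex, reorder = FALSE)
    idx <- as.integer(rownames(num))
    u0 <- numeric(nGeno)
    u0[idx] <- num / den
    u0
}

#' One (or more) marker-regression sweeps on the genetic values
#'
#' The whole-genome regression step of the single-stage algorithm: runs
#' coordinate-descent sweeps of \code{\link{fitFLM}}'s updates on the
#' response \code{u0 = M beta + eps}, where eps is genetic signal not
#' captured by the markers. Genotype weights (typically the replicate
#' counts \code{diag(Z'Z)}) enter all cross-products. Warm-starts from the
#' previous outer iteration's state.
#'
#' @param u0 genotype-level response, length equal to \code{nrow(M)}.
#' @param M \code{\link{GenotypeMatrix}} for the fitted genotypes.
#' @param weights positive genotype weights (all 1 for unweighted).
#' @param prior \code{"laplace"} or \code{"gaussian"}.
#' @param state engine state from a previous call, or \code{NULL} to start
#'   fresh.
#' @param innerSweeps number of sweeps to run (default 1: fully interleaved
#'   with the outer updates).
#' @param fixedTauInv2 optional frozen regularizer (test mode).
#' @return engine state list with elements \code{beta}, \code{tau_inv2},
#'   \code{resid_var}, \code{resid} (the eps of the marker step), ...
#' @export
wgrStep <- function(u0, M, weights = rep(1, length(u0)),
                    prior = c("laplace", "gaussian"), state = NULL,
                    innerSweeps = 1L, fixedTauInv2 = NULL) {
    prior <- match.arg(prior)
    if (!is(M, "GenotypeMatrix"))
        M <- genotypeMatrix(M)
    if (length(u0) != nrow(M@codes))
        stop("u0 must have one entry per genotype row of M")
    if (any(weights <= 0))
        stop("genotype weights must be strictly positive; drop unobserved ",
             "genotypes upstream")
    .flmEngine(u0, M, weights = weights, tol = 0, maxIter = innerSweeps,
               prior = prior, fixedTauInv2 = fixedTauInv2,
               updateVariances = is.null(fixedTauInv2),
               includeIntercept = FALSE, warm = state, residIn = NULL)
}

#' Fit the iterative single-stage model
#'
#' Jointly estimates environment fixed effects, genotype means and marker
#' effects from replicated, unbalanced trial data,
#' \code{y = Xb + Z(M beta) + e}, without ever forming the N x p matrix ZM.
#' Each outer iteration runs (1) a generalized-least-squares update of b on
#' \code{y - Za}; (2) the per-genotype weighted means \code{u0} of
#' \code{y - Xb}; (3) \code{innerSweeps} coordinate-descent sweeps of the
#' whole-genome regression \code{u0 = M beta + eps} (Laplace prior: FLM-SS;
#' Gaussian prior: RR-SS), optionally weighting genotypes by replicate
#' count; and (4) the breeding-value refresh \code{a = M beta}. Iterations
#' stop when the mean squared change in a falls below \code{outerTol}.
#'
#' Under the Gaussian prior the shared ridge regularizer is calibrated by
#' moments whenever replication provides pure-error degrees of freedom
#' (residual variance from within-genotype spread, marker variance from the
#' variance decomposition of the genotype means); with unreplicated data it
#' falls back to the pooled full-conditional update. The Laplace prior
#' always uses its per-marker full-conditional updates.
#'
#' @param data a \code{\link{TrialData}}.
#' @param M \code{\link{GenotypeMatrix}} whose individual ids cover the
#'   genotype ids in \code{data}; extra rows (unobserved genotypes) are
#'   ignored in the fit and can be predicted from the marker effects.
#' @param prior \code{"laplace"} (FLM-SS, default) or \code{"gaussian"}
#'   (RR-SS).
#' @param weighting \code{"none"} (default) or \code{"reps"} (weight
#'   genotypes by replicate count in the marker step).
#' @param innerSweeps marker-regression sweeps per outer iteration
#'   (default 1).
#' @param outerTol convergence threshold on mean((delta a)^2), default 1e-8.
#' @param outerMaxIter maximum outer iterations, default 300.
#' @return a \code{\link{SingleStageFit}}. Non-convergence yields a warning
#'   and \code{converged = FALSE}, never an error.
#' @examples
#' set.seed(42)
#' pop <- simulatePopulation(genomeSpec(nChrom = 2), seed = 42, popSize = 60)
#' pop <- assignQTL(pop, 2)
#' tr <- simulateTrials(pop, nObs = 120, seed = 7)
#' fit <- fitSingleStage(tr$trial, pop@genotypes, prior = "laplace")
#' fit
#' @export
fitSingleStage <- function(data, M, prior = c("laplace", "gaussian"),
                           weighting = c("none", "reps"),
                           innerSweeps = 1L, outerTol = 1e-8,
                           outerMaxIter = 300L) {
    prior <- match.arg(prior)
    weighting <- match.arg(weighting)
    stopifnot(is(data, "TrialData"))
    if (!is(M, "GenotypeMatrix"))
        M <- genotypeMatrix(M)
    if (innerSweeps < 1L)
        stop("innerSweeps must be >= 1")
    rows <- match(data@genoIds, M@individualIds)
    if (anyNA(rows))
        stop("genotype ids missing from the genotype matrix: ",
             paste(utils::head(data@genoIds[is.na(rows)], 5L),
                   collapse = ", "))
    Mg <- if (identical(rows, seq_len(nrow(M@codes)))) M else
        subsetIndividuals(M, rows)
    y <- data@y
    X <- data@X
    gi <- data@genoIndex
    RDiag <- data@RDiag
    ng <- length(data@genoIds)
    if (length(y) < ncol(X) + 1L)
        stop("need more observations than fixed effects")
    wg <- if (weighting == "reps") data@obsCounts else rep(1, ng)

    # For the Gaussian prior the shared regularizer lambda_r = sigma2_e /
    # sigma2_beta is calibrated from moments when replication identifies the
    # residual variance: pure-error sigma2_e from within-genotype spread,
    # sigma2_beta from the variance decomposition of the genotype means
    # (var(u0) = sigma2_beta * lambda2 + sampling noise). The per-marker
    # full-conditional EM update is kept as the fallback for unreplicated
    # data, where pure error has no degrees of freedom.
    dfePure <- length(y) - ng
    momentRR <- prior == "gaussian" && dfePure >= 10L
    infoW <- drop(.groupSums(1 / RDiag, gi, ng))   # Sum 1/R per genotype
    l2g <- sum(Mg@colVar)

    a <- numeric(ng)
    state <- NULL
    u0 <- numeric(ng)
    b <- numeric(ncol(X))
    s2ePure <- NA_real_
    converged <- FALSE
    it <- 0L
    for (it in seq_len(outerMaxIter)) {
        b <- solveFixedEffects(y, X, gi, a, RDiag)
        u0New <- solveGeneticValues(y, X, gi, b, ng, RDiag)
        # the marker-step residual tracks u0 - M beta; u0 moved, beta did not
        residIn <- if (is.null(state)) u0New else state$resid + (u0New - u0)
        u0 <- u0New
        if (momentRR) {
            eObs <- y - drop(X %*% b) - u0[gi]
            s2ePure <- sum(eObs^2 / RDiag) / dfePure
            s2b <- max((var(u0) - s2ePure * mean(1 / infoW)) / l2g,
                       s2ePure / 1e12)
            lamR <- min(s2ePure / s2b, 1e12)
            if (!is.null(state)) state$resid_var <- s2ePure
            state <- .flmEngine(u0, Mg, weights = wg, tol = 0,
                                maxIter = innerSweeps, prior = prior,
                                fixedTauInv2 = lamR,
                                updateVariances = FALSE,
                                includeIntercept = FALSE,
                                warm = state, residIn = residIn)
            state$resid_var <- s2ePure
        } else {
            state <- .flmEngine(u0, Mg, weights = wg, tol = 0,
                                maxIter = innerSweeps, prior = prior,
                                updateVariances = TRUE,
                                includeIntercept = FALSE,
                                warm = state, residIn = residIn)
        }
        aNew <- u0 - state$resid          # = M beta by bookkeeping
        d <- mean((aNew - a)^2)
        a <- aNew
        if (d < outerTol) {
            converged <- TRUE
            break
        }
    }
    if (!converged)
        warning("single-stage solver hit outerMaxIter without converging")

    beta <- state$beta
    a <- drop(Mg@codes %*% beta)          # exact refresh of the identity
    e <- y - drop(X %*% b) - a[gi]
    rX <- qr(X)$rank
    new("SingleStageFit", b = setNames(b, colnames(X)), u0 = u0,
        beta = beta, a = a, e = e, wgrResid = u0 - a,
        residVarObs = sum(e^2 / RDiag) / (length(y) - rX),
        residVarWGR = state$resid_var, prior = prior, weighting = weighting,
        extra = list(), nIter = it, converged = converged,
        genoIds = data@genoIds, markerIds = Mg@markerIds)
}

#' Predict breeding values for (possibly unobserved) genotypes
#'
#' Breeding values are \code{a = M beta}; any genotype with marker data can
#' be predicted, including genotypes excluded from the fit for lack of
#' observations.
#'
#' @param fit a \code{\link{SingleStageFit}}.
#' @param Mnew \code{\link{GenotypeMatrix}} or code matrix with the same
#'   markers.
#' @return named numeric vector of breeding values.
#' @export
predictSingleStage <- function(fit, Mnew) {
    stopifnot(is(fit, "SingleStageFit"))
    ids <- NULL
    if (is(Mnew, "GenotypeMatrix")) {
        ids <- Mnew@individualIds
        Mnew <- Mnew@codes
    }
    if (ncol(Mnew) != length(fit@beta))
        stop("marker count mismatch")
    setNames(drop(Mnew %*% fit@beta), ids)
}

#' @describeIn predictSingleStage predict method for SingleStageFit.
#' @param object a \code{SingleStageFit}.
#' @param ... unused.
#' @export
setMethod("predict", "SingleStageFit", function(object, Mnew, ...)
    predictSingleStage(object, Mnew))

#' Gauss-Seidel solve for an additional random effect
#'
#' For a model term \code{W g} with \code{g ~ N(0, I sigma2_g)} added to
#' the single-stage model, solves
#' \code{(W'R^-1 W + k I) g = W'R^-1 y_cond} with \code{k =
#' sigma2_e / sigma2_g} by per-coefficient Gauss-Seidel sweeps, where
#' \code{y_cond = y - Xb - Za} is the response conditioned on all other
#' terms. No matrix inverse is materialized.
#'
#' @param yCond conditioned response, length N.
#' @param W random-effect design, N x nw.
#' @param sigmaG2,sigmaE2 current variance components (both > 0).
#' @param RDiag residual weight diagonal.
#' @param tol,maxIter Gauss-Seidel stopping rule on the squared coefficient
#'   change.
#' @return list with components \code{g} and \code{k}.
#' @export
fitExtraRandomEffect <- function(yCond, W, sigmaG2, sigmaE2,
                                 RDiag = rep(1, length(yCond)),
                                 tol = 1e-20, maxIter = 2000L) {
    if (sigmaG2 <= 0)
        stop("sigmaG2 must be strictly positive")
    W <- as.matrix(W)
    k <- sigmaE2 / sigmaG2
    w <- 1 / RDiag
    nw <- ncol(W)
    diagW <- colSums(w * W * W)
    g <- numeric(nw)
    r <- yCond
    for (it in seq_len(maxIter)) {
        d2 <- 0
        for (j in seq_len(nw)) {
            gNew <- (sum(w * W[, j] * r) + g[j] * diagW[j]) / (diagW[j] + k)
            dg <- gNew - g[j]
            if (dg != 0) r <- r - W[, j] * dg
            g[j] <- gNew
            d2 <- d2 + dg^2
        }
        if (d2 < tol) break
    }
    list(g = g, k = k)
}

#' Variance component of an additional random effect
#'
#' Full-conditional estimator \code{sigma2_g = g'g / (nw - k *
#' sum_j (w_j'w_j + k)^-1)} (mode \code{"exact"}), or the moment
#' approximation \code{sigma2_g ~ (y - Xb)' W g / (n * sum_j var(w_j))}
#' intended for non-orthogonal designs such as spatial adjacency matrices
#' (mode \code{"approx"}; \code{n} is the observation count).
#'
#' @param g current coefficients.
#' @param W random-effect design.
#' @param k current variance ratio \code{sigma2_e / sigma2_g}.
#' @param yAdj for mode \code{"approx"}: the response adjusted for fixed
#'   effects only, \code{y - Xb}.
#' @param mode \code{"exact"} or \code{"approx"}.
#' @return scalar variance estimate (floored at a tiny positive value).
#' @export
updateExtraVariance <- function(g, W, k, yAdj = NULL,
                                mode = c("exact", "approx")) {
    mode <- match.arg(mode)
    W <- as.matrix(W)
    nw <- ncol(W)
    if (mode == "exact") {
        den <- nw - k * sum(1 / (colSums(W * W) + k))
        if (den <= 0)
            stop("nonpositive denominator in the variance update (nw = ",
                 nw, ", k = ", format(k), "); the ratio k is too large")
        s2 <- sum(g^2) / den
    } else {
        if (is.null(yAdj))
            stop("mode 'approx' needs yAdj = y - Xb")
        n <- nrow(W)
        svw <- sum(apply(W, 2L, function(x) mean(x^2) - mean(x)^2))
        if (svw <= 0)
            stop("nonpositive column-variance sum in the variance update")
        s2 <- sum(yAdj * drop(W %*% g)) / (n * svw)
    }
    max(s2, .Machine$double.eps)
}
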