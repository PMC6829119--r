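#' Predictive ability / accuracy
#'
#' Pearson correlation between predicted and true (or observed) breeding
#' values, the standard evaluation criterion for genomic prediction.
#'
#' @param pred,truth numeric vectors of equal length (>= 3).
#' @return scalar correlation in [-1, 1].
#' @export
accuracy <- function(pred, truth) {
    pred <- as.numeric(pred)
    truth <- as.numeric(truth)
    if (length(pred) != length(truth))
        stop("pred and truth must have equal length")
    if (length(pred) < 3L)
        stop("need at least 3 pairs")
    if (sd(truth) == 0)
        stop("truth is constant; the correlation is undefined")
    cor(pred, truth)
}

#' Repeated k-fold cross-validation of a whole-genome regression
#'
#' For each repetition, individuals are partitioned at random into k folds
#' (80/20 calibration/validation at the default k = 5); the model is fitted
#' on k-1 folds and the held-out fold is predicted. The per-fold Pearson
#' correlation between predictions and observed values is recorded. Folds
#' whose observed values are constant are skipped with a warning.
#'
#' @param y phenotypes.
#' @param M \code{\link{GenotypeMatrix}}.
#' @param fitFun function(y, M) returning an object accepted by
#'   \code{predFun}; defaults to \code{\link{fitFLM}}.
#' @param predFun function(fit, M) returning predictions; defaults to
#'   \code{\link{predictFLM}}.
#' @param k folds (default 5); @param reps repetitions (default 20).
#' @param seed integer seed for the partitions.
#' @return a \code{\link{CVResult}}; see \code{\link{cvSummary}}.
#' @export
kfoldCV <- function(y, M, fitFun = fitFLM, predFun = predictFLM,
                    k = 5L, reps = 20L, seed = 1L) {
    if (!is(M, "GenotypeMatrix"))
        M <- genotypeMatrix(M)
    n <- length(y)
    if (n < k)
        stop("need at least k observations")
    res <- .withSeed(seed, {
        out <- vector("list", reps)
        for (r in seq_len(reps)) {
            fold <- sample(rep_len(seq_len(k), n))
            rows <- lapply(seq_len(k), function(f) {
                test <- which(fold == f)
                yTest <- y[test]
                if (sd(yTest) == 0) {
                    warning("fold with constant observed values skipped")
                    return(data.frame(rep = r, split = f,
                                      n_test = length(test), r = NA_real_))
                }
                fit <- fitFun(y[-test], subsetIndividuals(M, -test))
                pred <- predFun(fit, M@codes[test, , drop = FALSE])
                rv <- if (sd(pred) == 0) NA_real_ else cor(pred, yTest)
                data.frame(rep = r, split = f, n_test = length(test),
                           r = rv)
            })
            out[[r]] <- do.call(rbind, rows)
        }
        do.call(rbind, out)
    })
    new("CVResult", scheme = "within_kfold", results = res)
}

#' Leave-group-out cross-validation
#'
#' One split per group (e.g. per family): the model is trained on all other
#' groups and the held-out group is predicted. Groups smaller than 3 are
#' skipped with a warning (the correlation would be meaningless).
#'
#' @inheritParams kfoldCV
#' @param groups group label per individual (>= 2 distinct groups).
#' @return a \code{\link{CVResult}}.
#' @export
leaveGroupOutCV <- function(y, M, groups, fitFun = fitFLM,
                            predFun = predictFLM) {
    if (!is(M, "GenotypeMatrix"))
        M <- genotypeMatrix(M)
    groups <- as.factor(groups)
    if (nlevels(groups) < 2L)
        stop("need at least 2 groups")
    rows <- lapply(seq_len(nlevels(groups)), function(gIdx) {
        test <- which(as.integer(groups) == gIdx)
        if (length(test) < 3L || sd(y[test]) == 0) {
            warning("group ", levels(groups)[gIdx],
                    " skipped (too small or constant)")
            return(data.frame(rep = 1L, split = gIdx,
                              n_test = length(test), r = NA_real_))
        }
        fit <- fitFun(y[-test], subsetIndividuals(M, -test))
        pred <- predFun(fit, M@codes[test, , drop = FALSE])
        rv <- if (sd(pred) == 0) NA_real_ else cor(pred, y[test])
        data.frame(rep = 1L, split = gIdx, n_test = length(test), r = rv)
    })
    new("CVResult", scheme = "leave_group_out",
        results = do.call(rbind, rows))
}

# Group sums robust to integer-vs-character row naming of rowsum().
.groupSums <- function(x, g, nG) {
    out <- numeric(nG)
    tmp <- rowsum(x, g, reorder = FALSE)
    out[as.integer(rownames(tmp))] <- tmp
    out
}

# 1-D REML profile over the variance ratio lambda = sigma2_a / sigma2_e
# for the model ytil = Xtil mu + atil + etil with Var(atil) = K sigma2_a,
# Var(etil) = I sigma2_e (EMMA-style: eigendecomposition of the projected
# kinship, then a golden-section search over log lambda).
.remlRatio <- function(ytil, Xtil, K, logRange = c(-12, 12)) {
    n <- length(ytil)
    f <- ncol(Xtil)
    P0 <- diag(n) - Xtil %*% solve(crossprod(Xtil), t(Xtil))
    ee <- eigen(P0 %*% K %*% P0, symmetric = TRUE)
    keep <- seq_len(n - f)
    xi <- pmax(ee$values[keep], 0)
    eta <- drop(crossprod(ee$vectors[, keep, drop = FALSE], ytil))
    nf <- n - f
    negRL <- function(logLam) {
        lam <- exp(logLam)
        d <- lam * xi + 1
        0.5 * (nf * log(sum(eta^2 / d)) + sum(log(d)))
    }
    opt <- optimize(negRL, logRange)
    lam <- exp(opt$minimum)
    s2e <- sum(eta^2 / (lam * xi + 1)) / nf
    list(lambda = lam, sigma2a = lam * s2e, sigma2e = s2e,
         negRL = negRL)
}

# Block Gauss-Seidel least squares for y = Xb + Z u0 (genotype means
# adjusted for fixed effects); converges to the joint LS solution.
.adjustedMeans <- function(y, X, genoIndex, nGeno, RDiag = rep(1, length(y)),
                           tol = 1e-12, maxIter = 200L) {
    u0 <- numeric(nGeno)
    b <- numeric(ncol(X))
    for (it in seq_len(maxIter)) {
        b <- solveFixedEffects(y, X, genoIndex, u0, RDiag)
        u0New <- solveGeneticValues(y, X, genoIndex, b, nGeno, RDiag)
        d <- mean((u0New - u0)^2)
        u0 <- u0New
        if (d < tol) break
    }
    list(b = b, u0 = u0)
}

#' Brute-force GBLUP oracle with EMMA-style REML
#'
#' Reference implementation of GBLUP on trial data, used as an independent
#' yardstick for the iterative single-stage solver. The genomic
#' relationship matrix is the VanRaden centered cross-product
#' \code{G = Mc Mc' / c} with \code{c = 2 sum p_j (1 - p_j)} (proportional
#' to the \code{M M' sigma2_beta} covariance of the marker model). The
#' variance ratio is estimated by restricted maximum likelihood on the
#' replicate-weighted adjusted genotype means (exact for balanced designs),
#' via an eigendecomposition and a 1-D search. Breeding values are then the
#' exact observation-level BLUPs, computed through the equivalent marker
#' model \code{a = Mc alpha}, \code{alpha ~ N(0, I sigma2_a / c)}, whose
#' mixed-model equations are a dense (f + p) system; this sidesteps
#' inverting G, which is singular whenever p < n_g. Dense decompositions
#' limit this oracle to test scale (a few thousand genotypes).
#'
#' @param data a \code{\link{TrialData}}.
#' @param M \code{\link{GenotypeMatrix}} for the pool (may include
#'   unobserved genotypes; ids must cover \code{data}'s genotypes).
#' @param logRange search interval for log(sigma2_a / sigma2_e).
#' @return list with \code{a} (breeding values for every row of M, named),
#'   \code{aFitted} (observed genotypes only), \code{b} (fixed effects),
#'   \code{varComp} (sigma2_a, sigma2_e, lambda) and \code{negRL} (the
#'   profiled objective, for diagnostics).
#' @export
gblupOracle <- function(data, M, logRange = c(-12, 12)) {
    stopifnot(is(data, "TrialData"))
    if (!is(M, "GenotypeMatrix"))
        M <- genotypeMatrix(M)
    rows <- match(data@genoIds, M@individualIds)
    if (anyNA(rows))
        stop("genotype ids missing from the genotype matrix")
    pFreq <- (colMeans(M@codes) + 1) / 2
    cc <- 2 * sum(pFreq * (1 - pFreq))
    if (cc <= 0)
        stop("all markers monomorphic; G is undefined")
    Mc <- sweep(M@codes, 2L, colMeans(M@codes))
    McObs <- Mc[rows, , drop = FALSE]

    ng <- length(data@genoIds)
    adj <- .adjustedMeans(data@y, data@X, data@genoIndex, ng, data@RDiag)
    wHalf <- sqrt(data@obsCounts)
    ytil <- wHalf * adj$u0
    Xtil <- matrix(wHalf, ncol = 1L)
    K <- tcrossprod(McObs * wHalf) / cc
    vc <- .remlRatio(ytil, Xtil, K, logRange)

    # exact MME of the equivalent marker model, ridge k*c on alpha
    k <- 1 / vc$lambda
    X <- data@X
    Q <- McObs[data@genoIndex, , drop = FALSE]
    w <- 1 / data@RDiag
    f <- ncol(X)
    p <- ncol(Q)
    lhs <- rbind(cbind(crossprod(X, X * w), crossprod(X, Q * w)),
                 cbind(crossprod(Q, X * w),
                       crossprod(Q, Q * w) + diag(k * cc, p)))
    rhs <- c(crossprod(X, w * data@y), crossprod(Q, w * data@y))
    sol <- solve(lhs, rhs)
    b <- sol[seq_len(f)]
    alpha <- sol[-seq_len(f)]
    aAll <- setNames(drop(Mc %*% alpha), M@individualIds)
    list(a = aAll, aFitted = aAll[rows], b = setNames(b, colnames(X)),
         varComp = c(sigma2a = vc$sigma2a, sigma2e = vc$sigma2e,
                     lambda = vc$lambda),
         negRL = vc$negRL)
}

#' Simplified two-stage baseline
#'
#' Stage 1: genotype means adjusted for environment, with genotype as a
#' fixed effect and environment as a random effect whose variance comes
#' from a moment estimate (variance of the unshrunken environment means
#' minus the average sampling noise), iterating shrunken environment
#' effects and genotype means to a joint fixed point. Stage 2: the fast
#' Laplace model fitted to the stage-1 means, weighting each genotype by
#' the information weight \code{S = Diag(Z' V^-1 Z)} with
#' \code{V = XX' sigma2_env + I sigma2_e} (block closed form per
#' environment), so replicated genotypes carry more weight. This is a
#' deliberately simplified stand-in for full two-stage pipelines that
#' propagate the complete first-stage covariance.
#'
#' @param data a \code{\link{TrialData}}.
#' @param M \code{\link{GenotypeMatrix}} for the pool.
#' @return list with \code{a} (breeding values for every row of M),
#'   \code{fit} (the stage-2 \code{\link{FLMFit}}), \code{u} (stage-1
#'   genotype means), \code{weights} (the S diagonal), and the stage-1
#'   variance components.
#' @export
twoStageBaseline <- function(data, M) {
    stopifnot(is(data, "TrialData"))
    if (!is(M, "GenotypeMatrix"))
        M <- genotypeMatrix(M)
    rows <- match(data@genoIds, M@individualIds)
    if (anyNA(rows))
        stop("genotype ids missing from the genotype matrix")
    y <- data@y
    ng <- length(data@genoIds)
    gi <- data@genoIndex
    ei <- as.integer(data@env)
    nEnv <- nlevels(data@env)
    nPerEnv <- tabulate(ei, nEnv)

    # stage 1 moment estimates: between-environment variance from the raw
    # environment means, residual (genetic + plot) variance from the
    # average within-environment spread; crude but only used for shrinkage
    # and the information weights of this simplified baseline
    envMeans <- .groupSums(y, ei, nEnv) / nPerEnv
    s2e <- max(mean(tapply(y, ei, var), na.rm = TRUE),
               .Machine$double.eps)
    s2env <- max(var(envMeans) - s2e * mean(1 / nPerEnv), s2e * 1e-6)
    if (nEnv < 2L) {
        warning("single environment: stage 1 degenerates to raw ",
                "genotype means")
        s2env <- s2e * 1e-6
    }
    kEnv <- s2e / s2env
    # iterate shrunken environment effects and genotype means
    cEnv <- numeric(nEnv)
    u <- numeric(ng)
    for (it in seq_len(100L)) {
        u <- .groupSums(y - cEnv[ei], gi, ng) / data@obsCounts
        cNew <- .groupSums(y - u[gi], ei, nEnv) / (nPerEnv + kEnv)
        d <- mean((cNew - cEnv)^2)
        cEnv <- cNew
        if (d < 1e-12) break
    }
    u <- .groupSums(y - cEnv[ei], gi, ng) / data@obsCounts

    # S = Diag(Z'V^-1 Z); V block diagonal per environment:
    # (V^-1)_oo = (1 - s2env/(s2e + n_E s2env)) / s2e for obs in env E
    vinvDiag <- (1 - s2env / (s2e + nPerEnv * s2env)) / s2e
    Sfull <- .groupSums(vinvDiag[ei], gi, ng)

    Sfull <- Sfull / mean(Sfull)   # relative precisions, canonical scale
    fit <- fitFLM(u, subsetIndividuals(M, rows), weights = Sfull)
    Mc <- M@codes
    a <- setNames(drop(Mc %*% fit@beta), M@individualIds)
    list(a = a, fit = fit, u = u, weights = Sfull,
         sigma2env = s2env, sigma2e = s2e)
}
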