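mkState <- function(resid, beta = numeric(1), tauInv2 = 1, residVar = 1,
                    lambda2 = 1, mu = 0) {
    p <- length(beta)
    new("FLMFit", mu = mu, beta = beta, betaVar = rep(NA_real_, p),
        tauInv2 = rep_len(tauInv2, p), residVar = residVar,
        resid = resid, lambda2 = lambda2, prior = "laplace", nIter = 0L,
        converged = FALSE, markerIds = paste0("m", seq_len(p)))
}

test_that("intercept update recenters the residuals", {
    st <- mkState(resid = c(1, -1, 2))
    st <- updateIntercept(st, 3)
    expect_equal(st@mu, 2 / 3)
    expect_equal(st@resid, c(1 / 3, -5 / 3, 4 / 3))

    # zero-sum residuals are a fixed point
    st2 <- mkState(resid = c(1, -1))
    st2b <- updateIntercept(st2, 2)
    expect_equal(st2b@mu, 0)
    expect_equal(st2b@resid, st2@resid)

    set.seed(5)
    st3 <- updateIntercept(mkState(resid = rnorm(100, 3)), 100)
    expect_lt(abs(sum(st3@resid)), 1e-12)

    expect_error(updateIntercept(mkState(c(1, 2)), 0), "positive")
})

test_that("marker update applies effect, variance and regularizer in order", {
    # m'eps = 4, beta = 0, m'm = 2, tau^-2 = 2 -> beta = 1;
    # sigma2_eps = 2 -> sigma2_beta = 1 + 2/4 = 1.5;
    # lambda2 = 3 -> tau^-2 = sqrt(3 * 2 / 1.5) = 2
    M <- genotypeMatrix(matrix(c(1, 1), 2, 1))
    st <- mkState(resid = c(2, 2), tauInv2 = 2, residVar = 2, lambda2 = 3)
    st <- updateMarker(st, 1, M)
    expect_equal(st@beta[1], 1)
    expect_equal(st@betaVar[1], 1.5)
    expect_equal(st@tauInv2[1], 2)
    expect_equal(st@resid, c(1, 1))   # decremented by m * delta beta

    # infinite-shrinkage limit
    st2 <- mkState(resid = c(2, 2), tauInv2 = 1e12, residVar = 2)
    st2 <- updateMarker(st2, 1, M)
    expect_lt(abs(st2@beta[1]), 1e-6)

    # no-shrinkage (test mode): OLS conditional slope
    st3 <- mkState(resid = c(2, 2), tauInv2 = 0)
    st3 <- updateMarker(st3, 1, M, updateVariances = FALSE)
    expect_equal(st3@beta[1], 2)       # m'(eps)/m'm = 4/2

    Mz <- genotypeMatrix(matrix(c(0, 0, -1, 1), 2, 2))
    expect_error(updateMarker(mkState(c(1, 1), beta = numeric(2)), 1, Mz),
                 "monomorphic")
    expect_error(updateMarker(mkState(c(1, 1), tauInv2 = 0), 1, M),
                 "positive")
})

test_that("residual-variance update is y'eps/(n-1), floored when degenerate", {
    st <- mkState(resid = c(1, -1))
    st <- updateResidVariance(st, y = c(1, -1), 2)
    expect_equal(st@residVar, 2)

    stPerfect <- mkState(resid = c(0, 0, 0))
    stPerfect <- updateResidVariance(stPerfect, y = c(1, 2, 3), 3)
    expect_gt(stPerfect@residVar, 0)

    set.seed(9)
    y <- rnorm(40)
    eps <- rnorm(40)
    st2 <- updateResidVariance(mkState(resid = eps), y, 40)
    expect_equal(st2@residVar, sum(y * eps) / 39)

    expect_error(updateResidVariance(mkState(0), y = 1, 1), "exceed")
})

test_that("compiled engine agrees with the step-composed R reference", {
    M <- randomGenotypes(50, 20, seed = 21)
    set.seed(22)
    y <- markerCodes(M)[, 3] - 0.5 * markerCodes(M)[, 11] + rnorm(50)
    fCpp <- fitFLM(y, M)
    fR <- flamix:::.fitFLMR(y, M)
    expect_equal(fCpp@beta, fR@beta, tolerance = 1e-10)
    expect_equal(fCpp@mu, fR@mu, tolerance = 1e-10)
    expect_equal(fCpp@residVar, fR@residVar, tolerance = 1e-10)
    expect_equal(fCpp@nIter, fR@nIter)
})

test_that("frozen-regularizer fit matches the dense ridge solution", {
    set.seed(31)
    for (rep in 1:3) {
        M <- randomGenotypes(30, 20, seed = 31 + rep)
        y <- rnorm(30) + markerCodes(M)[, 1]
        cPen <- 20
        fit <- fitFLM(y, M, fixedTauInv2 = cPen, updateVariances = FALSE,
                      tol = 1e-20, maxIter = 300)
        expect_lt(max(abs(fit@beta - ridgeOracle(y, M, cPen))), 1e-6)
    }
})

test_that("bookkeeping identity holds after a converged fit", {
    pop <- fixturePop()
    y <- simulatePhenotype(pop, 0.5, seed = 51)
    fit <- fitFLM(y, pop@genotypes)
    lhs <- y - fit@mu - drop(markerCodes(pop@genotypes) %*% fit@beta)
    expect_lt(max(abs(lhs - fit@resid)), 1e-8 * (1 + max(abs(y))))
    expect_true(fit@converged)
    expect_true(all(fit@tauInv2 > 0))
    expect_gt(fit@residVar, 0)
})

test_that("constant phenotypes give an intercept-only fit", {
    M <- randomGenotypes(20, 5, seed = 41)
    fit <- fitFLM(rep(7, 20), M)
    expect_equal(fit@mu, 7, tolerance = 1e-8)
    expect_lt(max(abs(fit@beta)), 1e-8)
})

test_that("all-monomorphic input reduces to the intercept with a warning", {
    gm <- genotypeMatrix(matrix(c(1, 1, 1, -1, -1, -1), 3, 2))
    expect_warning(fit <- fitFLM(c(1, 2, 3), gm), "monomorphic")
    expect_equal(fit@mu, 2)
    expect_equal(fit@beta, c(0, 0))
})

test_that("input contract violations are rejected", {
    M <- randomGenotypes(10, 4, seed = 61)
    expect_error(fitFLM(rnorm(9), M), "equal the number")
    expect_error(fitFLM(c(rnorm(9), NA), M), "missing")
    expect_error(fitFLM(rnorm(10), M, tol = 0), "tol")
})

test_that("shrinkage of a single effect is monotone in the regularizer", {
    M <- genotypeMatrix(matrix(c(-1, 0, 1, 1, -1, 0), 6, 1))
    set.seed(71)
    y <- markerCodes(M)[, 1] * 2 + rnorm(6, sd = 0.1)
    taus <- c(0, 0.5, 2, 10, 100, 1e4)
    betas <- vapply(taus, function(tau) {
        fitFLM(y, M, fixedTauInv2 = tau, updateVariances = FALSE,
               tol = 1e-16, maxIter = 200)@beta[1]
    }, numeric(1))
    expect_true(all(diff(abs(betas)) <= 1e-12))
})

test_that("prediction is mu + M beta and reproduces fitted values", {
    M <- randomGenotypes(25, 8, seed = 81)
    set.seed(82)
    y <- rnorm(25) + markerCodes(M)[, 2]
    fit <- fitFLM(y, M)
    # all-zero row -> intercept
    expect_equal(predictFLM(fit, matrix(0, 1, 8)), fit@mu)
    # training data -> y - resid
    expect_lt(max(abs(predictFLM(fit, M) - (y - fit@resid))), 1e-10)
    expect_error(predictFLM(fit, matrix(0, 1, 5)), "markers")

    oneFit <- mkState(resid = 0, beta = 0.5, mu = 1)
    expect_equal(predictFLM(oneFit, matrix(c(-1, 0, 1), 3, 1)),
                 c(0.5, 1, 1.5))
})

test_that("pure-noise fits stay well below the 10-QTL signal scale", {
    pop <- fixturePop()
    ySig <- simulatePhenotype(pop, 0.5, seed = 90)
    sigMax <- max(abs(fitFLM(ySig, pop@genotypes)@beta))
    set.seed(91)
    nullMax <- vapply(1:20, function(i) {
        yNull <- rnorm(1000, sd = sd(ySig))
        max(abs(fitFLM(yNull, pop@genotypes)@beta))
    }, numeric(1))
    expect_lt(mean(nullMax), sigMax / 2)
})

test_that("fits are deterministic for fixed input", {
    M <- randomGenotypes(40, 15, seed = 95)
    set.seed(96)
    y <- rnorm(40)
    f1 <- fitFLM(y, M)
    f2 <- fitFLM(y, M)
    expect_identical(f1@beta, f2@beta)
    expect_identical(f1@residVar, f2@residVar)
})
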