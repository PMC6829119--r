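test_that("fixed-effect solve matches generalized least squares", {
    # intercept only, a = 0: b is the mean
    y <- c(1, 2, 3, 6)
    X <- matrix(1, 4, 1)
    expect_equal(solveFixedEffects(y, X, c(1L, 1L, 2L, 2L), c(0, 0)), 3)
    # conditioning identity: b = mean(y - Za)
    a <- c(1, -1)
    expect_equal(solveFixedEffects(y, X, c(1L, 1L, 2L, 2L), a),
                 mean(y - a[c(1, 1, 2, 2)]))

    set.seed(11)
    N <- 50
    X <- cbind(1, matrix(rnorm(N * 2), N, 2))
    gi <- sample(1:10, N, replace = TRUE)
    a <- rnorm(10)
    R <- runif(N, 0.5, 2)
    y <- rnorm(N)
    bHat <- solveFixedEffects(y, X, gi, a, R)
    W <- diag(1 / R)
    bOracle <- solve(t(X) %*% W %*% X, t(X) %*% W %*% (y - a[gi]))
    expect_equal(bHat, drop(bOracle), tolerance = 1e-10)
})

test_that("genetic values are per-genotype weighted means", {
    # Z = identity: u0 = y - Xb
    y <- c(4, 5, 6)
    X <- matrix(1, 3, 1)
    expect_equal(solveGeneticValues(y, X, 1:3, b = 1, nGeno = 3),
                 y - 1)
    # two observations with residuals 2 and 4 -> mean 3
    expect_equal(solveGeneticValues(c(2, 4), matrix(0, 2, 0), c(1L, 1L),
                                    b = numeric(0), nGeno = 1), 3)
    # R weights [1, 3]: (1*2 + 3*4 wait - weights are 1/RDiag) ->
    # with RDiag = c(1, 1/3): w = c(1, 3), u0 = (1*2 + 3*4)/4 = 3.5
    expect_equal(solveGeneticValues(c(2, 4), matrix(0, 2, 0), c(1L, 1L),
                                    b = numeric(0), nGeno = 1,
                                    RDiag = c(1, 1 / 3)), 3.5)
    expect_error(solveGeneticValues(c(1, 2), matrix(0, 2, 0), c(1L, 1L),
                                    numeric(0), nGeno = 2), ">= 1")
})

test_that("marker step reduces to the plain update for unit weights", {
    M <- randomGenotypes(15, 6, seed = 21)
    set.seed(22)
    u0 <- rnorm(15)
    s1 <- wgrStep(u0, M)
    s2 <- flamix:::.flmEngine(u0, M, weights = rep(1, 15), tol = 0,
                              maxIter = 1L, prior = "laplace",
                              includeIntercept = FALSE)
    expect_equal(s1$beta, s2$beta)

    # weighted no-shrinkage plug-in: codes [-1, 1], weights [2, 2],
    # residual [-1, 1] -> beta = (2*1 + 2*1)/(2 + 2) = 1
    Mw <- genotypeMatrix(matrix(c(-1, 1), 2, 1))
    s3 <- wgrStep(c(-1, 1), Mw, weights = c(2, 2), fixedTauInv2 = 0)
    expect_equal(s3$beta, 1)

    expect_error(wgrStep(c(-1, 1), Mw, weights = c(0, 2)), "positive")
})

test_that("weighted frozen-ridge marker step matches dense weighted ridge", {
    M <- randomGenotypes(20, 10, seed = 31)
    set.seed(32)
    u0 <- rnorm(20)
    w <- sample(1:4, 20, replace = TRUE)
    lam <- 15
    st <- wgrStep(u0, M, weights = w, fixedTauInv2 = lam,
                  innerSweeps = 500L)
    codes <- markerCodes(M)
    bOracle <- solve(crossprod(codes, w * codes) + diag(lam, 10),
                     crossprod(codes, w * u0))
    expect_lt(max(abs(st$beta - bOracle)), 1e-6)
})

test_that("single-stage with Z = I and intercept-only X collapses to FLM", {
    pop <- fixturePop()
    y <- simulatePhenotype(pop, 0.5, seed = 41)
    idx <- 1:100
    Mg <- subsetIndividuals(pop@genotypes, idx)
    td <- trialData(individualIds(Mg), rep("E1", 100), y[idx])
    ss <- fitSingleStage(td, Mg, prior = "laplace", outerTol = 1e-20,
                         outerMaxIter = 3000)
    flm <- fitFLM(y[idx], Mg, tol = 1e-20, maxIter = 3000)
    expect_lt(max(abs(ss@beta - flm@beta)), 1e-6)
    expect_equal(ss@b[[1]], flm@mu, tolerance = 1e-6)
})

test_that("single-stage invariants hold on an unbalanced simulated trial", {
    pop <- fixturePop()
    tr <- simulateTrials(pop, 600, seed = 42)
    fit <- fitSingleStage(tr$trial, pop@genotypes)
    expect_true(fit@converged)
    rows <- match(fit@genoIds, individualIds(pop@genotypes))
    Mg <- markerCodes(pop@genotypes)[rows, , drop = FALSE]
    expect_lt(max(abs(fit@a - drop(Mg %*% fit@beta))), 1e-8)
    pred <- drop(tr$trial@X %*% fit@b) + fit@a[tr$trial@genoIndex]
    expect_lt(max(abs(fit@e - (tr$trial@y - pred))), 1e-6)
    # wgr residual is the genetic signal not captured by markers
    expect_equal(fit@wgrResid, fit@u0 - fit@a, tolerance = 1e-12)
})

test_that("converged single-stage state is a joint fixed point", {
    pop <- fixturePop()
    tr <- simulateTrials(pop, 500, seed = 43)
    fit <- fitSingleStage(tr$trial, pop@genotypes, outerTol = 1e-14,
                          outerMaxIter = 2000)
    td <- tr$trial
    bNew <- solveFixedEffects(td@y, td@X, td@genoIndex, fit@a, td@RDiag)
    expect_lt(max(abs(bNew - fit@b)), 1e-6)
    u0New <- solveGeneticValues(td@y, td@X, td@genoIndex, bNew,
                                length(td@genoIds), td@RDiag)
    expect_lt(max(abs(u0New - fit@u0)), 1e-6)
})

test_that("constant phenotypes give zero genetic signal", {
    M <- randomGenotypes(30, 10, seed = 51)
    td <- trialData(rep(individualIds(M), 2),
                    rep(c("E1", "E2"), each = 30), rep(5, 60))
    fit <- fitSingleStage(td, M)
    expect_equal(unname(fit@b), c(5, 0), tolerance = 1e-8)
    expect_lt(max(abs(fit@a)), 1e-8)
})

test_that("unmapped genotype ids are rejected", {
    M <- randomGenotypes(10, 5, seed = 61)
    td <- trialData(c("nope", individualIds(M)[1:3]),
                    rep("E1", 4), rnorm(4))
    expect_error(fitSingleStage(td, M), "missing from the genotype")
})

test_that("extra random-effect solve matches a dense oracle", {
    set.seed(71)
    W <- matrix(rnorm(200), 40, 5)
    y <- drop(W %*% c(1, -1, 0.5, 0, 2)) + rnorm(40, sd = 0.2)
    fit <- fitExtraRandomEffect(y, W, sigmaG2 = 2, sigmaE2 = 1)
    k <- 1 / 2
    gOracle <- solve(crossprod(W) + diag(k, 5), crossprod(W, y))
    expect_lt(max(abs(fit$g - gOracle)), 1e-8)
    expect_equal(fit$k, k)

    # infinite shrinkage
    fit2 <- fitExtraRandomEffect(y, W, sigmaG2 = 1e-12, sigmaE2 = 1)
    expect_lt(max(abs(fit2$g)), 1e-6)

    # orthonormal W with k = 1: g = W'y / 2
    Worth <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
    y2 <- rnorm(20)
    fit3 <- fitExtraRandomEffect(y2, Worth, sigmaG2 = 1, sigmaE2 = 1)
    expect_equal(fit3$g, drop(crossprod(Worth, y2)) / 2, tolerance = 1e-8)

    expect_error(fitExtraRandomEffect(y, W, sigmaG2 = 0, sigmaE2 = 1),
                 "positive")
})

test_that("extra-variance estimator matches hand plug-ins and modes agree", {
    # g'g = 2, nw = 2, k = 1, each w_j'w_j = 1 -> 2 / (2 - 1) = 2
    W <- diag(2)
    expect_equal(updateExtraVariance(c(1, 1), W, k = 1), 2)
    # zero coefficients floor at a tiny positive value
    expect_lt(updateExtraVariance(c(0, 0), W, k = 1), 1e-12)

    set.seed(81)
    nw <- 40
    Worth <- qr.Q(qr(matrix(rnorm(200 * nw), 200, nw))) * sqrt(200)
    g <- rnorm(nw, sd = 0.7)
    y <- drop(Worth %*% g) + rnorm(200, sd = 0.5)
    fitG <- fitExtraRandomEffect(y, Worth, sigmaG2 = 0.49, sigmaE2 = 0.25)
    exact <- updateExtraVariance(fitG$g, Worth, fitG$k)
    approx <- updateExtraVariance(fitG$g, Worth, fitG$k, yAdj = y,
                                  mode = "approx")
    expect_lt(abs(exact - approx) / exact, 0.10)
})
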