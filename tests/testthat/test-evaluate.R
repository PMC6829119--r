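test_that("accuracy is the Pearson correlation with guarded inputs", {
    expect_equal(accuracy(1:5, 1:5), 1)
    expect_equal(accuracy(-(1:5), 1:5), -1)
    set.seed(3)
    truth <- rnorm(1000)
    pred <- truth + rnorm(1000, sd = 5)
    manual <- sum((pred - mean(pred)) * (truth - mean(truth))) /
        sqrt(sum((pred - mean(pred))^2) * sum((truth - mean(truth))^2))
    expect_equal(accuracy(pred, truth), manual, tolerance = 1e-12)
    expect_error(accuracy(1:5, rep(1, 5)), "constant")
    expect_error(accuracy(1:4, 1:5), "equal length")
    expect_error(accuracy(1:2, 2:1), "at least 3")
})

test_that("k-fold partitions are exhaustive, disjoint and reproducible", {
    M <- randomGenotypes(100, 20, seed = 11)
    set.seed(12)
    y <- rnorm(100) + markerCodes(M)[, 1]
    cv <- kfoldCV(y, M, k = 5, reps = 2, seed = 99)
    res <- cv@results
    expect_equal(nrow(res), 10L)
    expect_true(all(res$n_test == 20))
    cv2 <- kfoldCV(y, M, k = 5, reps = 2, seed = 99)
    expect_identical(res$r, cv2@results$r)
    s <- cvSummary(cv)
    expect_true(s$mean_r >= -1 && s$mean_r <= 1)
})

test_that("k-fold predictive ability separates signal from noise", {
    pop <- fixturePop()
    idx <- 1:300
    Mg <- subsetIndividuals(pop@genotypes, idx)
    ySig <- simulatePhenotype(pop, 0.5, seed = 21)[idx]
    cvSig <- kfoldCV(ySig, Mg, k = 5, reps = 2, seed = 7)
    set.seed(22)
    cvNull <- kfoldCV(sample(ySig), Mg, k = 5, reps = 2, seed = 7)
    mSig <- cvSummary(cvSig)$mean_r
    mNull <- cvSummary(cvNull)$mean_r
    expect_gt(mSig, 0.3)
    expect_gt(mSig, mNull + 0.2)
})

test_that("leave-group-out trains on the complement of each group", {
    M <- randomGenotypes(60, 15, seed = 31)
    set.seed(32)
    y <- rnorm(60) + 0.8 * markerCodes(M)[, 3]
    groups <- rep(c("famA", "famB"), each = 30)
    cv <- leaveGroupOutCV(y, M, groups)
    expect_equal(nrow(cv@results), 2L)
    expect_equal(cv@results$n_test, c(30L, 30L))
    expect_error(leaveGroupOutCV(y, M, rep("famA", 60)), "2 groups")
    expect_warning(leaveGroupOutCV(y[1:32], subsetIndividuals(M, 1:32),
                                   c(rep("famA", 30), "famB", "famB")),
                   "skipped")
})

test_that("across-family prediction captures shared QTL signal", {
    gs <- genomeSpec(nChrom = 4)
    popA <- assignQTL(simulatePopulation(gs, seed = 41, popSize = 120), 4)
    popB <- assignQTL(simulatePopulation(gs, seed = 42, popSize = 120), 4)
    codes <- rbind(markerCodes(popA), markerCodes(popB))
    rownames(codes) <- paste0("x", seq_len(nrow(codes)))
    M <- genotypeMatrix(codes)
    y <- c(simulatePhenotype(popA, 0.6, seed = 43),
           simulatePhenotype(popB, 0.6, seed = 44))
    cv <- leaveGroupOutCV(y, M, rep(c("A", "B"), each = 120))
    expect_gt(mean(cv@results$r), 0.2)
})

test_that("GBLUP oracle matches a direct mixed-model-equation solve", {
    gs <- genomeSpec(nChrom = 4)
    pop <- assignQTL(simulatePopulation(gs, seed = 51, popSize = 50), 4)
    td <- balancedTrial(pop, nEnv = 3, seed = 52)
    orc <- gblupOracle(td, pop@genotypes)

    # dense genotype-level MME with jittered G at the oracle's ratio
    codes <- markerCodes(pop@genotypes)
    Mc <- scale(codes, scale = FALSE)
    pf <- (colMeans(codes) + 1) / 2
    cc <- 2 * sum(pf * (1 - pf))
    G <- tcrossprod(Mc) / cc + diag(1e-8, 50)
    k <- unname(orc$varComp["sigma2e"] / orc$varComp["sigma2a"])
    Z <- as.matrix(incidenceMatrix(td))
    X <- td@X
    lhs <- rbind(cbind(crossprod(X), crossprod(X, Z)),
                 cbind(crossprod(Z, X), crossprod(Z) + k * solve(G)))
    rhs <- c(crossprod(X, td@y), crossprod(Z, td@y))
    sol <- solve(lhs, rhs)
    aMME <- sol[-seq_len(ncol(X))]
    expect_lt(max(abs(orc$aFitted - aMME)), 1e-4 * max(abs(aMME)))
})

test_that("GBLUP restricted likelihood is unimodal along the ratio", {
    gs <- genomeSpec(nChrom = 4)
    pop <- assignQTL(simulatePopulation(gs, seed = 61, popSize = 80), 4)
    td <- balancedTrial(pop, nEnv = 3, seed = 62)
    orc <- gblupOracle(td, pop@genotypes)
    grid <- seq(-8, 8, length.out = 81)
    vals <- vapply(grid, orc$negRL, numeric(1))
    argCoarse <- grid[which.min(vals)]
    fine <- seq(argCoarse - 0.4, argCoarse + 0.4, length.out = 161)
    argFine <- fine[which.min(vapply(fine, orc$negRL, numeric(1)))]
    expect_lt(abs(argFine - log(orc$varComp[["lambda"]])), 0.05)
    # single sign change in the discrete derivative => unimodal profile
    expect_lte(sum(diff(sign(diff(vals))) != 0), 1L)
})

test_that("two-stage baseline reduces sensibly on balanced data", {
    gs <- genomeSpec(nChrom = 4)
    pop <- assignQTL(simulatePopulation(gs, seed = 71, popSize = 60), 4)
    td <- balancedTrial(pop, nEnv = 4, seed = 72)
    ts <- twoStageBaseline(td, pop@genotypes)
    # stage-1 means equal genotype means of environment-centered
    # phenotypes, up to a common constant
    ei <- as.integer(td@env)
    envMeans <- tapply(td@y, ei, mean)
    centered <- td@y - envMeans[ei]
    gMeans <- tapply(centered, td@genoIndex, mean)
    dev <- ts$u - gMeans[as.character(seq_along(ts$u))]
    expect_lt(max(abs(dev - mean(dev))), 1e-6)
    # balanced replication: equal information weights
    expect_lt(diff(range(ts$weights)), 1e-8)
})

test_that("two-stage weights increase with replication", {
    M <- randomGenotypes(12, 8, seed = 81)
    ids <- individualIds(M)
    g <- c(rep(ids[1], 4), ids[2:9])
    e <- c("E1", "E2", "E1", "E2", rep(c("E1", "E2"), 4))
    set.seed(82)
    td <- trialData(g, e, rnorm(12, 10))
    ts <- twoStageBaseline(td, M)
    expect_gt(ts$weights[1], max(ts$weights[-1]) - 1e-12)
})
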