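# Shared fixtures, built once per test run and cached. Populations use the
# default genome (10 chromosomes x 100 cM, 0.5 marker/cM -> 500 markers).

.fixtures <- new.env(parent = emptyenv())

# simulated pool, memoised on (seed, popSize, nQtl)
fixturePop <- function(seed = 101, popSize = 1000L, nQtl = 10L,
                       spec = genomeSpec()) {
    key <- paste("pop", seed, popSize, nQtl, spec$nChrom, sep = "_")
    if (is.null(.fixtures[[key]])) {
        base <- paste("base", seed, popSize, spec$nChrom, sep = "_")
        if (is.null(.fixtures[[base]]))
            .fixtures[[base]] <- simulatePopulation(spec, seed = seed,
                                                    popSize = popSize)
        .fixtures[[key]] <- assignQTL(.fixtures[[base]], nQtl)
    }
    .fixtures[[key]]
}

# small random genotype matrix with guaranteed polymorphic columns
randomGenotypes <- function(n, p, seed) {
    set.seed(seed)
    repeat {
        m <- matrix(sample(c(-1L, 0L, 1L), n * p, replace = TRUE), n, p)
        if (all(apply(m, 2L, function(x) length(unique(x))) > 1L)) break
    }
    genotypeMatrix(m)
}

# dense penalized normal-equations oracle: the exact fixed point of
# intercept + coordinate descent with frozen common regularizer c is the
# centered ridge system (Mc'Mc + cI) beta = Mc'(y - ybar)
ridgeOracle <- function(y, M, cPen) {
    codes <- if (is(M, "GenotypeMatrix")) markerCodes(M) else M
    Mc <- scale(codes, scale = FALSE)
    drop(solve(crossprod(Mc) + diag(cPen, ncol(Mc)),
               crossprod(Mc, y - mean(y))))
}

# balanced multi-environment trial: every genotype once per environment
balancedTrial <- function(pop, nEnv = 4L, seed = 1L) {
    ids <- individualIds(pop@genotypes)
    nG <- length(ids)
    set.seed(seed)
    envEff <- rnorm(nEnv, 100, 20)
    h2 <- runif(nEnv, 0.25, 0.75)
    noiseSd <- sqrt(var(trueBreedingValues(pop)) * (1 - h2) / h2)
    env <- rep(seq_len(nEnv), each = nG)
    y <- envEff[env] + rep(trueBreedingValues(pop), nEnv) +
        rnorm(nG * nEnv, 0, noiseSd[env])
    trialData(rep(ids, nEnv), sprintf("E%d", env), y)
}
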