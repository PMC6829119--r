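#' Genome specification for the breeding-population simulator
#'
#' Defines the simulated genome: number of chromosomes, map length per
#' chromosome and marker density. Defaults give 10 chromosomes of 100 cM at
#' 0.5 markers/cM, i.e. 500 markers at 2-cM spacing (positions 1, 3, ...,
#' 99 cM within each chromosome).
#'
#' @param nChrom number of chromosomes (default 10).
#' @param chromLenCM map length per chromosome in centimorgans (default 100).
#' @param markerDensity markers per cM (default 0.5).
#' @return list with the parameters and a data.frame \code{map} (columns
#'   marker, chrom, cM), positions strictly increasing within chromosome.
#' @export
genomeSpec <- function(nChrom = 10L, chromLenCM = 100, markerDensity = 0.5) {
    mPerChrom <- as.integer(round(chromLenCM * markerDensity))
    if (nChrom < 1L || mPerChrom < 1L)
        stop("genome must have >= 1 chromosome and >= 1 marker per chromosome")
    spacing <- chromLenCM / mPerChrom
    pos <- spacing * (seq_len(mPerChrom) - 0.5)   # marker midpoints
    map <- data.frame(
        marker = paste0("c", rep(seq_len(nChrom), each = mPerChrom), "_m",
                        rep(seq_len(mPerChrom), nChrom)),
        chrom = rep(seq_len(nChrom), each = mPerChrom),
        cM = rep(pos, nChrom), stringsAsFactors = FALSE)
    list(nChrom = as.integer(nChrom), chromLenCM = chromLenCM,
         markerDensity = markerDensity, markersPerChrom = mPerChrom,
         map = map)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards, so the generators are pure functions of (input, seed).
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    code
}

# One gamete per row of `parents`: a recombination mosaic of the parent's
# two haplotypes. Haldane's no-interference model is simulated as the
# equivalent Markov process along each chromosome: the starting haplotype
# is Bernoulli(1/2) and the phase switches between adjacent markers with
# probability r = 0.5 (1 - exp(-2 d / 100)) for map distance d in cM
# (identical in law to Poisson crossover counts with uniform breakpoints).
.makeGametes <- function(h1, h2, parents, map) {
    n <- length(parents)
    p <- ncol(h1)
    out <- matrix(0L, n, p)
    for (ch in unique(map$chrom)) {
        idx <- which(map$chrom == ch)
        d <- diff(map$cM[idx])
        r <- 0.5 * (1 - exp(-2 * d / 100))
        m <- length(idx)
        phase <- matrix(0L, n, m)
        phase[, 1L] <- rbinom(n, 1L, 0.5)
        if (m > 1L) {
            sw <- matrix(rbinom(n * (m - 1L), 1L, rep(r, each = n)),
                         n, m - 1L)
            phase <- t(apply(cbind(phase[, 1L], sw), 1L, cumsum)) %% 2L
        }
        a1 <- h1[parents, idx, drop = FALSE]
        a2 <- h2[parents, idx, drop = FALSE]
        out[, idx] <- ifelse(phase == 0L, a1, a2)
    }
    out
}

#' Simulate a bottlenecked F2-derived breeding population
#'
#' Forward-in-time simulation of the genetic pool: two fully homozygous,
#' maximally divergent inbred founders (all +1 vs all -1) are crossed; the
#' F1 is selfed/inter-mated by meiosis to give an F2 of \code{popSize}
#' individuals; then \code{nCycles} cycles of (sample \code{bottleneck}
#' individuals without replacement, random mating back up to
#' \code{popSize}) generate drift and linkage disequilibrium. Parents in
#' the random-mating step are drawn independently, so selfing can occur.
#' Meiosis uses Haldane's map function without interference.
#'
#' @param spec a \code{\link{genomeSpec}}.
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param popSize population size at the F2 and after every mating cycle
#'   (default 1000).
#' @param bottleneck individuals sampled before each random-mating cycle
#'   (default 250).
#' @param nCycles number of bottleneck/random-mating cycles (default 5).
#' @return a \code{\link{SimulatedPopulation}} (no QTL assigned yet; see
#'   \code{\link{assignQTL}}).
#' @examples
#' pop <- simulatePopulation(genomeSpec(nChrom = 2), seed = 1, popSize = 50)
#' pop
#' @export
simulatePopulation <- function(spec = genomeSpec(), seed, popSize = 1000L,
                               bottleneck = 250L, nCycles = 5L) {
    if (popSize < 2L)
        stop("population size must be >= 2")
    bottleneck <- min(bottleneck, popSize)
    map <- spec$map
    p <- nrow(map)
    .withSeed(seed, {
        # founders: haplotype allele 1 = founder A (+1), 0 = founder B (-1)
        # F1 is heterozygous everywhere: h1 all 1, h2 all 0
        h1 <- matrix(1L, 1L, p)
        h2 <- matrix(0L, 1L, p)
        # F2: each individual receives two independent F1 gametes
        par <- rep(1L, popSize)
        h1 <- rbind(.makeGametes(h1, h2, par, map))
        h2g <- .makeGametes(matrix(1L, 1L, p), matrix(0L, 1L, p), par, map)
        H1 <- h1
        H2 <- h2g
        for (cyc in seq_len(nCycles)) {
            keep <- sample.int(nrow(H1), bottleneck, replace = FALSE)
            H1k <- H1[keep, , drop = FALSE]
            H2k <- H2[keep, , drop = FALSE]
            mom <- sample.int(bottleneck, popSize, replace = TRUE)
            dad <- sample.int(bottleneck, popSize, replace = TRUE)
            H1 <- .makeGametes(H1k, H2k, mom, map)
            H2 <- .makeGametes(H1k, H2k, dad, map)
        }
        codes <- H1 + H2 - 1L   # {0,1}+{0,1}-1 -> {-1,0,1}
        rownames(codes) <- paste0("g", seq_len(popSize))
        colnames(codes) <- map$marker
        gm <- genotypeMatrix(codes)
        new("SimulatedPopulation", genotypes = gm, map = map,
            qtlIndex = integer(), qtlEffect = numeric(),
            tbv = numeric(popSize),
            alleleFreq = (colMeans(codes) + 1) / 2)
    })
}

#' Assign causal markers (QTL) and compute true breeding values
#'
#' For 10 QTL (one per chromosome on the default genome) the causal marker
#' is the central marker of each chromosome; for denser architectures the
#' QTL are placed evenly spaced within each chromosome. Effects alternate
#' +1, -1, +1, ... starting at +1, continuing across chromosomes. True
#' breeding values are the QTL-code weighted sums.
#'
#' @param pop a \code{\link{SimulatedPopulation}}.
#' @param nQtl number of causal markers; must be a multiple of the
#'   chromosome count (10, 50 and 100 on the default genome).
#' @return the population with \code{qtlIndex}, \code{qtlEffect} and
#'   \code{tbv} filled in.
#' @export
assignQTL <- function(pop, nQtl) {
    stopifnot(is(pop, "SimulatedPopulation"))
    map <- pop@map
    chroms <- unique(map$chrom)
    nc <- length(chroms)
    p <- nrow(map)
    if (nQtl > p)
        stop("more QTL requested than markers available")
    if (nQtl %% nc != 0L)
        stop("nQtl must be a multiple of the chromosome count (", nc, ")")
    perChrom <- nQtl %/% nc
    idx <- integer(0)
    for (ch in chroms) {
        mIdx <- which(map$chrom == ch)
        m <- length(mIdx)
        if (perChrom == 1L) {
            sel <- floor(m / 2) + 1L            # central marker
        } else {
            sel <- round((seq_len(perChrom) - 0.5) / perChrom * m)
            sel <- pmin(pmax(sel, 1L), m)
        }
        idx <- c(idx, mIdx[sel])
    }
    eff <- rep_len(c(1, -1), nQtl)
    pop@qtlIndex <- as.integer(idx)
    pop@qtlEffect <- eff
    pop@tbv <- drop(pop@genotypes@codes[, idx, drop = FALSE] %*% eff)
    pop
}

#' Simulate a single-value phenotype at a target heritability
#'
#' \code{y = tbv + e}, \code{e ~ N(0, var(tbv) (1 - h2) / h2)}, so the
#' expected ratio var(tbv)/var(y) equals \code{h2}.
#'
#' @param pop a \code{\link{SimulatedPopulation}} with QTL assigned.
#' @param h2 target narrow-sense heritability, in (0, 1).
#' @param seed integer seed.
#' @return numeric phenotype vector, one value per individual.
#' @export
simulatePhenotype <- function(pop, h2, seed) {
    stopifnot(is(pop, "SimulatedPopulation"))
    if (!(h2 > 0 && h2 < 1))
        stop("h2 must lie strictly between 0 and 1")
    vt <- var(pop@tbv)
    if (vt == 0)
        stop("true breeding values are constant; assign QTL first")
    .withSeed(seed,
        pop@tbv + rnorm(length(pop@tbv), 0, sqrt(vt * (1 - h2) / h2)))
}

#' Simulate an unbalanced multi-environment trial from a genetic pool
#'
#' Observations are sampled with replacement from the population's
#' genotypes and allocated to environments uniformly at random, so
#' environments end up with unequal entry counts and many genotypes are
#' unreplicated at small n. The number of environments is drawn uniformly
#' from \code{4..10}, environment effects from N(100, 20^2), and each
#' environment gets its own heritability drawn uniformly from
#' [0.25, 0.75] (heteroscedastic noise). Phenotype = environment effect +
#' true breeding value + N(0, var_pool(tbv) (1 - h2_env) / h2_env), where
#' the pool variance keeps the per-environment heritability interpretable.
#' No genotype-by-environment interaction, dominance or spatial structure
#' is generated.
#'
#' Draw order within one seed: environment count, environment effects,
#' environment heritabilities, genotype assignment, environment assignment,
#' noise.
#'
#' @param pop a \code{\link{SimulatedPopulation}} with QTL assigned.
#' @param nObs total number of observations across environments.
#' @param seed integer seed.
#' @param nEnvRange integer range to draw the environment count from
#'   (default 4:10).
#' @param envMean,envSd environment-effect distribution (default 100, 20).
#' @param h2Range per-environment heritability range (default
#'   c(0.25, 0.75)).
#' @return list with components \code{trial} (a \code{\link{TrialData}}),
#'   \code{scenario} (a \code{\link{TrialScenario}}) and \code{tbv} (pool
#'   true breeding values, named by genotype id).
#' @export
simulateTrials <- function(pop, nObs, seed, nEnvRange = 4:10,
                           envMean = 100, envSd = 20,
                           h2Range = c(0.25, 0.75)) {
    stopifnot(is(pop, "SimulatedPopulation"))
    nPool <- length(pop@tbv)
    if (var(pop@tbv) == 0)
        stop("assign QTL before simulating trials")
    .withSeed(seed, {
        nEnv <- sample(nEnvRange, 1L)
        if (nObs < nEnv)
            stop("nObs must be at least the number of environments")
        envEff <- rnorm(nEnv, envMean, envSd)
        envH2 <- runif(nEnv, h2Range[1L], h2Range[2L])
        geno <- sample.int(nPool, nObs, replace = TRUE)
        env <- sample.int(nEnv, nObs, replace = TRUE)
        vt <- var(pop@tbv)
        noiseSd <- sqrt(vt * (1 - envH2) / envH2)
        y <- envEff[env] + pop@tbv[geno] + rnorm(nObs, 0, noiseSd[env])
        ids <- pop@genotypes@individualIds
        trial <- trialData(genotype = ids[geno],
                           environment = sprintf("E%02d", env), y = y)
        scen <- new("TrialScenario", nObs = as.integer(nObs),
                    nEnv = as.integer(nEnv), envEffect = envEff,
                    envH2 = envH2, genotype = geno,
                    environment = as.integer(env))
        list(trial = trial, scenario = scen,
             tbv = setNames(pop@tbv, ids))
    })
}
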