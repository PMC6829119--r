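#' GenotypeMatrix: biallelic marker codes with per-column summaries
#'
#' Holds an \code{n} individuals by \code{p} markers matrix of allele-dosage
#' codes in \{-1, 0, 1\} (aa/Aa/AA), together with the per-column
#' cross-products \code{m_j'm_j}, the per-column variances used by the
#' Laplace scale parameter, and row/column identifiers. Construct with
#' \code{\link{genotypeMatrix}}.
#'
#' @slot codes numeric matrix of marker codes, entries in \{-1, 0, 1\}.
#' @slot colSq per-marker sum of squares \code{m_j'm_j}.
#' @slot colVar per-marker variance (denominator \code{n}, population
#'   convention); exactly 0 for monomorphic columns.
#' @slot markerIds,individualIds character labels.
#' @export
setClass("GenotypeMatrix",
    representation(codes = "matrix", colSq = "numeric", colVar = "numeric",
                   markerIds = "character", individualIds = "character"))

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    cd <- object@codes
    if (!all(cd %in% c(-1, 0, 1)))
        msg <- c(msg, "genotype codes must all be in {-1, 0, 1}")
    if (length(object@colSq) != ncol(cd) || length(object@colVar) != ncol(cd))
        msg <- c(msg, "colSq/colVar length must equal the marker count")
    if (length(object@markerIds) != ncol(cd))
        msg <- c(msg, "markerIds length must equal the marker count")
    if (length(object@individualIds) != nrow(cd))
        msg <- c(msg, "individualIds length must equal the individual count")
    if (length(msg)) msg else TRUE
})

#' FLMFit: converged state of the fast Laplace model
#'
#' Returned by \code{\link{fitFLM}}. Slots mirror the model parameters: the
#' intercept, per-marker effects and their full-conditional variances, the
#' per-marker regularizers, the residual variance estimated by maximum
#' likelihood, the residual vector, and the (data-determined) Laplace scale
#' \code{lambda2}, the sum of marker variances.
#'
#' @slot mu intercept, trait units.
#' @slot beta marker effects, length p.
#' @slot betaVar full-conditional marker-effect variances, length p
#'   (\code{NA} for monomorphic markers).
#' @slot tauInv2 per-marker regularizers, length p.
#' @slot residVar residual variance (strictly positive).
#' @slot resid residual vector, length n.
#' @slot lambda2 Laplace scale parameter (sum of marker variances).
#' @slot prior \code{"laplace"}, \code{"gaussian"} or \code{"fixed"}.
#' @slot nIter number of full sweeps used.
#' @slot converged logical.
#' @slot markerIds character labels carried from the genotypes.
#' @export
setClass("FLMFit",
    representation(mu = "numeric", beta = "numeric", betaVar = "numeric",
                   tauInv2 = "numeric", residVar = "numeric",
                   resid = "numeric", lambda2 = "numeric", prior = "character",
                   nIter = "integer", converged = "logical",
                   markerIds = "character"))

setValidity("FLMFit", function(object) {
    msg <- character()
    p <- length(object@beta)
    if (length(object@tauInv2) != p || length(object@betaVar) != p)
        msg <- c(msg, "beta, betaVar and tauInv2 must have equal length")
    if (length(object@residVar) != 1L || object@residVar <= 0)
        msg <- c(msg, "residVar must be a single strictly positive value")
    if (any(object@tauInv2 < 0, na.rm = TRUE))
        msg <- c(msg, "tauInv2 must be nonnegative (0 only in the",
                 " frozen no-shrinkage test mode)")
    if (length(msg)) msg else TRUE
})

#' TrialData: replicated multi-environment phenotypes
#'
#' Observation-level phenotypes with an environment fixed-effect design and
#' a genotype incidence. Only genotypes with at least one observation are
#' fitted; \code{genoIds} names them in the order of the incidence columns.
#' Construct with \code{\link{trialData}} or \code{\link{readTrials}}.
#'
#' @slot y phenotypes, length N.
#' @slot X fixed-effect design (intercept + environment treatment
#'   contrasts), N x f, full column rank.
#' @slot genoIndex integer, length N: which fitted genotype each observation
#'   belongs to (column of the implicit incidence Z).
#' @slot genoIds character, one per fitted genotype.
#' @slot env factor, length N.
#' @slot RDiag residual weight diagonal, length N (default all 1).
#' @slot obsCounts replicate counts per fitted genotype (diag of Z'Z).
#' @export
setClass("TrialData",
    representation(y = "numeric", X = "matrix", genoIndex = "integer",
                   genoIds = "character", env = "factor", RDiag = "numeric",
                   obsCounts = "numeric"))

setValidity("TrialData", function(object) {
    msg <- character()
    N <- length(object@y)
    if (nrow(object@X) != N || length(object@genoIndex) != N ||
        length(object@env) != N || length(object@RDiag) != N)
        msg <- c(msg, "y, X, genoIndex, env and RDiag must agree in length")
    ng <- length(object@genoIds)
    if (any(object@genoIndex < 1L) || any(object@genoIndex > ng))
        msg <- c(msg, "genoIndex out of range of genoIds")
    if (length(object@obsCounts) != ng)
        msg <- c(msg, "obsCounts must have one entry per fitted genotype")
    else if (any(object@obsCounts < 1))
        msg <- c(msg, "every fitted genotype needs >= 1 observation")
    if (any(object@RDiag <= 0))
        msg <- c(msg, "RDiag must be strictly positive")
    if (length(msg)) msg else TRUE
})

#' SingleStageFit: joint solution of the iterative single-stage model
#'
#' Returned by \code{\link{fitSingleStage}}. Holds the fixed-effect
#' coefficients, the intermediary least-squares genotype values, the marker
#' effects, the breeding values a = M beta for the fitted genotypes, the
#' observation-level residuals, and the marker-step residual (genetic signal
#' not captured by the markers).
#'
#' @slot b fixed-effect coefficients.
#' @slot u0 least-squares genetic values per fitted genotype.
#' @slot beta marker effects.
#' @slot a breeding values (fitted genotypes), a = M beta.
#' @slot e observation residuals y - Xb - Za.
#' @slot wgrResid genotype-level residual u0 - M beta.
#' @slot residVarObs observation residual variance.
#' @slot residVarWGR residual variance of the marker step.
#' @slot prior,weighting configuration actually used.
#' @slot extra list of additional random-effect fits (empty by default).
#' @slot nIter outer iterations used; @slot converged logical.
#' @slot genoIds,markerIds labels.
#' @export
setClass("SingleStageFit",
    representation(b = "numeric", u0 = "numeric", beta = "numeric",
                   a = "numeric", e = "numeric", wgrResid = "numeric",
                   residVarObs = "numeric", residVarWGR = "numeric",
                   prior = "character", weighting = "character",
                   extra = "list", nIter = "integer", converged = "logical",
                   genoIds = "character", markerIds = "character"))

#' SimulatedPopulation: forward-in-time simulated breeding population
#'
#' Output of \code{\link{simulatePopulation}} (optionally augmented by
#' \code{\link{assignQTL}}): genotypes, marker map, causal-marker positions
#' and effects, true breeding values, and allele frequencies.
#'
#' @slot genotypes a \code{GenotypeMatrix}.
#' @slot map data.frame with columns marker, chrom, cM.
#' @slot qtlIndex integer column indices of the causal markers (empty until
#'   \code{assignQTL} is called).
#' @slot qtlEffect numeric effects, alternating +1/-1.
#' @slot tbv true breeding values, one per individual.
#' @slot alleleFreq per-marker frequency of the +1 allele.
#' @export
setClass("SimulatedPopulation",
    representation(genotypes = "GenotypeMatrix", map = "data.frame",
                   qtlIndex = "integer", qtlEffect = "numeric",
                   tbv = "numeric", alleleFreq = "numeric"))

#' TrialScenario: sampled design of a simulated multi-environment trial
#'
#' @slot nObs total observations; @slot nEnv environment count (4..10).
#' @slot envEffect per-environment mean; @slot envH2 per-environment target
#'   heritability in [0.25, 0.75].
#' @slot genotype,environment integer assignment per observation.
#' @export
setClass("TrialScenario",
    representation(nObs = "integer", nEnv = "integer", envEffect = "numeric",
                   envH2 = "numeric", genotype = "integer",
                   environment = "integer"))

setValidity("TrialScenario", function(object) {
    msg <- character()
    if (object@nEnv < 4L || object@nEnv > 10L)
        msg <- c(msg, "nEnv must lie in [4, 10]")
    if (any(object@envH2 < 0.25 | object@envH2 > 0.75))
        msg <- c(msg, "every envH2 must lie in [0.25, 0.75]")
    if (length(msg)) msg else TRUE
})

#' CVResult: per-split predictive ability from cross-validation
#'
#' @slot scheme \code{"within_kfold"} or \code{"leave_group_out"}.
#' @slot results data.frame with columns rep, split, n_test, r (Pearson
#'   correlation of predicted vs observed on the held-out split; \code{NA}
#'   for skipped degenerate splits).
#' @export
setClass("CVResult",
    representation(scheme = "character", results = "data.frame"))

setValidity("CVResult", function(object) {
    r <- object@results$r
    if (any(!is.na(r) & (r < -1 | r > 1)))
        "correlations must lie in [-1, 1]" else TRUE
})
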