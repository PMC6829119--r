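#' @name flamix-accessors
#' @title Accessors for flamix objects
#' @description Small accessor generics: marker codes and per-column
#'   summaries of a \code{GenotypeMatrix}; effects, breeding values and
#'   variance components of fitted objects.
#' @param object a flamix S4 object.
#' @param ... unused.
NULL

#' @rdname flamix-accessors
#' @export
setGeneric("markerCodes", function(object, ...) standardGeneric("markerCodes"))
#' @rdname flamix-accessors
#' @export
setGeneric("colSq", function(object, ...) standardGeneric("colSq"))
#' @rdname flamix-accessors
#' @export
setGeneric("colVar", function(object, ...) standardGeneric("colVar"))
#' @rdname flamix-accessors
#' @export
setGeneric("lambda2", function(object, ...) standardGeneric("lambda2"))
#' @rdname flamix-accessors
#' @export
setGeneric("markerIds", function(object, ...) standardGeneric("markerIds"))
#' @rdname flamix-accessors
#' @export
setGeneric("individualIds", function(object, ...)
    standardGeneric("individualIds"))
#' @rdname flamix-accessors
#' @export
setGeneric("markerEffects", function(object, ...)
    standardGeneric("markerEffects"))
#' @rdname flamix-accessors
#' @export
setGeneric("breedingValues", function(object, ...)
    standardGeneric("breedingValues"))
#' @rdname flamix-accessors
#' @export
setGeneric("residVar", function(object, ...) standardGeneric("residVar"))
#' @rdname flamix-accessors
#' @export
setGeneric("fixedEffects", function(object, ...)
    standardGeneric("fixedEffects"))
#' @rdname flamix-accessors
#' @export
setGeneric("trueBreedingValues", function(object, ...)
    standardGeneric("trueBreedingValues"))
#' @rdname flamix-accessors
#' @export
setGeneric("incidenceMatrix", function(object, ...)
    standardGeneric("incidenceMatrix"))
#' @rdname flamix-accessors
#' @export
setGeneric("cvSummary", function(object, ...) standardGeneric("cvSummary"))

setMethod("markerCodes", "GenotypeMatrix", function(object, ...) object@codes)
setMethod("colSq", "GenotypeMatrix", function(object, ...) object@colSq)
setMethod("colVar", "GenotypeMatrix", function(object, ...) object@colVar)
setMethod("lambda2", "GenotypeMatrix", function(object, ...)
    sum(object@colVar))
setMethod("lambda2", "FLMFit", function(object, ...) object@lambda2)
setMethod("markerIds", "GenotypeMatrix", function(object, ...)
    object@markerIds)
setMethod("markerIds", "FLMFit", function(object, ...) object@markerIds)
setMethod("individualIds", "GenotypeMatrix", function(object, ...)
    object@individualIds)
setMethod("markerEffects", "FLMFit", function(object, ...)
    setNames(object@beta, object@markerIds))
setMethod("markerEffects", "SingleStageFit", function(object, ...)
    setNames(object@beta, object@markerIds))
setMethod("residVar", "FLMFit", function(object, ...) object@residVar)
setMethod("residVar", "SingleStageFit", function(object, ...)
    object@residVarObs)
setMethod("fixedEffects", "SingleStageFit", function(object, ...) object@b)
setMethod("breedingValues", "SingleStageFit", function(object, ...)
    setNames(object@a, object@genoIds))
setMethod("markerCodes", "SimulatedPopulation", function(object, ...)
    object@genotypes@codes)
setMethod("trueBreedingValues", "SimulatedPopulation", function(object, ...)
    object@tbv)

#' @importClassesFrom Matrix sparseMatrix
setMethod("incidenceMatrix", "TrialData", function(object, ...) {
    Matrix::sparseMatrix(i = seq_along(object@genoIndex),
                         j = object@genoIndex, x = 1,
                         dims = c(length(object@y), length(object@genoIds)),
                         dimnames = list(NULL, object@genoIds))
})

setMethod("cvSummary", "CVResult", function(object, ...) {
    r <- object@results$r
    ok <- !is.na(r)
    data.frame(scheme = object@scheme, n_splits = length(r),
               n_used = sum(ok), mean_r = mean(r[ok]), sd_r = sd(r[ok]))
})

setMethod("show", "GenotypeMatrix", function(object) {
    cat("GenotypeMatrix:", nrow(object@codes), "individuals x",
        ncol(object@codes), "markers\n")
    mono <- sum(object@colVar == 0)
    cat("  polymorphic:", ncol(object@codes) - mono,
        " monomorphic:", mono,
        " lambda2 (sum of marker variances):",
        format(sum(object@colVar), digits = 5), "\n")
})

setMethod("show", "FLMFit", function(object) {
    cat("FLMFit (", object@prior, " prior): ", length(object@beta),
        " markers\n", sep = "")
    cat("  mu =", format(object@mu, digits = 5),
        " residVar =", format(object@residVar, digits = 5),
        " lambda2 =", format(object@lambda2, digits = 5), "\n")
    cat("  sweeps =", object@nIter,
        if (object@converged) "(converged)" else "(NOT converged)", "\n")
})

setMethod("show", "TrialData", function(object) {
    cat("TrialData:", length(object@y), "observations,",
        length(object@genoIds), "genotypes,",
        nlevels(object@env), "environments\n")
    cat("  replicate counts: min", min(object@obsCounts),
        "median", stats::median(object@obsCounts),
        "max", max(object@obsCounts), "\n")
})

setMethod("show", "SingleStageFit", function(object) {
    cat("SingleStageFit (", object@prior, " prior, weighting ",
        object@weighting, ")\n", sep = "")
    cat("  ", length(object@genoIds), " genotypes, ",
        length(object@beta), " markers, ", length(object@b),
        " fixed effects\n", sep = "")
    cat("  outer iterations =", object@nIter,
        if (object@converged) "(converged)" else "(NOT converged)", "\n")
})

setMethod("show", "SimulatedPopulation", function(object) {
    cat("SimulatedPopulation:", nrow(object@genotypes@codes),
        "individuals,", ncol(object@genotypes@codes), "markers on",
        length(unique(object@map$chrom)), "chromosomes\n")
    if (length(object@qtlIndex))
        cat("  QTL:", length(object@qtlIndex),
            "causal markers, effects +/-1; var(tbv) =",
            format(var(object@tbv), digits = 4), "\n")
    else cat("  no QTL assigned yet (see assignQTL)\n")
})

setMethod("show", "CVResult", function(object) {
    s <- cvSummary(object)
    cat("CVResult [", object@scheme, "]: ", s$n_used, "/", s$n_splits,
        " splits, mean r = ", format(s$mean_r, digits = 4),
        " (sd ", format(s$sd_r, digits = 4), ")\n", sep = "")
})
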