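#' Construct a GenotypeMatrix from raw marker codes
#'
#' Validates that every cell is one of \{-1, 0, 1\} (aa/Aa/AA dosage coding,
#' symmetric convention) and precomputes the per-column summaries the
#' coordinate-descent solver needs: the cross-products \code{m_j'm_j} and the
#' per-column variances whose sum is the Laplace scale parameter
#' \code{lambda2}. Codes in \{0, 1, 2\} can be shifted on input with
#' \code{coding = "dosage"}.
#'
#' @param codes numeric/integer matrix, individuals in rows, markers in
#'   columns.
#' @param coding \code{"symmetric"} for \{-1,0,1\} input (default) or
#'   \code{"dosage"} for \{0,1,2\} input, which is mapped to \{-1,0,1\} by
#'   subtracting 1.
#' @param markerIds,individualIds optional labels; defaults come from
#'   dimnames or are generated.
#' @return a \code{\link{GenotypeMatrix}}.
#' @examples
#' M <- genotypeMatrix(rbind(c(-1, 0), c(1, 0)))
#' colSq(M)   # c(2, 0)
#' lambda2(M) # sum of column variances
#' @export
genotypeMatrix <- function(codes, coding = c("symmetric", "dosage"),
                           markerIds = NULL, individualIds = NULL) {
    coding <- match.arg(coding)
    if (!is.matrix(codes))
        codes <- as.matrix(codes)
    if (nrow(codes) < 2L || ncol(codes) < 1L)
        stop("genotype matrix needs >= 2 individuals and >= 1 marker")
    storage.mode(codes) <- "double"
    if (coding == "dosage")
        codes <- codes - 1
    bad <- which(!(codes %in% c(-1, 0, 1)))
    if (length(bad)) {
        i <- ((bad[1L] - 1L) %% nrow(codes)) + 1L
        j <- ((bad[1L] - 1L) %/% nrow(codes)) + 1L
        stop(sprintf(
            "invalid genotype code %s at row %d, column %d (allowed: -1, 0, 1)",
            format(codes[i, j]), i, j))
    }
    if (is.null(markerIds))
        markerIds <- colnames(codes)
    if (is.null(markerIds))
        markerIds <- paste0("m", seq_len(ncol(codes)))
    if (is.null(individualIds))
        individualIds <- rownames(codes)
    if (is.null(individualIds))
        individualIds <- paste0("id", seq_len(nrow(codes)))
    dimnames(codes) <- list(individualIds, markerIds)
    st <- columnStats(codes)
    new("GenotypeMatrix", codes = codes, colSq = st$colSq,
        colVar = st$colVar, markerIds = as.character(markerIds),
        individualIds = as.character(individualIds))
}

#' Per-column summaries of a genotype matrix
#'
#' Computes, for each marker column, the sum of squares \code{m_j'm_j} and
#' the variance with denominator \code{n} (population convention), plus the
#' Laplace scale parameter \code{lambda2}, defined as the sum of the marker
#' variances. Monomorphic (constant) columns have variance exactly 0.
#'
#' @param M numeric matrix or \code{GenotypeMatrix}.
#' @return list with components \code{colSq}, \code{colVar} and
#'   \code{lambda2}.
#' @examples
#' columnStats(cbind(c(-1, 1)))   # colSq 2, colVar 1, lambda2 1
#' @export
columnStats <- function(M) {
    if (is(M, "GenotypeMatrix"))
        M <- M@codes
    if (!is.matrix(M))
        M <- as.matrix(M)
    if (nrow(M) < 2L || ncol(M) < 1L)
        stop("columnStats needs a matrix with >= 2 rows and >= 1 column")
    n <- nrow(M)
    cs <- colSums(M * M)
    cm <- colMeans(M)
    cv <- cs / n - cm^2
    cv[cv < 0] <- 0          # guard round-off on constant columns
    cv[apply(M, 2L, function(x) all(x == x[1L]))] <- 0
    list(colSq = unname(cs), colVar = unname(cv), lambda2 = sum(cv))
}

#' Subset a GenotypeMatrix by individuals
#'
#' Returns a new \code{GenotypeMatrix} restricted to the given rows, with
#' column summaries recomputed on the subset (a marker monomorphic within
#' the subset is treated as monomorphic there).
#'
#' @param object a \code{GenotypeMatrix}.
#' @param i integer, logical or character row index.
#' @return a \code{GenotypeMatrix}.
#' @export
subsetIndividuals <- function(object, i) {
    stopifnot(is(object, "GenotypeMatrix"))
    genotypeMatrix(object@codes[i, , drop = FALSE])
}
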