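## Table dialects: UTF-8 delimited text, tab by default with comma
## auto-detect, decimal point only. Every writer emits a format-version
## comment line; readers skip comment lines. Identifiers are opaque strings
## whose order is taken from the genotype file and preserved everywhere.

.FORMAT_VERSION <- "flamix-table-v1"

.detectSep <- function(path) {
    ln <- readLines(path, n = 25L, warn = FALSE)
    ln <- ln[!startsWith(ln, "#")]
    if (!length(ln)) stop("empty file: ", path)
    if (grepl("\t", ln[1L])) "\t" else if (grepl(",", ln[1L])) "," else "\t"
}

.readTable <- function(path, ...) {
    if (!file.exists(path))
        stop("file not found: ", path)
    read.table(path, header = TRUE, sep = .detectSep(path),
               comment.char = "#", check.names = FALSE,
               stringsAsFactors = FALSE, ...)
}

.writeTable <- function(df, path, sep = "\t") {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# ", .FORMAT_VERSION), con)
    write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a genotype table
#'
#' Rows are individuals, the header gives marker ids, the first column the
#' individual id, cells are codes in \{-1, 0, 1\} (or \{0, 1, 2\} with
#' \code{coding = "dosage"}, shifted on input). Invalid cells are reported
#' with their row and column. Monomorphic markers are flagged with a
#' message.
#'
#' @param path file path (tab- or comma-delimited, UTF-8).
#' @param coding \code{"symmetric"} (default) or \code{"dosage"}.
#' @return a \code{\link{GenotypeMatrix}}.
#' @export
readGenotypes <- function(path, coding = c("symmetric", "dosage")) {
    coding <- match.arg(coding)
    df <- .readTable(path)
    if (ncol(df) < 2L)
        stop("genotype file needs an id column plus >= 1 marker column")
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[-1L])
    if (!is.numeric(m))
        stop("non-numeric genotype cells in ", path)
    allowed <- if (coding == "dosage") c(0, 1, 2) else c(-1, 0, 1)
    bad <- which(!(m %in% allowed))
    if (length(bad)) {
        i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
        j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
        stop(sprintf(
            "invalid genotype code %s at row %d (id %s), marker %s",
            format(m[i, j]), i, ids[i], colnames(m)[j]))
    }
    gm <- genotypeMatrix(m, coding = coding, markerIds = colnames(m),
                         individualIds = ids)
    nMono <- sum(gm@colVar == 0)
    if (nMono > 0)
        message(nMono, " monomorphic marker(s) flagged; they carry no ",
                "information and are excluded from sweeps")
    gm
}

#' Write a genotype table
#'
#' Inverse of \code{\link{readGenotypes}} (symmetric coding).
#'
#' @param object a \code{\link{GenotypeMatrix}}.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return the path, invisibly.
#' @export
writeGenotypes <- function(object, path, sep = "\t") {
    stopifnot(is(object, "GenotypeMatrix"))
    df <- data.frame(id = object@individualIds,
                     object@codes, check.names = FALSE)
    .writeTable(df, path, sep)
}

#' Read a phenotype table (id, value)
#'
#' @param path two-column delimited table: individual id, trait value.
#' @return data.frame with columns \code{id}, \code{value}.
#' @export
readPhenotypes <- function(path) {
    df <- .readTable(path)
    if (ncol(df) < 2L)
        stop("phenotype file needs columns (id, value)")
    out <- data.frame(id = as.character(df[[1L]]),
                      value = as.numeric(df[[2L]]),
                      stringsAsFactors = FALSE)
    if (anyNA(out$value))
        stop("missing phenotype values in ", path, "; filter first")
    out
}

#' Read a replicated-trial phenotype table
#'
#' Expects columns (genotype id, environment id, value) by name
#' (\code{genotype}/\code{id}, \code{environment}/\code{env},
#' \code{value}/\code{y}) or by position. Duplicated (genotype,
#' environment) rows are kept as replicates. If \code{genoIds} is given,
#' genotypes absent from it raise a cross-reference error.
#'
#' @param path delimited table path.
#' @param genoIds optional character vector of known genotype ids.
#' @return a \code{\link{TrialData}}.
#' @export
readTrials <- function(path, genoIds = NULL) {
    df <- .readTable(path)
    if (ncol(df) < 3L)
        stop("trial file needs columns (genotype id, environment id, value)")
    pick <- function(cands, fallback) {
        hit <- intersect(cands, names(df))
        if (length(hit)) df[[hit[1L]]] else df[[fallback]]
    }
    g <- as.character(pick(c("genotype", "geno", "id"), 1L))
    e <- as.character(pick(c("environment", "env"), 2L))
    v <- as.numeric(pick(c("value", "y"), 3L))
    if (!is.null(genoIds)) {
        unknown <- setdiff(unique(g), genoIds)
        if (length(unknown))
            stop("genotype ids absent from the genotype file: ",
                 paste(utils::head(unknown, 5L), collapse = ", "))
    }
    trialData(g, e, v)
}

#' Write a replicated-trial phenotype table
#'
#' @param data a \code{\link{TrialData}}.
#' @param path output path; @param sep separator.
#' @return the path, invisibly.
#' @export
writeTrials <- function(data, path, sep = "\t") {
    stopifnot(is(data, "TrialData"))
    .writeTable(data.frame(genotype = data@genoIds[data@genoIndex],
                           environment = as.character(data@env),
                           value = data@y), path, sep)
}

#' Write marker-effect and run-summary tables for a fit
#'
#' For an \code{\link{FLMFit}}: a marker table (marker, beta, beta_var,
#' tau_inv2) and a summary table (mu, resid_var, lambda2, n_iter,
#' converged). For a \code{\link{SingleStageFit}}: additionally the
#' breeding-value table (genotype, a, u0) and the fixed-effect table.
#'
#' @param fit an \code{FLMFit} or \code{SingleStageFit}.
#' @param dir output directory (created if missing).
#' @return character vector of files written, invisibly.
#' @export
writeFit <- function(fit, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    if (is(fit, "FLMFit")) {
        f1 <- file.path(dir, "marker_effects.tsv")
        .writeTable(data.frame(marker = fit@markerIds, beta = fit@beta,
                               beta_var = fit@betaVar,
                               tau_inv2 = fit@tauInv2), f1)
        f2 <- file.path(dir, "run_summary.tsv")
        .writeTable(data.frame(mu = fit@mu, resid_var = fit@residVar,
                               lambda2 = fit@lambda2, prior = fit@prior,
                               n_iter = fit@nIter,
                               converged = fit@converged), f2)
        files <- c(f1, f2)
    } else if (is(fit, "SingleStageFit")) {
        f1 <- file.path(dir, "marker_effects.tsv")
        .writeTable(data.frame(marker = fit@markerIds, beta = fit@beta), f1)
        f2 <- file.path(dir, "breeding_values.tsv")
        .writeTable(data.frame(genotype = fit@genoIds, a = fit@a,
                               u0 = fit@u0), f2)
        f3 <- file.path(dir, "fixed_effects.tsv")
        .writeTable(data.frame(term = names(fit@b), b = fit@b), f3)
        f4 <- file.path(dir, "run_summary.tsv")
        .writeTable(data.frame(prior = fit@prior, weighting = fit@weighting,
                               resid_var_obs = fit@residVarObs,
                               resid_var_wgr = fit@residVarWGR,
                               n_iter = fit@nIter,
                               converged = fit@converged), f4)
        files <- c(f1, f2, f3, f4)
    } else stop("unsupported fit object")
    invisible(files)
}

#' Write the marker map and truth files of a simulated population
#'
#' Emits the genotype table, a map file (marker, chrom, cM) and a truth
#' file (genotype id, tbv) for downstream evaluation.
#'
#' @param pop a \code{\link{SimulatedPopulation}}.
#' @param dir output directory.
#' @return character vector of files written, invisibly.
#' @export
writePopulation <- function(pop, dir) {
    stopifnot(is(pop, "SimulatedPopulation"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(dir, "genotypes.tsv")
    writeGenotypes(pop@genotypes, f1)
    f2 <- file.path(dir, "map.tsv")
    .writeTable(pop@map, f2)
    f3 <- file.path(dir, "truth.tsv")
    .writeTable(data.frame(id = pop@genotypes@individualIds,
                           tbv = pop@tbv), f3)
    invisible(c(f1, f2, f3))
}
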