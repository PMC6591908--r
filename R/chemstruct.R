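#' @include methods-accessors.R
NULL

#' MACCS fingerprint matrix of a StructureSet
#'
#' Assembles the 166-key MACCS substructure fingerprints of all parsed
#' structures into an unfiltered [FingerprintMatrix] (key indices 1..166).
#' Unparseable structures must have been resolved upstream: a non-empty
#' rejects table is an error here.
#'
#' @param structures a [StructureSet].
#' @return a [FingerprintMatrix].
#' @export
maccsFingerprints <- function(structures) {
    stopifnot(is(structures, "StructureSet"))
    if (nrow(structures@rejects) > 0L)
        stop("unparsed structures present (",
             paste(structures@rejects$id, collapse = ", "),
             "); resolve rejects before fingerprinting")
    bits <- structures@fingerprints
    storage.mode(bits) <- "integer"
    new("FingerprintMatrix", ids = structures@ids, bits = bits,
        keyIndices = seq_len(ncol(bits)))
}

#' Filter highly correlated fingerprint bits
#'
#' Removes redundant keys before distance computation: constant
#' (zero-variance) columns are dropped first, then a greedy scan in
#' ascending key order drops any column whose absolute Pearson correlation
#' with a previously retained column exceeds `cutoff` (so the
#' lower-numbered key of a violating pair is kept).  Deterministic and
#' order-stable.
#'
#' @param fp a [FingerprintMatrix] with at least 2 rows.
#' @param cutoff absolute Pearson correlation cutoff (default 0.9).
#' @return the filtered [FingerprintMatrix]; `keyIndices` records the
#'   surviving key numbers.
#' @export
filterCorrelatedBits <- function(fp, cutoff = 0.9) {
    stopifnot(is(fp, "FingerprintMatrix"))
    if (nrow(fp@bits) < 2L)
        stop("bit filtering needs at least 2 metabolites")
    b <- fp@bits
    keys <- fp@keyIndices
    variable <- apply(b, 2L, function(col) length(unique(col)) > 1L)
    b <- b[, variable, drop = FALSE]
    keys <- keys[variable]
    if (ncol(b) == 0L)
        stop("all fingerprint bits are constant")
    keep <- logical(ncol(b))
    for (j in seq_len(ncol(b))) {
        if (!any(keep)) { keep[j] <- TRUE; next }
        r <- suppressWarnings(
            abs(stats::cor(b[, j], b[, keep, drop = FALSE])))
        keep[j] <- !any(r > cutoff, na.rm = TRUE)
    }
    new("FingerprintMatrix", ids = fp@ids,
        bits = b[, keep, drop = FALSE], keyIndices = keys[keep])
}

#' Soergel (Tanimoto) distance between fingerprints
#'
#' For binary vectors, \eqn{d(i,j) = 1 - |b_i \wedge b_j| / |b_i \vee b_j|}
#' (one minus the Tanimoto similarity) — a true metric on binary vectors.
#' A pair of all-zero fingerprints is assigned distance 0 by convention
#' (the 0/0 Tanimoto ratio is undefined).
#'
#' @param fp a [FingerprintMatrix] with at least 2 rows.
#' @return a [DistanceMatrix] with metric `"soergel"`.
#' @export
soergelDistance <- function(fp) {
    stopifnot(is(fp, "FingerprintMatrix"))
    b <- fp@bits
    storage.mode(b) <- "numeric"
    inter <- b %*% t(b)
    counts <- rowSums(b)
    union <- outer(counts, counts, "+") - inter
    d <- 1 - inter / union
    d[union == 0] <- 0                    # all-zero pair convention
    diag(d) <- 0
    d <- (d + t(d)) / 2
    new("DistanceMatrix", ids = fp@ids, d = unname(d), metric = "soergel")
}

#' Correlation-based profile distance
#'
#' The alternate, structure-free grouping: dissimilarity between two
#' metabolites is one minus the absolute Spearman correlation of their
#' covariate-adjusted intensity profiles.  Zero-variance profiles have
#' undefined correlations; these are set to 0 (distance 1) with a warning.
#'
#' @param x a [MetaboSet] in state `"covariate_adjusted"` (>= 3 samples).
#' @param method correlation type; only `"spearman"` is supported.
#' @return a [DistanceMatrix] with metric `"spearman_correlation"`.
#' @export
correlationDistance <- function(x, method = c("spearman")) {
    method <- match.arg(method)
    stopifnot(is(x, "MetaboSet"))
    .requireState(x, "covariate_adjusted", "correlationDistance")
    if (ncol(x) < 3L) stop("correlation distance needs at least 3 samples")
    v <- t(intensities(x))                # samples x metabolites
    sds <- apply(v, 2L, stats::sd)
    if (any(sds == 0))
        warning("zero-variance profile(s): ",
                paste(colnames(v)[sds == 0], collapse = ", "),
                "; their correlations are set to 0")
    rho <- suppressWarnings(stats::cor(v, method = "spearman"))
    rho[is.na(rho)] <- 0
    d <- 1 - abs(rho)
    diag(d) <- 0
    d <- (d + t(d)) / 2
    new("DistanceMatrix", ids = metaboliteIds(x), d = unname(d),
        metric = "spearman_correlation")
}
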