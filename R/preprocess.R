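#' @include methods-accessors.R
NULL

.requireState <- function(x, allowed, op) {
    if (!x@state %in% allowed)
        stop(sprintf("%s expects state %s, got '%s'", op,
                     paste(sQuote(allowed), collapse = " or "), x@state))
}

#' Half-minimum imputation of non-detects
#'
#' Replaces every missing cell of a metabolite by half of the minimum
#' non-missing intensity observed for that metabolite, the usual
#' left-censoring assumption for mass-spectrometry non-detects.
#'
#' @param x a [MetaboSet] in state `"raw"`.
#' @return the imputed table, state `"imputed"`.
#' @export
imputeHalfMin <- function(x) {
    stopifnot(is(x, "MetaboSet"))
    .requireState(x, "raw", "imputeHalfMin")
    v <- intensities(x)
    allMissing <- rowSums(!is.na(v)) == 0L
    if (any(allMissing))
        stop("metabolite(s) with all values missing: ",
             paste(rownames(v)[allMissing], collapse = ", "))
    for (i in which(rowSums(is.na(v)) > 0L)) {
        half <- min(v[i, ], na.rm = TRUE) / 2
        v[i, is.na(v[i, ])] <- half
    }
    .setIntensity(x, v, "imputed")
}

#' Total quantity normalization
#'
#' Divides each sample's intensities by that sample's total signal, then
#' rescales by the mean total across samples so that magnitudes stay
#' interpretable.  After normalization all sample totals are equal.
#' Idempotent (up to floating-point round-off).
#'
#' @param x a [MetaboSet] in state `"imputed"`.
#' @return the normalized table, state `"normalized"`.
#' @export
totalQuantityNormalize <- function(x) {
    stopifnot(is(x, "MetaboSet"))
    .requireState(x, "imputed", "totalQuantityNormalize")
    v <- intensities(x)
    totals <- colSums(v)
    if (any(totals <= 0))
        stop("sample(s) with non-positive total signal: ",
             paste(colnames(v)[totals <= 0], collapse = ", "))
    v <- sweep(v, 2L, totals, "/") * mean(totals)
    .setIntensity(x, v, "normalized")
}

#' Log2 transform
#'
#' @param x a [MetaboSet] in state `"normalized"` with strictly positive
#'   values.
#' @return the transformed table, state `"logged"`.
#' @export
log2Transform <- function(x) {
    stopifnot(is(x, "MetaboSet"))
    .requireState(x, "normalized", "log2Transform")
    v <- intensities(x)
    if (any(v <= 0))
        stop("log2 transform requires strictly positive intensities")
    .setIntensity(x, log2(v), "logged")
}

#' Auto-scale metabolite profiles
#'
#' Centers each metabolite to mean zero and scales it to unit sample
#' standard deviation (n-1 denominator).  Zero-variance metabolites are
#' centered only and flagged in `rowData(x)$zero_variance`.
#'
#' @param x a [MetaboSet] in state `"logged"`.
#' @return the scaled table, state `"autoscaled"`.
#' @export
autoscale <- function(x) {
    stopifnot(is(x, "MetaboSet"))
    .requireState(x, "logged", "autoscale")
    v <- intensities(x)
    mu <- rowMeans(v)
    sdv <- apply(v, 1L, stats::sd)
    zero <- sdv == 0 | is.na(sdv)
    sdv[zero] <- 1
    v <- (v - mu) / sdv
    x <- .setIntensity(x, v, "autoscaled")
    rowData(x)$zero_variance <- zero
    x
}

#' Covariate adjustment by OLS residualization
#'
#' Regresses each metabolite profile on an intercept plus the named
#' covariates (categorical covariates are expanded into 0/1 indicator
#' columns, first-seen level as reference) and replaces the profile by the
#' residuals.  This removes nuisance variation (e.g. gender, smoking
#' history) before differential testing and classification.
#'
#' @param x a [MetaboSet] in state `"logged"` or `"autoscaled"`.
#' @param covariates names of `colData` columns to adjust for; `NULL` or
#'   empty means intercept-only (centering).
#' @return the residualized table, state `"covariate_adjusted"`.
#' @export
covariateAdjust <- function(x, covariates = NULL) {
    stopifnot(is(x, "MetaboSet"))
    .requireState(x, c("logged", "autoscaled"), "covariateAdjust")
    cd <- as.data.frame(colData(x))
    covariates <- covariates %||% character(0)
    missing <- setdiff(covariates, colnames(cd))
    if (length(missing))
        stop("covariate(s) not found: ", paste(missing, collapse = ", "))
    design <- matrix(1, ncol(x), 1L,
                     dimnames = list(colnames(x), "(Intercept)"))
    for (nm in covariates) {
        col <- cd[[nm]]
        if (is.numeric(col)) {
            if (length(unique(col)) < 2L) {
                warning("covariate '", nm, "' is constant; dropped")
                next
            }
            design <- cbind(design, col)
            colnames(design)[ncol(design)] <- nm
        } else {
            lv <- unique(as.character(col))
            if (length(lv) < 2L) {
                warning("covariate '", nm, "' is constant; dropped")
                next
            }
            for (l in lv[-1L]) {
                design <- cbind(design, as.numeric(as.character(col) == l))
                colnames(design)[ncol(design)] <- paste0(nm, l)
            }
        }
    }
    qrD <- qr(design)
    if (qrD$rank < ncol(design))
        warning("rank-deficient covariate design; least-norm fit used")
    v <- intensities(x)
    resid <- t(qr.resid(qrD, t(v)))
    dimnames(resid) <- dimnames(v)
    .setIntensity(x, resid, "covariate_adjusted")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Between/within-group variance decomposition
#'
#' Decomposes the total sum of squares of the (auto-scaled) metabolite
#' profiles about the grand mean into a between-group part
#' \eqn{BSS = \sum_g n_g \|\bar x_g - \bar x\|^2} and a within-group part
#' \eqn{WSS = \sum_g \sum_{i \in g} \|x_i - \bar x_g\|^2}, and reports the
#' fraction of profile variance explained by the grouping,
#' `ratio = BSS / (BSS + WSS)`.
#'
#' @param x a [MetaboSet] in state `"autoscaled"`.
#' @param grouping vector of group labels, one per sample (at least two
#'   groups, each non-empty); defaults to the trait labels.
#' @return list with elements `bss`, `wss`, `tss` and `ratio`.
#' @export
varianceDecomposition <- function(x, grouping = traitLabels(x)) {
    stopifnot(is(x, "MetaboSet"))
    .requireState(x, "autoscaled", "varianceDecomposition")
    grouping <- as.character(grouping)
    if (length(grouping) != ncol(x))
        stop("grouping must have one label per sample")
    groups <- unique(grouping)
    if (length(groups) < 2L)
        stop("variance decomposition requires at least two groups")
    v <- t(intensities(x))                       # samples x metabolites
    grand <- colMeans(v)
    bss <- 0; wss <- 0
    for (g in groups) {
        vg <- v[grouping == g, , drop = FALSE]
        mg <- colMeans(vg)
        bss <- bss + nrow(vg) * sum((mg - grand)^2)
        wss <- wss + sum(sweep(vg, 2L, mg)^2)
    }
    list(bss = bss, wss = wss, tss = bss + wss,
         ratio = if (bss + wss > 0) bss / (bss + wss) else 0)
}

#' Run the standard preprocessing chain
#'
#' Convenience wrapper: half-minimum imputation, total quantity
#' normalization and log2 transform, optionally followed by auto-scaling
#' or covariate adjustment.
#'
#' @param x a raw [MetaboSet].
#' @param covariates covariate names for [covariateAdjust()], or `NULL`
#'   to skip adjustment.
#' @param scale auto-scale to mean 0 / unit variance instead (only when
#'   `covariates` is `NULL`).
#' @return the processed [MetaboSet].
#' @export
preprocess <- function(x, covariates = NULL, scale = FALSE) {
    x <- log2Transform(totalQuantityNormalize(imputeHalfMin(x)))
    if (!is.null(covariates)) covariateAdjust(x, covariates)
    else if (scale) autoscale(x)
    else x
}
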