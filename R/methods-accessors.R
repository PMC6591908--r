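#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("processingState", "MetaboSet", function(x) x@state)

#' @rdname accessors
#' @export
setMethod("intensities", "MetaboSet",
          function(x) assay(x, "intensity"))

#' @rdname accessors
#' @export
setMethod("metaboliteIds", "MetaboSet", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("sampleIds", "MetaboSet", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("traitLabels", "MetaboSet", function(x) {
    tr <- colData(x)[[x@traitColumn]]
    factor(as.character(tr), levels = unique(as.character(tr)))
})

#' @rdname accessors
#' @export
setMethod("covariateData", "MetaboSet", function(x) {
    cd <- colData(x)
    as.data.frame(cd[, setdiff(colnames(cd), x@traitColumn), drop = FALSE])
})

setMethod("show", "MetaboSet", function(object) {
    cat(sprintf("MetaboSet: %d metabolites x %d samples [state: %s]\n",
                nrow(object), ncol(object), object@state))
    tr <- traitLabels(object)
    tb <- table(tr)
    cat(sprintf("trait '%s': %s\n", object@traitColumn,
                paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
    cov <- setdiff(colnames(colData(object)), object@traitColumn)
    if (length(cov))
        cat("covariates:", paste(cov, collapse = ", "), "\n")
    n <- sum(is.na(assay(object, "intensity")))
    if (n > 0) cat(sprintf("%d missing values\n", n))
})

## replace the intensity matrix, stamping a new state (internal)
.setIntensity <- function(x, values, state) {
    assays(x)[["intensity"]] <- values
    x@state <- state
    validObject(x)
    x
}

#' @importFrom SummarizedExperiment assays<-
NULL

#' @rdname accessors
#' @export
setMethod("structureIds", "StructureSet", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("fingerprints", "StructureSet", function(x) x@fingerprints)

#' @rdname accessors
#' @export
setMethod("rejects", "StructureSet", function(x) x@rejects)

#' Canonical SMILES of a StructureSet
#' @param x a [StructureSet].
#' @return named character vector of canonical SMILES.
#' @export
canonicalSmiles <- function(x) {
    stopifnot(is(x, "StructureSet"))
    stats::setNames(x@canonical, x@ids)
}

setMethod("show", "StructureSet", function(object) {
    cat(sprintf("StructureSet: %d parsed structures (%d rejected)\n",
                length(object@ids), nrow(object@rejects)))
    cat(sprintf("fingerprints: %d keys\n", ncol(object@fingerprints)))
})

#' Subset a StructureSet to a set of metabolite ids
#' @param x a [StructureSet].
#' @param i character vector of metabolite ids (order preserved).
#' @param j,drop,... unused.
#' @export
setMethod("[", "StructureSet", function(x, i, j, ..., drop = FALSE) {
    idx <- match(i, x@ids)
    if (anyNA(idx))
        stop("unknown metabolite ids: ",
             paste(i[is.na(idx)], collapse = ", "))
    initialize(x, ids = x@ids[idx], smiles = x@smiles[idx],
               canonical = x@canonical[idx],
               fingerprints = x@fingerprints[idx, , drop = FALSE])
})

#' @rdname accessors
#' @export
setMethod("structureIds", "FingerprintMatrix", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("keyIndices", "FingerprintMatrix", function(x) x@keyIndices)

#' Bit matrix of a FingerprintMatrix
#' @param x a [FingerprintMatrix].
#' @param ... unused.
#' @export
setMethod("as.matrix", "FingerprintMatrix", function(x, ...) {
    m <- x@bits
    dimnames(m) <- list(x@ids, paste0("key", x@keyIndices))
    m
})

setMethod("show", "FingerprintMatrix", function(object) {
    cat(sprintf("FingerprintMatrix: %d metabolites x %d keys\n",
                nrow(object@bits), ncol(object@bits)))
})

#' @rdname accessors
#' @export
setMethod("distanceIds", "DistanceMatrix", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("metricName", "DistanceMatrix", function(x) x@metric)

#' Coerce a DistanceMatrix to a square matrix
#' @param x a [DistanceMatrix].
#' @param ... unused.
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) {
    m <- x@d
    dimnames(m) <- list(x@ids, x@ids)
    m
})

#' Coerce a DistanceMatrix to a stats::dist object
#' @param m a [DistanceMatrix].
#' @param diag,upper passed to [stats::as.dist].
#' @export
asDist <- function(m, diag = FALSE, upper = FALSE) {
    stopifnot(is(m, "DistanceMatrix"))
    stats::as.dist(as.matrix(m), diag = diag, upper = upper)
}

setMethod("show", "DistanceMatrix", function(object) {
    cat(sprintf("DistanceMatrix (%s): %d x %d\n", object@metric,
                length(object@ids), length(object@ids)))
})

#' Subset a DistanceMatrix by metabolite ids
#' @param x a [DistanceMatrix].
#' @param i character vector of metabolite ids (order preserved).
#' @param j,drop,... unused.
#' @export
setMethod("[", "DistanceMatrix", function(x, i, j, ..., drop = FALSE) {
    idx <- match(i, x@ids)
    if (anyNA(idx))
        stop("unknown metabolite ids: ", paste(i[is.na(idx)], collapse = ", "))
    initialize(x, ids = x@ids[idx], d = x@d[idx, idx, drop = FALSE])
})

#' Pathway accessors
#' @param x a [PathwayAnnotation].
#' @export
pathwayIds <- function(x) {
    stopifnot(is(x, "PathwayAnnotation"))
    x@pathwayIds
}

#' @rdname pathwayIds
#' @export
pathwayMembers <- function(x) {
    stopifnot(is(x, "PathwayAnnotation"))
    stats::setNames(x@members, x@pathwayIds)
}

#' @rdname pathwayIds
#' @export
pathwayDescriptions <- function(x) {
    stopifnot(is(x, "PathwayAnnotation"))
    stats::setNames(x@descriptions, x@pathwayIds)
}

setMethod("show", "PathwayAnnotation", function(object) {
    cat(sprintf("PathwayAnnotation: %d pathways, %d distinct members\n",
                length(object@pathwayIds),
                length(unique(unlist(object@members)))))
})

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment",
          function(x) stats::setNames(x@labels, x@ids))

#' @rdname accessors
#' @export
setMethod("numberOfClusters", "ClusterAssignment", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("averageSilhouetteWidth", "ClusterAssignment", function(x) x@asw)

#' @rdname accessors
#' @export
setMethod("silhouetteValues", "ClusterAssignment",
          function(x) stats::setNames(x@silhouettes, x@ids))

#' @rdname accessors
#' @export
setMethod("linkageTree", "ClusterAssignment", function(x) x@tree)

setMethod("show", "ClusterAssignment", function(object) {
    sizes <- table(object@labels)
    cat(sprintf("ClusterAssignment: %d items in k = %d clusters (ASW %.3f)\n",
                length(object@ids), object@k, object@asw))
    cat("cluster sizes:", paste(sort(as.integer(sizes), decreasing = TRUE),
                                collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("internalMetrics", "ClassifierReport", function(x) x@internal)

#' @rdname accessors
#' @export
setMethod("externalMetrics", "ClassifierReport", function(x) x@external)

#' @rdname accessors
#' @export
setMethod("probabilityThreshold", "ClassifierReport", function(x) x@threshold)

#' Metabolites used by a classifier report
#' @param x a [ClassifierReport].
#' @export
reportMetabolites <- function(x) {
    stopifnot(is(x, "ClassifierReport"))
    x@spec@metabolites
}

#' Model family of a classifier report
#' @param x a [ClassifierReport] or [ClassifierSpec].
#' @export
modelFamily <- function(x) {
    if (is(x, "ClassifierReport")) x@spec@family
    else if (is(x, "ClassifierSpec")) x@family
    else stop("not a classifier object")
}

setMethod("show", "ClassifierReport", function(object) {
    cat(sprintf("ClassifierReport [%s] %s: %d metabolite(s)\n",
                object@spec@family, object@label,
                length(object@spec@metabolites)))
    cat(sprintf("  threshold %.3f | LOOCV acc %.3f sens %.3f spec %.3f auc %.3f\n",
                object@threshold, object@internal["accuracy"],
                object@internal["sensitivity"], object@internal["specificity"],
                object@internal["auc"]))
    if (length(object@external))
        cat(sprintf("  external acc %.3f sens %.3f spec %.3f auc %.3f\n",
                    object@external["accuracy"], object@external["sensitivity"],
                    object@external["specificity"], object@external["auc"]))
})
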