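#' @include methods-accessors.R
NULL

#' Average-linkage (UPGMA) agglomeration
#'
#' Builds the average-linkage merge history of a dissimilarity matrix:
#' repeatedly merges the pair of clusters with the smallest average
#' inter-cluster dissimilarity.  Ties are broken deterministically by the
#' lexicographically lowest pair of cluster representatives, where a
#' cluster is represented by its smallest original item index.  Returns a
#' standard `hclust` object (so [stats::cutree()] applies).
#'
#' @param d a [DistanceMatrix] with n >= 2 items.
#' @return an object of class `hclust`.
#' @export
averageLinkageTree <- function(d) {
    stopifnot(is(d, "DistanceMatrix"))
    n <- length(d@ids)
    if (n < 2L) stop("clustering needs at least 2 items")
    dm <- as.matrix(d)
    ## active clusters: representative = smallest member index
    clusterId <- -seq_len(n)           # hclust coding: negative = singleton
    rep <- seq_len(n)
    size <- rep(1L, n)
    active <- rep(TRUE, n)
    cd <- dm                           # average inter-cluster dissimilarity
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        idx <- which(active)
        ord <- idx[order(rep[idx])]     # ascending representative order
        sub <- cd[ord, ord, drop = FALSE]
        sub[lower.tri(sub, diag = TRUE)] <- Inf
        pos <- which(sub == min(sub), arr.ind = TRUE)
        ## lexicographic (i, j) tie rule in representative order
        pos <- pos[order(pos[, 1L], pos[, 2L]), , drop = FALSE]
        a <- ord[pos[1L, 1L]]; b <- ord[pos[1L, 2L]]
        best <- list(h = cd[a, b])
        merge[step, ] <- .orderMergePair(clusterId[a], clusterId[b])
        height[step] <- best$h
        ## weighted average update (UPGMA): exact average over member pairs
        for (cc in idx) {
            if (cc == a || cc == b) next
            cd[a, cc] <- cd[cc, a] <-
                (size[a] * cd[a, cc] + size[b] * cd[b, cc]) /
                (size[a] + size[b])
        }
        size[a] <- size[a] + size[b]
        rep[a] <- min(rep[a], rep[b])
        clusterId[a] <- step
        active[b] <- FALSE
    }
    tree <- list(merge = merge, height = height,
                 order = .treeOrder(merge, n), labels = d@ids,
                 method = "average", call = match.call(),
                 dist.method = d@metric)
    class(tree) <- "hclust"
    tree
}

## hclust merge-row convention: singletons (negative) before merged
## clusters; two singletons by item index; two clusters by merge step
.orderMergePair <- function(i, j) {
    if (i < 0 && j < 0) c(max(i, j), min(i, j))
    else if (i > 0 && j > 0) c(min(i, j), max(i, j))
    else if (i < 0) c(i, j) else c(j, i)
}

## leaf ordering by recursive traversal of the merge matrix
.treeOrder <- function(merge, n) {
    leaves <- function(row) {
        out <- integer(0)
        for (v in merge[row, ])
            out <- c(out, if (v < 0) -v else leaves(v))
        out
    }
    if (n == 1L) 1L else leaves(nrow(merge))
}

#' Cut a linkage tree into k clusters
#'
#' @param tree an `hclust` object (e.g. from [averageLinkageTree()]).
#' @param k number of clusters, `1 <= k <= n`.
#' @return integer labels named by item, numbered by first appearance in
#'   item order.
#' @export
cutTreeK <- function(tree, k) {
    n <- length(tree$labels)
    if (k < 1L || k > n) stop("k must lie in [1, ", n, "]")
    raw <- stats::cutree(tree, k = k)
    lab <- match(raw, unique(raw))
    stats::setNames(as.integer(lab), tree$labels)
}

#' Silhouette widths of a clustering
#'
#' For item i with mean within-cluster distance a(i) and smallest mean
#' distance to any other cluster b(i), the silhouette is
#' \eqn{s(i) = (b(i) - a(i)) / \max\{a(i), b(i)\}}.  Items in singleton
#' clusters score 0 by convention, as does an item with
#' \eqn{a(i) = b(i) = 0}.  The average silhouette width (ASW) is the mean
#' of s(i) over all items.
#'
#' @param d a [DistanceMatrix].
#' @param labels cluster labels aligned to (or named by) the ids of `d`;
#'   at least 2 clusters required.
#' @return list with `silhouettes` (named per-item s(i)) and `asw`.
#' @export
silhouetteWidths <- function(d, labels) {
    stopifnot(is(d, "DistanceMatrix"))
    ids <- d@ids
    if (!is.null(names(labels))) labels <- labels[ids]
    if (length(labels) != length(ids))
        stop("one cluster label per item required")
    if (length(unique(labels)) < 2L)
        stop("silhouettes require at least 2 clusters")
    dm <- as.matrix(d)
    s <- numeric(length(ids))
    for (i in seq_along(ids)) {
        own <- labels == labels[i]
        if (sum(own) == 1L) { s[i] <- 0; next }
        a <- mean(dm[i, own & seq_along(ids) != i])
        b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
            mean(dm[i, labels == cl]), numeric(1)))
        s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }
    list(silhouettes = stats::setNames(s, ids), asw = mean(s))
}

#' Select the number of clusters by maximal average silhouette width
#'
#' Builds the average-linkage tree once, cuts it at every k in `kRange`,
#' scores each flat clustering by its average silhouette width, and
#' returns the assignment with the highest ASW (ties resolved toward the
#' smallest k).
#'
#' @param d a [DistanceMatrix] with n >= 3 items.
#' @param kRange integer vector of candidate k values
#'   (default `2:(n-1)`).
#' @return a [ClusterAssignment] carrying the selected labels, per-item
#'   silhouettes, ASW and the linkage tree.
#' @export
selectK <- function(d, kRange = NULL) {
    stopifnot(is(d, "DistanceMatrix"))
    n <- length(d@ids)
    if (n < 3L) stop("silhouette-based selection needs at least 3 items")
    kRange <- if (is.null(kRange)) 2:(n - 1L) else sort(unique(kRange))
    if (any(kRange < 2L | kRange > n - 1L))
        stop("kRange must lie within [2, n-1]")
    tree <- averageLinkageTree(d)
    best <- NULL
    for (k in kRange) {
        labels <- cutTreeK(tree, k)
        sil <- silhouetteWidths(d, labels)
        if (is.null(best) || sil$asw > best$asw + 0) {
            best <- list(k = k, labels = labels, asw = sil$asw,
                         sil = sil$silhouettes)
        }
    }
    new("ClusterAssignment", ids = d@ids, labels = unname(best$labels),
        k = as.integer(best$k), asw = best$asw,
        silhouettes = unname(best$sil), tree = tree)
}

#' Cluster the significant metabolites
#'
#' Restricts a distance matrix to the significant metabolites and runs the
#' same ASW-selected average-linkage clustering; the resulting clusters of
#' size >= 2 are the candidate multi-metabolite bins for classifier
#' construction.  With fewer than 3 significant metabolites a degenerate
#' all-singleton assignment is returned with a warning.
#'
#' @param d a [DistanceMatrix] over all metabolites (or already
#'   restricted).
#' @param ids optional character vector of significant metabolite ids to
#'   restrict to; `NULL` uses `d` as given.
#' @param kRange passed to [selectK()].
#' @return a [ClusterAssignment].
#' @export
clusterSignificant <- function(d, ids = NULL, kRange = NULL) {
    stopifnot(is(d, "DistanceMatrix"))
    if (!is.null(ids)) d <- d[ids]
    n <- length(d@ids)
    if (n < 3L) {
        warning("fewer than 3 significant metabolites; ",
                "returning all-singleton assignment")
        return(new("ClusterAssignment", ids = d@ids,
                   labels = seq_len(n), k = n,
                   asw = 0, silhouettes = rep(0, n), tree = NULL))
    }
    selectK(d, kRange = kRange)
}

#' Multi-metabolite bins of a cluster assignment
#'
#' @param x a [ClusterAssignment].
#' @param minSize minimal cluster size to qualify as a bin (default 2).
#' @return named list of metabolite-id vectors, one per qualifying
#'   cluster.
#' @export
multiMetaboliteBins <- function(x, minSize = 2L) {
    stopifnot(is(x, "ClusterAssignment"))
    sizes <- table(x@labels)
    keep <- as.integer(names(sizes)[sizes >= minSize])
    out <- lapply(keep, function(cl) x@ids[x@labels == cl])
    names(out) <- as.character(keep)
    out
}

#' Export a linkage tree as Newick
#'
#' Writes the average-linkage dendrogram in Newick format with merge
#' heights as branch lengths.
#'
#' @param tree an `hclust` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLinkageNewick <- function(tree, path) {
    if (!requireNamespace("ape", quietly = TRUE))
        stop("package 'ape' is required for Newick export")
    ape::write.tree(ape::as.phylo(tree), file = path)
    invisible(path)
}
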