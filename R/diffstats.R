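#' @include methods-accessors.R
NULL

## Welch (or pooled) two-sample t statistics for many group assignments.
## z: pooled values; pick: n1 x B matrix of indices assigned to group A.
.tStatMany <- function(z, pick, n1, n2, varEqual = FALSE) {
    sumAll <- sum(z); sumsqAll <- sum(z^2)
    zp <- matrix(z[pick], nrow = n1)
    s1 <- colSums(zp); q1 <- colSums(zp^2)
    s2 <- sumAll - s1; q2 <- sumsqAll - q1
    m1 <- s1 / n1; m2 <- s2 / n2
    v1 <- pmax(0, (q1 - n1 * m1^2) / (n1 - 1))
    v2 <- pmax(0, (q2 - n2 * m2^2) / (n2 - 1))
    se <- if (varEqual) {
        sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        sqrt(sp * (1 / n1 + 1 / n2))
    } else sqrt(v1 / n1 + v2 / n2)
    t <- (m1 - m2) / se
    ## zero variance: zero difference -> t = 0; nonzero -> +/-Inf magnitude
    deg <- se == 0
    if (any(deg)) t[deg] <- sign(m1[deg] - m2[deg]) * Inf
    t[is.nan(t)] <- 0
    t
}

#' Monte Carlo permutation t-test
#'
#' Two-sample (Welch by default) t-test whose two-sided p-value is obtained
#' by uniformly random label permutations, with the add-one convention
#' \eqn{p = (1 + \#\{|t^*| \ge |t_{obs}|\}) / (n_{perm} + 1)} so that p is
#' always positive and a valid Monte Carlo p-value.
#'
#' @param x,y numeric values of the two groups (each of length >= 2).
#' @param nPerm number of label permutations (default 100000).
#' @param seed RNG seed for the permutations.
#' @param varEqual use the pooled-variance statistic instead of Welch.
#' @return list with `statistic` (observed t) and `p_value`.
#' @export
permutationTTest <- function(x, y, nPerm = 100000L, seed = 1L,
                             varEqual = FALSE) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(x) < 2L || length(y) < 2L)
        stop("both groups need at least 2 values")
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    tObs <- .tStatMany(c(x, y), matrix(seq_len(n1)), n1, n2, varEqual)
    ## permuted statistics are computed on the sorted pooled values with
    ## the smaller group permuted, so the Monte Carlo draw (and hence p)
    ## is invariant to swapping the group labels
    zs <- sort(c(x, y))
    m <- min(n1, n2)
    pick <- .withSeed(seed,
        vapply(seq_len(nPerm), function(b) sample.int(n, m), integer(m)))
    tPerm <- .tStatMany(zs, pick, m, n - m, varEqual)
    p <- (1 + sum(abs(tPerm) >= abs(tObs))) / (nPerm + 1)
    list(statistic = tObs, p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; q-values are returned in input
#' order and capped at 1.
#'
#' @param p vector of p-values in (0, 1].
#' @return vector of q-values.
#' @export
bhAdjust <- function(p) {
    if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

.caseLevel <- function(trait, caseLevel = NULL) {
    lv <- levels(trait)
    if (!is.null(caseLevel)) {
        if (!caseLevel %in% lv) stop("caseLevel '", caseLevel,
                                     "' is not a trait level")
        return(caseLevel)
    }
    if ("case" %in% lv) "case" else lv[2L]
}

#' Per-metabolite permutation differential analysis
#'
#' Runs a Monte Carlo permutation t-test per metabolite on the
#' covariate-adjusted profiles, adjusts with Benjamini-Hochberg and flags
#' metabolites significant at the configured FDR.  A fresh permutation set
#' is drawn per metabolite (seeded reproducibly from `seed`), so p-values
#' of independent metabolites carry independent Monte Carlo noise.
#'
#' @param x a [MetaboSet] in state `"covariate_adjusted"`.
#' @param fdr FDR significance threshold (default 0.075).
#' @param nPerm permutations per metabolite (default 100000).
#' @param seed master RNG seed.
#' @param caseLevel trait level treated as case; defaults to `"case"` if
#'   present, else the second trait level.
#' @param varEqual use the pooled-variance t statistic instead of Welch.
#' @param displayTable optional [MetaboSet] in state `"normalized"` used
#'   to compute display fold changes as ratios of group mean intensities;
#'   when absent the fold change is `2^mean_log_fc`.
#' @return a [DifferentialResult].
#' @export
differentialAnalysis <- function(x, fdr = 0.075, nPerm = 100000L, seed = 1L,
                                 caseLevel = NULL, varEqual = FALSE,
                                 displayTable = NULL) {
    stopifnot(is(x, "MetaboSet"))
    .requireState(x, "covariate_adjusted", "differentialAnalysis")
    trait <- traitLabels(x)
    case <- .caseLevel(trait, caseLevel)
    isCase <- trait == case
    if (sum(isCase) < 2L || sum(!isCase) < 2L)
        stop("each trait group needs at least 2 samples")
    v <- intensities(x)
    ids <- rownames(v)
    seeds <- .childSeeds(seed, nrow(v))
    stat <- p <- lfc <- numeric(nrow(v))
    for (i in seq_len(nrow(v))) {
        res <- permutationTTest(v[i, isCase], v[i, !isCase], nPerm = nPerm,
                                seed = seeds[i], varEqual = varEqual)
        stat[i] <- res$statistic
        p[i] <- res$p_value
        lfc[i] <- mean(v[i, isCase]) - mean(v[i, !isCase])
    }
    fc <- 2^lfc
    if (!is.null(displayTable)) {
        stopifnot(is(displayTable, "MetaboSet"))
        .requireState(displayTable, "normalized", "displayTable")
        dv <- intensities(displayTable)
        common <- intersect(ids, rownames(dv))
        dTrait <- traitLabels(displayTable)
        dCase <- dTrait == .caseLevel(dTrait, caseLevel)
        fc[match(common, ids)] <-
            rowMeans(dv[common, dCase, drop = FALSE]) /
            rowMeans(dv[common, !dCase, drop = FALSE])
    }
    q <- bhAdjust(p)
    res <- new("DifferentialResult",
               DataFrame(id = ids, statistic = stat, mean_log_fc = lfc,
                         fold_change = fc, p_value = p, q_value = q,
                         significant = q < fdr))
    metadata(res) <- list(fdr = fdr, n_permutations = as.integer(nPerm),
                          seed = as.integer(seed), case_level = case)
    res
}

#' Significant metabolite ids of a differential result
#' @param x a [DifferentialResult].
#' @export
significantIds <- function(x) {
    stopifnot(is(x, "DifferentialResult"))
    x$id[x$significant]
}

## Shared engine for one-sided (greater) Fisher enrichment over clusters.
.fisherEnrichment <- function(clusters, flag, flagName) {
    stopifnot(is(clusters, "ClusterAssignment"))
    ids <- clusters@ids
    if (is.null(names(flag))) {
        if (length(flag) != length(ids))
            stop(flagName, " flag must be named or aligned to cluster ids")
        names(flag) <- ids
    }
    if (!all(ids %in% names(flag)))
        stop("missing ", flagName, " flag for some clustered metabolites")
    flag <- as.logical(flag[ids])
    N <- length(ids)
    rows <- lapply(sort(unique(clusters@labels)), function(cl) {
        inC <- clusters@labels == cl
        a <- sum(inC & flag); b <- sum(inC & !flag)
        cc <- sum(!inC & flag); d <- sum(!inC & !flag)
        if (sum(inC) == N) {
            warning("cluster ", cl, " covers the whole population; p = 1")
            p <- 1
        } else {
            p <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2L),
                                    alternative = "greater")$p.value
        }
        DataFrame(unit_id = as.character(cl), n_in_flagged = a,
                  n_in = a + b, n_flagged = a + cc, n_total = N,
                  p_value = p)
    })
    out <- do.call(rbind, rows)
    out$q_value <- bhAdjust(out$p_value)
    out
}

#' Fisher exact enrichment of significant metabolites within clusters
#'
#' For each cluster, tests by a one-sided (greater) Fisher exact test
#' whether metabolites inside the cluster have a greater probability of
#' trait significance than those outside, and adjusts across clusters with
#' Benjamini-Hochberg.
#'
#' @param clusters a [ClusterAssignment].
#' @param significant logical vector of significance flags, either named
#'   by metabolite id or aligned to the cluster ids.
#' @return a `DataFrame` with one row per cluster: contingency counts,
#'   `p_value` and `q_value`.
#' @export
fisherClusterEnrichment <- function(clusters, significant)
    .fisherEnrichment(clusters, significant, "significance")

#' Fisher exact enrichment of pathway members within clusters
#'
#' Identical contract to [fisherClusterEnrichment()], with "significant"
#' replaced by "pathway member".
#'
#' @param clusters a [ClusterAssignment].
#' @param pathwayMembers character vector of member metabolite ids.
#' @return a `DataFrame` with one row per cluster.
#' @export
fisherPathwayInCluster <- function(clusters, pathwayMembers) {
    flag <- clusters@ids %in% pathwayMembers
    names(flag) <- clusters@ids
    .fisherEnrichment(clusters, flag, "pathway membership")
}

#' Hypergeometric pathway over-representation
#'
#' Upper-tail hypergeometric test per pathway: given `N` population
#' metabolites of which `K` belong to the pathway, and `n` significant
#' metabolites of which `k` belong, the p-value is
#' \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}.
#' Pathway membership is intersected with the population first; pathways
#' with no member in the population are skipped with a warning.
#'
#' @param annotation a [PathwayAnnotation].
#' @param significantSet significant metabolite ids (subset of
#'   `population`).
#' @param population all tested metabolite ids.
#' @param fdr FDR threshold for the `significant` flag (default 0.05).
#' @return a `DataFrame` with one row per tested pathway.
#' @export
pathwayEnrichment <- function(annotation, significantSet, population,
                              fdr = 0.05) {
    stopifnot(is(annotation, "PathwayAnnotation"))
    population <- unique(population)
    significantSet <- unique(significantSet)
    if (!all(significantSet %in% population))
        stop("significantSet must be a subset of the population")
    N <- length(population); n <- length(significantSet)
    rows <- list()
    for (i in seq_along(annotation@pathwayIds)) {
        members <- intersect(annotation@members[[i]], population)
        K <- length(members)
        if (K == 0L) {
            warning("pathway '", annotation@pathwayIds[i],
                    "' has no member in the population; skipped")
            next
        }
        k <- length(intersect(members, significantSet))
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        rows[[length(rows) + 1L]] <- DataFrame(
            unit_id = annotation@pathwayIds[i],
            description = annotation@descriptions[i],
            n_members = K, n_overlap = k, n_significant = n, n_total = N,
            p_value = p)
    }
    if (length(rows) == 0L)
        stop("no pathway overlaps the population")
    out <- do.call(rbind, rows)
    out$q_value <- bhAdjust(out$p_value)
    out$significant <- out$q_value < fdr
    out
}
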