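# Fixture builders and independent brute-force oracles used across tests.

suppressWarnings(suppressMessages(library(metaboclust)))

# -- fixture builders ------------------------------------------------------

# small intensity table; values: samples x metabolites matrix
makeTable <- function(values, trait = NULL, state = "raw", meta = NULL) {
    n <- nrow(values)
    if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(n))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("m", seq_len(ncol(values)))
    if (is.null(trait)) trait <- rep(c("control", "case"), length.out = n)
    sd <- data.frame(trait = trait, stringsAsFactors = FALSE)
    if (!is.null(meta)) sd <- cbind(sd, meta)
    rownames(sd) <- rownames(values)
    MetaboSet(t(values), sd, traitColumn = "trait", state = state)
}

# adjusted-state table straight from a samples x metabolites matrix
makeAdjusted <- function(values, trait = NULL, meta = NULL)
    makeTable(values, trait = trait, state = "covariate_adjusted",
              meta = meta)

# distance matrix from a square symmetric matrix
makeDistance <- function(m, ids = NULL, metric = "soergel") {
    if (is.null(ids)) ids <- paste0("x", seq_len(nrow(m)))
    new("DistanceMatrix", ids = ids, d = unname(as.matrix(m)),
        metric = metric)
}

# random metric distance matrix (euclidean on random points)
randomDistance <- function(n, p = 3) {
    pts <- matrix(rnorm(n * p), n)
    makeDistance(as.matrix(dist(pts)), metric = "euclidean")
}

# fingerprint matrix from a binary matrix
makeFingerprints <- function(bits, ids = NULL) {
    storage.mode(bits) <- "integer"
    if (is.null(ids)) ids <- paste0("x", seq_len(nrow(bits)))
    new("FingerprintMatrix", ids = ids, bits = bits,
        keyIndices = seq_len(ncol(bits)))
}

# -- independent oracles ---------------------------------------------------

# textbook silhouette, straight from the definition
oracleSilhouette <- function(dm, labels) {
    n <- nrow(dm)
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- which(labels == labels[i] & seq_len(n) != i)
        if (length(own) == 0) { s[i] <- 0; next }
        a <- sum(dm[i, own]) / length(own)
        b <- Inf
        for (cl in unique(labels)) {
            if (cl == labels[i]) next
            mem <- which(labels == cl)
            b <- min(b, sum(dm[i, mem]) / length(mem))
        }
        s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }
    s
}

# naive UPGMA: inter-cluster distance recomputed as the mean over all
# original member pairs at every step (no Lance-Williams update)
oracleUPGMA <- function(dm) {
    n <- nrow(dm)
    clusters <- as.list(seq_len(n))
    heights <- numeric(0)
    while (length(clusters) > 1) {
        best <- NULL
        for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
            if (a >= b) next
            h <- mean(dm[clusters[[a]], clusters[[b]]])
            if (is.null(best) || h < best$h) best <- list(h = h, a = a, b = b)
        }
        heights <- c(heights, best$h)
        clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
        clusters[[best$b]] <- NULL
    }
    sort(heights)
}

# one-sided (greater) Fisher p by hypergeometric enumeration:
# population N, K flagged, cluster of size nc, observed overlap k
oracleFisherGreater <- function(k, K, N, nc) {
    kmax <- min(K, nc)
    num <- 0
    for (j in k:kmax) num <- num + choose(K, j) * choose(N - K, nc - j)
    num / choose(N, nc)
}

# literal step-up BH
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    sorted <- p[o]
    for (i in seq_len(m))
        q[i] <- min(1, min(m * sorted[i:m] / (i:m)))
    out <- numeric(m)
    out[o] <- q
    out
}

# concordant-pair AUC with ties counted half
oracleAUC <- function(prob, y) {
    pos <- prob[y == 1]; neg <- prob[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
}

# Soergel distance by explicit bit counting
oracleSoergel <- function(bi, bj) {
    inter <- sum(bi == 1 & bj == 1)
    uni <- sum(bi == 1 | bj == 1)
    if (uni == 0) 0 else 1 - inter / uni
}

# adjusted Rand index (via mclust when present, else own contingency form)
ari <- function(a, b) {
    if (requireNamespace("mclust", quietly = TRUE))
        return(mclust::adjustedRandIndex(a, b))
    tab <- table(a, b)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
    sn <- choose(sum(tab), 2)
    exp <- si * sj / sn
    (sij - exp) / ((si + sj) / 2 - exp)
}

# shared tiny SMILES sets
aminoSmiles <- c(glycine = "NCC(=O)O", alanine = "CC(N)C(=O)O",
                 serine = "OCC(N)C(=O)O", valine = "CC(C)C(N)C(=O)O",
                 leucine = "CC(C)CC(N)C(=O)O")
fattySmiles <- c(laurate = "CCCCCCCCCCCC(=O)O",
                 myristate = "CCCCCCCCCCCCCC(=O)O",
                 palmitate = "CCCCCCCCCCCCCCCC(=O)O",
                 stearate = "CCCCCCCCCCCCCCCCCC(=O)O",
                 oleate = "CCCCCCCC/C=C\\CCCCCCCC(=O)O")
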