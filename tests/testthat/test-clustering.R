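test_that("average linkage reproduces the hand-worked 3-point example", {
    d <- makeDistance(rbind(c(0, 1, 4), c(1, 0, 5), c(4, 5, 0)),
                      ids = c("A", "B", "C"))
    tree <- averageLinkageTree(d)
    expect_equal(tree$height, c(1, 4.5))
    expect_equal(tree$merge[1, ], c(-1, -2))
    labels <- cutTreeK(tree, 2)
    expect_equal(unname(labels[c("A", "B")]), c(1L, 1L))
    expect_equal(unname(labels["C"]), 2L)
    expect_equal(length(unique(cutTreeK(tree, 1))), 1L)
    expect_equal(unname(cutTreeK(tree, 3)), 1:3)
    expect_error(cutTreeK(tree, 4), "k must lie")
})

test_that("equidistant points merge at equal heights with the tie rule", {
    n <- 5
    m <- matrix(1, n, n); diag(m) <- 0
    tree <- averageLinkageTree(makeDistance(m))
    expect_equal(tree$height, rep(1, n - 1))
    # ties resolved lexicographically: first merge is items 1 and 2
    expect_equal(tree$merge[1, ], c(-1, -2))
})

test_that("merge heights agree with the naive pair-averaging oracle", {
    set.seed(41)
    for (i in 1:30) {
        n <- sample(4:8, 1)
        d <- randomDistance(n)
        tree <- averageLinkageTree(d)
        expect_equal(sort(tree$height), oracleUPGMA(as.matrix(d)),
                     tolerance = 1e-9)
        # heights are monotone for a metric + average linkage
        expect_true(all(diff(tree$height) >= -1e-12))
        # same heights as stats::hclust on tie-free instances
        ref <- hclust(asDist(d), method = "average")
        expect_equal(tree$height, ref$height, tolerance = 1e-9)
    }
})

test_that("cut partitions nest as k decreases", {
    set.seed(43)
    d <- randomDistance(12)
    tree <- averageLinkageTree(d)
    for (k in 11:2) {
        fine <- cutTreeK(tree, k + 1)
        coarse <- cutTreeK(tree, k)
        # every fine cluster maps into exactly one coarse cluster
        expect_true(all(tapply(coarse, fine,
                               function(v) length(unique(v))) == 1))
    }
})

test_that("silhouettes follow the displayed equation", {
    # two tight pairs: within 0.1, across 1.0 -> every s(i) = 0.9
    m <- matrix(1, 4, 4); diag(m) <- 0
    m[1, 2] <- m[2, 1] <- 0.1
    m[3, 4] <- m[4, 3] <- 0.1
    d <- makeDistance(m)
    sil <- silhouetteWidths(d, c(1, 1, 2, 2))
    expect_equal(unname(sil$silhouettes), rep(0.9, 4))
    expect_equal(sil$asw, 0.9)
    # singleton convention
    sil2 <- silhouetteWidths(d, c(1, 1, 2, 3))
    expect_equal(unname(sil2$silhouettes[4]), 0)
    # single cluster errors
    expect_error(silhouetteWidths(d, rep(1, 4)), "2 clusters")
})

test_that("silhouettes match the brute-force and cluster-package oracles", {
    skip_if_not_installed("cluster")
    set.seed(47)
    for (i in 1:40) {
        n <- sample(6:20, 1)
        k <- sample(2:4, 1)
        d <- randomDistance(n)
        labels <- sample(rep(seq_len(k), length.out = n))
        got <- silhouetteWidths(d, labels)
        expect_equal(unname(got$silhouettes),
                     oracleSilhouette(as.matrix(d), labels),
                     tolerance = 1e-12)
        ref <- cluster::silhouette(labels, dmatrix = as.matrix(d))
        if (!any(tabulate(labels) == 1))   # ref scores singletons 0 too,
            expect_equal(unname(got$silhouettes),  # but reorders them
                         unname(ref[, "sil_width"]), tolerance = 1e-12)
    }
})

test_that("selectK maximizes the average silhouette width by definition", {
    set.seed(53)
    for (i in 1:10) {
        d <- randomDistance(10)
        ca <- selectK(d)
        tree <- linkageTree(ca)
        asws <- vapply(2:9, function(k)
            silhouetteWidths(d, cutTreeK(tree, k))$asw, numeric(1))
        expect_equal(averageSilhouetteWidth(ca), max(asws))
        expect_equal(numberOfClusters(ca), (2:9)[which.max(asws)])
        expect_equal(averageSilhouetteWidth(ca),
                     mean(silhouetteValues(ca)))
    }
})

test_that("two structure families separate into two clusters", {
    ss <- structuresFromSmiles(c(aminoSmiles, fattySmiles))
    d <- soergelDistance(maccsFingerprints(ss))
    ca <- selectK(d)
    expect_equal(numberOfClusters(ca), 2L)
    fam <- rep(c("amino", "fatty"), each = 5)
    expect_equal(ari(clusterLabels(ca), fam), 1)
})

test_that("equidistant data drive ASW to zero and the smallest k wins", {
    m <- matrix(1, 6, 6); diag(m) <- 0
    ca <- selectK(makeDistance(m))
    expect_equal(averageSilhouetteWidth(ca), 0)
    expect_equal(numberOfClusters(ca), 2L)
})

test_that("selectK is invariant to input order up to relabeling", {
    set.seed(59)
    d <- randomDistance(9)
    perm <- sample(9)
    dPerm <- makeDistance(as.matrix(d)[perm, perm],
                          ids = distanceIds(d)[perm])
    a <- selectK(d); b <- selectK(dPerm)
    expect_equal(numberOfClusters(a), numberOfClusters(b))
    expect_equal(averageSilhouetteWidth(a), averageSilhouetteWidth(b),
                 tolerance = 1e-12)
    la <- clusterLabels(a)
    lb <- clusterLabels(b)[names(la)]
    expect_equal(ari(la, lb), 1)
})

test_that("clusterSignificant restricts, clusters, and degrades gracefully", {
    ss <- structuresFromSmiles(c(aminoSmiles[1:3], fattySmiles[3:4],
                                 adenosine = "Nc1ncnc2c1ncn2C1OC(CO)C(O)C1O"))
    d <- soergelDistance(maccsFingerprints(ss))
    sig <- structureIds(ss)
    ca <- clusterSignificant(d, sig)
    bins <- multiMetaboliteBins(ca)
    sets <- lapply(bins, sort)
    expect_true(any(vapply(sets, identical, TRUE,
                           sort(names(aminoSmiles)[1:3]))))
    expect_true(any(vapply(sets, identical, TRUE,
                           sort(names(fattySmiles)[3:4]))))
    # the lone dissimilar metabolite stays a singleton
    expect_false("adenosine" %in% unlist(sets))
    # restriction then clustering == clustering the restricted matrix
    ca2 <- clusterSignificant(d[sig])
    expect_identical(clusterLabels(ca), clusterLabels(ca2))
    # fewer than 3 significant: all singletons with a warning
    expect_warning(deg <- clusterSignificant(d, sig[1:2]), "fewer than 3")
    expect_equal(numberOfClusters(deg), 2L)
    expect_equal(length(multiMetaboliteBins(deg)), 0L)
})
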