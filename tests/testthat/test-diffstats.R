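test_that("permutation p-values follow the add-one convention", {
    # separation no random regrouping can reach (the original split is
    # one of choose(20, 10) assignments, never drawn here)
    x <- 100 + 1:10
    y <- 1:10
    res <- permutationTTest(x, y, nPerm = 199, seed = 1)
    expect_equal(res$p_value, 1 / 200)
    # identical multisets: t = 0, p = 1
    res2 <- permutationTTest(c(1, 2, 3), c(3, 2, 1), nPerm = 99, seed = 1)
    expect_equal(res2$statistic, 0)
    expect_equal(res2$p_value, 1)
    # p is invariant to swapping the group labels
    set.seed(2)
    a <- rnorm(6); b <- rnorm(7, 1)
    expect_equal(permutationTTest(a, b, nPerm = 499, seed = 5)$p_value,
                 permutationTTest(b, a, nPerm = 499, seed = 5)$p_value)
    # degenerate variance: zero spread, nonzero difference
    res3 <- permutationTTest(c(1, 1), c(2, 2), nPerm = 99, seed = 1)
    expect_true(is.infinite(res3$statistic))
    expect_true(res3$p_value <= 1)
    # zero spread and zero difference: p = 1
    res4 <- permutationTTest(c(1, 1), c(1, 1), nPerm = 99, seed = 1)
    expect_equal(res4$p_value, 1)
})

test_that("permutation p-values are calibrated under the null", {
    set.seed(100)
    nTests <- 300
    p <- vapply(seq_len(nTests), function(i)
        permutationTTest(rnorm(10), rnorm(10), nPerm = 199,
                         seed = i)$p_value, numeric(1))
    rate <- mean(p <= 0.05)
    bound <- 2.58 * sqrt(0.05 * 0.95 / nTests)
    expect_lt(abs(rate - 0.05), bound + 0.005)  # discreteness slack
})

test_that("BH adjustment matches the literal step-up oracle", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.04, 0.5)),
                 c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
    expect_equal(bhAdjust(rep(0.3, 5)), rep(0.3, 5))
    expect_equal(bhAdjust(0.123), 0.123)
    set.seed(7)
    for (i in 1:50) {
        p <- runif(sample(2:40, 1))
        expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-12)
    }
    expect_error(bhAdjust(c(0.5, 0)), "p-values")
})

test_that("differential analysis flags a planted shift and nothing else", {
    set.seed(21)
    n <- 20; m <- 30
    v <- matrix(rnorm(n * m), n, m)
    shift <- 1:5
    trait <- rep(c("control", "case"), each = n / 2)
    v[trait == "case", shift] <- v[trait == "case", shift] + 2.5
    tab <- makeAdjusted(v, trait = trait)
    res <- differentialAnalysis(tab, nPerm = 499, seed = 9)
    expect_s4_class(res, "DifferentialResult")
    expect_setequal(significantIds(res), paste0("m", shift))
    expect_true(all(res$q_value >= res$p_value - 1e-15))
    expect_true(all(res$mean_log_fc[shift] > 0))
    # bit-reproducible given the seed
    res2 <- differentialAnalysis(tab, nPerm = 499, seed = 9)
    expect_identical(as.data.frame(res), as.data.frame(res2))
    # identical case/control values: nothing significant
    v0 <- rbind(v[1:10, ], v[1:10, ])
    tab0 <- makeAdjusted(v0, trait = trait)
    res0 <- differentialAnalysis(tab0, nPerm = 199, seed = 2)
    expect_equal(sum(res0$significant), 0L)
})

test_that("display fold changes can come from the normalized table", {
    set.seed(4)
    raw <- makeTable(matrix(rlnorm(40, 5), 8, 5),
                     trait = rep(c("control", "case"), each = 4))
    norm <- totalQuantityNormalize(imputeHalfMin(raw))
    adj <- covariateAdjust(log2Transform(norm), NULL)
    res <- differentialAnalysis(adj, nPerm = 99, seed = 1,
                                displayTable = norm)
    nv <- intensities(norm)
    expectFc <- rowMeans(nv[, 5:8]) / rowMeans(nv[, 1:4])
    expect_equal(res$fold_change, unname(expectFc))
})

test_that("Fisher cluster enrichment equals hypergeometric enumeration", {
    # both in-cluster significant, both out-cluster not: p = 1/6
    ca <- new("ClusterAssignment", ids = paste0("m", 1:4),
              labels = c(1L, 1L, 2L, 2L), k = 2L, asw = 0,
              silhouettes = rep(0, 4), tree = NULL)
    res <- fisherClusterEnrichment(ca, c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(res$p_value[res$unit_id == "1"], 1 / 6)
    # no significant metabolites -> p = 1 everywhere
    res0 <- fisherClusterEnrichment(ca, rep(FALSE, 4))
    expect_true(all(res0$p_value == 1))
    # random small instances vs enumeration oracle
    set.seed(13)
    for (i in 1:40) {
        N <- sample(4:12, 1)
        k <- sample(2:3, 1)
        labels <- sample(rep(seq_len(k), length.out = N))
        sig <- runif(N) < 0.4
        caR <- new("ClusterAssignment", ids = paste0("m", 1:N),
                   labels = as.integer(labels),
                   k = length(unique(labels)), asw = 0,
                   silhouettes = rep(0, N), tree = NULL)
        got <- fisherClusterEnrichment(caR, sig)
        for (r in seq_len(nrow(got))) {
            cl <- as.integer(got$unit_id[r])
            expect_equal(got$p_value[r],
                         oracleFisherGreater(sum(labels == cl & sig),
                                             sum(sig), N,
                                             sum(labels == cl)),
                         tolerance = 1e-12)
        }
    }
})

test_that("pathway enrichment matches combinatorial enumeration", {
    pw <- new("PathwayAnnotation", pathwayIds = c("p1", "p2"),
              descriptions = c("d1", "d2"),
              members = list(paste0("m", 1:3), paste0("m", 8:9)))
    pop <- paste0("m", 1:10)
    sig <- paste0("m", 1:5)
    res <- pathwayEnrichment(pw, sig, pop)
    # N=10, K=3, n=5, k=3: p = C(7,2)/C(10,5) = 21/252
    expect_equal(res$p_value[res$unit_id == "p1"], 21 / 252)
    # k = 0 -> upper tail from 0 covers all mass
    expect_equal(res$p_value[res$unit_id == "p2"], 1)
    # significant set = population: k = K for every pathway
    resAll <- pathwayEnrichment(pw, pop, pop)
    expect_true(all(resAll$n_overlap == resAll$n_members))
    expect_true(all(resAll$p_value == 1))
    # enumeration oracle on random instances
    set.seed(17)
    for (i in 1:30) {
        N <- sample(5:12, 1)
        pop <- paste0("m", 1:N)
        K <- sample(1:N, 1)
        members <- sample(pop, K)
        n <- sample(1:N, 1)
        sig <- sample(pop, n)
        got <- pathwayEnrichment(new("PathwayAnnotation",
                                     pathwayIds = "p",
                                     descriptions = "d",
                                     members = list(members)),
                                 sig, pop)
        k <- length(intersect(members, sig))
        expect_equal(got$p_value[1], oracleFisherGreater(k, K, N, n),
                     tolerance = 1e-12)
    }
    # pathway outside the population is skipped with a warning
    pwOut <- new("PathwayAnnotation", pathwayIds = c("p1", "px"),
                 descriptions = c("", ""),
                 members = list(paste0("m", 1:2), "zz"))
    expect_warning(res2 <- pathwayEnrichment(pwOut, "m1", paste0("m", 1:5)),
                   "no member")
    expect_equal(nrow(res2), 1L)
})

test_that("pathway-in-cluster enrichment mirrors the significance contract", {
    # all 3 members inside a cluster of exactly that size, population 10
    ca <- new("ClusterAssignment", ids = paste0("m", 1:10),
              labels = as.integer(c(1, 1, 1, rep(2, 7))), k = 2L, asw = 0,
              silhouettes = rep(0, 10), tree = NULL)
    res <- fisherPathwayInCluster(ca, paste0("m", 1:3))
    expect_equal(res$p_value[res$unit_id == "1"], 1 / choose(10, 3))
    # empty intersection
    res0 <- fisherPathwayInCluster(ca, c("zz1", "zz2"))
    expect_true(all(res0$p_value == 1))
    # spread members are not enriched
    resS <- fisherPathwayInCluster(ca, c("m1", "m4", "m5"))
    expect_gte(resS$p_value[resS$unit_id == "1"], 0.5)
})

test_that("whole-population cluster yields p = 1 with a warning", {
    ca <- new("ClusterAssignment", ids = paste0("m", 1:3),
              labels = c(1L, 1L, 1L), k = 1L, asw = 0,
              silhouettes = rep(0, 3), tree = NULL)
    expect_warning(res <- fisherClusterEnrichment(ca, c(TRUE, FALSE, TRUE)),
                   "whole population")
    expect_equal(res$p_value, 1)
})
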