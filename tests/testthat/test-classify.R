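# small separable fixture: one informative metabolite among noise
separableTable <- function(n = 10, seed = 1) {
    set.seed(seed)
    trait <- rep(c("control", "case"), each = n / 2)
    v <- cbind(ifelse(trait == "case", 3, -3) + rnorm(n, sd = 0.3),
               rnorm(n), rnorm(n))
    makeAdjusted(v, trait = trait)
}

test_that("LOOCV emits one out-of-fold probability per sample", {
    tab <- separableTable(10)
    spec <- classifierSpec("m1", "logistic", seed = 3)
    prob <- loocvProbabilities(tab, spec)
    expect_length(prob, 10)
    expect_equal(names(prob), sampleIds(tab))
    # perfectly separable: every probability on the correct side of 0.5
    y <- as.integer(traitLabels(tab) == "case")
    expect_true(all((prob > 0.5) == (y == 1)))
})

test_that("out-of-fold predictions ignore the held-out sample entirely", {
    tab <- separableTable(20, seed = 5)
    spec <- classifierSpec("m1", "logistic", seed = 7)
    prob <- loocvProbabilities(tab, spec)
    v <- intensities(tab)
    cd <- as.data.frame(SummarizedExperiment::colData(tab))
    for (i in c(1, 7, 20)) {
        # poison sample i: flip its held-out label
        cd2 <- cd
        cd2$trait[i] <- ifelse(cd2$trait[i] == "case", "control", "case")
        tab2 <- MetaboSet(v, cd2, traitColumn = "trait",
                          state = "covariate_adjusted")
        prob2 <- loocvProbabilities(tab2, spec)
        expect_equal(unname(prob2[i]), unname(prob[i]), tolerance = 1e-12)
    }
})

test_that("LOOCV refuses degenerate class counts", {
    v <- cbind(rnorm(4))
    tab <- makeAdjusted(v, trait = c("case", "control", "control",
                                     "control"))
    spec <- classifierSpec("m1", "logistic")
    expect_error(loocvProbabilities(tab, spec), "at least 2 samples")
})

test_that("threshold selection maximizes accuracy with the stated ties", {
    sel <- selectThreshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
    expect_equal(sel$accuracy, 1)
    expect_equal(sel$auc, 1)
    expect_gt(sel$threshold, 0.2)
    expect_lt(sel$threshold, 0.8)
    # anti-aligned: AUC 0, accuracy from the best constant side
    sel2 <- selectThreshold(c(0.9, 0.8, 0.1, 0.2), c(0, 0, 1, 1))
    expect_equal(sel2$auc, 0)
    expect_equal(sel2$accuracy, 0.5)
    # constant classifiers are always candidates
    set.seed(61)
    for (i in 1:20) {
        n <- sample(6:20, 1)
        y <- rbinom(n, 1, 0.5)
        if (length(unique(y)) < 2) next
        prob <- runif(n)
        sel3 <- selectThreshold(prob, y)
        expect_gte(sel3$accuracy, max(sum(y == 1), sum(y == 0)) / n)
    }
    expect_error(selectThreshold(c(0.2, 0.4), c(1, 1)), "both classes")
})

test_that("rank AUC equals the concordant-pair oracle", {
    set.seed(67)
    for (i in 1:50) {
        n <- sample(5:15, 1)
        y <- rbinom(n, 1, 0.5)
        if (length(unique(y)) < 2) next
        prob <- round(runif(n), 1)        # force ties
        expect_equal(rankAUC(prob, y), oracleAUC(prob, y),
                     tolerance = 1e-12)
    }
})

test_that("grid search keeps the best point and reports consistently", {
    tab <- separableTable(12, seed = 11)
    # degenerate ncomp=0 is not expressible; contrast tiny/fine svm costs
    spec <- classifierSpec(c("m1", "m2"), "svm",
                           grid = list(cost = c(1e-6, 1)), seed = 3)
    rep <- gridSearch(tab, spec)
    expect_equal(rep@hyperparameters$cost, 1)
    expect_true(all(rep@internal >= 0 & rep@internal <= 1))
    # one-point grid equals direct evaluation
    spec1 <- classifierSpec("m1", "logistic", seed = 3)
    rep1 <- gridSearch(tab, spec1)
    prob <- loocvProbabilities(tab, spec1)
    sel <- selectThreshold(prob, as.integer(traitLabels(tab) == "case"))
    expect_equal(unname(rep1@internal["accuracy"]), sel$accuracy)
    expect_equal(rep1@threshold, sel$threshold)
    # chosen hyperparameters always come from the grid
    spec2 <- classifierSpec(c("m1", "m2"), "plsda",
                            grid = list(ncomp = 1:2), seed = 3)
    rep2 <- gridSearch(tab, spec2)
    expect_true(rep2@hyperparameters$ncomp %in% 1:2)
})

test_that("every family fits, predicts deterministically, and validates", {
    tab <- separableTable(12, seed = 13)
    fams <- c(logistic = 1L, svm = 2L, plsda = 2L, random_forest = 2L,
              gradient_boosted_trees = 2L)
    for (fam in names(fams)) {
        mets <- paste0("m", seq_len(fams[[fam]]))
        spec <- classifierSpec(mets, fam,
                               grid = switch(fam,
                                   logistic = NULL,
                                   svm = list(cost = 1),
                                   plsda = list(ncomp = 1),
                                   random_forest = list(mtry = 1,
                                                        ntree = 100),
                                   gradient_boosted_trees =
                                       list(max_depth = 1, nrounds = 20)),
                               seed = 5)
        rep <- finalizeReport(tab, gridSearch(tab, spec))
        p1 <- predictProbabilities(rep, tab)
        m2 <- trainFinal(tab, spec, rep@hyperparameters)
        rep2 <- rep; rep2@model <- m2
        expect_equal(predictProbabilities(rep2, tab), p1,
                     tolerance = 1e-12, label = fam)
        val <- externalValidate(rep, tab)
        expect_true(all(val@external >= 0 & val@external <= 1))
        # resubstitution on the training table matches direct computation
        y <- as.integer(traitLabels(tab) == "case")
        yhat <- as.integer(p1 >= rep@threshold)
        expect_equal(unname(val@external["accuracy"]), mean(yhat == y),
                     label = fam)
    }
})

test_that("separable ridge logistic keeps finite coefficients", {
    v <- cbind(c(-2, -1, 1, 2, -1.5, 1.5))
    tab <- makeAdjusted(v, trait = c("control", "control", "case", "case",
                                     "control", "case"))
    model <- trainFinal(tab, classifierSpec("m1", "logistic"))
    expect_true(all(is.finite(model$fit$beta)))
    prob <- predictProbabilities(
        finalizeReport(tab, gridSearch(tab, classifierSpec("m1",
                                                           "logistic"))),
        tab)
    expect_true(all((prob > 0.5) == c(FALSE, FALSE, TRUE, TRUE, FALSE,
                                      TRUE)))
})

test_that("external validation fails fast on a missing metabolite", {
    tab <- separableTable(10)
    rep <- finalizeReport(tab, gridSearch(tab, classifierSpec(
        "m1", "logistic", seed = 1)))
    test <- makeAdjusted(matrix(rnorm(8), 4, 2,
                                dimnames = list(NULL, c("mX", "mY"))))
    expect_error(externalValidate(rep, test), "not in table")
})

test_that("shuffled external labels give chance-level performance", {
    tab <- separableTable(12, seed = 17)
    rep <- finalizeReport(tab, gridSearch(tab, classifierSpec(
        "m1", "logistic", seed = 1)))
    set.seed(19)
    n <- 200
    v <- cbind(rnorm(n, 0, 3), rnorm(n), rnorm(n))
    test <- makeAdjusted(v, trait = sample(rep(c("control", "case"),
                                               each = n / 2)))
    val <- externalValidate(rep, test)
    expect_lt(abs(val@external["auc"] - 0.5), 0.12)
    expect_lt(val@external["accuracy"], 0.65)
})

test_that("the suite enumerates single, cluster, and baseline models", {
    set.seed(71)
    n <- 12
    trait <- rep(c("control", "case"), each = n / 2)
    shift <- ifelse(trait == "case", 2, -2)
    v <- cbind(shift + rnorm(n, sd = .5), shift + rnorm(n, sd = .5),
               -shift + rnorm(n, sd = .5), shift + rnorm(n, sd = .5),
               rnorm(n), rnorm(n))
    tab <- makeAdjusted(v, trait = trait)
    diff <- differentialAnalysis(tab, nPerm = 499, seed = 23, fdr = 0.075)
    sig <- significantIds(diff)
    expect_setequal(sig, paste0("m", 1:4))
    clusters <- new("ClusterAssignment", ids = paste0("m", 1:4),
                    labels = c(1L, 1L, 2L, 3L), k = 3L, asw = 0.5,
                    silhouettes = rep(0.5, 4), tree = NULL)
    cheap <- list(svm = list(cost = 1), plsda = list(ncomp = 1),
                  random_forest = list(mtry = 1, ntree = 50),
                  gradient_boosted_trees = list(max_depth = 1,
                                                nrounds = 10))
    suite <- buildModelSuite(tab, diff, clusters, grids = cheap, seed = 3)
    # 4 single + 4 families x 1 pair-cluster + 8 baselines = 16
    expect_length(suite, 16L)
    labels <- vapply(suite, function(r) r@label, "")
    expect_equal(sum(startsWith(labels, "single:")), 4L)
    expect_equal(sum(labels == "cluster:1"), 4L)
    expect_equal(sum(labels == "significant"), 4L)
    expect_equal(sum(labels == "all_metabolites"), 4L)
    # metabolite sets: subsets of the significant set except baselines
    for (r in suite)
        if (r@label != "all_metabolites")
            expect_true(all(reportMetabolites(r) %in% sig))
    # selection ignores external metrics entirely
    best <- selectBest(suite)
    poisoned <- lapply(suite, function(r) {
        r@external <- c(accuracy = 1, sensitivity = 1, specificity = 1,
                        auc = 1)
        r
    })
    best2 <- selectBest(poisoned)
    expect_equal(best2@label, best@label)
    expect_equal(best2@spec@family, best@spec@family)
})

test_that("a suite without significant metabolites degrades with warning", {
    set.seed(73)
    tab <- makeAdjusted(matrix(rnorm(40), 10, 4))
    diff <- differentialAnalysis(tab, nPerm = 99, seed = 1)
    expect_equal(length(significantIds(diff)), 0L)
    expect_warning(
        suite <- buildModelSuite(tab, diff, NULL,
                                 families = "plsda",
                                 grids = list(plsda = list(ncomp = 1))),
        "no significant")
    expect_length(suite, 1L)
    expect_equal(suite[[1]]@label, "all_metabolites")
})

test_that("logistic specs are restricted to single metabolites", {
    expect_error(classifierSpec(c("m1", "m2"), "logistic"),
                 "single-metabolite")
    expect_error(classifierSpec(character(0), "svm"), "non-empty")
})
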