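#' @include methods-accessors.R
NULL

## ---- internal model engines -------------------------------------------

## Ridge-stabilized logistic regression by iteratively reweighted least
## squares.  The tiny default penalty keeps coefficients finite on
## separable data without materially biasing non-separable fits.
.ridgeLogistic <- function(X, y, lambda = 1e-8, maxit = 100L, tol = 1e-10) {
    X <- as.matrix(X)
    Xd <- cbind(`(Intercept)` = 1, X)
    pen <- c(0, rep(lambda, ncol(X)))
    beta <- numeric(ncol(Xd))
    for (it in seq_len(maxit)) {
        eta <- drop(Xd %*% beta)
        mu <- stats::plogis(eta)
        w <- pmax(mu * (1 - mu), 1e-12)
        H <- crossprod(Xd, Xd * w) + diag(pen, ncol(Xd))
        g <- crossprod(Xd, y - mu) - pen * beta
        delta <- tryCatch(solve(H, g), error = function(e) NULL)
        if (is.null(delta)) break
        beta <- beta + drop(delta)
        if (max(abs(delta)) < tol) break
    }
    list(beta = stats::setNames(beta, colnames(Xd)))
}

.predictRidgeLogistic <- function(fit, X)
    stats::plogis(drop(cbind(1, as.matrix(X)) %*% fit$beta))

## Platt-style link: logistic fit of the class on a decision value.
.plattFit <- function(scores, y)
    .ridgeLogistic(matrix(scores, ncol = 1L), y, lambda = 1e-6)

.plattPredict <- function(fit, scores)
    .predictRidgeLogistic(fit, matrix(scores, ncol = 1L))

## RBF kernel width by the median heuristic on pairwise squared distances.
.gammaHeuristic <- function(X) {
    d2 <- as.numeric(stats::dist(X))^2
    med <- stats::median(d2[d2 > 0])
    if (!is.finite(med) || med <= 0) 1 / ncol(X) else 1 / med
}

## Fit one model family; returns an object understood by .predictModel.
.fitModel <- function(family, X, y, hyper, seed) {
    X <- as.matrix(X)
    yf <- factor(ifelse(y == 1, "case", "control"),
                 levels = c("control", "case"))
    fit <- switch(family,
        logistic = .withSeed(seed, .ridgeLogistic(X, y)),
        svm = .withSeed(seed, {
            gamma <- hyper$gamma %||% .gammaHeuristic(X)
            m <- e1071::svm(X, yf, kernel = "radial",
                            cost = hyper$cost %||% 1, gamma = gamma,
                            scale = FALSE)
            dv <- drop(attr(stats::predict(m, X, decision.values = TRUE),
                            "decision.values"))
            list(svm = m, platt = .plattFit(dv, y))
        }),
        plsda = .withSeed(seed, {
            ncomp <- min(hyper$ncomp %||% 2L, ncol(X),
                         nrow(X) - 1L)
            m <- mixOmics::plsda(X, yf, ncomp = ncomp)
            sc <- stats::predict(m, X)$predict[, "case", ncomp]
            list(plsda = m, ncomp = ncomp, platt = .plattFit(sc, y))
        }),
        random_forest = .withSeed(seed, {
            mtry <- min(hyper$mtry %||% max(1L, floor(sqrt(ncol(X)))),
                        ncol(X))
            randomForest::randomForest(X, yf,
                                       ntree = hyper$ntree %||% 500L,
                                       mtry = mtry)
        }),
        gradient_boosted_trees = .withSeed(seed, {
            dtr <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
            xgboost::xgb.train(
                params = list(objective = "binary:logistic",
                              max_depth = hyper$max_depth %||% 2L,
                              learning_rate = hyper$learning_rate %||% 0.3,
                              nthread = 1L, seed = as.integer(seed)),
                data = dtr, nrounds = hyper$nrounds %||% 50L)
        }),
        stop("unknown model family: ", family))
    structure(list(family = family, fit = fit,
                   metabolites = colnames(X)),
              class = "mcModel")
}

.predictModel <- function(model, X) {
    X <- as.matrix(X)[, model$metabolites, drop = FALSE]
    fit <- model$fit
    switch(model$family,
        logistic = .predictRidgeLogistic(fit, X),
        svm = {
            dv <- drop(attr(stats::predict(fit$svm, X,
                                           decision.values = TRUE),
                            "decision.values"))
            .plattPredict(fit$platt, dv)
        },
        plsda = {
            sc <- stats::predict(fit$plsda, X)$predict[, "case", fit$ncomp]
            .plattPredict(fit$platt, sc)
        },
        random_forest =
            unname(stats::predict(fit, X, type = "prob")[, "case"]),
        gradient_boosted_trees =
            stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1L)))
}

## ---- public surface ----------------------------------------------------

#' Default hyperparameter grid for a model family
#'
#' svm: RBF kernel with cost in \{0.25, 0.5, 1, 2, 4\} (kernel width by the
#' median-distance heuristic); plsda: components 1..min(5, p); random
#' forest: 500 trees with mtry in 1..p; gradient boosted trees: depth
#' \{1, 2, 3\} by rounds \{50, 150\} at learning rate 0.3.  Logistic models
#' have nothing to tune.
#'
#' @param family model family name.
#' @param p number of metabolites available to the model.
#' @return named list of hyperparameter value vectors.
#' @export
defaultGrid <- function(family, p) {
    switch(family,
        logistic = list(),
        svm = list(cost = c(0.25, 0.5, 1, 2, 4)),
        plsda = list(ncomp = seq_len(min(5L, p))),
        random_forest = list(mtry = seq_len(p)),
        gradient_boosted_trees = list(max_depth = c(1L, 2L, 3L),
                                      nrounds = c(50L, 150L)),
        stop("unknown model family: ", family))
}

#' Construct a ClassifierSpec
#'
#' @param metabolites metabolite ids the model may use.
#' @param family model family; `"logistic"` is restricted to single
#'   metabolites.
#' @param grid named list of hyperparameter vectors; `NULL` uses
#'   [defaultGrid()].
#' @param seed seed for stochastic fitting.
#' @return a [ClassifierSpec].
#' @export
classifierSpec <- function(metabolites, family, grid = NULL, seed = 1L) {
    if (is.null(grid)) grid <- defaultGrid(family, length(metabolites))
    new("ClassifierSpec", metabolites = as.character(metabolites),
        family = family, grid = grid, seed = as.integer(seed))
}

.gridPoints <- function(grid) {
    if (length(grid) == 0L) return(list(list()))
    g <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

.designFor <- function(x, metabolites) {
    miss <- setdiff(metabolites, metaboliteIds(x))
    if (length(miss))
        stop("metabolite(s) not in table: ", paste(miss, collapse = ", "))
    t(intensities(x))[, metabolites, drop = FALSE]
}

.binaryLabels <- function(x, caseLevel = NULL) {
    trait <- traitLabels(x)
    as.integer(trait == .caseLevel(trait, caseLevel))
}

#' Leave-one-out cross-validated probabilities
#'
#' For each sample i, fits the specified model on all samples except i and
#' records the predicted case-probability for i.  Deterministic given the
#' spec seed.
#'
#' @param x a [MetaboSet] in state `"covariate_adjusted"`.
#' @param spec a [ClassifierSpec].
#' @param hyper one hyperparameter setting (named list).
#' @param caseLevel trait level treated as case (see
#'   [differentialAnalysis()]).
#' @return named numeric vector of out-of-fold probabilities, one per
#'   sample.
#' @export
loocvProbabilities <- function(x, spec, hyper = list(), caseLevel = NULL) {
    stopifnot(is(x, "MetaboSet"), is(spec, "ClassifierSpec"))
    .requireState(x, "covariate_adjusted", "loocvProbabilities")
    X <- .designFor(x, spec@metabolites)
    y <- .binaryLabels(x, caseLevel)
    if (min(table(y)) < 2L)
        stop("each class needs at least 2 samples for LOOCV")
    n <- nrow(X)
    prob <- numeric(n)
    for (i in seq_len(n)) {
        if (length(unique(y[-i])) < 2L)
            stop("LOOCV fold ", i, " has a single class in training")
        model <- .fitModel(spec@family, X[-i, , drop = FALSE], y[-i],
                           hyper, seed = spec@seed)
        prob[i] <- .predictModel(model, X[i, , drop = FALSE])
    }
    stats::setNames(prob, rownames(X))
}

#' Select a probability threshold by maximal accuracy
#'
#' Candidate thresholds are the midpoints of adjacent sorted unique
#' probabilities plus guards below the smallest and above the largest
#' probability (so the constant classifiers are always candidates).  A
#' sample is called a case when its probability is >= the threshold.  The
#' threshold maximizing accuracy is returned; ties go to the highest
#' specificity, then the lowest threshold.  AUC is the rank-based
#' Mann-Whitney statistic with ties counted half.
#'
#' @param prob predicted case-probabilities.
#' @param labels 0/1 (or logical) true labels, 1 = case; both classes must
#'   be present.
#' @return list with `threshold`, `accuracy`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
selectThreshold <- function(prob, labels) {
    y <- as.integer(as.logical(labels))
    if (length(prob) != length(y))
        stop("probabilities and labels must have the same length")
    if (length(unique(y)) < 2L) stop("both classes must be present")
    u <- sort(unique(prob))
    cand <- unique(c(max(u[1L] / 2, 1e-12),
                     (u[-1L] + u[-length(u)]) / 2,
                     min((u[length(u)] + 1) / 2, 1 - 1e-12)))
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    best <- NULL
    for (thr in cand) {
        yhat <- as.integer(prob >= thr)
        sens <- sum(yhat == 1L & y == 1L) / n1
        spc <- sum(yhat == 0L & y == 0L) / n0
        acc <- mean(yhat == y)
        if (is.null(best) || acc > best$accuracy ||
            (acc == best$accuracy && spc > best$specificity))
            best <- list(threshold = thr, accuracy = acc,
                         sensitivity = sens, specificity = spc)
    }
    best$auc <- rankAUC(prob, y)
    best
}

#' Rank-based AUC (Mann-Whitney with ties counted half)
#'
#' @param prob predicted case-probabilities.
#' @param labels 0/1 labels, 1 = case.
#' @return the area under the ROC curve.
#' @export
rankAUC <- function(prob, labels) {
    y <- as.integer(as.logical(labels))
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    if (n1 == 0L || n0 == 0L) stop("both classes must be present")
    r <- rank(prob)
    (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.metricsAt <- function(prob, y, thr) {
    yhat <- as.integer(prob >= thr)
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    c(accuracy = mean(yhat == y),
      sensitivity = sum(yhat == 1L & y == 1L) / n1,
      specificity = sum(yhat == 0L & y == 0L) / n0,
      auc = rankAUC(prob, y))
}

#' Grid search over hyperparameters by LOOCV accuracy
#'
#' Evaluates every grid point of the spec by LOOCV, selects the
#' probability threshold per point, and keeps the point (then threshold)
#' with the highest LOOCV accuracy (ties resolved toward the first point
#' in declared grid order).
#'
#' @inheritParams loocvProbabilities
#' @param label short description stored on the report.
#' @return a [ClassifierReport] with internal metrics only (no final
#'   model; see [trainFinal()]).
#' @export
gridSearch <- function(x, spec, caseLevel = NULL, label = "model") {
    stopifnot(is(x, "MetaboSet"), is(spec, "ClassifierSpec"))
    points <- .gridPoints(spec@grid)
    if (length(points) == 0L) stop("empty hyperparameter grid")
    y <- .binaryLabels(x, caseLevel)
    best <- NULL
    for (pt in points) {
        prob <- loocvProbabilities(x, spec, hyper = pt,
                                   caseLevel = caseLevel)
        sel <- selectThreshold(prob, y)
        if (is.null(best) || sel$accuracy > best$sel$accuracy)
            best <- list(pt = pt, sel = sel, prob = prob)
    }
    internal <- .metricsAt(best$prob, y, best$sel$threshold)
    new("ClassifierReport", spec = spec, label = label,
        hyperparameters = best$pt, threshold = best$sel$threshold,
        internal = internal, external = numeric(0), model = NULL)
}

#' Fit the final model on all training samples
#'
#' @inheritParams loocvProbabilities
#' @param hyper the hyperparameters chosen by [gridSearch()].
#' @return an internal model object usable with [externalValidate()].
#' @export
trainFinal <- function(x, spec, hyper = list(), caseLevel = NULL) {
    stopifnot(is(x, "MetaboSet"), is(spec, "ClassifierSpec"))
    .requireState(x, "covariate_adjusted", "trainFinal")
    X <- .designFor(x, spec@metabolites)
    y <- .binaryLabels(x, caseLevel)
    .fitModel(spec@family, X, y, hyper, seed = spec@seed)
}

#' Attach the final model to a grid-search report
#'
#' @param x the training [MetaboSet].
#' @param report a [ClassifierReport] from [gridSearch()].
#' @param caseLevel trait level treated as case.
#' @return the report with its `model` slot filled.
#' @export
finalizeReport <- function(x, report, caseLevel = NULL) {
    stopifnot(is(report, "ClassifierReport"))
    report@model <- trainFinal(x, report@spec, report@hyperparameters,
                               caseLevel = caseLevel)
    report
}

#' Externally validate a frozen model and threshold
#'
#' Applies the final model and the LOOCV-selected probability threshold to
#' an independently preprocessed test cohort and reports accuracy,
#' sensitivity, specificity and AUC.  Neither the model nor the threshold
#' is refitted.
#'
#' @param report a finalized [ClassifierReport] (see [finalizeReport()]).
#' @param test a [MetaboSet] in state `"covariate_adjusted"` containing
#'   all model metabolites.
#' @param caseLevel trait level treated as case.
#' @return the report with its `external` metrics filled.
#' @export
externalValidate <- function(report, test, caseLevel = NULL) {
    stopifnot(is(report, "ClassifierReport"), is(test, "MetaboSet"))
    .requireState(test, "covariate_adjusted", "externalValidate")
    if (is.null(report@model))
        stop("report has no final model; run finalizeReport() first")
    X <- .designFor(test, report@spec@metabolites)
    y <- .binaryLabels(test, caseLevel)
    prob <- .predictModel(report@model, X)
    report@external <- .metricsAt(prob, y, report@threshold)
    report
}

#' Build the full classifier suite
#'
#' Mirrors the comparison design of the workflow: one logistic model per
#' significant metabolite, every requested machine-learning family on each
#' multi-metabolite cluster bin, and every family on the two baselines
#' (all metabolites; all significant metabolites).  Each entry is tuned by
#' [gridSearch()] and finalized on the full training set.
#'
#' @param x the training [MetaboSet] (state `"covariate_adjusted"`).
#' @param diff a [DifferentialResult] for `x`.
#' @param clusters a [ClusterAssignment] of the significant metabolites.
#' @param families machine-learning families for multi-metabolite models.
#' @param grids optional named list (by family) overriding
#'   [defaultGrid()].
#' @param seed seed for stochastic fitting.
#' @param caseLevel trait level treated as case.
#' @return list of finalized [ClassifierReport] objects.
#' @export
buildModelSuite <- function(x, diff, clusters,
                            families = c("svm", "plsda", "random_forest",
                                         "gradient_boosted_trees"),
                            grids = list(), seed = 1L, caseLevel = NULL) {
    stopifnot(is(x, "MetaboSet"), is(diff, "DifferentialResult"))
    sig <- significantIds(diff)
    reports <- list()
    specFor <- function(mets, family)
        classifierSpec(mets, family,
                       grid = grids[[family]] %||%
                           defaultGrid(family, length(mets)),
                       seed = seed)
    addModel <- function(mets, family, label) {
        rep <- gridSearch(x, specFor(mets, family), caseLevel = caseLevel,
                          label = label)
        reports[[length(reports) + 1L]] <<-
            finalizeReport(x, rep, caseLevel = caseLevel)
    }
    if (length(sig) == 0L) {
        warning("no significant metabolites; ",
                "suite contains only all-metabolite models")
    } else {
        for (id in sig) addModel(id, "logistic", paste0("single:", id))
        if (!is.null(clusters)) {
            stopifnot(is(clusters, "ClusterAssignment"))
            bins <- multiMetaboliteBins(clusters)
            for (b in names(bins))
                for (fam in families)
                    addModel(bins[[b]], fam, paste0("cluster:", b))
        }
        for (fam in families)
            addModel(sig, fam, "significant")
    }
    for (fam in families)
        addModel(metaboliteIds(x), fam, "all_metabolites")
    reports
}

#' Select the best classifier by internal LOOCV accuracy
#'
#' Ties are resolved toward the higher internal AUC, then the smaller
#' metabolite set.  External metrics are never consulted.
#'
#' @param reports non-empty list of [ClassifierReport] objects.
#' @return the selected [ClassifierReport].
#' @export
selectBest <- function(reports) {
    if (length(reports) == 0L) stop("empty report list")
    best <- reports[[1L]]
    for (r in reports[-1L]) {
        ra <- r@internal["accuracy"]; ba <- best@internal["accuracy"]
        if (ra > ba ||
            (ra == ba && r@internal["auc"] > best@internal["auc"]) ||
            (ra == ba && r@internal["auc"] == best@internal["auc"] &&
             length(r@spec@metabolites) < length(best@spec@metabolites)))
            best <- r
    }
    best
}

#' Tabulate a classifier suite
#'
#' One row per report in the layout of the workflow's performance tables:
#' metabolite set, family, tuned hyperparameters, threshold, internal
#' (LOOCV) block and, where present, external block.
#'
#' @param reports list of [ClassifierReport] objects.
#' @return a `data.frame`.
#' @export
suiteSummary <- function(reports) {
    rows <- lapply(reports, function(r) {
        hp <- if (length(r@hyperparameters))
            paste(names(r@hyperparameters), unlist(r@hyperparameters),
                  sep = "=", collapse = ";") else ""
        ext <- if (length(r@external)) r@external
               else c(accuracy = NA_real_, sensitivity = NA_real_,
                      specificity = NA_real_, auc = NA_real_)
        data.frame(label = r@label, family = r@spec@family,
                   n_metabolites = length(r@spec@metabolites),
                   metabolites = paste(r@spec@metabolites, collapse = ";"),
                   hyperparameters = hp, threshold = r@threshold,
                   loocv_accuracy = unname(r@internal["accuracy"]),
                   loocv_sensitivity = unname(r@internal["sensitivity"]),
                   loocv_specificity = unname(r@internal["specificity"]),
                   loocv_auc = unname(r@internal["auc"]),
                   external_accuracy = unname(ext["accuracy"]),
                   external_sensitivity = unname(ext["sensitivity"]),
                   external_specificity = unname(ext["specificity"]),
                   external_auc = unname(ext["auc"]),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
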