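#' @include classify.R
NULL

## tiny deterministic FNV-1a hash for provenance stamping
.configHash <- function(x) {
    s <- paste(deparse(x), collapse = "")
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", as.integer(h))
}

.writeCsvProv <- function(df, path, prov) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", prov), con)
    utils::write.csv(df, con, row.names = FALSE)
    invisible(path)
}

#' Configuration for the end-to-end pipeline
#'
#' Collects the inputs and the parameters of every stage.  Tables,
#' structures and pathways may be given as file paths or as in-memory
#' objects ([MetaboSet], [StructureSet], [PathwayAnnotation]).
#'
#' @param train training intensity table (path or [MetaboSet]).
#' @param structures structure table (path or [StructureSet]).
#' @param test optional test-cohort intensity table.
#' @param pathways optional pathway annotation.
#' @param metaColumns,traitColumn passed to [readIntensityTable()] when
#'   tables are paths.
#' @param covariates covariate names for [covariateAdjust()].
#' @param fdrDiff FDR threshold of the differential analysis
#'   (default 0.075).
#' @param fdrEnrich FDR threshold of the enrichment tests (default 0.05).
#' @param bitCorrCutoff Pearson cutoff of [filterCorrelatedBits()]
#'   (default 0.9).
#' @param nPerm permutations per metabolite (default 100000).
#' @param families,grids model families and optional grid overrides for
#'   [buildModelSuite()].
#' @param seed master seed.
#' @param outputDir directory for stage artifacts (`NULL`: nothing
#'   written).
#' @return a validated `pipeline_config` list.
#' @export
pipelineConfig <- function(train, structures, test = NULL, pathways = NULL,
                           metaColumns = c("trait", "gender", "smoking"),
                           traitColumn = metaColumns[1],
                           covariates = setdiff(metaColumns, traitColumn),
                           fdrDiff = 0.075, fdrEnrich = 0.05,
                           bitCorrCutoff = 0.9, nPerm = 100000L,
                           families = c("svm", "plsda", "random_forest",
                                        "gradient_boosted_trees"),
                           grids = list(), seed = 1L, outputDir = NULL) {
    stopifnot(fdrDiff > 0, fdrDiff < 1, fdrEnrich > 0, fdrEnrich < 1,
              bitCorrCutoff > 0, bitCorrCutoff < 1)
    for (f in list(train, structures, test, pathways))
        if (is.character(f) && !file.exists(f))
            stop("input file does not exist: ", f)
    structure(list(train = train, structures = structures, test = test,
                   pathways = pathways, metaColumns = metaColumns,
                   traitColumn = traitColumn, covariates = covariates,
                   fdrDiff = fdrDiff, fdrEnrich = fdrEnrich,
                   bitCorrCutoff = bitCorrCutoff,
                   nPerm = as.integer(nPerm), families = families,
                   grids = grids, seed = as.integer(seed),
                   outputDir = outputDir),
              class = "pipeline_config")
}

#' Run the full chemocentric workflow
#'
#' Executes, in order: panel alignment, preprocessing (imputation, total
#' quantity normalization, log2, covariate adjustment), permutation
#' differential analysis, MACCS fingerprinting with correlated-bit
#' filtering and Soergel distances, silhouette-selected average-linkage
#' clustering of all metabolites (with Fisher cluster-enrichment tests)
#' and of the significant metabolites, optional pathway
#' over-representation, classifier-suite construction with LOOCV grid
#' search, external validation on the test cohort, and model selection by
#' LOOCV accuracy.  When `outputDir` is set, every intermediate artifact
#' plus a summary table is written with a provenance header (package
#' version, seed, config hash); reruns with the same config are
#' byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @return list with the loaded/processed tables, `differential`,
#'   `distance`, `fullClusters`, `clusterEnrichment`,
#'   `pathwayEnrichment`, `pathwayClusterEnrichment`,
#'   `significantClusters`, `suite`, `best` and `summary`.
#' @export
runAll <- function(config) {
    stopifnot(inherits(config, "pipeline_config"))
    lastGood <- "none"
    stage <- function(name, expr) {
        out <- tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 " (last good artifact: ", lastGood, ")", call. = FALSE))
        lastGood <<- name
        out
    }
    ## hash the scalar configuration; in-memory data objects contribute
    ## their class tag only (their content is reflected in the artifacts)
    hashable <- lapply(config[setdiff(names(config), "outputDir")],
                       function(el) if (is.object(el)) class(el)[1] else el)
    prov <- sprintf("metaboclust %s | seed %d | config %s",
                    as.character(utils::packageVersion("metaboclust")),
                    config$seed, .configHash(hashable))
    outDir <- config$outputDir
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    emit <- function(df, name) {
        if (!is.null(outDir))
            .writeCsvProv(as.data.frame(df), file.path(outDir, name), prov)
    }

    loadTable <- function(f) {
        if (is(f, "MetaboSet")) f
        else readIntensityTable(f, metaColumns = config$metaColumns,
                                traitColumn = config$traitColumn)
    }
    train <- stage("load_train", loadTable(config$train))
    test <- if (!is.null(config$test))
        stage("load_test", loadTable(config$test)) else NULL
    structures <- stage("load_structures", {
        if (is(config$structures, "StructureSet")) config$structures
        else readStructures(config$structures)
    })
    annotation <- if (!is.null(config$pathways)) {
        if (is(config$pathways, "PathwayAnnotation")) config$pathways
        else stage("load_pathways", readPathways(config$pathways))
    } else NULL

    companions <- if (is.null(test)) list() else list(test)
    trainAligned <- stage("align",
                          alignDataset(train, structures, companions))
    if (!is.null(test)) {
        test <- stage("align_test",
                      alignDataset(test, structures, list(train)))
        test <- test[metaboliteIds(trainAligned), ]
    }
    train <- trainAligned

    prep <- function(tab) {
        norm <- totalQuantityNormalize(imputeHalfMin(tab))
        adj <- covariateAdjust(log2Transform(norm), config$covariates)
        list(norm = norm, adj = adj)
    }
    trainPrep <- stage("preprocess_train", prep(train))
    testPrep <- if (!is.null(test))
        stage("preprocess_test", prep(test)) else NULL
    if (!is.null(outDir)) {
        writeIntensityTable(trainPrep$adj,
                            file.path(outDir, "train_adjusted.csv"))
        if (!is.null(testPrep))
            writeIntensityTable(testPrep$adj,
                                file.path(outDir, "test_adjusted.csv"))
    }

    diff <- stage("differential_analysis",
                  differentialAnalysis(trainPrep$adj, fdr = config$fdrDiff,
                                       nPerm = config$nPerm,
                                       seed = config$seed,
                                       displayTable = trainPrep$norm))
    emit(as.data.frame(diff), "differential.csv")
    sig <- significantIds(diff)

    dist <- stage("fingerprints", {
        fp <- maccsFingerprints(structures[metaboliteIds(train)])
        soergelDistance(filterCorrelatedBits(fp, config$bitCorrCutoff))
    })
    if (!is.null(outDir))
        writeDistanceMatrix(dist, file.path(outDir, "soergel_distance.csv"))

    fullClusters <- stage("cluster_all", selectK(dist))
    if (!is.null(outDir)) {
        writeClusterAssignment(fullClusters,
                               file.path(outDir, "clusters_all.csv"))
        writeLinkageNewick(linkageTree(fullClusters),
                           file.path(outDir, "tree.nwk"))
    }
    sigFlag <- stats::setNames(diff$significant, diff$id)
    clusterEnrich <- stage("cluster_enrichment",
                           fisherClusterEnrichment(fullClusters, sigFlag))
    emit(as.data.frame(clusterEnrich), "cluster_enrichment.csv")

    pathEnrich <- NULL; pathClusterEnrich <- NULL
    if (!is.null(annotation) && length(sig) > 0) {
        pathEnrich <- stage("pathway_enrichment",
                            pathwayEnrichment(annotation, sig,
                                              metaboliteIds(train),
                                              fdr = config$fdrEnrich))
        emit(as.data.frame(pathEnrich), "pathway_enrichment.csv")
        hits <- pathEnrich$unit_id[pathEnrich$significant]
        if (length(hits)) {
            members <- pathwayMembers(annotation)
            rows <- lapply(hits, function(pw) {
                r <- fisherPathwayInCluster(fullClusters, members[[pw]])
                r$pathway <- pw
                r
            })
            pathClusterEnrich <- do.call(rbind, rows)
            emit(as.data.frame(pathClusterEnrich),
                 "pathway_cluster_enrichment.csv")
        }
    }

    sigClusters <- stage("cluster_significant",
                         if (length(sig) >= 1L)
                             clusterSignificant(dist, sig)
                         else NULL)
    if (!is.null(sigClusters) && !is.null(outDir))
        writeClusterAssignment(sigClusters,
                               file.path(outDir, "clusters_significant.csv"))

    suite <- stage("build_model_suite",
                   buildModelSuite(trainPrep$adj, diff, sigClusters,
                                   families = config$families,
                                   grids = config$grids,
                                   seed = config$seed))
    if (!is.null(testPrep))
        suite <- stage("external_validation",
                       lapply(suite, externalValidate, test = testPrep$adj))
    best <- stage("select_best", selectBest(suite))
    summary <- suiteSummary(suite)
    summary$selected <- summary$label == best@label &
        summary$family == best@spec@family
    emit(summary, "summary.csv")

    list(train = trainPrep$adj, test = if (!is.null(testPrep))
             testPrep$adj else NULL,
         trainNormalized = trainPrep$norm, structures = structures,
         differential = diff, distance = dist,
         fullClusters = fullClusters, clusterEnrichment = clusterEnrich,
         pathwayEnrichment = pathEnrich,
         pathwayClusterEnrichment = pathClusterEnrich,
         significantClusters = sigClusters, suite = suite, best = best,
         summary = summary)
}
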