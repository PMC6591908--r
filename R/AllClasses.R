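#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData rowData<- colData<-
NULL

## ordered processing states of an intensity table
.MC_STATES <- c("raw", "imputed", "normalized", "logged",
                "autoscaled", "covariate_adjusted")

.stateIndex <- function(state) match(state, .MC_STATES)

#' MetaboSet: a sample-by-metabolite intensity table with metadata
#'
#' `MetaboSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' processing-state flag and a designated binary trait column.  The single
#' assay `"intensity"` stores metabolites as rows and samples as columns
#' (the usual features-by-samples orientation); `colData` holds the
#' per-sample trait label and any covariates.
#'
#' The state flag enforces the preprocessing order
#' raw -> imputed -> normalized -> logged -> (autoscaled | covariate_adjusted):
#' each stage checks the state of its input and stamps its output.
#'
#' @slot state one of `"raw"`, `"imputed"`, `"normalized"`, `"logged"`,
#'   `"autoscaled"`, `"covariate_adjusted"`.
#' @slot traitColumn name of the `colData` column holding the binary
#'   case/control label.
#'
#' @seealso [readIntensityTable()], [imputeHalfMin()], [autoscale()]
#' @export
setClass("MetaboSet",
         contains = "SummarizedExperiment",
         slots = c(state = "character", traitColumn = "character"))

setValidity("MetaboSet", function(object) {
    msg <- NULL
    if (length(object@state) != 1L || !object@state %in% .MC_STATES)
        msg <- c(msg, sprintf("state must be one of: %s",
                              paste(.MC_STATES, collapse = ", ")))
    if (!"intensity" %in% names(assays(object)))
        msg <- c(msg, "assay 'intensity' is required")
    if (length(object@traitColumn) != 1L ||
        !object@traitColumn %in% colnames(colData(object)))
        msg <- c(msg, sprintf("trait column '%s' not found in colData",
                              object@traitColumn))
    else {
        trait <- colData(object)[[object@traitColumn]]
        if (anyNA(trait))
            msg <- c(msg, "every sample must have a trait label")
        lv <- unique(as.character(trait[!is.na(trait)]))
        ## at most 2 levels; tiny slices (e.g. single-sample tables) may
        ## show only one, and the two-group analyses re-check presence
        if (length(lv) > 2L)
            msg <- c(msg, sprintf(
                "trait label must take at most 2 levels (found %d)",
                length(lv)))
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate metabolite ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (length(msg) == 0L && "intensity" %in% names(assays(object))) {
        v <- assay(object, "intensity")
        if (identical(object@state, "raw")) {
            if (any(v < 0, na.rm = TRUE))
                msg <- c(msg, "raw intensities must be non-negative")
        } else if (anyNA(v)) {
            msg <- c(msg, sprintf(
                "missing values are not allowed in state '%s'", object@state))
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' @importFrom SummarizedExperiment assays
NULL

#' Construct a MetaboSet
#'
#' @param intensity numeric matrix, metabolites as rows, samples as columns;
#'   dimnames required.
#' @param sampleData `data.frame` or `DataFrame` of per-sample metadata,
#'   one row per sample, containing at least the trait column.
#' @param traitColumn name of the binary case/control column in `sampleData`.
#' @param state processing state of `intensity` (default `"raw"`).
#'
#' @return a [MetaboSet] object.
#' @export
MetaboSet <- function(intensity, sampleData, traitColumn = "trait",
                      state = "raw") {
    intensity <- as.matrix(intensity)
    if (is.null(rownames(intensity)) || is.null(colnames(intensity)))
        stop("intensity matrix must have metabolite row names and sample ",
             "column names")
    se <- SummarizedExperiment(
        assays  = list(intensity = intensity),
        colData = DataFrame(sampleData, row.names = colnames(intensity)))
    new("MetaboSet", se, state = state, traitColumn = traitColumn)
}

#' StructureSet: metabolite structures with MACCS fingerprints
#'
#' Holds the parsed (canonicalized) SMILES and the 166-key MACCS
#' fingerprint of each metabolite, plus a rejects table for entries whose
#' SMILES could not be parsed.
#'
#' @slot ids metabolite identifiers (unique).
#' @slot smiles input SMILES, parallel to `ids`.
#' @slot canonical canonical SMILES produced by the chemistry backend.
#' @slot fingerprints integer 0/1 matrix, one row per metabolite, 166
#'   columns (MACCS keys 1..166).
#' @slot rejects data.frame (id, smiles, reason) of unparseable entries.
#' @export
setClass("StructureSet",
         slots = c(ids = "character", smiles = "character",
                   canonical = "character", fingerprints = "matrix",
                   rejects = "data.frame"))

setValidity("StructureSet", function(object) {
    msg <- NULL
    n <- length(object@ids)
    if (anyDuplicated(object@ids))
        msg <- c(msg, "metabolite ids must be unique")
    if (length(object@smiles) != n || length(object@canonical) != n)
        msg <- c(msg, "smiles/canonical must be parallel to ids")
    if (nrow(object@fingerprints) != n)
        msg <- c(msg, "one fingerprint row per metabolite required")
    if (n > 0L && !all(object@fingerprints %in% c(0L, 1L)))
        msg <- c(msg, "fingerprints must be binary")
    if (is.null(msg)) TRUE else msg
})

#' FingerprintMatrix: binary substructure-key matrix
#'
#' A metabolites-by-keys 0/1 matrix.  `keyIndices` records the original
#' MACCS key numbers of the retained columns, so a filtered matrix (after
#' [filterCorrelatedBits()]) stays traceable to the 166-key dictionary.
#'
#' @slot ids metabolite identifiers.
#' @slot bits integer 0/1 matrix (metabolites x retained keys).
#' @slot keyIndices strictly increasing original key numbers of columns.
#' @export
setClass("FingerprintMatrix",
         slots = c(ids = "character", bits = "matrix",
                   keyIndices = "integer"))

setValidity("FingerprintMatrix", function(object) {
    msg <- NULL
    if (nrow(object@bits) != length(object@ids))
        msg <- c(msg, "bits must have one row per id")
    if (ncol(object@bits) != length(object@keyIndices))
        msg <- c(msg, "keyIndices must correspond 1:1 to bit columns")
    if (length(object@keyIndices) > 1L && any(diff(object@keyIndices) <= 0L))
        msg <- c(msg, "keyIndices must be strictly increasing")
    if (length(object@bits) > 0L && !all(object@bits %in% c(0L, 1L)))
        msg <- c(msg, "bits must be binary")
    if (is.null(msg)) TRUE else msg
})

#' DistanceMatrix: symmetric metabolite dissimilarities
#'
#' @slot ids metabolite identifiers, ordering the rows/columns of `d`.
#' @slot d symmetric numeric matrix with zero diagonal.
#' @slot metric name of the dissimilarity (`"soergel"` or
#'   `"spearman_correlation"`).
#' @export
setClass("DistanceMatrix",
         slots = c(ids = "character", d = "matrix", metric = "character"))

setValidity("DistanceMatrix", function(object) {
    msg <- NULL
    n <- length(object@ids)
    if (!all(dim(object@d) == c(n, n)))
        msg <- c(msg, "d must be |ids| x |ids|")
    else {
        if (max(abs(object@d - t(object@d))) > 1e-12)
            msg <- c(msg, "d must be symmetric within 1e-12")
        if (any(abs(diag(object@d)) > 1e-12))
            msg <- c(msg, "diagonal of d must be zero")
        if (any(object@d < -1e-12))
            msg <- c(msg, "distances must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
})

#' PathwayAnnotation: pathway membership sets
#'
#' @slot pathwayIds pathway identifiers (unique).
#' @slot descriptions human-readable pathway names, parallel to ids.
#' @slot members list of non-empty character vectors of metabolite ids;
#'   membership is case-exact on the id.
#' @export
setClass("PathwayAnnotation",
         slots = c(pathwayIds = "character", descriptions = "character",
                   members = "list"))

setValidity("PathwayAnnotation", function(object) {
    msg <- NULL
    n <- length(object@pathwayIds)
    if (anyDuplicated(object@pathwayIds))
        msg <- c(msg, "pathway ids must be unique")
    if (length(object@members) != n || length(object@descriptions) != n)
        msg <- c(msg, "descriptions/members must be parallel to pathwayIds")
    if (any(lengths(object@members) == 0L))
        msg <- c(msg, "pathway member sets must be non-empty")
    if (is.null(msg)) TRUE else msg
})

#' DifferentialResult: per-metabolite permutation-test results
#'
#' A `DFrame` with one row per metabolite and columns `id`, `mean_log_fc`
#' (difference of group means, case minus control, log2 scale),
#' `fold_change` (back-transformed, for display), `p_value` (Monte Carlo
#' permutation p), `q_value` (Benjamini-Hochberg) and `significant`
#' (at the configured FDR).  `metadata()` records `fdr`,
#' `n_permutations` and `seed`.
#' @export
setClass("DifferentialResult", contains = "DFrame")

setValidity("DifferentialResult", function(object) {
    need <- c("id", "mean_log_fc", "p_value", "q_value", "significant")
    if (!all(need %in% colnames(object)))
        return(sprintf("missing columns: %s",
                       paste(setdiff(need, colnames(object)), collapse = ", ")))
    if (nrow(object) > 0L) {
        if (any(object$p_value <= 0 | object$p_value > 1))
            return("p_value must lie in (0, 1]")
        if (any(object$q_value + 1e-15 < object$p_value))
            return("q_value must be >= p_value")
    }
    TRUE
})

#' ClusterAssignment: a flat clustering with its silhouette profile
#'
#' @slot ids metabolite identifiers.
#' @slot labels integer cluster label per id (numbered by first appearance
#'   in id order).
#' @slot k number of clusters.
#' @slot asw average silhouette width of the assignment.
#' @slot silhouettes per-id silhouette values s(i); singletons score 0.
#' @slot tree the `hclust`-style average-linkage merge history the
#'   assignment was cut from (may be NULL for degenerate assignments).
#' @export
setClass("ClusterAssignment",
         slots = c(ids = "character", labels = "integer", k = "integer",
                   asw = "numeric", silhouettes = "numeric", tree = "ANY"))

setValidity("ClusterAssignment", function(object) {
    msg <- NULL
    n <- length(object@ids)
    if (length(object@labels) != n)
        msg <- c(msg, "one label per id required")
    if (length(unique(object@labels)) != object@k)
        msg <- c(msg, "labels must take exactly k distinct values")
    if (length(object@silhouettes) == n && n > 0L &&
        is.finite(object@asw) &&
        abs(object@asw - mean(object@silhouettes)) > 1e-12)
        msg <- c(msg, "asw must equal the mean silhouette within 1e-12")
    if (is.null(msg)) TRUE else msg
})

.MC_FAMILIES <- c("logistic", "svm", "plsda", "random_forest",
                  "gradient_boosted_trees")

#' ClassifierSpec: what to fit and how to tune it
#'
#' @slot metabolites metabolite ids the model may use.
#' @slot family one of `"logistic"`, `"svm"`, `"plsda"`,
#'   `"random_forest"`, `"gradient_boosted_trees"`.  Logistic models are
#'   reserved for single-metabolite classifiers.
#' @slot grid named list of hyperparameter value vectors; crossed with
#'   `expand.grid` during the grid search.
#' @slot seed integer seed controlling any stochastic fitting.
#' @export
setClass("ClassifierSpec",
         slots = c(metabolites = "character", family = "character",
                   grid = "list", seed = "integer"))

setValidity("ClassifierSpec", function(object) {
    msg <- NULL
    if (!object@family %in% .MC_FAMILIES)
        msg <- c(msg, sprintf("family must be one of: %s",
                              paste(.MC_FAMILIES, collapse = ", ")))
    if (identical(object@family, "logistic") &&
        length(object@metabolites) != 1L)
        msg <- c(msg, "logistic family is restricted to single-metabolite models")
    if (length(object@metabolites) == 0L)
        msg <- c(msg, "metabolite set must be non-empty")
    if (is.null(msg)) TRUE else msg
})

#' ClassifierReport: a tuned classifier and its performance
#'
#' @slot spec the [ClassifierSpec] the report was built from.
#' @slot label short description of the metabolite set
#'   (`"single:<id>"`, `"cluster:<j>"`, `"all_metabolites"`,
#'   `"significant"`).
#' @slot hyperparameters the grid point selected by LOOCV accuracy.
#' @slot threshold probability cutoff selected from internal (LOOCV)
#'   predictions only.
#' @slot internal named numeric: LOOCV accuracy, sensitivity, specificity,
#'   auc.
#' @slot external same metrics on a held-out cohort, or length-0 if not
#'   validated externally.
#' @slot model the final model fitted on all training samples.
#' @export
setClass("ClassifierReport",
         slots = c(spec = "ClassifierSpec", label = "character",
                   hyperparameters = "list", threshold = "numeric",
                   internal = "numeric", external = "numeric",
                   model = "ANY"))

setValidity("ClassifierReport", function(object) {
    msg <- NULL
    need <- c("accuracy", "sensitivity", "specificity", "auc")
    if (!all(need %in% names(object@internal)))
        msg <- c(msg, "internal metrics must include accuracy, sensitivity, specificity, auc")
    ok <- function(v) all(v >= -1e-12 & v <= 1 + 1e-12)
    if (length(object@internal) && !ok(object@internal))
        msg <- c(msg, "internal metrics must lie in [0, 1]")
    if (length(object@external) && !ok(object@external))
        msg <- c(msg, "external metrics must lie in [0, 1]")
    if (length(object@threshold) == 1L &&
        (object@threshold <= 0 || object@threshold >= 1))
        msg <- c(msg, "threshold must lie in (0, 1)")
    if (is.null(msg)) TRUE else msg
})
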