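#' @include classify.R
NULL

#' Case-probabilities of a finalized classifier on a table
#'
#' @param report a finalized [ClassifierReport].
#' @param x a [MetaboSet] in state `"covariate_adjusted"` containing the
#'   model's metabolites.
#' @return named numeric vector of predicted case-probabilities.
#' @export
predictProbabilities <- function(report, x) {
    stopifnot(is(report, "ClassifierReport"), is(x, "MetaboSet"))
    .requireState(x, "covariate_adjusted", "predictProbabilities")
    if (is.null(report@model))
        stop("report has no final model; run finalizeReport() first")
    X <- .designFor(x, report@spec@metabolites)
    stats::setNames(.predictModel(report@model, X), rownames(X))
}
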