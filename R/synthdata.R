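#' @include io.R
NULL

## session cache for the parsed structure library (one OpenBabel pass)
.mcCache <- new.env(parent = emptyenv())

#' The bundled metabolite structure library
#'
#' Forty named metabolites with real SMILES across seven chemical
#' families (amino acids, mono- and di-saccharides, organic acids, purine
#' and pyrimidine nucleosides, fatty acids), grouped finely enough that a
#' family is tight under fingerprint dissimilarity; used by the synthetic
#' cohort generator so that the
#' cheminformatics stages are exercised on real chemistry without network
#' access.
#'
#' @return `data.frame` with columns `id`, `family`, `smiles`.
#' @export
structureLibrary <- function() {
    path <- system.file("extdata", "metabolite_library.tsv",
                        package = "metaboclust", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}

## parsed + fingerprinted library, cached per session
.libraryStructures <- function() {
    if (is.null(.mcCache$structures)) {
        lib <- structureLibrary()
        smi <- stats::setNames(lib$smiles, paste(lib$family, lib$id,
                                                 sep = "."))
        .mcCache$structures <- structuresFromSmiles(smi)
        .mcCache$families <- stats::setNames(lib$family,
                                             names(smi))
    }
    .mcCache$structures
}

.libraryFamilies <- function() {
    .libraryStructures()
    .mcCache$families
}

#' Configuration of the synthetic cohort-pair generator
#'
#' The defaults define the simulated study conditions: two cohorts
#' ("training" and "test") of 40 cases and 40 controls each over the full
#' 40-metabolite structure library; trait signal planted in two chemically
#' tight families (5 fatty acids shifted up, 4 disaccharides shifted down,
#' each by 2 within-group SDs); gender and smoking covariate effects on a
#' random 30% of metabolites; 5% left-censored non-detects; and a
#' log-normal multiplicative batch shift (2^N(0, 0.5) per metabolite)
#' applied to the test cohort.
#'
#' @param nCase,nControl samples per class in each cohort.
#' @param familyCounts named integer vector: metabolites drawn per
#'   structure family (`NULL` = entire library).
#' @param signalSpec `data.frame` with columns `family`, `n` (signal
#'   metabolites drawn from that family), `effect` (mean shift in units of
#'   the metabolite's SD) and `direction` (+1/-1).
#' @param missingRate expected fraction of non-detects per metabolite
#'   column (in `[0, 1)`).
#' @param batchShift per-metabolite multiplicative bias applied to the
#'   raw test-cohort intensities; `NULL` draws `2^N(0, batchShiftSd)`
#'   from the seed.
#' @param batchShiftSd SD (log2 scale) of the drawn batch shift.
#' @param covariateEffects named numeric: per-covariate coefficient
#'   magnitude (log2 units) applied to a random `covariateFraction` of
#'   metabolites.
#' @param covariateFraction fraction of metabolites affected by each
#'   covariate.
#' @param seed master seed; all randomness flows from it.
#' @return a validated `simulation_config` list.
#' @export
simulationConfig <- function(nCase = 40L, nControl = 40L,
                             familyCounts = NULL,
                             signalSpec = data.frame(
                                 family = c("fatty_acid", "disaccharide"),
                                 n = c(5L, 4L),
                                 effect = c(2, 2),
                                 direction = c(1, -1)),
                             missingRate = 0.05,
                             batchShift = NULL, batchShiftSd = 0.5,
                             covariateEffects = c(gender = 0.5,
                                                  smoking = 0.5),
                             covariateFraction = 0.3,
                             seed = 1L) {
    lib <- structureLibrary()
    if (is.null(familyCounts)) {
        familyCounts <- table(lib$family)
        familyCounts <- stats::setNames(as.integer(familyCounts),
                                        names(familyCounts))
    }
    avail <- table(lib$family)
    for (f in names(familyCounts)) {
        if (!f %in% names(avail))
            stop("unknown structure family: ", f)
        if (familyCounts[[f]] > avail[[f]])
            stop("family '", f, "' has only ", avail[[f]],
                 " structures (requested ", familyCounts[[f]], ")")
    }
    if (missingRate < 0 || missingRate >= 1)
        stop("missingRate must lie in [0, 1)")
    if (nrow(signalSpec) > 0) {
        stopifnot(all(c("family", "n", "effect", "direction") %in%
                      colnames(signalSpec)))
        if (!all(signalSpec$family %in% names(familyCounts)))
            stop("signalSpec references families outside familyCounts")
        if (!all(is.finite(signalSpec$effect)))
            stop("effect sizes must be finite")
        bad <- signalSpec$n >
            familyCounts[as.character(signalSpec$family)]
        if (any(bad))
            stop("signalSpec requests more signal metabolites than drawn")
    }
    structure(list(nCase = as.integer(nCase),
                   nControl = as.integer(nControl),
                   familyCounts = familyCounts, signalSpec = signalSpec,
                   missingRate = missingRate, batchShift = batchShift,
                   batchShiftSd = batchShiftSd,
                   covariateEffects = covariateEffects,
                   covariateFraction = covariateFraction,
                   seed = as.integer(seed)),
              class = "simulation_config")
}

#' Draw structures per family from the bundled library
#'
#' Samples `familyCounts[f]` structures from each family without
#' replacement (deterministically from the config seed).  Ids encode the
#' family (`<family>.<name>`) so downstream clusterings can be scored
#' against ground truth.
#'
#' @param config a [simulationConfig()].
#' @return a [StructureSet].
#' @export
sampleStructures <- function(config) {
    stopifnot(inherits(config, "simulation_config"))
    all <- .libraryStructures()
    fam <- .libraryFamilies()
    ids <- .withSeed(.childSeeds(config$seed, 1L)[1L], {
        unlist(lapply(names(config$familyCounts), function(f) {
            pool <- names(fam)[fam == f]
            sort(sample(pool, config$familyCounts[[f]]))
        }), use.names = FALSE)
    })
    all[ids]
}

## draw one cohort's log2-intensity matrix given shared parameters
.drawCohort <- function(par, nCase, nControl, covEffects) {
    m <- length(par$ids)
    n <- nCase + nControl
    status <- rep(c("control", "case"), c(nControl, nCase))
    gender <- sample(c("F", "M"), n, replace = TRUE)
    smoking <- sample(c("never", "ever"), n, replace = TRUE,
                      prob = c(0.6, 0.4))
    z <- matrix(stats::rnorm(m * n), m, n)
    L <- par$mu + par$sigma * z
    isCase <- status == "case"
    L[, isCase] <- L[, isCase] +
        par$effect * par$sigma * par$direction
    cov <- list(gender = as.numeric(gender == "M"),
                smoking = as.numeric(smoking == "ever"))
    for (cv in names(covEffects))
        L <- L + outer(covEffects[[cv]], cov[[cv]])
    list(log2 = L,
         meta = data.frame(trait = status, gender = gender,
                           smoking = smoking, stringsAsFactors = FALSE))
}

## left-censored non-detects: a Binomial(n, rate) count of the lowest
## values per metabolite column is deleted
.censorLow <- function(v, rate) {
    if (rate <= 0) return(v)
    n <- ncol(v)
    for (i in seq_len(nrow(v))) {
        k <- stats::rbinom(1L, n, rate)
        while (k >= n) {
            warning("metabolite ", rownames(v)[i],
                    ": all values censored; redrawing missingness")
            k <- stats::rbinom(1L, n, rate)
        }
        if (k > 0L) v[i, order(v[i, ])[seq_len(k)]] <- NA_real_
    }
    v
}

#' Simulate a train/test cohort pair with planted chemical-family signal
#'
#' Generates two case/control cohorts sharing metabolite parameters:
#' log2 intensities are normal with metabolite-specific baselines
#' (Unif(10, 20)) and SDs (log-uniform on [0.3, 1]); signal metabolites
#' receive a case-mean shift of `effect` SDs in the planted direction;
#' covariate effects (gender, smoking) are added; values are
#' exponentiated to the raw scale; the test cohort is multiplied by a
#' per-metabolite batch shift; and non-detects are introduced by deleting
#' a Binomial(n, missingRate) count of each metabolite's lowest values
#' (left-censoring).
#'
#' @param config a [simulationConfig()].
#' @return list with `train` and `test` (raw [MetaboSet]s), `structures`
#'   (the [StructureSet] drawn), and `truth` (`data.frame` of id, family,
#'   signal flag, effect, direction).
#' @export
simulateCohortPair <- function(config) {
    stopifnot(inherits(config, "simulation_config"))
    structures <- sampleStructures(config)
    ids <- structureIds(structures)
    fam <- .libraryFamilies()[ids]
    m <- length(ids)
    seeds <- .childSeeds(config$seed, 5L)
    par <- .withSeed(seeds[2L], {
        mu <- stats::runif(m, 10, 20)
        sigma <- exp(stats::runif(m, log(0.3), log(1)))
        effect <- numeric(m); direction <- numeric(m)
        sp <- config$signalSpec
        for (r in seq_len(nrow(sp))) {
            pool <- which(fam == sp$family[r])
            pick <- sample(pool, sp$n[r])
            effect[pick] <- sp$effect[r]
            direction[pick] <- sp$direction[r]
        }
        covEffects <- lapply(config$covariateEffects, function(beta) {
            hit <- stats::runif(m) < config$covariateFraction
            beta * hit
        })
        names(covEffects) <- names(config$covariateEffects)
        shift <- config$batchShift
        if (is.null(shift))
            shift <- 2^stats::rnorm(m, 0, config$batchShiftSd)
        list(ids = ids, mu = mu, sigma = sigma, effect = effect,
             direction = direction, covEffects = covEffects,
             batchShift = shift)
    })
    mkTable <- function(seed, prefix, applyShift) {
        .withSeed(seed, {
            coh <- .drawCohort(par, config$nCase, config$nControl,
                               par$covEffects)
            raw <- 2^coh$log2
            if (applyShift) raw <- raw * par$batchShift
            raw <- .censorLow(raw, config$missingRate)
            dimnames(raw) <- list(ids, paste0(prefix,
                                              seq_len(ncol(raw))))
            rownames(coh$meta) <- colnames(raw)
            MetaboSet(raw, coh$meta, traitColumn = "trait", state = "raw")
        })
    }
    train <- mkTable(seeds[3L], "tr_s", applyShift = FALSE)
    test <- mkTable(seeds[4L], "te_s", applyShift = TRUE)
    truth <- data.frame(id = ids, family = unname(fam),
                        signal = par$effect != 0,
                        effect = par$effect, direction = par$direction,
                        stringsAsFactors = FALSE)
    list(train = train, test = test, structures = structures,
         truth = truth)
}
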