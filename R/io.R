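#' @include methods-accessors.R
NULL

#' Read a sample-by-metabolite intensity table
#'
#' Parses a CSV/TSV file with one row per sample: the first column holds the
#' sample identifier, `metaColumns` name the per-sample metadata columns
#' (trait label and covariates), and every remaining column is a metabolite.
#' Empty cells and the `missingToken` are read as missing (non-detects);
#' zeros are detected values, not missing.
#'
#' @param path file to read.
#' @param metaColumns character vector of metadata column names present in
#'   the file; must include the trait column.
#' @param traitColumn name of the binary case/control column
#'   (default: first element of `metaColumns`).
#' @param sep field separator; inferred from the extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @param missingToken string representing a non-detect (default `"NA"`);
#'   empty cells are always treated as missing.
#' @param transpose set `TRUE` for the transposed dialect: rows are
#'   metabolites (first column the metabolite id, remaining columns
#'   samples), with metadata rows identified by `metaColumns`.
#'
#' @return a [MetaboSet], metabolite order as in the file; the state is
#'   `"raw"` unless the file carries the state comment written by
#'   [writeIntensityTable()].
#' @export
readIntensityTable <- function(path, metaColumns, traitColumn = metaColumns[1],
                               sep = NULL, missingToken = "NA",
                               transpose = FALSE) {
    sep <- .sepFor(path, sep)
    ## tables written by writeIntensityTable() carry their processing
    ## state in a leading comment line
    state <- "raw"
    first <- readLines(path, n = 1L, warn = FALSE)
    skip <- 0L
    if (grepl("^# metaboclust-state:", first)) {
        state <- .trim(sub("^# metaboclust-state:", "", first))
        skip <- 1L
    }
    raw <- utils::read.table(path, header = TRUE, sep = sep, skip = skip,
                             colClasses = "character", check.names = FALSE,
                             comment.char = "", quote = "\"",
                             stringsAsFactors = FALSE)
    if (nrow(raw) == 0L) stop("empty intensity table: ", path)
    if (transpose) {
        ids <- .trim(raw[[1L]])
        samples <- .trim(colnames(raw)[-1L])
        body <- as.matrix(raw[, -1L, drop = FALSE])
        metaRows <- ids %in% metaColumns
        meta <- t(body[metaRows, , drop = FALSE])
        colnames(meta) <- ids[metaRows]
        metaDf <- as.data.frame(meta, stringsAsFactors = FALSE)
        metIds <- ids[!metaRows]
        valueChr <- t(body[!metaRows, , drop = FALSE])
        colnames(valueChr) <- metIds
        rownames(valueChr) <- samples
    } else {
        samples <- .trim(raw[[1L]])
        cols <- .trim(colnames(raw)[-1L])
        missingMeta <- setdiff(metaColumns, cols)
        if (length(missingMeta))
            stop("metadata columns not found: ",
                 paste(missingMeta, collapse = ", "))
        if (anyDuplicated(cols))
            stop("duplicate metabolite id: ",
                 paste(unique(cols[duplicated(cols)]), collapse = ", "))
        body <- raw[, -1L, drop = FALSE]
        colnames(body) <- cols
        metaDf <- as.data.frame(body[, metaColumns, drop = FALSE],
                                stringsAsFactors = FALSE)
        metIds <- setdiff(cols, metaColumns)
        valueChr <- as.matrix(body[, metIds, drop = FALSE])
        rownames(valueChr) <- samples
    }
    if (anyDuplicated(samples))
        stop("duplicate sample id: ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    if (anyDuplicated(metIds))
        stop("duplicate metabolite id: ",
             paste(unique(metIds[duplicated(metIds)]), collapse = ", "))
    values <- matrix(NA_real_, nrow(valueChr), ncol(valueChr),
                     dimnames = dimnames(valueChr))
    for (j in seq_len(ncol(valueChr))) {
        cell <- .trim(valueChr[, j])
        miss <- is.na(cell) | cell == "" | cell == missingToken
        num <- suppressWarnings(as.numeric(cell))
        bad <- !miss & is.na(num)
        if (any(bad))
            stop(sprintf(
                "non-numeric abundance '%s' at sample '%s', metabolite '%s'",
                cell[which(bad)[1L]], rownames(valueChr)[which(bad)[1L]],
                colnames(valueChr)[j]))
        num[miss] <- NA_real_
        values[, j] <- num
    }
    ## covariates: numeric where fully numeric, character otherwise
    for (nm in names(metaDf)) {
        v <- .trim(metaDf[[nm]])
        num <- suppressWarnings(as.numeric(v))
        metaDf[[nm]] <- if (!anyNA(num) && nm != traitColumn) num else v
    }
    rownames(metaDf) <- samples
    MetaboSet(t(values), metaDf, traitColumn = traitColumn, state = state)
}

#' Write an intensity table as CSV
#'
#' Emits one row per sample with a header: sample id, metadata columns,
#' then metabolites in table order.  Missing values are written as empty
#' cells.  Numbers are serialized at full double precision so a
#' write/read round trip is value-identical.
#'
#' @param x a [MetaboSet].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeIntensityTable <- function(x, path) {
    stopifnot(is(x, "MetaboSet"))
    v <- t(intensities(x))                       # samples x metabolites
    meta <- as.data.frame(colData(x))
    df <- data.frame(sample_id = rownames(v), stringsAsFactors = FALSE,
                     check.names = FALSE)
    for (nm in colnames(meta)) df[[nm]] <- as.character(meta[[nm]])
    for (j in colnames(v)) df[[j]] <- .fmtNum(v[, j])
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# metaboclust-state: ", processingState(x)), con)
    writeLines(paste(colnames(df), collapse = ","), con)
    writeLines(do.call(paste, c(unname(as.list(df)), sep = ",")), con)
    invisible(path)
}

## Parse one structure with the OpenBabel backend; NULL + reason on failure.
.parseStructure <- function(text, format = "SMILES") {
    fp <- tryCatch(
        suppressWarnings(ChemmineOB::forEachMol(format, text, function(mol)
            ChemmineOB::fingerprint_OB(list(mol), "MACCS"))),
        error = function(e) conditionMessage(e))
    if (!is.list(fp) || length(fp) != 1L || !is.numeric(fp[[1L]]))
        return(list(ok = FALSE, reason = if (is.character(fp)) fp
                    else "structure could not be parsed"))
    fpv <- fp[[1L]]
    if (is.matrix(fpv)) fpv <- fpv[1L, ]
    bits <- as.integer(fpv[seq_len(166L)])
    can <- tryCatch(
        suppressWarnings(.trim(strsplit(
            ChemmineOB::convertFormat(format, "CAN", text),
            "[\t\n]")[[1L]][1L])),
        error = function(e) NA_character_)
    if (is.na(can) || !nzchar(can))
        return(list(ok = FALSE, reason = "canonicalization failed"))
    list(ok = TRUE, canonical = can, bits = bits)
}

#' Read metabolite structures and fingerprint them
#'
#' Accepts a two-column TSV (`metabolite_id`, SMILES; a header line is
#' detected and skipped) or an SDF file (ids taken from the
#' `metabolite_id` data field when present, else the molecule title).
#' Each structure is canonicalized and characterized by its 166-key MACCS
#' fingerprint.  Entries whose structure cannot be parsed are collected in
#' the rejects table rather than aborting the read.
#'
#' @param path structure file (.tsv/.smi/.txt or .sdf).
#' @param format `"auto"` (by extension), `"tsv"` or `"sdf"`.
#' @return a [StructureSet]; see [rejects()] for unparseable entries.
#' @export
readStructures <- function(path, format = c("auto", "tsv", "sdf")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf"
                  else "tsv"
    if (format == "tsv") {
        lines <- readLines(path, warn = FALSE)
        lines <- lines[nzchar(.trim(lines))]
        if (length(lines) == 0L) stop("no structures in file: ", path)
        parts <- strsplit(lines, "\t")
        bad <- lengths(parts) < 2L
        if (any(bad))
            stop("malformed structure line (need id<TAB>SMILES): ",
                 lines[which(bad)[1L]])
        ids <- .trim(vapply(parts, `[[`, "", 1L))
        smi <- .trim(vapply(parts, `[[`, "", 2L))
        ## drop a header line if present
        if (length(ids) && grepl("^(metabolite_)?id$|^name$", ids[1L],
                                 ignore.case = TRUE)) {
            ids <- ids[-1L]; smi <- smi[-1L]
        }
        if (length(ids) == 0L) stop("no structures in file: ", path)
        entries <- lapply(smi, function(s)
            list(text = paste0(s, "\n"), format = "SMILES"))
    } else {
        txt <- readLines(path, warn = FALSE)
        recEnd <- grep("^\\$\\$\\$\\$\\s*$", txt)
        if (length(recEnd) == 0L) stop("no SDF records in file: ", path)
        recStart <- c(1L, utils::head(recEnd, -1L) + 1L)
        ids <- character(0); smi <- character(0); entries <- list()
        for (r in seq_along(recEnd)) {
            rec <- txt[recStart[r]:recEnd[r]]
            if (all(!nzchar(.trim(rec)))) next
            idLine <- grep("^>.*<metabolite_id>", rec)
            id <- if (length(idLine)) .trim(rec[idLine[1L] + 1L])
                  else .trim(rec[1L])
            ids <- c(ids, id)
            smi <- c(smi, NA_character_)
            entries <- c(entries, list(list(
                text = paste(c(rec, ""), collapse = "\n"), format = "SDF")))
        }
    }
    if (anyDuplicated(ids))
        stop("duplicate metabolite id in structure file: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    okIds <- character(0); okSmi <- character(0); okCan <- character(0)
    fps <- list()
    rej <- data.frame(id = character(0), smiles = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
    for (i in seq_along(ids)) {
        p <- .parseStructure(entries[[i]]$text, entries[[i]]$format)
        if (p$ok) {
            okIds <- c(okIds, ids[i])
            okSmi <- c(okSmi, if (is.na(smi[i])) p$canonical else smi[i])
            okCan <- c(okCan, p$canonical)
            fps[[length(fps) + 1L]] <- p$bits
        } else {
            rej <- rbind(rej, data.frame(
                id = ids[i], smiles = if (is.na(smi[i])) "" else smi[i],
                reason = p$reason, stringsAsFactors = FALSE))
        }
    }
    if (length(okIds) == 0L)
        stop("no parseable structures in file: ", path)
    fpm <- do.call(rbind, fps)
    rownames(fpm) <- okIds
    colnames(fpm) <- paste0("key", seq_len(166L))
    new("StructureSet", ids = okIds, smiles = okSmi, canonical = okCan,
        fingerprints = fpm, rejects = rej)
}

#' Build a StructureSet from in-memory SMILES
#'
#' Programmatic twin of [readStructures()]: takes a named character vector
#' of SMILES (names are metabolite ids) and returns a fingerprinted
#' [StructureSet] with unparseable entries in the rejects table.
#'
#' @param smiles named character vector of SMILES strings.
#' @return a [StructureSet].
#' @export
structuresFromSmiles <- function(smiles) {
    if (is.null(names(smiles)) || any(!nzchar(names(smiles))))
        stop("smiles must be a named vector (names are metabolite ids)")
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp))
    writeLines(paste(.trim(names(smiles)), .trim(smiles), sep = "\t"), tmp)
    readStructures(tmp, format = "tsv")
}

#' Read a pathway annotation file
#'
#' GMT-like format, one pathway per line:
#' `pathway_id <TAB> description <TAB> member_id [<TAB> member_id ...]`.
#'
#' @param path annotation file.
#' @return a [PathwayAnnotation].
#' @export
readPathways <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(.trim(lines))]
    if (length(lines) == 0L) stop("empty pathway file: ", path)
    parts <- strsplit(lines, "\t")
    if (any(lengths(parts) < 3L))
        stop("malformed pathway line (need id, description, >=1 member): ",
             lines[which(lengths(parts) < 3L)[1L]])
    ids <- .trim(vapply(parts, `[[`, "", 1L))
    desc <- .trim(vapply(parts, `[[`, "", 2L))
    members <- lapply(parts, function(p) unique(.trim(p[-c(1L, 2L)])))
    new("PathwayAnnotation", pathwayIds = ids, descriptions = desc,
        members = members)
}

#' Retain metabolites with structures that are detected everywhere
#'
#' Applies the panel-retention rule: keep exactly the metabolites that
#' (1) have a parsed chemical structure and (2) are detected (non-missing
#' in at least one sample) in `x` and in every companion table.  Order is
#' preserved.  Idempotent, and invariant to the order of the companions.
#'
#' @param x a raw [MetaboSet].
#' @param structures a [StructureSet].
#' @param companions list of raw [MetaboSet] companion tables (e.g. the
#'   other cohort) that must also detect each retained metabolite.
#' @return `x` restricted to the retained metabolites (state `"raw"`).
#' @export
alignDataset <- function(x, structures, companions = list()) {
    stopifnot(is(x, "MetaboSet"), is(structures, "StructureSet"))
    if (x@state != "raw") stop("alignDataset expects a raw table")
    for (cp in companions) {
        stopifnot(is(cp, "MetaboSet"))
        if (cp@state != "raw") stop("companion tables must be raw")
    }
    detected <- function(tab, ids)
        ids %in% metaboliteIds(tab)[rowSums(!is.na(intensities(tab))) > 0L]
    keep <- metaboliteIds(x)
    keep <- keep[keep %in% structureIds(structures)]
    keep <- keep[detected(x, keep)]
    for (cp in companions) keep <- keep[detected(cp, keep)]
    if (length(keep) == 0L)
        stop("no metabolite has a structure and is detected in every table")
    x[keep, ]
}

#' Write / read a square distance matrix as CSV
#'
#' @param d a [DistanceMatrix].
#' @param path CSV path; id header row and id first column.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
    stopifnot(is(d, "DistanceMatrix"))
    m <- as.matrix(d)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("id", colnames(m)), collapse = ","), con)
    writeLines(vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], .fmtNum(m[i, ])), collapse = ","),
        character(1)), con)
    invisible(path)
}

#' @rdname writeDistanceMatrix
#' @param metric metric name to stamp on the object read back.
#' @export
readDistanceMatrix <- function(path, metric = "soergel") {
    raw <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    ids <- .trim(as.character(raw[[1L]]))
    m <- as.matrix(raw[, -1L, drop = FALSE])
    m <- matrix(as.numeric(m), nrow(m), dimnames = list(ids, colnames(m)))
    ## symmetrize away formatting round-off
    m <- (m + t(m)) / 2
    new("DistanceMatrix", ids = ids, d = m, metric = metric)
}

#' Write a cluster assignment as CSV (id, cluster, silhouette)
#'
#' @param x a [ClusterAssignment].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeClusterAssignment <- function(x, path) {
    stopifnot(is(x, "ClusterAssignment"))
    utils::write.csv(data.frame(id = x@ids, cluster = x@labels,
                                silhouette = x@silhouettes),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write differential-analysis results as CSV
#'
#' @param x a [DifferentialResult].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeDifferentialResult <- function(x, path) {
    stopifnot(is(x, "DifferentialResult"))
    utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
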