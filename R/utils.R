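## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = .GlobalEnv)
        else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
            rm(".Random.seed", envir = .GlobalEnv)
    })
    set.seed(as.integer(seed))
    expr
}

## Derive a stream of child seeds from one master seed, staying < 2^31.
.childSeeds <- function(seed, n) {
    (as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483629
}

## Format numbers for CSV so that read -> write -> read is value-identical.
.fmtNum <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- ""
    out
}

.trim <- function(x) gsub("^\\s+|\\s+$", "", x)

## Infer a field separator from a file extension.
.sepFor <- function(path, sep = NULL) {
    if (!is.null(sep)) return(sep)
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}
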