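# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed)
        old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_seed)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Derive a stream of child seeds from one parent seed, staying in 32-bit
# integer range.
deriveSeeds <- function(seed, n) {
    withSeed(seed, sample.int(.Machine$integer.max, n))
}

# Add-one (Phipson-Smyth) permutation p-value estimator.
permPvalue <- function(n_as_extreme, n_perm) {
    (1 + n_as_extreme) / (1 + n_perm)
}

# Stop with a classed error (so callers/tests can condition on the class).
mtStop <- function(class, msg, call. = FALSE) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = if (call.) sys.call(-1))))
}

# Write a data.frame as TSV with stable column order.
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

readTsv <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "")
}

#' Read and write a TraitTable as TSV
#'
#' The on-disk format is a TSV matrix with a leading \code{genome_id}
#' column and one integer column per trait.
#'
#' @param x a [TraitTable-class].
#' @param path file path.
#' @return `writeTraitTable` returns `path` invisibly; `readTraitTable`
#'   returns a [TraitTable-class].
#' @export
writeTraitTable <- function(x, path) {
    stopifnot(is(x, "TraitTable"))
    df <- data.frame(genome_id = genomeIds(x), counts(x),
                     check.names = FALSE)
    writeTsv(df, path)
}

#' @rdname writeTraitTable
#' @export
readTraitTable <- function(path) {
    df <- readTsv(path)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    TraitTable(m)
}
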