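## Seed discipline helpers.

## Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Derive a child seed from a master seed and an index
#'
#' Counter-based scheme so that enlarging an ensemble never perturbs the
#' seeds (hence results) of earlier members. Stays below 2^31.
#'
#' @param master integer master seed.
#' @param index nonnegative integer counter (e.g. injury index).
#' @return an integer seed.
#' @export
childSeed <- function(master, index) {
    as.integer((as.numeric(master) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

.writeJSON <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
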