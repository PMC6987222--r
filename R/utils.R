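# Evaluate expr under a fixed RNG state without touching the caller's stream.
withSeed <- function(seed, expr) {
    if (!is.null(globalenv()$.Random.seed)) {
        old <- globalenv()$.Random.seed
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

stopifnotCount <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
        stop(name, " must be a single non-negative integer")
    invisible(as.integer(x))
}
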