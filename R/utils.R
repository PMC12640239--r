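# internal helpers: seeded evaluation and deterministic per-cell seeds

# evaluate expr under a temporary RNG state; restores the caller's stream
withSeed <- function(seed, expr) {
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

# deterministic 31-bit hash of a character key, for per-cell seed derivation
hashSeed <- function(...) {
    key <- paste(vapply(list(...), as.character, character(1)), collapse = "|")
    h <- 0
    for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
    as.integer(max(h, 1))
}

checkSameNames <- function(a, b, what = "objects") {
    if (!identical(nodeNames(a), nodeNames(b)))
        stop(what, " have mismatched metabolite name order", call. = FALSE)
    invisible(TRUE)
}

upperTriValues <- function(m) m[upper.tri(m)]

# symmetric matrix from its strict upper triangle (column-major order)
symmetricFromUpper <- function(vals, n, nms) {
    m <- matrix(0, n, n, dimnames = list(nms, nms))
    m[upper.tri(m)] <- vals
    m + t(m)
}

newAssociation <- function(m, family, method = NA_character_) {
    diag(m) <- 0
    new("AssociationMatrix", entries = m, family = family, method = method)
}

# percentile 95% CI
ci95 <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE,
                                    na.rm = TRUE)
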