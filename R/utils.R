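# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates expr as-is.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    expr
}

# Derive a stream-specific sub-seed, kept below 2^31.
.subSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

.randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Single-nucleotide crosslink position for each tag: the nucleotide
# immediately 5' (transcript orientation) of the tag start. In 1-based
# coordinates: start - 1 on '+', end + 1 on '-'. Records falling off either
# chromosome edge get position 0 / length + 1 and are filtered by callers
# that know the sequence lengths.
.crosslinkPos <- function(gr) {
    st <- as.character(strand(gr))
    if (any(st == "*"))
        stop("tags must be stranded to locate crosslink positions")
    pos <- ifelse(st == "+", start(gr) - 1L, end(gr) + 1L)
    # seqlengths are deliberately not attached: edge positions (0 or
    # length + 1) must be representable so callers can count and drop them
    GRanges(seqnames(gr), IRanges(pos, width = 1L), strand = st)
}

# Pooled-variance (equal-variance) two-sample t-test; Welch via stats::t.test.
# Zero variance in both groups is handled explicitly: equal means give
# t = 0, p = 1; unequal means an infinite statistic with p = 0.
.tTest <- function(a, b, equalVar = TRUE) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 observations")
    df <- length(a) + length(b) - 2L
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        eq <- isTRUE(all.equal(mean(a), mean(b)))
        return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                    p = if (eq) 1 else 0, df = df))
    }
    ht <- stats::t.test(a, b, var.equal = equalVar)
    list(t = unname(ht$statistic), p = ht$p.value,
         df = unname(ht$parameter))
}

.checkDna <- function(x, what = "sequence") {
    bad <- grepl("[^ACGTN]", x)
    if (any(bad))
        stop("non-ACGTN characters in ", what, " (first offending record ",
             which(bad)[1L], ")")
    invisible(TRUE)
}
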