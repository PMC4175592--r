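#' Count k-mers in windows around crosslink sites
#'
#' Every overlapping k-mer occurrence on the site's strand within
#' \code{[position - flank, position + flank]} is counted (windows are
#' trimmed at chromosome edges). Counting is on the annotated strand only,
#' since crosslinking is to the transcript.
#'
#' @param sites width-1 \code{GRanges} of crosslink sites.
#' @param genome named \code{DNAStringSet}.
#' @param flank half-window in nt (default 30).
#' @param k k-mer length (default 5, pentamers).
#' @return Named integer vector over all \code{4^k} k-mers; the attribute
#'   \code{total_positions} carries the total number of k-mer start
#'   positions across windows (conservation check: the counts sum to it).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "TTAGAAATT"))
#' s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 5), strand = "+")
#' head(sort(kmerCounts(s, g, flank = 2), decreasing = TRUE), 2)
#' @export
kmerCounts <- function(sites, genome, flank = 30L, k = 5L) {
    if (2L * flank + 1L < k)
        stop("k exceeds the window size (2 * flank + 1)")
    counts <- integer(4L^k)
    names(counts) <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    if (length(sites) == 0L)
        return(structure(counts, total_positions = 0L))
    glen <- setNames(width(genome), names(genome))
    ws <- pmax(1L, start(sites) - flank)
    we <- pmin(glen[as.character(seqnames(sites))], start(sites) + flank)
    total <- 0L
    for (ch in unique(as.character(seqnames(sites)))) {
        ii <- which(as.character(seqnames(sites)) == ch)
        seqs <- Biostrings::extractAt(genome[[ch]],
                                      IRanges(ws[ii], we[ii]))
        neg <- as.character(strand(sites))[ii] == "-"
        if (any(neg)) seqs[neg] <- reverseComplement(seqs[neg])
        counts <- counts + colSums(oligonucleotideFrequency(seqs, width = k))
        total <- total + sum(pmax(0L, width(seqs) - k + 1L))
    }
    structure(counts, total_positions = total)
}

#' K-mer enrichment z-scores against a within-gene randomization null
#'
#' The null re-draws every site position uniformly within its gene span and
#' repeats the identical window counting \code{R} times; the z-score is
#' \code{(observed - null mean) / null sd}. K-mers whose null standard
#' deviation is zero get z = 0 and are flagged as degenerate.
#'
#' @param sites width-1 \code{GRanges} of crosslink sites.
#' @param geneSpans \code{GRanges} of gene spans; sites not overlapping any
#'   span are dropped (with a message) from both observed and null counts.
#' @param genome named \code{DNAStringSet}.
#' @param flank,k window half-width and k-mer length.
#' @param R number of randomizations (>= 10).
#' @param seed RNG seed.
#' @return \code{data.frame} with one row per k-mer: \code{kmer},
#'   \code{observed}, \code{null_mean}, \code{null_sd}, \code{z},
#'   \code{degenerate}, \code{rank} (by descending z, ties lexicographic).
#' @export
kmerZscores <- function(sites, geneSpans, genome, flank = 30L, k = 5L,
                        R = 100L, seed = NULL) {
    if (R < 10L) stop("R must be >= 10")
    ov <- findOverlaps(sites, geneSpans, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov)
    first <- !duplicated(qh)
    gidx <- rep(NA_integer_, length(sites))
    gidx[qh[first]] <- S4Vectors::subjectHits(ov)[first]
    if (anyNA(gidx)) {
        message(sum(is.na(gidx)), " site(s) outside any gene span dropped ",
                "from k-mer enrichment")
        sites <- sites[!is.na(gidx)]
        gidx <- gidx[!is.na(gidx)]
    }
    if (length(sites) == 0L) stop("no sites within gene spans")
    obs <- kmerCounts(sites, genome, flank = flank, k = k)

    spanStart <- start(geneSpans)[gidx]
    spanW <- width(geneSpans)[gidx]
    sums <- numeric(length(obs)); sqs <- numeric(length(obs))
    .withSeed(seed, {
        for (r in seq_len(R)) {
            rpos <- spanStart + floor(stats::runif(length(sites)) * spanW)
            rs <- GRanges(seqnames(sites), IRanges(rpos, width = 1L),
                          strand = strand(sites),
                          seqlengths = seqlengths(sites))
            cc <- kmerCounts(rs, genome, flank = flank, k = k)
            sums <- sums + cc
            sqs <- sqs + cc^2
        }
    })
    nm <- sums / R
    nsd <- sqrt(pmax(0, (sqs - R * nm^2) / (R - 1)))
    degen <- nsd == 0
    z <- ifelse(degen, 0, (as.numeric(obs) - nm) / nsd)
    df <- data.frame(kmer = names(obs), observed = as.integer(obs),
                     null_mean = nm, null_sd = nsd, z = z,
                     degenerate = degen, stringsAsFactors = FALSE)
    df$rank <- match(seq_len(nrow(df)), order(-df$z, df$kmer))
    df
}

#' Extract the top enriched k-mers
#'
#' @param scores a k-mer score table from \code{\link{kmerZscores}}.
#' @param nTop number of k-mers to return (default 10).
#' @return Character vector of the \code{nTop} highest-z k-mers; ties at the
#'   boundary are broken lexicographically (and reported via a message).
#' @export
topKmers <- function(scores, nTop = 10L) {
    finite <- scores[is.finite(scores$z) & !scores$degenerate, ]
    if (nrow(finite) < nTop) {
        warning("only ", nrow(finite), " k-mers with a finite, ",
                "non-degenerate z; returning all")
        nTop <- nrow(finite)
    }
    o <- order(-finite$z, finite$kmer)
    picked <- finite[o[seq_len(nTop)], ]
    if (nTop > 0L && nTop < nrow(finite) &&
        finite$z[o[nTop]] == finite$z[o[nTop + 1L]])
        message("tie at rank ", nTop, " between ", finite$kmer[o[nTop]],
                " and ", finite$kmer[o[nTop + 1L]],
                "; broken lexicographically")
    picked$kmer
}

#' Binding-site density of exons
#'
#' The density of an exon is the percentage of its nucleotides covered by
#' at least one occurrence of any of the given k-mers (union coverage;
#' overlapping occurrences do not double-count).
#'
#' @param exonSeqs character vector or \code{DNAStringSet} of exon
#'   sequences (transcript orientation), ideally named by exon id.
#' @param kmers character vector of k-mers (e.g. from
#'   \code{\link{topKmers}}).
#' @return \code{data.frame}: \code{exon_id}, \code{length}, \code{covered},
#'   \code{density_pct}, \code{too_short} (exon shorter than the shortest
#'   k-mer; density 0).
#' @examples
#' bindingDensity(c(e1 = "CAGAAGTTTT"), "AGAAG")
#' @export
bindingDensity <- function(exonSeqs, kmers) {
    seqs <- as.character(exonSeqs)
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("exon", seq_along(seqs))
    kmin <- min(nchar(kmers))
    res <- lapply(seqs, function(s) {
        len <- nchar(s)
        if (len < kmin) return(c(len, 0, 1))
        hits <- IRanges()
        subj <- DNAString(s)
        for (km in kmers) {
            m <- matchPattern(km, subj)
            if (length(m)) hits <- c(hits, as(m, "IRanges"))
        }
        cov <- sum(width(reduce(hits)))
        c(len, cov, 0)
    })
    m <- do.call(rbind, res)
    data.frame(exon_id = ids, length = as.integer(m[, 1L]),
               covered = as.integer(m[, 2L]),
               density_pct = 100 * m[, 2L] / m[, 1L],
               too_short = m[, 3L] == 1, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Compare binding-site densities between two exon groups
#'
#' Two-sided independent two-sample t-test (pooled variance by default,
#' df = nA + nB - 2; Welch via \code{equalVar = FALSE}).
#'
#' @param groupA,groupB numeric density values (each of length >= 2).
#' @param equalVar use the pooled-variance test (default TRUE).
#' @return List: \code{mean_a}, \code{mean_b}, \code{t}, \code{df},
#'   \code{p}.
#' @examples
#' compareDensity(c(10, 12, 14), c(1, 2, 3))
#' @export
compareDensity <- function(groupA, groupB, equalVar = TRUE) {
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("each group needs at least 2 values")
    ht <- .tTest(groupA, groupB, equalVar = equalVar)
    list(mean_a = mean(groupA), mean_b = mean(groupB),
         t = ht$t, df = ht$df, p = ht$p)
}
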