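#' Score exons by iCLIP tag enrichment relative to their gene
#'
#' For each candidate exon the scoring window is the exon span extended by
#' \code{flank} nt on both sides (boundary inclusive) and clipped to the
#' gene span. The enrichment score is the number of unique cDNAs whose
#' crosslink position falls inside the window, divided by the gene's total
#' unique-cDNA count, so scores lie in [0, 1]. Genes without any tag are
#' skipped (reported via a message).
#'
#' @param cdnas \code{GRanges} of unique cDNAs (crosslink positions derived
#'   internally) or width-1 crosslink positions.
#' @param exons exon \code{GRanges} with \code{gene_id} and
#'   \code{exon_class} metadata (e.g. \code{simGenes(sim)}).
#' @param flank window extension in nt beyond each splice site
#'   (default 300).
#' @param exonClass which exons to score (default \code{"cassette"};
#'   \code{NULL} scores all exons).
#' @return \code{data.frame}: \code{gene_id}, \code{exon_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{window_count},
#'   \code{gene_count}, \code{score}.
#' @export
scoreExons <- function(cdnas, exons, flank = 300L, exonClass = "cassette") {
    stopifnot(is(cdnas, "GRanges"), is(exons, "GRanges"))
    spans <- geneSpans(exons)
    cand <- if (is.null(exonClass)) exons else
        exons[mcols(exons)$exon_class %in% exonClass]
    if (length(cand) == 0L) stop("no candidate exons to score")
    gi <- match(mcols(cand)$gene_id, mcols(spans)$gene_id)
    if (any(start(cand) < start(spans)[gi] | end(cand) > end(spans)[gi]))
        stop("exon outside its gene span: annotation error")

    pos <- if (all(width(cdnas) == 1L)) granges(cdnas) else
        .crosslinkPos(cdnas)
    geneCount <- countOverlaps(spans, pos, ignore.strand = FALSE)
    win <- granges(cand)
    start(win) <- pmax(start(cand) - flank, start(spans)[gi])
    end(win) <- pmin(end(cand) + flank, end(spans)[gi])
    winCount <- countOverlaps(win, pos, ignore.strand = FALSE)

    gc <- geneCount[gi]
    zero <- gc == 0L
    if (any(zero))
        message(length(unique(mcols(cand)$gene_id[zero])),
                " gene(s) without tags skipped")
    out <- data.frame(
        gene_id = mcols(cand)$gene_id,
        exon_id = paste0(mcols(cand)$gene_id, ".cas"),
        chrom = as.character(seqnames(cand)), start = start(cand),
        end = end(cand), strand = as.character(strand(cand)),
        window_count = as.integer(winCount), gene_count = as.integer(gc),
        score = ifelse(gc > 0L, winCount / gc, NA_real_),
        stringsAsFactors = FALSE)
    if (is.null(exonClass) || !identical(exonClass, "cassette"))
        out$exon_id <- paste0(out$gene_id, ".e",
                              mcols(cand)$exon_number)
    out[!zero, , drop = FALSE]
}

#' Rank candidate exons
#'
#' Descending by enrichment score; ties broken by raw window count, then by
#' genomic coordinate, so the ranking is deterministic.
#'
#' @param candidates output of \code{\link{scoreExons}}.
#' @param topN number of top candidates to return (default all).
#' @return The ranked \code{data.frame} with a \code{rank} column.
#' @export
rankCandidates <- function(candidates, topN = Inf) {
    o <- order(-candidates$score, -candidates$window_count,
               candidates$chrom, candidates$start)
    out <- candidates[o, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    head(out, n = min(topN, nrow(out)))
}
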