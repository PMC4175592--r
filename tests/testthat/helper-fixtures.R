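# Shared fixtures, built once per test run and cached.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
})

.fixtures <- new.env(parent = emptyenv())

# The reference planted-signal study: 50 genes, motif weight 50, defaults
# otherwise; one iCLIP replicate processed to unique cDNAs and sites.
plantedStudy <- function() {
    if (is.null(.fixtures$planted)) {
        sim <- generateGenome(simConfig(seed = 11, nGenes = 50))
        ic <- simulateIclip(sim, 1)
        cdnas <- deduplicate(ic$alignments)
        sites <- callCrosslinkSites(cdnas)
        .fixtures$planted <- list(
            sim = sim, iclip = ic, cdnas = cdnas, sites = sites,
            spans = geneSpans(sim),
            planted = simTruth(sim)$planted_clusters)
    }
    .fixtures$planted
}

plantedGR <- function(study) {
    with(study$planted,
         GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                strand = strand))
}

# Rank-based (Wilcoxon) AUC of scores for a binary label.
aucOf <- function(scores, labels) {
    r <- rank(scores)
    n1 <- sum(labels); n0 <- sum(!labels)
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A hand-buildable two-gene annotation (one coding, one ncRNA) with known
# per-class sizes, used by the region-mapping tests.
toyAnnotation <- function() {
    gr <- GenomicRanges::GRanges(
        "chr1",
        IRanges::IRanges(start = c(101, 201, 401, 701, 801),
                         end = c(150, 260, 460, 750, 840)),
        strand = c("+", "+", "+", "-", "-"))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        gene_id = c("g1", "g1", "g1", "g2", "g2"),
        transcript_id = c("g1.t1", "g1.t1", "g1.t1", "g2.t1", "g2.t1"),
        exon_number = c(1L, 2L, 3L, 2L, 1L),
        exon_class = "constitutive",
        region = c("UTR5", "CDS", "UTR3", "ncRNA", "ncRNA"),
        biotype = c("coding", "coding", "coding", "ncRNA", "ncRNA"),
        planted = FALSE)
    GenomeInfoDb::seqlengths(gr) <- c(chr1 = 1000L)
    gr
}

# Closed-form pooled-variance two-sample t-test, kept independent of the
# package implementation.
pooledT <- function(a, b) {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}
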