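.REGION_CLASSES <- c("ncRNA", "3'UTR", "5'UTR", "ORF", "intron",
                     "intergenic")

#' Build a genomic region index
#'
#' Partitions the genome into the six classes 5'UTR, ORF, 3'UTR, intron,
#' ncRNA and intergenic. Overlaps between raw annotation classes are
#' resolved by precedence (default ncRNA > 3'UTR > 5'UTR > ORF > intron >
#' intergenic), so the resulting intervals are disjoint and tile the
#' genome; per-class total sizes in nt are recorded.
#'
#' @param x exon \code{GRanges} with \code{gene_id}, \code{region} and
#'   \code{biotype} metadata (as from \code{\link{generateGenome}} or
#'   \code{\link{readGenesGtf}}), or a GTF file path.
#' @param seqlens named chromosome lengths; defaults to
#'   \code{seqlengths(x)} and is required for the intergenic class.
#' @param precedence class precedence order (highest first).
#' @return List of class \code{regionIndex}: \code{classes} (named list of
#'   disjoint unstranded \code{GRanges}), \code{sizes} (named nt totals)
#'   and \code{precedence}.
#' @export
buildRegionIndex <- function(x, seqlens = NULL,
                             precedence = .REGION_CLASSES[1:5]) {
    if (is.character(x)) x <- readGenesGtf(x)
    stopifnot(is(x, "GRanges"))
    if (is.null(seqlens)) seqlens <- seqlengths(x)
    if (anyNA(seqlens) || length(seqlens) == 0L)
        stop("chromosome lengths are required (seqlens)")
    m <- mcols(x)
    raw <- list(
        "ncRNA" = x[m$biotype == "ncRNA"],
        "3'UTR" = x[m$region == "UTR3"],
        "5'UTR" = x[m$region == "UTR5"],
        "ORF"   = x[m$region == "CDS"])
    spans <- geneSpans(x)
    raw[["intron"]] <- GenomicRanges::setdiff(spans, x,
                                              ignore.strand = TRUE)
    taken <- GRanges()
    classes <- list()
    for (cl in precedence) {
        g <- reduce(granges(raw[[cl]]), ignore.strand = TRUE)
        strand(g) <- "*"
        g <- GenomicRanges::setdiff(g, taken, ignore.strand = TRUE)
        classes[[cl]] <- g
        taken <- reduce(c(taken, g))
    }
    full <- GRanges(names(seqlens), IRanges(1L, unname(seqlens)))
    classes[["intergenic"]] <- GenomicRanges::setdiff(full, taken,
                                                      ignore.strand = TRUE)
    sizes <- vapply(classes, function(g) sum(as.numeric(width(g))), 0)
    structure(list(classes = classes, sizes = sizes,
                   precedence = c(precedence, "intergenic")),
              class = "regionIndex")
}

#' Assign tags to genomic region classes
#'
#' Each unique cDNA is assigned to exactly one class by the single
#' nucleotide of its crosslink position, following the index precedence.
#' Positions outside every annotated class fall into intergenic.
#'
#' @param cdnas \code{GRanges} of unique cDNAs (their crosslink positions
#'   are derived internally), or width-1 crosslink-site positions used
#'   as-is (heights are ignored: counting is per cDNA record).
#' @param index a \code{regionIndex} from \code{\link{buildRegionIndex}}.
#' @return \code{data.frame} of class \code{regionDistribution}:
#'   \code{class}, \code{count}, \code{raw_pct}, \code{size} (nt); raw
#'   percentages sum to 100.
#' @export
assignTags <- function(cdnas, index) {
    stopifnot(inherits(index, "regionIndex"), is(cdnas, "GRanges"))
    if (length(cdnas) == 0L) stop("no tags to assign")
    pos <- if (all(width(cdnas) == 1L)) granges(cdnas) else
        .crosslinkPos(cdnas)
    sl <- seqlengths(cdnas)[as.character(seqnames(pos))]
    pos <- pos[start(pos) >= 1L & (is.na(sl) | start(pos) <= sl)]
    assigned <- rep(NA_character_, length(pos))
    for (cl in index$precedence) {
        hit <- overlapsAny(pos, index$classes[[cl]], ignore.strand = TRUE)
        assigned[is.na(assigned) & hit] <- cl
    }
    assigned[is.na(assigned)] <- "intergenic"
    cls <- index$precedence
    cnt <- vapply(cls, function(cl) sum(assigned == cl), numeric(1))
    out <- data.frame(class = cls, count = as.integer(cnt),
                      raw_pct = 100 * cnt / sum(cnt),
                      size = unname(index$sizes[cls]),
                      stringsAsFactors = FALSE, row.names = NULL)
    class(out) <- c("regionDistribution", class(out))
    out
}

#' Region-size-normalized tag distribution
#'
#' Divides each class's tag count by the class's total size in nt and
#' renormalizes the resulting densities to percentages, correcting for the
#' very different genomic footprints of the classes (exons cover only a
#' small fraction of a genome, so raw exonic percentages understate
#' exonic enrichment).
#'
#' @param dist a \code{regionDistribution} from \code{\link{assignTags}}.
#' @param index the matching \code{regionIndex} (used to validate sizes;
#'   optional when \code{dist} already carries them).
#' @return \code{dist} with added \code{density} (count per nt) and
#'   \code{norm_pct} columns; normalized percentages sum to 100.
#' @export
sizeNormalize <- function(dist, index = NULL) {
    stopifnot(inherits(dist, "regionDistribution"))
    if (!is.null(index)) dist$size <- unname(index$sizes[dist$class])
    bad <- dist$count > 0 & dist$size == 0
    if (any(bad))
        stop("class with tags but zero size: ",
             paste(dist$class[bad], collapse = ", "))
    dens <- ifelse(dist$size > 0, dist$count / dist$size, 0)
    dist$density <- dens
    dist$norm_pct <- 100 * dens / sum(dens)
    dist
}

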