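#' Randomize crosslink positions within a gene
#'
#' Builds the within-gene randomization null for significant-site calling:
#' each randomization redistributes the gene's observed unique-cDNA total
#' uniformly (multinomially) over the gene's permissible positions, and the
#' resulting height census (number of positions reaching height >= h) is
#' recorded per randomization.
#'
#' @param sites \code{GRanges} of observed crosslink sites in the gene, with
#'   \code{score} = height; alternatively a single integer giving the
#'   gene's cDNA total.
#' @param geneSpan \code{GRanges} of permissible positions (one or more
#'   disjoint intervals; the full gene span by default usage).
#' @param R number of randomizations (>= 1).
#' @param seed RNG seed.
#' @return A list of class \code{clipNull}: \code{R}, \code{total} (cDNAs
#'   placed per randomization), \code{L} (permissible positions) and
#'   \code{census}, an \code{R x Hmax} matrix whose \code{[r, h]} entry is
#'   the number of positions with height >= h in randomization \code{r}.
#' @examples
#' gs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
#' nd <- randomizePositions(3L, gs, R = 100, seed = 1)
#' colMeans(nd$census)
#' @export
randomizePositions <- function(sites, geneSpan, R = 100L, seed = NULL) {
    stopifnot(R >= 1L)
    L <- sum(width(geneSpan))
    if (L < 1L) stop("empty gene span")
    total <- if (is(sites, "GRanges")) {
        h <- mcols(sites)$score
        if (is.null(h)) h <- rep(1L, length(sites))
        sum(h)
    } else as.integer(sites)
    if (total < 1L) stop("gene has no cDNAs to randomize")
    census <- .withSeed(seed, {
        draws <- stats::rmultinom(R, total, rep(1 / L, L))
        hmax <- max(draws)
        t(apply(draws, 2L, function(cnt) {
            tb <- tabulate(cnt[cnt > 0L], nbins = hmax)
            rev(cumsum(rev(tb))) # positions with height >= h
        }))
    })
    if (is.null(dim(census))) census <- matrix(census, nrow = R)
    structure(list(R = R, total = total, L = L, census = census),
              class = "clipNull")
}

#' Randomization FDR of observed crosslink-site heights
#'
#' For each observed height h, the false discovery rate is estimated as the
#' mean (over randomizations) number of null positions reaching height >= h,
#' divided by the number of observed sites with height >= h, clamped to
#' [0, 1] and made monotone non-increasing in h. A site is significant when
#' its height's FDR falls below \code{alpha}.
#'
#' @param sites observed \code{GRanges} sites with \code{score} = height.
#' @param null a \code{clipNull} from \code{\link{randomizePositions}} built
#'   from the same gene.
#' @param alpha significance threshold on the FDR (default 0.05).
#' @return \code{sites} with added metadata columns \code{fdr},
#'   \code{fdr_se} (Monte-Carlo standard error of the raw estimate) and
#'   \code{significant}.
#' @export
siteFdr <- function(sites, null, alpha = 0.05) {
    stopifnot(inherits(null, "clipNull"), is(sites, "GRanges"))
    h <- mcols(sites)$score
    if (is.null(h)) stop("sites need a score (height) column")
    h <- as.integer(h)
    hs <- sort(unique(h))
    hmax <- ncol(null$census)
    nullGE <- vapply(hs, function(hh)
        if (hh <= hmax) mean(null$census[, hh]) else 0, 0)
    nullSD <- vapply(hs, function(hh)
        if (hh <= hmax) stats::sd(null$census[, hh]) else 0, 0)
    obsGE <- vapply(hs, function(hh) sum(h >= hh), numeric(1))
    raw <- pmin(1, nullGE / obsGE)
    fdr <- cummin(raw)            # monotone non-increasing in h
    se <- nullSD / obsGE / sqrt(null$R)
    idx <- match(h, hs)
    mcols(sites)$fdr <- fdr[idx]
    mcols(sites)$fdr_se <- se[idx]
    mcols(sites)$significant <- fdr[idx] < alpha
    sites
}

#' Merge significant crosslink sites into clusters
#'
#' Greedy left-to-right merge within each chromosome and strand: a site
#' joins the open cluster when its distance to the previous member is at
#' most \code{maxGap} nucleotides (boundary inclusive, measured between
#' crosslink positions).
#'
#' @param sites \code{GRanges} of (significant) crosslink sites with
#'   \code{score} and optionally \code{fdr}.
#' @param maxGap maximum gap between consecutive member sites (default 15).
#' @return \code{GRanges} of clusters with \code{n_sites},
#'   \code{total_height} and \code{fdr} (minimum member FDR, NA when the
#'   input carries none).
#' @export
mergeClusters <- function(sites, maxGap = 15L) {
    stopifnot(is(sites, "GRanges"))
    if (length(sites) == 0L) {
        out <- GRanges()
        mcols(out) <- DataFrame(n_sites = integer(),
                                total_height = integer(), fdr = numeric())
        return(out)
    }
    if (is.unsorted(order(as.factor(seqnames(sites)),
                          as.factor(strand(sites)), start(sites)))) {
        message("mergeClusters: input not sorted; sorting internally")
    }
    o <- order(as.factor(seqnames(sites)), as.factor(strand(sites)),
               start(sites))
    sites <- sites[o]
    grpKey <- paste(as.character(seqnames(sites)),
                    as.character(strand(sites)), sep = "\r")
    newGrp <- c(TRUE, grpKey[-1L] != grpKey[-length(grpKey)])
    gap <- c(Inf, diff(start(sites)))
    newCl <- newGrp | gap > maxGap
    cl <- cumsum(newCl)
    h <- mcols(sites)$score
    if (is.null(h)) h <- rep(1L, length(sites))
    fdr <- mcols(sites)$fdr
    if (is.null(fdr)) fdr <- rep(NA_real_, length(sites))
    sp <- split(seq_along(sites), cl)
    res <- lapply(sp, function(ii) {
        c(first = ii[1L], s = min(start(sites)[ii]),
          e = max(start(sites)[ii]), n = length(ii), th = sum(h[ii]),
          f = if (all(is.na(fdr[ii]))) NA_real_ else
              min(fdr[ii], na.rm = TRUE))
    })
    m <- do.call(rbind, res)
    out <- GRanges(seqnames(sites)[m[, "first"]],
                   IRanges(m[, "s"], m[, "e"]),
                   strand = strand(sites)[m[, "first"]],
                   seqlengths = seqlengths(sites))
    mcols(out)$n_sites <- as.integer(m[, "n"])
    mcols(out)$total_height <- as.integer(m[, "th"])
    mcols(out)$fdr <- m[, "f"]
    out
}

#' Call significant crosslink-site clusters per gene
#'
#' Driver over a whole experiment: for each gene, builds the within-gene
#' randomization null, computes site FDRs, keeps significant sites and
#' merges them into clusters. With \code{method = "window"}, an additional
#' cluster-level FDR is attached: the fraction of randomizations whose
#' maximal \code{maxGap}-nt window cDNA sum reaches the cluster's total
#' height.
#'
#' @param sites \code{GRanges} of crosslink sites (all genes pooled) with
#'   \code{score} = height.
#' @param genes gene spans (\code{GRanges} with \code{gene_id}), e.g. from
#'   \code{\link{geneSpans}}.
#' @param R randomizations per gene (default 100).
#' @param alpha FDR threshold (default 0.05).
#' @param maxGap cluster window in nt (default 15).
#' @param seed RNG seed.
#' @param method \code{"site"} (default; cluster FDR = min member site FDR)
#'   or \code{"window"} (adds a window-sum cluster FDR).
#' @return List with \code{clusters} (\code{GRanges}; with
#'   \code{cluster_fdr} when \code{method = "window"}), \code{sites} (all
#'   sites with FDR columns) and \code{n_genes_tested}.
#' @export
callClusters <- function(sites, genes, R = 100L, alpha = 0.05,
                         maxGap = 15L, seed = NULL,
                         method = c("site", "window")) {
    method <- match.arg(method)
    ov <- findOverlaps(sites, genes, ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(ov)
    keep <- !duplicated(qh)
    siteGene <- rep(NA_integer_, length(sites))
    siteGene[qh[keep]] <- S4Vectors::subjectHits(ov)[keep]

    outSites <- list(); outClusters <- list(); tested <- 0L
    for (gi in sort(unique(siteGene[!is.na(siteGene)]))) {
        gs <- sites[which(siteGene == gi)]
        span <- genes[gi]
        nd <- randomizePositions(gs, span, R = R,
                                 seed = if (is.null(seed)) NULL else
                                     .subSeed(seed, gi))
        gs <- siteFdr(gs, nd, alpha = alpha)
        tested <- tested + 1L
        sig <- gs[mcols(gs)$significant]
        cl <- mergeClusters(sig, maxGap = maxGap)
        if (method == "window" && length(cl)) {
            maxWin <- .nullMaxWindowSums(nd, span, maxGap, seed = if
                (is.null(seed)) NULL else .subSeed(seed, 100000L + gi))
            mcols(cl)$cluster_fdr <- vapply(mcols(cl)$total_height,
                function(th) mean(maxWin >= th), 0)
        }
        mcols(cl)$gene_id <- rep(mcols(genes)$gene_id[gi], length(cl))
        outSites[[length(outSites) + 1L]] <- gs
        outClusters[[length(outClusters) + 1L]] <- cl
    }
    allSites <- if (length(outSites)) sort(do.call(c, outSites)) else
        GRanges()
    allCl <- if (length(outClusters)) sort(do.call(c, outClusters)) else
        GRanges()
    list(clusters = allCl, sites = allSites, n_genes_tested = tested)
}

# Max sum of cDNA counts over any maxGap-nt window, per randomization.
.nullMaxWindowSums <- function(null, span, maxGap, seed = NULL) {
    L <- null$L
    .withSeed(seed, {
        draws <- stats::rmultinom(null$R, null$total, rep(1 / L, L))
        w <- min(maxGap, L)
        apply(draws, 2L, function(cnt) {
            cs <- cumsum(c(0, cnt))
            max(cs[(w + 1L):(L + 1L)] - cs[1L:(L - w + 1L)])
        })
    })
}
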