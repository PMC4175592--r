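#' Register and remove barcodes from raw iCLIP reads
#'
#' Splits each read into experiment barcode, random barcode and insert
#' according to the barcode mask (a string over \code{N} = random-barcode
#' position, \code{X} = experiment-barcode position; any trailing \code{I}
#' run stands for the insert). Reads whose insert after trimming is shorter
#' than \code{minLen} nucleotides are dropped and counted, as are reads
#' shorter than the mask itself. When \code{expectedBarcode} is given,
#' reads whose experiment barcode does not match exactly are dropped and
#' counted separately.
#'
#' @param reads a named \code{DNAStringSet}, character vector of read
#'   sequences, or a FASTQ file path.
#' @param barcodeMask barcode layout (default \code{"NNNXXXXNN"}).
#' @param minLen minimum retained insert length (default 11 nt; an insert of
#'   exactly \code{minLen} is retained).
#' @param expectedBarcode optional experiment barcode to demultiplex on.
#' @return A list with \code{reads} (data.frame: read_id,
#'   experiment_barcode, random_barcode, insert_seq, insert_len),
#'   \code{rejected_short} and \code{rejected_barcode} counts.
#' @examples
#' r <- c(r1 = "AAACGGTTCCAGAAGAAGAAGAAG", r2 = "AAACGGTTC")
#' extractBarcodes(r, "NNNXXXXNN", minLen = 11)
#' @export
extractBarcodes <- function(reads, barcodeMask = "NNNXXXXNN", minLen = 11L,
                            expectedBarcode = NULL) {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- readReadsFastq(reads)
    ids <- names(reads)
    seqs <- as.character(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
    ids <- sub("\\s.*$", "", ids)
    .checkDna(seqs, "reads")

    maskCh <- strsplit(barcodeMask, "")[[1L]]
    maskCh <- maskCh[maskCh != "I"]
    mlen <- length(maskCh)
    if (minLen < 0L) stop("minLen must be >= 0")

    len <- nchar(seqs)
    tooShort <- len < mlen
    insert <- ifelse(tooShort, "", substr(seqs, mlen + 1L, len))
    prefCh <- function(which) {
        idx <- which(maskCh == which)
        vapply(seqs, function(s) paste(strsplit(substr(s, 1L, mlen),
                                                "")[[1L]][idx],
                                       collapse = ""), "",
               USE.NAMES = FALSE)
    }
    rb <- ifelse(tooShort, NA_character_, prefCh("N"))
    xb <- ifelse(tooShort, NA_character_, prefCh("X"))

    keep <- !tooShort & nchar(insert) >= minLen
    rejectedShort <- sum(!keep)
    rejectedBarcode <- 0L
    if (!is.null(expectedBarcode)) {
        mism <- keep & xb != expectedBarcode
        rejectedBarcode <- sum(mism)
        keep <- keep & !mism
    }
    list(reads = data.frame(read_id = ids[keep],
                            experiment_barcode = xb[keep],
                            random_barcode = rb[keep],
                            insert_seq = insert[keep],
                            insert_len = nchar(insert[keep]),
                            stringsAsFactors = FALSE),
         rejected_short = rejectedShort,
         rejected_barcode = rejectedBarcode)
}

#' Collapse mapped tags to unique cDNAs
#'
#' One unique cDNA is kept per distinct combination of chromosome, strand,
#' strand-aware start position (5' end in transcript orientation: start on
#' \code{+}, end on \code{-}) and random barcode. The truncation point
#' defines the cDNA, so the 3' end does not enter the key; the first tag of
#' each group is retained as the representative interval.
#'
#' @param tags \code{GRanges} of mapped tags with a \code{random_barcode}
#'   metadata column (e.g. from \code{\link{readAlignmentsBed}}).
#' @return \code{GRanges} of unique cDNAs (subset of \code{tags}).
#' @export
deduplicate <- function(tags) {
    stopifnot(is(tags, "GRanges"))
    bc <- mcols(tags)$random_barcode
    if (is.null(bc) || anyNA(bc))
        stop("every tag needs a random barcode for deduplication")
    if (length(tags) == 0L) return(tags)
    st <- as.character(strand(tags))
    fiveP <- ifelse(st == "+", start(tags), end(tags))
    key <- paste(as.character(seqnames(tags)), st, fiveP, bc, sep = "\r")
    tags[!duplicated(key)]
}

#' Call single-nucleotide crosslink sites from unique cDNAs
#'
#' The crosslink site of a cDNA is the nucleotide immediately 5' (in
#' transcript orientation) of the tag start: position \code{start - 1} for
#' \code{+} tags and \code{end + 1} for \code{-} tags (1-based; this equals
#' the conventional 0-based \code{s - 1} / \code{e} for a tag \code{[s, e)}).
#' cDNAs sharing a site position and strand aggregate into its height.
#' Sites falling off a chromosome edge are discarded with a warning and
#' counted in the \code{n_edge_discarded} attribute.
#'
#' @param cdnas \code{GRanges} of unique cDNAs.
#' @return \code{GRanges} of width-1 sites, sorted, with a \code{score}
#'   column holding the unique-cDNA count (height); the number of
#'   edge-discarded cDNAs is attached as metadata
#'   (\code{metadata(sites)$n_edge_discarded}).
#' @export
callCrosslinkSites <- function(cdnas) {
    stopifnot(is(cdnas, "GRanges"))
    if (length(cdnas) == 0L) {
        out <- GRanges()
        metadata(out)$n_edge_discarded <- 0L
        return(out)
    }
    pos <- .crosslinkPos(cdnas)
    sl <- seqlengths(cdnas)[as.character(seqnames(pos))]
    offLow <- start(pos) < 1L
    offHigh <- !is.na(sl) & start(pos) > sl
    drop <- offLow | offHigh
    if (any(drop))
        warning(sum(drop), " crosslink site(s) at a chromosome edge ",
                "discarded")
    pos <- pos[!drop]
    key <- paste(as.character(seqnames(pos)), as.character(strand(pos)),
                 start(pos), sep = "\r")
    tab <- table(key)
    first <- pos[!duplicated(key)]
    mcols(first)$score <- as.integer(tab[paste(
        as.character(seqnames(first)), as.character(strand(first)),
        start(first), sep = "\r")])
    out <- sort(first)
    if (!anyNA(seqlengths(cdnas)))
        seqlengths(out) <- seqlengths(cdnas)[seqlevels(out)]
    metadata(out)$n_edge_discarded <- sum(drop)
    out
}
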