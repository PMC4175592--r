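# Readers/writers for the plain-text interchange formats. All files follow
# the usual conventions (BED 0-based half-open, GTF 1-based closed);
# in-memory objects are 1-based GRanges and rtracklayer converts on I/O.

#' Write gene models as GTF
#'
#' Emits one \code{exon} feature per exon plus \code{CDS},
#' \code{five_prime_utr} and \code{three_prime_utr} features for coding
#' genes, with \code{gene_id}, \code{transcript_id}, \code{exon_number},
#' \code{exon_class} and \code{gene_biotype} attributes.
#'
#' @param exons exon \code{GRanges} as produced by
#'   \code{\link{generateGenome}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGenesGtf <- function(exons, path) {
    regionType <- c(UTR5 = "five_prime_utr", CDS = "CDS",
                    UTR3 = "three_prime_utr", ncRNA = "exon")
    m <- mcols(exons)
    mkRows <- function(type) {
        g <- granges(exons)
        mcols(g) <- DataFrame(
            source = "clipScreen", type = type,
            gene_id = m$gene_id, transcript_id = m$transcript_id,
            exon_number = as.character(m$exon_number),
            exon_class = m$exon_class,
            gene_biotype = ifelse(m$biotype == "coding", "protein_coding",
                                  "ncRNA"))
        mcols(g)$phase <- ifelse(type == "CDS", 0L, NA_integer_)
        g
    }
    ex <- mkRows("exon")
    feat <- mkRows(regionType[m$region])
    feat <- feat[m$region != "ncRNA"] # ncRNA exons have no second feature
    out <- c(ex, feat)
    out <- out[order(start(out), match(mcols(out)$type,
                                       c("exon", "five_prime_utr", "CDS",
                                         "three_prime_utr")))]
    rtracklayer::export(out, path, format = "gtf")
    invisible(path)
}

#' Read gene models from GTF
#'
#' Inverse of \code{\link{writeGenesGtf}}: reconstructs the exon-level
#' \code{GRanges} (with \code{region} derived from the CDS/UTR features and
#' \code{biotype} from \code{gene_biotype}).
#'
#' @param path GTF file.
#' @return exon \code{GRanges}.
#' @export
readGenesGtf <- function(path) {
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                   error = function(e) stop("malformed GTF '", path, "': ",
                                            conditionMessage(e)))
    ex <- gr[mcols(gr)$type == "exon"]
    m <- mcols(ex)
    region <- rep("ncRNA", length(ex))
    coding <- m$gene_biotype == "protein_coding"
    for (ty in c("CDS", "five_prime_utr", "three_prime_utr")) {
        f <- gr[mcols(gr)$type == ty]
        hit <- findOverlaps(ex, f, type = "equal")
        region[S4Vectors::queryHits(hit)] <-
            c(CDS = "CDS", five_prime_utr = "UTR5",
              three_prime_utr = "UTR3")[ty]
    }
    out <- granges(ex)
    mcols(out) <- DataFrame(
        gene_id = m$gene_id, transcript_id = m$transcript_id,
        exon_number = as.integer(m$exon_number),
        exon_class = if ("exon_class" %in% colnames(m)) m$exon_class
                     else NA_character_,
        region = region,
        biotype = ifelse(coding, "coding", "ncRNA"),
        planted = FALSE)
    out
}

#' Write raw reads as FASTQ
#' @param reads named \code{DNAStringSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
    quals <- Biostrings::BStringSet(strrep("I", width(reads)))
    writeXStringSet(reads, path, format = "fastq", qualities = quals)
    invisible(path)
}

#' Read raw reads from FASTQ
#' @param path FASTQ file.
#' @return named \code{DNAStringSet}.
#' @export
readReadsFastq <- function(path) {
    readDNAStringSet(path, format = "fastq")
}

#' Write mapped tags as BED6
#'
#' The BED name field carries \code{read_id:random_barcode}, the score is 1.
#' @param aln alignment \code{GRanges} with \code{read_id} and
#'   \code{random_barcode} (or a prebuilt \code{name}) metadata columns.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAlignmentsBed <- function(aln, path) {
    out <- granges(aln)
    nm <- mcols(aln)$name
    if (is.null(nm))
        nm <- paste(mcols(aln)$read_id, mcols(aln)$random_barcode, sep = ":")
    mcols(out)$name <- nm
    mcols(out)$score <- 1L
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Read mapped tags from BED6
#'
#' Splits the name field back into \code{read_id} and \code{random_barcode}.
#' @param path BED file.
#' @return \code{GRanges} of mapped tags.
#' @export
readAlignmentsBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- mcols(gr)$name
    parts <- strsplit(nm, ":", fixed = TRUE)
    mcols(gr)$read_id <- vapply(parts, `[`, "", 1L)
    mcols(gr)$random_barcode <- vapply(parts, function(p)
        if (length(p) > 1L) p[2L] else NA_character_, "")
    gr
}

#' Write crosslink sites (or any scored single-nucleotide ranges) as BED6
#' @param sites \code{GRanges} with a \code{score} column (tag height).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSitesBed <- function(sites, path) {
    out <- granges(sites)
    mcols(out)$name <- if (!is.null(mcols(sites)$name)) mcols(sites)$name
                       else paste0("site", seq_along(sites))
    mcols(out)$score <- mcols(sites)$score
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Read crosslink sites from BED6
#' @param path BED file.
#' @return \code{GRanges} with \code{score}.
#' @export
readSitesBed <- function(path) {
    rtracklayer::import(path, format = "BED")
}
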