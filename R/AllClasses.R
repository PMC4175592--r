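#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames strand strand<- start end
#'   width granges start<- end<- resize shift
#' @importFrom IRanges IRanges reduce setdiff findOverlaps countOverlaps
#'   overlapsAny
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   oligonucleotideFrequency matchPattern subseq writeXStringSet
#'   readDNAStringSet quality
#' @importFrom stats plogis pt rnorm runif rmultinom setNames t.test sd
#' @importFrom utils write.table read.table head
NULL

#' Simulation configuration
#'
#' Parameters controlling the synthetic iCLIP study: toy-genome layout,
#' per-gene expression weights, the crosslink propensity model
#' (background rate plus a multiplicative bonus on planted AGAA motif runs),
#' read generation (count, lengths, PCR duplication, barcode layout) and the
#' replicate design.
#'
#' The barcode mask is a string over \code{N} (random-barcode position),
#' \code{X} (experiment-barcode position) and optionally a trailing run of
#' \code{I} (insert); everything after the N/X prefix is insert sequence.
#'
#' @slot seed integer master seed; all randomness derives from it.
#' @slot nGenes number of genes on the toy chromosome.
#' @slot exprWeights positive per-gene expression weights (length 1 is
#'   recycled; genes are also assigned weights at generation time when
#'   length differs from \code{nGenes}).
#' @slot motifWeight crosslink propensity multiplier \code{w} applied on
#'   planted motif positions (propensity is \code{expr * (b0 + w * motif)}).
#' @slot backgroundRate background propensity \code{b0 > 0}.
#' @slot nReads number of raw reads emitted per replicate.
#' @slot readLengthRange inclusive range of insert lengths in nt.
#' @slot pcrRate probability that an emitted read is a PCR duplicate of an
#'   earlier molecule; in [0, 1).
#' @slot barcodeMask barcode layout string (default \code{"NNNXXXXNN"}).
#' @slot experimentBarcode experiment barcode, one base per \code{X}.
#' @slot nReplicates replicates per condition.
#' @slot motifFraction fraction of coding genes receiving a planted motif run.
#' @slot ncrnaFraction fraction of genes with ncRNA biotype.
#' @slot intergenicWeight expression weight of the intergenic background.
#' @export
setClass("SimConfig", representation(
    seed = "integer", nGenes = "integer", exprWeights = "numeric",
    motifWeight = "numeric", backgroundRate = "numeric", nReads = "integer",
    readLengthRange = "integer", pcrRate = "numeric", barcodeMask = "character",
    experimentBarcode = "character", nReplicates = "integer",
    motifFraction = "numeric", ncrnaFraction = "numeric",
    intergenicWeight = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed must be a single integer")
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (any(object@exprWeights <= 0)) msg <- c(msg, "exprWeights must be > 0")
    if (object@motifWeight < 0) msg <- c(msg, "motifWeight must be >= 0")
    if (object@backgroundRate <= 0) msg <- c(msg, "backgroundRate must be > 0")
    if (object@nReads < 1L) msg <- c(msg, "nReads must be >= 1")
    if (length(object@readLengthRange) != 2L ||
        any(object@readLengthRange < 1L) ||
        diff(object@readLengthRange) < 0L)
        msg <- c(msg, "readLengthRange must be two increasing positive ints")
    if (object@pcrRate < 0 || object@pcrRate >= 1)
        msg <- c(msg, "pcrRate must be in [0, 1)")
    mask <- strsplit(object@barcodeMask, "")[[1L]]
    if (!all(mask %in% c("N", "X", "I")))
        msg <- c(msg, "barcodeMask may only contain N, X, I")
    if (sum(mask == "N") < 1L || sum(mask == "X") < 1L)
        msg <- c(msg, "barcodeMask needs at least one N and one X")
    if (nchar(object@experimentBarcode) != sum(mask == "X"))
        msg <- c(msg, "experimentBarcode length must equal number of X in mask")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (object@motifFraction < 0 || object@motifFraction > 1)
        msg <- c(msg, "motifFraction must be in [0, 1]")
    if (object@ncrnaFraction < 0 || object@ncrnaFraction > 1)
        msg <- c(msg, "ncrnaFraction must be in [0, 1]")
    if (object@intergenicWeight < 0)
        msg <- c(msg, "intergenicWeight must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param seed master seed (integer).
#' @param nGenes number of genes.
#' @param exprWeights positive per-gene expression weights; a single value is
#'   recycled, \code{NULL} draws log-normal weights at generation time.
#' @param motifWeight motif crosslink propensity multiplier \code{w}.
#' @param backgroundRate background propensity \code{b0}.
#' @param nReads raw reads per replicate.
#' @param readLengthRange inclusive insert length range (nt).
#' @param pcrRate PCR duplication probability in [0, 1).
#' @param barcodeMask barcode layout over N/X(/I).
#' @param experimentBarcode experiment barcode (one base per X).
#' @param nReplicates replicates per condition.
#' @param motifFraction fraction of coding genes with a planted motif run.
#' @param ncrnaFraction fraction of ncRNA-biotype genes.
#' @param intergenicWeight expression weight of intergenic background.
#' @return A \linkS4class{SimConfig} object.
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 5)
#' cfg
#' @export
simConfig <- function(seed = 1L, nGenes = 20L, exprWeights = NULL,
                      motifWeight = 50, backgroundRate = 1, nReads = 20000L,
                      readLengthRange = c(20L, 40L), pcrRate = 0.3,
                      barcodeMask = "NNNXXXXNN", experimentBarcode = "GGTT",
                      nReplicates = 3L, motifFraction = 0.4,
                      ncrnaFraction = 0.1, intergenicWeight = 0.01) {
    if (is.null(exprWeights)) exprWeights <- numeric(0) # drawn at generation
    new("SimConfig", seed = as.integer(seed), nGenes = as.integer(nGenes),
        exprWeights = as.numeric(exprWeights),
        motifWeight = as.numeric(motifWeight),
        backgroundRate = as.numeric(backgroundRate),
        nReads = as.integer(nReads),
        readLengthRange = as.integer(readLengthRange),
        pcrRate = as.numeric(pcrRate), barcodeMask = barcodeMask,
        experimentBarcode = experimentBarcode,
        nReplicates = as.integer(nReplicates),
        motifFraction = as.numeric(motifFraction),
        ncrnaFraction = as.numeric(ncrnaFraction),
        intergenicWeight = as.numeric(intergenicWeight))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes |", object@nReads,
        "reads/replicate | w =", object@motifWeight,
        "| b0 =", object@backgroundRate,
        "| rho =", object@pcrRate, "| mask", object@barcodeMask,
        "| seed", object@seed, "\n")
})

#' Paralog cross-regulation feedback model
#'
#' Encodes asymmetric cross-repression between two paralogous splicing
#' factors (an abundant factor beta repressing a scarce factor alpha via
#' poison-exon activation, with a weak reverse arm) and the logistic map
#' from total factor activity to exon percent-spliced-in (PSI).
#'
#' After knockdown to residual activities \code{kAlpha}, \code{kBeta} in
#' [0, 1], effective activities are
#' \deqn{e_\beta = k_\beta E_\beta (1 + \gamma_r E_\alpha) /
#'       (1 + \gamma_r k_\alpha E_\alpha)}
#' \deqn{e_\alpha = k_\alpha E_\alpha (1 + \gamma E_\beta) /
#'       (1 + \gamma e_{\beta 0})}
#' with \eqn{e_{\beta 0} = k_\beta E_\beta}: depleting beta de-represses
#' alpha (and weakly vice versa). True PSI of exon e is
#' \eqn{100 \cdot \mathrm{logistic}(\theta_0 + d_e (e_\alpha + e_\beta))}
#' where \eqn{d_e \ge 0} is the exon's dependence coefficient.
#'
#' @slot eAlpha baseline activity of the scarce paralog.
#' @slot eBeta baseline activity of the abundant paralog; must exceed
#'   \code{eAlpha}.
#' @slot gamma feedback gain of beta-represses-alpha (>= 0).
#' @slot gammaRev weak reverse gain (>= 0).
#' @slot theta0 PSI logit intercept.
#' @slot dRange range from which dependence coefficients of motif-carrying
#'   exons are drawn.
#' @slot sigmaRep replicate PSI noise (PSI points, additive Gaussian,
#'   clipped to [0, 100]).
#' @export
setClass("FeedbackModel", representation(
    eAlpha = "numeric", eBeta = "numeric", gamma = "numeric",
    gammaRev = "numeric", theta0 = "numeric", dRange = "numeric",
    sigmaRep = "numeric"))

setValidity("FeedbackModel", function(object) {
    msg <- character()
    if (object@eBeta <= object@eAlpha)
        msg <- c(msg, "eBeta must exceed eAlpha (abundance asymmetry)")
    if (object@gamma < 0 || object@gammaRev < 0)
        msg <- c(msg, "feedback gains must be >= 0")
    if (any(object@dRange < 0) || length(object@dRange) != 2L)
        msg <- c(msg, "dRange must be two values >= 0")
    if (object@sigmaRep < 0) msg <- c(msg, "sigmaRep must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Create a feedback model
#'
#' Defaults give near-exact paralog buffering: the de-repression of the
#' scarce factor after depleting the abundant one compensates the lost
#' activity almost completely, so single knockdowns barely move PSI while
#' the double knockdown collapses it (see the package vignette for the
#' algebra behind the default choice).
#'
#' @param eAlpha,eBeta baseline activities (eBeta > eAlpha).
#' @param gamma,gammaRev forward and reverse feedback gains.
#' @param theta0 PSI logit intercept.
#' @param dRange range of dependence coefficients for motif-carrying exons.
#' @param sigmaRep replicate PSI noise, PSI points.
#' @return A \linkS4class{FeedbackModel}.
#' @examples
#' feedbackModel()
#' @export
feedbackModel <- function(eAlpha = 0.15, eBeta = 1.0, gamma = 10,
                          gammaRev = 1, theta0 = -1.5, dRange = c(2, 4),
                          sigmaRep = 3) {
    new("FeedbackModel", eAlpha = eAlpha, eBeta = eBeta, gamma = gamma,
        gammaRev = gammaRev, theta0 = theta0, dRange = as.numeric(dRange),
        sigmaRep = sigmaRep)
}

setMethod("show", "FeedbackModel", function(object) {
    cat("FeedbackModel: E_alpha =", object@eAlpha, "E_beta =", object@eBeta,
        "| gamma =", object@gamma, "gamma_rev =", object@gammaRev,
        "| theta0 =", object@theta0, "| sigma_rep =", object@sigmaRep, "\n")
})

#' Synthetic iCLIP study container
#'
#' Holds the toy genome, the exon-level gene models and the accumulating
#' ground-truth tables of a simulated study. Created by
#' \code{\link{generateGenome}}; \code{\link{simulateIclip}} and
#' \code{\link{simulateSplicing}} consume it and return reads / PSI tables
#' together with truth records.
#'
#' @slot genome a \code{DNAStringSet} with one entry per chromosome.
#' @slot exons a \code{GRanges} of exons with metadata columns
#'   \code{gene_id}, \code{transcript_id}, \code{exon_number},
#'   \code{exon_class} (constitutive/cassette), \code{region}
#'   (UTR5/CDS/UTR3/ncRNA), \code{biotype} and \code{planted}.
#' @slot config the \linkS4class{SimConfig} used.
#' @slot truth list of ground-truth tables (\code{planted_clusters},
#'   \code{expr_weights}, later \code{read_provenance}, \code{true_psi}).
#' @export
setClass("ClipSimulation", representation(
    genome = "DNAStringSet", exons = "GRanges", config = "SimConfig",
    truth = "list"))

setValidity("ClipSimulation", function(object) {
    msg <- character()
    if (length(object@genome) < 1L) msg <- c(msg, "empty genome")
    if (!all(c("gene_id", "exon_class", "region", "biotype") %in%
             colnames(mcols(object@exons))))
        msg <- c(msg, "exons lack required metadata columns")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ClipSimulation", function(object) {
    cat("ClipSimulation:", length(object@genome), "chromosome(s),",
        sum(width(object@genome)), "nt;",
        length(unique(mcols(object@exons)$gene_id)), "genes,",
        length(object@exons), "exons (",
        sum(mcols(object@exons)$exon_class == "cassette"), "cassette,",
        sum(mcols(object@exons)$planted), "with planted motif runs )\n")
})

#' @describeIn ClipSimulation-class the toy genome (\code{DNAStringSet}).
#' @param x a \code{ClipSimulation}.
#' @export
simGenome <- function(x) x@genome

#' @describeIn ClipSimulation-class the exon models (\code{GRanges}).
#' @export
simGenes <- function(x) x@exons

#' @describeIn ClipSimulation-class the ground-truth list.
#' @export
simTruth <- function(x) x@truth

#' @describeIn ClipSimulation-class the configuration used.
#' @export
simConfigOf <- function(x) x@config

#' Per-gene spans of a simulation
#'
#' @param x a \code{ClipSimulation} or an exon \code{GRanges} with a
#'   \code{gene_id} metadata column.
#' @return \code{GRanges}, one range per gene (the full genomic span from
#'   first to last exon), with \code{gene_id}, \code{biotype} and the gene's
#'   expression weight when known.
#' @export
geneSpans <- function(x) {
    exons <- if (is(x, "ClipSimulation")) x@exons else x
    ids <- mcols(exons)$gene_id
    o <- order(match(ids, unique(ids)))
    exons <- exons[o]; ids <- ids[o]
    sp <- unlist(range(GenomicRanges::split(exons, factor(ids, unique(ids)))))
    mcols(sp)$gene_id <- names(sp)
    first <- exons[!duplicated(ids)]
    mcols(sp)$biotype <- mcols(first)$biotype[match(names(sp),
                                                   mcols(first)$gene_id)]
    if (is(x, "ClipSimulation") && !is.null(x@truth$expr_weights))
        mcols(sp)$expr_weight <-
            x@truth$expr_weights[match(names(sp),
                                       names(x@truth$expr_weights))]
    names(sp) <- NULL
    sp
}
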