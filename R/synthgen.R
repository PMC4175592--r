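#' Generate a toy genome with planted motif runs
#'
#' Lays out \code{nGenes} non-overlapping genes on one random-sequence
#' chromosome. Coding genes carry five exons (first = 5'UTR, last = 3'UTR,
#' internal = CDS in transcript orientation) with the middle exon annotated
#' as a cassette exon; ncRNA genes carry two constitutive exons. A fixed
#' fraction of coding genes receives a planted AGAA-repeat run in the centre
#' of the cassette exon, written strand-aware so the transcript reads the
#' motif. Planted runs, per-gene expression weights and all layout choices
#' are recorded in the ground-truth tables.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param outdir optional directory; when given, \code{genome.fa} and
#'   \code{genes.gtf} are written there.
#' @return A \linkS4class{ClipSimulation}.
#' @examples
#' sim <- generateGenome(simConfig(seed = 1, nGenes = 3))
#' sim
#' @export
generateGenome <- function(config, outdir = NULL) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    sim <- .withSeed(config@seed, .generateGenomeImpl(config))
    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        writeXStringSet(sim@genome, file.path(outdir, "genome.fa"))
        writeGenesGtf(sim@exons, file.path(outdir, "genes.gtf"))
    }
    sim
}

# A planted binding-site run is a concatenation of AGAA/GAA units in a
# random register (8 units, 24-32 nt), emulating AGAA-rich binding regions
# whose pentamer content varies with phasing (AGAAA, AGAAG, GAAAG, ...).
.motifRun <- function() {
    paste(sample(c("AGAA", "GAA"), 8L, replace = TRUE), collapse = "")
}

.generateGenomeImpl <- function(config) {
    n <- config@nGenes
    nNc <- round(n * config@ncrnaFraction)
    biotype <- rep("coding", n)
    if (nNc > 0) biotype[sample(n, nNc)] <- "ncRNA"
    coding <- which(biotype == "coding")
    nPlant <- round(n * config@motifFraction)
    if (nPlant > length(coding))
        stop("motifFraction + ncrnaFraction leave too few coding genes ",
             "to plant motifs in")
    planted <- sort(sample(coding, nPlant))

    chrom <- "chrT"
    cursor <- 1L
    exList <- list()
    plantRows <- list()
    for (i in seq_len(n)) {
        gid <- sprintf("gene%03d", i)
        gap <- sample(200:500, 1L)
        cursor <- cursor + gap
        st <- sample(c("+", "-"), 1L)
        if (biotype[i] == "coding") {
            exLen <- sample(80:200, 5L, replace = TRUE)
            inLen <- sample(100:300, 4L, replace = TRUE)
            cls <- c("constitutive", "constitutive", "cassette",
                     "constitutive", "constitutive")
        } else {
            exLen <- sample(80:200, 2L, replace = TRUE)
            inLen <- sample(100:300, 1L)
            cls <- c("constitutive", "constitutive")
        }
        starts <- cursor + cumsum(c(0L, exLen[-length(exLen)] + inLen))
        ends <- starts + exLen - 1L
        cursor <- ends[length(ends)] + 1L
        # transcript-order exon numbers (genomic order reversed on '-')
        exNum <- if (st == "+") seq_along(exLen) else rev(seq_along(exLen))
        region <- if (biotype[i] == "coding") {
            r <- rep("CDS", length(exLen))
            r[exNum == 1L] <- "UTR5"
            r[exNum == length(exLen)] <- "UTR3"
            r
        } else rep("ncRNA", length(exLen))
        isPl <- (i %in% planted) & (cls == "cassette")
        exList[[i]] <- data.frame(
            chrom = chrom, start = starts, end = ends, strand = st,
            gene_id = gid, transcript_id = paste0(gid, ".t1"),
            exon_number = exNum, exon_class = cls, region = region,
            biotype = biotype[i], planted = isPl)
        if (any(isPl)) {
            ce <- which(isPl)
            run <- .motifRun()
            mid <- floor((starts[ce] + ends[ce]) / 2)
            ps <- mid - nchar(run) %/% 2L
            plantRows[[length(plantRows) + 1L]] <- data.frame(
                gene_id = gid, chrom = chrom, start = ps,
                end = ps + nchar(run) - 1L, strand = st, motif_run = run)
        }
    }
    ex <- do.call(rbind, exList)
    glen <- cursor + sample(200:500, 1L)

    seqChars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
    plantTab <- if (length(plantRows)) do.call(rbind, plantRows) else
        data.frame(gene_id = character(), chrom = character(),
                   start = integer(), end = integer(),
                   strand = character(), motif_run = character())
    for (j in seq_len(nrow(plantTab))) {
        run <- if (plantTab$strand[j] == "+") plantTab$motif_run[j] else
            as.character(reverseComplement(DNAString(plantTab$motif_run[j])))
        seqChars[plantTab$start[j]:plantTab$end[j]] <- strsplit(run, "")[[1L]]
    }
    genome <- DNAStringSet(setNames(paste(seqChars, collapse = ""), chrom))

    w <- config@exprWeights
    expr <- if (length(w) == n) w else if (length(w) == 1L) rep(w, n) else
        stats::rlnorm(n, meanlog = 0, sdlog = 0.5)
    names(expr) <- sprintf("gene%03d", seq_len(n))

    gr <- GRanges(ex$chrom, IRanges(ex$start, ex$end), strand = ex$strand)
    seqlengths(gr) <- setNames(glen, chrom)
    mcols(gr) <- DataFrame(ex[, c("gene_id", "transcript_id", "exon_number",
                                  "exon_class", "region", "biotype",
                                  "planted")])

    # expected share of the gene's crosslinks falling inside the planted run
    if (nrow(plantTab)) {
        spans <- tapply(seq_len(nrow(ex)), ex$gene_id, function(ii)
            max(ex$end[ii]) - min(ex$start[ii]) + 1L)
        L <- as.integer(spans[plantTab$gene_id])
        m <- plantTab$end - plantTab$start + 1L
        b0 <- config@backgroundRate; wm <- config@motifWeight
        plantTab$expected_share <- m * (b0 + wm) / (m * (b0 + wm) +
                                                    (L - m) * b0)
    } else plantTab$expected_share <- numeric(0)

    new("ClipSimulation", genome = genome, exons = gr, config = config,
        truth = list(planted_clusters = plantTab, expr_weights = expr))
}

#' Simulate one replicate of an iCLIP experiment
#'
#' Draws crosslinked molecules with per-position propensity proportional to
#' \code{expression * (b0 + w * motif)}, where \code{motif} indicates
#' positions inside a planted run; intergenic background positions get a
#' small configurable weight. Each read truncates at the crosslink, so the
#' read starts one nucleotide downstream of the crosslinked nucleotide in
#' transcript orientation. Each molecule receives a random barcode; PCR
#' duplicates (probability \code{pcrRate} per emitted read) copy an earlier
#' molecule's position, length and barcode. Raw reads carry the barcode
#' layout of \code{barcodeMask} as a prefix.
#'
#' @param sim a \linkS4class{ClipSimulation} from \code{\link{generateGenome}}.
#' @param replicate replicate number (drives the replicate-specific seed and
#'   read ids).
#' @param outdir optional directory; when given, \code{repN.fastq} (raw
#'   reads) and \code{repN.bed} (true unique-hit alignments, BED6 with
#'   name \code{read_id:barcode}) are written.
#' @return A list with \code{reads} (named \code{DNAStringSet} of raw reads),
#'   \code{alignments} (\code{GRanges} of the true mapped inserts with
#'   \code{name}, \code{random_barcode}, \code{score = 1}) and
#'   \code{provenance} (one row per emitted read: molecule id, duplicate-of,
#'   true crosslink chrom/pos/strand, barcode).
#' @export
simulateIclip <- function(sim, replicate = 1L, outdir = NULL) {
    stopifnot(is(sim, "ClipSimulation"))
    config <- sim@config
    res <- .withSeed(.subSeed(config@seed, 1000L + replicate),
                     .simulateIclipImpl(sim, config, replicate))
    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        writeReadsFastq(res$reads,
                        file.path(outdir, sprintf("rep%d.fastq", replicate)))
        writeAlignmentsBed(res$alignments,
                           file.path(outdir, sprintf("rep%d.bed", replicate)))
    }
    res
}

.simulateIclipImpl <- function(sim, config, replicate) {
    genome <- sim@genome
    glen <- width(genome)[1L]
    chrom <- names(genome)[1L]
    spans <- geneSpans(sim)
    expr <- sim@truth$expr_weights[mcols(spans)$gene_id]
    b0 <- config@backgroundRate
    wmot <- config@motifWeight

    # propensity over every genomic position: gene positions at
    # expr*(b0 + w*motif), intergenic at intergenicWeight*b0
    prop <- rep(config@intergenicWeight * b0, glen)
    posStrand <- rep(NA_character_, glen)
    for (i in seq_along(spans)) {
        ii <- start(spans)[i]:end(spans)[i]
        prop[ii] <- expr[i] * b0
        posStrand[ii] <- as.character(strand(spans))[i]
    }
    pc <- sim@truth$planted_clusters
    for (j in seq_len(nrow(pc))) {
        ii <- pc$start[j]:pc$end[j]
        prop[ii] <- expr[pc$gene_id[j]] * (b0 + wmot)
    }
    if (sum(prop) <= 0) stop("zero total crosslink propensity")

    n <- config@nReads
    dup <- stats::runif(n) < config@pcrRate
    dup[1L] <- FALSE
    molOf <- integer(n)
    molOf[!dup] <- seq_len(sum(!dup))
    created <- cumsum(!dup)
    di <- which(dup)
    if (length(di))
        molOf[di] <- vapply(di, function(i) sample.int(created[i], 1L), 1L)
    nMol <- sum(!dup)

    xpos <- sample.int(glen, nMol, replace = TRUE, prob = prop)
    xstr <- posStrand[xpos]
    xstr[is.na(xstr)] <- sample(c("+", "-"), sum(is.na(xstr)), replace = TRUE)
    rlen <- sample(config@readLengthRange[1L]:config@readLengthRange[2L],
                   nMol, replace = TRUE)
    insStart <- ifelse(xstr == "+", xpos + 1L, pmax(1L, xpos - rlen))
    insEnd <- ifelse(xstr == "+", pmin(glen, xpos + rlen), xpos - 1L)
    ok <- insStart <= insEnd
    if (!all(ok)) { # crosslink at the chromosome edge: no insert possible
        keepMol <- which(ok)
        remap <- match(molOf, keepMol)
        keepRead <- !is.na(remap)
        molOf <- remap[keepRead]
        xpos <- xpos[keepMol]; xstr <- xstr[keepMol]
        insStart <- insStart[keepMol]; insEnd <- insEnd[keepMol]
        n <- sum(keepRead)
        nMol <- length(keepMol)
    }

    nN <- sum(strsplit(config@barcodeMask, "")[[1L]] == "N")
    bcs <- vapply(seq_len(nMol), function(i) .randomDna(nN), "")

    ins <- as.character(subseq(rep(genome[1L], nMol),
                               start = insStart, end = insEnd))
    neg <- xstr == "-"
    if (any(neg))
        ins[neg] <- as.character(reverseComplement(DNAStringSet(ins[neg])))

    readId <- sprintf("rep%d_read%06d", replicate, seq_len(n))
    maskCh <- strsplit(config@barcodeMask, "")[[1L]]
    maskCh <- maskCh[maskCh != "I"]
    xbCh <- strsplit(config@experimentBarcode, "")[[1L]]
    prefixFor <- function(bc) {
        bcCh <- strsplit(bc, "")[[1L]]
        iN <- 0L; iX <- 0L
        out <- character(length(maskCh))
        for (k in seq_along(maskCh)) {
            if (maskCh[k] == "N") { iN <- iN + 1L; out[k] <- bcCh[iN] }
            else { iX <- iX + 1L; out[k] <- xbCh[iX] }
        }
        paste(out, collapse = "")
    }
    prefix <- vapply(bcs, prefixFor, "", USE.NAMES = FALSE)

    seqs <- paste0(prefix[molOf], ins[molOf])
    reads <- DNAStringSet(setNames(seqs, readId))

    firstRead <- readId[match(seq_len(nMol), molOf)]
    prov <- data.frame(
        read_id = readId, replicate = replicate, molecule = molOf,
        duplicate_of = ifelse(firstRead[molOf] == readId, NA_character_,
                              firstRead[molOf]),
        chrom = chrom, crosslink_pos = xpos[molOf], strand = xstr[molOf],
        random_barcode = bcs[molOf], stringsAsFactors = FALSE)

    aln <- GRanges(chrom, IRanges(insStart[molOf], insEnd[molOf]),
                   strand = xstr[molOf], seqlengths = setNames(glen, chrom))
    mcols(aln)$name <- paste(readId, bcs[molOf], sep = ":")
    mcols(aln)$score <- 1L
    mcols(aln)$read_id <- readId
    mcols(aln)$random_barcode <- bcs[molOf]

    list(reads = reads, alignments = aln, provenance = prov)
}

#' Effective paralog activities under knockdown
#'
#' Applies the cross-regulatory de-repression model: knocking down the
#' abundant paralog releases repression of the scarce one (and weakly vice
#' versa), buffering the total activity that drives splicing.
#'
#' @param feedback a \linkS4class{FeedbackModel}.
#' @param kAlpha,kBeta residual activity fractions in [0, 1] after knockdown
#'   (1 = untreated).
#' @return Named numeric vector with \code{e_alpha}, \code{e_beta} and their
#'   sum \code{total}.
#' @examples
#' effectiveActivities(feedbackModel(), kAlpha = 1, kBeta = 0.05)
#' @export
effectiveActivities <- function(feedback, kAlpha = 1, kBeta = 1) {
    stopifnot(is(feedback, "FeedbackModel"))
    if (any(c(kAlpha, kBeta) < 0) || any(c(kAlpha, kBeta) > 1))
        stop("knockdown residuals must be in [0, 1]")
    eB0 <- kBeta * feedback@eBeta
    eA0 <- kAlpha * feedback@eAlpha
    eA <- eA0 * (1 + feedback@gamma * feedback@eBeta) /
        (1 + feedback@gamma * eB0)
    eB <- eB0 * (1 + feedback@gammaRev * feedback@eAlpha) /
        (1 + feedback@gammaRev * eA0)
    c(e_alpha = eA, e_beta = eB, total = eA + eB)
}

#' True PSI under the feedback model
#'
#' @param feedback a \linkS4class{FeedbackModel}.
#' @param d dependence coefficients (one per exon, >= 0).
#' @param kAlpha,kBeta residual activities after knockdown.
#' @return PSI values in [0, 100], one per element of \code{d}.
#' @export
truePsi <- function(feedback, d, kAlpha = 1, kBeta = 1) {
    act <- effectiveActivities(feedback, kAlpha, kBeta)
    100 * plogis(feedback@theta0 + d * act[["total"]])
}

.CONDITIONS <- c("control", "kd_alpha", "kd_beta", "kd_double")

#' Simulate replicate splicing measurements under knockdown
#'
#' Assigns each cassette exon a dependence coefficient (drawn from
#' \code{dRange} for exons carrying a planted motif run, 0 otherwise),
#' computes noise-free true PSI per condition from the feedback model, adds
#' Gaussian replicate noise clipped to [0, 100], and emits included/skipped
#' molar quantities per sample (included = PSI/100 of a fixed per-sample
#' total).
#'
#' @param sim a \linkS4class{ClipSimulation}.
#' @param feedback a \linkS4class{FeedbackModel}.
#' @param conditions subset of \code{control, kd_alpha, kd_beta, kd_double}.
#' @param nReplicates replicates per condition (default from the config).
#' @param kdResidual residual activity fraction of a knocked-down factor.
#' @param d optional named vector of dependence coefficients overriding the
#'   default assignment (names = exon ids).
#' @param outdir optional directory; writes \code{psi.tsv} (measurements)
#'   and \code{true_psi.tsv}.
#' @return List with \code{measurements} (exon_id, sample_id, condition,
#'   included, skipped), \code{true_psi} (long table exon x condition),
#'   \code{d} (named dependence coefficients) and \code{activities}
#'   (per-condition effective activities).
#' @export
simulateSplicing <- function(sim, feedback = feedbackModel(),
                             conditions = .CONDITIONS,
                             nReplicates = NULL, kdResidual = 0.05,
                             d = NULL, outdir = NULL) {
    stopifnot(is(sim, "ClipSimulation"), is(feedback, "FeedbackModel"))
    bad <- setdiff(conditions, .CONDITIONS)
    if (length(bad))
        stop("unknown condition label(s): ", paste(bad, collapse = ", "))
    config <- sim@config
    if (is.null(nReplicates)) nReplicates <- config@nReplicates

    ex <- sim@exons[mcols(sim@exons)$exon_class == "cassette"]
    exonId <- paste0(mcols(ex)$gene_id, ".cas")
    res <- .withSeed(.subSeed(config@seed, 2000L), {
        if (is.null(d)) {
            d <- ifelse(mcols(ex)$planted,
                        stats::runif(length(ex), feedback@dRange[1L],
                                     feedback@dRange[2L]), 0)
            names(d) <- exonId
        } else {
            d <- d[exonId]
            if (anyNA(d)) stop("d must name every cassette exon")
        }
        kk <- list(control = c(1, 1), kd_alpha = c(kdResidual, 1),
                   kd_beta = c(1, kdResidual),
                   kd_double = c(kdResidual, kdResidual))
        act <- vapply(conditions, function(cn)
            effectiveActivities(feedback, kk[[cn]][1L], kk[[cn]][2L]),
            numeric(3))
        truth <- do.call(rbind, lapply(conditions, function(cn)
            data.frame(exon_id = names(d), condition = cn,
                       psi = truePsi(feedback, unname(d),
                                     kk[[cn]][1L], kk[[cn]][2L]))))
        meas <- do.call(rbind, lapply(conditions, function(cn) {
            tp <- truth$psi[truth$condition == cn]
            do.call(rbind, lapply(seq_len(nReplicates), function(r) {
                psi <- pmin(100, pmax(0, tp + stats::rnorm(length(tp), 0,
                                                    feedback@sigmaRep)))
                data.frame(exon_id = names(d),
                           sample_id = sprintf("%s_rep%d", cn, r),
                           condition = cn, included = psi,
                           skipped = 100 - psi)
            }))
        }))
        list(measurements = meas, true_psi = truth, d = d,
             activities = t(act))
    })
    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        write.table(res$measurements, file.path(outdir, "psi.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(res$true_psi, file.path(outdir, "true_psi.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res
}
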