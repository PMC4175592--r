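#' Demo pipeline configuration
#'
#' A small, fully specified configuration for the end-to-end pipeline on
#' simulated data. Every stage constant (11-nt minimum insert, 15-nt
#' cluster window, 300-nt screen flank, pentamers, top-10 k-mers, FDR 0.05,
#' 15/40-point response thresholds, 95% constitutive cut-off) is surfaced
#' as a named parameter.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @return Nested configuration list understood by
#'   \code{\link{runPipeline}}.
#' @export
demoConfig <- function(outdir = tempfile("clipscreen_"), seed = 1L) {
    list(
        outdir = outdir, seed = as.integer(seed), replicates = 2L,
        sim = list(nGenes = 12L, nReads = 6000L, motifWeight = 50,
                   backgroundRate = 1, pcrRate = 0.3,
                   barcodeMask = "NNNXXXXNN", experimentBarcode = "GGTT",
                   motifFraction = 0.4, ncrnaFraction = 0.1),
        preprocess = list(minLen = 11L),
        clusters = list(alpha = 0.05, maxGap = 15L, R = 50L),
        kmers = list(flank = 30L, k = 5L, nTop = 10L, R = 50L),
        screen = list(flank = 300L),
        psi = list(responsiveThreshold = 15, strongThreshold = 40,
                   constitutiveThreshold = 95, alpha = 0.05,
                   minBuffer = 15, maxSingle = 10))
}

.configError <- function(...) {
    stop(errorCondition(paste0(...), class = c("clipscreen_config_error",
                                               "error", "condition")))
}

.validateConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (!is.list(config)) .configError("config must be a list or YAML file")
    if (is.null(config$outdir)) .configError("config lacks an outdir")
    if (is.null(config$seed)) .configError("config lacks a seed")
    defaults <- demoConfig()
    for (sec in c("sim", "preprocess", "clusters", "kmers", "screen",
                  "psi")) {
        if (is.null(config[[sec]])) config[[sec]] <- list()
        miss <- setdiff(names(defaults[[sec]]), names(config[[sec]]))
        config[[sec]][miss] <- defaults[[sec]][miss]
    }
    if (is.null(config$replicates)) config$replicates <- 2L
    thr <- unlist(config$psi[c("responsiveThreshold", "strongThreshold",
                               "constitutiveThreshold")])
    if (any(thr <= 0)) .configError("PSI thresholds must be positive")
    if (config$clusters$alpha <= 0 || config$clusters$alpha >= 1)
        .configError("alpha must be in (0, 1)")
    config
}

.stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
        if (inherits(e, "clipscreen_config_error")) stop(e)
        stop("pipeline stage '", name, "' failed: ",
             conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
}

#' Run the full pipeline on simulated data
#'
#' simulate -> preprocess -> clusters -> kmers -> density -> regions ->
#' screen -> psi -> report, writing every stage output plus a run manifest
#' (parameters, seed, package version, md5 checksums) to the configured
#' output directory. All randomness derives from the configured seed, so a
#' rerun with the same configuration reproduces every file byte for byte
#' (the manifest timestamp aside).
#'
#' @param config configuration list (see \code{\link{demoConfig}}) or path
#'   to a YAML file with the same structure.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config) {
    config <- .validateConfig(config)
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

    sim <- .stage("simulate", {
        cfg <- do.call(simConfig, c(list(seed = config$seed,
                                         nReplicates = config$replicates),
                                    config$sim))
        s <- generateGenome(cfg, outdir = outdir)
        for (r in seq_len(config$replicates)) simulateIclip(s, r, outdir)
        simulateSplicing(s, outdir = outdir)
        s
    })
    genome <- simGenome(sim)
    exons <- simGenes(sim)
    spans <- geneSpans(sim)

    pp <- .stage("preprocess", {
        counts <- list(); cdnasAll <- list()
        for (r in seq_len(config$replicates)) {
            fq <- file.path(outdir, sprintf("rep%d.fastq", r))
            bed <- file.path(outdir, sprintf("rep%d.bed", r))
            bc <- extractBarcodes(fq,
                                  barcodeMask = config$sim$barcodeMask,
                                  minLen = config$preprocess$minLen,
                                  expectedBarcode =
                                      config$sim$experimentBarcode)
            aln <- readAlignmentsBed(bed)
            aln <- aln[mcols(aln)$read_id %in% bc$reads$read_id]
            cdnas <- deduplicate(aln)
            counts[[r]] <- data.frame(
                replicate = r,
                total_reads = nrow(bc$reads) + bc$rejected_short +
                    bc$rejected_barcode,
                retained_reads = nrow(bc$reads),
                unique_cdnas = length(cdnas))
            cdnasAll[[r]] <- cdnas
        }
        cdnas <- do.call(c, cdnasAll)
        sites <- callCrosslinkSites(cdnas)
        writeAlignmentsBed(cdnas, file.path(outdir, "unique_cdnas.bed"))
        writeSitesBed(sites, file.path(outdir, "crosslink_sites.bed"))
        summary <- do.call(rbind, counts)
        write.table(summary, file.path(outdir, "preprocess_summary.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        list(cdnas = cdnas, sites = sites, summary = summary)
    })

    cl <- .stage("clusters", {
        cc <- callClusters(pp$sites, spans, R = config$clusters$R,
                           alpha = config$clusters$alpha,
                           maxGap = config$clusters$maxGap,
                           seed = .subSeed(config$seed, 31L))
        df <- data.frame(
            chrom = as.character(seqnames(cc$clusters)),
            start = start(cc$clusters) - 1L, end = end(cc$clusters),
            name = sprintf("cluster%03d", seq_along(cc$clusters)),
            score = mcols(cc$clusters)$total_height,
            strand = as.character(strand(cc$clusters)),
            n_sites = mcols(cc$clusters)$n_sites,
            fdr = mcols(cc$clusters)$fdr)
        write.table(df, file.path(outdir, "clusters.bed"), sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
        cc
    })

    km <- .stage("kmers", {
        z <- kmerZscores(pp$sites, spans, genome,
                         flank = config$kmers$flank, k = config$kmers$k,
                         R = config$kmers$R,
                         seed = .subSeed(config$seed, 32L))
        write.table(z, file.path(outdir, "kmers.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        z
    })

    dens <- .stage("density", {
        top <- topKmers(km, nTop = config$kmers$nTop)
        cas <- exons[mcols(exons)$exon_class == "cassette"]
        seqs <- Biostrings::extractAt(genome[[1L]],
                                      IRanges(start(cas), end(cas)))
        neg <- as.character(strand(cas)) == "-"
        if (any(neg)) seqs[neg] <- reverseComplement(seqs[neg])
        names(seqs) <- paste0(mcols(cas)$gene_id, ".cas")
        d <- bindingDensity(seqs, top)
        write.table(d, file.path(outdir, "density.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        list(top_kmers = top, density = d)
    })

    reg <- .stage("regions", {
        idx <- buildRegionIndex(exons)
        dist <- sizeNormalize(assignTags(pp$cdnas, idx), idx)
        write.table(dist, file.path(outdir, "regions.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        dist
    })

    scr <- .stage("screen", {
        sc <- rankCandidates(scoreExons(pp$cdnas, exons,
                                        flank = config$screen$flank))
        write.table(sc, file.path(outdir, "screen.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        sc
    })

    resp <- .stage("psi", {
        meas <- read.table(file.path(outdir, "psi.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
        dp <- deltaPsi(meas)
        cls <- classifyResponse(
            dp, responsiveThreshold = config$psi$responsiveThreshold,
            strongThreshold = config$psi$strongThreshold,
            constitutiveThreshold = config$psi$constitutiveThreshold,
            alpha = config$psi$alpha)
        comp <- compensationTest(dp, minBuffer = config$psi$minBuffer,
                                 maxSingle = config$psi$maxSingle)
        out <- merge(merge(dp, cls[, setdiff(colnames(cls),
                                             "dpsi_double")],
                           by = "exon_id"), comp, by = "exon_id")
        write.table(out, file.path(outdir, "psi_response.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        out
    })

    rpt <- .stage("report", makeReport(outdir))

    manifest <- list(
        package = as.character(utils::packageVersion("clipScreen")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
        seed = config$seed,
        parameters = config[c("replicates", "sim", "preprocess",
                              "clusters", "kmers", "screen", "psi")],
        checksums = as.list(tools::md5sum(
            sort(list.files(outdir, pattern = "\\.(fa|gtf|fastq|bed|tsv)$",
                            full.names = TRUE)))))
    names(manifest$checksums) <- basename(names(manifest$checksums))
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
    invisible(list(sim = sim, preprocess = pp, clusters = cl, kmers = km,
                   density = dens, regions = reg, screen = scr,
                   response = resp, report = rpt, manifest = manifest))
}

#' Summarize a pipeline run
#'
#' Builds the per-replicate read/cDNA/crosslink counts table (recounted
#' from the raw files) and the candidate-exon table joining enrichment
#' scores, PSI responses, classes and binding-site densities. Sections
#' whose inputs are missing are skipped and listed in \code{missing}.
#'
#' @param outdir a pipeline output directory.
#' @return List with \code{counts}, \code{candidates} and \code{missing};
#'   the tables are also written to \code{report_counts.tsv} and
#'   \code{report_candidates.tsv}.
#' @export
makeReport <- function(outdir) {
    missing <- character()
    fqs <- sort(list.files(outdir, pattern = "^rep[0-9]+\\.fastq$",
                           full.names = TRUE))
    counts <- NULL
    if (length(fqs)) {
        counts <- do.call(rbind, lapply(fqs, function(fq) {
            r <- as.integer(sub("^rep([0-9]+)\\.fastq$", "\\1",
                                basename(fq)))
            bed <- file.path(outdir, sprintf("rep%d.bed", r))
            aln <- readAlignmentsBed(bed)
            cdnas <- deduplicate(aln)
            sites <- suppressWarnings(callCrosslinkSites(cdnas))
            data.frame(replicate = r,
                       total_reads = length(readReadsFastq(fq)),
                       unique_cdnas = length(cdnas),
                       crosslink_sites = length(sites))
        }))
        write.table(counts, file.path(outdir, "report_counts.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    } else missing <- c(missing, "counts")

    cand <- NULL
    scr <- file.path(outdir, "screen.tsv")
    if (file.exists(scr)) {
        cand <- read.table(scr, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
        for (f in c("psi_response.tsv", "density.tsv")) {
            fp <- file.path(outdir, f)
            if (file.exists(fp)) {
                tab <- read.table(fp, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
                cand <- merge(cand, tab, by = "exon_id", all.x = TRUE)
            } else missing <- c(missing, f)
        }
        cand <- cand[order(cand$rank), ]
        write.table(cand, file.path(outdir, "report_candidates.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    } else missing <- c(missing, "candidates")
    list(counts = counts, candidates = cand, missing = missing)
}
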