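test_that("genome generation is deterministic and plants the configured motif runs", {
    cfg <- simConfig(seed = 3, nGenes = 50)
    sim <- generateGenome(cfg)

    # exactly round(nGenes * motifFraction) genes carry planted runs
    pl <- simTruth(sim)$planted_clusters
    expect_equal(nrow(pl), 20L)
    expect_equal(sum(mcols(simGenes(sim))$planted), 20L)
    # ncRNA fraction honoured
    ex <- simGenes(sim)
    byGene <- split(as.character(mcols(ex)$biotype), mcols(ex)$gene_id)
    expect_equal(sum(vapply(byGene, `[`, "", 1L) == "ncRNA"), 5L)

    # per gene: exons sorted, non-overlapping; cassette exons flanked
    for (gid in unique(mcols(ex)$gene_id)) {
        g <- ex[mcols(ex)$gene_id == gid]
        expect_false(is.unsorted(start(g)))
        expect_true(all(start(g)[-1] > end(g)[-length(g)]))
        ci <- which(mcols(g)$exon_class == "cassette")
        if (length(ci)) expect_true(ci > 1 && ci < length(g))
    }
    # planted runs really are in the sequence, transcript-oriented
    gseq <- simGenome(sim)[[1]]
    for (j in seq_len(nrow(pl))) {
        s <- as.character(Biostrings::subseq(gseq, pl$start[j], pl$end[j]))
        if (pl$strand[j] == "-")
            s <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(s)))
        expect_identical(s, pl$motif_run[j])
    }

    # byte-identical files from the same seed
    d1 <- tempfile(); d2 <- tempfile()
    generateGenome(simConfig(seed = 9, nGenes = 8), outdir = d1)
    generateGenome(simConfig(seed = 9, nGenes = 8), outdir = d2)
    for (f in c("genome.fa", "genes.gtf"))
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))))
})

test_that("gene models round-trip through GTF", {
    sim <- generateGenome(simConfig(seed = 5, nGenes = 6))
    fp <- tempfile(fileext = ".gtf")
    writeGenesGtf(simGenes(sim), fp)
    back <- readGenesGtf(fp)
    orig <- simGenes(sim)
    expect_equal(length(back), length(orig))
    expect_equal(start(back), start(orig))
    expect_equal(as.character(mcols(back)$region),
                 as.character(mcols(orig)$region))
    expect_equal(as.character(mcols(back)$exon_class),
                 as.character(mcols(orig)$exon_class))
})

test_that("iCLIP reads truncate at the crosslink and respect the duplication model", {
    sim <- generateGenome(simConfig(seed = 2, nGenes = 5, nReads = 2000,
                                    pcrRate = 0))
    ic <- simulateIclip(sim, 1)
    # no duplication: every read is its own molecule
    expect_equal(length(ic$reads), 2000L)
    expect_equal(length(unique(ic$provenance$molecule)), 2000L)
    expect_true(all(is.na(ic$provenance$duplicate_of)))
    # conservation: exactly one provenance record per emitted read
    expect_identical(ic$provenance$read_id, names(ic$reads))

    # read starts one nucleotide downstream of the crosslink
    aln <- ic$alignments
    pos <- ifelse(as.character(strand(aln)) == "+", start(aln) - 1L,
                  end(aln) + 1L)
    expect_equal(pos, ic$provenance$crosslink_pos)

    # insert sequence matches the genome, strand-aware
    gseq <- simGenome(sim)[[1]]
    mlen <- sum(strsplit("NNNXXXXNN", "")[[1]] %in% c("N", "X"))
    for (i in c(1L, 50L, 777L)) {
        ins <- substring(as.character(ic$reads[[i]]), mlen + 1L)
        ref <- as.character(Biostrings::subseq(gseq, start(aln)[i],
                                               end(aln)[i]))
        if (as.character(strand(aln))[i] == "-")
            ref <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(ref)))
        expect_identical(ins, ref)
    }

    # with duplication, duplicates copy barcode and position
    ic2 <- simulateIclip(generateGenome(simConfig(seed = 2, nGenes = 5,
                                                  nReads = 2000,
                                                  pcrRate = 0.5)), 1)
    pv <- ic2$provenance
    expect_lt(length(unique(pv$molecule)), nrow(pv))
    dups <- pv[!is.na(pv$duplicate_of), ]
    src <- pv[match(dups$duplicate_of, pv$read_id), ]
    expect_equal(dups$random_barcode, src$random_barcode)
    expect_equal(dups$crosslink_pos, src$crosslink_pos)
})

test_that("crosslink propensity follows the expression-times-motif model", {
    # w = 0: positions uniform within an expressed gene
    sim <- generateGenome(simConfig(seed = 4, nGenes = 4, nReads = 8000,
                                    motifWeight = 0, pcrRate = 0,
                                    exprWeights = 1))
    ic <- simulateIclip(sim, 1)
    sp <- geneSpans(sim)
    g <- sp[1]
    inG <- ic$provenance$crosslink_pos >= start(g) &
        ic$provenance$crosslink_pos <= end(g)
    posRel <- ic$provenance$crosslink_pos[inG] - start(g) + 1L
    cuts <- cut(posRel, breaks = seq(0, width(g), length.out = 11))
    expect_gt(chisq.test(table(cuts))$p.value, 0.01)

    # w = 50: crosslinks concentrate in the planted run at the share
    # predicted by the propensity ratio
    sim2 <- generateGenome(simConfig(seed = 4, nGenes = 1, nReads = 5000,
                                     motifWeight = 50, motifFraction = 1,
                                     ncrnaFraction = 0, pcrRate = 0))
    ic2 <- simulateIclip(sim2, 1)
    pl <- simTruth(sim2)$planted_clusters
    inRun <- ic2$provenance$crosslink_pos >= (pl$start - 5L) &
        ic2$provenance$crosslink_pos <= (pl$end + 5L)
    share <- mean(inRun)
    exp_share <- pl$expected_share
    se <- sqrt(exp_share * (1 - exp_share) / nrow(ic2$provenance))
    expect_lt(abs(share - exp_share), 4 * se + 0.02)
    # and far above the uniform expectation
    unif <- (pl$end - pl$start + 11) / width(geneSpans(sim2))
    expect_gt(share, 10 * unif)
})

test_that("splicing simulation matches the closed-form feedback model", {
    fb <- feedbackModel(eAlpha = 0.1, eBeta = 1.0, gamma = 10,
                        gammaRev = 0, theta0 = -1.5)
    # hand evaluation: e_beta = 0.05; e_alpha = 0.1 * 11 / 1.5
    act <- effectiveActivities(fb, kAlpha = 1, kBeta = 0.05)
    expect_equal(act[["e_beta"]], 0.05, tolerance = 1e-12)
    expect_equal(act[["e_alpha"]], 0.1 * 11 / 1.5, tolerance = 1e-12)
    expect_equal(truePsi(fb, d = 2, kAlpha = 1, kBeta = 0.05),
                 100 * plogis(-1.5 + 2 * (0.1 * 11 / 1.5 + 0.05)),
                 tolerance = 1e-9)
    # no knockdown: activities equal baselines, PSI equals control PSI
    act0 <- effectiveActivities(feedbackModel())
    expect_equal(act0[["e_alpha"]], 0.15, tolerance = 1e-12)
    expect_equal(act0[["e_beta"]], 1.0, tolerance = 1e-12)

    # dependence-free exons do not respond (up to replicate noise)
    sim <- generateGenome(simConfig(seed = 6, nGenes = 6,
                                    motifFraction = 0))
    ss <- simulateSplicing(sim, feedbackModel(sigmaRep = 3))
    dp <- deltaPsi(ss$measurements)
    expect_lt(mean(abs(dp$dpsi_kd_double)), 3)
    # and with k = 1 everywhere the truth equals control PSI exactly
    ctl <- ss$true_psi[ss$true_psi$condition == "control", ]
    expect_equal(ctl$psi,
                 truePsi(feedbackModel(sigmaRep = 3), unname(ss$d)),
                 tolerance = 1e-12)

    expect_error(simulateSplicing(sim, conditions = c("control", "mock")),
                 "unknown condition")
})

test_that("feedback asymmetry and compensation hold on noise-free truth", {
    fb <- feedbackModel() # E_beta >> E_alpha, gamma large
    base <- effectiveActivities(fb)
    aKD <- effectiveActivities(fb, kAlpha = 0.05)
    bKD <- effectiveActivities(fb, kBeta = 0.05)
    # beta-KD raises e_alpha more than alpha-KD raises e_beta
    expect_gt(bKD[["e_alpha"]] - base[["e_alpha"]],
              aKD[["e_beta"]] - base[["e_beta"]])
    # single-KD PSI shifts are smaller than double-KD shifts for all d > 0
    for (d in c(0.5, 1, 2, 4)) {
        p0 <- truePsi(fb, d)
        dA <- abs(truePsi(fb, d, kAlpha = 0.05) - p0)
        dB <- abs(truePsi(fb, d, kBeta = 0.05) - p0)
        dD <- abs(truePsi(fb, d, kAlpha = 0.05, kBeta = 0.05) - p0)
        expect_lt(max(dA, dB), dD)
    }
})
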