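test_that("k-mer counting matches a brute-force scan and conserves totals", {
    g <- DNAStringSet(c(chr1 = "TTAGAAATT"))
    s <- GRanges("chr1", IRanges(5, 5), strand = "+")
    cnt <- kmerCounts(s, g, flank = 2, k = 5) # window [3,7] = "AGAAA"
    expect_equal(unname(cnt["AGAAA"]), 1L)
    expect_equal(sum(cnt), 1L)

    # empty site list: all-zero counts
    cnt0 <- kmerCounts(GRanges(), g, flank = 2, k = 5)
    expect_equal(sum(cnt0), 0L)
    expect_equal(length(cnt0), 4^5)
    expect_error(kmerCounts(s, g, flank = 1, k = 5), "window")

    # brute-force oracle on random windows, both strands
    set.seed(31)
    gs <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
    genome <- DNAStringSet(c(chrX = gs))
    pos <- sample(20:380, 12)
    sites <- GRanges("chrX", IRanges(pos, width = 1),
                     strand = sample(c("+", "-"), 12, replace = TRUE))
    got <- kmerCounts(sites, genome, flank = 7, k = 5)
    brute <- integer(4^5)
    names(brute) <- names(got)
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    for (i in seq_along(sites)) {
        w <- substr(gs, pos[i] - 7, pos[i] + 7)
        if (as.character(strand(sites))[i] == "-") w <- rc(w)
        for (j in 1:(nchar(w) - 4)) {
            km <- substr(w, j, j + 4)
            brute[km] <- brute[km] + 1L
        }
    }
    expect_equal(as.integer(got), as.integer(brute))
    expect_equal(sum(got), attr(got, "total_positions"))
})

test_that("planted AGAA-rich runs dominate the pentamer enrichment ranking", {
    st <- plantedStudy()
    z <- suppressMessages(
        kmerZscores(st$sites, st$spans, simGenome(st$sim), R = 100,
                    seed = 22))
    top <- suppressMessages(topKmers(z, 10))
    expect_gte(sum(grepl("AGAA", top) | grepl("GAA", top)), 8)
    expect_true("AGAAG" %in% top)
    # degenerate k-mers (zero null variance) are flagged with z = 0
    expect_true(all(z$z[z$degenerate] == 0))
    # rank 1 is the highest z
    expect_equal(z$kmer[z$rank == 1], top[1])
})

test_that("uniform (motif-free) sites give no extreme pentamer z-scores", {
    sim <- generateGenome(simConfig(seed = 41, nGenes = 5, nReads = 3000,
                                    motifWeight = 0))
    ic <- simulateIclip(sim, 1)
    sites <- callCrosslinkSites(deduplicate(ic$alignments))
    z <- suppressMessages(
        kmerZscores(sites, geneSpans(sim), simGenome(sim), R = 50,
                    seed = 42))
    expect_lt(max(abs(z$z)), 5)
})

test_that("top-kmer selection breaks ties lexicographically", {
    sc <- data.frame(kmer = c("CCCCC", "AAAAA", "GGGGG", "TTTTT"),
                     z = c(5, 1, 1, 0.5), degenerate = FALSE)
    expect_message(tk <- topKmers(sc, 2), "tie")
    expect_equal(tk, c("CCCCC", "AAAAA"))
    expect_warning(all3 <- topKmers(sc[1:2, ], 10), "returning all")
    expect_equal(length(all3), 2L)
})

test_that("binding density is the union coverage of k-mer hits", {
    d <- bindingDensity(c(e1 = "CAGAAGTTTT"), "AGAAG")
    expect_equal(d$covered, 5L)
    expect_equal(d$density_pct, 50)

    expect_equal(bindingDensity(c(x = "CCCCCCCC"), "AGAAG")$density_pct, 0)

    # overlapping occurrences at 0 and 3 cover the union (8 of 8 nt)
    d2 <- bindingDensity(c(x = "AGAAGAAG"), "AGAAG")
    expect_equal(d2$covered, 8L)
    expect_equal(d2$density_pct, 100)

    # exon shorter than k: density 0 with a flag
    d3 <- bindingDensity(c(x = "AGA"), "AGAAG")
    expect_true(d3$too_short)
    expect_equal(d3$density_pct, 0)

    # invariance under reverse complement of both exon and k-mer set
    set.seed(5)
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    kms <- c("AGAAG", "GAAGA", "TTCTT")
    expect_equal(bindingDensity(s, kms)$density_pct,
                 bindingDensity(rc(s), vapply(kms, rc, ""))$density_pct)
})

test_that("density comparison reproduces pooled-variance arithmetic and has power", {
    idg <- compareDensity(c(3, 4, 5), c(3, 4, 5))
    expect_equal(idg$t, 0)
    expect_equal(idg$p, 1)

    a <- c(10, 12, 14); b <- c(1, 2, 3)
    got <- compareDensity(a, b)
    ref <- pooledT(a, b)
    expect_equal(got$t, ref$t, tolerance = 1e-9)
    expect_equal(got$p, ref$p, tolerance = 1e-9)
    expect_equal(got$df, 4)

    # planted vs motif-free exons separate at n = 20/20
    st <- plantedStudy()
    z <- suppressMessages(
        kmerZscores(st$sites, st$spans, simGenome(st$sim), R = 50,
                    seed = 52))
    top <- topKmers(z, 10)
    ex <- simGenes(st$sim)
    cas <- ex[mcols(ex)$exon_class == "cassette"]
    seqs <- Biostrings::extractAt(simGenome(st$sim)[[1]],
                                  IRanges(start(cas), end(cas)))
    neg <- as.character(strand(cas)) == "-"
    seqs[neg] <- Biostrings::reverseComplement(seqs[neg])
    names(seqs) <- mcols(cas)$gene_id
    dens <- bindingDensity(seqs, top)
    pl <- dens$exon_id %in% st$planted$gene_id
    cmp <- compareDensity(head(dens$density_pct[pl], 20),
                          head(dens$density_pct[!pl], 20))
    expect_lt(cmp$p, 0.01)
    expect_gt(cmp$mean_a, cmp$mean_b)
})
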