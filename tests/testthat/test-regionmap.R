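test_that("region index sizes match hand-computed totals", {
    ex <- toyAnnotation()
    # hand arithmetic: UTR5 50, ORF 60, UTR3 60, ncRNA 50+40,
    # introns g1 (151..200, 261..400) = 190, g2 (751..800) = 50,
    # intergenic = 1000 - 360 - 90 - 240 = 410
    idx <- buildRegionIndex(ex)
    expect_equal(unname(idx$sizes["5'UTR"]), 50)
    expect_equal(unname(idx$sizes["ORF"]), 60)
    expect_equal(unname(idx$sizes["3'UTR"]), 60)
    expect_equal(unname(idx$sizes["ncRNA"]), 90)
    expect_equal(unname(idx$sizes["intron"]), 240)
    expect_equal(unname(idx$sizes["intergenic"]), 500)
    expect_equal(sum(idx$sizes), 1000)

    # the same index from a GTF round trip
    fp <- tempfile(fileext = ".gtf")
    writeGenesGtf(ex, fp)
    idx2 <- buildRegionIndex(fp, seqlens = c(chr1 = 1000L))
    expect_equal(idx2$sizes, idx$sizes)

    expect_error(buildRegionIndex(readGenesGtf(fp)), "lengths")
})

test_that("tags are assigned by crosslink position with precedence", {
    ex <- toyAnnotation()
    idx <- buildRegionIndex(ex)
    # width-1 positions, one per class
    pos <- GRanges("chr1", IRanges(c(120, 230, 420, 820, 180, 50),
                                   width = 1),
                   strand = c("+", "+", "+", "-", "+", "+"))
    dist <- assignTags(pos, idx)
    expect_equal(dist$count[match(c("5'UTR", "ORF", "3'UTR", "ncRNA",
                                    "intron", "intergenic"), dist$class)],
                 c(1L, 1L, 1L, 1L, 1L, 1L))
    expect_equal(sum(dist$raw_pct), 100, tolerance = 0.01)

    # full cDNAs are located by their crosslink position: a + tag starting
    # at 232 belongs to the ORF via position 231 even if it spans the UTR3
    tag <- GRanges("chr1", IRanges(232, 420), strand = "+",
                   seqlengths = c(chr1 = 1000))
    dist2 <- assignTags(tag, idx)
    expect_equal(dist2$count[dist2$class == "ORF"], 1L)
    expect_equal(sum(dist2$count), 1L)

    expect_error(assignTags(GRanges(), idx), "no tags")

    # all tags in one intron
    intr <- GRanges("chr1", IRanges(rep(170, 5), width = 1), strand = "+")
    d3 <- assignTags(intr, idx)
    expect_equal(d3$raw_pct[d3$class == "intron"], 100)
})

test_that("size normalization follows the relative-size correction", {
    # counts 50/50 on relative sizes 1%/99%
    dist <- structure(data.frame(class = c("ORF", "intron"),
                                 count = c(50L, 50L),
                                 raw_pct = c(50, 50),
                                 size = c(10, 990)),
                      class = c("regionDistribution", "data.frame"))
    nd <- sizeNormalize(dist)
    # densities 5 and 5/99 give exactly 99% / 1%
    expect_equal(nd$norm_pct, c(99, 1), tolerance = 1e-9)
    expect_equal(sum(nd$norm_pct), 100, tolerance = 0.01)

    # equal sizes: normalized equals raw
    d2 <- structure(data.frame(class = c("a", "b"), count = c(30L, 70L),
                               raw_pct = c(30, 70), size = c(100, 100)),
                    class = c("regionDistribution", "data.frame"))
    expect_equal(sizeNormalize(d2)$norm_pct, c(30, 70))

    # scale invariance: multiplying all sizes leaves percentages unchanged
    d3 <- d2; d3$size <- d3$size * 7
    expect_equal(sizeNormalize(d3)$norm_pct, sizeNormalize(d2)$norm_pct)

    # three-class toy by hand to full precision
    d4 <- structure(data.frame(class = c("a", "b", "c"),
                               count = c(10L, 20L, 30L),
                               raw_pct = c(100 / 6, 200 / 6, 300 / 6),
                               size = c(5, 10, 100)),
                    class = c("regionDistribution", "data.frame"))
    dens <- c(2, 2, 0.3)
    expect_equal(sizeNormalize(d4)$norm_pct, 100 * dens / sum(dens),
                 tolerance = 1e-9)

    # a zero-size class holding tags is an error
    d5 <- d2; d5$size[1] <- 0
    expect_error(sizeNormalize(d5), "zero size")
})

test_that("simulated tag classes match the ground truth provenance", {
    st <- plantedStudy()
    idx <- buildRegionIndex(simGenes(st$sim))
    dist <- assignTags(st$cdnas, idx)
    expect_equal(sum(dist$raw_pct), 100, tolerance = 0.01)
    nd <- sizeNormalize(dist, idx)
    expect_equal(sum(nd$norm_pct), 100, tolerance = 0.01)
    # the planted runs sit in cassette (ORF) exons, so exonic classes are
    # strongly enriched after size correction
    exonic <- sum(nd$norm_pct[nd$class %in% c("5'UTR", "ORF", "3'UTR")])
    raw_exonic <- sum(nd$raw_pct[nd$class %in% c("5'UTR", "ORF", "3'UTR")])
    expect_gt(exonic, raw_exonic)

    # independent recount of the intron class from crosslink positions
    pv <- st$iclip$provenance
    sites1 <- callCrosslinkSites(st$cdnas)
    intr <- idx$classes[["intron"]]
    inIntron <- sum(countOverlaps(
        GRanges(pv$chrom[1], IRanges(start(sites1), width = 1)), intr) *
        mcols(sites1)$score)
    expect_equal(dist$count[dist$class == "intron"], inIntron)
})
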