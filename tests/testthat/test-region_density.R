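test_that("plus-strand gene regions match the printed offsets exactly", {
    si <- toy_seqinfo(c(chr1 = 30000L))
    genes <- data.frame(chrom = "chr1", strand = "+", tss = 10000L,
                        tts = 20000L)
    rs <- buildRegions(genes, si)
    asDF <- function(lbl) {
        gr <- regionRanges(rs)[[lbl]]
        data.frame(start0 = GenomicRanges::start(gr) - 1L,
                   end0 = GenomicRanges::end(gr))
    }
    expect_equal(asDF("promoter"), data.frame(start0 = 9000L, end0 = 9750L))
    expect_equal(asDF("TSS"), data.frame(start0 = 9750L, end0 = 10250L))
    expect_equal(asDF("TTS"), data.frame(start0 = 19750L, end0 = 20250L))
    expect_equal(asDF("gene_body"),
                 data.frame(start0 = 10250L, end0 = 19750L))
    expect_equal(sum(regionWidths(rs)), 30000)
})

test_that("minus-strand genes mirror the geometry", {
    si <- toy_seqinfo(c(chr1 = 30000L))
    genes <- data.frame(chrom = "chr1", strand = "-", tss = 20000L,
                        tts = 10000L)
    rs <- buildRegions(genes, si)
    prom <- regionRanges(rs)$promoter
    expect_equal(GenomicRanges::start(prom) - 1L, 20250L)  # upstream = right
    expect_equal(GenomicRanges::end(prom), 21000L)
    body <- regionRanges(rs)$gene_body
    expect_equal(GenomicRanges::start(body) - 1L, 10250L)
    expect_equal(GenomicRanges::end(body), 19750L)
})

test_that("labels partition the genome under the fixed precedence", {
    si <- toy_seqinfo(c(chr1 = 6000L, chr2 = 3000L))
    ## overlapping genes, one on each strand, promoters colliding
    genes <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        strand = c("+", "-", "+"),
                        tss = c(2000L, 3100L, 800L),
                        tts = c(2900L, 2200L, 2500L))
    rs <- buildRegions(genes, si)
    ## exact partition: total width == genome size
    expect_equal(sum(regionWidths(rs)), 9000)
    ## per-base sweep oracle with the same precedence order
    labelOf <- function(chrom, p0) {
        g <- genes[genes$chrom == chrom, , drop = FALSE]
        inAny <- function(lo, hi) any(p0 >= lo & p0 < hi)  # 0-based half-open
        fwd <- g$strand == "+"
        if (inAny(g$tss - 250L, g$tss + 250L)) return("TSS")
        if (inAny(ifelse(fwd, g$tss - 1000L, g$tss + 250L),
                  ifelse(fwd, g$tss - 250L, g$tss + 1000L)))
            return("promoter")
        if (inAny(g$tts - 250L, g$tts + 250L)) return("TTS")
        if (inAny(ifelse(fwd, g$tss + 250L, g$tts + 250L),
                  ifelse(fwd, g$tts - 250L, g$tss - 250L)))
            return("gene_body")
        "intergenic"
    }
    set.seed(12)
    probe <- data.frame(chrom = sample(c("chr1", "chr2"), 400, TRUE))
    probe$p0 <- ifelse(probe$chrom == "chr1",
                       sample.int(6000L, 400, TRUE),
                       sample.int(3000L, 400, TRUE)) - 1L
    pgr <- GenomicRanges::GRanges(probe$chrom,
                                  IRanges::IRanges(probe$p0 + 1L, width = 1L))
    memberships <- vapply(names(regionRanges(rs)), function(lbl)
        IRanges::overlapsAny(pgr, regionRanges(rs)[[lbl]]), logical(400))
    expect_true(all(rowSums(memberships) == 1))   # no double labels
    got <- colnames(memberships)[apply(memberships, 1L, which)]
    want <- mapply(labelOf, probe$chrom, probe$p0)
    expect_equal(got, unname(want))
})

test_that("no genes means everything is intergenic; short genes no body", {
    si <- toy_seqinfo(c(chr1 = 5000L))
    rs <- buildRegions(NULL, si)
    expect_equal(unname(regionWidths(rs)["intergenic"]), 5000)
    short <- buildRegions(data.frame(chrom = "chr1", strand = "+",
                                     tss = 2000L, tts = 2400L), si)
    expect_equal(unname(regionWidths(short)["gene_body"]), 0)
    expect_equal(sum(regionWidths(short)), 5000)
})

test_that("BPMM follows its unit definition and conserves breaks", {
    si <- toy_seqinfo(c(chr1 = 5000000L))
    genes <- data.frame(chrom = "chr1", strand = "+", tss = 1000000L,
                        tts = 2999750L)   # gene body spans ~2 Mb
    rs <- buildRegions(genes, si)
    bodyW <- unname(regionWidths(rs)["gene_body"])
    ## place 100 breaks inside a 1-Mb stretch of the body, and the rest of
    ## a million total elsewhere (intergenic)
    pos <- StrandProfile("+", si, data.frame(
        chrom = "chr1", pos = 1100000L, count = 100))
    neg <- StrandProfile("-", si, data.frame(
        chrom = "chr1", pos = 4500000L, count = 999900))
    ## shrink the body label to exactly 1 Mb for the worked example
    rs@regions$intergenic <- GenomicRanges::union(
        rs@regions$intergenic,
        GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(1250251, 1250250 + bodyW - 1e6)))
    rs@regions$gene_body <- GenomicRanges::setdiff(
        rs@regions$gene_body, rs@regions$intergenic)
    expect_equal(unname(regionWidths(rs)["gene_body"]), 1e6)
    bpmm <- breakDensityBPMM(pos, neg, rs)
    expect_equal(unname(bpmm["gene_body"]), 100)
    ## conservation across labels
    counts <- vapply(names(regionRanges(rs)), function(lbl)
        cncc:::.breaksIn(regionRanges(rs)[[lbl]], pos, neg), numeric(1))
    expect_equal(sum(counts), 1e6)
    ## duplicating the dataset leaves BPMM unchanged
    bpmm2 <- breakDensityBPMM(scaleCounts(pos, 2), scaleCounts(neg, 2), rs)
    expect_equal(bpmm2, bpmm)
})

test_that("uniform breaks give equal BPMM across labels", {
    si <- toy_seqinfo(c(chr1 = 2000000L))
    genes <- data.frame(chrom = "chr1", strand = c("+", "-"),
                        tss = c(300000L, 1400000L),
                        tts = c(800000L, 1100000L))
    rs <- buildRegions(genes, si)
    set.seed(77)
    mk <- function(str) StrandProfile(str, si, data.frame(
        chrom = "chr1", pos = sample.int(2000000L, 150000L) - 1L, count = 1))
    bpmm <- breakDensityBPMM(mk("+"), mk("-"), rs)
    ## uniform density -> all labels near the genome-wide expectation
    expect_true(all(abs(bpmm / mean(bpmm) - 1) < 0.1))
})

test_that("group comparison reproduces rank-statistic oracles", {
    x <- c(1.2, 3.4, 2.2, 5.1, 4.7, 6.3)
    g <- c("a", "a", "a", "b", "b", "b")
    dens <- list(a = list(TSS = x[g == "a"]), b = list(TSS = x[g == "b"]))
    rep <- compareDensities(dens)
    ## Kruskal-Wallis H for two groups of 3 with these ranks:
    ## ranks a = {1,3,2}, b = {5,4,6}; H = 12/(N(N+1)) * sum n(Rbar-
    ## (N+1)/2)^2 = 12/42 * (3*(2-3.5)^2 + 3*(5-3.5)^2) = 3.857142...
    expect_equal(unname(rep$kw$H), 12 / 42 * (3 * 1.5^2 + 3 * 1.5^2),
                 tolerance = 1e-10)
    expect_equal(unname(rep$dunn$z), naive_dunn_z(x, g, "a", "b"),
                 tolerance = 1e-10)
    ## identical groups: H ~ 0
    same <- list(a = list(TSS = c(1, 2, 3)), b = list(TSS = c(3, 1, 2)))
    expect_lt(compareDensities(same)$kw$H, 1e-10)
    ## constant data: p = 1, no crash
    const <- list(a = list(TSS = c(2, 2)), b = list(TSS = c(2, 2)))
    expect_equal(compareDensities(const)$kw$p, 1)
    expect_equal(compareDensities(const)$dunn$p.adj, 1)
})

test_that("three shifted groups keep BH monotonicity and find the split", {
    set.seed(5)
    mkg <- function(mu) list(TSS = mu + stats::runif(12))
    dens <- list(low = mkg(0), mid = mkg(0.7), high = mkg(3))
    rep <- compareDensities(dens)
    expect_lt(rep$kw$p, 0.01)
    d <- rep$dunn
    expect_equal(order(d$p.adj), order(d$p))   # BH preserves the order
    expect_true(all(d$p.adj >= d$p))
    ## disjoint supports give the minimal attainable p for these n
    disj <- list(a = list(TSS = 1:6), b = list(TSS = 7:12))
    expect_equal(compareDensities(disj)$kw$H, 12 / (12 * 13) *
                     (6 * (3.5 - 6.5)^2 + 6 * (9.5 - 6.5)^2),
                 tolerance = 1e-10)
})

test_that("per-window densities feed the comparison pipeline", {
    si <- toy_seqinfo(c(chr1 = 100000L))
    genes <- data.frame(chrom = "chr1", strand = "+", tss = 20000L,
                        tts = 60000L)
    rs <- buildRegions(genes, si)
    set.seed(31)
    mk <- function(str, n) StrandProfile(str, si, data.frame(
        chrom = "chr1", pos = sample.int(100000L, n) - 1L, count = 1))
    wd <- windowDensities(mk("+", 5000), mk("-", 5000), rs,
                          windowSize = 1000L)
    expect_named(wd, c("promoter", "TSS", "TTS", "gene_body", "intergenic"))
    ## gene body: [20250, 59750) -> 39 full 1-kb windows
    expect_length(wd$gene_body, 39L)
    expect_true(all(wd$gene_body >= 0))
})

test_that("gene models load from TSV and GTF alike", {
    tsv <- withr::local_tempfile()
    writeLines(c("chr1\t+\t100\t900", "chr1\t-\t2000\t1200"), tsv)
    g1 <- readGenesTSV(tsv)
    expect_equal(g1$tss, c(100L, 2000L))
    gtf <- withr::local_tempfile()
    writeLines(c("# comment",
                 paste("chr1", "src", "gene", 101, 900, ".", "+", ".",
                       "gene_id \"g1\";", sep = "\t"),
                 paste("chr1", "src", "exon", 101, 200, ".", "+", ".",
                       "gene_id \"g1\";", sep = "\t"),
                 paste("chr1", "src", "gene", 1201, 2001, ".", "-", ".",
                       "gene_id \"g2\";", sep = "\t")), gtf)
    g2 <- readGenesGTF(gtf)
    expect_equal(g2$tss, c(100L, 2000L))
    expect_equal(g2$tts, c(899L, 1200L))
})
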