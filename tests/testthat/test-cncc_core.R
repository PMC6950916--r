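si <- toy_seqinfo(c(chr1 = 500L, chr2 = 400L))

test_that("a single perfect blunt pair reaches the Cauchy-Schwarz bound", {
    p <- StrandProfile("+", si, data.frame(chrom = "chr1", pos = 10, count = 4))
    n <- StrandProfile("-", si, data.frame(chrom = "chr1", pos = 9, count = 4))
    cv <- computeCNCC(p, n, -5, 5)
    expect_equal(cnccValues(cv)[shifts(cv) == -1], 1)
    expect_equal(cnccValues(cv)[shifts(cv) != -1], rep(0, 10))
    expect_equal(argmaxShift(cv), -1L)
})

test_that("sparse evaluation matches the brute-force nested-loop oracle", {
    for (seed in 1:4) {
        pos <- random_profile(si, "+", n = 50L, seed = seed)
        neg <- random_profile(si, "-", n = 40L, seed = seed + 100L)
        cv <- computeCNCC(pos, neg, -30, 30)
        expect_equal(cnccValues(cv), brute_cncc(pos, neg, -30, 30),
                     tolerance = 1e-12)
        ## single-shift fast path agrees with the full curve
        for (t in c(-30L, -3L, 0L, 17L))
            expect_equal(cnccAtShift(pos, neg, t),
                         cnccValues(cv)[shifts(cv) == t])
    }
})

test_that("|CNCC| <= 1 for arbitrary profiles (Cauchy-Schwarz)", {
    for (seed in 1:10) {
        pos <- random_profile(si, "+", n = 30L, maxCount = 20L, seed = seed)
        neg <- random_profile(si, "-", n = 60L, maxCount = 3L,
                              seed = seed + 7L)
        expect_true(all(abs(cnccValues(computeCNCC(pos, neg, -20, 20))) <= 1))
    }
})

test_that("the curve is invariant to rescaling all counts", {
    pos <- random_profile(si, "+", seed = 11L)
    neg <- random_profile(si, "-", seed = 12L)
    ref <- cnccValues(computeCNCC(pos, neg, -20, 20))
    for (c in c(3, 0.5, 1e4))
        expect_equal(cnccValues(computeCNCC(scaleCounts(pos, c),
                                            scaleCounts(neg, c), -20, 20)),
                     ref, tolerance = 1e-12)
})

test_that("the curve is covariant under a common genomic translation", {
    set.seed(21)
    mk <- function(str) StrandProfile(str, si, data.frame(
        chrom = "chr1", pos = sample.int(400L, 40L) + 19L,
        count = sample.int(5L, 40L, replace = TRUE)))
    pos <- mk("+"); neg <- mk("-")
    shiftBy <- function(p, d)
        StrandProfile(strand(p), seqinfo(p),
                      transform(profileData(p), pos = pos + d))
    ref <- cnccValues(computeCNCC(pos, neg, -10, 10))
    expect_equal(cnccValues(computeCNCC(shiftBy(pos, 7L), shiftBy(neg, 7L),
                                        -10, 10)),
                 ref, tolerance = 1e-12)
})

test_that("an exact translated copy attains CNCC 1 at the encoding shift", {
    set.seed(31)
    pos <- StrandProfile("+", si, data.frame(
        chrom = "chr1", pos = sample.int(400L, 25L) + 49L,
        count = sample.int(5L, 25L, replace = TRUE)))
    df <- profileData(pos)
    t0 <- -4L   # neg is pos translated so that y(i) = x(i - t0)
    neg <- StrandProfile("-", si, transform(df, pos = pos + t0))
    cv <- computeCNCC(pos, neg, -20, 20)
    expect_equal(max(cnccValues(cv)), 1)
    expect_equal(argmaxShift(cv), t0)
    expect_equal(sum(cnccValues(cv) == 1), 1L)   # unique for non-degenerate x
})

test_that("empty profiles make the normalization undefined", {
    pos <- random_profile(si, "+", seed = 1L)
    empty <- StrandProfile("-", si, NULL)
    expect_error(computeCNCC(pos, empty, -5, 5), "undefined normalization")
})

test_that("shifts decode to end structures and back", {
    expect_equal(endKind(shiftToStructure(-1)), "blunt")
    s <- shiftToStructure(-5)
    expect_equal(endKind(s), "three_prime_overhang")
    expect_equal(overhangLength(s), 4L)
    s <- shiftToStructure(3)
    expect_equal(endKind(s), "five_prime_overhang")
    expect_equal(overhangLength(s), 4L)
    s <- shiftToStructure(-3)
    expect_equal(endKind(s), "three_prime_overhang")
    expect_equal(overhangLength(s), 2L)
    expect_equal(structureToShift(EndStructure("blunt")), -1L)
    expect_equal(structureToShift(EndStructure("three_prime_overhang", 2)), -3L)
    expect_equal(structureToShift(EndStructure("five_prime_overhang", 4)), 3L)
    for (t in -10:10)
        expect_equal(structureToShift(shiftToStructure(t)), t)
    ## malformed structures are rejected by the validity method
    expect_error(EndStructure("blunt", 2), "overhang")
    expect_error(EndStructure("three_prime_overhang", 0), "overhang")
})

test_that("dominant shifts recover peaks and ignore flat curves", {
    mkCurve <- function(values, minShift)
        new("CNCCCurve", shift = seq(minShift, by = 1L,
                                     length.out = length(values)),
            value = values, sumsqPos = 1, sumsqNeg = 1, metadata = list())
    spike <- mkCurve(c(0, 0, 0.8, 0, 0), -3L)
    top <- dominantShifts(spike, k = 3)
    expect_equal(top$shift, -1L)
    expect_equal(top$cncc, 0.8)
    expect_equal(top$kind, "blunt")
    expect_equal(nrow(dominantShifts(mkCurve(rep(0.2, 7), -3L), k = 3)), 0L)
    ## agreement with the exhaustive local-maximum scan on a rough curve
    set.seed(99)
    v <- abs(stats::rnorm(41))
    cv <- mkCurve(v, -20L)
    got <- dominantShifts(cv, k = 100L, minProminence = 0)
    expect_setequal(got$shift, shifts(cv)[naive_local_maxima(v)])
})

test_that("a two-species mixture yields both characteristic shifts", {
    gsi <- toy_seqinfo(c(chr1 = 200000L))
    blunt <- simulateDigest(simConfig(gsi, nSites = 200,
                                      endStructure = EndStructure("blunt"),
                                      readsPerEnd = 5, seed = 41))
    five <- simulateDigest(simConfig(gsi, nSites = 200,
                                     endStructure =
                                         EndStructure("five_prime_overhang", 4),
                                     readsPerEnd = 5, seed = 43))
    cv <- computeCNCC(combineProfiles(blunt$pos, five$pos),
                      combineProfiles(blunt$neg, five$neg), -20, 20)
    top <- dominantShifts(cv, k = 2, minProminence = 0.01)
    expect_setequal(top$shift, c(-1L, 3L))
})

test_that("resection range reduces to the spike for point signals", {
    v <- rep(0, 250)
    v[250] <- 0.5                            # shift -3 within [-252, -3]
    cv <- new("CNCCCurve", shift = seq(-252L, -3L), value = v,
              sumsqPos = 1, sumsqNeg = 1, metadata = list())
    sig <- resectionRange(cv, windowLo = -200L, windowHi = -3L,
                          thresholdFrac = 0.9)
    expect_equal(sig@shiftLo, -3L)
    expect_equal(sig@shiftHi, -3L)
    expect_equal(overhangRange(sig), c(2L, 2L))
    expect_error(resectionRange(cv, -500L, -2L), "outside")
    expect_error(resectionRange(cv, -50L, -1L), "below shift -1")
})

test_that("thresholdFrac = 1 collapses the range to the exact-maximum run", {
    v <- c(0.1, 0.5, 0.5, 0.2, 0.5, 0.1)
    cv <- new("CNCCCurve", shift = seq(-8L, -3L), value = v,
              sumsqPos = 1, sumsqNeg = 1, metadata = list())
    sig <- resectionRange(cv, -8L, -3L, thresholdFrac = 1)
    ## three tied maxima; tie-break picks shift -4, whose exact-max run is
    ## just itself
    expect_equal(sig@peakShift, -4L)
    expect_equal(c(sig@shiftLo, sig@shiftHi), c(-4L, -4L))
})

test_that("curves round-trip through TSV", {
    pos <- random_profile(si, "+", seed = 51L)
    neg <- random_profile(si, "-", seed = 52L)
    cv <- computeCNCC(pos, neg, -10, 10)
    f <- withr::local_tempfile()
    writeCurve(cv, f)
    back <- readCurve(f)
    expect_equal(shifts(back), shifts(cv))
    expect_equal(cnccValues(back), cnccValues(cv))
    expect_equal(back@sumsqPos, cv@sumsqPos)
})
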