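#' @include cncc_core.R
NULL

#' Configure a synthetic break-mapping simulation
#'
#' The simulator emulates the input domain of the CNCC analysis: mapped
#' read-1 5'-end positions, post-alignment.  A restriction-style cut at
#' position `p` (0-based, `p` is the last nucleotide left of the cut on the
#' negative-strand side) emits a negative-strand 5' end at `p` and a
#' positive-strand 5' end whose offset encodes the end structure, exactly
#' as end-blunting does in the wet protocol:
#' `p + 1` for a blunt cut, `p + 1 + L` for a 3' overhang of `L` nt
#' (trimming separates the blunted ends) and `p + 1 - L` for a 5' overhang
#' (fill-in overlaps them).  Uniform background breaks with random strand
#' and position can be layered on top.
#'
#' @param seqinfo Genome frame ([GenomeInfoDb::Seqinfo]).
#' @param sites `data.frame` with columns `chrom`, `pos` of cut positions,
#'   or `NULL` to draw `nSites` cut positions uniformly at random.
#' @param nSites Number of random cut sites when `sites` is `NULL`.
#' @param endStructure An [EndStructure-class] shared by all sites.
#' @param overhangDist Optional resection mode: a `function(n)` returning
#'   `n` positive integer 3'-overhang lengths (one drawn per site,
#'   overriding `endStructure`), or an integer vector sampled uniformly.
#' @param readsPerEnd Reads emitted at each break end of a captured site:
#'   a scalar, or a `function(n)` returning `n` counts.
#' @param captureEfficiency Probability in (0, 1] that a site is captured.
#' @param backgroundRate Expected uniform background breaks per nucleotide
#'   per strand (Poisson).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A `SimConfig` list, input to [simulateDigest()] and
#'   [simulateResection()].
#' @export
simConfig <- function(seqinfo, sites = NULL, nSites = 1000L,
                      endStructure = EndStructure("blunt"),
                      overhangDist = NULL, readsPerEnd = 10L,
                      captureEfficiency = 1, backgroundRate = 0,
                      seed = 1L) {
    stopifnot(is(seqinfo, "Seqinfo"),
              captureEfficiency > 0, captureEfficiency <= 1,
              backgroundRate >= 0)
    if (is.null(sites)) stopifnot(nSites >= 1L)
    else if (!nrow(sites)) stopifnot(backgroundRate > 0)  # background-only run
    if (!is.null(overhangDist) && !is.function(overhangDist)) {
        lens <- as.integer(overhangDist)
        stopifnot(all(lens >= 1L))
        overhangDist <- function(n) lens[sample.int(length(lens), n,
                                                    replace = TRUE)]
    }
    if (!is.function(readsPerEnd)) {
        r <- as.integer(readsPerEnd)
        stopifnot(r >= 1L)
        readsPerEnd <- function(n) rep(r, n)
    }
    structure(list(seqinfo = seqinfo, sites = sites, nSites = nSites,
                   endStructure = endStructure, overhangDist = overhangDist,
                   readsPerEnd = readsPerEnd,
                   captureEfficiency = captureEfficiency,
                   backgroundRate = backgroundRate, seed = seed),
              class = "SimConfig")
}

#' Simulate a restriction-digest break-mapping dataset
#'
#' Draws cut sites (or uses the configured ones), flips a capture coin per
#' site, emits the configured read counts at the two truth end positions of
#' each captured site, and adds uniform background breaks.  Sites whose
#' geometry would fall off a chromosome edge are skipped with a warning and
#' recorded in the truth table.
#'
#' @param cfg A `SimConfig` from [simConfig()].
#' @return A list with elements `pos`, `neg` (the full
#'   [StrandProfile-class] pair including background), `truth` (one row per
#'   site: `chrom`, `cut`, `kind`, `overhang`, `negEnd`, `posEnd`,
#'   `negReads`, `posReads`, `captured`, `skipped`) and `bgPos`, `bgNeg`
#'   (the background-only profiles, so signal and background are separately
#'   accountable).
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chr1", 10000)
#' cfg <- simConfig(si, sites = data.frame(chrom = "chr1", pos = 100),
#'                  readsPerEnd = 3, seed = 7)
#' sim <- simulateDigest(cfg)
#' profileData(sim$neg)  # 3 reads at 100
#' profileData(sim$pos)  # 3 reads at 101 (blunt)
#' @export
simulateDigest <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    .withSeed(cfg$seed, .simulateImpl(cfg))
}

#' Simulate a resected-break dataset (per-site 3'-overhang lengths)
#'
#' Identical to [simulateDigest()] except every site draws its own
#' 3'-overhang length from `cfg$overhangDist`, emulating a population of
#' breaks at different stages of 5'->3' resection.  A point-mass
#' distribution reproduces [simulateDigest()] with that fixed length.
#'
#' @param cfg A `SimConfig` with a non-`NULL` `overhangDist`.
#' @inherit simulateDigest return
#' @export
simulateResection <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"), is.function(cfg$overhangDist))
    .withSeed(cfg$seed, .simulateImpl(cfg))
}

.simulateImpl <- function(cfg) {
    si <- cfg$seqinfo
    sl <- seqlengths(si)
    ## 1. cut sites
    if (is.null(cfg$sites)) {
        nchr <- sample.int(length(sl), cfg$nSites, replace = TRUE,
                           prob = as.numeric(sl) / sum(as.numeric(sl)))
        sites <- data.frame(
            chrom = seqnames(si)[nchr],
            pos = as.integer(pmin(floor(stats::runif(cfg$nSites) *
                                        as.numeric(sl[nchr])),
                                  as.numeric(sl[nchr]) - 1)))
    } else sites <- data.frame(chrom = as.character(cfg$sites$chrom),
                               pos = as.integer(cfg$sites$pos))
    ns <- nrow(sites)
    ## 2. per-site overhang geometry
    if (!is.null(cfg$overhangDist)) {
        L <- as.integer(cfg$overhangDist(ns))
        stopifnot(all(L >= 1L))
        kind <- rep("three_prime_overhang", ns)
    } else {
        L <- rep(overhangLength(cfg$endStructure), ns)
        kind <- rep(endKind(cfg$endStructure), ns)
    }
    negEnd <- sites$pos
    posEnd <- sites$pos + 1L +
        ifelse(kind == "three_prime_overhang", L,
               ifelse(kind == "five_prime_overhang", -L, 0L))
    len <- sl[sites$chrom]
    skipped <- negEnd < 0L | negEnd >= len | posEnd < 0L | posEnd >= len
    if (any(skipped))
        warning(sum(skipped), " site(s) too close to a chromosome edge ",
                "for their geometry; skipped")
    ## 3. capture and read emission
    captured <- !skipped &
        (stats::runif(ns) <= cfg$captureEfficiency)
    negReads <- posReads <- integer(ns)
    negReads[captured] <- cfg$readsPerEnd(sum(captured))
    posReads[captured] <- cfg$readsPerEnd(sum(captured))
    truth <- data.frame(chrom = sites$chrom, cut = sites$pos, kind = kind,
                        overhang = ifelse(kind == "blunt", 0L, L),
                        negEnd = negEnd, posEnd = posEnd,
                        negReads = negReads, posReads = posReads,
                        captured = captured, skipped = skipped)
    sig <- profilesFromTruth(truth, si)
    ## 4. uniform background, each read one count, random strand/position
    bg <- lapply(c(pos = "+", neg = "-"), function(str) {
        if (cfg$backgroundRate <= 0) return(.emptyProfile(str, si))
        perChrom <- lapply(seqnames(si), function(chrom) {
            nbg <- stats::rpois(1L, cfg$backgroundRate * sl[[chrom]])
            if (!nbg) return(NULL)
            data.frame(chrom = chrom,
                       pos = sample.int(sl[[chrom]], nbg, replace = TRUE) - 1L,
                       count = 1)
        })
        StrandProfile(str, si, do.call(rbind, perChrom))
    })
    list(pos = combineProfiles(sig$pos, bg$pos),
         neg = combineProfiles(sig$neg, bg$neg),
         truth = truth, bgPos = bg$pos, bgNeg = bg$neg)
}

#' Rebuild the site-only strand profiles from a simulation truth table
#'
#' @param truth The `truth` data.frame of [simulateDigest()].
#' @param seqinfo Genome frame.
#' @return List of [StrandProfile-class] elements `pos`, `neg` containing
#'   exactly the reads emitted at captured sites (no background).
#' @export
profilesFromTruth <- function(truth, seqinfo) {
    cap <- truth[truth$captured, , drop = FALSE]
    mk <- function(col, reads, str) {
        keep <- cap[[reads]] > 0
        StrandProfile(str, seqinfo,
                      data.frame(chrom = cap$chrom[keep],
                                 pos = cap[[col]][keep],
                                 count = cap[[reads]][keep]))
    }
    list(pos = mk("posEnd", "posReads", "+"),
         neg = mk("negEnd", "negReads", "-"))
}

#' Sum two strand profiles position-wise
#'
#' @param x,y [StrandProfile-class] objects on the same strand and genome.
#' @return The combined profile.
#' @export
combineProfiles <- function(x, y) {
    stopifnot(identical(x@strand, y@strand),
              identical(seqlengths(x@seqinfo), seqlengths(y@seqinfo)))
    if (!length(y@data)) return(x)
    if (!length(x@data)) return(y)
    StrandProfile(x@strand, x@seqinfo,
                  rbind(profileData(x), profileData(y)))
}

#' Simulate a mixture in which one break species is a minor fraction
#'
#' Simulates the major and minor configurations independently, then scales
#' the minor species' read emission so that it contributes exactly
#' `minorFraction` of the total counts, emulating e.g. a limited digestion
#' whose cut-site reads are a fraction of a percent of the library.
#'
#' @param majorCfg,minorCfg `SimConfig` objects sharing a genome frame.
#' @param minorFraction Fraction in (0, 1) of total counts contributed by
#'   the minor species.
#' @return A list with the mixed `pos`, `neg` profiles, both truth tables
#'   (`majorTruth`, `minorTruth`), and `minorScale`, the factor applied to
#'   the minor species' counts.
#' @export
simulateMinorSpecies <- function(majorCfg, minorCfg, minorFraction) {
    stopifnot(minorFraction > 0, minorFraction < 1)
    major <- simulateDigest(majorCfg)
    minor <- if (is.function(minorCfg$overhangDist))
        simulateResection(minorCfg) else simulateDigest(minorCfg)
    M <- totalCount(major$pos) + totalCount(major$neg)
    m <- totalCount(minor$pos) + totalCount(minor$neg)
    if (m <= 0) stop("minor simulation emitted no reads")
    scale <- minorFraction * M / ((1 - minorFraction) * m)
    list(pos = combineProfiles(major$pos, scaleCounts(minor$pos, scale)),
         neg = combineProfiles(major$neg, scaleCounts(minor$neg, scale)),
         majorTruth = major$truth, minorTruth = minor$truth,
         minorScale = scale)
}
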