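#' @include shuffle_control.R
NULL

#' Construct a BreakSiteSet
#'
#' @param sites `data.frame` with columns `chrom`, `negEnd`, `posEnd` and
#'   optionally `reads`.
#' @param minReads Strict read-count threshold carried by the set (sites
#'   with `reads > minReads` survive [filterSites()]); default 5.
#' @return A [BreakSiteSet-class].
#' @export
BreakSiteSet <- function(sites, minReads = 5) {
    if (!"reads" %in% names(sites))
        sites$reads <- rep(NA_real_, nrow(sites))
    new("BreakSiteSet",
        sites = data.frame(chrom = as.character(sites$chrom),
                           negEnd = as.integer(sites$negEnd),
                           posEnd = as.integer(sites$posEnd),
                           reads = as.numeric(sites$reads)),
        minReads = minReads)
}

#' @describeIn BreakSiteSet The site table (`chrom`, `negEnd`, `posEnd`,
#'   `reads`).
#' @param x A `BreakSiteSet`.
#' @export
setMethod("siteTable", "BreakSiteSet", function(x) x@sites)

#' @describeIn BreakSiteSet Keep only sites with `reads > minReads`
#'   (strictly more; the conventional cut is "more than 5 reads").
#' @param minReads Strict threshold; defaults to the set's own.
#' @export
setMethod("filterSites", "BreakSiteSet", function(x, minReads) {
    if (missing(minReads)) minReads <- x@minReads
    keep <- !is.na(x@sites$reads) & x@sites$reads > minReads
    new("BreakSiteSet", sites = x@sites[keep, , drop = FALSE],
        minReads = minReads)
})

setMethod("show", "BreakSiteSet", function(object) {
    cat("BreakSiteSet with", nrow(object@sites), "site(s); minReads >",
        object@minReads, "\n")
})

#' Locate cut sites of an IUPAC motif and derive break-end positions
#'
#' Scans both orientations of the reference for a recognition motif and,
#' from the cut geometry, derives where each site's two blunted break ends
#' are expected to map: the negative-strand 5' end (`negEnd`) and the
#' positive-strand 5' end (`posEnd`).  For a motif occurrence on the plus
#' strand starting at 0-based position `s`, `negEnd = s + cutOffset` and
#' `posEnd = negEnd + 1 + L` (3' overhang of `L`), `negEnd + 1` (blunt) or
#' `negEnd + 1 - L` (5' overhang); minus-strand occurrences use the
#' mirror-image geometry.  Palindromic motifs found in both orientations at
#' one locus are reported once.
#'
#' @param reference A named [Biostrings::DNAStringSet] (names = chromosome
#'   identifiers) or path to a FASTA file.
#' @param motif IUPAC recognition string (e.g. `"GGCC"`, `"GRGCYC"`).
#' @param structure The [EndStructure-class] the enzyme produces.
#' @param cutOffset 0-based offset, within the plus-strand motif, of the
#'   negative-strand break end.
#' @param minReads Strict read threshold stored on the returned set.
#' @return A [BreakSiteSet-class] with `reads = NA` (see
#'   [countSiteReads()]).
#' @importFrom Biostrings DNAStringSet DNAString readDNAStringSet
#'   matchPattern reverseComplement IUPAC_CODE_MAP
#' @export
sitesFromMotif <- function(reference, motif, structure, cutOffset,
                           minReads = 5) {
    if (is.character(reference)) reference <- readDNAStringSet(reference)
    stopifnot(is(reference, "DNAStringSet"), nchar(motif) >= 1L)
    bad <- setdiff(strsplit(toupper(motif), "")[[1L]],
                   names(IUPAC_CODE_MAP))
    if (length(bad))
        stop("invalid IUPAC code(s) in motif: ", paste(bad, collapse = ", "))
    if (is.null(names(reference)))
        stop("reference sequences must be named by chromosome")
    names(reference) <- sub("\\s.*$", "", names(reference))
    L <- overhangLength(structure)
    delta <- switch(endKind(structure), blunt = 0L,
                    three_prime_overhang = L, five_prime_overhang = -L)
    m <- nchar(motif)
    fwd <- DNAString(toupper(motif))
    rev <- reverseComplement(fwd)
    rows <- list()
    for (chrom in names(reference)) {
        subject <- reference[[chrom]]
        for (ori in c("+", "-")) {
            hits <- matchPattern(if (ori == "+") fwd else rev, subject,
                                 fixed = FALSE)
            if (!length(hits)) next
            s0 <- BiocGenerics::start(hits) - 1L         # 0-based motif start
            if (ori == "+") {
                negEnd <- s0 + cutOffset
                posEnd <- negEnd + 1L + delta
            } else {
                ## reflect the plus-orientation cut pair through the motif
                refl <- function(g) s0 + (s0 + m - 1L) - g
                negEnd <- refl((s0 + cutOffset) + 1L + delta)
                posEnd <- refl(s0 + cutOffset)
            }
            rows[[length(rows) + 1L]] <-
                data.frame(chrom = chrom, negEnd = negEnd, posEnd = posEnd)
        }
    }
    if (!length(rows))
        return(BreakSiteSet(data.frame(chrom = character(),
                                       negEnd = integer(),
                                       posEnd = integer()),
                            minReads = minReads))
    tab <- unique(do.call(rbind, rows))
    tab <- tab[order(tab$chrom, tab$negEnd), , drop = FALSE]
    rownames(tab) <- NULL
    BreakSiteSet(tab, minReads = minReads)
}

#' Count observed reads at each site's expected break-end positions
#'
#' `reads` for a site is the negative-strand count at `negEnd` plus the
#' positive-strand count at `posEnd`.
#'
#' @param sites A [BreakSiteSet-class].
#' @param pos,neg The observed [StrandProfile-class] pair.
#' @return The [BreakSiteSet-class] with its `reads` column filled in.
#' @export
countSiteReads <- function(sites, pos, neg) {
    tab <- sites@sites
    lookup <- function(profile, chrom, p) {
        out <- numeric(length(p))
        for (ch in unique(chrom)) {
            e <- .chromData(profile, ch)
            sel <- chrom == ch
            m <- match(p[sel], e$pos)
            out[sel] <- ifelse(is.na(m), 0, e$count[m])
        }
        out
    }
    tab$reads <- lookup(neg, tab$chrom, tab$negEnd) +
        lookup(pos, tab$chrom, tab$posEnd)
    new("BreakSiteSet", sites = tab, minReads = sites@minReads)
}

#' Build a BreakSiteSet from a simulation truth table
#'
#' @param truth Truth table of [simulateDigest()].
#' @param minReads Strict read threshold stored on the set.
#' @return A [BreakSiteSet-class] of the captured sites, with `reads` the
#'   emitted reads per site.
#' @export
sitesFromTruth <- function(truth, minReads = 5) {
    cap <- truth[truth$captured, , drop = FALSE]
    BreakSiteSet(data.frame(chrom = cap$chrom, negEnd = cap$negEnd,
                            posEnd = cap$posEnd,
                            reads = cap$negReads + cap$posReads),
                 minReads = minReads)
}

#' Mask a random fraction of cut sites out of the profiles
#'
#' Chooses `floor(fraction * n)` sites uniformly without replacement and
#' removes ALL reads at each chosen site's expected end positions — the
#' `negEnd` position from the negative-strand profile and the `posEnd`
#' position from the positive-strand profile (optionally widened by
#' `window` nt on each side).  Everything else is untouched.
#'
#' @param pos,neg The [StrandProfile-class] pair.
#' @param sites A [BreakSiteSet-class].
#' @param fraction Fraction of sites to mask, in \[0, 1\].
#' @param seed Integer seed for the site choice.
#' @param window Half-width in nt around each end position (default 0:
#'   exact single-nucleotide positions only).
#' @return List with masked `pos`, `neg` profiles and `masked`, the rows of
#'   the chosen sites.
#' @export
maskSites <- function(pos, neg, sites, fraction, seed, window = 0L) {
    stopifnot(fraction >= 0, fraction <= 1)
    tab <- sites@sites
    nPick <- floor(fraction * nrow(tab))
    if (nPick == 0L)
        return(list(pos = pos, neg = neg, masked = tab[0, , drop = FALSE]))
    pick <- .withSeed(seed, sample.int(nrow(tab), nPick))
    chosen <- tab[pick, , drop = FALSE]
    dropAt <- function(profile, chrom, p) {
        dat <- profile@data
        for (ch in unique(chrom)) {
            e <- dat[[ch]]
            if (is.null(e)) next
            targets <- p[chrom == ch]
            if (window > 0L)
                targets <- unique(as.vector(outer(targets,
                                                  (-window):window, "+")))
            keep <- !(e$pos %in% targets)
            dat[[ch]] <- list(pos = e$pos[keep], count = e$count[keep])
        }
        .profileFromList(profile@strand, profile@seqinfo, dat)
    }
    list(pos = dropAt(pos, chosen$chrom, chosen$posEnd),
         neg = dropAt(neg, chosen$chrom, chosen$negEnd),
         masked = chosen)
}

#' Site-masking sensitivity scan of the CNCC signal
#'
#' For each masking fraction and iteration, masks a fresh random subset of
#' cut sites with [maskSites()] and records the CNCC value at the target
#' shift (the characteristic shift of the masked species).  Optionally the
#' same scan is run on two-step shuffled companions of the masked profiles,
#' which should stay flat while the genuine signal decreases linearly with
#' the masked fraction.
#'
#' @inheritParams maskSites
#' @param increments Masking fractions (default 0 to 1 in steps of 0.1).
#' @param iterations Random maskings per fraction (default 100).
#' @param targetShift Shift at which CNCC is tracked (e.g. -3 for a 2-nt 3'
#'   overhang).
#' @param seed Master seed; each (fraction, iteration) gets a
#'   deterministically derived sub-seed.
#' @param shuffleWiggle If non-`NULL`, evaluate shuffled companions with
#'   this wiggle magnitude instead of the raw masked profiles.
#' @return List with `results` (long `data.frame`: `fraction`, `iteration`,
#'   `cncc`) and `summary` (per fraction: `median`, `q25`, `q75`, `p5`,
#'   `p95`, matching the box-and-whisker convention with whiskers at 5 and
#'   95%).
#' @export
sensitivityScan <- function(pos, neg, sites, increments = seq(0, 1, 0.1),
                            iterations = 100L, targetShift = -3L,
                            seed = 1L, window = 0L, shuffleWiggle = NULL) {
    stopifnot(iterations >= 1L, all(increments >= 0 & increments <= 1))
    nCell <- length(increments) * iterations
    sub <- .withSeed(seed, matrix(sample.int(.Machine$integer.max,
                                             3L * nCell),
                                  nrow = 3L))
    res <- data.frame(fraction = rep(increments, each = iterations),
                      iteration = rep(seq_len(iterations),
                                      length(increments)),
                      cncc = NA_real_)
    for (k in seq_len(nCell)) {
        masked <- maskSites(pos, neg, sites, res$fraction[k],
                            seed = sub[1L, k], window = window)
        mp <- masked$pos; mn <- masked$neg
        if (!is.null(shuffleWiggle)) {
            mp <- shuffleProfile(mp, shuffleWiggle, sub[2L, k])
            mn <- shuffleProfile(mn, shuffleWiggle, sub[3L, k])
        }
        res$cncc[k] <- cnccAtShift(mp, mn, targetShift)
    }
    qs <- function(v, p) as.numeric(stats::quantile(v, p, names = FALSE))
    summ <- do.call(rbind, lapply(split(res$cncc, res$fraction), function(v)
        data.frame(median = stats::median(v), q25 = qs(v, 0.25),
                   q75 = qs(v, 0.75), p5 = qs(v, 0.05), p95 = qs(v, 0.95))))
    summ <- data.frame(fraction = as.numeric(rownames(summ)), summ,
                       row.names = NULL)
    summ <- summ[order(summ$fraction), , drop = FALSE]
    list(results = res, summary = summ)
}
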