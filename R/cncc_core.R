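#' @include profile.R
NULL

#' Coverage-normalized cross correlation between strand profiles
#'
#' Computes, for every integer shift `t` in `[minShift, maxShift]`,
#' \deqn{CNCC(t) = \frac{\sum_i y(i)\,x(i-t)}
#'                      {\sqrt{\sum_i x^2(i)\,\sum_i y^2(i)}}}
#' where `x` is positive-strand and `y` negative-strand break-end coverage.
#' The numerator is accumulated per chromosome (cross-chromosome products
#' never occur) and summed; the denominator is a single genome-wide
#' normalization, which makes the statistic independent of chromosome order,
#' invariant to rescaling all counts, and comparable across samples of
#' different sequencing depth.  Evaluation is sparse: only stored positions
#' contribute, with results identical to a dense evaluation.
#'
#' The characteristic shift of a break end structure is -1 for blunt ends,
#' `-1 - L` for 3' overhangs of `L` nt (blunting trims them, separating the
#' two mapped ends) and `-1 + L` for 5' overhangs (fill-in overlaps them).
#'
#' @param pos,neg [StrandProfile-class] objects for the positive and
#'   negative strand; both must be non-empty and share a genome frame.
#' @param minShift,maxShift Inclusive shift range.  The default
#'   `c(-1000, 1000)` suits treatment data with long resection tracts;
#'   single-enzyme digests are typically analyzed at `c(-50, 50)`.
#' @return A [CNCCCurve-class].
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chr1", 1000)
#' p <- StrandProfile("+", si, data.frame(chrom = "chr1", pos = 10, count = 2))
#' n <- StrandProfile("-", si, data.frame(chrom = "chr1", pos = 9, count = 2))
#' curve <- computeCNCC(p, n, -5, 5)
#' argmaxShift(curve)   # -1: a blunt break
#' @export
computeCNCC <- function(pos, neg, minShift = -1000L, maxShift = 1000L) {
    minShift <- as.integer(minShift); maxShift <- as.integer(maxShift)
    stopifnot(is(pos, "StrandProfile"), is(neg, "StrandProfile"),
              minShift <= maxShift)
    if (!identical(seqlengths(pos@seqinfo), seqlengths(neg@seqinfo)))
        stop("profiles use different genome frames")
    ssp <- sum(vapply(pos@data, function(e) sum(e$count^2), numeric(1)))
    ssn <- sum(vapply(neg@data, function(e) sum(e$count^2), numeric(1)))
    if (ssp <= 0 || ssn <= 0)
        stop("undefined normalization: both strand profiles must be non-empty")
    shiftv <- seq(minShift, maxShift)
    num <- numeric(length(shiftv))
    for (chrom in intersect(names(pos@data), names(neg@data))) {
        ex <- pos@data[[chrom]]; ey <- neg@data[[chrom]]
        num <- num + .cnccNumerator(ex$pos, ex$count, ey$pos, ey$count,
                                    minShift, maxShift)
    }
    new("CNCCCurve", shift = shiftv,
        value = num / sqrt(ssp * ssn),
        sumsqPos = ssp, sumsqNeg = ssn,
        metadata = list(minShift = minShift, maxShift = maxShift))
}

## Sparse windowed numerator on one chromosome: for each negative-strand
## position p the positive-strand positions in [p - maxShift, p - minShift]
## contribute count products at shift t = p - q.  Chunked so the expanded
## pair list stays bounded.
.cnccNumerator <- function(px, cx, py, cy, minShift, maxShift,
                           chunkPairs = 4e6) {
    num <- numeric(maxShift - minShift + 1L)
    if (!length(px) || !length(py)) return(num)
    lo <- findInterval(py - maxShift - 1L, px) + 1L
    hi <- findInterval(py - minShift, px)
    n <- pmax(hi - lo + 1L, 0L)
    keep <- base::which(n > 0L)
    if (!length(keep)) return(num)
    csum <- cumsum(as.numeric(n[keep]))
    block <- ceiling(csum / chunkPairs)   # bounded expanded-pair chunks
    for (b in unique(block)) {
        j <- keep[block == b]
        idx <- sequence(n[j], from = lo[j])
        jrep <- rep(j, n[j])
        tv <- py[jrep] - px[idx]
        w <- cy[jrep] * cx[idx]
        rs <- rowsum(w, tv)
        at <- as.integer(rownames(rs)) - minShift + 1L
        num[at] <- num[at] + rs[, 1L]
    }
    num
}

#' CNCC at a single shift
#'
#' Fast path used by the sensitivity scan, where only the value at the
#' characteristic shift of the masked species is tracked.
#'
#' @inheritParams computeCNCC
#' @param shift A single integer shift.
#' @return The CNCC value at `shift`.
#' @export
cnccAtShift <- function(pos, neg, shift) {
    shift <- as.integer(shift)
    ssp <- sum(vapply(pos@data, function(e) sum(e$count^2), numeric(1)))
    ssn <- sum(vapply(neg@data, function(e) sum(e$count^2), numeric(1)))
    if (ssp <= 0 || ssn <= 0)
        stop("undefined normalization: both strand profiles must be non-empty")
    num <- 0
    for (chrom in intersect(names(pos@data), names(neg@data))) {
        ex <- pos@data[[chrom]]; ey <- neg@data[[chrom]]
        m <- match(ey$pos - shift, ex$pos)
        ok <- !is.na(m)
        if (any(ok)) num <- num + sum(ey$count[ok] * ex$count[m[ok]])
    }
    num / sqrt(ssp * ssn)
}

#' @describeIn CNCCCurve The shift vector.
#' @param x A `CNCCCurve`.
#' @export
setMethod("shifts", "CNCCCurve", function(x) x@shift)

#' @describeIn CNCCCurve The CNCC values, parallel to `shifts(x)`.
#' @export
setMethod("cnccValues", "CNCCCurve", function(x) x@value)

#' @describeIn CNCCCurve The shift with the maximal CNCC value; ties are
#'   broken deterministically toward the smallest absolute shift (and the
#'   negative one of a +/- pair).
#' @export
setMethod("argmaxShift", "CNCCCurve", function(x) {
    cand <- base::which(x@value == max(x@value))
    cand <- cand[order(abs(x@shift[cand]), x@shift[cand])]
    x@shift[cand[1L]]
})

setMethod("show", "CNCCCurve", function(object) {
    cat("CNCCCurve over shifts [", object@shift[1L], ", ",
        object@shift[length(object@shift)], "]\n", sep = "")
    am <- argmaxShift(object)
    cat("  max ", format(max(object@value), digits = 4), " at shift ", am,
        " (", endKind(shiftToStructure(am)), ")\n", sep = "")
})

#' @export
as.data.frame.CNCCCurve <- function(x, ...)
    data.frame(shift = x@shift, cncc = x@value)

setMethod("as.data.frame", "CNCCCurve",
          function(x, ...) as.data.frame.CNCCCurve(x, ...))

#' Write / read a CNCC curve as two-column TSV
#'
#' The TSV has columns `shift` and `cncc`; the normalization terms are kept
#' in `#`-prefixed header lines so a round trip preserves the object.
#'
#' @param x A [CNCCCurve-class].
#' @param path File path.
#' @return `writeCurve` returns `path` invisibly; `readCurve` a
#'   [CNCCCurve-class].
#' @export
writeCurve <- function(x, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# sumsqPos=%.17g", x@sumsqPos),
                 sprintf("# sumsqNeg=%.17g", x@sumsqNeg),
                 "shift\tcncc"), con)
    utils::write.table(data.frame(x@shift, x@value), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeCurve
#' @export
readCurve <- function(path) {
    hdr <- readLines(path, n = 10L)
    getTerm <- function(key) {
        ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
        if (length(ln)) as.numeric(sub(".*=", "", ln[1L])) else 1
    }
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             comment.char = "#")
    new("CNCCCurve", shift = as.integer(tab$shift),
        value = as.numeric(tab$cncc),
        sumsqPos = getTerm("sumsqPos"), sumsqNeg = getTerm("sumsqNeg"),
        metadata = list())
}

#' Decode a CNCC shift into a break end structure
#'
#' Shift -1 is a blunt break; shifts below -1 are 3' overhangs of length
#' `-1 - t` (end-blunting trims the overhang, separating the two blunted
#' ends on the reference); shifts above -1 are 5' overhangs of length
#' `t + 1` (fill-in overlaps the two ends).
#'
#' @param t Integer shift.
#' @return An [EndStructure-class].
#' @examples
#' shiftToStructure(-1)  # blunt
#' shiftToStructure(-5)  # 4-nt 3' overhang
#' shiftToStructure(3)   # 4-nt 5' overhang
#' @export
shiftToStructure <- function(t) {
    t <- as.integer(t)
    stopifnot(length(t) == 1L, !is.na(t))
    if (t == -1L) new("EndStructure", kind = "blunt", overhang = 0L)
    else if (t < -1L) new("EndStructure", kind = "three_prime_overhang",
                          overhang = -1L - t)
    else new("EndStructure", kind = "five_prime_overhang", overhang = t + 1L)
}

#' Characteristic CNCC shift of an end structure
#'
#' Exact inverse of [shiftToStructure()].
#'
#' @param call An [EndStructure-class] (or the result of [EndStructure()]).
#' @return The integer shift at which that structure concentrates CNCC
#'   signal.
#' @export
structureToShift <- function(call) {
    stopifnot(is(call, "EndStructure"))
    switch(call@kind,
           blunt = -1L,
           three_prime_overhang = -1L - call@overhang,
           five_prime_overhang = call@overhang - 1L)
}

#' Construct an EndStructure
#'
#' @param kind `"blunt"`, `"three_prime_overhang"` or
#'   `"five_prime_overhang"`.
#' @param overhang Overhang length in nt (0 for blunt).
#' @return An [EndStructure-class].
#' @export
EndStructure <- function(kind, overhang = 0L)
    new("EndStructure", kind = kind, overhang = as.integer(overhang))

#' @describeIn EndStructure The structure kind.
#' @param x An `EndStructure`.
#' @export
setMethod("endKind", "EndStructure", function(x) x@kind)

#' @describeIn EndStructure The overhang length in nt.
#' @export
setMethod("overhangLength", "EndStructure", function(x) x@overhang)

setMethod("show", "EndStructure", function(object) {
    lab <- switch(object@kind, blunt = "blunt end",
                  three_prime_overhang =
                      sprintf("%d-nt 3' overhang", object@overhang),
                  five_prime_overhang =
                      sprintf("%d-nt 5' overhang", object@overhang))
    cat("EndStructure:", lab, "(characteristic shift",
        structureToShift(object), ")\n")
})

#' Most abundant end structures of a CNCC curve
#'
#' Finds local maxima of the curve, computes their topographic prominence,
#' keeps those with prominence at least `minProminence`, and returns the top
#' `k` by CNCC value with their decoded end structures.  A flat curve has no
#' local maxima and yields an empty table.
#'
#' @param curve A [CNCCCurve-class].
#' @param k Maximum number of peaks to report.
#' @param minProminence Minimum peak prominence (same units as CNCC).
#' @return `data.frame` with columns `shift`, `cncc`, `prominence`, `kind`,
#'   `overhang`, sorted by decreasing CNCC value.
#' @export
dominantShifts <- function(curve, k = 5L, minProminence = 0) {
    stopifnot(k >= 1L)
    v <- curve@value; s <- curve@shift; n <- length(v)
    empty <- data.frame(shift = integer(), cncc = numeric(),
                        prominence = numeric(), kind = character(),
                        overhang = integer())
    if (n < 3L) return(empty)
    i <- 2:(n - 1L)
    isPeak <- v[i] > v[i - 1L] & v[i] >= v[i + 1L]
    peaks <- i[isPeak]
    if (!length(peaks)) return(empty)
    prom <- vapply(peaks, function(p) {
        leftHigher <- base::which(v[seq_len(p - 1L)] > v[p])
        lmin <- if (length(leftHigher)) min(v[(max(leftHigher) + 1L):(p - 1L)])
                else min(v[seq_len(p - 1L)])
        rightIdx <- (p + 1L):n
        rightHigher <- rightIdx[v[rightIdx] > v[p]]
        rmin <- if (length(rightHigher))
                    min(v[(p + 1L):(min(rightHigher) - 1L)])
                else min(v[rightIdx])
        v[p] - max(lmin, rmin)
    }, numeric(1))
    keep <- prom >= minProminence
    peaks <- peaks[keep]; prom <- prom[keep]
    if (!length(peaks)) return(empty)
    o <- order(-v[peaks], abs(s[peaks]), s[peaks])
    o <- o[seq_len(min(k, length(o)))]
    peaks <- peaks[o]; prom <- prom[o]
    structs <- lapply(s[peaks], shiftToStructure)
    data.frame(shift = s[peaks], cncc = v[peaks], prominence = prom,
               kind = vapply(structs, endKind, character(1)),
               overhang = vapply(structs, overhangLength, integer(1)))
}

#' Quantify a resection signature as a 90%-of-maximum shift range
#'
#' Within a window of shifts strictly below -1 (the 3'-overhang side of the
#' curve, where 5'->3' resection deposits signal), locates the CNCC maximum
#' and expands the maximal contiguous run of shifts around it whose values
#' all reach `thresholdFrac` of the peak.  The run is reported both as
#' shifts and, via the 3'-overhang decoding `L = -1 - t`, as overhang
#' lengths.  The default window corresponds to overhangs of 1-200 nt,
#' comfortably covering resection tracts of the ~165 nt scale seen after
#' topoisomerase-II poisoning.
#'
#' @param curve A [CNCCCurve-class] whose range covers the window.
#' @param windowLo,windowHi Inclusive shift window, both < -1.
#' @param thresholdFrac Fraction of the window maximum (default 0.9).
#' @return A [ResectionSignature-class].
#' @export
resectionRange <- function(curve, windowLo = -201L, windowHi = -2L,
                           thresholdFrac = 0.9) {
    windowLo <- as.integer(windowLo); windowHi <- as.integer(windowHi)
    stopifnot(windowLo <= windowHi, thresholdFrac > 0, thresholdFrac <= 1)
    if (windowHi >= -1L)
        stop("resection window must lie entirely below shift -1")
    s <- curve@shift
    if (windowLo < s[1L] || windowHi > s[length(s)])
        stop("resection window outside the curve's shift range")
    idx <- base::which(s >= windowLo & s <= windowHi)
    v <- curve@value[idx]; sw <- s[idx]
    peakIdx <- base::which(v == max(v))
    peakIdx <- peakIdx[order(abs(sw[peakIdx]), sw[peakIdx])][1L]
    thr <- thresholdFrac * v[peakIdx]
    ok <- v >= thr
    lo <- peakIdx
    while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
    hi <- peakIdx
    while (hi < length(ok) && ok[hi + 1L]) hi <- hi + 1L
    new("ResectionSignature",
        windowLo = windowLo, windowHi = windowHi,
        peakShift = sw[peakIdx], peakValue = v[peakIdx],
        shiftLo = sw[lo], shiftHi = sw[hi],
        thresholdFrac = thresholdFrac)
}

#' Overhang-length range of a resection signature
#'
#' @param x A [ResectionSignature-class].
#' @return Integer vector `c(min, max)` of 3'-overhang lengths in nt.
#' @export
overhangRange <- function(x) {
    stopifnot(is(x, "ResectionSignature"))
    c(-1L - x@shiftHi, -1L - x@shiftLo)
}

setMethod("show", "ResectionSignature", function(object) {
    or <- overhangRange(object)
    cat("ResectionSignature in shift window [", object@windowLo, ", ",
        object@windowHi, "]\n", sep = "")
    cat(sprintf("  peak %.4g at shift %d;  >= %.0f%% of peak over shifts [%d, %d]\n",
                object@peakValue, object@peakShift,
                100 * object@thresholdFrac, object@shiftLo, object@shiftHi))
    cat("  3' overhang lengths ", or[1L], "-", or[2L], " nt\n", sep = "")
})
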