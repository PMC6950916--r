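#' @include cncc_core.R
NULL

## Evaluate expr with a locally seeded RNG, restoring global RNG state.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Two-step stringent shuffle of a strand profile
#'
#' Builds the minimally perturbed null for a break-end profile: (1) the
#' coverage values are permuted uniformly at random among the positions
#' that originally had non-zero coverage, preserving break clustering and
#' the count distribution; (2) each position is then moved by an
#' independent random wiggle drawn uniformly from
#' `{-W, ..., -1, 1, ..., W}` (0 excluded).  Counts landing on the same
#' final position are summed, so total coverage is conserved exactly.
#' A simple unrestrained genome-wide shuffle destroys all local structure
#' and yields a near-zero background that controls for nothing; the wiggle
#' magnitude `W` should instead match the maximum spike range under study
#' (W = 2 for single-enzyme digests, W = 2000 for resection-scale
#' treatment data).
#'
#' Positions wiggled past a chromosome edge are reflected back inside;
#' permutation and wiggle act within each chromosome independently.
#'
#' @param profile A non-empty [StrandProfile-class].
#' @param wiggle Positive integer `W`.
#' @param seed Integer seed; identical inputs give identical output.
#' @return The shuffled [StrandProfile-class].
#' @seealso [controlCurves()], [relativeCNCC()]
#' @export
shuffleProfile <- function(profile, wiggle, seed) {
    wiggle <- as.integer(wiggle)
    stopifnot(is(profile, "StrandProfile"), wiggle >= 1L)
    if (!length(profile@data)) stop("cannot shuffle an empty profile")
    sl <- seqlengths(profile@seqinfo)
    pool <- c(seq.int(-wiggle, -1L), seq.int(1L, wiggle))
    .withSeed(seed, {
        dat <- profile@data
        for (chrom in names(dat)) {
            e <- dat[[chrom]]
            n <- length(e$pos)
            cnt <- e$count[sample.int(n)]                  # value permutation
            w <- pool[sample.int(length(pool), n, replace = TRUE)]
            p <- e$pos + w                                 # position wiggle
            len <- sl[[chrom]]
            while (any(bad <- p < 0L | p >= len)) {        # reflect at edges
                p[bad & p < 0L] <- -p[bad & p < 0L] - 1L
                bad2 <- p >= len
                p[bad2] <- 2L * len - p[bad2] - 1L
            }
            agg <- rowsum(cnt, p)                          # collisions summed
            np <- as.integer(rownames(agg))
            o <- order(np)
            dat[[chrom]] <- list(pos = np[o], count = as.numeric(agg[o, 1L]))
        }
        .profileFromList(profile@strand, profile@seqinfo, dat)
    })
}

#' Shuffled-control CNCC curves
#'
#' For each replicate, both strand profiles are shuffled independently with
#' [shuffleProfile()] (sub-seeds derived deterministically from `seed` and
#' the replicate index) and the CNCC curve of the perturbed pair is
#' computed.  This is the stringent control against which a genuine
#' end-structure spike is judged.
#'
#' @inheritParams computeCNCC
#' @param wiggle Wiggle magnitude `W` (see [shuffleProfile()]).
#' @param seed Integer master seed.
#' @param replicates Number of independent control replicates (default 1).
#' @return A list of [CNCCCurve-class], one per replicate.
#' @export
controlCurves <- function(pos, neg, wiggle, minShift = -1000L,
                          maxShift = 1000L, seed = 1L, replicates = 1L) {
    stopifnot(replicates >= 1L)
    sub <- .withSeed(seed,
                     sample.int(.Machine$integer.max, 2L * replicates))
    lapply(seq_len(replicates), function(r) {
        sp <- shuffleProfile(pos, wiggle, sub[2L * r - 1L])
        sn <- shuffleProfile(neg, wiggle, sub[2L * r])
        curve <- computeCNCC(sp, sn, minShift, maxShift)
        curve@metadata$control <- list(wiggle = wiggle, replicate = r)
        curve
    })
}

#' Relative CNCC: subtract the shuffled-control median
#'
#' Subtracts the median of the shuffled control from a CNCC curve so that
#' different treatments can be compared on a common baseline.  By default
#' the median is a single scalar taken over all control values (all shifts,
#' all replicates), i.e. the control is used as a flat baseline; set
#' `perShift = TRUE` to subtract a per-shift median across replicates
#' instead.
#'
#' @param curve The treatment [CNCCCurve-class].
#' @param controls List of control curves from [controlCurves()] (or a
#'   single curve).
#' @param perShift Use a per-shift median rather than one global scalar.
#' @return A [CNCCCurve-class]; the subtracted baseline is recorded in
#'   `metadata(x)$controlMedian`.
#' @export
relativeCNCC <- function(curve, controls, perShift = FALSE) {
    if (is(controls, "CNCCCurve")) controls <- list(controls)
    stopifnot(length(controls) >= 1L)
    for (ctl in controls)
        if (!identical(ctl@shift, curve@shift))
            stop("control curve shift range differs from treatment curve")
    vals <- vapply(controls, function(c) c@value,
                   numeric(length(curve@shift)))
    vals <- matrix(vals, nrow = length(curve@shift))
    out <- curve
    if (perShift) {
        base <- apply(vals, 1L, stats::median)
        out@value <- curve@value - base
        out@metadata$controlMedian <- base
        out@metadata$controlMedianPerShift <- TRUE
    } else {
        base <- stats::median(as.vector(vals))
        out@value <- curve@value - base
        out@metadata$controlMedian <- base
        out@metadata$controlMedianPerShift <- FALSE
    }
    out
}
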