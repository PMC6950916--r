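#' @include profile.R
NULL

#' Find positive/negative coverage spike pairs at a fixed separation
#'
#' A spike pair is the per-locus fingerprint of a processed break end
#' structure: a single-nucleotide negative-strand spike at position `p`
#' with a positive-strand spike at `p + gapNt + 1`, i.e. separated by a
#' `gapNt`-nt gap.  For the trim-to-blunt processing of a 3' overhang of
#' `L` nt the gap equals `L` (and the pair generates CNCC signal at shift
#' `-1 - L`); blunt breaks give `gapNt = 0`.  "Separated by 4 nt" is read
#' as a 4-nt gap between the two single-nucleotide spikes
#' (`posPos = negPos + 5`), the geometry forced by blunting a 4-nt 3'
#' overhang and consistent with its CNCC spike at -5.
#'
#' @param pos,neg The [StrandProfile-class] pair.
#' @param gapNt Gap in nt between the negative- and positive-strand spike.
#' @param minReads Minimum reads required on BOTH spikes (default 2).
#' @return `data.frame` sorted by coordinate with columns `chrom`,
#'   `negPos`, `posPos`, `negReads`, `posReads`, `gapNt`.
#' @export
findPairs <- function(pos, neg, gapNt, minReads = 2) {
    stopifnot(minReads >= 1)
    gapNt <- as.integer(gapNt)
    rows <- list()
    for (chrom in intersect(names(neg@data), names(pos@data))) {
        ey <- neg@data[[chrom]]; ex <- pos@data[[chrom]]
        m <- match(ey$pos + gapNt + 1L, ex$pos)
        ok <- !is.na(m) & ey$count >= minReads
        ok[ok] <- ex$count[m[ok]] >= minReads
        if (!any(ok)) next
        rows[[chrom]] <- data.frame(chrom = chrom, negPos = ey$pos[ok],
                                    posPos = ey$pos[ok] + gapNt + 1L,
                                    negReads = ey$count[ok],
                                    posReads = ex$count[m[ok]],
                                    gapNt = gapNt)
    }
    if (!length(rows))
        return(data.frame(chrom = character(), negPos = integer(),
                          posPos = integer(), negReads = numeric(),
                          posReads = numeric(), gapNt = integer()))
    out <- do.call(rbind, rows)
    out <- out[order(out$chrom, out$negPos), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write spike pairs as BED
#'
#' One record per pair spanning `[negPos, posPos + 1)` with the two read
#' counts in the name column (`negReads|posReads`).
#'
#' @param pairs Output of [findPairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePairsBed <- function(pairs, path) {
    out <- data.frame(chrom = pairs$chrom, start = pairs$negPos,
                      end = pairs$posPos + 1L,
                      name = paste0(pairs$negReads, "|", pairs$posReads),
                      score = pairs$negReads + pairs$posReads,
                      strand = ".")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Extract pair-locus sequences for motif discovery
#'
#' Produces one record per spike pair spanning
#' `[negPos - flank, posPos + flank]` (0-based inclusive of both spike
#' positions), headers encoding the coordinates — direct input for motif
#' discovery tools.  Pairs running over a chromosome edge are clipped with
#' a warning.
#'
#' @param pairs Output of [findPairs()].
#' @param reference Named [Biostrings::DNAStringSet] or FASTA path.
#' @param flank Flanking nt on each side (default 5).
#' @param path Optional output FASTA path; written if non-`NULL`.
#' @return A [Biostrings::DNAStringSet] (empty for an empty pair list).
#' @importFrom Biostrings DNAStringSet readDNAStringSet subseq
#'   writeXStringSet
#' @export
exportPairFasta <- function(pairs, reference, flank = 5L, path = NULL) {
    if (is.character(reference)) reference <- readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
    if (!nrow(pairs)) {
        out <- DNAStringSet()
    } else {
        missing <- setdiff(unique(pairs$chrom), names(reference))
        if (length(missing))
            stop("reference lacks chromosome(s): ",
                 paste(missing, collapse = ", "))
        lens <- vapply(reference, length, integer(1))[pairs$chrom]
        from0 <- pairs$negPos - flank
        to0 <- pairs$posPos + flank          # inclusive, 0-based
        clipped <- from0 < 0L | to0 >= lens
        if (any(clipped)) {
            warning(sum(clipped), " pair(s) near a chromosome edge clipped")
            from0 <- pmax(from0, 0L)
            to0 <- pmin(to0, lens - 1L)
        }
        out <- DNAStringSet(vapply(seq_len(nrow(pairs)), function(i)
            as.character(subseq(reference[[pairs$chrom[i]]],
                                start = from0[i] + 1L, end = to0[i] + 1L)),
            character(1)))
        names(out) <- sprintf("%s:%d-%d", pairs$chrom, from0, to0 + 1L)
    }
    if (!is.null(path)) writeXStringSet(out, path)
    out
}
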