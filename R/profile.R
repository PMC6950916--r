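#' @include AllGenerics.R
NULL

#' Build a chromosome frame from a sizes table
#'
#' Reads a two-column `chrom <TAB> length` file (the samtools/bedtools
#' "chrom sizes" convention) into a [GenomeInfoDb::Seqinfo], the genome
#' frame used by every function in the package.
#'
#' @param path Path to a tab-separated chrom-sizes file (no header).
#' @param genome Optional genome build label stored on the Seqinfo.
#' @return A [GenomeInfoDb::Seqinfo].
#' @examples
#' tf <- tempfile()
#' writeLines("chr1\t10000", tf)
#' readGenome(tf)
#' @export
readGenome <- function(path, genome = NA_character_) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "integer"))
    if (!nrow(tab)) stop("empty chrom-sizes file: ", path)
    if (anyDuplicated(tab$chrom)) stop("duplicated chromosome names in ", path)
    if (any(tab$length <= 0L)) stop("chromosome lengths must be positive")
    Seqinfo(seqnames = tab$chrom, seqlengths = tab$length, genome = genome)
}

#' Construct a StrandProfile from a position/count table
#'
#' @param strand `"+"` or `"-"`.
#' @param seqinfo A [GenomeInfoDb::Seqinfo]; positions are validated against
#'   its chromosome lengths.
#' @param data A `data.frame` with columns `chrom`, `pos` (0-based) and
#'   `count`, or `NULL` for an empty profile.
#' @param aggregate If `TRUE` (default) rows sharing `(chrom, pos)` are
#'   summed; if `FALSE` duplicated positions are an error (the contract of
#'   per-base depth files, which emit each position once).
#' @return A [StrandProfile-class].
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chr1", 1000)
#' StrandProfile("+", si, data.frame(chrom = "chr1", pos = 99, count = 3))
#' @export
StrandProfile <- function(strand, seqinfo, data = NULL, aggregate = TRUE) {
    if (is.null(data) || !nrow(data))
        return(new("StrandProfile", strand = strand, seqinfo = seqinfo,
                   data = list()))
    stopifnot(all(c("chrom", "pos", "count") %in% names(data)))
    chrom <- as.character(data$chrom)
    pos <- as.integer(data$pos)
    count <- as.numeric(data$count)
    if (anyDuplicated(paste0(chrom, ":", pos))) {
        if (!aggregate) stop("duplicated position(s) in profile input")
        agg <- rowsum(count, paste0(chrom, ":", pos), reorder = FALSE)
        key <- rownames(agg)
        chrom <- sub(":.*$", "", key)
        pos <- as.integer(sub("^.*:", "", key))
        count <- as.numeric(agg[, 1L])
    }
    lst <- split(data.frame(pos = pos, count = count),
                 factor(chrom, levels = unique(chrom)))
    dat <- lapply(lst, function(d) {
        o <- order(d$pos)
        list(pos = d$pos[o], count = d$count[o])
    })
    new("StrandProfile", strand = strand, seqinfo = seqinfo, data = dat)
}

.emptyProfile <- function(strand, seqinfo)
    new("StrandProfile", strand = strand, seqinfo = seqinfo, data = list())

## Rebuild a profile from per-chromosome pos/count vectors without the
## data.frame round trip (hot path for shuffling and masking).
.profileFromList <- function(strand, seqinfo, dat) {
    dat <- dat[vapply(dat, function(e) length(e$pos) > 0L, logical(1))]
    new("StrandProfile", strand = strand, seqinfo = seqinfo, data = dat)
}

#' @describeIn StrandProfile Total read count over all stored positions.
#' @param x A `StrandProfile`.
#' @export
setMethod("totalCount", "StrandProfile", function(x)
    sum(vapply(x@data, function(e) sum(e$count), numeric(1))))

#' @describeIn StrandProfile Number of distinct positions with coverage.
#' @export
setMethod("nPositions", "StrandProfile", function(x)
    sum(vapply(x@data, function(e) length(e$pos), integer(1))))

#' @describeIn StrandProfile All positions as a `data.frame` with columns
#'   `chrom`, `pos` (0-based), `count`.
#' @export
setMethod("profileData", "StrandProfile", function(x) {
    if (!length(x@data))
        return(data.frame(chrom = character(), pos = integer(),
                          count = numeric()))
    do.call(rbind, lapply(names(x@data), function(chrom) {
        e <- x@data[[chrom]]
        data.frame(chrom = chrom, pos = e$pos, count = e$count,
                   row.names = NULL)
    }))
})

#' @importFrom BiocGenerics strand
#' @export
setMethod("strand", "StrandProfile", function(x) x@strand)

#' @export
setMethod("seqinfo", "StrandProfile", function(x) x@seqinfo)

setMethod("show", "StrandProfile", function(object) {
    cat("StrandProfile on strand", object@strand, "\n")
    cat("  genome:", paste(seqnames(object@seqinfo), collapse = ", "), "\n")
    cat("  ", nPositions(object), " positions, total count ",
        format(totalCount(object)), "\n", sep = "")
})

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
setAs("StrandProfile", "GRanges", function(from) {
    df <- profileData(from)
    gr <- GRanges(df$chrom, IRanges(df$pos + 1L, width = 1L),
                  strand = from@strand, score = df$count,
                  seqinfo = from@seqinfo)
    gr
})

#' Multiply all counts of a profile by a positive constant
#'
#' CNCC is invariant to this operation (its normalization is the point of
#' the statistic); scaling is used when composing mixtures of simulated
#' break species.
#'
#' @param x A [StrandProfile-class].
#' @param factor Positive scalar.
#' @return The scaled profile.
#' @export
scaleCounts <- function(x, factor) {
    stopifnot(is(x, "StrandProfile"), factor > 0, is.finite(factor))
    dat <- lapply(x@data, function(e)
        list(pos = e$pos, count = e$count * factor))
    .profileFromList(x@strand, x@seqinfo, dat)
}

## chromosome-wise pos/count accessor with empty fallback
.chromData <- function(profile, chrom) {
    e <- profile@data[[chrom]]
    if (is.null(e)) list(pos = integer(), count = numeric()) else e
}
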