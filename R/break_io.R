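#' @include profile.R
NULL

#' Read per-base depth in the `genomecov -dz` dialect
#'
#' Parses a three-column `chrom <TAB> pos0 <TAB> depth` file (the sparse
#' per-base output of `bedtools genomecov -dz`, 0-based, zero-depth
#' positions omitted) into a [StrandProfile-class].  Each position must
#' appear at most once, depths must be >= 1, and every chromosome must be
#' present in `seqinfo` — unknown chromosomes are rejected rather than
#' dropped because silent drops would corrupt the CNCC normalization.
#'
#' @param path Path to the dz file (may be empty).
#' @param strand `"+"` or `"-"`: which strand this coverage file describes.
#' @param seqinfo The genome frame ([GenomeInfoDb::Seqinfo] or from
#'   [readGenome()]).
#' @return A [StrandProfile-class].
#' @seealso [writeDepthDZ()], [loadBreakBed()]
#' @export
loadDepthDZ <- function(path, strand, seqinfo) {
    tab <- tryCatch(
        utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "numeric"),
                          col.names = c("chrom", "pos", "depth")),
        error = function(e) {
            if (grepl("no lines available", conditionMessage(e)))
                return(NULL)
            stop("cannot parse dz file ", path, ": ", conditionMessage(e))
        })
    if (is.null(tab) || !nrow(tab))
        return(.emptyProfile(strand, seqinfo))
    bad <- which(is.na(tab$pos) | is.na(tab$depth))
    if (length(bad))
        stop("malformed dz line ", bad[1L], " in ", path)
    if (any(tab$depth < 1))
        stop("dz depth < 1 at line ", which(tab$depth < 1)[1L], " in ", path)
    key <- paste0(tab$chrom, ":", tab$pos)
    if (anyDuplicated(key)) {
        line <- which(duplicated(key))[1L]
        stop("duplicated position at dz line ", line, " in ", path,
             " (each position must appear once)")
    }
    unknown <- setdiff(unique(tab$chrom), seqnames(seqinfo))
    if (length(unknown))
        stop("dz file references chromosomes absent from genome: ",
             paste(unknown, collapse = ", "))
    sl <- seqlengths(seqinfo)
    over <- tab$pos >= sl[tab$chrom] | tab$pos < 0L
    if (any(over))
        stop("dz position out of chromosome bounds at line ",
             which(over)[1L], " in ", path)
    StrandProfile(strand, seqinfo,
                  data.frame(chrom = tab$chrom, pos = tab$pos,
                             count = tab$depth),
                  aggregate = FALSE)
}

#' Write a StrandProfile as `genomecov -dz` style depth text
#'
#' @param x A [StrandProfile-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDepthDZ <- function(x, path) {
    df <- profileData(x)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a StrandProfile as bedGraph
#'
#' @param x A [StrandProfile-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(x, path) {
    df <- profileData(x)
    out <- data.frame(chrom = df$chrom, start = df$pos, end = df$pos + 1L,
                      score = df$count)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read single-nucleotide break ends from BED6
#'
#' Each BED record must be exactly one nucleotide wide (`end == start + 1`)
#' and carries the 5'-most nucleotide of read 1 for one captured break end;
#' the strand column routes the record into the positive- or negative-strand
#' profile and multiple records at a position accumulate.
#'
#' @param path Path to a BED6 file.
#' @param seqinfo The genome frame.
#' @return A list with elements `pos` and `neg`, the two
#'   [StrandProfile-class] objects.
#' @export
loadBreakBed <- function(path, seqinfo) {
    tab <- tryCatch(
        utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "character",
                                         "character")[1:6],
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand")),
        error = function(e) {
            if (grepl("no lines available", conditionMessage(e)))
                return(NULL)
            stop("cannot parse BED6 file ", path, ": ", conditionMessage(e))
        })
    if (is.null(tab))
        return(list(pos = .emptyProfile("+", seqinfo),
                    neg = .emptyProfile("-", seqinfo)))
    if (any(tab$end != tab$start + 1L))
        stop("BED record wider than one nucleotide at line ",
             which(tab$end != tab$start + 1L)[1L],
             " (break ends must be single-nt)")
    if (!all(tab$strand %in% c("+", "-")))
        stop("BED strand column must be '+' or '-'")
    unknown <- setdiff(unique(tab$chrom), seqnames(seqinfo))
    if (length(unknown))
        stop("BED references chromosomes absent from genome: ",
             paste(unknown, collapse = ", "))
    mk <- function(str) {
        sel <- tab$strand == str
        StrandProfile(str, seqinfo,
                      data.frame(chrom = tab$chrom[sel], pos = tab$start[sel],
                                 count = 1))
    }
    list(pos = mk("+"), neg = mk("-"))
}

#' Read an interval mask (e.g. centromeres) from BED
#'
#' Intervals are imported, sorted and merged; the result is suitable for
#' [applyMask()].  Requires the rtracklayer package.
#'
#' @param path Path to a BED file of intervals to discard.
#' @param seqinfo The genome frame.
#' @return A reduced [GenomicRanges::GRanges].
#' @importFrom GenomicRanges reduce
#' @export
readMask <- function(path, seqinfo) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("readMask requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "BED")
    GenomeInfoDb::seqlevels(gr) <- seqnames(seqinfo)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
    reduce(gr, ignore.strand = TRUE)
}

#' Remove profile coverage inside masked intervals
#'
#' Positions falling inside the mask (e.g. centromeres) are discarded before
#' the final CNCC calculation; everything else is untouched.  The operation
#' never increases a count and is idempotent.
#'
#' @param profile A [StrandProfile-class].
#' @param mask A [GenomicRanges::GRanges] of intervals to discard (strand
#'   ignored), e.g. from [readMask()].
#' @return The masked [StrandProfile-class].
#' @importFrom GenomicRanges GRanges start end
#' @importFrom BiocGenerics which
#' @export
applyMask <- function(profile, mask) {
    if (!length(mask) || !length(profile@data)) return(profile)
    mchrom <- as.character(GenomeInfoDb::seqnames(mask))
    ms <- start(mask) - 1L          # to 0-based half-open
    me <- end(mask)
    dat <- profile@data
    for (chrom in names(dat)) {
        sel <- mchrom == chrom
        if (!any(sel)) next
        e <- dat[[chrom]]
        drop <- rep(FALSE, length(e$pos))
        for (k in base::which(sel))
            drop <- drop | (e$pos >= ms[k] & e$pos < me[k])
        dat[[chrom]] <- list(pos = e$pos[!drop], count = e$count[!drop])
    }
    .profileFromList(profile@strand, profile@seqinfo, dat)
}

#' Extract read-1 5'-end break positions from coordinate-sorted alignments
#'
#' Applies the break-mapping filter contract — paired, proper pair, read 1
#' (`-f 67`), not unmapped/secondary/supplementary/QC-fail (`-F 2820`), not
#' a PCR duplicate (`-F 1024`) — and records the 5' end of each surviving
#' alignment: the leftmost aligned reference base for forward-strand reads
#' and the rightmost aligned base for reverse-strand reads (soft-clips
#' excluded, mirroring `genomecov -5`).  No MAPQ cutoff is applied by
#' default because the upstream filters leave that choice open; set
#' `minMapq` to impose one.
#'
#' @param bamPath Path to an indexed BAM file.
#' @param seqinfo The genome frame.
#' @param minMapq Minimum mapping quality (default 0, i.e. no cutoff).
#' @return A list with [StrandProfile-class] elements `pos` and `neg`.
#' @export
extractRead1FivePrime <- function(bamPath, seqinfo, minMapq = 0L) {
    if (!requireNamespace("Rsamtools", quietly = TRUE) ||
        !requireNamespace("GenomicAlignments", quietly = TRUE))
        stop("extractRead1FivePrime requires Rsamtools and GenomicAlignments")
    flag <- Rsamtools::scanBamFlag(
        isPaired = TRUE, isProperPair = TRUE, isFirstMateRead = TRUE,
        isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
        isSupplementaryAlignment = FALSE, isNotPassingQualityControls = FALSE,
        isDuplicate = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, what = "mapq")
    aln <- GenomicAlignments::readGAlignments(bamPath, param = param)
    if (minMapq > 0L) {
        mapq <- S4Vectors::mcols(aln)$mapq
        aln <- aln[!is.na(mapq) & mapq >= minMapq]
    }
    if (!length(aln)) {
        warning("no alignments pass the read-1 break-mapping filter")
        return(list(pos = .emptyProfile("+", seqinfo),
                    neg = .emptyProfile("-", seqinfo)))
    }
    chrom <- as.character(GenomeInfoDb::seqnames(aln))
    fwd <- as.character(BiocGenerics::strand(aln)) == "+"
    ## 0-based: leftmost aligned base for +, rightmost for -
    p5 <- ifelse(fwd, BiocGenerics::start(aln) - 1L, BiocGenerics::end(aln) - 1L)
    mk <- function(sel, str)
        StrandProfile(str, seqinfo,
                      data.frame(chrom = chrom[sel], pos = p5[sel], count = 1))
    list(pos = mk(fwd, "+"), neg = mk(!fwd, "-"))
}
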