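#' @import methods
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqinfo
#' @importFrom S4Vectors metadata
NULL

setClassUnion("ListOrNULL", c("list", "NULL"))

#' StrandProfile: sparse single-nucleotide break-end coverage on one strand
#'
#' A `StrandProfile` stores, for one strand, the number of sequencing-read
#' 5' ends (read 1 of each pair, i.e. the break-proximal nucleotide) observed
#' at each genomic position.  Positions are 0-based and only positions with
#' at least one read are stored; this is the `x(i)` / `y(i)` signal of the
#' coverage-normalized cross correlation.
#'
#' @slot strand `"+"` or `"-"`.
#' @slot seqinfo A [GenomeInfoDb::Seqinfo] giving the chromosome frame;
#'   every stored position must be `< seqlengths` of its chromosome.
#' @slot data Named list (one element per chromosome with data); each element
#'   is a `list(pos = <0-based integer, strictly increasing>,
#'   count = <positive numeric>)`.
#'
#' @seealso [StrandProfile()], [loadDepthDZ()], [loadBreakBed()],
#'   [computeCNCC()]
#' @exportClass StrandProfile
setClass("StrandProfile",
         representation(strand = "character",
                        seqinfo = "Seqinfo",
                        data = "list"))

setValidity("StrandProfile", function(object) {
    msg <- character()
    if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be a single \"+\" or \"-\"")
    sl <- seqlengths(object@seqinfo)
    nm <- names(object@data)
    if (length(object@data) && (is.null(nm) || anyDuplicated(nm)))
        msg <- c(msg, "data must be a uniquely named list")
    bad <- setdiff(nm, seqnames(object@seqinfo))
    if (length(bad))
        msg <- c(msg, paste0("chromosomes absent from genome: ",
                             paste(bad, collapse = ", ")))
    for (chrom in intersect(nm, seqnames(object@seqinfo))) {
        el <- object@data[[chrom]]
        if (!is.list(el) || !all(c("pos", "count") %in% names(el))) {
            msg <- c(msg, sprintf("malformed data for %s", chrom)); next
        }
        p <- el$pos; k <- el$count
        if (length(p) != length(k))
            msg <- c(msg, sprintf("%s: pos/count length mismatch", chrom))
        if (length(p)) {
            if (is.unsorted(p, strictly = TRUE))
                msg <- c(msg, sprintf("%s: positions must be strictly increasing", chrom))
            if (min(p) < 0L || max(p) >= sl[[chrom]])
                msg <- c(msg, sprintf("%s: positions out of chromosome bounds", chrom))
            if (any(!is.finite(k)) || any(k <= 0))
                msg <- c(msg, sprintf("%s: counts must be positive and finite", chrom))
        }
    }
    if (length(msg)) msg else TRUE
})

#' CNCCCurve: coverage-normalized cross correlation over a shift range
#'
#' Holds `CNCC(t)` for every integer shift `t` in a contiguous range,
#' together with the global normalization terms.  `CNCC(t) =
#' sum_i y(i) x(i - t) / sqrt(sum_i x(i)^2 * sum_i y(i)^2)` where `x` is
#' positive-strand and `y` negative-strand break-end coverage; products are
#' only taken within a chromosome while the normalization is genome-wide.
#' Cauchy-Schwarz guarantees `|CNCC(t)| <= 1`.
#'
#' @slot shift Integer vector of shifts (contiguous, increasing).
#' @slot value Numeric CNCC value per shift.
#' @slot sumsqPos,sumsqNeg The genome-wide sums of squared coverage used in
#'   the denominator.
#' @slot metadata List of provenance (e.g. the control median subtracted by
#'   [relativeCNCC()]).
#' @seealso [computeCNCC()], [dominantShifts()], [resectionRange()]
#' @exportClass CNCCCurve
setClass("CNCCCurve",
         representation(shift = "integer",
                        value = "numeric",
                        sumsqPos = "numeric",
                        sumsqNeg = "numeric",
                        metadata = "list"))

setValidity("CNCCCurve", function(object) {
    msg <- character()
    if (length(object@shift) != length(object@value))
        msg <- c(msg, "shift and value lengths differ")
    if (length(object@shift) &&
        !identical(object@shift, seq(object@shift[1L],
                                     object@shift[length(object@shift)])))
        msg <- c(msg, "shifts must be a contiguous increasing integer range")
    if (object@sumsqPos <= 0 || object@sumsqNeg <= 0)
        msg <- c(msg, "normalization terms must be positive")
    if (length(msg)) msg else TRUE
})

#' EndStructure: the geometry of a double-strand-break terminus
#'
#' A break end is blunt, a 3' overhang, or a 5' overhang.  End-blunting
#' during library preparation trims 3' overhangs (separating the two mapped
#' 5' ends) and fills in 5' overhangs (overlapping them), so each structure
#' maps to a characteristic shift of the CNCC curve: -1 for blunt,
#' `-1 - L` for a 3' overhang of `L` nt, `-1 + L` for a 5' overhang of
#' `L` nt.
#'
#' @slot kind One of `"blunt"`, `"three_prime_overhang"`,
#'   `"five_prime_overhang"`.
#' @slot overhang Non-negative integer overhang length in nt (0 iff blunt).
#' @seealso [shiftToStructure()], [structureToShift()]
#' @exportClass EndStructure
setClass("EndStructure",
         representation(kind = "character", overhang = "integer"))

setValidity("EndStructure", function(object) {
    kinds <- c("blunt", "three_prime_overhang", "five_prime_overhang")
    msg <- character()
    if (length(object@kind) != 1L || !object@kind %in% kinds)
        msg <- c(msg, paste("kind must be one of:", paste(kinds, collapse = ", ")))
    if (length(object@overhang) != 1L || is.na(object@overhang) ||
        object@overhang < 0L)
        msg <- c(msg, "overhang must be a single non-negative integer")
    else if ((object@kind == "blunt") != (object@overhang == 0L))
        msg <- c(msg, "overhang must be 0 for blunt ends and >= 1 otherwise")
    if (length(msg)) msg else TRUE
})

#' BreakSiteSet: candidate cut sites with expected end positions and reads
#'
#' Each site records where its two blunted break ends are expected to map:
#' the negative-strand 5' end (`negEnd`) and the positive-strand 5' end
#' (`posEnd`), both 0-based, plus the number of reads observed at those two
#' positions.  Used by the site-masking sensitivity scan and by spike-pair
#' analysis.
#'
#' @slot sites `data.frame` with columns `chrom`, `negEnd`, `posEnd`,
#'   `reads` (NA until counted against profiles).
#' @slot minReads The strict lower read-count bound applied by
#'   [filterSites()] (sites with `reads > minReads` are kept).
#' @seealso [sitesFromMotif()], [countSiteReads()], [maskSites()]
#' @exportClass BreakSiteSet
setClass("BreakSiteSet",
         representation(sites = "data.frame", minReads = "numeric"))

setValidity("BreakSiteSet", function(object) {
    need <- c("chrom", "negEnd", "posEnd", "reads")
    if (!all(need %in% names(object@sites)))
        return(paste("sites must have columns:", paste(need, collapse = ", ")))
    s <- object@sites
    if (anyDuplicated(s[c("chrom", "negEnd")]))
        return("duplicated site (chrom, negEnd)")
    TRUE
})

#' RegionSet: a five-way labelled partition of the genome
#'
#' Labels every base of the genome as exactly one of `promoter`, `TSS`,
#' `TTS`, `gene_body` or `intergenic`, built strand-aware from gene models
#' with overlap precedence TSS > promoter > TTS > gene_body.
#'
#' @slot regions Named list of [GenomicRanges::GRanges] (1-based, as usual
#'   for GRanges), one per label; disjoint across labels and jointly
#'   covering the genome.
#' @slot seqinfo The genome frame the partition covers.
#' @seealso [buildRegions()], [breakDensityBPMM()]
#' @exportClass RegionSet
setClass("RegionSet",
         representation(regions = "list", seqinfo = "Seqinfo"))

setValidity("RegionSet", function(object) {
    lbl <- c("promoter", "TSS", "TTS", "gene_body", "intergenic")
    if (!identical(sort(names(object@regions)), sort(lbl)))
        return(paste("regions must be named:", paste(lbl, collapse = ", ")))
    TRUE
})

#' ResectionSignature: the 90%-of-maximum CNCC range in a resection window
#'
#' Summarizes a spread of 3'-overhang signal (shifts < -1) as the maximal
#' contiguous run of shifts around the window maximum whose CNCC values all
#' reach `thresholdFrac` of that maximum, reported both as shifts and as
#' overhang lengths.
#'
#' @slot windowLo,windowHi The searched shift window (both < -1).
#' @slot peakShift,peakValue Argmax shift in the window and its CNCC value.
#' @slot shiftLo,shiftHi The contiguous above-threshold run of shifts.
#' @slot thresholdFrac Fraction of the peak defining the run (default 0.9).
#' @seealso [resectionRange()]
#' @exportClass ResectionSignature
setClass("ResectionSignature",
         representation(windowLo = "integer", windowHi = "integer",
                        peakShift = "integer", peakValue = "numeric",
                        shiftLo = "integer", shiftHi = "integer",
                        thresholdFrac = "numeric"))

setValidity("ResectionSignature", function(object) {
    msg <- character()
    if (object@windowHi >= -1L)
        msg <- c(msg, "resection window must lie entirely below shift -1")
    if (object@shiftLo > object@shiftHi)
        msg <- c(msg, "shiftLo must be <= shiftHi")
    if (object@shiftLo < object@windowLo || object@shiftHi > object@windowHi)
        msg <- c(msg, "recovered range must lie within the window")
    if (object@thresholdFrac <= 0 || object@thresholdFrac > 1)
        msg <- c(msg, "thresholdFrac must be in (0, 1]")
    if (length(msg)) msg else TRUE
})
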