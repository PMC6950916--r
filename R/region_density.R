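#' @include profile.R
NULL

#' Read minimal gene models from a 4-column TSV
#'
#' Columns: `chrom`, `strand`, `tss`, `tts` (0-based transcription start
#' and termination positions; for minus-strand genes `tss > tts` in genomic
#' coordinates).
#'
#' @param path Path to the TSV (header optional; detected).
#' @return `data.frame` with those four columns.
#' @export
readGenesTSV <- function(path) {
    first <- readLines(path, n = 1L)
    hasHeader <- grepl("chrom", first, ignore.case = TRUE)
    tab <- utils::read.table(path, sep = "\t", header = hasHeader,
                             col.names = c("chrom", "strand", "tss", "tts"),
                             colClasses = c("character", "character",
                                            "integer", "integer"))
    stopifnot(all(tab$strand %in% c("+", "-")))
    tab
}

#' Read gene models from the gene lines of a GTF
#'
#' Keeps records with feature type `gene` and converts them to the minimal
#' model: TSS at the strand-aware start of the gene, TTS at its end.
#'
#' @param path Path to a GTF(-like) file.
#' @return `data.frame` with columns `chrom`, `strand`, `tss`, `tts`
#'   (0-based).
#' @export
readGenesGTF <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             comment.char = "#", quote = "",
                             col.names = c("chrom", "source", "feature",
                                           "start", "end", "score", "strand",
                                           "frame", "attr"))
    tab <- tab[tab$feature == "gene", , drop = FALSE]
    stopifnot(all(tab$strand %in% c("+", "-")))
    ## GTF is 1-based closed; TSS/TTS 0-based, strand-aware
    data.frame(chrom = tab$chrom, strand = tab$strand,
               tss = ifelse(tab$strand == "+", tab$start - 1L, tab$end - 1L),
               tts = ifelse(tab$strand == "+", tab$end - 1L, tab$start - 1L))
}

#' Partition the genome into promoter/TSS/TTS/gene-body/intergenic
#'
#' Builds the five-way labelled partition used for break-density
#' annotation, strand-aware around each gene (0-based half-open spans,
#' upstream meaning 5' of the gene):
#' promoter `[TSS-1000, TSS-250)`, TSS region `[TSS-250, TSS+250)`,
#' TTS region `[TTS-250, TTS+250)`, gene body `[TSS+250, TTS-250)`,
#' intergenic everything else.  Overlaps are resolved by the fixed
#' precedence TSS > promoter > TTS > gene body, so every base receives
#' exactly one label; genes shorter than 500 nt simply have an empty body.
#' Spans are clipped at chromosome edges.
#'
#' @param genes `data.frame` with columns `chrom`, `strand`, `tss`, `tts`
#'   (0-based; see [readGenesTSV()]).
#' @param seqinfo Genome frame.
#' @return A [RegionSet-class].
#' @importFrom GenomicRanges GRanges reduce setdiff union
#' @importFrom IRanges IRanges
#' @export
buildRegions <- function(genes, seqinfo) {
    sl <- seqlengths(seqinfo)
    mkGR <- function(chrom, start0, end0) {
        len <- sl[chrom]
        start0 <- pmax(start0, 0L)
        end0 <- pmin(end0, len)
        keep <- start0 < end0
        gr <- GRanges(chrom[keep],
                      IRanges(start0[keep] + 1L, end0[keep]),
                      seqinfo = seqinfo)
        reduce(gr)
    }
    genomeGR <- GRanges(seqnames(seqinfo), IRanges(1L, sl),
                        seqinfo = seqinfo)
    if (is.null(genes) || !nrow(genes)) {
        empty <- GRanges(seqinfo = seqinfo)
        return(new("RegionSet",
                   regions = list(promoter = empty, TSS = empty, TTS = empty,
                                  gene_body = empty, intergenic = genomeGR),
                   seqinfo = seqinfo))
    }
    fwd <- genes$strand == "+"
    g <- genes
    tssR <- mkGR(g$chrom, g$tss - 250L, g$tss + 250L)
    ttsR <- mkGR(g$chrom, g$tts - 250L, g$tts + 250L)
    promR <- mkGR(g$chrom,
                  ifelse(fwd, g$tss - 1000L, g$tss + 250L),
                  ifelse(fwd, g$tss - 250L, g$tss + 1000L))
    bodyR <- mkGR(g$chrom,
                  ifelse(fwd, g$tss + 250L, g$tts + 250L),
                  ifelse(fwd, g$tts - 250L, g$tss - 250L))
    ## fixed precedence: TSS > promoter > TTS > gene body
    prom <- setdiff(promR, tssR)
    tts <- setdiff(ttsR, union(tssR, prom))
    claimed <- base::Reduce(union, list(tssR, prom, tts))
    body <- setdiff(bodyR, claimed)
    inter <- setdiff(genomeGR, union(claimed, body))
    new("RegionSet",
        regions = list(promoter = prom, TSS = tssR, TTS = tts,
                       gene_body = body, intergenic = inter),
        seqinfo = seqinfo)
}

#' @describeIn RegionSet Named list of the five labels' [GenomicRanges::GRanges].
#' @param x A `RegionSet`.
#' @export
setMethod("regionRanges", "RegionSet", function(x) x@regions)

#' @describeIn RegionSet Total bp per label.
#' @importFrom BiocGenerics width
#' @export
setMethod("regionWidths", "RegionSet", function(x)
    vapply(x@regions, function(gr) sum(as.numeric(width(gr))), numeric(1)))

setMethod("show", "RegionSet", function(object) {
    w <- regionWidths(object)
    cat("RegionSet partition:\n")
    for (lbl in names(w))
        cat(sprintf("  %-10s %12.0f bp\n", lbl, w[[lbl]]))
})

#' Export a RegionSet as labelled BED
#'
#' @param x A [RegionSet-class].
#' @param path Output path (BED4: chrom, start, end, label).
#' @return `path`, invisibly.
#' @importFrom GenomicRanges start end
#' @export
writeRegionsBed <- function(x, path) {
    rows <- do.call(rbind, lapply(names(x@regions), function(lbl) {
        gr <- x@regions[[lbl]]
        if (!length(gr)) return(NULL)
        data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr), label = lbl)
    }))
    rows <- rows[order(rows$chrom, rows$start), , drop = FALSE]
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

## Sum of break counts (both strands) inside a GRanges
#' @importFrom IRanges findOverlaps
#' @importFrom S4Vectors queryHits
.breaksIn <- function(gr, pos, neg) {
    tot <- 0
    for (profile in list(pos, neg)) {
        df <- profileData(profile)
        if (!nrow(df)) next
        pgr <- GRanges(df$chrom, IRanges(df$pos + 1L, width = 1L))
        hits <- findOverlaps(pgr, gr)
        tot <- tot + sum(df$count[unique(queryHits(hits))])
    }
    tot
}

#' Break density per region class, in BPMM
#'
#' BPMM (breaks per megabase per million mapped breaks) normalizes a
#' label's break count by both the label's size and the library depth:
#' `BPMM = (breaks_in_label / (label_Mb)) / (total_breaks / 1e6)`.
#' 100 breaks falling in a 1-Mb label out of a million total is a BPMM of
#' 100; duplicating the whole dataset leaves every BPMM unchanged.
#'
#' @param pos,neg The [StrandProfile-class] pair (counts from both strands
#'   are summed).
#' @param regions A [RegionSet-class].
#' @return Named numeric vector of BPMM per label (NA, with a warning, for
#'   a zero-width label).
#' @export
breakDensityBPMM <- function(pos, neg, regions) {
    total <- totalCount(pos) + totalCount(neg)
    if (total <= 0) stop("no breaks: BPMM undefined")
    w <- regionWidths(regions)
    out <- rep(NA_real_, length(w)); names(out) <- names(w)
    for (lbl in names(w)) {
        if (w[[lbl]] == 0) {
            warning("zero-width label '", lbl, "' excluded from BPMM")
            next
        }
        b <- .breaksIn(regions@regions[[lbl]], pos, neg)
        out[[lbl]] <- (b / (w[[lbl]] / 1e6)) / (total / 1e6)
    }
    out
}

#' Per-window break densities within each region class
#'
#' Tiles each label's intervals into non-overlapping windows (partial
#' windows at interval ends are dropped) and computes the BPMM of every
#' window, providing the per-window observations used by the rank-based
#' group comparison.
#'
#' @inheritParams breakDensityBPMM
#' @param windowSize Window width in nt (default 1000).
#' @return Named list label -> numeric vector of window BPMM values.
#' @importFrom GenomicRanges slidingWindows
#' @importFrom S4Vectors subjectHits
#' @export
windowDensities <- function(pos, neg, regions, windowSize = 1000L) {
    total <- totalCount(pos) + totalCount(neg)
    if (total <= 0) stop("no breaks: densities undefined")
    dfs <- lapply(list(pos, neg), profileData)
    df <- do.call(rbind, dfs)
    pgr <- GRanges(df$chrom, IRanges(df$pos + 1L, width = 1L))
    out <- list()
    for (lbl in names(regions@regions)) {
        gr <- regions@regions[[lbl]]
        if (!length(gr)) { out[[lbl]] <- numeric(); next }
        win <- BiocGenerics::unlist(slidingWindows(gr, windowSize,
                                                   windowSize))
        win <- win[width(win) == windowSize]
        if (!length(win)) { out[[lbl]] <- numeric(); next }
        counts <- numeric(length(win))
        hits <- findOverlaps(pgr, win)
        if (length(hits)) {
            agg <- rowsum(df$count[queryHits(hits)], subjectHits(hits))
            counts[as.integer(rownames(agg))] <- agg[, 1L]
        }
        out[[lbl]] <- (counts / (windowSize / 1e6)) / (total / 1e6)
    }
    out
}

#' Rank-based comparison of break densities between treatment groups
#'
#' A thin convenience over standard rank statistics: per region label, a
#' Kruskal-Wallis test across groups ([stats::kruskal.test]) followed by
#' pairwise Dunn z tests (rank-sum differences with tie correction) whose
#' p values are Benjamini-Hochberg adjusted within the label.  Constant
#' data yields H = 0 and p = 1 rather than an error.
#'
#' @param densities Named list: group -> (named list: label -> numeric
#'   vector of per-window densities, e.g. from [windowDensities()]).
#'   At least two groups with at least two observations each.
#' @return List with `kw` (`data.frame`: `label`, `H`, `df`, `p`) and
#'   `dunn` (`data.frame`: `label`, `group1`, `group2`, `z`, `p`, `p.adj`).
#' @export
compareDensities <- function(densities) {
    stopifnot(length(densities) >= 2L)
    groups <- names(densities)
    labels <- base::Reduce(base::intersect, lapply(densities, names))
    kwRows <- list(); dunnRows <- list()
    for (lbl in labels) {
        vals <- lapply(densities, `[[`, lbl)
        if (any(vapply(vals, length, integer(1)) < 2L))
            stop("each group needs >= 2 observations for label ", lbl)
        x <- unlist(vals, use.names = FALSE)
        gfac <- factor(rep(groups, vapply(vals, length, integer(1))),
                       levels = groups)
        if (length(unique(x)) == 1L) {
            kwRows[[lbl]] <- data.frame(label = lbl, H = 0,
                                        df = length(groups) - 1L, p = 1)
            cmb <- utils::combn(groups, 2L)
            dunnRows[[lbl]] <- data.frame(label = lbl, group1 = cmb[1L, ],
                                          group2 = cmb[2L, ], z = 0, p = 1,
                                          p.adj = 1)
            next
        }
        kw <- stats::kruskal.test(x, gfac)
        kwRows[[lbl]] <- data.frame(label = lbl,
                                    H = unname(kw$statistic),
                                    df = unname(kw$parameter),
                                    p = kw$p.value)
        dunnRows[[lbl]] <- cbind(label = lbl, .dunnTest(x, gfac))
    }
    list(kw = do.call(rbind, c(kwRows, list(make.row.names = FALSE))),
         dunn = do.call(rbind, c(dunnRows, list(make.row.names = FALSE))))
}

## Dunn's pairwise z statistics with tie correction; BH-adjusted p values.
.dunnTest <- function(x, g) {
    N <- length(x)
    r <- rank(x)
    rbar <- tapply(r, g, mean)
    n <- tapply(r, g, length)
    ties <- table(x)
    C <- sum(ties^3 - ties) / (12 * (N - 1))
    s2 <- N * (N + 1) / 12 - C
    cmb <- utils::combn(levels(g), 2L)
    z <- vapply(seq_len(ncol(cmb)), function(k) {
        a <- cmb[1L, k]; b <- cmb[2L, k]
        (rbar[[a]] - rbar[[b]]) /
            sqrt(s2 * (1 / n[[a]] + 1 / n[[b]]))
    }, numeric(1))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ], z = z, p = p,
               p.adj = stats::p.adjust(p, "BH"))
}
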