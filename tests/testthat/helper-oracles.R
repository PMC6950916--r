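## Shared fixtures and independent oracles.

toy_seqinfo <- function(lens = c(chr1 = 1000L))
    GenomeInfoDb::Seqinfo(names(lens), unname(lens))

## A random sparse profile: n distinct positions per chromosome,
## counts uniform on 1..maxCount.
random_profile <- function(seqinfo, strand, n = 50L, maxCount = 5L,
                           seed = 1L) {
    set.seed(seed)
    sl <- GenomeInfoDb::seqlengths(seqinfo)
    df <- do.call(rbind, lapply(names(sl), function(chrom)
        data.frame(chrom = chrom,
                   pos = sample.int(sl[[chrom]], n) - 1L,
                   count = sample.int(maxCount, n, replace = TRUE))))
    StrandProfile(strand, seqinfo, df)
}

## Brute-force CNCC oracle: dense per-chromosome vectors, explicit loop
## over every (position, shift) pair.  Deliberately naive.
brute_cncc <- function(pos, neg, minShift, maxShift) {
    sl <- GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(pos))
    pdf <- profileData(pos); ndf <- profileData(neg)
    shiftv <- minShift:maxShift
    num <- numeric(length(shiftv))
    for (chrom in names(sl)) {
        len <- sl[[chrom]]
        x <- numeric(len); y <- numeric(len)
        s <- pdf[pdf$chrom == chrom, ]; x[s$pos + 1L] <- s$count
        s <- ndf[ndf$chrom == chrom, ]; y[s$pos + 1L] <- s$count
        for (k in seq_along(shiftv)) {
            t <- shiftv[k]
            acc <- 0
            for (i in seq_len(len)) {
                j <- i - t
                if (j >= 1L && j <= len) acc <- acc + y[i] * x[j]
            }
            num[k] <- num[k] + acc
        }
    }
    num / sqrt(sum(pdf$count^2) * sum(ndf$count^2))
}

## Exhaustive local-maximum scan (oracle for dominantShifts peak finding).
naive_local_maxima <- function(values) {
    n <- length(values)
    if (n < 3L) return(integer())
    out <- integer()
    for (i in 2:(n - 1L))
        if (values[i] > values[i - 1L] && values[i] >= values[i + 1L])
            out <- c(out, i)
    out
}

## Naive IUPAC motif scan of one sequence string (both orientations),
## returning 0-based match starts on the plus-strand sequence.
naive_motif_scan <- function(seqChar, motif) {
    expand <- Biostrings::IUPAC_CODE_MAP
    matchAt <- function(s, m, at) {
        for (k in seq_len(nchar(m))) {
            sc <- substr(s, at + k - 1L, at + k - 1L)
            if (!grepl(sc, expand[[substr(m, k, k)]], fixed = TRUE))
                return(FALSE)
        }
        TRUE
    }
    rc <- function(m) {
        comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                  S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                  D = "H", H = "D", N = "N")
        paste(rev(comp[strsplit(m, "")[[1L]]]), collapse = "")
    }
    res <- list(fwd = integer(), rev = integer())
    for (ori in c("fwd", "rev")) {
        m <- if (ori == "fwd") motif else rc(motif)
        for (at in seq_len(nchar(seqChar) - nchar(m) + 1L))
            if (matchAt(seqChar, m, at))
                res[[ori]] <- c(res[[ori]], at - 1L)
    }
    res
}

## Dunn z statistic oracle on a small vector/group pair: textbook rank-sum
## formula written out independently of the package implementation.
naive_dunn_z <- function(x, g, a, b) {
    r <- rank(x)
    N <- length(x)
    tie <- table(x)
    C <- sum(tie^3 - tie) / (12 * (N - 1))
    Ra <- mean(r[g == a]); Rb <- mean(r[g == b])
    na <- sum(g == a); nb <- sum(g == b)
    (Ra - Rb) / sqrt((N * (N + 1) / 12 - C) * (1 / na + 1 / nb))
}
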