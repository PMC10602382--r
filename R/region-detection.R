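## Enriched-region detection: triangular-weighted moving average,
## tolerance automaton, terminal trimming.

#' @importFrom IRanges IRanges start end width
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Triangular window weights
#'
#' A symmetric triangular weight vector of a given length, normalized to
#' sum 1. Odd lengths peak at the single central offset; even lengths have
#' a two-position central plateau (length 12 gives
#' `(1,2,3,4,5,6,6,5,4,3,2,1)/42`).
#'
#' @param windowLen window length in residues
#' @return numeric vector of `windowLen` weights summing to 1
#' @export
triangularWeights <- function(windowLen) {
    w <- as.integer(windowLen)
    if (w < 1L) stop("windowLen must be >= 1")
    half <- w %/% 2L
    raw <- if (w %% 2L == 0L) c(seq_len(half), rev(seq_len(half)))
           else c(seq_len(half + 1L), rev(seq_len(half)))
    raw / sum(raw)
}

#' Windowed enrichment score track
#'
#' Per-residue enrichment for a target residue set: a weighted fraction of
#' target-set membership over a window centered at each residue. Windows
#' truncated at the sequence ends are renormalized over the in-bounds
#' weights, so every position - including terminal ones - carries a score
#' in [0, 1] and the tolerance rule (counted in residues) is well-defined
#' across the whole sequence. For even window lengths the window covers
#' offsets `-(w/2 - 1) .. w/2` around the scored residue.
#'
#' @param seq a single protein sequence
#' @param config a [DetectionConfig-class]
#' @param invalid see [fcr()]
#' @return numeric vector of per-residue scores, same length as the
#'   sequence
#' @export
windowedScore <- function(seq, config = detectionConfig(),
                          invalid = "reject") {
    chars <- .residues(.asSequenceVector(seq)[1L], invalid)
    L <- length(chars)
    x <- as.numeric(chars %in% config@targetSet)
    w <- config@weights
    wl <- config@windowLen
    offsets <- seq_len(wl) - (wl %/% 2L + wl %% 2L)  # centered; even: -(w/2-1)..w/2
    num <- den <- numeric(L)
    pos <- seq_len(L)
    for (k in seq_along(offsets)) {
        idx <- pos + offsets[k]
        ok <- idx >= 1L & idx <= L
        num[ok] <- num[ok] + w[k] * x[idx[ok]]
        den[ok] <- den[ok] + w[k]
    }
    num / den
}

#' Call candidate intervals from a score track
#'
#' Scans a per-residue score track and returns the maximal intervals that
#' begin and end on positions at or above the threshold and in which every
#' internal run of below-threshold positions is no longer than the
#' tolerance. Intervals shorter than `minLen` are discarded (the length
#' filter precedes trimming).
#'
#' @param track numeric score track (from [windowedScore()])
#' @param config a [DetectionConfig-class]
#' @return an [IRanges::IRanges] of candidate intervals (1-based, closed)
#' @export
detectIntervals <- function(track, config = detectionConfig()) {
    above <- which(track >= config@threshold)
    if (length(above) == 0L)
        return(IRanges::IRanges())
    ## split the above-threshold positions wherever the gap between
    ## consecutive ones exceeds the tolerance
    grp <- cumsum(c(1L, diff(above) - 1L > config@tolerance))
    st <- tapply(above, grp, min)
    en <- tapply(above, grp, max)
    keep <- (en - st + 1L) >= config@minLen
    IRanges::IRanges(start = as.integer(st[keep]), end = as.integer(en[keep]))
}

#' Trim interval ends to target-set residues
#'
#' Shrinks each interval so that its first and last residues belong to the
#' target set (uncharged terminal residues are artifacts of the triangular
#' weighting and the tolerance). Intervals containing no target-set
#' residue are dropped; the number dropped is reported via the
#' `"nEmpty"` attribute. Trimmed intervals may fall below the detector's
#' minimum length; they are retained and flagged (`belowMinLen`) unless
#' `strict = TRUE`.
#'
#' @param seq the protein sequence the intervals refer to
#' @param intervals an [IRanges::IRanges]
#' @param config a [DetectionConfig-class]
#' @param strict drop post-trim intervals shorter than `minLen`
#'   (default FALSE)
#' @param invalid see [fcr()]
#' @return an `IRanges` with metadata columns `belowMinLen` and
#'   `preTrimWidth`
#' @export
trimIntervals <- function(seq, intervals, config = detectionConfig(),
                          strict = FALSE, invalid = "reject") {
    chars <- .residues(.asSequenceVector(seq)[1L], invalid)
    isTarget <- chars %in% config@targetSet
    st <- en <- integer(0); pre <- integer(0)
    nEmpty <- 0L
    for (i in seq_along(intervals)) {
        s <- IRanges::start(intervals)[i]; e <- IRanges::end(intervals)[i]
        hit <- which(isTarget[s:e])
        if (length(hit) == 0L) { nEmpty <- nEmpty + 1L; next }
        st <- c(st, s + hit[1L] - 1L)
        en <- c(en, s + hit[length(hit)] - 1L)
        pre <- c(pre, e - s + 1L)
    }
    out <- IRanges::IRanges(start = st, end = en)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        preTrimWidth = pre,
        belowMinLen = IRanges::width(out) < config@minLen)
    if (strict)
        out <- out[!S4Vectors::mcols(out)$belowMinLen]
    attr(out, "nEmpty") <- nEmpty
    out
}

#' Detect enriched regions across a proteome
#'
#' Runs the full per-protein pipeline - windowed score, tolerance-automaton
#' interval calling, terminal trimming - over every sequence and collects
#' the results as a `GRanges` whose seqnames are protein identifiers
#' (coordinates 1-based closed, strand `*`). Detection is fully
#' deterministic.
#'
#' @param proteome named character vector or `AAStringSet` of protein
#'   sequences
#' @param config a [DetectionConfig-class]
#' @param strict drop post-trim regions shorter than `minLen`
#' @param invalid see [fcr()]
#' @return a `GRanges` with metadata columns `sequence` (the spanned
#'   residues), `preTrimWidth`, `belowMinLen` and `targetSet`
#' @examples
#' prot <- c(p1 = paste0(strrep("G", 40), strrep("EK", 30), strrep("G", 40)))
#' detectEnrichedRegions(prot)
#' @export
detectEnrichedRegions <- function(proteome, config = detectionConfig(),
                                  strict = FALSE, invalid = "reject") {
    seqs <- .asSequenceVector(proteome)
    if (length(seqs) == 0L) stop("empty proteome")
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stop("proteome sequences must carry unique names")
    res <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
        track <- windowedScore(seqs[i], config, invalid)
        iv <- detectIntervals(track, config)
        if (length(iv) == 0L) next
        iv <- trimIntervals(seqs[i], iv, config, strict, invalid)
        if (length(iv) == 0L) next
        gr <- GenomicRanges::GRanges(names(seqs)[i], iv)
        S4Vectors::mcols(gr) <- S4Vectors::mcols(iv)
        res[[i]] <- gr
    }
    res <- res[!vapply(res, is.null, logical(1))]
    out <- if (length(res)) suppressWarnings(do.call(c, res))
           else GenomicRanges::GRanges()
    if (length(out)) {
        S4Vectors::mcols(out)$sequence <- vapply(seq_along(out), function(j) {
            p <- as.character(GenomicRanges::seqnames(out))[j]
            substr(seqs[p], IRanges::start(out)[j], IRanges::end(out)[j])
        }, character(1))
        S4Vectors::mcols(out)$targetSet <-
            paste(sort(config@targetSet), collapse = "")
    }
    out
}

#' Write regions as a BED-like TSV
#'
#' Exports regions in BED convention (0-based, half-open): columns
#' `protein`, `start`, `end`, plus the region sequence and flags. Internal
#' coordinates are 1-based closed; only this export uses the BED
#' convention.
#'
#' @param regions a `GRanges` from [detectEnrichedRegions()]
#' @param file output path
#' @return the file path, invisibly
#' @export
writeRegionsBed <- function(regions, file) {
    df <- data.frame(
        protein = as.character(GenomicRanges::seqnames(regions)),
        start = IRanges::start(regions) - 1L,
        end = IRanges::end(regions),
        sequence = S4Vectors::mcols(regions)$sequence,
        belowMinLen = S4Vectors::mcols(regions)$belowMinLen,
        stringsAsFactors = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
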