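## Alignment-based conservation statistics and the compositional-drift
## score over 4-amino-acid sets.

## Alignments are represented as named character vectors of equal-length
## gapped sequences ("-" gaps); Biostrings::AAMultipleAlignment input is
## accepted and converted.
.asAlignment <- function(aln) {
    if (is(aln, "AAMultipleAlignment") || is(aln, "MultipleAlignment"))
        aln <- as.character(Biostrings::unmasked(aln))
    if (is(aln, "XStringSet")) aln <- as.character(aln)
    if (!is.character(aln) || length(aln) == 0L)
        stop("expected a named character vector of aligned sequences")
    if (length(unique(nchar(aln))) != 1L)
        stop("alignment rows must have equal length")
    aln
}

.alnMatrix <- function(aln) {
    do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
}

#' Read an aligned FASTA file
#'
#' @param file path to an aligned (gapped) FASTA file
#' @return named character vector of equal-length rows
#' @export
readAlignmentFasta <- function(file) {
    x <- Biostrings::readAAStringSet(file)
    .asAlignment(x)
}

#' Trim an alignment for conservation statistics
#'
#' Removes exactly one longest and one shortest row (by ungapped length;
#' ties broken by first occurrence, and the two removed rows are always
#' distinct) and then drops any columns consisting only of gaps. Dropping
#' the extremes robs single outlier species of their leverage on the gap
#' and divergence statistics.
#'
#' @param aln an alignment (named character vector, `AAStringSet` or
#'   `AAMultipleAlignment`)
#' @return the trimmed alignment as a named character vector
#' @export
trimAlignment <- function(aln) {
    aln <- .asAlignment(aln)
    if (length(aln) < 4L)
        stop("need at least 4 rows so that 2 survive trimming")
    ungapped <- nchar(gsub("-", "", aln, fixed = TRUE))
    iLong <- which.max(ungapped)
    rest <- setdiff(seq_along(aln), iLong)
    iShort <- rest[which.min(ungapped[rest])]
    kept <- aln[-c(iLong, iShort)]
    m <- .alnMatrix(kept)
    allGap <- colSums(m != "-") == 0L
    if (any(allGap))
        kept <- apply(m[, !allGap, drop = FALSE], 1L, paste, collapse = "")
    setNames(as.character(kept), names(aln)[-c(iLong, iShort)])
}

#' Global gap frequency of an alignment
#'
#' The number of "-" characters divided by the total number of characters
#' across all rows.
#'
#' @inheritParams trimAlignment
#' @return fraction in [0, 1]
#' @export
gapFrequency <- function(aln) {
    m <- .alnMatrix(.asAlignment(aln))
    if (length(m) == 0L) stop("empty alignment")
    mean(m == "-")
}

#' Sequence divergence (mean column-wise entropy)
#'
#' Summarizes each column's amino-acid usage as a probability distribution
#' and averages the Shannon entropy over columns containing at least one
#' non-gap character. Gaps are excluded from the column distributions by
#' default (an indel is already captured by [gapFrequency()]); set
#' `includeGaps = TRUE` to count the gap as a 21st symbol. Reported in
#' nats by default; the base only rescales.
#'
#' @inheritParams trimAlignment
#' @param includeGaps treat "-" as a 21st symbol (default FALSE)
#' @param base logarithm base (default natural)
#' @return mean per-column entropy, >= 0; 0 iff every column distribution
#'   is degenerate
#' @export
divergence <- function(aln, includeGaps = FALSE, base = exp(1)) {
    m <- .alnMatrix(.asAlignment(aln))
    if (length(m) == 0L) stop("empty alignment")
    ent <- apply(m, 2L, function(col) {
        if (!includeGaps) col <- col[col != "-"]
        if (length(col) == 0L) return(NA_real_)
        p <- as.numeric(table(col)) / length(col)
        -sum(p * log(p, base = base))
    })
    mean(ent, na.rm = TRUE)
}

#' Map a reference interval to alignment columns
#'
#' Converts an interval on the *ungapped* reference row (1-based closed)
#' into the contiguous span of alignment columns bounded by the columns of
#' its first and last residues. The span includes any internal columns
#' where the reference is gapped (insertions in other species).
#'
#' @param alnRow the reference row (gapped string)
#' @param start,end interval on the ungapped reference, 1-based closed
#' @return integer vector `c(colStart, colEnd)`
#' @export
mapRegionToColumns <- function(alnRow, start, end) {
    resCols <- which(strsplit(alnRow, "", fixed = TRUE)[[1L]] != "-")
    if (end > length(resCols) || start < 1L || start > end)
        stop("interval [", start, ", ", end,
             "] outside the ungapped reference of length ", length(resCols))
    c(resCols[start], resCols[end])
}

#' Per-species enrichment of a region across an alignment
#'
#' Maps a region on a reference row into alignment columns and computes,
#' for every row, the fraction of target-set residues among its non-gap
#' residues within those columns. A species "retains" (is present in) the
#' region when it has at least `minAligned` non-gap residues there; the
#' profile's `meanEnrichment` averages over present species only.
#'
#' @inheritParams trimAlignment
#' @param refId name of the reference row
#' @param start,end region on the ungapped reference, 1-based closed
#' @param targetSet residue set whose enrichment is measured
#' @param minAligned minimum non-gap residues for presence (default 30)
#' @return list with per-species `enrichment`, `nAligned`, `present`, the
#'   column span, and `meanEnrichment` over present species (NaN if none)
#' @export
regionAlignmentProfile <- function(aln, refId, start, end,
                                   targetSet = c("D", "E", "K", "R"),
                                   minAligned = 30L) {
    aln <- .asAlignment(aln)
    if (!refId %in% names(aln))
        stop("reference row '", refId, "' not in alignment")
    span <- mapRegionToColumns(aln[[refId]], start, end)
    m <- .alnMatrix(aln)[, span[1L]:span[2L], drop = FALSE]
    nAligned <- rowSums(m != "-")
    enrich <- vapply(seq_len(nrow(m)), function(i) {
        res <- m[i, m[i, ] != "-"]
        if (length(res) == 0L) NA_real_ else mean(res %in% targetSet)
    }, numeric(1))
    present <- nAligned >= minAligned
    names(enrich) <- names(nAligned) <- names(present) <- names(aln)
    list(enrichment = enrich, nAligned = nAligned, present = present,
         columns = span,
         meanEnrichment = mean(enrich[present]))
}

#' Enumerate candidate 4-amino-acid sets
#'
#' All sets of four amino acids drawn from the sixteen non-excluded
#' residues whose combined frequency in the supplied vector lies within
#' `freqTol` of `freqTarget`. With the defaults this reproduces the
#' candidate sets of the compositional-drift scan: sets matching the
#' combined frequency of the four charged residues.
#'
#' @param freqs named amino-acid frequency vector (see
#'   [aminoAcidFrequencies()])
#' @param config a [DriftConfig-class] (supplies target and tolerance)
#' @param exclude residues never drawn into a set (default the charged
#'   four)
#' @return list of character vectors of length 4
#' @export
enumerateResidueSets <- function(freqs, config = driftConfig(),
                                 exclude = c("D", "E", "K", "R")) {
    pool <- setdiff(AA_ALPHABET20, exclude)
    cmb <- utils::combn(pool, 4L)
    sums <- colSums(matrix(freqs[cmb], nrow = 4L))
    keep <- abs(sums - config@freqTarget) <= config@freqTol
    lapply(which(keep), function(j) cmb[, j])
}

#' Compositional-drift score for one residue set
#'
#' Scales a raw conservation measurement - the mean over regions of the
#' alignment-mean enrichment - onto a unit scale anchored at the proteome
#' average (0) and at the central enrichment of the originally detected
#' hits (1). Values near 1 mean the enrichment is retained across
#' homologs; values near 0 mean it has drifted back to background. The
#' scaled score can slightly exceed [0, 1].
#'
#' @param regionMeans numeric vector: alignment-mean enrichment of each
#'   region (from [regionAlignmentProfile()])
#' @param proteomeAvg combined proteome frequency of the residue set (the
#'   0-anchor)
#' @param center central enrichment of the detected hits (the 1-anchor)
#' @return list with `raw` and `scaled`
#' @export
driftScore <- function(regionMeans, proteomeAvg, center) {
    regionMeans <- regionMeans[!is.na(regionMeans)]
    if (length(regionMeans) == 0L)
        stop("no region measurements")
    if (abs(center - proteomeAvg) < 1e-12)
        stop("degenerate scale: hits center equals the proteome average")
    raw <- mean(regionMeans)
    list(raw = raw, scaled = (raw - proteomeAvg) / (center - proteomeAvg))
}

#' Compositional-drift scan over residue sets
#'
#' For each candidate 4-amino-acid set: detect regions enriched for the
#' set across the proteome (relaxed detector: threshold, tolerance and
#' minimum length from the [DriftConfig-class]), measure each detected
#' region's alignment-mean enrichment in its family alignment, and compute
#' the drift score with the proteome-wide combined frequency of the set as
#' the 0-anchor and the central enrichment of the detected hits themselves
#' as the 1-anchor. The center statistic is the median by default (robust
#' to a few extreme hits); the mean is available.
#'
#' @param proteome named character vector or `AAStringSet`
#' @param alignments named list of alignments, keyed by protein id; each
#'   alignment must contain a row whose name is the protein id (the
#'   reference species row)
#' @param config a [DriftConfig-class]
#' @param sets list of 4-residue sets to scan; default: enumerate from the
#'   proteome frequencies via [enumerateResidueSets()], with the charged
#'   set prepended
#' @param designated the set whose percentile is reported (default the
#'   charged four)
#' @param centerStat `"median"` (default) or `"mean"`
#' @return list with `table` (one row per set: set, nRegions, raw, center,
#'   proteomeAvg, scaled) and `percentile` of the designated set among the
#'   scaled scores (100 = most conserved)
#' @export
driftScan <- function(proteome, alignments, config = driftConfig(),
                      sets = NULL,
                      designated = c("D", "E", "K", "R"),
                      centerStat = c("median", "mean")) {
    centerStat <- match.arg(centerStat)
    proteome <- .asSequenceVector(proteome)
    freqs <- aminoAcidFrequencies(proteome)
    if (is.null(sets))
        sets <- c(list(sort(designated)), enumerateResidueSets(freqs, config))
    sets <- unique(lapply(sets, sort))
    rows <- lapply(sets, function(s) {
        det <- detectionConfig(threshold = config@threshold,
                               tolerance = config@tolerance,
                               minLen = config@minLen, targetSet = s)
        regions <- detectEnrichedRegions(proteome, det)
        if (length(regions) == 0L)
            return(data.frame(set = paste(s, collapse = ""), nRegions = 0L,
                              raw = NA, center = NA,
                              proteomeAvg = sum(freqs[s]), scaled = NA))
        own <- vapply(S4Vectors::mcols(regions)$sequence,
                      function(sq) mean(.residues(sq) %in% s), numeric(1))
        center <- if (centerStat == "median") stats::median(own) else mean(own)
        prot <- as.character(GenomicRanges::seqnames(regions))
        alnMean <- vapply(seq_along(regions), function(j) {
            fam <- alignments[[prot[j]]]
            if (is.null(fam)) return(NA_real_)
            pr <- regionAlignmentProfile(fam, prot[j],
                                         IRanges::start(regions)[j],
                                         IRanges::end(regions)[j],
                                         targetSet = s,
                                         minAligned = config@minAligned)
            pr$meanEnrichment
        }, numeric(1))
        alnMean <- alnMean[is.finite(alnMean)]
        if (length(alnMean) == 0L)
            return(data.frame(set = paste(s, collapse = ""),
                              nRegions = length(regions), raw = NA,
                              center = center, proteomeAvg = sum(freqs[s]),
                              scaled = NA))
        ds <- driftScore(alnMean, sum(freqs[s]), center)
        data.frame(set = paste(s, collapse = ""),
                   nRegions = length(regions), raw = ds$raw,
                   center = center, proteomeAvg = sum(freqs[s]),
                   scaled = ds$scaled)
    })
    tab <- do.call(rbind, rows)
    desKey <- paste(sort(designated), collapse = "")
    sc <- tab$scaled[!is.na(tab$scaled)]
    desScore <- tab$scaled[tab$set == desKey]
    percentile <- if (length(desScore) == 1L && !is.na(desScore))
        100 * mean(sc <= desScore) else NA_real_
    list(table = tab, percentile = percentile)
}
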