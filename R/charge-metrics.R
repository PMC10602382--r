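## Per-sequence charge metrics: FCR, NCPR, kappa patterning, hydropathy.

#' @importFrom Biostrings AAStringSet DNAStringSet
NULL

## Split a sequence into uppercase residue characters, enforcing the
## 20-letter alphabet. mode "reject" errors on any non-standard character;
## mode "ignore" drops them (with a warning) from both the counts and the
## effective length.
.residues <- function(seq, invalid = c("reject", "ignore")) {
    invalid <- match.arg(invalid)
    if (length(seq) != 1L || is.na(seq))
        stop("expected a single sequence string")
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
    if (length(chars) == 0L)
        stop("empty sequence")
    bad <- !(chars %in% AA_ALPHABET20)
    if (any(bad)) {
        if (invalid == "reject")
            stop("non-standard residue(s): ",
                 paste(unique(chars[bad]), collapse = ", "))
        warning("dropping ", sum(bad), " non-standard residue(s)")
        chars <- chars[!bad]
        if (length(chars) == 0L)
            stop("no standard residues left after dropping invalid ones")
    }
    chars
}

.asSequenceVector <- function(x) {
    if (is(x, "XStringSet")) as.character(x)
    else if (is.character(x)) x
    else stop("expected character sequences or an (AA/DNA)StringSet")
}

## +1 / -1 / 0 charge per residue under a ChargeModel.
.chargeVector <- function(chars, model) {
    ch <- integer(length(chars))
    ch[chars %in% model@positive] <- 1L
    ch[chars %in% model@negative] <- -1L
    ch
}

#' Fraction of charged residues (FCR)
#'
#' The fraction of residues belonging to the positive or negative set of a
#' [ChargeModel-class].
#'
#' @param x a character vector of sequences or an `AAStringSet`
#' @param model a [ChargeModel-class] (default: K/R positive, D/E negative)
#' @param invalid how to handle non-standard residues: `"reject"` (error)
#'   or `"ignore"` (drop from counts and length, with a warning)
#' @return numeric vector of fractions in [0, 1]
#' @examples
#' fcr(c("EKEK", "GSGS"))
#' @export
fcr <- function(x, model = chargeModel(), invalid = "reject") {
    vapply(.asSequenceVector(x), function(s) {
        chars <- .residues(s, invalid)
        mean(chars %in% chargedResidues(model))
    }, numeric(1), USE.NAMES = !is.null(names(x)))
}

#' Net charge per residue (NCPR)
#'
#' Signed net charge per residue, `(n_pos - n_neg) / L`; positive values
#' indicate a K/R excess under the default model.
#'
#' @inheritParams fcr
#' @return numeric vector in [-1, 1]
#' @examples
#' ncpr(c("EK", "EE", "KKGG"))
#' @export
ncpr <- function(x, model = chargeModel(), invalid = "reject") {
    vapply(.asSequenceVector(x), function(s) {
        chars <- .residues(s, invalid)
        mean(.chargeVector(chars, model))
    }, numeric(1), USE.NAMES = !is.null(names(x)))
}

## ---------------------------------------------------------------------------
## kappa (Das-Pappu charge patterning)
## ---------------------------------------------------------------------------

## Charge asymmetry of a composition: sigma = (f+ - f-)^2 / (f+ + f-),
## with sigma = 0 for an uncharged composition.
.sigma <- function(fpos, fneg) {
    tot <- fpos + fneg
    ifelse(tot > 0, (fpos - fneg)^2 / ifelse(tot > 0, tot, 1), 0)
}

## Blob-wise asymmetry statistic delta for blob size g: the mean squared
## deviation of per-blob sigma (overlapping windows, step 1) from the
## whole-sequence sigma.
.delta <- function(charges, g) {
    L <- length(charges)
    if (L < g) return(NA_real_)
    cpos <- c(0, cumsum(charges > 0))
    cneg <- c(0, cumsum(charges < 0))
    nb <- L - g + 1L
    fpos <- (cpos[(g + 1L):(L + 1L)] - cpos[1L:nb]) / g
    fneg <- (cneg[(g + 1L):(L + 1L)] - cneg[1L:nb]) / g
    sGlobal <- .sigma(cpos[L + 1L] / L, cneg[L + 1L] / L)
    mean((.sigma(fpos, fneg) - sGlobal)^2)
}

## Maximum delta over rearrangements of the same composition, from a
## deterministic construction: the positive residues form one block, the
## negative residues another, and the neutral residues are distributed as
## (n1, n2, n3) blocks before, between and after the charge blocks. All
## integer splits are enumerated and the largest delta is kept. delta is
## invariant under sequence reversal and global charge flip, so the
## positive-block-first orientation suffices.
.deltaMax <- function(nPos, nNeg, nNeut, g) {
    best <- 0
    for (n1 in 0:nNeut) {
        for (n2 in 0:(nNeut - n1)) {
            n3 <- nNeut - n1 - n2
            arr <- c(integer(n1), rep.int(1L, nPos), integer(n2),
                     rep.int(-1L, nNeg), integer(n3))
            d <- .delta(arr, g)
            if (!is.na(d) && d > best) best <- d
        }
    }
    best
}

#' Charge-patterning parameter kappa and its components
#'
#' Computes the Das-Pappu charge-patterning parameter: for blob sizes 5 and
#' 6, the blob-wise asymmetry statistic delta is normalized by deltamax,
#' the delta of the maximally segregated rearrangement of the identical
#' composition, and kappa is the mean of the two ratios. Kappa is 0 when
#' opposite charges are maximally mixed and 1 when the sequence is its own
#' maximally segregated arrangement.
#'
#' Kappa is undefined (returned as `NA` with a `reason` element) when
#' deltamax is 0 for any blob size - i.e. for sequences with no charged
#' residues, for charged homopolymer-like sequences with no neutral
#' residues and a single charge species, or for sequences shorter than the
#' largest blob. Sequences carrying a single charge species *plus* neutral
#' residues have a well-defined kappa (sigma reduces to the charged
#' fraction), which is required to score strongly one-sided acidic regions.
#'
#' @param x a single sequence (character or `AAString`)
#' @param model a [ChargeModel-class]
#' @param blobSizes integer vector of blob sizes (default `c(5, 6)`)
#' @param invalid see [fcr()]
#' @return a list with elements `kappa`, `delta` and `deltaMax` (named by
#'   blob size), and `reason` (`NA` unless kappa is undefined)
#' @seealso [kappa()] for the scalar, vectorized form
#' @export
patterning <- function(x, model = chargeModel(), blobSizes = c(5L, 6L),
                       invalid = "reject") {
    chars <- .residues(.asSequenceVector(x)[1L], invalid)
    ch <- .chargeVector(chars, model)
    nPos <- sum(ch > 0); nNeg <- sum(ch < 0); nNeut <- sum(ch == 0)
    d <- dm <- setNames(numeric(length(blobSizes)),
                        paste0("g", blobSizes))
    for (i in seq_along(blobSizes)) {
        g <- blobSizes[i]
        d[i] <- .delta(ch, g)
        dm[i] <- if (length(ch) < g) 0 else .deltaMax(nPos, nNeg, nNeut, g)
    }
    if (anyNA(d) || any(dm == 0)) {
        reason <- if (nPos + nNeg == 0) "no charged residues"
                  else if (length(ch) < max(blobSizes)) "sequence shorter than blob"
                  else "degenerate composition (deltamax = 0)"
        return(list(kappa = NA_real_, delta = d, deltaMax = dm,
                    reason = reason))
    }
    list(kappa = mean(d / dm), delta = d, deltaMax = dm, reason = NA_character_)
}

#' Charge-patterning parameter kappa
#'
#' Vectorized scalar form of [patterning()]: `NA` where kappa is
#' undefined.
#'
#' @inheritParams fcr
#' @param blobSizes blob sizes averaged over (default 5 and 6)
#' @return numeric vector of kappa values in [0, 1] (NA when undefined)
#' @examples
#' kappa(strrep("EK", 25))                 # well mixed, near 0
#' kappa(paste0(strrep("E", 25), strrep("K", 25)))  # fully segregated, 1
#' @export
kappa <- function(x, model = chargeModel(), blobSizes = c(5L, 6L),
                  invalid = "reject") {
    vapply(.asSequenceVector(x), function(s)
        patterning(s, model, blobSizes, invalid)$kappa,
        numeric(1), USE.NAMES = !is.null(names(x)))
}

## ---------------------------------------------------------------------------
## Hydropathy
## ---------------------------------------------------------------------------

#' Mean normalized hydropathy
#'
#' Mean of per-residue hydropathy values linearly rescaled to [0, 1] by the
#' scale minimum and maximum (Kyte-Doolittle by default: R at -4.5 maps to
#' 0, I at 4.5 maps to 1). No smoothing window is applied.
#'
#' @inheritParams fcr
#' @param scale named numeric vector of raw per-residue hydropathy values
#'   covering all residues that occur
#' @return numeric vector of unit-interval means
#' @examples
#' meanHydropathy(c("IIII", "RRRR", "IR"))
#' @export
meanHydropathy <- function(x, scale = KD_HYDROPATHY, invalid = "reject") {
    rng <- range(scale)
    unit <- (scale - rng[1]) / diff(rng)
    vapply(.asSequenceVector(x), function(s) {
        chars <- .residues(s, invalid)
        miss <- setdiff(chars, names(unit))
        if (length(miss))
            stop("residue(s) missing from hydropathy scale: ",
                 paste(miss, collapse = ", "))
        mean(unit[chars])
    }, numeric(1), USE.NAMES = !is.null(names(x)))
}

## ---------------------------------------------------------------------------
## Uversky charge/hydropathy rule
## ---------------------------------------------------------------------------

#' Classify by the charge/hydropathy (Uversky) boundary
#'
#' Places a point with absolute mean net charge `R` and normalized mean
#' hydropathy `H` relative to the linear boundary `R = slope * H +
#' intercept` separating natively unfolded from folded proteins (the
#' default coefficients are the published dividing line, 2.785 H - 1.151).
#' Points strictly above the line are classified disordered; points on or
#' below the line are classified folded (the boundary is assigned to
#' folded by convention).
#'
#' @param absNetCharge absolute mean net charge per residue, in [0, 1]
#' @param hydropathy normalized mean hydropathy, in [0, 1]
#' @param slope,intercept boundary-line coefficients (configuration, not
#'   hard-coded science; defaults from the classic charge/hydropathy plot)
#' @return character vector, `"disordered"` or `"folded"`
#' @examples
#' uverskyClassify(0.9, 0.1)
#' uverskyClassify(0.0, 1.0)
#' @export
uverskyClassify <- function(absNetCharge, hydropathy,
                            slope = 2.785, intercept = -1.151) {
    if (any(absNetCharge < 0 | absNetCharge > 1, na.rm = TRUE) ||
        any(hydropathy < 0 | hydropathy > 1, na.rm = TRUE))
        stop("absNetCharge and hydropathy must lie in [0, 1]")
    ifelse(absNetCharge > slope * hydropathy + intercept,
           "disordered", "folded")
}

## ---------------------------------------------------------------------------
## Codon-based null expectation for amino-acid usage
## ---------------------------------------------------------------------------

#' Expected amino-acid frequencies from pooled nucleotide composition
#'
#' Pools nucleotide frequencies over a set of ORFs, computes the expected
#' frequency of each codon as the product of the frequencies of its three
#' nucleotides, and sums codon expectations per amino acid. This is the
#' null model for amino-acid usage under the observed nucleotide
#' composition: deviations from it indicate selection on amino-acid
#' content beyond base composition.
#'
#' @param orfs DNA sequences (character vector or `DNAStringSet`) over
#'   A, C, G, T
#' @return a list with `nucleotide` (4 pooled frequencies), `codon` (64
#'   expectations summing to 1), `aaRaw` (20 amino-acid expectations, stop
#'   codons excluded, summing to < 1) and `aaSense` (the raw vector
#'   renormalized over sense codons, summing to 1)
#' @examples
#' # uniform nucleotides: Leu expectation is 6/64 raw, 6/61 renormalized
#' x <- expectedAAFreqs(paste(rep(c("A","C","G","T"), 25), collapse = ""))
#' x$aaRaw["L"]
#' @export
expectedAAFreqs <- function(orfs) {
    seqs <- toupper(.asSequenceVector(orfs))
    if (length(seqs) == 0L || all(nchar(seqs) == 0L))
        stop("empty ORF input")
    chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(chars), c("A", "C", "G", "T"))
    if (length(bad))
        stop("non-ACGT character(s) in ORFs: ", paste(bad, collapse = ", "))
    nt <- table(factor(chars, levels = c("A", "C", "G", "T")))
    ntFreq <- as.numeric(nt) / sum(nt)
    names(ntFreq) <- c("A", "C", "G", "T")

    code <- Biostrings::GENETIC_CODE
    codons <- names(code)
    codonExp <- vapply(codons, function(cd) {
        b <- strsplit(cd, "", fixed = TRUE)[[1L]]
        prod(ntFreq[b])
    }, numeric(1))
    sense <- code != "*"
    aaRaw <- vapply(AA_ALPHABET20, function(a)
        sum(codonExp[sense & code == a]), numeric(1))
    aaSense <- aaRaw / sum(codonExp[sense])
    list(nucleotide = ntFreq, codon = codonExp, aaRaw = aaRaw,
         aaSense = aaSense)
}

## ---------------------------------------------------------------------------
## Composition helpers and the bundled per-region record
## ---------------------------------------------------------------------------

#' Amino-acid composition matrix
#'
#' Converts sequences into rows of composition fractions over the 20
#' standard amino acids (each row sums to 1).
#'
#' @inheritParams fcr
#' @return numeric matrix, one row per sequence, 20 columns
#' @export
compositionMatrix <- function(x, invalid = "reject") {
    seqs <- .asSequenceVector(x)
    m <- t(vapply(seqs, function(s) {
        chars <- .residues(s, invalid)
        as.numeric(table(factor(chars, levels = AA_ALPHABET20))) /
            length(chars)
    }, numeric(20)))
    colnames(m) <- AA_ALPHABET20
    rownames(m) <- names(x)
    m
}

#' Observed amino-acid frequencies of a sequence collection
#'
#' Pooled residue frequencies over all sequences (the "proteome average"
#' composition).
#'
#' @inheritParams fcr
#' @return named numeric vector over the 20 amino acids, summing to 1
#' @export
aminoAcidFrequencies <- function(x, invalid = "reject") {
    seqs <- .asSequenceVector(x)
    counts <- numeric(20)
    names(counts) <- AA_ALPHABET20
    for (s in seqs) {
        chars <- .residues(s, invalid)
        tab <- table(factor(chars, levels = AA_ALPHABET20))
        counts <- counts + as.numeric(tab)
    }
    counts / sum(counts)
}

#' Per-region metrics record
#'
#' Bundles the scalar sequence metrics for one or more regions into a
#' data.frame: length, FCR, NCPR, kappa (NA when undefined), mean
#' normalized hydropathy, and complexity against one or more reference
#' languages.
#'
#' @inheritParams fcr
#' @param languages named list of [ComplexityLanguage-class] objects; each
#'   contributes a `complexity_<name>` column
#' @param scale hydropathy scale (see [meanHydropathy()])
#' @return data.frame with one row per input sequence
#' @examples
#' metricsRecord("EKEKEKEKEK",
#'               languages = list(charged = chargedEnrichedLanguage()))
#' @export
metricsRecord <- function(x, model = chargeModel(),
                          languages = list(charged = chargedEnrichedLanguage()),
                          scale = KD_HYDROPATHY, invalid = "reject") {
    seqs <- .asSequenceVector(x)
    out <- data.frame(
        length = nchar(seqs),
        fcr = unname(fcr(seqs, model, invalid)),
        ncpr = unname(ncpr(seqs, model, invalid)),
        kappa = unname(kappa(seqs, model, invalid = invalid)),
        mean_hydropathy = unname(meanHydropathy(seqs, scale, invalid)),
        stringsAsFactors = FALSE)
    for (nm in names(languages))
        out[[paste0("complexity_", nm)]] <-
            unname(sequenceComplexity(seqs, languages[[nm]], invalid = invalid))
    if (!is.null(names(x))) rownames(out) <- names(x)
    out
}
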