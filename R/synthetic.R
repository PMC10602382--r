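## Synthetic proteomes, ORFs, structure tracks and evolved alignments with
## known ground truth. All generators are deterministic functions of their
## seed (seed = NULL continues from the current RNG state, for composing
## generators inside a seeded scenario).

.maybeSeed <- function(seed) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    invisible(NULL)
}

#' Default background amino-acid frequencies
#'
#' The uniform composition (0.05 per amino acid), under which the four
#' charged residues jointly make up 0.20 of the background - the baseline
#' condition for region-recovery experiments.
#'
#' @return named numeric vector over the 20 amino acids
#' @export
uniformBackgroundFreqs <- function() {
    setNames(rep(0.05, 20), AA_ALPHABET20)
}

## Codon choices per amino acid (sense codons only).
.codonsByAA <- function() {
    code <- Biostrings::GENETIC_CODE
    split(names(code)[code != "*"], code[code != "*"])
}

#' Generate a synthetic proteome with matching ORFs
#'
#' Draws protein sequences with i.i.d. residues from a background
#' frequency vector, and reverse-translates each protein into an ORF by
#' sampling a synonymous codon per residue (uniform per synonym by
#' default, or weighted by a supplied codon-usage table). ORFs translate
#' exactly back to the proteins.
#'
#' @param nProteins number of proteins
#' @param lengthRange integer range (min, max) of protein lengths; a single
#'   value fixes the length
#' @param freqs background amino-acid frequencies (default uniform)
#' @param codonWeights optional named numeric vector of codon weights for
#'   reverse translation (names are codons); default uniform per synonym
#' @param seed integer seed (NULL = use current RNG state)
#' @return list with `proteins` and `orfs` (named character vectors,
#'   `p1..pN`)
#' @examples
#' pg <- genProteome(3, c(50, 80), seed = 1)
#' nchar(pg$proteins)
#' @export
genProteome <- function(nProteins, lengthRange = c(300L, 700L),
                        freqs = uniformBackgroundFreqs(),
                        codonWeights = NULL, seed = NULL) {
    if (abs(sum(freqs) - 1) > 1e-8 || any(freqs < 0))
        stop("background frequencies must be non-negative and sum to 1")
    .maybeSeed(seed)
    if (length(lengthRange) == 1L) lengthRange <- rep(lengthRange, 2L)
    byAA <- .codonsByAA()
    proteins <- orfs <- character(nProteins)
    for (i in seq_len(nProteins)) {
        L <- if (lengthRange[1L] == lengthRange[2L]) lengthRange[1L]
             else sample(lengthRange[1L]:lengthRange[2L], 1L)
        aa <- sample(names(freqs), L, replace = TRUE, prob = freqs)
        proteins[i] <- paste(aa, collapse = "")
        cods <- vapply(aa, function(a) {
            ch <- byAA[[a]]
            if (is.null(codonWeights)) sample(ch, 1L)
            else sample(ch, 1L, prob = codonWeights[ch])
        }, character(1))
        orfs[i] <- paste(cods, collapse = "")
    }
    names(proteins) <- names(orfs) <- paste0("p", seq_len(nProteins))
    list(proteins = proteins, orfs = orfs)
}

## Build a charged segment with exact composition counts and, optionally,
## a target kappa reached by seeded stochastic position swaps. The
## composition is fixed, so deltamax is computed once per blob size and
## only delta changes during the search.
.buildSegment <- function(len, fcrTarget, sign, kappaTarget, model, freqs,
                          kappaTol = 0.05, maxIter = 4000L, restarts = 3L) {
    nC <- round(fcrTarget * len)
    if (nC < 1L || nC > len)
        stop("infeasible FCR target for segment length")
    nPos <- switch(sign,
                   neutral = nC %/% 2L,
                   negative = round(0.15 * nC),
                   positive = nC - round(0.15 * nC),
                   stop("sign must be negative, neutral or positive"))
    nNeg <- nC - nPos
    ## a one-sided charge model forces a single charge species
    if (length(model@negative) == 0L) { nPos <- nC; nNeg <- 0L }
    if (length(model@positive) == 0L) { nNeg <- nC; nPos <- 0L }
    if (!is.na(kappaTarget) && (nPos == 0L || nNeg == 0L) && nC == len)
        stop("kappa targeting infeasible: single charge species, ",
             "no neutrals (kappa undefined)")
    filler <- setdiff(AA_ALPHABET20, chargedResidues(model))
    fw <- freqs[filler] / sum(freqs[filler])
    ## Charged positions are placed by systematic sampling (even spacing,
    ## random phase) so the enrichment is sustained along the segment, as
    ## in a genuinely enriched region, rather than fluctuating like an
    ## i.i.d. draw of the same composition.
    draw <- function() {
        res <- character(len)
        u <- stats::runif(1)
        chargedPos <- floor((seq_len(nC) - u) * len / nC) + 1L
        chargedRes <- sample(c(sample(model@positive, nPos, replace = TRUE),
                               sample(model@negative, nNeg, replace = TRUE)))
        res[chargedPos] <- chargedRes
        if (len > nC)
            res[-chargedPos] <- sample(filler, len - nC, replace = TRUE,
                                       prob = fw)
        res
    }
    if (is.na(kappaTarget))
        return(paste(draw(), collapse = ""))
    ## swap search toward the kappa target
    best <- NULL; bestGap <- Inf
    for (r in seq_len(restarts)) {
        chars <- draw()
        pat <- patterning(paste(chars, collapse = ""), model)
        if (is.na(pat$kappa))
            stop("kappa undefined for the requested composition")
        dm <- pat$deltaMax
        cur <- pat$kappa
        for (it in seq_len(maxIter)) {
            if (abs(cur - kappaTarget) <= kappaTol / 2) break
            i <- sample.int(len, 1L); j <- sample.int(len, 1L)
            if (chars[i] == chars[j]) next
            cand <- chars; cand[i] <- chars[j]; cand[j] <- chars[i]
            ch <- .chargeVector(cand, model)
            k2 <- mean(c(.delta(ch, 5L) / dm[1L], .delta(ch, 6L) / dm[2L]))
            if (abs(k2 - kappaTarget) < abs(cur - kappaTarget)) {
                chars <- cand; cur <- k2
            }
        }
        if (abs(cur - kappaTarget) < bestGap) {
            best <- chars; bestGap <- abs(cur - kappaTarget)
        }
        if (bestGap <= kappaTol / 2) break
    }
    if (bestGap > kappaTol)
        warning(sprintf("kappa target %.2f reached only within %.3f",
                        kappaTarget, bestGap))
    paste(best, collapse = "")
}

#' Splice a charged region into a protein
#'
#' Replaces a stretch of the protein with a constructed segment that has
#' an exact number of charged residues (`round(fcr * length)`), a chosen
#' net-charge sign, and optionally a target kappa reached by a seeded
#' stochastic swap search (achieved kappa is returned alongside the
#' target; infeasible targets error rather than silently clamping). The
#' net-sign convention places 15% of the charges on the minority species
#' for signed regions and splits them evenly for neutral ones.
#'
#' @param protein a single protein sequence
#' @param regionLength length of the inserted region
#' @param fcr target fraction of charged residues (exact by construction)
#' @param sign `"negative"`, `"neutral"` or `"positive"`
#' @param kappaTarget optional kappa target in [0, 1] (NA = free)
#' @param at 1-based start position (default: centered)
#' @param model a [ChargeModel-class]
#' @param freqs background frequencies used for the uncharged filler
#' @param seed integer seed (NULL = use current RNG state)
#' @return list with `protein` (modified sequence), `start`, `end`
#'   (1-based closed truth interval), and `achievedKappa`
#' @export
insertRegion <- function(protein, regionLength = 60L, fcr = 0.55,
                         sign = "neutral", kappaTarget = NA_real_,
                         at = NULL, model = chargeModel(),
                         freqs = uniformBackgroundFreqs(), seed = NULL) {
    .maybeSeed(seed)
    protein <- .asSequenceVector(protein)[1L]
    L <- nchar(protein)
    if (regionLength > L)
        stop("region longer than protein")
    if (is.null(at)) at <- max(1L, (L - regionLength) %/% 2L + 1L)
    if (at + regionLength - 1L > L)
        stop("region placement outside protein")
    seg <- .buildSegment(regionLength, fcr, sign, kappaTarget, model, freqs)
    out <- paste0(substr(protein, 1L, at - 1L), seg,
                  substr(protein, at + regionLength, L))
    list(protein = out, start = at, end = at + regionLength - 1L,
         achievedKappa = kappa(seg, model))
}

#' Generate a structure track with known truth
#'
#' Builds a [StructureTrack-class] for a protein given truth intervals:
#' helical-truth residues get a helix call with high confidence (uniform
#' 85-95), disordered-truth residues get a coil call with low confidence
#' (uniform 20-45), and background residues get a mixed diet (helix 30% /
#' sheet 20% / coil 50%) with confidence uniform on 55-95 - a mix under
#' which single-class runs longer than the training minimum are
#' vanishingly rare. A noise fraction re-draws the secondary-structure
#' call of that share of residues from the other two classes.
#'
#' @param protein a single protein sequence
#' @param truth data.frame with columns `start`, `end`, `label`
#'   ("helical"/"disordered"); may be empty
#' @param noise fraction of residues whose ss call is flipped (default 0)
#' @param seed integer seed (NULL = use current RNG state)
#' @return a [StructureTrack-class]
#' @export
genStructureTrack <- function(protein, truth = NULL, noise = 0,
                              seed = NULL) {
    .maybeSeed(seed)
    L <- nchar(.asSequenceVector(protein)[1L])
    ss <- sample(c("helix", "sheet", "coil"), L, replace = TRUE,
                 prob = c(0.3, 0.2, 0.5))
    conf <- stats::runif(L, 55, 95)
    if (!is.null(truth) && nrow(truth)) {
        for (i in seq_len(nrow(truth))) {
            idx <- truth$start[i]:truth$end[i]
            if (truth$label[i] == "helical") {
                ss[idx] <- "helix"; conf[idx] <- stats::runif(length(idx), 85, 95)
            } else if (truth$label[i] == "disordered") {
                ss[idx] <- "coil"; conf[idx] <- stats::runif(length(idx), 20, 45)
            } else stop("truth labels must be 'helical' or 'disordered'")
        }
    }
    if (noise > 0) {
        flip <- which(stats::runif(L) < noise)
        for (i in flip)
            ss[i] <- sample(setdiff(c("helix", "sheet", "coil"), ss[i]), 1L)
    }
    structureTrack(ss, conf)
}

#' Evolve a protein family with ground-truth alignment
#'
#' Derives `nSpecies` descendants of a root protein independently (star
#' phylogeny): each site substitutes with probability `pSub` and suffers
#' an indel with probability `pIndel` (deletion or insertion with equal
#' odds; insertion lengths geometric with mean 2). Substitutions inside
#' designated composition-preserving regions resample within the target
#' set when the original residue is in it (and within the non-target
#' residues otherwise), so the region's enrichment is invariant while its
#' sequence diverges; everywhere else, and in "free" mode, replacements
#' are drawn from the background frequencies. The alignment is produced by
#' the generator's own indel bookkeeping - each root position is one
#' column, plus insertion columns sized to the largest insertion at that
#' junction - never by realignment, so column maps are exact.
#'
#' @param root the root protein sequence (reference row of the family)
#' @param nSpecies number of derived species
#' @param pSub per-site substitution probability
#' @param pIndel per-site indel probability
#' @param regions optional data.frame (`start`, `end`) of
#'   composition-preserving regions on the root
#' @param conservation `"composition-preserving"` (default) or `"free"`;
#'   applies to sites inside `regions`
#' @param targetSet residue set preserved inside conserved regions
#' @param freqs background frequencies for free substitutions and
#'   insertions
#' @param rootId name of the reference row (default "root")
#' @param seed integer seed (NULL = use current RNG state)
#' @return list with `alignment` (named character vector; reference row
#'   first) and `columnMap` (alignment column of each root position)
#' @export
evolveFamily <- function(root, nSpecies = 8L, pSub = 0.1, pIndel = 0.01,
                         regions = NULL,
                         conservation = c("composition-preserving", "free"),
                         targetSet = c("D", "E", "K", "R"),
                         freqs = uniformBackgroundFreqs(),
                         rootId = "root", seed = NULL) {
    conservation <- match.arg(conservation)
    .maybeSeed(seed)
    rootChars <- .residues(.asSequenceVector(root)[1L])
    L <- length(rootChars)
    inRegion <- logical(L)
    if (!is.null(regions) && nrow(regions))
        for (i in seq_len(nrow(regions)))
            inRegion[regions$start[i]:regions$end[i]] <- TRUE
    preserve <- inRegion & conservation == "composition-preserving"
    nonTarget <- setdiff(AA_ALPHABET20, targetSet)
    fwAll <- freqs / sum(freqs)
    fwT <- freqs[targetSet] / sum(freqs[targetSet])
    fwN <- freqs[nonTarget] / sum(freqs[nonTarget])

    ## per species: residue-or-gap at each root position + insertions
    resMat <- matrix("", nrow = nSpecies, ncol = L)
    insMat <- matrix("", nrow = nSpecies, ncol = L + 1L)  # junction j = before pos j
    for (sp in seq_len(nSpecies)) {
        chars <- rootChars
        subs <- which(stats::runif(L) < pSub)
        for (i in subs) {
            chars[i] <- if (preserve[i]) {
                if (rootChars[i] %in% targetSet)
                    sample(targetSet, 1L, prob = fwT)
                else sample(nonTarget, 1L, prob = fwN)
            } else sample(names(fwAll), 1L, prob = fwAll)
        }
        indels <- which(stats::runif(L) < pIndel)
        for (i in indels) {
            if (stats::runif(1) < 0.5) {
                chars[i] <- "-"
            } else {
                n <- stats::rgeom(1L, 0.5) + 1L
                insMat[sp, i] <- paste(sample(names(fwAll), n, replace = TRUE,
                                              prob = fwAll), collapse = "")
            }
        }
        resMat[sp, ] <- chars
    }
    ## assemble alignment columns: [ins junction 1][pos 1][ins 2][pos 2]...
    ## Insertions by different species at the same junction are independent
    ## events on a star phylogeny, not homologous, so each species gets its
    ## own insertion columns rather than sharing left-aligned ones.
    columnMap <- integer(L)
    blocks <- list()
    col <- 0L
    nRows <- nSpecies + 1L  # root row first
    for (j in seq_len(L + 1L)) {
        for (sp in seq_len(nSpecies)) {
            insLen <- nchar(insMat[sp, j])
            if (insLen > 0L) {
                ins <- rep(strrep("-", insLen), nRows)
                ins[sp + 1L] <- insMat[sp, j]
                blocks[[length(blocks) + 1L]] <- ins
                col <- col + insLen
            }
        }
        if (j <= L) {
            blocks[[length(blocks) + 1L]] <- c(rootChars[j], resMat[, j])
            col <- col + 1L
            columnMap[j] <- col
        }
    }
    alnRows <- do.call(paste0, blocks)
    names(alnRows) <- c(rootId, paste0("sp", seq_len(nSpecies)))
    list(alignment = alnRows, columnMap = columnMap)
}
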