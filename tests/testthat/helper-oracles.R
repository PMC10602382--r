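## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## Brute-force interval caller: enumerate all pairs of above-threshold
## endpoints, keep those whose internal below-threshold runs never exceed
## the tolerance, discard non-maximal intervals, then apply the length
## filter. Checks detectIntervals() by exhaustion.
bruteForceIntervals <- function(track, threshold, tolerance, minLen) {
    above <- which(track >= threshold)
    if (length(above) == 0L) return(matrix(integer(), ncol = 2))
    ok <- matrix(integer(), ncol = 2)
    for (s in above) for (e in above[above >= s]) {
        seg <- track[s:e] < threshold
        runs <- rle(seg)
        bad <- any(runs$values & runs$lengths > tolerance)
        if (!bad) ok <- rbind(ok, c(s, e))
    }
    ## maximality: drop intervals contained in another valid one
    keep <- vapply(seq_len(nrow(ok)), function(i) {
        !any(ok[, 1] <= ok[i, 1] & ok[, 2] >= ok[i, 2] &
             (ok[, 1] != ok[i, 1] | ok[, 2] != ok[i, 2]))
    }, logical(1))
    ok <- ok[keep, , drop = FALSE]
    ok[ok[, 2] - ok[, 1] + 1L >= minLen, , drop = FALSE]
}

## Interval Jaccard on 1-based closed coordinates.
intervalJaccard <- function(s1, e1, s2, e2) {
    inter <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
    uni <- (e1 - s1 + 1L) + (e2 - s2 + 1L) - inter
    inter / uni
}

## Separable labeled composition corpus: helical rows are depleted of
## proline and glycine, disordered rows enriched; all other residues are
## drawn from a shared background. Returns the same shape as
## extractPureRegions().
makeSeparableCorpus <- function(n, len = 40L, pHelical = 0.5,
                                depleted = c("P", "G"), shift = 0.10,
                                seed = 1L) {
    set.seed(seed)
    base <- setNames(rep(0.05, 20), ChargedRegions::AA_ALPHABET20)
    fH <- base; fH[depleted] <- 0.005
    fH <- fH / sum(fH)
    fD <- base; fD[depleted] <- 0.05 + shift
    fD <- fD / sum(fD)
    lab <- ifelse(runif(n) < pHelical, "helical", "disordered")
    seqs <- vapply(lab, function(l) {
        f <- if (l == "helical") fH else fD
        paste(sample(names(f), len, replace = TRUE, prob = f),
              collapse = "")
    }, character(1))
    df <- data.frame(protein = sprintf("r%04d", seq_len(n)), start = 1L,
                     end = len, label = lab, sequence = seqs,
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(compositionMatrix(seqs)))
}

## Published kappa values for the packaged worked-example regions.
exampleKappas <- c(SIS2 = 0.756, RNA1 = 0.393, COP1 = 0.064,
                   RIO1 = 0.433, SEC3 = 0.106, MNN4 = 0.061,
                   TMA23 = 0.317, ZDS2 = 0.185, FAF1 = 0.071)
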