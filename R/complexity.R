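## Compositional (Shannon) complexity normalized to a reference language.

#' Reference language built from observed frequencies
#'
#' Builds a [ComplexityLanguage-class] from a frequency vector, typically
#' the proteome-average composition from [aminoAcidFrequencies()]. Zero
#' frequencies are rejected: a language must assign positive probability
#' to every letter or its entropy normalization is ill-defined.
#'
#' @param freqs named numeric vector over the 20 amino acids
#' @return a [ComplexityLanguage-class]
#' @export
proteomeLanguage <- function(freqs) {
    new("ComplexityLanguage", p = freqs[AA_ALPHABET20])
}

#' The charged-enriched reference language
#'
#' A hypothetical mostly-charged proteome: each of D, E, K, R at frequency
#' 0.125 (half the composition), with the remaining 0.5 spread evenly over
#' the other sixteen amino acids (0.03125 each). Its entropy is exactly 4
#' bits. Normalizing complexity to this language corrects for the
#' selection bias inherent in searching for charge-enriched sequences.
#'
#' @return a [ComplexityLanguage-class]
#' @examples
#' languageEntropy(chargedEnrichedLanguage(), base = 2)  # exactly 4
#' @export
chargedEnrichedLanguage <- function() {
    p <- setNames(rep(0.5 / 16, 20), AA_ALPHABET20)
    p[c("D", "E", "K", "R")] <- 0.125
    new("ComplexityLanguage", p = p)
}

#' The uniform reference language
#'
#' All twenty amino acids at frequency 0.05; the maximum-entropy reference,
#' under which normalized complexity is bounded by 1.
#'
#' @return a [ComplexityLanguage-class]
#' @export
uniformLanguage <- function() {
    new("ComplexityLanguage", p = setNames(rep(0.05, 20), AA_ALPHABET20))
}

#' Entropy of a reference language
#'
#' `H = -sum(p_i * log(p_i))` in the requested base.
#'
#' @param language a [ComplexityLanguage-class]
#' @param base logarithm base (default natural; use 2 for bits)
#' @return numeric scalar
#' @export
languageEntropy <- function(language, base = exp(1)) {
    p <- language@p
    -sum(p * log(p, base = base))
}

#' Normalized sequence complexity
#'
#' The compositional entropy of a sequence,
#' `K2 = -sum_i (n_i / L) log(n_i / L)` over the twenty amino acids
#' (zero-count terms contribute 0), divided by the entropy of a reference
#' language. The ratio is invariant to the logarithm base, which therefore
#' cancels; internally natural logarithms are used. A sequence whose
#' composition equals the reference frequencies has complexity 1; a
#' homopolymer has complexity 0. Values above 1 are possible when the
#' language is not the maximum-entropy reference and are reported
#' unclamped.
#'
#' @inheritParams fcr
#' @param language a [ComplexityLanguage-class]
#' @return numeric vector of non-negative complexities
#' @examples
#' sequenceComplexity(strrep("K", 8), uniformLanguage())   # 0
#' sequenceComplexity(paste(AA_ALPHABET20, collapse = ""),
#'                    uniformLanguage())                   # 1
#' @export
sequenceComplexity <- function(x, language, invalid = "reject") {
    H <- languageEntropy(language)
    vapply(.asSequenceVector(x), function(s) {
        chars <- .residues(s, invalid)
        f <- as.numeric(table(factor(chars, levels = AA_ALPHABET20))) /
            length(chars)
        f <- f[f > 0]
        -sum(f * log(f)) / H
    }, numeric(1), USE.NAMES = !is.null(names(x)))
}
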