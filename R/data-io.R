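## FASTA IO wrappers and the packaged worked examples.

#' Read a protein FASTA file
#' @param file path to a FASTA file
#' @return named character vector of protein sequences
#' @export
readProteomeFasta <- function(file) {
    x <- Biostrings::readAAStringSet(file)
    setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a DNA FASTA file of ORFs
#' @param file path to a FASTA file
#' @return named character vector of DNA sequences
#' @export
readOrfsFasta <- function(file) {
    x <- Biostrings::readDNAStringSet(file)
    setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences as FASTA
#' @param seqs named character vector
#' @param file output path
#' @return the file path, invisibly
#' @export
writeFasta <- function(seqs, file) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), file)
    invisible(file)
}

#' Worked examples: highly charged regions from budding yeast
#'
#' Nine highly charged regions from the budding yeast proteome spanning
#' the net-negative, near-neutral and net-positive categories - classic
#' worked examples for the charge-patterning metrics (the MNN4 region, an
#' (E4K4)-type repeat, is a textbook single-alpha-helix candidate).
#'
#' @return data.frame with columns `category`, `gene`, `sequence`
#' @examples
#' ex <- chargedRegionExamples()
#' kappa(setNames(ex$sequence, ex$gene))
#' @export
chargedRegionExamples <- function() {
    f <- system.file("extdata", "yeast_charged_regions.tsv",
                     package = "ChargedRegions", mustWork = TRUE)
    utils::read.table(f, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
}
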