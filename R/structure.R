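## Structure-track ingestion and residue / region structural classification.
## Secondary structure is consumed, never computed: tracks come from DSSP
## output, plain class strings, or AlphaFold-style PDB files whose
## temperature-factor column stores per-residue confidence (pLDDT).

#' Construct a StructureTrack
#'
#' @param ss secondary structure: either a character vector of
#'   "helix"/"sheet"/"coil" per residue, or a single string of one-letter
#'   DSSP codes, which is collapsed to three classes via [collapseDssp()]
#' @param conf numeric per-residue confidence in [0, 100]
#' @param protein optional protein identifier
#' @return a [StructureTrack-class]
#' @examples
#' structureTrack("HHHHCCCEE", conf = rep(90, 9))
#' @export
structureTrack <- function(ss, conf, protein = "") {
    if (length(ss) == 1L && !ss %in% c("helix", "sheet", "coil"))
        ss <- collapseDssp(strsplit(ss, "", fixed = TRUE)[[1L]])
    if (length(ss) != length(conf))
        stop("ss and conf lengths differ (", length(ss), " vs ",
             length(conf), ")")
    new("StructureTrack", protein = protein, ss = ss, conf = as.numeric(conf))
}

#' Collapse DSSP codes to three classes
#'
#' Maps eight-class DSSP codes onto helix / sheet / coil: H, G and I to
#' helix; E and B to sheet; everything else (T, S, C, blank, "-", "~") to
#' coil. Unknown codes are an error.
#'
#' @param codes character vector of one-letter DSSP codes
#' @return character vector of "helix", "sheet" or "coil"
#' @export
collapseDssp <- function(codes) {
    out <- rep(NA_character_, length(codes))
    out[codes %in% c("H", "G", "I")] <- "helix"
    out[codes %in% c("E", "B")] <- "sheet"
    out[codes %in% c("T", "S", "C", " ", "-", "~", "P")] <- "coil"
    if (anyNA(out))
        stop("unknown DSSP code(s): ",
             paste(unique(codes[is.na(out)]), collapse = ", "))
    out
}

#' Parse classic DSSP output
#'
#' Reads the per-residue table of a DSSP-format output file (the section
#' following the `#  RESIDUE AA STRUCTURE ...` header line) and extracts
#' the one-letter secondary-structure code from its fixed column (17).
#' Chain-break records (`!`) are skipped.
#'
#' @param file path to a DSSP output file
#' @return character vector of one-letter DSSP codes, one per residue
#' @export
parseDssp <- function(file) {
    lines <- readLines(file)
    hdr <- grep("^\\s*#\\s+RESIDUE", lines)
    if (length(hdr) == 0L)
        stop("not a DSSP output file (missing '#  RESIDUE' header): ", file)
    body <- lines[(hdr[1L] + 1L):length(lines)]
    body <- body[nchar(body) >= 17]
    aa <- substr(body, 14, 14)
    body <- body[aa != "!"]
    substr(body, 17, 17)
}

#' Read per-residue confidence from an AlphaFold-style PDB file
#'
#' Extracts the temperature-factor (B-factor) column, which AlphaFold-style
#' files use to store per-residue confidence (pLDDT), and averages it per
#' residue. Within a residue all atoms should agree; if they do not, a
#' warning is raised and the mean is used.
#'
#' @param file path to a PDB file
#' @return numeric vector of per-residue confidences, in residue order
#' @export
readConfidencePDB <- function(file) {
    pdb <- bio3d::read.pdb(file, verbose = FALSE)
    at <- pdb$atom[pdb$atom$type == "ATOM", ]
    if (nrow(at) == 0L) stop("no ATOM records in ", file)
    key <- paste(at$chain, at$resno, at$insert)
    key <- factor(key, levels = unique(key))  # preserve file order
    spread <- tapply(at$b, key, function(v) diff(range(v)))
    if (any(spread > 1e-6))
        warning("atoms within ", sum(spread > 1e-6),
                " residue(s) carry differing confidence values; using means")
    as.numeric(tapply(at$b, key, mean))
}

#' Load a merged structure track
#'
#' Assembles a [StructureTrack-class] from whichever sources are at hand:
#' secondary structure from a DSSP output file (`dssp`) or a class/code
#' string (`ss`), and confidence from a numeric vector (`conf`) or an
#' AlphaFold-style PDB file (`pdb`). Residue counts from all sources must
#' agree.
#'
#' @param ss secondary structure as for [structureTrack()] (optional if
#'   `dssp` given)
#' @param conf numeric confidence vector (optional if `pdb` given)
#' @param dssp path to a DSSP output file
#' @param pdb path to a PDB file carrying per-residue confidence
#' @param protein optional protein identifier
#' @return a [StructureTrack-class]
#' @export
loadStructureTrack <- function(ss = NULL, conf = NULL, dssp = NULL,
                               pdb = NULL, protein = "") {
    if (is.null(ss) && is.null(dssp))
        stop("provide secondary structure via 'ss' or 'dssp'")
    if (is.null(conf) && is.null(pdb))
        stop("provide confidence via 'conf' or 'pdb'")
    if (is.null(ss)) ss <- collapseDssp(parseDssp(dssp))
    if (is.null(conf)) conf <- readConfidencePDB(pdb)
    structureTrack(ss, conf, protein)
}

#' Read a two-column per-residue track TSV
#'
#' Plain-text ingestion path: a TSV with columns `ss` (three-class labels
#' or one-letter DSSP codes) and `conf`.
#'
#' @param file path to the TSV
#' @param protein optional protein identifier
#' @return a [StructureTrack-class]
#' @export
readStructureTrackTSV <- function(file, protein = "") {
    df <- utils::read.table(file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    ss <- as.character(df$ss)
    if (!all(ss %in% c("helix", "sheet", "coil")))
        ss <- collapseDssp(ss)
    structureTrack(ss, df$conf, protein)
}

#' Classify residues as helix, sheet, disordered or other
#'
#' Applies the confidence-gated classification rule: a residue is helix
#' (or sheet) when its secondary-structure call is helix (or sheet) *and*
#' its confidence is at or above `confHigh`; disordered when it is coil at
#' high confidence, or when its confidence falls below `confLow`
#' regardless of the call; anything else - including coil in the ambiguous
#' [confLow, confHigh) band - is "other". Every residue receives exactly
#' one class.
#'
#' @param track a [StructureTrack-class]
#' @param config a [StructureConfig-class]
#' @return factor with levels helix, sheet, disordered, other
#' @examples
#' tr <- structureTrack(rep(c("helix", "coil", "helix"), 1),
#'                      conf = c(90, 40, 60))
#' classifyResidues(tr)   # helix, disordered, other
#' @export
classifyResidues <- function(track, config = structureConfig()) {
    ss <- track@ss; conf <- track@conf
    out <- rep("other", length(ss))
    out[ss == "helix" & conf >= config@confHigh] <- "helix"
    out[ss == "sheet" & conf >= config@confHigh] <- "sheet"
    out[(ss == "coil" & conf >= config@confHigh) | conf < config@confLow] <-
        "disordered"
    factor(out, levels = c("helix", "sheet", "disordered", "other"))
}

#' Summarize the structural state of a region
#'
#' Computes the class fractions over a region of a residue-class vector and
#' labels the region `"helical"` or `"disordered"` when the corresponding
#' class exceeds the dominance fraction (strict inequality; exactly 60%
#' is *not* dominant), and `"intermediate"` otherwise.
#'
#' @param classes factor from [classifyResidues()]
#' @param start,end region interval, 1-based closed (defaults: whole
#'   vector)
#' @param config a [StructureConfig-class]
#' @return list with `fractions` (named, summing to 1) and `label`
#' @export
summarizeRegion <- function(classes, start = 1L, end = length(classes),
                            config = structureConfig()) {
    if (start < 1L || end > length(classes) || start > end)
        stop("region [", start, ", ", end, "] outside track of length ",
             length(classes))
    sub <- classes[start:end]
    fr <- as.numeric(table(sub)) / length(sub)
    names(fr) <- levels(classes)
    label <- if (fr["helix"] > config@dominance) "helical"
             else if (fr["disordered"] > config@dominance) "disordered"
             else "intermediate"
    list(fractions = fr, label = label)
}
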