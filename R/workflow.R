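## Orchestration of the two headline analyses: the charged-region atlas
## and the compositional-drift scan.

#' Build the charged-region atlas
#'
#' Runs the full per-region pipeline over a proteome: detect enriched
#' regions, score every region ([metricsRecord()]), summarize its
#' structural state from the matching track (class fractions and the
#' dominant-type label), classify it with the composition model when one
#' is supplied, and place it relative to the charge/hydropathy boundary.
#' The run is deterministic: identical inputs give identical tables.
#'
#' Proteins without a structure track get `NA` structure fields and a
#' warning, not an error.
#'
#' @param proteome named character vector or `AAStringSet`
#' @param tracks named list of [StructureTrack-class] objects, keyed by
#'   protein id (may be NULL or partial)
#' @param config a [DetectionConfig-class]
#' @param structConfig a [StructureConfig-class]
#' @param model optional fitted [CompositionClassifier-class]
#' @param languages complexity references; defaults to the proteome's own
#'   composition plus the charged-enriched language
#' @return data.frame, one row per region, with a `summary` attribute
#'   (region/protein counts, structural label counts, fraction
#'   majority-structured among regions with tracks)
#' @export
runAtlas <- function(proteome, tracks = NULL, config = detectionConfig(),
                     structConfig = structureConfig(), model = NULL,
                     languages = NULL) {
    proteome <- .asSequenceVector(proteome)
    if (length(proteome) == 0L) stop("empty proteome")
    regions <- detectEnrichedRegions(proteome, config)
    if (length(regions) == 0L) {
        out <- data.frame()
        attr(out, "summary") <- list(nRegions = 0L, nProteins = 0L)
        return(out)
    }
    if (is.null(languages))
        languages <- list(
            proteome = proteomeLanguage(aminoAcidFrequencies(proteome)),
            charged = chargedEnrichedLanguage())
    seqs <- S4Vectors::mcols(regions)$sequence
    met <- metricsRecord(seqs, languages = languages)
    out <- data.frame(
        protein = as.character(GenomicRanges::seqnames(regions)),
        start = IRanges::start(regions),
        end = IRanges::end(regions),
        sequence = seqs,
        stringsAsFactors = FALSE)
    out <- cbind(out, met)
    out$uversky <- uverskyClassify(abs(out$ncpr), out$mean_hydropathy)

    fracHelix <- fracSheet <- fracDisord <- fracOther <- rep(NA_real_, nrow(out))
    structLabel <- rep(NA_character_, nrow(out))
    missing <- character()
    for (j in seq_len(nrow(out))) {
        tr <- tracks[[out$protein[j]]]
        if (is.null(tr)) { missing <- c(missing, out$protein[j]); next }
        cl <- classifyResidues(tr, structConfig)
        sm <- summarizeRegion(cl, out$start[j], out$end[j], structConfig)
        fracHelix[j] <- sm$fractions["helix"]
        fracSheet[j] <- sm$fractions["sheet"]
        fracDisord[j] <- sm$fractions["disordered"]
        fracOther[j] <- sm$fractions["other"]
        structLabel[j] <- sm$label
    }
    if (length(missing))
        warning("no structure track for ", length(unique(missing)),
                " protein(s); structure fields set to NA")
    out$fracHelix <- fracHelix; out$fracSheet <- fracSheet
    out$fracDisordered <- fracDisord; out$fracOther <- fracOther
    out$structLabel <- structLabel
    if (!is.null(model)) {
        pr <- predict(model, out$sequence)
        out$predLabel <- pr$label
        out$probHelical <- pr$probHelical
    }
    hasTrack <- !is.na(structLabel)
    attr(out, "summary") <- list(
        nRegions = nrow(out),
        nProteins = length(unique(out$protein)),
        medianLength = stats::median(out$length),
        labelCounts = table(structLabel[hasTrack]),
        fracMajorityStructured = if (any(hasTrack))
            mean(fracHelix[hasTrack] + fracSheet[hasTrack] > 0.5) else NA)
    out
}

#' Run the compositional-drift analysis
#'
#' Thin orchestration over [driftScan()]: enumerates (or accepts)
#' candidate residue sets, scans them against the proteome and family
#' alignments, and reports the designated set's percentile. Returns an
#' explicit empty-result status instead of erroring when no set qualifies.
#'
#' @inheritParams driftScan
#' @return list with `table`, `percentile` and `status`
#'   (`"ok"` or `"no-qualifying-sets"`)
#' @export
runDrift <- function(proteome, alignments, config = driftConfig(),
                     sets = NULL, designated = c("D", "E", "K", "R"),
                     centerStat = "median") {
    res <- driftScan(proteome, alignments, config, sets, designated,
                     centerStat)
    status <- if (nrow(res$table) == 0L ||
                  all(is.na(res$table$scaled))) "no-qualifying-sets" else "ok"
    c(res, list(status = status))
}
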