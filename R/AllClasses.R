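#' @import methods
#' @importFrom stats predict
NULL

#' The twenty standard amino acids
#'
#' One-letter codes for the twenty standard amino acids, in alphabetical
#' order. All composition vectors in the package are indexed by this
#' alphabet.
#'
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy scale
#'
#' Raw per-residue hydropathy values. [meanHydropathy()] linearly rescales
#' them so that the scale minimum (R, -4.5) maps to 0 and the maximum
#' (I, 4.5) maps to 1.
#'
#' @export
KD_HYDROPATHY <- c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
                   G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
                   M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                   S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

## ---------------------------------------------------------------------------
## ChargeModel
## ---------------------------------------------------------------------------

#' ChargeModel: which residues carry charge
#'
#' Defines the positively and negatively charged residue sets used by every
#' charge-based metric. The default treats lysine and arginine as positive
#' and aspartate and glutamate as negative; histidine is deliberately
#' excluded from the default model because its protonation state at
#' physiological pH is ambiguous.
#'
#' @slot positive character vector of positively charged residues
#' @slot negative character vector of negatively charged residues
#'
#' @seealso [chargeModel()]
#' @export
setClass("ChargeModel",
         representation(positive = "character", negative = "character"),
         prototype(positive = c("K", "R"), negative = c("D", "E")))

setValidity("ChargeModel", function(object) {
    msg <- character()
    if (!all(object@positive %in% AA_ALPHABET20) ||
        !all(object@negative %in% AA_ALPHABET20))
        msg <- c(msg, "charged residues must be standard amino acids")
    if (length(intersect(object@positive, object@negative)) > 0)
        msg <- c(msg, "positive and negative sets must be disjoint")
    if (length(object@positive) == 0 && length(object@negative) == 0)
        msg <- c(msg, "at least one charged residue is required")
    if (anyDuplicated(object@positive) || anyDuplicated(object@negative))
        msg <- c(msg, "residue sets must not contain duplicates")
    if (length(msg)) msg else TRUE
})

#' Construct a ChargeModel
#'
#' @param positive positively charged residues (default K, R)
#' @param negative negatively charged residues (default D, E)
#' @return a [ChargeModel-class] object
#' @examples
#' chargeModel()
#' chargeModel(positive = c("K", "R", "H"))
#' @export
chargeModel <- function(positive = c("K", "R"), negative = c("D", "E")) {
    new("ChargeModel", positive = positive, negative = negative)
}

#' Residues regarded as charged by a model
#' @param model a [ChargeModel-class]
#' @return character vector, union of the positive and negative sets
#' @export
chargedResidues <- function(model) c(model@positive, model@negative)

setMethod("show", "ChargeModel", function(object) {
    cat("ChargeModel: +{", paste(object@positive, collapse = ","),
        "}  -{", paste(object@negative, collapse = ","), "}\n", sep = "")
})

## ---------------------------------------------------------------------------
## ComplexityLanguage
## ---------------------------------------------------------------------------

#' ComplexityLanguage: reference composition for complexity normalization
#'
#' A "language" is a reference amino-acid frequency vector; sequence
#' complexity is the compositional Shannon entropy of a sequence divided by
#' the entropy of the language, so a sequence whose composition equals the
#' reference frequencies scores 1.
#'
#' @slot p named numeric vector of reference frequencies over the 20 amino
#'   acids; all strictly positive, summing to 1
#'
#' @seealso [proteomeLanguage()], [chargedEnrichedLanguage()],
#'   [languageEntropy()], [sequenceComplexity()]
#' @export
setClass("ComplexityLanguage", representation(p = "numeric"))

setValidity("ComplexityLanguage", function(object) {
    p <- object@p
    if (length(p) != 20 || !setequal(names(p), AA_ALPHABET20))
        return("p must be named by the 20 standard amino acids")
    if (any(p <= 0))
        return("all reference frequencies must be strictly positive")
    if (abs(sum(p) - 1) > 1e-8)
        return("reference frequencies must sum to 1")
    TRUE
})

setMethod("show", "ComplexityLanguage", function(object) {
    cat(sprintf("ComplexityLanguage (entropy %.4f nats, %.4f bits)\n",
                languageEntropy(object), languageEntropy(object, base = 2)))
})

## ---------------------------------------------------------------------------
## DetectionConfig
## ---------------------------------------------------------------------------

#' DetectionConfig: parameters of the enriched-region detector
#'
#' Controls the triangular-weighted moving average and the region-calling
#' automaton. Defaults are the published operating point for highly charged
#' regions: a 12-residue window, an enrichment threshold of 0.40, a
#' tolerance of 10 residues for transient dips below threshold, and a
#' minimum region length of 30 residues.
#'
#' @slot windowLen window size in residues
#' @slot weights per-offset weight vector (triangular, normalized to sum 1)
#' @slot threshold enrichment threshold in (0, 1]
#' @slot tolerance maximum run of below-threshold residues absorbed inside
#'   a region
#' @slot minLen minimum pre-trim region length
#' @slot targetSet residue set whose enrichment is scored
#'
#' @seealso [detectionConfig()], [detectEnrichedRegions()]
#' @export
setClass("DetectionConfig",
         representation(windowLen = "integer", weights = "numeric",
                        threshold = "numeric", tolerance = "integer",
                        minLen = "integer", targetSet = "character"))

setValidity("DetectionConfig", function(object) {
    msg <- character()
    if (object@windowLen < 1L)
        msg <- c(msg, "windowLen must be >= 1")
    if (length(object@weights) != object@windowLen)
        msg <- c(msg, "weights length must equal windowLen")
    if (abs(sum(object@weights) - 1) > 1e-8 || any(object@weights <= 0))
        msg <- c(msg, "weights must be positive and sum to 1")
    if (object@threshold <= 0 || object@threshold > 1)
        msg <- c(msg, "threshold must be in (0, 1]")
    if (object@tolerance < 0L)
        msg <- c(msg, "tolerance must be >= 0")
    if (object@minLen < 1L)
        msg <- c(msg, "minLen must be >= 1")
    if (!all(object@targetSet %in% AA_ALPHABET20) ||
        length(object@targetSet) == 0)
        msg <- c(msg, "targetSet must be a non-empty set of standard residues")
    if (length(msg)) msg else TRUE
})

#' Construct a DetectionConfig
#'
#' @param windowLen window size in residues (default 12)
#' @param threshold enrichment threshold (default 0.40)
#' @param tolerance below-threshold run length absorbed inside a region
#'   (default 10)
#' @param minLen minimum pre-trim region length (default 30)
#' @param targetSet residues whose enrichment is scored (default the four
#'   charged residues D, E, K, R)
#' @param weights window weights; defaults to [triangularWeights()] of
#'   `windowLen`
#' @return a [DetectionConfig-class]
#' @examples
#' detectionConfig()
#' detectionConfig(threshold = 0.35, tolerance = 15L) # the drift-scan variant
#' @export
detectionConfig <- function(windowLen = 12L, threshold = 0.40,
                            tolerance = 10L, minLen = 30L,
                            targetSet = c("D", "E", "K", "R"),
                            weights = triangularWeights(windowLen)) {
    new("DetectionConfig", windowLen = as.integer(windowLen),
        weights = weights, threshold = threshold,
        tolerance = as.integer(tolerance), minLen = as.integer(minLen),
        targetSet = targetSet)
}

setMethod("show", "DetectionConfig", function(object) {
    cat(sprintf(paste0("DetectionConfig: window %d, threshold %.2f, ",
                       "tolerance %d, minLen %d, target {%s}\n"),
                object@windowLen, object@threshold, object@tolerance,
                object@minLen, paste(object@targetSet, collapse = ",")))
})

## ---------------------------------------------------------------------------
## StructureConfig / StructureTrack
## ---------------------------------------------------------------------------

#' StructureConfig: thresholds for structural classification
#'
#' @slot confHigh confidence at or above which a secondary-structure call is
#'   trusted (pLDDT semantics; default 70)
#' @slot confLow confidence below which a residue is imputed disordered
#'   regardless of its secondary-structure call (default 50)
#' @slot dominance fraction of residues (strict >) a class needs to label a
#'   region (default 0.60)
#' @slot pureMinLen minimum length (strict >) of a single-class run used for
#'   classifier training (default 25)
#'
#' @seealso [structureConfig()], [classifyResidues()], [summarizeRegion()]
#' @export
setClass("StructureConfig",
         representation(confHigh = "numeric", confLow = "numeric",
                        dominance = "numeric", pureMinLen = "integer"))

setValidity("StructureConfig", function(object) {
    msg <- character()
    if (!(object@confLow >= 0 && object@confLow < object@confHigh &&
          object@confHigh <= 100))
        msg <- c(msg, "need 0 <= confLow < confHigh <= 100")
    if (object@dominance <= 0.5 || object@dominance > 1)
        msg <- c(msg, "dominance must be in (0.5, 1]")
    if (object@pureMinLen < 1L)
        msg <- c(msg, "pureMinLen must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a StructureConfig
#' @param confHigh high-confidence cutoff (default 70)
#' @param confLow low-confidence cutoff (default 50)
#' @param dominance strict dominance fraction for region labels (default 0.6)
#' @param pureMinLen strict minimum run length for pure training regions
#'   (default 25)
#' @return a [StructureConfig-class]
#' @export
structureConfig <- function(confHigh = 70, confLow = 50, dominance = 0.60,
                            pureMinLen = 25L) {
    new("StructureConfig", confHigh = confHigh, confLow = confLow,
        dominance = dominance, pureMinLen = as.integer(pureMinLen))
}

setMethod("show", "StructureConfig", function(object) {
    cat(sprintf(paste0("StructureConfig: confHigh %g, confLow %g, ",
                       "dominance %.2f, pureMinLen %d\n"),
                object@confHigh, object@confLow, object@dominance,
                object@pureMinLen))
})

#' StructureTrack: per-residue secondary structure plus confidence
#'
#' A track aligned to a protein sequence: a three-class secondary-structure
#' call per residue (helix / sheet / coil) and a per-residue confidence in
#' [0, 100] with pLDDT semantics. Tracks are consumed, never computed:
#' secondary structure arrives as DSSP output or a plain class string, and
#' confidence arrives from the temperature-factor column of
#' AlphaFold-style PDB files.
#'
#' @slot protein protein identifier (may be "")
#' @slot ss character vector, one of "helix", "sheet", "coil" per residue
#' @slot conf numeric vector of per-residue confidences in [0, 100]
#'
#' @seealso [structureTrack()], [loadStructureTrack()], [classifyResidues()]
#' @export
setClass("StructureTrack",
         representation(protein = "character", ss = "character",
                        conf = "numeric"))

setValidity("StructureTrack", function(object) {
    msg <- character()
    if (length(object@ss) != length(object@conf))
        msg <- c(msg, "ss and conf must have equal length")
    if (!all(object@ss %in% c("helix", "sheet", "coil")))
        msg <- c(msg, "ss values must be helix, sheet or coil")
    if (length(object@conf) && (any(object@conf < 0) || any(object@conf > 100)))
        msg <- c(msg, "conf must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "StructureTrack", function(object) {
    n <- length(object@ss)
    cat(sprintf("StructureTrack%s: %d residues (%.0f%% helix, %.0f%% sheet, %.0f%% coil), mean conf %.1f\n",
                if (nzchar(object@protein)) paste0(" [", object@protein, "]") else "",
                n, 100 * mean(object@ss == "helix"),
                100 * mean(object@ss == "sheet"),
                100 * mean(object@ss == "coil"), mean(object@conf)))
})

#' @describeIn StructureTrack-class number of residues in the track
#' @param x a StructureTrack
#' @export
setMethod("length", "StructureTrack", function(x) length(x@ss))

## ---------------------------------------------------------------------------
## DriftConfig
## ---------------------------------------------------------------------------

#' DriftConfig: parameters of the compositional-drift scan
#'
#' The drift scan enumerates sets of four non-charged amino acids whose
#' combined proteome frequency matches that of the four charged residues
#' (0.233 in budding yeast) within `freqTol`, detects regions enriched for
#' each set with a relaxed detector (threshold 0.35, tolerance 15, minimum
#' length 30), and scores how well each set's enrichment is retained across
#' ortholog alignments.
#'
#' @slot threshold detector enrichment threshold (default 0.35)
#' @slot tolerance detector tolerance in residues (default 15)
#' @slot minLen detector minimum region length (default 30)
#' @slot freqTarget combined-frequency target for candidate sets
#'   (default 0.233)
#' @slot freqTol tolerance around `freqTarget` (default 0.01)
#' @slot minAligned minimum non-gap residues for a species to count as
#'   retaining a region (default 30)
#'
#' @seealso [driftConfig()], [driftScan()]
#' @export
setClass("DriftConfig",
         representation(threshold = "numeric", tolerance = "integer",
                        minLen = "integer", freqTarget = "numeric",
                        freqTol = "numeric", minAligned = "integer"))

setValidity("DriftConfig", function(object) {
    msg <- character()
    if (object@threshold <= 0 || object@threshold > 1)
        msg <- c(msg, "threshold must be in (0, 1]")
    if (object@tolerance < 0L) msg <- c(msg, "tolerance must be >= 0")
    if (object@minLen < 1L) msg <- c(msg, "minLen must be >= 1")
    if (object@freqTarget <= 0 || object@freqTarget >= 1)
        msg <- c(msg, "freqTarget must be in (0, 1)")
    if (object@freqTol < 0) msg <- c(msg, "freqTol must be >= 0")
    if (object@minAligned < 1L) msg <- c(msg, "minAligned must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a DriftConfig
#' @param threshold detector enrichment threshold (default 0.35)
#' @param tolerance detector tolerance (default 15)
#' @param minLen detector minimum region length (default 30)
#' @param freqTarget combined-frequency target (default 0.233)
#' @param freqTol tolerance around the target (default 0.01)
#' @param minAligned minimum non-gap residues for species presence
#'   (default 30)
#' @return a [DriftConfig-class]
#' @export
driftConfig <- function(threshold = 0.35, tolerance = 15L, minLen = 30L,
                        freqTarget = 0.233, freqTol = 0.01,
                        minAligned = 30L) {
    new("DriftConfig", threshold = threshold,
        tolerance = as.integer(tolerance), minLen = as.integer(minLen),
        freqTarget = freqTarget, freqTol = freqTol,
        minAligned = as.integer(minAligned))
}

setMethod("show", "DriftConfig", function(object) {
    cat(sprintf(paste0("DriftConfig: threshold %.2f, tolerance %d, minLen %d, ",
                       "freq target %.3f +/- %.3f\n"),
                object@threshold, object@tolerance, object@minLen,
                object@freqTarget, object@freqTol))
})

## ---------------------------------------------------------------------------
## CompositionClassifier
## ---------------------------------------------------------------------------

#' CompositionClassifier: composition-only logistic model
#'
#' A logistic regression over amino-acid composition fractions that
#' separates helical from disordered regions. Helical is the positive
#' class: the decision value is `intercept + sum(coef_i * freq_i)` and a
#' positive value predicts helical. Features are fractions (not counts) and
#' are not standardized, so coefficients are directly comparable across
#' amino acids.
#'
#' @slot coefficients named numeric vector, one coefficient per feature
#'   amino acid
#' @slot intercept numeric scalar
#' @slot features amino acids used as features (all 20, or a top-k subset)
#' @slot lambda L2 regularization strength used in fitting
#' @slot metadata list with the training split fraction, seed, class
#'   counts, and the held-out evaluation report
#'
#' @seealso [trainCompositionClassifier()], [predict()], [topKModel()]
#' @export
setClass("CompositionClassifier",
         representation(coefficients = "numeric", intercept = "numeric",
                        features = "character", lambda = "numeric",
                        metadata = "list"))

setValidity("CompositionClassifier", function(object) {
    msg <- character()
    if (length(object@coefficients) != length(object@features))
        msg <- c(msg, "one coefficient per feature required")
    if (!all(object@features %in% AA_ALPHABET20))
        msg <- c(msg, "features must be standard amino acids")
    if (length(object@intercept) != 1)
        msg <- c(msg, "intercept must be a scalar")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CompositionClassifier", function(object) {
    cat(sprintf("CompositionClassifier: %d features, lambda %g\n",
                length(object@features), object@lambda))
    top <- sort(abs(object@coefficients), decreasing = TRUE)
    k <- min(5, length(top))
    cat("  largest |coef|:",
        paste(sprintf("%s=%.2f", names(top)[seq_len(k)],
                      object@coefficients[names(top)[seq_len(k)]]),
              collapse = ", "), "\n")
    ho <- object@metadata$heldOut
    if (!is.null(ho))
        cat(sprintf("  held-out accuracy: %.3f (n = %d)\n",
                    ho$accuracy, sum(ho$confusion)))
})

#' @describeIn CompositionClassifier-class model coefficients (named by
#'   amino acid)
#' @param object a CompositionClassifier
#' @export
setMethod("coef", "CompositionClassifier",
          function(object) object@coefficients)
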