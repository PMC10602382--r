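## Composition-only logistic classifier: pure-region corpus extraction,
## ridge-regularized fit, restricted (top-k) variants, and comparison with
## the charge/hydropathy rule.

#' Extract pure helical / disordered regions for training
#'
#' Scans per-protein residue-class vectors for maximal single-class runs of
#' helix or disordered residues strictly longer than `pureMinLen` and
#' returns them as a labeled composition dataset: one row per region with
#' provenance (protein, interval), the raw sequence, the label, and the 20
#' composition-fraction columns.
#'
#' @param classes named list of residue-class factors (one per protein,
#'   from [classifyResidues()])
#' @param sequences named character vector or `AAStringSet` of the matching
#'   protein sequences
#' @param config a [StructureConfig-class] (supplies `pureMinLen`)
#' @return data.frame with columns `protein`, `start`, `end`, `label`,
#'   `sequence` and one column per amino acid
#' @export
extractPureRegions <- function(classes, sequences,
                               config = structureConfig()) {
    seqs <- .asSequenceVector(sequences)
    stopifnot(all(names(classes) %in% names(seqs)))
    rows <- list()
    for (p in names(classes)) {
        cl <- as.character(classes[[p]])
        if (length(cl) != nchar(seqs[[p]]))
            stop("class vector and sequence length differ for ", p)
        r <- rle(cl)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values %in% c("helix", "disordered") &
            r$lengths > config@pureMinLen
        for (i in which(keep)) {
            rows[[length(rows) + 1L]] <- data.frame(
                protein = p, start = starts[i], end = ends[i],
                label = ifelse(r$values[i] == "helix", "helical",
                               "disordered"),
                sequence = substr(seqs[[p]], starts[i], ends[i]),
                stringsAsFactors = FALSE)
        }
    }
    if (length(rows) == 0L)
        return(cbind(data.frame(protein = character(), start = integer(),
                                end = integer(), label = character(),
                                sequence = character()),
                     as.data.frame(matrix(numeric(), 0, 20,
                                          dimnames = list(NULL, AA_ALPHABET20)))))
    df <- do.call(rbind, rows)
    cbind(df, as.data.frame(compositionMatrix(df$sequence)))
}

## Confusion-based evaluation with helical as the positive class.
## FPR = disordered regions called helical / all disordered;
## FNR = helical regions called disordered / all helical.
.evalReport <- function(predicted, truth) {
    lev <- c("disordered", "helical")
    cm <- table(factor(truth, lev), factor(predicted, lev),
                dnn = c("truth", "predicted"))
    list(accuracy = sum(diag(cm)) / sum(cm),
         fpr = if (sum(cm["disordered", ]) > 0)
                   cm["disordered", "helical"] / sum(cm["disordered", ]) else NA,
         fnr = if (sum(cm["helical", ]) > 0)
                   cm["helical", "disordered"] / sum(cm["helical", ]) else NA,
         confusion = cm)
}

## Ridge-logistic fit on a composition matrix; helical is the positive
## class. glmnet is deterministic for fixed data and lambda; stats::glm
## handles the single-feature case glmnet cannot.
.fitLogistic <- function(xmat, y, lambda) {
    if (ncol(xmat) >= 2L) {
        fit <- glmnet::glmnet(xmat, y, family = "binomial", alpha = 0,
                              lambda = lambda, standardize = FALSE)
        cf <- as.numeric(stats::coef(fit))
        list(intercept = cf[1L],
             coefficients = setNames(cf[-1L], colnames(xmat)),
             lambda = lambda)
    } else {
        df <- data.frame(y = y, x = xmat[, 1L])
        fit <- stats::glm(y ~ x, data = df, family = stats::binomial())
        list(intercept = unname(stats::coef(fit)[1L]),
             coefficients = setNames(unname(stats::coef(fit)[2L]),
                                     colnames(xmat)),
             lambda = 0)
    }
}

#' Train the composition classifier
#'
#' Splits the labeled dataset region-wise into training and testing
#' fractions (stratified by label, seeded), fits a ridge-regularized
#' logistic regression of label on the 20 composition fractions, and
#' evaluates on the held-out rows. Mild fixed L2 regularization keeps the
#' solver stable on near-separable compositions without materially
#' shrinking the coefficients; the strength is recorded in the model.
#'
#' @param dataset data.frame from [extractPureRegions()] (or any frame
#'   with a `label` column and the 20 amino-acid columns)
#' @param split training fraction (default 0.75)
#' @param seed integer seed for the split
#' @param lambda L2 strength (default 1e-3)
#' @return a [CompositionClassifier-class]; the held-out evaluation report
#'   is in `@metadata$heldOut`
#' @export
trainCompositionClassifier <- function(dataset, split = 0.75, seed = 1L,
                                       lambda = 1e-3) {
    labs <- unique(dataset$label)
    if (!setequal(labs, c("helical", "disordered")))
        stop("dataset must contain both labels 'helical' and 'disordered'")
    if (nrow(dataset) < 20L)
        stop("dataset too small (need >= 20 regions)")
    xmat <- as.matrix(dataset[, AA_ALPHABET20])
    y <- factor(dataset$label, levels = c("disordered", "helical"))
    idxTrain <- local({
        set.seed(seed)
        unlist(lapply(levels(y), function(l) {
            i <- which(y == l)
            sample(i, size = round(split * length(i)))
        }), use.names = FALSE)
    })
    fit <- .fitLogistic(xmat[idxTrain, , drop = FALSE], y[idxTrain], lambda)
    model <- new("CompositionClassifier",
                 coefficients = fit$coefficients,
                 intercept = fit$intercept,
                 features = AA_ALPHABET20, lambda = fit$lambda,
                 metadata = list(split = split, seed = seed,
                                 nTrain = length(idxTrain),
                                 nTest = nrow(dataset) - length(idxTrain),
                                 classCounts = table(y)))
    held <- setdiff(seq_len(nrow(dataset)), idxTrain)
    pr <- predict(model, xmat[held, , drop = FALSE])
    model@metadata$heldOut <- .evalReport(pr$label, y[held])
    model@metadata$testIndex <- held
    model
}

#' Predict helical vs disordered from composition
#'
#' Applies the logistic model. Input may be a composition matrix, a
#' data.frame containing the 20 amino-acid columns, raw sequences
#' (character or `AAStringSet`; converted to composition first, so any
#' permutation of a sequence gives an identical prediction), or a single
#' composition vector. A positive decision value (`intercept +
#' sum(coef * freq)`) predicts helical; the probability comes through the
#' logistic link.
#'
#' @param object a [CompositionClassifier-class]
#' @param newdata input as described above
#' @param ... unused
#' @return data.frame with columns `label` and `probHelical`
#' @export
setMethod("predict", "CompositionClassifier", function(object, newdata, ...) {
    x <- newdata
    if (is.character(x) || is(x, "XStringSet"))
        x <- compositionMatrix(x)
    if (is.data.frame(x))
        x <- as.matrix(x[, object@features, drop = FALSE])
    if (is.null(dim(x)))
        x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
    if (!all(object@features %in% colnames(x)))
        stop("newdata lacks required composition columns")
    eta <- object@intercept +
        as.numeric(x[, object@features, drop = FALSE] %*% object@coefficients)
    p <- stats::plogis(eta)
    data.frame(label = ifelse(eta > 0, "helical", "disordered"),
               probHelical = p, stringsAsFactors = FALSE)
})

#' Restricted (top-k) classifier
#'
#' Refits the logistic model using only the `k` amino acids with the
#' largest absolute coefficients in the full model. Refitting (rather than
#' truncating the coefficient vector) is the default because dropped
#' features shift the optimal weights of those retained; truncation is
#' available for comparison.
#'
#' @param model a fitted full [CompositionClassifier-class]
#' @param dataset the labeled dataset used for refitting/evaluation
#' @param k number of amino acids to keep (1..20)
#' @param refit refit on the restricted features (default) or truncate
#' @return a restricted [CompositionClassifier-class] with its own
#'   held-out report
#' @export
topKModel <- function(model, dataset, k = 5L, refit = TRUE) {
    if (k < 1L || k > length(model@features))
        stop("k must be between 1 and ", length(model@features))
    keep <- names(sort(abs(model@coefficients),
                       decreasing = TRUE))[seq_len(k)]
    xmat <- as.matrix(dataset[, AA_ALPHABET20])
    y <- factor(dataset$label, levels = c("disordered", "helical"))
    meta <- model@metadata
    idxTrain <- setdiff(seq_len(nrow(dataset)), meta$testIndex)
    if (refit) {
        fit <- .fitLogistic(xmat[idxTrain, keep, drop = FALSE],
                            y[idxTrain], model@lambda)
        sub <- new("CompositionClassifier",
                   coefficients = fit$coefficients,
                   intercept = fit$intercept, features = keep,
                   lambda = fit$lambda,
                   metadata = list(parent = "topK-refit", k = k,
                                   seed = meta$seed))
    } else {
        sub <- new("CompositionClassifier",
                   coefficients = model@coefficients[keep],
                   intercept = model@intercept, features = keep,
                   lambda = model@lambda,
                   metadata = list(parent = "topK-truncate", k = k,
                                   seed = meta$seed))
    }
    pr <- predict(sub, xmat[meta$testIndex, keep, drop = FALSE])
    sub@metadata$heldOut <- .evalReport(pr$label, y[meta$testIndex])
    sub@metadata$testIndex <- meta$testIndex
    sub
}

#' Compare the composition classifier with the charge/hydropathy rule
#'
#' Scores the identical rows with both rules: the logistic model on
#' composition, and the charge/hydropathy boundary, which maps the
#' "disordered side" of the line to disordered and the folded side to
#' helical. Requires the dataset to carry raw sequences (for |NCPR| and
#' hydropathy).
#'
#' @param dataset labeled dataset with `sequence` and `label` columns
#' @param model a fitted [CompositionClassifier-class]
#' @param charge a [ChargeModel-class]
#' @param slope,intercept boundary coefficients (see [uverskyClassify()])
#' @return named list of evaluation reports (`classifier`, `uversky`),
#'   each with accuracy, FPR, FNR and the confusion table
#' @export
compareRules <- function(dataset, model, charge = chargeModel(),
                         slope = 2.785, intercept = -1.151) {
    truth <- dataset$label
    prLR <- predict(model, dataset$sequence)$label
    u <- uverskyClassify(abs(ncpr(dataset$sequence, charge)),
                         meanHydropathy(dataset$sequence),
                         slope, intercept)
    prU <- ifelse(u == "disordered", "disordered", "helical")
    list(classifier = .evalReport(prLR, truth),
         uversky = .evalReport(prU, truth))
}

#' Correlation of coefficients with a per-residue scale
#'
#' Pearson correlation between the model coefficients and a user-supplied
#' per-amino-acid scale (e.g. an experimental helix-propensity scale).
#' Scale values are configuration supplied by the caller, not bundled
#' ground truth.
#'
#' @param model a [CompositionClassifier-class]
#' @param scale named numeric vector covering every model feature
#' @return Pearson correlation coefficient
#' @export
coefficientScaleCorrelation <- function(model, scale) {
    miss <- setdiff(model@features, names(scale))
    if (length(miss))
        stop("scale missing entries for: ", paste(miss, collapse = ", "))
    stats::cor(model@coefficients, scale[model@features])
}
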