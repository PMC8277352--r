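#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom stats aov anova coef complete.cases cor cor.test density fisher.test
#'   lm median na.omit p.adjust pchisq pf pnorm prcomp pt qnorm quantile rbinom
#'   residuals rexp rnorm rpois runif sd setNames t.test var wilcox.test
#'   friedman.test fitted dbinom hclust as.dist cutree predict
#' @importFrom utils head tail read.csv write.csv combn packageVersion
NULL

CONDITION_LEVELS <- c("HBT_ingroup", "HBT_outgroup",
                      "brief_ingroup", "brief_outgroup",
                      "two_free_ingroup", "two_free_outgroup",
                      "chocolate", "trapped", "baseline")

REGION_CATEGORIES <- c("frontal", "insular", "striatal", "hippocampal",
                       "hypothalamic", "sensory", "other")

#' ActivityDataset: subject-by-region c-Fos counts
#'
#' An \linkS4class{SummarizedExperiment} subclass holding a brain-region
#' (rows) by subject (columns) matrix of c-Fos positive cell counts
#' (average over replicate 250 x 250 um ROIs, so values may be
#' non-integer). Missing values are \code{NA} in the \code{"counts"}
#' assay. \code{rowData} carries region metadata (\code{region_id},
#' \code{full_name}, \code{category}, \code{ap_mm}); \code{colData}
#' carries \code{subject_id} and \code{condition}.
#'
#' @seealso \code{\link{ActivityDataset}} for the constructor,
#'   \code{\link{loadActivity}} to read one from CSV files.
#' @export
setClass("ActivityDataset", contains = "SummarizedExperiment")

setValidity("ActivityDataset", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("subject_id", "condition") %in% colnames(cd)))
        msg <- c(msg, "colData must have 'subject_id' and 'condition'")
    else {
        if (anyDuplicated(cd$subject_id))
            msg <- c(msg, "duplicate subject ids")
        bad <- setdiff(unique(as.character(cd$condition)), CONDITION_LEVELS)
        if (length(bad))
            msg <- c(msg, paste0("unknown condition label(s): ",
                                 paste(bad, collapse = ", ")))
    }
    rd <- SummarizedExperiment::rowData(object)
    if (!"region_id" %in% colnames(rd))
        msg <- c(msg, "rowData must have 'region_id'")
    else if (anyDuplicated(rd$region_id))
        msg <- c(msg, "duplicate region ids")
    if ("counts" %in% SummarizedExperiment::assayNames(object)) {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative where observed")
    }
    if (length(msg)) msg else TRUE
})

#' OutlierReport: record of removed count values
#'
#' Returned by \code{\link{removeOutliers}}. The \code{entries} slot is a
#' \code{DataFrame} with one row per removed value (subject, region,
#' value, its condition-group mean and SD, and the pooled range of the
#' other conditions); \code{skipped} lists (condition, region) cells with
#' too few observations for a standard deviation.
#'
#' @export
setClass("OutlierReport",
         representation(entries = "DataFrame", skipped = "DataFrame"))

#' @describeIn OutlierReport number of values removed
#' @param object an \code{OutlierReport}
#' @export
setGeneric("nRemoved", function(object) standardGeneric("nRemoved"))

#' @rdname OutlierReport
#' @export
setMethod("nRemoved", "OutlierReport", function(object) nrow(object@entries))

setMethod("show", "OutlierReport", function(object) {
    cat("OutlierReport:", nrow(object@entries), "value(s) removed,",
        nrow(object@skipped), "cell(s) skipped (n < 2)\n")
})

#' PLSResult: task partial least squares decomposition
#'
#' Holds the singular value decomposition of the mean-centered
#' condition-by-region matrix together with the permutation p-value per
#' latent variable (LV) and bootstrap ratios per region salience.
#'
#' @slot singularValues non-negative, descending
#' @slot conditionSaliences condition x LV contrast matrix (left singular
#'   vectors)
#' @slot regionSaliences region x LV salience matrix (right singular
#'   vectors)
#' @slot permutationP per-LV permutation p (add-one estimator, never 0)
#' @slot bootstrapRatios region x LV salience / bootstrap SE
#' @slot nPerm,nBoot,seed sampling parameters
#' @slot nBootRejected bootstrap resamples redrawn because a condition
#'   had fewer than 2 distinct subjects
#' @export
setClass("PLSResult",
         representation(singularValues = "numeric",
                        conditionSaliences = "matrix",
                        regionSaliences = "matrix",
                        permutationP = "numeric",
                        bootstrapRatios = "matrix",
                        nPerm = "integer",
                        nBoot = "integer",
                        nBootRejected = "integer",
                        seed = "integer"))

setValidity("PLSResult", function(object) {
    msg <- character()
    sv <- object@singularValues
    if (any(sv < -1e-12)) msg <- c(msg, "singular values must be >= 0")
    if (is.unsorted(rev(sv), strictly = FALSE))
        msg <- c(msg, "singular values must be descending")
    p <- object@permutationP
    if (length(p) && (any(p <= 0) || any(p > 1)))
        msg <- c(msg, "permutation p must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PLSResult", function(object) {
    k <- length(object@singularValues)
    cat("PLSResult with", k, "latent variable(s)\n")
    df <- data.frame(LV = seq_len(k),
                     singular_value = round(object@singularValues, 4),
                     perm_p = signif(object@permutationP, 3))
    print(df, row.names = FALSE)
    cat("permutations:", object@nPerm, " bootstraps:", object@nBoot, "\n")
})

#' CoactivationNetwork: thresholded inter-region correlation graph
#'
#' Pairwise Pearson correlation matrix between region c-Fos counts plus
#' the binary adjacency obtained by keeping the top fraction of
#' off-diagonal pairs ranked by |r| (tied pairs at the cutoff are all
#' kept). Edge signs are retained as an attribute matrix.
#'
#' @slot rMatrix symmetric region x region Pearson r, unit diagonal
#' @slot pairwiseN per-cell number of complete observation pairs
#' @slot thresholdFrac fraction of off-diagonal pairs retained
#' @slot adjacency symmetric hollow binary matrix
#' @slot edgeSigns sign of r for retained edges (0 elsewhere)
#' @slot condition label of the condition the matrix was computed on
#' @export
setClass("CoactivationNetwork",
         representation(rMatrix = "matrix",
                        pairwiseN = "matrix",
                        thresholdFrac = "numeric",
                        adjacency = "matrix",
                        edgeSigns = "matrix",
                        condition = "character"))

setValidity("CoactivationNetwork", function(object) {
    msg <- character()
    A <- object@adjacency
    if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
    else {
        if (!isTRUE(all.equal(A, t(A)))) msg <- c(msg, "adjacency must be symmetric")
        if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    }
    if (object@thresholdFrac <= 0 || object@thresholdFrac > 1)
        msg <- c(msg, "thresholdFrac must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CoactivationNetwork", function(object) {
    e <- sum(object@adjacency) / 2
    cat(sprintf("CoactivationNetwork (%s): %d regions, %d edges (top %.0f%% of |r|)\n",
                object@condition, nrow(object@adjacency), e,
                100 * object@thresholdFrac))
})

#' EnsembleTally: per-region occurrence counts over ensemble configurations
#'
#' For every region, how many of the ensemble's configurations put it in
#' a cluster classified as significant for the ingroup only, the
#' outgroup only, both, or neither; the four counts sum to the number of
#' configurations.
#'
#' @slot tally \code{DataFrame} with columns \code{region},
#'   \code{n_ingroup_only}, \code{n_outgroup_only}, \code{n_both},
#'   \code{n_none} and the corresponding ratios (percent)
#' @slot nConfigs number of configurations run
#' @export
setClass("EnsembleTally",
         representation(tally = "DataFrame", nConfigs = "integer"))

setValidity("EnsembleTally", function(object) {
    tl <- object@tally
    cols <- c("n_ingroup_only", "n_outgroup_only", "n_both", "n_none")
    if (!all(cols %in% colnames(tl)))
        return("tally must have the four category count columns")
    tot <- Reduce(`+`, lapply(cols, function(cc) tl[[cc]]))
    if (length(tot) && any(tot != object@nConfigs))
        return("category counts must sum to nConfigs for every region")
    TRUE
})

setMethod("show", "EnsembleTally", function(object) {
    cat("EnsembleTally over", object@nConfigs, "configurations,",
        nrow(object@tally), "regions\n")
    o <- order(object@tally$ratio_ingroup_only, decreasing = TRUE)
    print(head(as.data.frame(object@tally[o, ]), 5), row.names = FALSE)
})

#' PhotometrySession: synchronized two-channel fiber photometry trace
#'
#' @slot t sample times (s), uniform rate, strictly increasing
#' @slot s470 calcium-dependent (470 nm) fluorescence
#' @slot s405 isosbestic control (405 nm) fluorescence
#' @slot events named list of sorted event-time vectors
#'   (\code{zone_entry}, \code{door_opening}, \code{eating})
#' @slot inZone per-sample logical, rat inside the restrainer zone
#' @slot sessionKind one of ingroup, outgroup, empty_restrainer,
#'   empty_arena
#' @slot groundTruth list of planted-signal parameters when the session
#'   is synthetic (empty otherwise)
#' @export
setClass("PhotometrySession",
         representation(t = "numeric", s470 = "numeric", s405 = "numeric",
                        events = "list", inZone = "logical",
                        sessionKind = "character", groundTruth = "list"))

setValidity("PhotometrySession", function(object) {
    msg <- character()
    n <- length(object@t)
    if (length(object@s470) != n || length(object@s405) != n)
        msg <- c(msg, "t, s470, s405 must have equal length")
    if (length(object@inZone) && length(object@inZone) != n)
        msg <- c(msg, "inZone must match trace length")
    if (n > 1 && any(diff(object@t) <= 0))
        msg <- c(msg, "t must be strictly increasing")
    rng <- range(object@t)
    for (ev in object@events)
        if (length(ev) && (min(ev) < rng[1] || max(ev) > rng[2]))
            msg <- c(msg, "event times must lie within [t0, t_end]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PhotometrySession", function(object) {
    cat(sprintf("PhotometrySession (%s): %.1f s at %.1f Hz, events:",
                object@sessionKind, diff(range(object@t)),
                1 / median(diff(object@t))))
    cat(" ", paste(names(object@events),
                   vapply(object@events, length, 1L),
                   sep = "=", collapse = ", "), "\n")
})

#' TestResult: a single statistical test outcome
#'
#' Lightweight container used by every test in the package: method name,
#' statistic, degrees of freedom (scalar or pair), p-value, sample size,
#' plus method-specific extras (group means, post-hoc tables, flags).
#'
#' @export
setClass("TestResult",
         representation(method = "character", statistic = "numeric",
                        df = "numeric", pValue = "numeric", n = "integer",
                        extras = "list"))

setValidity("TestResult", function(object) {
    msg <- character()
    if (!is.na(object@pValue) &&
        (object@pValue < 0 || object@pValue > 1))
        msg <- c(msg, "p-value must lie in [0, 1]")
    if (length(object@df) && any(object@df < 0, na.rm = TRUE))
        msg <- c(msg, "df must be >= 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TestResult", function(object) {
    dfs <- if (length(object@df)) paste(round(object@df, 2), collapse = ", ")
           else "NA"
    cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g, n = %d\n",
                object@method, object@statistic, dfs, object@pValue,
                object@n))
    if (isTRUE(object@extras$degenerate)) cat("  (degenerate input)\n")
})

newTestResult <- function(method, statistic, df, pValue, n, extras = list()) {
    new("TestResult", method = method, statistic = as.numeric(statistic),
        df = as.numeric(df), pValue = as.numeric(pValue),
        n = as.integer(n), extras = extras)
}

#' @describeIn TestResult the p-value
#' @param object a \code{TestResult}
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname TestResult
#' @export
setMethod("pValue", "TestResult", function(object) object@pValue)

#' @describeIn TestResult the test statistic
#' @export
setGeneric("statistic", function(object) standardGeneric("statistic"))

#' @rdname TestResult
#' @export
setMethod("statistic", "TestResult", function(object) object@statistic)

#' Serialize a TestResult to a JSON record
#'
#' @param object a \code{TestResult}
#' @return a JSON string \code{{method, statistic, df, p, n}}
#' @export
testResultJSON <- function(object) {
    stopifnot(is(object, "TestResult"))
    jsonlite::toJSON(list(method = object@method,
                          statistic = object@statistic,
                          df = object@df, p = object@pValue,
                          n = object@n),
                     auto_unbox = TRUE, digits = NA)
}
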