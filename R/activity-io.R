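#' Construct an ActivityDataset
#'
#' @param counts numeric matrix, regions in rows and subjects in columns
#'   (a subject x region matrix is transposed automatically when
#'   dimnames allow disambiguation is not needed: pass regions in rows).
#'   \code{NA} marks missing values.
#' @param regionInfo data.frame with columns \code{region_id},
#'   \code{full_name}, \code{category} and optionally \code{ap_mm};
#'   \code{region_id} must match \code{rownames(counts)}.
#' @param conditions character vector of condition labels, one per
#'   subject, from the controlled vocabulary (see
#'   \code{\link{conditionLevels}}).
#' @param subjects subject ids; defaults to \code{colnames(counts)}.
#' @return an \linkS4class{ActivityDataset}
#' @examples
#' cnt <- matrix(rpois(12, 20), nrow = 4,
#'               dimnames = list(paste0("R", 1:4), paste0("s", 1:3)))
#' ri <- data.frame(region_id = paste0("R", 1:4),
#'                  full_name = paste("region", 1:4), category = "other")
#' ads <- ActivityDataset(cnt, ri, rep("baseline", 3))
#' @export
ActivityDataset <- function(counts, regionInfo, conditions,
                            subjects = colnames(counts)) {
    counts <- as.matrix(counts)
    if (is.null(subjects)) subjects <- paste0("s", seq_len(ncol(counts)))
    if (is.null(rownames(counts))) rownames(counts) <- regionInfo$region_id
    regionInfo <- as.data.frame(regionInfo)
    if (!all(rownames(counts) %in% regionInfo$region_id)) {
        missing <- setdiff(rownames(counts), regionInfo$region_id)
        stop("region(s) in counts absent from metadata: ",
             paste(missing, collapse = ", "))
    }
    regionInfo <- regionInfo[match(rownames(counts), regionInfo$region_id), ,
                             drop = FALSE]
    bad <- setdiff(unique(regionInfo$category), REGION_CATEGORIES)
    if (length(bad))
        stop("unknown region category: ", paste(bad, collapse = ", "))
    conditions <- as.character(conditions)
    if (length(conditions) != ncol(counts))
        stop("one condition label per subject required")
    neg <- which(counts < 0, arr.ind = TRUE)
    if (nrow(neg))
        stop(sprintf("negative count for subject '%s', region '%s'",
                     subjects[neg[1, 2]], rownames(counts)[neg[1, 1]]))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(regionInfo, row.names = regionInfo$region_id),
        colData = S4Vectors::DataFrame(subject_id = as.character(subjects),
                                       condition = conditions,
                                       row.names = as.character(subjects)))
    new("ActivityDataset", se)
}

#' Controlled vocabulary of condition labels
#' @return character vector of the nine recognized condition labels
#' @export
conditionLevels <- function() CONDITION_LEVELS

#' Region categories
#' @return character vector of anatomical group labels
#' @export
regionCategories <- function() REGION_CATEGORIES

#' @describeIn ActivityDataset condition label per subject
#' @param object an \code{ActivityDataset}
#' @export
setGeneric("conditions", function(object) standardGeneric("conditions"))

#' @rdname ActivityDataset
#' @export
setMethod("conditions", "ActivityDataset", function(object)
    setNames(as.character(SummarizedExperiment::colData(object)$condition),
             SummarizedExperiment::colData(object)$subject_id))

#' @describeIn ActivityDataset region x subject count matrix (NA = missing)
#' @export
setGeneric("fosCounts", function(object) standardGeneric("fosCounts"))

#' @rdname ActivityDataset
#' @export
setMethod("fosCounts", "ActivityDataset", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @describeIn ActivityDataset logical region x subject missingness mask
#' @export
setGeneric("missingMask", function(object) standardGeneric("missingMask"))

#' @rdname ActivityDataset
#' @export
setMethod("missingMask", "ActivityDataset", function(object)
    is.na(SummarizedExperiment::assay(object, "counts")))

#' @describeIn ActivityDataset region ids
#' @export
setGeneric("regionIds", function(object) standardGeneric("regionIds"))

#' @rdname ActivityDataset
#' @export
setMethod("regionIds", "ActivityDataset", function(object)
    as.character(SummarizedExperiment::rowData(object)$region_id))

setCounts <- function(object, counts) {
    SummarizedExperiment::assay(object, "counts") <- counts
    validObject(object)
    object
}

#' Read an activity dataset from counts and region-metadata CSV files
#'
#' The counts file has columns \code{subject_id}, \code{condition}, then
#' one column per region id; blank cells denote missing values. The
#' regions file has columns \code{region_id}, \code{full_name},
#' \code{category} and optionally \code{ap_mm}.
#'
#' @param countsPath,regionsPath CSV paths
#' @return an \linkS4class{ActivityDataset}
#' @export
loadActivity <- function(countsPath, regionsPath) {
    cts <- read.csv(countsPath, check.names = FALSE,
                    stringsAsFactors = FALSE)
    if (!all(c("subject_id", "condition") %in% colnames(cts)))
        stop("counts file must have 'subject_id' and 'condition' columns")
    if (anyDuplicated(cts$subject_id))
        stop("duplicate subject ids in counts file")
    regions <- read.csv(regionsPath, stringsAsFactors = FALSE)
    regionCols <- setdiff(colnames(cts), c("subject_id", "condition"))
    mat <- t(as.matrix(cts[, regionCols, drop = FALSE]))
    storage.mode(mat) <- "double"
    colnames(mat) <- cts$subject_id
    ActivityDataset(mat, regions, cts$condition, cts$subject_id)
}

#' Write an activity dataset to counts and region-metadata CSV files
#'
#' Inverse of \code{\link{loadActivity}}; missing values are written as
#' blank cells.
#'
#' @param ds an \linkS4class{ActivityDataset}
#' @param countsPath,regionsPath output CSV paths
#' @return invisibly, the two paths
#' @export
writeActivity <- function(ds, countsPath, regionsPath) {
    cnt <- fosCounts(ds)
    df <- data.frame(subject_id = colnames(cnt),
                     condition = unname(conditions(ds)),
                     t(cnt), check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.csv(df, countsPath, row.names = FALSE, na = "")
    rd <- as.data.frame(SummarizedExperiment::rowData(ds))
    write.csv(rd, regionsPath, row.names = FALSE, na = "")
    message(sprintf("wrote %d subjects x %d regions to %s",
                    ncol(cnt), nrow(cnt), countsPath))
    invisible(c(countsPath, regionsPath))
}

#' Remove outlying c-Fos counts
#'
#' A value is removed iff it is (a) more than \code{nsd} standard
#' deviations above or below its own (condition, region) group mean, and
#' (b) strictly outside the observed range of that region's values
#' pooled over all other conditions. The rule is single-pass: group
#' statistics come from the data as given. Cells with fewer than two
#' observed values have no SD and are never flagged (they are listed as
#' skipped in the report).
#'
#' @param ds an \linkS4class{ActivityDataset}
#' @param nsd SD multiplier (default 2)
#' @return list with elements \code{dataset} (flagged values set to
#'   missing) and \code{report} (an \linkS4class{OutlierReport})
#' @export
removeOutliers <- function(ds, nsd = 2) {
    cnt <- fosCounts(ds)
    cond <- unname(conditions(ds))
    entries <- list()
    skipped <- list()
    for (r in seq_len(nrow(cnt))) {
        x <- cnt[r, ]
        for (cc in unique(cond)) {
            inC <- cond == cc
            vals <- x[inC & !is.na(x)]
            if (length(vals) < 2) {
                if (length(vals) >= 1)
                    skipped[[length(skipped) + 1L]] <-
                        data.frame(condition = cc,
                                   region = rownames(cnt)[r])
                next
            }
            m <- mean(vals); s <- sd(vals)
            others <- x[!inC & !is.na(x)]
            if (!length(others)) next
            lo <- min(others); hi <- max(others)
            for (j in which(inC & !is.na(x))) {
                v <- x[j]
                if (abs(v - m) > nsd * s && (v < lo || v > hi)) {
                    entries[[length(entries) + 1L]] <-
                        data.frame(subject = colnames(cnt)[j],
                                   region = rownames(cnt)[r],
                                   value = v, group_mean = m,
                                   group_sd = s, other_min = lo,
                                   other_max = hi)
                }
            }
        }
    }
    bind <- function(lst, proto) {
        if (length(lst)) do.call(rbind, lst) else proto
    }
    ent <- bind(entries,
                data.frame(subject = character(), region = character(),
                           value = numeric(), group_mean = numeric(),
                           group_sd = numeric(), other_min = numeric(),
                           other_max = numeric()))
    skp <- bind(skipped,
                data.frame(condition = character(), region = character()))
    out <- cnt
    if (nrow(ent))
        out[cbind(match(ent$region, rownames(cnt)),
                  match(ent$subject, colnames(cnt)))] <- NA
    list(dataset = setCounts(ds, out),
         report = new("OutlierReport",
                      entries = S4Vectors::DataFrame(ent),
                      skipped = S4Vectors::DataFrame(unique(skp))))
}

#' Write an outlier report as TSV
#' @param report an \linkS4class{OutlierReport}
#' @param path output path
#' @return invisibly, the path
#' @export
writeOutlierReport <- function(report, path) {
    df <- as.data.frame(report@entries)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    message(sprintf("wrote %d outlier entries to %s", nrow(df), path))
    invisible(path)
}

#' Impute missing counts by the condition mean
#'
#' Every missing value is replaced by the mean of the observed values of
#' the same condition and region; observed values are untouched. Used to
#' complete the matrix before task PLS.
#'
#' @param ds an \linkS4class{ActivityDataset}
#' @return an \linkS4class{ActivityDataset} with no missing values
#' @export
imputeConditionMean <- function(ds) {
    cnt <- fosCounts(ds)
    if (!anyNA(cnt)) return(ds)
    cond <- unname(conditions(ds))
    for (cc in unique(cond)) {
        inC <- cond == cc
        sub <- cnt[, inC, drop = FALSE]
        miss <- which(is.na(sub), arr.ind = TRUE)
        if (!nrow(miss)) next
        rm <- rowMeans(sub, na.rm = TRUE)
        empty <- unique(miss[, 1])[is.nan(rm[unique(miss[, 1])])]
        if (length(empty))
            stop(sprintf("cell (condition '%s', region '%s') entirely missing",
                         cc, rownames(cnt)[empty[1]]))
        sub[miss] <- rm[miss[, 1]]
        cnt[, inC] <- sub
    }
    setCounts(ds, cnt)
}

#' Per-subject total and per-condition mean c-Fos activity
#'
#' Missing values are ignored (not zero-filled) in the sums.
#'
#' @param ds an \linkS4class{ActivityDataset}
#' @return list with \code{subjectTotals} (data.frame subject,
#'   condition, total) and \code{conditionSummary} (data.frame
#'   condition, mean, sem, n)
#' @export
conditionTotals <- function(ds) {
    cnt <- fosCounts(ds)
    tot <- colSums(cnt, na.rm = TRUE)
    cond <- unname(conditions(ds))
    st <- data.frame(subject = colnames(cnt), condition = cond,
                     total = unname(tot), stringsAsFactors = FALSE)
    agg <- lapply(split(st$total, st$condition), function(v)
        c(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v)))
    cs <- data.frame(condition = names(agg),
                     do.call(rbind, agg), row.names = NULL)
    list(subjectTotals = st, conditionSummary = cs)
}
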