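## Mean-centered task partial least squares over conditions, with
## permutation testing of latent variables and bootstrap estimation of
## region-salience reliability.

#' Mean-centered condition-by-region matrix
#'
#' Rows are the per-condition means of each region (mean over the
#' condition's subjects); columns are then centered by the unweighted
#' grand mean of the condition means, so every column sums to zero.
#' The dataset must be complete (impute first, see
#' \code{\link{imputeConditionMean}}).
#'
#' @param ds an \linkS4class{ActivityDataset} without missing values
#' @param useConditions conditions to include (default: all present);
#'   at least 2, each with at least one subject
#' @return condition x region numeric matrix with zero column sums
#' @export
buildCenteredConditionMatrix <- function(ds, useConditions = NULL) {
    cnt <- fosCounts(ds)
    if (anyNA(cnt)) stop("dataset has missing values; impute first")
    cond <- unname(conditions(ds))
    if (is.null(useConditions)) useConditions <- unique(cond)
    if (length(useConditions) < 2) stop("need at least 2 conditions")
    M <- do.call(rbind, lapply(useConditions, function(cc) {
        sel <- cond == cc
        if (!any(sel)) stop("condition with 0 subjects: ", cc)
        rowMeans(cnt[, sel, drop = FALSE])
    }))
    rownames(M) <- useConditions
    sweep(M, 2, colMeans(M))
}

svdLV <- function(M) {
    s <- svd(M)
    k <- min(dim(M))
    list(d = s$d[seq_len(k)],
         u = s$u[, seq_len(k), drop = FALSE],
         v = s$v[, seq_len(k), drop = FALSE])
}

## orthogonal Procrustes rotation matrix aligning B's columns to A's
procrustesRotation <- function(B, A) {
    s <- svd(crossprod(B, A))
    s$u %*% t(s$v)
}

#' Run task PLS with permutation and bootstrap assessment
#'
#' Singular value decomposition of the mean-centered condition-by-region
#' matrix yields mutually orthogonal latent variables (LVs), each
#' pairing a condition contrast with a region salience profile. LV
#' significance is assessed by permutation: subject-to-condition
#' assignments are shuffled without replacement (group sizes fixed), the
#' pipeline recomputed, and p(LV) = (# permuted singular values >=
#' observed + 1) / (nPerm + 1). Salience reliability is assessed by
#' bootstrap: subjects are resampled with replacement while keeping them
#' assigned to their conditions; each bootstrap solution is aligned to
#' the observed one by an orthogonal Procrustes rotation estimated on
#' the condition saliences and applied to the singular-value-scaled
#' region saliences (SVD sign/order indeterminacy otherwise makes the
#' SE meaningless), and the bootstrap ratio is observed scaled salience
#' / bootstrap SE.
#'
#' @param ds an \linkS4class{ActivityDataset} without missing values
#' @param useConditions conditions to include (default: all)
#' @param nPerm,nBoot resampling counts (default 500 each)
#' @param seed mandatory integer seed
#' @return a \linkS4class{PLSResult}
#' @export
runTaskPLS <- function(ds, useConditions = NULL, nPerm = 500L,
                       nBoot = 500L, seed) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(nPerm >= 1, nBoot >= 0)
    cnt <- fosCounts(ds)
    if (anyNA(cnt)) stop("dataset has missing values; impute first")
    cond <- unname(conditions(ds))
    if (is.null(useConditions)) useConditions <- unique(cond)
    keep <- cond %in% useConditions
    cnt <- cnt[, keep, drop = FALSE]
    cond <- cond[keep]
    center <- function(labels) {
        M <- do.call(rbind, lapply(useConditions, function(cc)
            rowMeans(cnt[, labels == cc, drop = FALSE])))
        sweep(M, 2, colMeans(M))
    }
    M <- center(cond)
    obs <- svdLV(M)
    k <- length(obs$d)
    set.seed(seed)
    exceed <- integer(k)
    for (i in seq_len(nPerm)) {
        dPerm <- svdLV(center(sample(cond)))$d
        exceed <- exceed + (dPerm >= obs$d)
    }
    permP <- (exceed + 1) / (nPerm + 1)
    br <- matrix(NA_real_, nrow(cnt), k)
    nRejected <- 0L
    if (nBoot > 0) {
        idxByCond <- lapply(useConditions, function(cc) which(cond == cc))
        boots <- array(NA_real_, c(nrow(cnt), k, nBoot))
        for (b in seq_len(nBoot)) {
            repeat {
                draws <- lapply(idxByCond, function(ii)
                    sample(ii, length(ii), replace = TRUE))
                # reject resamples leaving a condition with < 2 distinct subjects
                distinct <- vapply(draws, function(dd)
                    length(unique(dd)), numeric(1))
                if (all(distinct >= 2 | lengths(idxByCond) < 2)) break
                nRejected <- nRejected + 1L
            }
            idx <- unlist(draws)
            condB <- cond[idx]
            cntB <- cnt[, idx, drop = FALSE]
            Mb <- do.call(rbind, lapply(useConditions, function(cc)
                rowMeans(cntB[, condB == cc, drop = FALSE])))
            Mb <- sweep(Mb, 2, colMeans(Mb))
            sb <- svdLV(Mb)
            # rotation from the condition side, applied to the scaled
            # region saliences V S (standard task-PLS bootstrap)
            R <- procrustesRotation(sb$u, obs$u)
            boots[, , b] <- (sb$v %*% diag(sb$d, length(sb$d))) %*% R
        }
        se <- apply(boots, c(1, 2), sd)
        br <- (obs$v %*% diag(obs$d, k)) / pmax(se, .Machine$double.eps)
    }
    rownames(obs$v) <- rownames(cnt)
    rownames(br) <- rownames(cnt)
    rownames(obs$u) <- useConditions
    new("PLSResult", singularValues = obs$d,
        conditionSaliences = obs$u, regionSaliences = obs$v,
        permutationP = permP, bootstrapRatios = br,
        nPerm = as.integer(nPerm), nBoot = as.integer(nBoot),
        nBootRejected = nRejected, seed = as.integer(seed))
}

#' Regions reliably contributing to a latent variable
#'
#' Regions whose |bootstrap ratio| exceeds the threshold (default 2.57,
#' roughly a 99 percent confidence interval on a normal scale) are
#' considered reliable, partitioned by the sign of their salience.
#'
#' @param result a \linkS4class{PLSResult}
#' @param lv latent variable index (default 1)
#' @param threshold bootstrap-ratio cutoff (default 2.57)
#' @return list with character vectors \code{positive} and
#'   \code{negative}
#' @export
reliableRegions <- function(result, lv = 1, threshold = 2.57) {
    stopifnot(is(result, "PLSResult"))
    br <- result@bootstrapRatios[, lv]
    list(positive = names(br)[!is.na(br) & br > threshold],
         negative = names(br)[!is.na(br) & br < -threshold])
}

#' Write PLS results
#'
#' JSON per-LV summary plus a per-region TSV of saliences and bootstrap
#' ratios.
#'
#' @param result a \linkS4class{PLSResult}
#' @param jsonPath,tsvPath output paths
#' @return invisibly, the two paths
#' @export
writePLSResult <- function(result, jsonPath, tsvPath) {
    k <- length(result@singularValues)
    lvs <- lapply(seq_len(k), function(l) list(
        lv = l, singular_value = result@singularValues[l],
        p = result@permutationP[l],
        condition_saliences = as.list(setNames(
            result@conditionSaliences[, l],
            rownames(result@conditionSaliences)))))
    jsonlite::write_json(lvs, jsonPath, auto_unbox = TRUE, digits = NA)
    df <- data.frame(region = rownames(result@regionSaliences),
                     result@regionSaliences,
                     bootstrap_ratio = result@bootstrapRatios)
    utils::write.table(df, tsvPath, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    message(sprintf("wrote %d LVs to %s and %d regions to %s",
                    k, jsonPath, nrow(df), tsvPath))
    invisible(c(jsonPath, tsvPath))
}
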