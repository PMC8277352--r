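## Ensemble eigen-region procedure: 40 configurations of
## threshold / clustering / weighting / reference group, each yielding a
## cluster partition, per-cluster eigen-region scores, and a
## ridge-stabilized multinomial logistic regression of ingroup and
## outgroup against the reference; per-region occurrence tallies over
## the configurations single out condition-specific regions.

BROAD_REFERENCE <- c("brief_ingroup", "brief_outgroup", "two_free_ingroup",
                     "two_free_outgroup", "trapped", "baseline")

#' Default ensemble configuration grid
#'
#' Full factorial of 5 threshold fractions (0.05-0.25), 2 clustering
#' algorithms (Louvain, adaptive tree cut), 2 weightings (binary,
#' soft power) and 2 reference groups (baseline only, broad reference):
#' 40 configurations with deterministic ids and per-config seeds derived
#' from the grid seed.
#'
#' @param seed mandatory integer grid seed
#' @param thresholdFracs threshold fractions (default 0.05, 0.10, 0.15,
#'   0.20, 0.25)
#' @return data.frame of 40 configurations
#' @export
defaultConfigGrid <- function(seed,
                              thresholdFracs = c(0.05, 0.10, 0.15,
                                                 0.20, 0.25)) {
    if (missing(seed)) stop("seed is mandatory")
    grid <- expand.grid(threshold_frac = thresholdFracs,
                        clustering = c("louvain", "dynamic_tree_cut"),
                        weighting = c("binary", "soft_power"),
                        reference = c("baseline_only", "broad_reference"),
                        stringsAsFactors = FALSE)
    grid$config_id <- sprintf("cfg%02d", seq_len(nrow(grid)))
    grid$soft_power_beta <- NA_real_   # NA = auto
    grid$seed <- as.integer(seed) + seq_len(nrow(grid))
    grid[, c("config_id", "threshold_frac", "clustering", "weighting",
             "soft_power_beta", "reference", "seed")]
}

#' Read / write an ensemble configuration grid as YAML
#'
#' @param path YAML path
#' @return for \code{readConfigGrid}, the grid data.frame
#' @export
readConfigGrid <- function(path) {
    lst <- yaml::read_yaml(path)
    do.call(rbind, lapply(lst, function(cfg)
        data.frame(config_id = cfg$config_id,
                   threshold_frac = cfg$threshold_frac,
                   clustering = cfg$clustering,
                   weighting = cfg$weighting,
                   soft_power_beta = if (is.null(cfg$soft_power_beta))
                       NA_real_ else cfg$soft_power_beta,
                   reference = cfg$reference, seed = cfg$seed,
                   stringsAsFactors = FALSE)))
}

#' @rdname readConfigGrid
#' @param grid a configuration grid data.frame
#' @return for \code{writeConfigGrid}, invisibly the path
#' @export
writeConfigGrid <- function(grid, path) {
    yaml::write_yaml(lapply(seq_len(nrow(grid)),
                            function(i) as.list(grid[i, ])), path)
    invisible(path)
}

#' Soft-power weighted adjacency
#'
#' a_ij = |r_ij|^beta. With \code{beta = "auto"}, the smallest integer
#' beta in 1..20 whose weighted connectivity distribution reaches a
#' scale-free topology index of at least 0.8 is chosen; if none does,
#' beta falls back to 6 (with a message).
#'
#' @param r symmetric correlation matrix
#' @param beta positive power or "auto"
#' @return list(adjacency, beta)
#' @export
softPowerAdjacency <- function(r, beta = "auto") {
    absr <- abs(r)
    diag(absr) <- 0
    absr[is.na(absr)] <- 0
    if (identical(beta, "auto") || is.na(beta)) {
        beta <- NA_real_
        for (b in 1:20) {
            k <- rowSums(absr^b)
            sfi <- scaleFreeIndex(k)
            if (!is.na(sfi) && sfi >= 0.8) { beta <- b; break }
        }
        if (is.na(beta)) {
            message("auto soft-power search failed to reach 0.8; using beta = 6")
            beta <- 6
        }
    }
    stopifnot(beta > 0)
    list(adjacency = absr^beta, beta = beta)
}

## Adaptive branch cutting of an average-linkage dendrogram: choose the
## partition (k = 2..kMax) maximizing the mean silhouette width, then
## merge clusters smaller than minSize into the nearest cluster when
## their average dissimilarity to it is below the median dissimilarity,
## otherwise mark them unclustered (id 0).
adaptiveTreeCut <- function(d, minSize = 3) {
    dm <- as.matrix(d)
    n <- nrow(dm)
    hc <- hclust(as.dist(dm), method = "average")
    kMax <- max(2L, min(n - 1L, floor(n / minSize)))
    best <- NULL; bestSil <- -Inf
    for (k in 2:kMax) {
        labs <- cutree(hc, k = k)
        sil <- cluster::silhouette(labs, dmatrix = dm)
        ms <- mean(sil[, "sil_width"])
        if (ms > bestSil) { bestSil <- ms; best <- labs }
    }
    labs <- best
    medD <- median(dm[upper.tri(dm)])
    sizes <- table(labs)
    small <- as.integer(names(sizes)[sizes < minSize])
    for (cl in small) {
        members <- which(labs == cl)
        others <- unique(labs[!labs %in% c(small, 0)])
        for (m in members) {
            if (!length(others)) { labs[m] <- 0L; next }
            avg <- vapply(others, function(o)
                mean(dm[m, labs == o & seq_len(n) != m]), numeric(1))
            if (min(avg, na.rm = TRUE) < medD)
                labs[m] <- others[which.min(avg)]
            else labs[m] <- 0L
        }
    }
    # renumber 1..K keeping 0 for unclustered
    ids <- sort(unique(labs[labs != 0]))
    labs[labs != 0] <- match(labs[labs != 0], ids)
    setNames(as.integer(labs), rownames(dm))
}

#' Cluster regions under one ensemble configuration
#'
#' The correlation structure is computed on counts pooled over the
#' compared conditions plus the reference group (the partition must be
#' condition-agnostic since every subject needs a cluster score).
#' Louvain clustering runs on the thresholded binary graph (binary
#' weighting) or the soft-power weighted graph; the tree-cut path runs
#' average-linkage hierarchical clustering of 1 - |r| (or 1 - a under
#' soft power) with adaptive branch cutting and minimum cluster size 3.
#' Leftover regions get the pseudo-cluster id 0 and are excluded from
#' regression.
#'
#' @param ds an \linkS4class{ActivityDataset} (complete data)
#' @param config one row of a configuration grid
#' @param useConditions conditions whose subjects enter the pooled
#'   correlation
#' @return named integer vector region -> cluster id (0 = unclustered)
#' @export
clusterRegions <- function(ds, config, useConditions = NULL) {
    cnt <- fosCounts(ds)
    cond <- unname(conditions(ds))
    if (!is.null(useConditions)) {
        cnt <- cnt[, cond %in% useConditions, drop = FALSE]
    }
    if (nrow(cnt) < 3) stop("need >= 3 regions")
    r <- suppressWarnings(cor(t(cnt), use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0
    diag(r) <- 1
    soft <- config$weighting == "soft_power"
    if (soft) {
        sp <- softPowerAdjacency(r, if (is.na(config$soft_power_beta))
            "auto" else config$soft_power_beta)
        A <- sp$adjacency
    }
    if (config$clustering == "louvain") {
        if (soft) {
            labs <- louvainCommunities(A, seed = config$seed)
        } else {
            net <- thresholdNetwork(r, config$threshold_frac)
            labs <- louvainCommunities(net, seed = config$seed)
        }
        # enforce the minimum cluster size: tiny communities -> unclustered
        sizes <- table(labs)
        labs[labs %in% as.integer(names(sizes)[sizes < 3])] <- 0L
        ids <- sort(unique(labs[labs != 0]))
        labs[labs != 0] <- match(labs[labs != 0], ids)
        labs
    } else {
        D <- if (soft) 1 - A else 1 - abs(r)
        diag(D) <- 0
        adaptiveTreeCut(D, minSize = 3)
    }
}

#' Eigen-region scores per cluster
#'
#' Regions are z-scored across subjects; each cluster's first principal
#' component across subjects is its representative eigen region, with
#' the sign fixed so the score correlates positively with the cluster's
#' mean z-profile. Singleton clusters pass through the standardized
#' region values; zero-variance regions are dropped with a warning.
#' Cluster id 0 (unclustered) is skipped.
#'
#' @param ds an \linkS4class{ActivityDataset} (complete data)
#' @param clusters named integer vector region -> cluster id
#' @return subject x cluster score matrix (columns "ER<k>") with the
#'   per-cluster explained variance fraction as attribute
#'   \code{"explained"}
#' @export
eigenRegions <- function(ds, clusters) {
    cnt <- fosCounts(ds)
    if (anyNA(cnt)) stop("dataset has missing values; impute first")
    zerovar <- apply(cnt, 1, sd) == 0
    if (any(zerovar)) {
        warning("dropping zero-variance region(s): ",
                paste(rownames(cnt)[zerovar], collapse = ", "))
        cnt <- cnt[!zerovar, , drop = FALSE]
        clusters <- clusters[rownames(cnt)]
    }
    Z <- t(scale(t(cnt)))   # z-score each region across subjects
    ids <- sort(unique(clusters[clusters != 0]))
    scores <- matrix(NA_real_, ncol(cnt), length(ids),
                     dimnames = list(colnames(cnt), paste0("ER", ids)))
    expl <- numeric(length(ids))
    for (j in seq_along(ids)) {
        members <- names(clusters)[clusters == ids[j]]
        sub <- Z[members, , drop = FALSE]
        if (length(members) == 1) {
            scores[, j] <- sub[1, ]
            expl[j] <- 1
            next
        }
        pc <- prcomp(t(sub), center = FALSE, scale. = FALSE)
        s <- pc$x[, 1]
        if (cor(s, colMeans(sub)) < 0) s <- -s
        scores[, j] <- s
        expl[j] <- pc$sdev[1]^2 / sum(pc$sdev^2)
    }
    attr(scores, "explained") <- setNames(expl, colnames(scores))
    attr(scores, "clusterIds") <- ids
    scores
}

## Penalized log-likelihood of a 3-class multinomial logit (reference =
## baseline class) with a single predictor.
multinomPenLL <- function(beta, X, Y, lambda) {
    eta <- X %*% beta
    expEta <- exp(pmin(eta, 30))
    sum(Y * eta) - sum(log(1 + rowSums(expEta))) -
        lambda / 2 * sum(beta^2)
}

## Ridge-stabilized Newton fit; `free` marks which of the 2 x 2
## parameters (rows: intercept, slope; columns: contrasts) are estimated
## (the rest stay 0), so constrained fits for likelihood-ratio tests
## reuse the same routine.
multinomNewton <- function(X, Y, lambda = 0.1,
                           free = matrix(TRUE, 2, 2),
                           maxIter = 200, tol = 1e-8) {
    beta <- matrix(0, 2, 2)
    fv <- as.vector(free)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        eta <- X %*% beta
        expEta <- exp(pmin(eta, 30))
        P <- expEta / (1 + rowSums(expEta))
        grad <- crossprod(X, Y - P) - lambda * beta
        H <- matrix(0, 4, 4)
        for (a in 1:2) for (b in 1:2) {
            W <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
            H[(2 * a - 1):(2 * a), (2 * b - 1):(2 * b)] <-
                crossprod(X, X * W)
        }
        H <- H + lambda * diag(4)
        step <- rep(0, 4)
        sol <- tryCatch(solve(H[fv, fv, drop = FALSE],
                              as.vector(grad)[fv]),
                        error = function(e) NULL)
        if (is.null(sol)) break
        step[fv] <- sol
        beta <- beta + matrix(step, 2, 2)
        if (max(abs(step)) < tol) { converged <- TRUE; break }
    }
    list(beta = beta, H = H, converged = converged,
         ll = multinomPenLL(beta, X, Y, lambda))
}

## Fit the 3-class model and test each contrast slope. The default test
## is a penalized likelihood-ratio test (slope of the tested contrast
## fixed to 0 in the reduced fit, 1 df chi-square); Wald p-values from
## the penalized information are also returned, but under quasi-complete
## separation -- likely at these sample sizes -- the Wald statistic
## collapses (Hauck-Donner), so the LRT is what the classifier uses.
multinomLogitRidge <- function(x, y, reference, lambda = 0.1,
                               test = c("lrt", "wald")) {
    test <- match.arg(test)
    y <- as.character(y)
    classes <- c(reference, sort(setdiff(unique(y), reference)))
    stopifnot(length(classes) == 3)
    X <- cbind(1, x)
    Y <- outer(y, classes[-1], `==`) * 1
    full <- multinomNewton(X, Y, lambda)
    cov <- tryCatch(solve(full$H), error = function(e)
        matrix(NA_real_, 4, 4))
    se <- sqrt(diag(cov))[c(2, 4)]
    slopes <- full$beta[2, ]
    pWald <- 2 * pnorm(-abs(slopes / se))
    pLRT <- vapply(1:2, function(j) {
        fr <- matrix(TRUE, 2, 2); fr[2, j] <- FALSE
        red <- multinomNewton(X, Y, lambda, free = fr)
        pchisq(max(0, 2 * (full$ll - red$ll)), 1, lower.tail = FALSE)
    }, numeric(1))
    list(classes = classes[-1], coef = slopes, se = se,
         p = if (test == "lrt") pLRT else pWald,
         pWald = pWald, pLRT = pLRT, converged = full$converged)
}

#' Multinomial logistic test of eigen regions against a reference group
#'
#' One model per cluster: the cluster's eigen-region score (plus
#' intercept) predicts class membership among ingroup, outgroup and the
#' reference group (the model's baseline class). The fit is
#' maximum-likelihood Newton iteration with a ridge stabilizer (default
#' lambda = 0.1) against perfect separation. Each contrast slope is
#' tested, by default with a penalized likelihood-ratio test: the Wald
#' statistic degenerates under the quasi-complete separation these
#' sample sizes invite (Hauck-Donner), and a near-zero ridge leaves the
#' null contrast's LR inflated in the same regime, so the moderate
#' default keeps the test calibrated while leaving detectable effects
#' untouched. Wald p-values are still reported. P-values are
#' Bonferroni-corrected over clusters x 2 contrasts.
#'
#' @param scores subject x cluster eigen-region matrix
#' @param labels per-subject class in \{"ingroup", "outgroup",
#'   "reference"\}
#' @param alpha corrected significance cutoff (default 0.05)
#' @param test "lrt" (default) or "wald"
#' @param lambda ridge penalty of the multinomial fit (default 0.1)
#' @return data.frame(cluster, coef_ingroup, p_ingroup, coef_outgroup,
#'   p_outgroup, p_ingroup_adj, p_outgroup_adj, sig_ingroup,
#'   sig_outgroup, converged)
#' @export
multinomialTest <- function(scores, labels, alpha = 0.05,
                            test = c("lrt", "wald"), lambda = 0.1) {
    test <- match.arg(test)
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("ingroup", "outgroup", "reference")),
              length(labels) == nrow(scores))
    if (any(table(labels) < 3)) stop("need >= 3 subjects per class")
    rows <- lapply(seq_len(ncol(scores)), function(j) {
        fit <- multinomLogitRidge(scores[, j], labels, "reference",
                                  lambda = lambda, test = test)
        iIn <- match("ingroup", fit$classes)
        iOut <- match("outgroup", fit$classes)
        data.frame(cluster = colnames(scores)[j],
                   coef_ingroup = fit$coef[iIn], p_ingroup = fit$p[iIn],
                   coef_outgroup = fit$coef[iOut],
                   p_outgroup = fit$p[iOut],
                   converged = fit$converged, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    m <- 2 * nrow(out)
    out$p_ingroup_adj <- pmin(1, out$p_ingroup * m)
    out$p_outgroup_adj <- pmin(1, out$p_outgroup * m)
    out$sig_ingroup <- out$converged & !is.na(out$p_ingroup_adj) &
        out$p_ingroup_adj < alpha
    out$sig_outgroup <- out$converged & !is.na(out$p_outgroup_adj) &
        out$p_outgroup_adj < alpha
    out
}

#' Run the full ensemble and tally per-region occurrences
#'
#' For each configuration: cluster the regions, extract eigen-region
#' scores, test ingroup and outgroup against the configuration's
#' reference group, classify each cluster as significant for the
#' ingroup only, the outgroup only, both or none, and let every region
#' inherit its cluster's classification (unclustered regions count as
#' none). Counts are accumulated over all configurations.
#'
#' @param ds an \linkS4class{ActivityDataset} containing both HBT
#'   conditions and the reference conditions (missing values are
#'   imputed internally)
#' @param configs a configuration grid (see
#'   \code{\link{defaultConfigGrid}})
#' @param ingroup,outgroup the two compared condition labels
#' @return an \linkS4class{EnsembleTally}
#' @export
runEnsemble <- function(ds, configs, ingroup = "HBT_ingroup",
                        outgroup = "HBT_outgroup") {
    ds <- imputeConditionMean(ds)
    cond <- unname(conditions(ds))
    regions <- regionIds(ds)
    counts <- matrix(0L, length(regions), 4,
                     dimnames = list(regions, c("ingroup_only",
                                                "outgroup_only",
                                                "both", "none")))
    for (i in seq_len(nrow(configs))) {
        cfg <- configs[i, ]
        refConds <- if (cfg$reference == "baseline_only") "baseline"
                    else BROAD_REFERENCE
        refConds <- intersect(refConds, unique(cond))
        use <- c(ingroup, outgroup, refConds)
        sel <- cond %in% use
        sub <- ds[, sel]
        clusters <- clusterRegions(sub, cfg, useConditions = use)
        category <- setNames(rep("none", length(regions)), regions)
        if (any(clusters != 0)) {
            scores <- eigenRegions(sub, clusters)
            labels <- ifelse(conditions(sub) == ingroup, "ingroup",
                             ifelse(conditions(sub) == outgroup,
                                    "outgroup", "reference"))
            tst <- multinomialTest(scores, labels)
            clCat <- ifelse(tst$sig_ingroup & tst$sig_outgroup, "both",
                            ifelse(tst$sig_ingroup, "ingroup_only",
                                   ifelse(tst$sig_outgroup,
                                          "outgroup_only", "none")))
            ids <- attr(scores, "clusterIds")
            for (j in seq_along(ids)) {
                members <- names(clusters)[clusters == ids[j]]
                category[members] <- clCat[j]
            }
        }
        for (cc in colnames(counts))
            counts[, cc] <- counts[, cc] + (category == cc)
    }
    nCfg <- nrow(configs)
    tl <- S4Vectors::DataFrame(
        region = regions,
        n_ingroup_only = counts[, "ingroup_only"],
        n_outgroup_only = counts[, "outgroup_only"],
        n_both = counts[, "both"], n_none = counts[, "none"],
        ratio_ingroup_only = 100 * counts[, "ingroup_only"] / nCfg,
        ratio_outgroup_only = 100 * counts[, "outgroup_only"] / nCfg,
        ratio_both = 100 * counts[, "both"] / nCfg,
        ratio_none = 100 * counts[, "none"] / nCfg)
    new("EnsembleTally", tally = tl, nConfigs = as.integer(nCfg))
}

#' Write an ensemble tally as TSV
#' @param tally an \linkS4class{EnsembleTally}
#' @param path output path
#' @return invisibly, the path
#' @export
writeEnsembleTally <- function(tally, path) {
    df <- as.data.frame(tally@tally)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    message(sprintf("wrote tallies for %d regions to %s", nrow(df), path))
    invisible(path)
}
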