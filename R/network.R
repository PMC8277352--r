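## Co-activation network inference: pairwise Pearson correlation between
## region c-Fos counts, top-|r| thresholding, scale-free / small-world
## threshold diagnostics, centrality, hubs and Louvain communities.

#' Pairwise inter-region correlation matrix for one condition
#'
#' Pearson correlations between the c-Fos counts of all region pairs
#' over the subjects of one condition, using pairwise-complete
#' observations. Cells with fewer than 3 complete pairs are marked
#' invalid (NA) and excluded from any later ranking.
#'
#' @param ds an \linkS4class{ActivityDataset}
#' @param condition condition label (>= 3 subjects)
#' @return list with \code{r} (symmetric, unit diagonal) and \code{n}
#'   (pairwise complete-observation counts)
#' @export
correlationMatrix <- function(ds, condition) {
    cond <- unname(conditions(ds))
    sel <- cond == condition
    if (sum(sel) < 3) stop("need >= 3 subjects in condition ", condition)
    X <- t(fosCounts(ds)[, sel, drop = FALSE])   # subjects x regions
    r <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
    obs <- !is.na(X)
    nPair <- crossprod(obs)
    r[nPair < 3] <- NA
    diag(r) <- 1
    list(r = r, n = nPair, condition = condition)
}

#' Threshold a correlation matrix into a co-activation network
#'
#' Off-diagonal pairs are ranked by |r| descending and the top
#' \code{thresholdFrac} are retained as edges of an unweighted graph
#' (retained correlations are set to 1); the sign of each retained r is
#' kept as an edge attribute so negative co-activations remain visible.
#' Pairs tied with the cutoff value are all retained (the realized
#' fraction is reported in a message when it differs).
#'
#' @param rMatrix output of \code{\link{correlationMatrix}}, or a plain
#'   symmetric correlation matrix
#' @param thresholdFrac fraction of off-diagonal pairs to keep, in
#'   (0, 1] (default 0.10)
#' @param condition label stored on the network
#' @return a \linkS4class{CoactivationNetwork}
#' @export
thresholdNetwork <- function(rMatrix, thresholdFrac = 0.10,
                             condition = NULL) {
    if (is.list(rMatrix)) {
        if (is.null(condition)) condition <- rMatrix$condition
        nPair <- rMatrix$n
        r <- rMatrix$r
    } else {
        r <- rMatrix
        nPair <- matrix(NA_integer_, nrow(r), ncol(r))
    }
    if (is.null(condition)) condition <- ""
    if (thresholdFrac <= 0 || thresholdFrac > 1)
        stop("thresholdFrac must lie in (0, 1]")
    p <- nrow(r)
    ut <- upper.tri(r)
    vals <- abs(r[ut])
    valid <- !is.na(vals)
    nKeep <- round(thresholdFrac * sum(ut))
    nKeep <- min(nKeep, sum(valid))
    A <- matrix(0, p, p, dimnames = dimnames(r))
    if (nKeep > 0) {
        cutoff <- sort(vals[valid], decreasing = TRUE)[nKeep]
        keep <- ut & !is.na(r) & abs(r) >= cutoff
        A[keep] <- 1
        A <- A + t(A)
        realized <- sum(A) / 2
        if (realized != nKeep)
            message(sprintf("ties at cutoff: %d edges retained (target %d)",
                            realized, nKeep))
    }
    signs <- sign(r) * (A != 0)
    signs[is.na(signs)] <- 0
    new("CoactivationNetwork", rMatrix = r, pairwiseN = nPair * 1,
        thresholdFrac = thresholdFrac, adjacency = A, edgeSigns = signs,
        condition = as.character(condition))
}

networkGraph <- function(network) {
    igraph::graph_from_adjacency_matrix(network@adjacency,
                                        mode = "undirected")
}

#' Scale-free topology index
#'
#' Signed goodness of fit of the log-log degree distribution: node
#' degrees (or continuous connectivities) are grouped into up to
#' \code{nBins} equal-occupancy bins, the log10 per-bin probability
#' density p(k) (occupancy divided by bin width) is regressed on the log10
#' bin-mean degree, and the index is R-squared times the sign of the
#' negative slope, so decaying (scale-free-like) distributions score
#' positive. Needs at least 3 occupied bins; otherwise the index is
#' undefined (NA, with the reason as an attribute).
#'
#' @param x a \linkS4class{CoactivationNetwork} or a numeric vector of
#'   (possibly continuous) node connectivities
#' @param nBins target number of bins (default 10)
#' @return the index in [-1, 1], or NA with attribute \code{"reason"}
#' @export
scaleFreeIndex <- function(x, nBins = 10) {
    k <- if (is(x, "CoactivationNetwork")) rowSums(x@adjacency)
         else as.numeric(x)
    k <- k[k > 0]
    if (length(k) < 3)
        return(structure(NA_real_, reason = "fewer than 3 connected nodes"))
    breaks <- unique(quantile(k, probs = seq(0, 1, length.out = nBins + 1)))
    if (length(breaks) < 4)   # < 3 bins
        return(structure(NA_real_, reason = "fewer than 3 occupied bins"))
    bin <- cut(k, breaks, include.lowest = TRUE)
    kMean <- tapply(k, bin, mean)
    # probability density per bin: equal-occupancy bins make raw
    # proportions flat, so divide by the bin width
    width <- diff(breaks)
    width[width == 0] <- min(width[width > 0], 1)
    pk <- tabulate(bin, nbins = nlevels(bin)) / length(k) / width
    ok <- pk > 0 & !is.na(kMean) & kMean > 0
    if (sum(ok) < 3)
        return(structure(NA_real_, reason = "fewer than 3 occupied bins"))
    fit <- lm(log10(pk[ok]) ~ log10(kMean[ok]))
    r2 <- summary(fit)$r.squared
    slope <- coef(fit)[2]
    unname(r2 * sign(-slope))
}

#' Percent connectivity
#'
#' Percentage of nodes with at least one edge (non-isolated). Reported
#' separately from network density, which divides by all possible
#' pairs.
#'
#' @param network a \linkS4class{CoactivationNetwork}
#' @return percentage in [0, 100]
#' @export
pctConnectivity <- function(network) {
    deg <- rowSums(network@adjacency)
    100 * mean(deg >= 1)
}

#' Small-worldness and network density
#'
#' sigma = (C / C_rand) / (L / L_rand), with C the mean local clustering
#' coefficient and L the characteristic path length of the largest
#' connected component, normalized by the averages over \code{nRandom}
#' Erdos-Renyi graphs with matched node and edge counts (largest
#' component used when a random instance is disconnected). Density is
#' 2E / (N (N - 1)) over the whole network.
#'
#' @param network a \linkS4class{CoactivationNetwork} or igraph graph
#' @param nRandom number of random reference graphs (default 100)
#' @param seed mandatory integer seed
#' @return list(sigma, density, C, L, C_rand, L_rand)
#' @export
smallWorldness <- function(network, nRandom = 100, seed) {
    if (missing(seed)) stop("seed is mandatory")
    g <- if (is(network, "CoactivationNetwork")) networkGraph(network)
         else network
    N <- igraph::vcount(g); E <- igraph::ecount(g)
    comp <- igraph::components(g)
    if (max(comp$csize) < 4)
        stop("largest connected component must have >= 4 nodes")
    lcc <- igraph::induced_subgraph(
        g, which(comp$membership == which.max(comp$csize)))
    cl <- function(gg) {
        v <- igraph::transitivity(gg, type = "localaverage",
                                  isolates = "zero")
        if (is.nan(v)) 0 else v
    }
    pathLen <- function(gg) {
        cc <- igraph::components(gg)
        sub <- igraph::induced_subgraph(
            gg, which(cc$membership == which.max(cc$csize)))
        igraph::mean_distance(sub)
    }
    C <- cl(lcc); L <- pathLen(lcc)
    set.seed(seed)
    nR <- igraph::vcount(lcc); eR <- igraph::ecount(lcc)
    cr <- numeric(nRandom); lr <- numeric(nRandom)
    for (i in seq_len(nRandom)) {
        gr <- igraph::sample_gnm(nR, eR)
        cr[i] <- cl(gr)
        lr[i] <- pathLen(gr)    # largest-component convention
    }
    Cr <- mean(cr); Lr <- mean(lr)
    sigma <- if (Cr > 0 && Lr > 0) (C / Cr) / (L / Lr) else NA_real_
    list(sigma = sigma, density = 2 * E / (N * (N - 1)),
         C = C, L = L, C_rand = Cr, L_rand = Lr)
}

#' Sweep correlation-threshold cutoffs
#'
#' Applies every requested top-fraction cutoff to the correlation
#' matrix and records the scale-free topology index, percent
#' connectivity, small-worldness and density of each resulting network.
#' The recommended cutoff is the smallest fraction with a positive
#' (defined) scale-free index and percent connectivity at or above
#' \code{connectivityFloor}.
#'
#' @param rMatrix output of \code{\link{correlationMatrix}} or a plain
#'   correlation matrix
#' @param fracs threshold fractions in (0, 1] (sorted internally)
#' @param seed mandatory integer seed (random graphs of the
#'   small-worldness normalization)
#' @param nRandom random reference graphs per cutoff (default 50)
#' @param connectivityFloor minimum percent connectivity for the
#'   recommendation (default 50)
#' @return data.frame(threshold_frac, scale_free_index,
#'   pct_connectivity, small_worldness, density) sorted ascending, with
#'   the recommended cutoff in attribute \code{"recommended"} (NA when
#'   no cutoff qualifies)
#' @export
sweepThresholds <- function(rMatrix, fracs = seq(0.05, 0.5, by = 0.05),
                            seed, nRandom = 50, connectivityFloor = 50) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(all(fracs > 0), all(fracs <= 1))
    fracs <- sort(unique(fracs))
    rows <- lapply(seq_along(fracs), function(i) {
        net <- thresholdNetwork(rMatrix, fracs[i])
        sw <- tryCatch(smallWorldness(net, nRandom = nRandom,
                                      seed = seed + i),
                       error = function(e) list(sigma = NA_real_,
                                                density = NA_real_))
        data.frame(threshold_frac = fracs[i],
                   scale_free_index = as.numeric(scaleFreeIndex(net)),
                   pct_connectivity = pctConnectivity(net),
                   small_worldness = sw$sigma,
                   density = if (is.na(sw$density))
                       sum(net@adjacency) / (nrow(net@adjacency) *
                                             (nrow(net@adjacency) - 1))
                   else sw$density)
    })
    out <- do.call(rbind, rows)
    ok <- !is.na(out$scale_free_index) & out$scale_free_index > 0 &
        out$pct_connectivity >= connectivityFloor
    attr(out, "recommended") <- if (any(ok)) min(out$threshold_frac[ok])
                                else NA_real_
    out
}

#' Degree and betweenness centrality
#'
#' Degree is the adjacency row sum; betweenness is unnormalized
#' shortest-path betweenness on the binary graph, with pairs split
#' equally among multiple shortest paths. Ranks are 1 = highest, ties
#' sharing the smallest rank.
#'
#' @param network a \linkS4class{CoactivationNetwork}
#' @return data.frame(region, degree, betweenness, degree_rank,
#'   betweenness_rank)
#' @export
centrality <- function(network) {
    g <- networkGraph(network)
    deg <- rowSums(network@adjacency)
    btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
    data.frame(region = rownames(network@adjacency),
               degree = unname(deg), betweenness = unname(btw),
               degree_rank = rank(-deg, ties.method = "min"),
               betweenness_rank = rank(-btw, ties.method = "min"),
               stringsAsFactors = FALSE)
}

#' Identify central hubs
#'
#' Hubs are the regions in the top \code{topFrac} of both degree and
#' betweenness (intersection of the two top sets). Regions tied with
#' the boundary value are included.
#'
#' @param centralityTable output of \code{\link{centrality}}
#' @param topFrac top fraction per metric (default 0.20)
#' @return character vector of hub region ids
#' @export
identifyHubs <- function(centralityTable, topFrac = 0.20) {
    N <- nrow(centralityTable)
    if (N < 5) stop("need >= 5 regions")
    m <- ceiling(topFrac * N)
    topBy <- function(v) {
        cutoff <- sort(v, decreasing = TRUE)[m]
        centralityTable$region[v >= cutoff]
    }
    intersect(topBy(centralityTable$degree),
              topBy(centralityTable$betweenness))
}

#' Louvain community detection
#'
#' Modularity-maximizing partition of the thresholded (or weighted)
#' graph; deterministic given the seed. An empty graph returns every
#' node as its own community.
#'
#' @param x a \linkS4class{CoactivationNetwork} or a symmetric
#'   non-negative weight matrix
#' @param seed mandatory integer seed
#' @return named integer vector region -> community id
#' @export
louvainCommunities <- function(x, seed) {
    if (missing(seed)) stop("seed is mandatory")
    if (is(x, "CoactivationNetwork")) {
        A <- x@adjacency
    } else {
        A <- as.matrix(x)
        diag(A) <- 0
    }
    if (sum(A) == 0)
        return(setNames(seq_len(nrow(A)), rownames(A)))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    set.seed(seed)
    cm <- igraph::cluster_louvain(g)
    setNames(as.integer(igraph::membership(cm)), rownames(A))
}

#' Export a network as GraphML and an edge-list TSV
#'
#' @param network a \linkS4class{CoactivationNetwork}
#' @param graphmlPath,edgeTsvPath output paths
#' @return invisibly, the two paths
#' @export
writeNetwork <- function(network, graphmlPath, edgeTsvPath) {
    g <- networkGraph(network)
    igraph::write_graph(g, graphmlPath, format = "graphml")
    idx <- which(upper.tri(network@adjacency) & network@adjacency == 1,
                 arr.ind = TRUE)
    df <- data.frame(source = rownames(network@adjacency)[idx[, 1]],
                     target = colnames(network@adjacency)[idx[, 2]],
                     r = network@rMatrix[idx],
                     sign = network@edgeSigns[idx])
    utils::write.table(df, edgeTsvPath, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    message(sprintf("wrote %d edges to %s", nrow(df), edgeTsvPath))
    invisible(c(graphmlPath, edgeTsvPath))
}
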