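# Shared fixtures and independent oracles used across test files.

# small activity dataset built by hand
toyDataset <- function(counts = NULL, conditions = NULL) {
    if (is.null(counts))
        counts <- matrix(c(2, 3, 5,
                           4, 6, 8,
                           1, 1, 1,
                           10, 20, 30), nrow = 4, byrow = TRUE,
                         dimnames = list(paste0("R", 1:4),
                                         paste0("s", 1:3)))
    if (is.null(conditions))
        conditions <- c("HBT_ingroup", "HBT_ingroup", "baseline")
    ri <- data.frame(region_id = rownames(counts),
                     full_name = paste("region", rownames(counts)),
                     category = "other", stringsAsFactors = FALSE)
    ActivityDataset(counts, ri, conditions)
}

socialConditions <- c("HBT_ingroup", "HBT_outgroup", "brief_ingroup",
                      "brief_outgroup", "two_free_ingroup",
                      "two_free_outgroup")

# brute-force betweenness: enumerate all shortest paths between every
# node pair and split each pair's unit weight equally among them
bruteBetweenness <- function(adj) {
    n <- nrow(adj)
    btw <- numeric(n)
    allPaths <- function(s, t) {
        # BFS distances from s
        dist <- rep(Inf, n); dist[s] <- 0
        queue <- s
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            for (w in which(adj[v, ] == 1))
                if (dist[w] > dist[v] + 1) {
                    dist[w] <- dist[v] + 1
                    queue <- c(queue, w)
                }
        }
        if (!is.finite(dist[t])) return(list())
        # enumerate shortest paths recursively backwards from t
        rec <- function(v) {
            if (v == s) return(list(s))
            preds <- which(adj[v, ] == 1 & dist == dist[v] - 1)
            out <- list()
            for (p in preds)
                for (pp in rec(p))
                    out[[length(out) + 1]] <- c(pp, v)
            out
        }
        rec(t)
    }
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
        paths <- allPaths(s, t)
        if (!length(paths)) next
        for (p in paths) {
            inner <- setdiff(p, c(s, t))
            btw[inner] <- btw[inner] + 1 / length(paths)
        }
    }
    btw
}

# exact Wilcoxon signed-rank p by enumerating all 2^n sign assignments
enumWilcoxonP <- function(d, alternative = "two.sided") {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n))
    Wnull <- as.matrix(signs) %*% r
    switch(alternative,
           greater = mean(Wnull >= W),
           less = mean(Wnull <= W),
           two.sided = {
               mu <- n * (n + 1) / 4
               min(1, 2 * min(mean(Wnull >= W), mean(Wnull <= W)))
           })
}

# adjusted Rand index between two labelings
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    nij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    nn <- choose(sum(tab), 2)
    exp_ <- ai * bj / nn
    (nij - exp_) / ((ai + bj) / 2 - exp_)
}

# counts CSV fixture on disk; returns the two paths
writeToyCsv <- function(dir = tempdir()) {
    counts <- file.path(dir, "counts.csv")
    regions <- file.path(dir, "regions.csv")
    writeLines(c("subject_id,condition,R1,R2,R3,R4",
                 "s1,HBT_ingroup,2,4,1,10",
                 "s2,HBT_ingroup,3,6,1,20",
                 "s3,baseline,5,8,1,30"), counts)
    writeLines(c("region_id,full_name,category,ap_mm",
                 "R1,region one,frontal,3.2",
                 "R2,region two,striatal,1.2",
                 "R3,region three,other,0",
                 "R4,region four,insular,2.8"), regions)
    c(counts = counts, regions = regions)
}
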