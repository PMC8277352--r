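test_that("correlation matrix is symmetric with pairwise-n annotation", {
    set.seed(41)
    cnt <- matrix(rexp(5 * 8, 1 / 20), nrow = 5,
                  dimnames = list(paste0("R", 1:5), paste0("s", 1:8)))
    cnt[2, ] <- cnt[1, ]            # duplicated region
    cnt[3, 1:6] <- NA               # only 2 complete pairs with others
    ds <- toyDataset(cnt, rep("HBT_ingroup", 8))
    cm <- correlationMatrix(ds, "HBT_ingroup")
    expect_equal(cm$r, t(cm$r))
    expect_equal(cm$r[1, 2], 1)
    expect_true(all(is.na(cm$r[3, -3])))   # n < 3 marked invalid
    expect_equal(cm$n[1, 2], 8)
    expect_error(correlationMatrix(ds, "baseline"), "3 subjects")
})

test_that("independent regions stay below the small-sample noise bound", {
    rs <- vapply(1:10, function(s) {
        ds <- simulateActivity(activitySpec(
            nPerCondition = c(HBT_ingroup = 8L), nRegions = 20,
            moduleLoading = 0, missingRate = 0, seed = s))
        cm <- correlationMatrix(ds, "HBT_ingroup")
        mean(abs(cm$r[upper.tri(cm$r)]))
    }, numeric(1))
    expect_lt(mean(rs), 0.45)
})

test_that("planted modules give higher within- than between-module correlation", {
    hits <- 0
    for (s in 1:20) {
        ds <- simulateActivity(activitySpec(
            nPerCondition = c(HBT_ingroup = 10L), nRegions = 12,
            nModules = 3, moduleLoading = 0.8, missingRate = 0, seed = s))
        cm <- correlationMatrix(ds, "HBT_ingroup")
        mods <- S4Vectors::metadata(ds)$groundTruth$modules
        same <- outer(mods, mods, `==`) & upper.tri(cm$r)
        diff <- !outer(mods, mods, `==`) & upper.tri(cm$r)
        hits <- hits + (mean(cm$r[same]) > mean(cm$r[diff]))
    }
    expect_gte(hits / 20, 0.95)
})

test_that("thresholding keeps the top |r| fraction with signs and ties", {
    r <- diag(4)
    r[1, 2] <- r[2, 1] <- -0.9
    r[3, 4] <- r[4, 3] <- 0.5
    r[1, 3] <- r[3, 1] <- 0.2
    r[1, 4] <- r[4, 1] <- 0.1
    r[2, 3] <- r[3, 2] <- 0.15
    r[2, 4] <- r[4, 2] <- 0.05
    dimnames(r) <- list(paste0("R", 1:4), paste0("R", 1:4))
    # keep 1 of 6 edges: the dominant |r| = 0.9 with its negative sign
    net <- thresholdNetwork(r, 1 / 6)
    expect_equal(sum(net@adjacency) / 2, 1)
    expect_equal(net@adjacency[1, 2], 1)
    expect_equal(net@edgeSigns[1, 2], -1)
    # threshold 1 -> complete graph
    netC <- thresholdNetwork(r, 1)
    expect_true(all(netC@adjacency[upper.tri(netC@adjacency)] == 1))
    expect_equal(diag(netC@adjacency), rep(0, 4), ignore_attr = TRUE)
    # ties at the cutoff are all retained
    rt <- diag(4); dimnames(rt) <- dimnames(r)
    rt[1, 2] <- rt[2, 1] <- 0.8
    rt[3, 4] <- rt[4, 3] <- 0.8
    rt[1, 3] <- rt[3, 1] <- 0.1
    netT <- suppressMessages(thresholdNetwork(rt, 1 / 6))
    expect_equal(sum(netT@adjacency) / 2, 2)
    expect_error(thresholdNetwork(r, 0), "0, 1")
})

test_that("scale-free index separates decaying from peaked degree distributions", {
    # k-regular graph: single occupied bin -> undefined
    ring <- igraph::as_adjacency_matrix(
        igraph::make_ring(12), sparse = FALSE)
    sfiRing <- scaleFreeIndex(rowSums(ring))
    expect_true(is.na(sfiRing))
    expect_match(attr(sfiRing, "reason"), "bins|nodes")
    # preferential attachment: positive index in most seeds
    posHits <- negHits <- 0
    for (s in 1:10) {
        set.seed(s)
        gPA <- igraph::sample_pa(200, directed = FALSE)
        sfiPA <- scaleFreeIndex(igraph::degree(gPA))
        posHits <- posHits + (!is.na(sfiPA) && sfiPA > 0.5)
        gER <- igraph::sample_gnp(200, 0.5)
        sfiER <- scaleFreeIndex(igraph::degree(gER))
        # a dense binomial degree distribution never looks scale-free:
        # the signed index stays near zero (its sign is unstable around
        # the symmetric peak, so only its magnitude is diagnostic)
        negHits <- negHits + (!is.na(sfiER) && sfiER < 0.5)
    }
    expect_gte(posHits, 9)
    expect_gte(negHits, 9)
})

test_that("percent connectivity counts non-isolated nodes", {
    mk <- function(adj) new("CoactivationNetwork",
                            rMatrix = diag(nrow(adj)) * 0 + adj,
                            pairwiseN = adj * 0, thresholdFrac = 0.5,
                            adjacency = adj, edgeSigns = sign(adj),
                            condition = "x")
    full <- matrix(1, 6, 6) - diag(6)
    expect_equal(pctConnectivity(mk(full)), 100)
    expect_equal(pctConnectivity(mk(matrix(0, 6, 6))), 0)
    # star over 5 of 10 nodes
    adj <- matrix(0, 10, 10)
    adj[1, 2:5] <- adj[2:5, 1] <- 1
    expect_equal(pctConnectivity(mk(adj)), 50)
})

test_that("small-worldness matches closed forms and the rewiring property", {
    # complete graph: C = 1, density = 1, sigma ~ 1
    full <- matrix(1, 8, 8) - diag(8)
    dimnames(full) <- list(paste0("R", 1:8), paste0("R", 1:8))
    netF <- thresholdNetwork(full * 0.9 + diag(8) * 0.1, 1)
    sw <- smallWorldness(netF, nRandom = 10, seed = 1)
    expect_equal(sw$C, 1)
    expect_equal(sw$density, 1)
    expect_equal(sw$sigma, 1, tolerance = 1e-8)
    # density closed form: N = 10, E = 9 -> 0.2
    g <- igraph::make_star(10, mode = "undirected")
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    dimnames(adj) <- list(paste0("R", 1:10), paste0("R", 1:10))
    netS <- new("CoactivationNetwork", rMatrix = adj, pairwiseN = adj * 0,
                thresholdFrac = 0.2, adjacency = adj,
                edgeSigns = sign(adj), condition = "x")
    expect_equal(smallWorldness(netS, nRandom = 5, seed = 2)$density,
                 0.2)
    # Watts-Strogatz: rewiring a ring lattice shortens paths while
    # clustering persists, so sigma increases with rewiring probability
    mono <- 0
    for (s in 1:10) {
        sig <- vapply(c(0, 0.05, 0.10), function(pr) {
            set.seed(s * 100 + round(pr * 100))
            gws <- igraph::sample_smallworld(1, 50, 2, pr)
            gws <- igraph::simplify(gws)
            smallWorldness(gws, nRandom = 20, seed = s)$sigma
        }, numeric(1))
        mono <- mono + (sig[2] > sig[1] && sig[3] > sig[1])
    }
    expect_gte(mono, 8)
})

test_that("threshold sweep orders cutoffs and recommends one on modular data", {
    ds <- simulateActivity(activitySpec(
        nPerCondition = c(HBT_ingroup = 10L), nRegions = 30,
        nModules = 5, moduleLoading = 0.8, missingRate = 0, seed = 44))
    cm <- correlationMatrix(ds, "HBT_ingroup")
    sw <- sweepThresholds(cm, fracs = c(0.3, 0.05, 0.15), seed = 9,
                          nRandom = 10)
    expect_equal(sw$threshold_frac, c(0.05, 0.15, 0.3))
    # single frac -> single row
    sw1 <- sweepThresholds(cm, fracs = 0.1, seed = 9, nRandom = 10)
    expect_equal(nrow(sw1), 1L)
    # planted modular matrices usually admit a recommended cutoff <= 0.2
    recs <- vapply(1:10, function(s) {
        dss <- simulateActivity(activitySpec(
            nPerCondition = c(HBT_ingroup = 10L), nRegions = 30,
            nModules = 5, moduleLoading = 0.8, missingRate = 0, seed = s))
        cms <- correlationMatrix(dss, "HBT_ingroup")
        sws <- sweepThresholds(cms, fracs = seq(0.05, 0.3, 0.05),
                               seed = s, nRandom = 10)
        attr(sws, "recommended")
    }, numeric(1))
    expect_gte(mean(!is.na(recs) & recs <= 0.2), 0.8)
})

test_that("betweenness matches closed forms and the brute-force oracle", {
    # star with 4 leaves: center C(4,2) = 6, leaves 0
    adj <- matrix(0, 5, 5)
    adj[1, 2:5] <- adj[2:5, 1] <- 1
    dimnames(adj) <- list(paste0("R", 1:5), paste0("R", 1:5))
    net <- new("CoactivationNetwork", rMatrix = adj, pairwiseN = adj * 0,
               thresholdFrac = 0.4, adjacency = adj,
               edgeSigns = sign(adj), condition = "x")
    ct <- centrality(net)
    expect_equal(ct$betweenness, c(6, 0, 0, 0, 0))
    expect_equal(sum(ct$degree), 2 * 4)
    # complete graph: all betweenness 0
    full <- matrix(1, 6, 6) - diag(6)
    dimnames(full) <- list(paste0("R", 1:6), paste0("R", 1:6))
    netF <- new("CoactivationNetwork", rMatrix = full, pairwiseN = full * 0,
                thresholdFrac = 1, adjacency = full,
                edgeSigns = sign(full), condition = "x")
    expect_true(all(centrality(netF)$betweenness == 0))
    # random graphs up to 10 nodes vs exhaustive shortest-path oracle
    set.seed(45)
    for (i in 1:12) {
        n <- sample(4:10, 1)
        adj <- matrix(rbinom(n * n, 1, 0.4), n, n)
        adj[lower.tri(adj, diag = TRUE)] <- 0
        adj <- adj + t(adj)
        dimnames(adj) <- list(paste0("R", 1:n), paste0("R", 1:n))
        netR <- new("CoactivationNetwork", rMatrix = adj,
                    pairwiseN = adj * 0, thresholdFrac = 0.5,
                    adjacency = adj, edgeSigns = sign(adj),
                    condition = "x")
        expect_equal(centrality(netR)$betweenness, bruteBetweenness(adj),
                     tolerance = 1e-10)
        expect_equal(sum(centrality(netR)$degree), sum(adj))
    }
})

test_that("hub identification intersects the top degree and betweenness sets", {
    # node 1 dominant in both among 20 nodes: a hub
    adj <- matrix(0, 20, 20)
    adj[1, 2:15] <- adj[2:15, 1] <- 1
    adj[16, 17] <- adj[17, 16] <- 1
    dimnames(adj) <- list(paste0("R", 1:20), paste0("R", 1:20))
    net <- new("CoactivationNetwork", rMatrix = adj, pairwiseN = adj * 0,
               thresholdFrac = 0.1, adjacency = adj,
               edgeSigns = sign(adj), condition = "x")
    hubs <- identifyHubs(centrality(net))
    expect_true("R1" %in% hubs)
    # disjoint top sets give an empty hub set
    ct <- data.frame(region = paste0("R", 1:10),
                     degree = c(10:6, rep(1, 5)),
                     betweenness = c(rep(0, 5), 10:6))
    expect_length(identifyHubs(ct), 0)
    expect_error(identifyHubs(ct[1:3, ]), "5 regions")
    # planted connector between two hubs-and-spokes modules
    hubHits <- 0
    for (s in 1:10) {
        n <- 21
        adj <- matrix(0, n, n)
        adj[2, 3:11] <- adj[3:11, 2] <- 1       # hub A
        adj[12, 13:21] <- adj[13:21, 12] <- 1   # hub B
        adj[1, 2] <- adj[2, 1] <- 1             # connector
        adj[1, 12] <- adj[12, 1] <- 1
        set.seed(s)
        extra <- sample(3:11, 2)
        adj[1, extra] <- adj[extra, 1] <- 1
        dimnames(adj) <- list(paste0("R", 1:n), paste0("R", 1:n))
        netP <- new("CoactivationNetwork", rMatrix = adj,
                    pairwiseN = adj * 0, thresholdFrac = 0.1,
                    adjacency = adj, edgeSigns = sign(adj),
                    condition = "x")
        hubHits <- hubHits + ("R1" %in% identifyHubs(centrality(netP)))
    }
    expect_gte(hubHits, 9)
})

test_that("Louvain communities recover planted structure deterministically", {
    # two disconnected cliques
    adj <- matrix(0, 8, 8)
    adj[1:4, 1:4] <- 1; adj[5:8, 5:8] <- 1; diag(adj) <- 0
    dimnames(adj) <- list(paste0("R", 1:8), paste0("R", 1:8))
    net <- new("CoactivationNetwork", rMatrix = adj, pairwiseN = adj * 0,
               thresholdFrac = 0.4, adjacency = adj,
               edgeSigns = sign(adj), condition = "x")
    cm <- louvainCommunities(net, seed = 3)
    expect_equal(length(unique(cm)), 2L)
    expect_equal(length(unique(cm[1:4])), 1L)
    expect_equal(length(unique(cm[5:8])), 1L)
    expect_identical(cm, louvainCommunities(net, seed = 3))
    # empty graph: every node its own community
    e <- matrix(0, 4, 4, dimnames = list(paste0("R", 1:4),
                                         paste0("R", 1:4)))
    netE <- new("CoactivationNetwork", rMatrix = e, pairwiseN = e,
                thresholdFrac = 0.5, adjacency = e, edgeSigns = e,
                condition = "x")
    expect_equal(length(unique(louvainCommunities(netE, seed = 1))), 4L)
    # planted 3-module synthetic matrix: ARI > 0.8 in most seeds
    ariHits <- 0
    for (s in 1:10) {
        ds <- simulateActivity(activitySpec(
            nPerCondition = c(HBT_ingroup = 12L), nRegions = 18,
            nModules = 3, moduleLoading = 0.85, missingRate = 0,
            seed = s))
        cmx <- correlationMatrix(ds, "HBT_ingroup")
        netM <- thresholdNetwork(cmx, 0.2)
        labs <- louvainCommunities(netM, seed = s)
        truth <- S4Vectors::metadata(ds)$groundTruth$modules
        ariHits <- ariHits + (adjustedRand(labs, truth) > 0.8)
    }
    expect_gte(ariHits, 9)
})
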