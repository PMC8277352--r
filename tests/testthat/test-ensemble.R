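test_that("the default grid is the 40-configuration full factorial", {
    grid <- defaultConfigGrid(seed = 1)
    expect_equal(nrow(grid), 40L)
    expect_false(anyDuplicated(grid$config_id) > 0)
    expect_equal(sort(unique(grid$threshold_frac)),
                 c(0.05, 0.10, 0.15, 0.20, 0.25))
    expect_setequal(unique(grid$clustering),
                    c("louvain", "dynamic_tree_cut"))
    expect_setequal(unique(grid$weighting), c("binary", "soft_power"))
    expect_setequal(unique(grid$reference),
                    c("baseline_only", "broad_reference"))
    expect_identical(grid, defaultConfigGrid(seed = 1))
    # YAML round-trip
    f <- tempfile(fileext = ".yaml")
    writeConfigGrid(grid, f)
    back <- readConfigGrid(f)
    expect_equal(back$threshold_frac, grid$threshold_frac)
    expect_equal(back$config_id, grid$config_id)
})

test_that("soft power adjacency follows |r|^beta with a terminating auto search", {
    r <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
    expect_equal(softPowerAdjacency(r, 1)$adjacency[1, 2], 0.5)
    rpm <- matrix(c(1, -1, -1, 1), 2, 2)
    expect_equal(softPowerAdjacency(rpm, 7)$adjacency[1, 2], 1)
    # modular matrix: auto beta terminates; contrast is preserved
    ds <- simulateActivity(activitySpec(
        nPerCondition = c(HBT_ingroup = 10L), nRegions = 30,
        nModules = 5, moduleLoading = 0.8, missingRate = 0, seed = 51))
    r <- correlationMatrix(ds, "HBT_ingroup")$r
    hits <- 0
    for (s in 1:10) {
        dss <- simulateActivity(activitySpec(
            nPerCondition = c(HBT_ingroup = 10L), nRegions = 30,
            nModules = 5, moduleLoading = 0.8, missingRate = 0, seed = s))
        rs <- correlationMatrix(dss, "HBT_ingroup")$r
        sp <- suppressMessages(softPowerAdjacency(rs, "auto"))
        expect_true(sp$beta >= 1 && sp$beta <= 20)
        mods <- S4Vectors::metadata(dss)$groundTruth$modules
        same <- outer(mods, mods, `==`) & upper.tri(rs)
        diff <- !outer(mods, mods, `==`) & upper.tri(rs)
        hits <- hits + (mean(sp$adjacency[same]) >
                        mean(sp$adjacency[diff]))
    }
    expect_gte(hits, 10 * 0.95)
})

test_that("both clusterings recover block structure", {
    # two disconnected clique blocks: identical 2-cluster output
    cnt <- rbind(matrix(rep(rnorm(12), each = 4), 4, 12) +
                     matrix(rnorm(48, 0, 0.01), 4, 12),
                 matrix(rep(rnorm(12), each = 4), 4, 12) +
                     matrix(rnorm(48, 0, 0.01), 4, 12))
    rownames(cnt) <- paste0("R", 1:8); colnames(cnt) <- paste0("s", 1:12)
    ds <- toyDataset(abs(cnt) + 1, rep("HBT_ingroup", 12))
    cfgL <- data.frame(threshold_frac = 12 / 28, clustering = "louvain",
                       weighting = "binary", soft_power_beta = NA,
                       reference = "baseline_only", seed = 7)
    cfgT <- cfgL; cfgT$clustering <- "dynamic_tree_cut"
    labsL <- clusterRegions(ds, cfgL)
    labsT <- clusterRegions(ds, cfgT)
    for (labs in list(labsL, labsT)) {
        expect_equal(length(unique(labs[1:4])), 1L)
        expect_equal(length(unique(labs[5:8])), 1L)
        expect_equal(length(setdiff(unique(labs), 0L)), 2L)
    }
    # determinism
    expect_identical(labsT, clusterRegions(ds, cfgT))
    # planted 3-module recovery under both clusterings
    for (meth in c("louvain", "dynamic_tree_cut")) {
        hits <- 0
        for (s in 1:10) {
            dss <- simulateActivity(activitySpec(
                nPerCondition = c(HBT_ingroup = 12L), nRegions = 18,
                nModules = 3, moduleLoading = 0.85, missingRate = 0,
                seed = s))
            cfg <- cfgL; cfg$clustering <- meth; cfg$seed <- s
            cfg$threshold_frac <- 0.3   # ~ within-module pair fraction
            labs <- clusterRegions(dss, cfg)
            truth <- S4Vectors::metadata(dss)$groundTruth$modules
            keep <- labs != 0
            hits <- hits + (adjustedRand(labs[keep], truth[keep]) > 0.7)
        }
        expect_gte(hits, 8)
    }
})

test_that("eigen regions maximize explained variance with fixed sign", {
    set.seed(52)
    cnt <- matrix(rexp(5 * 12, 1 / 20), 5, 12,
                  dimnames = list(paste0("R", 1:5), paste0("s", 1:12)))
    ds <- toyDataset(cnt, rep("HBT_ingroup", 12))
    # singleton cluster: scores are the z-scored region values
    clusters <- setNames(c(1L, 2L, 2L, 2L, 2L), rownames(cnt))
    sc <- eigenRegions(ds, clusters)
    z1 <- as.numeric(scale(cnt[1, ]))
    expect_equal(unname(sc[, "ER1"]), z1, tolerance = 1e-10)
    # two perfectly correlated regions: rank-1, 100% explained
    cnt2 <- rbind(cnt[2, ], cnt[2, ] * 2 + 5)
    rownames(cnt2) <- c("A", "B"); colnames(cnt2) <- paste0("s", 1:12)
    ds2 <- toyDataset(cnt2, rep("HBT_ingroup", 12))
    sc2 <- eigenRegions(ds2, setNames(c(1L, 1L), c("A", "B")))
    expect_equal(attr(sc2, "explained")[["ER1"]], 1, tolerance = 1e-10)
    expect_gt(cor(sc2[, 1], cnt2[1, ]), 0.999)
    # variance-maximization vs 1-degree grid oracle in the 2-region case
    cnt3 <- cnt[2:3, ]; rownames(cnt3) <- c("A", "B")
    ds3 <- toyDataset(cnt3, rep("HBT_ingroup", 12))
    sc3 <- eigenRegions(ds3, setNames(c(1L, 1L), c("A", "B")))
    Z <- scale(t(cnt3))
    best <- max(vapply(seq(0, 180, by = 1), function(deg) {
        v <- c(cos(deg * pi / 180), sin(deg * pi / 180))
        var(Z %*% v)
    }, numeric(1)))
    expect_gte(var(sc3[, 1]) + 1e-8, best - 0.01 * best)
    # zero-variance region is dropped with a warning
    cnt4 <- cnt; cnt4[4, ] <- 7
    ds4 <- toyDataset(cnt4, rep("HBT_ingroup", 12))
    expect_warning(eigenRegions(ds4, clusters), "zero-variance")
})

test_that("multinomial contrast test is calibrated and detects planted shifts", {
    set.seed(53)
    # null calibration of the uncorrected per-contrast p
    nSim <- 1000
    rej <- 0
    for (i in seq_len(nSim)) {
        x <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "ER1"))
        labels <- rep(c("ingroup", "outgroup", "reference"),
                      c(15, 15, 20))
        tst <- multinomialTest(x, labels)
        rej <- rej + (tst$p_ingroup < 0.05)
    }
    rate <- rej / nSim
    expect_gte(rate, 0.03)
    expect_lte(rate, 0.07)
    # a +3 SD ingroup-only shift is detected, outgroup is not
    hits <- 0
    for (s in 1:40) {
        set.seed(s + 200)
        x <- matrix(c(rnorm(8, 3), rnorm(8), rnorm(10)), ncol = 1,
                    dimnames = list(NULL, "ER1"))
        labels <- rep(c("ingroup", "outgroup", "reference"), c(8, 8, 10))
        tst <- multinomialTest(x, labels)
        hits <- hits + (tst$p_ingroup < 0.05 / 2 &&
                        tst$p_outgroup > 0.05 / 2)
    }
    expect_gte(hits / 40, 0.95)
    # identical predictor columns give identical p-values
    x2 <- matrix(rnorm(26), 26, 2, dimnames = list(NULL, c("a", "b")))
    x2[, 2] <- x2[, 1]
    labels <- rep(c("ingroup", "outgroup", "reference"), c(8, 8, 10))
    tst2 <- multinomialTest(x2, labels)
    expect_equal(tst2$p_ingroup[1], tst2$p_ingroup[2], tolerance = 1e-10)
    expect_error(multinomialTest(x2[1:5, , drop = FALSE],
                                 labels[c(1, 2, 9, 10, 17)]),
                 "3 subjects")
})

test_that("tally arithmetic and conservation hold", {
    # a region significant for the ingroup in 34 of 40 configs -> 85%
    tl <- S4Vectors::DataFrame(region = "NacSh", n_ingroup_only = 34L,
                               n_outgroup_only = 2L, n_both = 1L,
                               n_none = 3L,
                               ratio_ingroup_only = 100 * 34 / 40,
                               ratio_outgroup_only = 5,
                               ratio_both = 2.5, ratio_none = 7.5)
    tal <- new("EnsembleTally", tally = tl, nConfigs = 40L)
    expect_equal(tal@tally$ratio_ingroup_only, 85)
    # counts that do not sum to nConfigs are rejected by the validity
    tl$n_none <- 10L
    expect_error(new("EnsembleTally", tally = tl, nConfigs = 40L),
                 "sum")
})

test_that("the ensemble is null-safe, order-invariant and recovers a planted region", {
    grid <- defaultConfigGrid(seed = 60)
    # null data: no region stands out
    nullMax <- vapply(1:5, function(s) {
        ds <- simulateActivity(activitySpec(missingRate = 0, seed = s))
        tal <- suppressMessages(runEnsemble(ds, grid))
        max(tal@tally$ratio_ingroup_only)
    }, numeric(1))
    expect_gte(mean(nullMax < 20), 0.9)
    # planted ingroup-specific co-activation module: its seed region has
    # the maximal ingroup-only ratio, at >= 80% of configurations
    regs <- defaultRegionTable(84)$region_id
    mod1 <- regs[seq(1, 84, by = 6)]
    eff <- data.frame(region = mod1, condition = "HBT_ingroup",
                      effect = 1.8)
    hits <- 0
    tallies <- NULL
    for (s in 1:5) {
        ds <- simulateActivity(activitySpec(
            moduleLoading = c(0.2, rep(0.6, 5)), dispersion = 0.1,
            effectTable = eff, missingRate = 0, seed = s))
        tal <- suppressMessages(runEnsemble(ds, grid))
        tl <- tal@tally
        # conservation: the four counts sum to the config count
        expect_true(all(tl$n_ingroup_only + tl$n_outgroup_only +
                        tl$n_both + tl$n_none == tal@nConfigs))
        r <- tl$ratio_ingroup_only[tl$region == "NacSh"]
        hits <- hits + (r >= 80 && r == max(tl$ratio_ingroup_only))
        tallies <- tal
    }
    expect_gte(hits, 4)
    # config order invariance
    ds <- simulateActivity(activitySpec(
        moduleLoading = c(0.2, rep(0.6, 5)), dispersion = 0.1,
        effectTable = eff, missingRate = 0, seed = 1))
    t1 <- suppressMessages(runEnsemble(ds, grid))
    t2 <- suppressMessages(runEnsemble(ds, grid[rev(seq_len(nrow(grid))), ]))
    expect_equal(as.data.frame(t1@tally), as.data.frame(t2@tally))
})
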