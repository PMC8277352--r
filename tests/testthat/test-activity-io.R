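test_that("loadActivity round-trips a constructed file", {
    paths <- writeToyCsv()
    ds <- loadActivity(paths["counts"], paths["regions"])
    expect_s4_class(ds, "ActivityDataset")
    expect_equal(dim(fosCounts(ds)), c(4L, 3L))
    expect_equal(sum(missingMask(ds)), 0L)
    expect_equal(unname(conditions(ds)),
                 c("HBT_ingroup", "HBT_ingroup", "baseline"))
    # write and reload: bit-identical counts and labels
    out <- tempfile(fileext = ".csv"); outR <- tempfile(fileext = ".csv")
    suppressMessages(writeActivity(ds, out, outR))
    ds2 <- loadActivity(out, outR)
    expect_identical(fosCounts(ds2), fosCounts(ds))
    expect_identical(conditions(ds2), conditions(ds))
})

test_that("loadActivity flags blank cells as missing and rejects bad input", {
    paths <- writeToyCsv()
    lines <- readLines(paths["counts"])
    lines[2] <- "s1,HBT_ingroup,2,,1,10"
    writeLines(lines, paths["counts"])
    ds <- loadActivity(paths["counts"], paths["regions"])
    expect_equal(sum(missingMask(ds)), 1L)
    expect_true(missingMask(ds)["R2", "s1"])
    # negative count names subject and region
    lines[2] <- "s1,HBT_ingroup,2,-2,1,10"
    writeLines(lines, paths["counts"])
    expect_error(loadActivity(paths["counts"], paths["regions"]),
                 "s1.*R2|R2.*s1")
    # region absent from metadata
    lines[1] <- "subject_id,condition,R1,R2,R3,R9"
    lines[2] <- "s1,HBT_ingroup,2,4,1,10"
    writeLines(lines, paths["counts"])
    expect_error(loadActivity(paths["counts"], paths["regions"]), "R9")
    # unknown condition label
    paths <- writeToyCsv()
    lines <- readLines(paths["counts"])
    lines[2] <- "s1,bogus_condition,2,4,1,10"
    writeLines(lines, paths["counts"])
    expect_error(loadActivity(paths["counts"], paths["regions"]),
                 "condition")
    # duplicate subjects
    lines <- readLines(writeToyCsv()["counts"])
    writeLines(c(lines, lines[2]), paths["counts"])
    expect_error(loadActivity(paths["counts"], paths["regions"]),
                 "duplicate")
})

test_that("outlier rule requires both the SD clause and the pooled-range clause", {
    # region R1: group A = {10, 11, 12}; group B holds a 300 among
    # ordinary values (the group is big enough for 300 to exceed 2 SD),
    # and every other condition spans well below it -> 300 flagged
    counts <- matrix(c(10, 11, 12, 28, 30, 29, 31, 27, 30, 300,
                       5, 6, 7, 8, 9, 5, 6, 7, 8, 9,
                       1, 2, 3, 4, 5, 1, 2, 3, 4, 5),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(paste0("R", 1:3), paste0("s", 1:10)))
    cond <- rep(c("HBT_ingroup", "HBT_outgroup"), c(3, 7))
    ri <- data.frame(region_id = rownames(counts), full_name = "x",
                     category = "other")
    ds <- ActivityDataset(counts, ri, cond)
    grp <- counts["R1", 4:10]
    expect_gt(abs(300 - mean(grp)), 2 * sd(grp))   # clause (a) holds
    res <- removeOutliers(ds)
    expect_equal(nRemoved(res$report), 1L)
    expect_equal(as.character(res$report@entries$region), "R1")
    expect_equal(res$report@entries$value, 300)
    expect_true(is.na(fosCounts(res$dataset)["R1", "s10"]))

    # same extreme value, but another condition's observed range covers
    # it -> NOT flagged (clause b fails)
    counts2 <- counts
    counts2["R1", 1:3] <- c(10, 11, 400)   # ingroup range now [10, 400]
    ds2 <- ActivityDataset(counts2, ri, cond)
    res2 <- removeOutliers(ds2)
    expect_false(any(res2$report@entries$value == 300))
})

test_that("outlier removal is single-pass idempotent", {
    set.seed(11)
    ds <- simulateActivity(activitySpec(nRegions = 20, missingRate = 0,
                                        seed = 12))
    cnt <- fosCounts(ds)
    cnt[1, 1] <- max(cnt) * 10   # plant a gross outlier
    ds <- toyDataset(cnt, unname(conditions(ds)))
    res <- removeOutliers(ds)
    expect_gte(nRemoved(res$report), 1L)
    # second pass on the cleaned data removes nothing new for the same
    # planted points (statistics recomputed excluding removed values)
    res2 <- removeOutliers(res$dataset)
    flagged1 <- paste(res$report@entries$subject, res$report@entries$region)
    flagged2 <- paste(res2$report@entries$subject, res2$report@entries$region)
    expect_length(intersect(flagged1, flagged2), 0)
})

test_that("imputation fills by condition mean and preserves observed values", {
    counts <- matrix(c(4, NA, 8, 10, 20,
                       1, 2, 3, NA, 5), nrow = 2, byrow = TRUE,
                     dimnames = list(c("R1", "R2"), paste0("s", 1:5)))
    cond <- c("HBT_ingroup", "HBT_ingroup", "HBT_ingroup",
              "baseline", "baseline")
    ri <- data.frame(region_id = c("R1", "R2"), full_name = "x",
                     category = "other")
    ds <- ActivityDataset(counts, ri, cond)
    imp <- imputeConditionMean(ds)
    expect_equal(fosCounts(imp)["R1", "s2"], 6)       # mean(4, 8)
    expect_equal(fosCounts(imp)["R2", "s4"], 5)       # baseline mean
    expect_equal(sum(missingMask(imp)), 0L)
    # observed entries unchanged, condition means preserved exactly
    obs <- !is.na(counts)
    expect_identical(fosCounts(imp)[obs], counts[obs])
    expect_equal(mean(fosCounts(imp)["R1", cond == "HBT_ingroup"]),
                 mean(counts["R1", cond == "HBT_ingroup"], na.rm = TRUE))
    # dataset with no missing returned unchanged
    ds2 <- toyDataset()
    expect_identical(fosCounts(imputeConditionMean(ds2)), fosCounts(ds2))
    # entirely missing cell errors with its name
    counts[1, 1:3] <- NA
    ds3 <- ActivityDataset(counts, ri, cond)
    expect_error(imputeConditionMean(ds3), "HBT_ingroup.*R1")
})

test_that("condition totals ignore missing values and sum per subject", {
    ds <- toyDataset(matrix(c(2, 3, 5), nrow = 3,
                            dimnames = list(paste0("R", 1:3), "s1")),
                     "baseline")
    tot <- conditionTotals(ds)
    expect_equal(tot$subjectTotals$total, 10)
    zero <- toyDataset(matrix(0, 4, 3,
                              dimnames = list(paste0("R", 1:4),
                                              paste0("s", 1:3))))
    expect_true(all(conditionTotals(zero)$subjectTotals$total == 0))
})

test_that("planted condition elevation shows in condition totals", {
    regs <- defaultRegionTable(30)$region_id
    eff <- data.frame(region = regs, condition = "HBT_ingroup",
                      effect = 1.5)
    hits <- 0
    for (s in 1:20) {
        ds <- simulateActivity(activitySpec(
            nPerCondition = c(HBT_ingroup = 8L, baseline = 8L),
            nRegions = 30, effectTable = eff, missingRate = 0, seed = s))
        cs <- conditionTotals(ds)$conditionSummary
        hits <- hits + (cs$mean[cs$condition == "HBT_ingroup"] >
                        cs$mean[cs$condition == "baseline"])
    }
    expect_gte(hits, 19)
})
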