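## End-to-end orchestration: a seeded run over all stages with a JSON
## manifest. The exported functions are the package's entry points; a
## thin Rscript wrapper around runPipeline() is all a shell interface
## needs.

stageSeed <- function(seed, stage) {
    # stable per-stage derivation so adding stages never reshuffles others
    (as.integer(seed) + sum(utf8ToInt(stage))) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes clean (outlier removal) -> impute -> condition totals ->
#' task PLS -> co-activation network -> ensemble, plus behavior,
#' photometry and tracing stages when their inputs (or the synthetic
#' default) are present. All stage seeds derive deterministically from
#' the global seed.
#'
#' @param config named list or YAML path with fields: \code{seed}
#'   (mandatory), \code{output_dir}, optional \code{counts_csv} and
#'   \code{regions_csv} (a synthetic dataset is generated otherwise),
#'   \code{threshold_frac} (default 0.10), \code{n_perm}, \code{n_boot}
#'   (default 500), \code{ensemble_grid} (YAML path, default grid
#'   otherwise), \code{stages} (subset to run)
#' @return named list of stage outputs, including \code{manifest}
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (is.null(config$seed)) stop("config validation: seed is mandatory")
    for (f in c("counts_csv", "regions_csv", "ensemble_grid"))
        if (!is.null(config[[f]]) && !file.exists(config[[f]]))
            stop("config validation: missing file for ", f, ": ",
                 config[[f]])
    seed <- as.integer(config$seed)
    outDir <- config$output_dir
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    stages <- config$stages %||% c("clean", "pls", "network", "ensemble",
                                   "behavior", "photometry", "tracing")
    thr <- config$threshold_frac %||% 0.10
    nPerm <- config$n_perm %||% 500L
    nBoot <- config$n_boot %||% 500L
    out <- list()
    manifest <- list(package_version = as.character(packageVersion("fosmap")),
                     seed = seed, parameters = list(threshold_frac = thr,
                                                    n_perm = nPerm,
                                                    n_boot = nBoot),
                     stages = list())
    runStage <- function(name, fun) {
        res <- tryCatch(fun(), error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        manifest$stages[[name]] <<- list(seed = stageSeed(seed, name),
                                         completed = TRUE)
        res
    }
    ds <- if (!is.null(config$counts_csv))
        loadActivity(config$counts_csv, config$regions_csv)
    else simulateActivity(activitySpec(seed = stageSeed(seed, "simulate")))
    if ("clean" %in% stages) {
        out$clean <- runStage("clean", function() removeOutliers(ds))
        ds <- out$clean$dataset
    }
    dsImp <- imputeConditionMean(ds)
    out$totals <- conditionTotals(ds)
    social <- c("HBT_ingroup", "HBT_outgroup", "brief_ingroup",
                "brief_outgroup", "two_free_ingroup", "two_free_outgroup")
    if ("pls" %in% stages)
        out$pls <- runStage("pls", function()
            runTaskPLS(dsImp, intersect(social, conditions(dsImp)),
                       nPerm = nPerm, nBoot = nBoot,
                       seed = stageSeed(seed, "pls")))
    if ("network" %in% stages)
        out$network <- runStage("network", function() {
            lapply(intersect(c("HBT_ingroup", "HBT_outgroup"),
                             conditions(dsImp)), function(cc) {
                rm <- correlationMatrix(dsImp, cc)
                net <- thresholdNetwork(rm, thr)
                ct <- centrality(net)
                list(condition = cc, network = net, centrality = ct,
                     hubs = identifyHubs(ct),
                     communities = louvainCommunities(
                         net, seed = stageSeed(seed, paste0("louvain_", cc))))
            })
        })
    if ("ensemble" %in% stages &&
        all(c("HBT_ingroup", "HBT_outgroup", "baseline") %in%
                conditions(dsImp)))
        out$ensemble <- runStage("ensemble", function() {
            grid <- if (!is.null(config$ensemble_grid))
                readConfigGrid(config$ensemble_grid)
            else defaultConfigGrid(seed = stageSeed(seed, "ensemble"))
            runEnsemble(dsImp, grid)
        })
    if ("behavior" %in% stages)
        out$behavior <- runStage("behavior", function() {
            beh <- simulateBehavior(behaviorSpec(
                seed = stageSeed(seed, "behavior")))
            list(sessions = beh$sessions,
                 openers = classifyOpeners(beh$sessions),
                 curves = openingCurves(beh$sessions),
                 cochranQ = cochranQ(matrix(
                     beh$sessions$opened_by_rat * 1L,
                     nrow = length(unique(beh$sessions$rat_id)),
                     byrow = TRUE)))
        })
    if ("photometry" %in% stages)
        out$photometry <- runStage("photometry", function() {
            entries <- sort(runif(40, 15, 580))
            ses <- simulatePhotometry(photometrySpec(
                eventTimes = list(zone_entry = entries),
                seed = stageSeed(seed, "photometry")))
            dff <- computeDff(ses)
            list(session = ses, dff = dff,
                 psth = eventPsth(dff, ses@t, ses@events$zone_entry),
                 prePost = prePostEntryTest(dff, ses@t,
                                            ses@events$zone_entry))
        })
    if ("tracing" %in% stages)
        out$tracing <- runStage("tracing", function() {
            tr <- simulateTracing(seed = stageSeed(seed, "tracing"))
            list(data = tr,
                 correlation = behaviorCorrelation(tr$counts,
                                                   tr$behavior, "ACC"))
        })
    out$manifest <- manifest
    if (!is.null(outDir))
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize pipeline outputs
#'
#' Produces a plain-text summary plus a machine-readable JSON list of
#' the main quantities of each completed stage; stages without output
#' are noted and omitted.
#'
#' @param outputs result of \code{\link{runPipeline}}
#' @param textPath,jsonPath optional output paths
#' @return invisibly, the report list
#' @export
reportPipeline <- function(outputs, textPath = NULL, jsonPath = NULL) {
    rep <- list()
    lines <- character()
    add <- function(x) lines <<- c(lines, x)
    add("== fosmap pipeline report ==")
    if (!is.null(outputs$clean)) {
        rep$n_outliers_removed <- nRemoved(outputs$clean$report)
        add(sprintf("clean: %d outlier value(s) removed",
                    rep$n_outliers_removed))
    }
    if (!is.null(outputs$pls)) {
        rep$pls <- list(lv1_singular_value = outputs$pls@singularValues[1],
                        lv1_p = outputs$pls@permutationP[1])
        add(sprintf("pls: LV1 singular value %.3f, permutation p %.4f",
                    rep$pls$lv1_singular_value, rep$pls$lv1_p))
    } else add("pls: no output (section omitted)")
    if (!is.null(outputs$network)) {
        rep$network <- lapply(outputs$network, function(nn)
            list(condition = nn$condition, hubs = nn$hubs,
                 n_edges = sum(nn$network@adjacency) / 2))
        for (nn in outputs$network)
            add(sprintf("network [%s]: %d edges, hubs: %s", nn$condition,
                        sum(nn$network@adjacency) / 2,
                        paste(nn$hubs, collapse = ", ")))
    } else add("network: no output (section omitted)")
    if (!is.null(outputs$ensemble)) {
        tl <- outputs$ensemble@tally
        top <- tl[which.max(tl$ratio_ingroup_only), ]
        rep$ensemble <- list(top_region = top$region,
                             top_ratio_ingroup_only =
                                 top$ratio_ingroup_only)
        add(sprintf("ensemble: top ingroup-only region %s (%.1f%%)",
                    top$region, top$ratio_ingroup_only))
    } else add("ensemble: no output (section omitted)")
    if (!is.null(outputs$behavior)) {
        rep$behavior <- list(
            n_openers = sum(outputs$behavior$openers),
            cochran_q = outputs$behavior$cochranQ@statistic)
        add(sprintf("behavior: %d opener(s), Cochran's Q %.2f",
                    rep$behavior$n_openers, rep$behavior$cochran_q))
    } else add("behavior: no output (section omitted)")
    if (!is.null(outputs$photometry)) {
        rep$photometry <- list(
            pre_post_p = pValue(outputs$photometry$prePost),
            n_events = outputs$photometry$psth$n_events)
        add(sprintf("photometry: %d events, pre/post p %.4g",
                    rep$photometry$n_events, rep$photometry$pre_post_p))
    } else add("photometry: no output (section omitted)")
    if (!is.null(outputs$tracing)) {
        rep$tracing <- list(
            r2 = outputs$tracing$correlation@extras$r2,
            p = pValue(outputs$tracing$correlation))
        add(sprintf("tracing: co-label r2 %.3f (p %.4g)",
                    rep$tracing$r2, rep$tracing$p))
    } else add("tracing: no output (section omitted)")
    if (!is.null(textPath)) writeLines(lines, textPath)
    else message(paste(lines, collapse = "\n"))
    if (!is.null(jsonPath))
        jsonlite::write_json(rep, jsonPath, auto_unbox = TRUE, digits = NA)
    invisible(rep)
}
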