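## Retrograde tracing: Fluoro-Gold / c-Fos co-label quantification and
## its correlation with door-opening behavior.

#' Percent of FG+ cells co-labeled with c-Fos
#'
#' Rows with \code{fg_count} = 0 are excluded (not reported as 0) with a
#' message.
#'
#' @param counts data.frame(rat_id, region_id, fg_count, cfos_count,
#'   colabel_count)
#' @return the counts with a \code{colabel_pct} column, fg = 0 rows
#'   removed
#' @export
colabelFraction <- function(counts) {
    stopifnot(all(c("rat_id", "region_id", "fg_count",
                    "colabel_count") %in% colnames(counts)))
    if (any(counts$colabel_count > pmin(counts$fg_count,
                                        counts$cfos_count)))
        stop("colabel_count exceeds min(fg_count, cfos_count)")
    drop <- counts$fg_count == 0
    if (any(drop))
        message(sum(drop), " cell(s) with fg_count = 0 excluded")
    out <- counts[!drop, , drop = FALSE]
    out$colabel_pct <- 100 * out$colabel_count / out$fg_count
    out
}

#' Correlation of region co-labeling with door-opening
#'
#' Pearson correlation between a region's co-label percentage and each
#' rat's door-opening percentage; the same correlation for the raw
#' c-Fos counts (the negative control) is provided in extras.
#'
#' @param counts tracing counts (see \code{\link{colabelFraction}})
#' @param behavior data.frame(rat_id, pct_door_openings)
#' @param region region id (>= 4 rats with data)
#' @return a \linkS4class{TestResult} for the co-label correlation;
#'   \code{extras$cfosControl} holds the raw-count control
#' @export
behaviorCorrelation <- function(counts, behavior, region) {
    cf <- colabelFraction(counts[counts$region_id == region, ,
                                 drop = FALSE])
    m <- merge(cf, behavior, by = "rat_id")
    if (nrow(m) < 4) stop("need >= 4 rats with data for region ", region)
    res <- pearsonCor(m$pct_door_openings, m$colabel_pct)
    res@extras$cfosControl <- pearsonCor(m$pct_door_openings,
                                         m$cfos_count)
    res@extras$region <- region
    res
}

#' Opener vs non-opener comparison across regions
#'
#' Two-way (opener status x region) ANOVA on each measure (c-Fos
#' counts, FG counts, co-label percentage) with the group main effect,
#' plus per-region contrasts Sidak-corrected over regions.
#'
#' @param counts tracing counts
#' @param behavior data.frame(rat_id, opener)
#' @param measures column(s) to analyze (default all three)
#' @return named list per measure: \code{main} (a
#'   \linkS4class{TestResult} for the opener main effect) and
#'   \code{contrasts} (data.frame region, t, p, p_sidak)
#' @export
openerGroupComparison <- function(counts, behavior,
                                  measures = c("cfos_count", "fg_count",
                                               "colabel_pct")) {
    cf <- colabelFraction(counts)
    m <- merge(cf, behavior[, c("rat_id", "opener")], by = "rat_id")
    if (length(unique(m$opener)) < 2) stop("both groups must be non-empty")
    out <- list()
    for (ms in measures) {
        y <- m[[ms]]
        grp <- factor(m$opener, levels = c(FALSE, TRUE),
                      labels = c("non_opener", "opener"))
        reg <- factor(m$region_id)
        fit <- if (nlevels(reg) > 1) aov(y ~ grp * reg) else aov(y ~ grp)
        tab <- anova(fit)
        main <- newTestResult(
            paste0("two-way ANOVA opener main effect (", ms, ")"),
            tab["grp", "F value"],
            c(tab["grp", "Df"], tab["Residuals", "Df"]),
            tab["grp", "Pr(>F)"], nrow(m))
        regions <- levels(reg)
        ct <- do.call(rbind, lapply(regions, function(r) {
            a <- y[reg == r & m$opener]
            b <- y[reg == r & !m$opener]
            if (length(a) < 2 || length(b) < 2 ||
                (var(a) == 0 && var(b) == 0))
                return(data.frame(region = r, t = NA_real_,
                                  p = NA_real_))
            tt <- tTestTwoSample(a, b)
            data.frame(region = r, t = tt@statistic, p = tt@pValue)
        }))
        ct$p_sidak <- correctPvalues(ct$p, "sidak", m = nrow(ct))
        out[[ms]] <- list(main = main, contrasts = ct)
    }
    out
}
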