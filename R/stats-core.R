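## Statistical tests used throughout the pipeline. Standard tests are
## delegated to stats::; Cochran's Q, the tie-corrected Friedman
## statistic and the exact opener power enumeration are implemented here.

#' Cochran's Q test for related binary observations
#'
#' Tests whether the proportion of successes (e.g., door-openings)
#' differs across k related samples (days), given a rats x days 0/1
#' matrix. Rows that are all 0 or all 1 contribute nothing to the
#' statistic.
#'
#' @param x binary matrix, subjects in rows, repeated measures in columns
#' @return a \linkS4class{TestResult}; \code{extras$degenerate} is TRUE
#'   when every row is constant (Q reported as 0, p = 1)
#' @examples
#' m <- matrix(c(1,1,1, 0,1,1, 0,0,1, 0,0,0), nrow = 4, byrow = TRUE)
#' cochranQ(m)
#' @export
cochranQ <- function(x) {
    x <- as.matrix(x)
    if (ncol(x) < 2) stop("need at least 2 columns")
    if (anyNA(x)) stop("missing entries not allowed")
    if (!all(x %in% c(0, 1))) stop("entries must be 0/1")
    k <- ncol(x)
    Cj <- colSums(x)
    Ri <- rowSums(x)
    N <- sum(x)
    denom <- k * N - sum(Ri^2)
    if (denom == 0)
        return(newTestResult("Cochran's Q", 0, k - 1, 1, nrow(x),
                             list(degenerate = TRUE)))
    Q <- (k - 1) * (k * sum(Cj^2) - N^2) / denom
    newTestResult("Cochran's Q", Q, k - 1,
                  pchisq(Q, k - 1, lower.tail = FALSE), nrow(x))
}

#' Friedman test with tie correction
#'
#' Rank-based test for k related samples using within-row mid-ranks.
#' The tie-corrected chi-square statistic is used because capped
#' latencies (non-opening sessions are all recorded at the 2400 s cap)
#' guarantee heavy ties.
#'
#' @param x numeric matrix, subjects in rows, repeated measures in
#'   columns
#' @return a \linkS4class{TestResult}
#' @export
friedmanRM <- function(x) {
    x <- as.matrix(x)
    if (ncol(x) < 2) stop("need at least 2 columns")
    if (anyNA(x)) stop("missing entries not allowed")
    n <- nrow(x); k <- ncol(x)
    R <- t(apply(x, 1, rank))          # mid-ranks for ties
    Rj <- colSums(R)
    num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
    den <- sum(R^2) - n * k * (k + 1)^2 / 4
    if (den == 0)
        return(newTestResult("Friedman", 0, k - 1, 1, n,
                             list(degenerate = TRUE)))
    stat <- num / den
    newTestResult("Friedman", stat, k - 1,
                  pchisq(stat, k - 1, lower.tail = FALSE), n)
}

#' Two-sample t-test (pooled variance) or paired t-test
#'
#' Unpaired comparisons use Student's pooled-variance t with
#' df = na + nb - 2 (the design the reported df = n1 + n2 - 2 implies,
#' rather than Welch's).
#'
#' @param a,b numeric vectors
#' @param paired logical; if TRUE, \code{a} and \code{b} must have equal
#'   length
#' @param alternative passed to \code{\link[stats]{t.test}}
#' @return a \linkS4class{TestResult} with group means in \code{extras}
#' @export
tTestTwoSample <- function(a, b, paired = FALSE,
                           alternative = "two.sided") {
    if (paired) {
        if (length(a) != length(b)) stop("paired vectors must match")
        if (length(a) < 2) stop("need n >= 2")
        if (var(a - b) == 0) stop("zero variance of differences")
        ht <- t.test(a, b, paired = TRUE, alternative = alternative)
    } else {
        if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
        sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
            (length(a) + length(b) - 2)
        if (sp2 == 0) stop("zero pooled variance")
        ht <- t.test(a, b, var.equal = TRUE, alternative = alternative)
    }
    newTestResult(if (paired) "paired t" else "Student t (pooled)",
                  unname(ht$statistic), unname(ht$parameter),
                  ht$p.value, length(a) + if (paired) 0L else length(b),
                  list(means = c(mean(a), mean(b))))
}

#' One-way ANOVA with Bonferroni post-hoc comparisons
#'
#' @param groups list of numeric vectors, one per group (each n >= 2)
#' @return a \linkS4class{TestResult}; \code{extras$posthoc} holds the
#'   Bonferroni-corrected pairwise t-test p-value matrix and
#'   \code{extras$means} the group means
#' @export
anovaOneway <- function(groups) {
    if (length(groups) < 2) stop("need at least 2 groups")
    if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
    if (all(vapply(groups, var, 1) == 0)) stop("zero within-group variance")
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
    fit <- aov(y ~ g)
    tab <- anova(fit)
    ph <- stats::pairwise.t.test(y, g, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)
    newTestResult("one-way ANOVA", tab$`F value`[1],
                  c(tab$Df[1], tab$Df[2]),
                  tab$`Pr(>F)`[1], length(y),
                  list(posthoc = ph$p.value,
                       means = vapply(groups, mean, 1)))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; the exact distribution is used up to
#' \code{exactMax} pairs (when no ties among the absolute differences),
#' the continuity-corrected normal approximation beyond.
#'
#' @param pre,post equal-length numeric vectors
#' @param alternative "two.sided" (default), "greater" (post > pre) or
#'   "less"
#' @param exactMax largest n for the exact distribution (default 25)
#' @return a \linkS4class{TestResult}; degenerate (all differences zero)
#'   inputs return statistic 0, p = 1 with \code{extras$degenerate}
#' @export
wilcoxonSignedRank <- function(pre, post, alternative = "two.sided",
                               exactMax = 25) {
    if (length(pre) != length(post)) stop("vectors must have equal length")
    d <- post - pre
    d <- d[d != 0]
    if (!length(d))
        return(newTestResult("Wilcoxon signed-rank", 0, NA_real_, 1,
                             length(pre), list(degenerate = TRUE)))
    exact <- length(d) <= exactMax && !any(duplicated(abs(d)))
    ht <- suppressWarnings(
        wilcox.test(d, mu = 0, alternative = alternative,
                    exact = exact, correct = TRUE))
    newTestResult("Wilcoxon signed-rank", unname(ht$statistic), NA_real_,
                  ht$p.value, length(d), list(exact = exact))
}

#' Pearson correlation with t-based p-value
#'
#' No multiple-comparison correction is applied by default; use
#' \code{\link{correctPvalues}} explicitly when needed.
#'
#' @param x,y numeric vectors, length >= 3, non-constant
#' @return a \linkS4class{TestResult} with \code{extras$r} and
#'   \code{extras$r2}
#' @export
pearsonCor <- function(x, y) {
    if (length(x) != length(y)) stop("vectors must have equal length")
    if (length(x) < 3) stop("need n >= 3")
    if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
    ht <- cor.test(x, y, method = "pearson")
    r <- unname(ht$estimate)
    newTestResult("Pearson correlation", r, unname(ht$parameter),
                  ht$p.value, length(x), list(r = r, r2 = r^2))
}

#' Bonferroni or Sidak correction of p-values
#'
#' @param p vector of p-values in [0, 1]
#' @param method "bonferroni" (min(1, m p)) or "sidak" (1 - (1 - p)^m)
#' @param m number of comparisons; defaults to \code{length(p)}
#' @return corrected p-values
#' @export
correctPvalues <- function(p, method = c("bonferroni", "sidak"),
                           m = length(p)) {
    method <- match.arg(method)
    if (isTRUE(any(p < 0 | p > 1, na.rm = TRUE)))
        stop("p-values must lie in [0, 1]")
    switch(method,
           bonferroni = pmin(1, m * p),
           sidak = 1 - (1 - p)^m)
}

#' Exact power for detecting a difference in opener incidence
#'
#' Enumerates all (k1, k2) binomial outcomes for two groups of size
#' \code{nPerGroup} with opener probabilities \code{pIngroup} and
#' \code{pOutgroup}, applies a one-sided Fisher exact test at
#' \code{alpha} to each 2 x 2 table, and sums the probability of
#' rejection. The direction (ingroup > outgroup) is pre-specified;
#' set \code{alternative} for other variants.
#'
#' @param nPerGroup group size
#' @param pIngroup,pOutgroup opener probabilities
#' @param alpha significance level (default 0.05)
#' @param alternative Fisher-test alternative (default "greater")
#' @return the exact power as a probability in [0, 1]
#' @export
openerPower <- function(nPerGroup, pIngroup, pOutgroup, alpha = 0.05,
                        alternative = "greater") {
    stopifnot(nPerGroup >= 1,
              pIngroup >= 0, pIngroup <= 1,
              pOutgroup >= 0, pOutgroup <= 1)
    pow <- 0
    for (k1 in 0:nPerGroup) {
        p1 <- dbinom(k1, nPerGroup, pIngroup)
        if (p1 == 0) next
        for (k2 in 0:nPerGroup) {
            p2 <- dbinom(k2, nPerGroup, pOutgroup)
            if (p2 == 0) next
            tab <- matrix(c(k1, nPerGroup - k1, k2, nPerGroup - k2), 2)
            pv <- fisher.test(tab, alternative = alternative)$p.value
            if (pv <= alpha) pow <- pow + p1 * p2
        }
    }
    pow
}
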