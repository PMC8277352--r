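## Two-channel fiber photometry: isosbestic motion correction,
## session-median dF/F, zone-entry event extraction, event-triggered
## averages (PSTH) and the pre/post entry statistics.

#' Motion-corrected dF/F trace
#'
#' The 405 nm isosbestic control is fitted to the 470 nm calcium signal
#' by ordinary least squares over the whole session; the fitted motion
#' component is subtracted and the residual normalized to the session
#' median of the raw 470 nm signal: dF/F = (s470 - fit(s405)) /
#' median(s470). Because the numerator is an OLS residual its mean is ~0
#' (the median need not be). With \code{denominator = "fitted"} the
#' fitted control trace is used as a per-sample denominator instead.
#'
#' @param session a \linkS4class{PhotometrySession}
#' @param denominator "median470" (default) or "fitted"
#' @return numeric dF/F trace, same length as the session
#' @export
computeDff <- function(session, denominator = c("median470", "fitted")) {
    denominator <- match.arg(denominator)
    s470 <- session@s470; s405 <- session@s405
    if (sd(s405) == 0) {
        warning("constant 405 nm control; fitted motion component is the mean")
        fitted <- rep(mean(s470), length(s470))
    } else {
        fit <- lm(s470 ~ s405)
        fitted <- fitted(fit)
    }
    corrected <- s470 - fitted
    if (denominator == "median470") corrected / median(s470)
    else corrected / fitted
}

#' Detect zone-entry events from an in-zone mask or a track
#'
#' Entry times are the samples where in-zone changes from FALSE to TRUE.
#'
#' @param x a \linkS4class{PhotometrySession} (uses its inZone mask), or
#'   a track data.frame (t_s, x_cm, y_cm) with \code{zone}
#' @param zone c(x0, y0, x1, y1), required for track input
#' @param minGap minimum time since the previous entry for a new entry
#'   to count (default 0: every transition counts)
#' @return numeric vector of entry times (s)
#' @export
detectZoneEntries <- function(x, zone = NULL, minGap = 0) {
    if (is(x, "PhotometrySession")) {
        tt <- x@t; inz <- x@inZone
    } else {
        if (is.null(zone)) zone <- attr(x, "zone")
        if (is.null(zone)) stop("zone must be supplied for track input")
        tt <- x$t_s; inz <- inZoneMask(x, zone)
    }
    if (!any(inz)) return(numeric(0))
    times <- tt[which(diff(inz) == 1) + 1L]
    if (minGap > 0 && length(times) > 1) {
        keep <- c(TRUE, diff(times) >= minGap)
        last <- times[1]
        for (i in seq_along(times)[-1]) {
            keep[i] <- (times[i] - last) >= minGap
            if (keep[i]) last <- times[i]
        }
        times <- times[keep]
    }
    times
}

#' Event-triggered average (PSTH) of a dF/F trace
#'
#' Trace segments around each event are aligned at lag 0 and averaged;
#' dispersion is the SEM across events. Events whose window extends
#' beyond the session are dropped (with a message).
#'
#' @param dff dF/F trace
#' @param t sample times (s)
#' @param events event times (s)
#' @param window c(before, after) in seconds (default c(-10, 10))
#' @return list(lag, mean, sem, n_events, segments); \code{sem} is NA
#'   when a single event is usable
#' @export
eventPsth <- function(dff, t, events, window = c(-10, 10)) {
    stopifnot(length(dff) == length(t), window[1] < 0, window[2] > 0)
    dt <- median(diff(t))
    nb <- round(-window[1] / dt); na <- round(window[2] / dt)
    idx0 <- round((events - t[1]) / dt) + 1L
    usable <- idx0 - nb >= 1 & idx0 + na <= length(dff)
    if (any(!usable))
        message(sum(!usable), " event(s) with partial window dropped")
    idx0 <- idx0[usable]
    if (!length(idx0)) stop("no usable events")
    segments <- t(vapply(idx0, function(i0) dff[(i0 - nb):(i0 + na)],
                         numeric(nb + na + 1)))
    lag <- seq(-nb, na) * dt
    m <- colMeans(segments)
    sem <- if (nrow(segments) > 1)
        apply(segments, 2, sd) / sqrt(nrow(segments)) else
        rep(NA_real_, ncol(segments))
    list(lag = lag, mean = m, sem = sem, n_events = nrow(segments),
         segments = segments)
}

#' Pre- vs post-entry signal comparison
#'
#' For every event the mean dF/F over the second before entry [-1, 0)
#' is compared to the second after entry (0, +1]; the per-event pairs
#' are tested with a Wilcoxon signed-rank test (no distributional
#' assumption on the signal).
#'
#' @param dff dF/F trace
#' @param t sample times (s)
#' @param events event times (s); at least \code{minEvents} must have a
#'   full +-1 s window
#' @param minEvents minimum usable events (default 5); pooled sessions
#'   are advised below this
#' @param alternative Wilcoxon alternative (default "two.sided")
#' @return a \linkS4class{TestResult} with per-event means in
#'   \code{extras}
#' @export
prePostEntryTest <- function(dff, t, events, minEvents = 5,
                             alternative = "two.sided") {
    dt <- median(diff(t))
    k <- round(1 / dt)
    idx0 <- round((events - t[1]) / dt) + 1L
    usable <- idx0 - k >= 1 & idx0 + k <= length(dff)
    idx0 <- idx0[usable]
    if (length(idx0) < minEvents)
        stop("fewer than ", minEvents,
             " usable events; consider pooling sessions")
    pre <- vapply(idx0, function(i0) mean(dff[(i0 - k):(i0 - 1)]),
                  numeric(1))
    post <- vapply(idx0, function(i0) mean(dff[(i0 + 1):(i0 + k)]),
                   numeric(1))
    res <- wilcoxonSignedRank(pre, post, alternative = alternative)
    res@extras$pre <- pre
    res@extras$post <- post
    res
}

#' In-zone vs out-of-zone activity across sessions
#'
#' Per session the mean dF/F inside and outside the restrainer zone is
#' computed; the paired per-session means are compared with a two-level
#' repeated-measures test (paired t; for two levels the RM-ANOVA F is
#' exactly t squared, reported in extras).
#'
#' @param sessions list of \linkS4class{PhotometrySession}s (>= 2 after
#'   dropping sessions with an empty zone side)
#' @return a \linkS4class{TestResult}; \code{extras$perSession} has the
#'   per-session means, \code{extras$F} the equivalent RM-ANOVA F
#' @export
zoneOccupancyComparison <- function(sessions) {
    rows <- lapply(sessions, function(s) {
        dff <- computeDff(s)
        if (!any(s@inZone) || all(s@inZone)) return(NULL)  # dropped
        c(inside = mean(dff[s@inZone]), outside = mean(dff[!s@inZone]))
    })
    dropped <- sum(vapply(rows, is.null, logical(1)))
    if (dropped) message(dropped, " session(s) with empty zone side dropped")
    rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(rows) || nrow(rows) < 2)
        stop("need >= 2 sessions with both zone sides occupied")
    res <- tTestTwoSample(rows[, "inside"], rows[, "outside"],
                          paired = TRUE)
    res@extras$perSession <- rows
    res@extras$F <- res@statistic^2
    res
}
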