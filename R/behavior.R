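## Behavioral measures: opener classification, acquisition curves,
## implausible-velocity filtering, restrainer-zone occupancy metrics and
## tidy per-day/per-minute exports for external mixed-model tooling.

HALFWAY_S <- 2400   # experimenter opens the door half-way at 40 min

#' Classify rats as openers
#'
#' A rat is an opener iff it opened the restrainer on all of the final
#' \code{finalK} testing days. Rows flagged in a logical \code{latched}
#' column (the final c-Fos session, during which the restrainer is
#' latched shut) are skipped before determining the final days.
#'
#' @param records data.frame with columns rat_id, day, opened_by_rat and
#'   optionally latched
#' @param finalK number of final days that must all be openings
#'   (default 3)
#' @return named logical vector, one flag per rat
#' @export
classifyOpeners <- function(records, finalK = 3) {
    stopifnot(all(c("rat_id", "day", "opened_by_rat") %in% colnames(records)))
    if ("latched" %in% colnames(records))
        records <- records[!records$latched, , drop = FALSE]
    finalDays <- tail(sort(unique(records$day)), finalK)
    if (length(finalDays) < finalK)
        stop("fewer than ", finalK, " testing days in records")
    out <- vapply(split(records, records$rat_id), function(rr) {
        sub <- rr[rr$day %in% finalDays, , drop = FALSE]
        if (length(unique(sub$day)) < finalK)
            stop("rat ", rr$rat_id[1], " missing final-day records")
        all(sub$opened_by_rat)
    }, logical(1))
    out
}

#' Per-day opening percentage and latency curves
#'
#' @param records data.frame with columns rat_id, day, opened_by_rat,
#'   latency_s (non-opening sessions carry the cap latency)
#' @return data.frame(day, pct_openings, latency_mean, latency_sem,
#'   n_rats)
#' @export
openingCurves <- function(records) {
    stopifnot(nrow(records) >= 1)
    byDay <- split(records, records$day)
    out <- lapply(byDay, function(dd)
        data.frame(day = dd$day[1],
                   pct_openings = 100 * mean(dd$opened_by_rat),
                   latency_mean = mean(dd$latency_s),
                   latency_sem = if (nrow(dd) > 1)
                       sd(dd$latency_s) / sqrt(nrow(dd)) else NA_real_,
                   n_rats = nrow(dd)))
    out <- do.call(rbind, out)
    out[order(out$day), , drop = FALSE]
}

## speed of each sample relative to the previous one (first sample NA)
successiveSpeed <- function(track) {
    n <- nrow(track)
    c(NA, sqrt(diff(track$x_cm)^2 + diff(track$y_cm)^2) / diff(track$t_s))
}

#' Drop physically implausible track samples
#'
#' Scans the track forward and drops every sample whose speed relative
#' to the last retained sample exceeds \code{maxV}; speeds are
#' recomputed across the gaps left by dropped samples (no
#' interpolation), so a single teleporting sample is removed without
#' discarding its neighbours.
#'
#' @param track data.frame(t_s, x_cm, y_cm, ...)
#' @param maxV speed cutoff in cm/s (default 30)
#' @return the filtered track, with attribute \code{"n_dropped"}
#' @export
filterVelocity <- function(track, maxV = 30) {
    n <- nrow(track)
    if (n < 2) return(track)
    keep <- logical(n); keep[1] <- TRUE
    last <- 1L
    for (i in 2:n) {
        v <- sqrt((track$x_cm[i] - track$x_cm[last])^2 +
                  (track$y_cm[i] - track$y_cm[last])^2) /
            (track$t_s[i] - track$t_s[last])
        if (v <= maxV) { keep[i] <- TRUE; last <- i }
    }
    out <- track[keep, , drop = FALSE]
    zone <- attr(track, "zone")
    if (!is.null(zone)) attr(out, "zone") <- zone
    attr(out, "n_dropped") <- n - sum(keep)
    out
}

inZoneMask <- function(track, zone) {
    # half-open containment so adjacent zones partition the arena
    track$x_cm >= zone[1] & track$x_cm < zone[3] &
        track$y_cm >= zone[2] & track$y_cm < zone[4]
}

## central-difference speed (one-sided at the ends)
centralSpeed <- function(track) {
    n <- nrow(track)
    if (n < 2) return(rep(NA_real_, n))
    x <- track$x_cm; y <- track$y_cm; tt <- track$t_s
    i0 <- c(1, seq_len(n - 2), n - 1)
    i1 <- c(2, seq_len(n - 2) + 2, n)
    sqrt((x[i1] - x[i0])^2 + (y[i1] - y[i0])^2) / (tt[i1] - tt[i0])
}

#' Restrainer-zone occupancy metrics
#'
#' Time in the zone is the sum of inter-sample intervals whose starting
#' sample lies inside the half-open rectangle [x0, x1) x [y0, y1); an
#' entry is an out-to-in transition (a track that starts inside the zone
#' has 0 entries until it exits and re-enters). Mean velocity uses
#' central differences.
#'
#' @param track a (filtered) track data.frame(t_s, x_cm, y_cm)
#' @param zone c(x0, y0, x1, y1) in cm; defaults to
#'   \code{attr(track, "zone")}
#' @param bin "per_session" (default) or "per_minute"
#' @return data.frame with time_in_zone_s, time_out_zone_s, entries,
#'   exits, mean_velocity (and minute when binned)
#' @export
zoneMetrics <- function(track, zone = attr(track, "zone"),
                        bin = c("per_session", "per_minute")) {
    bin <- match.arg(bin)
    if (is.null(zone)) stop("zone must be supplied")
    if (zone[3] <= zone[1] || zone[4] <= zone[2])
        stop("zone is degenerate (zero area)")
    inz <- inZoneMask(track, zone)
    n <- nrow(track)
    dt <- c(diff(track$t_s), 0)       # last sample carries no interval
    vel <- centralSpeed(track)
    trans <- diff(inz)
    entryIdx <- which(trans == 1) + 1L
    exitIdx <- which(trans == -1) + 1L
    one <- function(sel) {
        data.frame(time_in_zone_s = sum(dt[sel][inz[sel]]),
                   time_out_zone_s = sum(dt[sel][!inz[sel]]),
                   entries = sum(entryIdx %in% which(sel)),
                   exits = sum(exitIdx %in% which(sel)),
                   mean_velocity = mean(vel[sel], na.rm = TRUE))
    }
    if (bin == "per_session") {
        sel <- rep(TRUE, n)
        return(one(sel))
    }
    minute <- floor(track$t_s / 60)
    out <- do.call(rbind, lapply(sort(unique(minute)), function(m) {
        row <- one(minute == m)
        cbind(minute = m, row)
    }))
    out
}

#' Export tidy per-day/per-minute movement tables
#'
#' One row per rat x day x minute with mean velocity and time in the
#' restrainer zone, suitable for external mixed-model tooling; a
#' door_state column is included when the tracks carry one.
#'
#' @param tracks nested list: \code{tracks[[rat_id]][[as.character(day)]]}
#'   is a track data.frame (with a \code{"zone"} attribute and optional
#'   \code{door_state} column)
#' @param records session records (merged on rat_id and day when given)
#' @return long data.frame(rat, day, minute, velocity, time_in_zone
#'   [, door_state])
#' @export
exportDayMinuteTables <- function(tracks, records = NULL) {
    rows <- list()
    anyDoor <- FALSE
    for (rat in names(tracks)) for (day in names(tracks[[rat]])) {
        tr <- tracks[[rat]][[day]]
        zm <- zoneMetrics(tr, bin = "per_minute")
        row <- data.frame(rat = rat, day = as.integer(day),
                          minute = zm$minute, velocity = zm$mean_velocity,
                          time_in_zone = zm$time_in_zone_s,
                          stringsAsFactors = FALSE)
        if ("door_state" %in% colnames(tr)) {
            anyDoor <- TRUE
            minute <- floor(tr$t_s / 60)
            ds <- vapply(split(tr$door_state, minute),
                         function(v) as.integer(any(v == 1)), 1L)
            row$door_state <- ds[as.character(zm$minute)]
        }
        rows[[length(rows) + 1L]] <- row
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (!anyDoor) out$door_state <- NULL
    if (!is.null(records) &&
        all(c("rat_id", "day", "opened_by_rat") %in% colnames(records))) {
        key <- paste(out$rat, out$day)
        rkey <- paste(records$rat_id, records$day)
        out$opened_by_rat <- records$opened_by_rat[match(key, rkey)]
    }
    out
}
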