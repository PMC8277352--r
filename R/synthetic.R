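## Seeded generators that emulate every input the pipeline consumes:
## multi-condition c-Fos count matrices with planted correlation modules
## and condition effects, door-opening acquisition curves, movement
## tracks, two-channel photometry, and retrograde-tracing tables.
## Each generator is a pure function of its spec (seed included).

#' Default brain-region metadata table
#'
#' Builds a synthetic region table at the study's scale (84 regions by
#' default). The first six ids are the anatomically named regions the
#' downstream analyses refer to (NacSh, NacC, ACC, PrL, MO, AI); the
#' rest are placeholders spread over the anatomical categories.
#'
#' @param nRegions number of regions (>= 6)
#' @return data.frame with region_id, full_name, category, ap_mm
#' @export
defaultRegionTable <- function(nRegions = 84) {
    stopifnot(nRegions >= 6)
    named <- data.frame(
        region_id = c("NacSh", "NacC", "ACC", "PrL", "MO", "AI"),
        full_name = c("nucleus accumbens shell", "nucleus accumbens core",
                      "anterior cingulate cortex", "prelimbic cortex",
                      "medial orbitofrontal cortex", "anterior insula"),
        category = c("striatal", "striatal", "frontal", "frontal",
                     "frontal", "insular"),
        ap_mm = c(1.2, 1.6, 1.0, 3.2, 4.2, 2.8),
        stringsAsFactors = FALSE)
    extra <- nRegions - 6L
    filler <- data.frame(
        region_id = sprintf("R%02d", seq_len(extra) + 6L),
        full_name = sprintf("region %02d", seq_len(extra) + 6L),
        category = rep_len(REGION_CATEGORIES, extra),
        ap_mm = round(seq(-6, 5, length.out = max(extra, 2))[seq_len(extra)], 2),
        stringsAsFactors = FALSE)
    rbind(named, filler)
}

#' Specification for a synthetic activity dataset
#'
#' Defaults follow the study design: nine conditions (six social plus
#' chocolate, trapped and baseline) with 7-10 subjects each and 84
#' regions grouped into latent correlation modules.
#'
#' @param nPerCondition named integer vector, subjects per condition
#' @param nRegions number of regions
#' @param nModules number of latent correlation modules
#' @param moduleLoading shared-factor loading per module in [0, 1);
#'   scalar or one value per module
#' @param effectTable data.frame(region, condition, effect) of planted
#'   multiplicative condition effects (effect > 0)
#' @param baselineMean expected c-Fos count per region at baseline
#' @param dispersion SD of the log-normal overdispersion term
#' @param missingRate probability a cell is blanked
#' @param nRoi replicate ROIs averaged per (region, subject)
#' @param seed mandatory integer seed
#' @return a list of class \code{fosmap_activity_spec}
#' @export
activitySpec <- function(nPerCondition = c(HBT_ingroup = 8L, HBT_outgroup = 8L,
                                           brief_ingroup = 7L, brief_outgroup = 8L,
                                           two_free_ingroup = 8L, two_free_outgroup = 7L,
                                           chocolate = 8L, trapped = 8L,
                                           baseline = 10L),
                         nRegions = 84L, nModules = 6L, moduleLoading = 0.6,
                         effectTable = NULL, baselineMean = 30,
                         dispersion = 0.25, missingRate = 0.02,
                         nRoi = 2L, seed) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(all(nPerCondition >= 1),
              all(names(nPerCondition) %in% CONDITION_LEVELS),
              nRegions >= nModules,
              all(moduleLoading >= 0), all(moduleLoading < 1),
              missingRate >= 0, missingRate < 1,
              dispersion >= 0, baselineMean > 0)
    if (!is.null(effectTable)) {
        stopifnot(all(c("region", "condition", "effect") %in%
                          colnames(effectTable)),
                  all(effectTable$effect > 0))
    }
    structure(list(nPerCondition = nPerCondition, nRegions = as.integer(nRegions),
                   nModules = as.integer(nModules),
                   moduleLoading = rep_len(moduleLoading, nModules),
                   effectTable = effectTable, baselineMean = baselineMean,
                   dispersion = dispersion, missingRate = missingRate,
                   nRoi = as.integer(nRoi), seed = as.integer(seed)),
              class = "fosmap_activity_spec")
}

#' Generate a synthetic activity dataset
#'
#' Counts follow a log-normal--Poisson mixture: the log-mean of each
#' (region, subject) cell is log(baseline) + loading x subject's module
#' factor + log(planted effect) + dispersion noise, and the observed
#' value is the average of \code{nRoi} Poisson replicate ROIs (hence
#' possibly non-integer, like averaged ROI counts). One shared Gaussian
#' factor per module induces block correlation between regions of the
#' same module. Ground truth (module assignment, planted effects) is
#' stored in \code{metadata(ds)$groundTruth}.
#'
#' @param spec an \code{\link{activitySpec}}
#' @return an \linkS4class{ActivityDataset}
#' @export
simulateActivity <- function(spec) {
    stopifnot(inherits(spec, "fosmap_activity_spec"))
    set.seed(spec$seed)
    regions <- defaultRegionTable(spec$nRegions)
    conds <- rep(names(spec$nPerCondition), spec$nPerCondition)
    nSub <- length(conds)
    subjects <- sprintf("s%03d", seq_len(nSub))
    modules <- rep_len(seq_len(spec$nModules), spec$nRegions)
    if (!is.null(spec$effectTable)) {
        bad <- setdiff(spec$effectTable$region, regions$region_id)
        if (length(bad)) stop("effect references unknown region: ",
                              paste(bad, collapse = ", "))
        bad <- setdiff(spec$effectTable$condition, names(spec$nPerCondition))
        if (length(bad)) stop("effect references unknown condition: ",
                              paste(bad, collapse = ", "))
    }
    logEffect <- matrix(0, spec$nRegions, nSub)
    if (!is.null(spec$effectTable)) {
        for (i in seq_len(nrow(spec$effectTable))) {
            r <- match(spec$effectTable$region[i], regions$region_id)
            sel <- conds == spec$effectTable$condition[i]
            logEffect[r, sel] <- logEffect[r, sel] +
                log(spec$effectTable$effect[i])
        }
    }
    z <- matrix(rnorm(spec$nModules * nSub), spec$nModules, nSub)
    lambda <- spec$moduleLoading[modules]
    eta <- log(spec$baselineMean) +
        lambda * z[modules, , drop = FALSE] +
        logEffect +
        spec$dispersion * matrix(rnorm(spec$nRegions * nSub),
                                 spec$nRegions, nSub)
    mu <- exp(eta)
    cnt <- matrix(rpois(length(mu) * spec$nRoi, rep(mu, spec$nRoi)),
                  nrow = length(mu))
    cnt <- matrix(rowMeans(cnt), spec$nRegions, nSub)
    if (spec$missingRate > 0) {
        drop <- runif(length(cnt)) < spec$missingRate
        cnt[drop] <- NA
    }
    dimnames(cnt) <- list(regions$region_id, subjects)
    ds <- ActivityDataset(cnt, regions, conds, subjects)
    S4Vectors::metadata(ds)$groundTruth <-
        list(modules = setNames(modules, regions$region_id),
             effectTable = spec$effectTable,
             moduleLoading = spec$moduleLoading,
             spec = spec)
    ds
}

#' Specification for synthetic helping-behavior sessions
#'
#' @param nRats number of tested rats
#' @param nDays testing days (default 12)
#' @param openerFraction probability a rat becomes an opener
#' @param acquisitionDays integer vector of candidate acquisition days
#'   (uniform draw per opener); keep max <= nDays - 2 so designated
#'   openers open on the final three days
#' @param latencyFloor asymptotic latency of practiced openers (s)
#' @param latencyDecay per-day exponential decay rate of latency
#' @param latencyNoiseSd multiplicative log-latency noise
#' @param sessionLength session length (default 3600 s)
#' @param halfway experimenter half-way door opening (default 2400 s);
#'   latencies of non-opening sessions are recorded at this cap
#' @param condition condition label for the cohort
#' @param seed mandatory integer seed
#' @return a list of class \code{fosmap_behavior_spec}
#' @export
behaviorSpec <- function(nRats = 8L, nDays = 12L, openerFraction = 0.75,
                         acquisitionDays = 2:8, latencyFloor = 120,
                         latencyDecay = 0.5, latencyNoiseSd = 0.25,
                         sessionLength = 3600, halfway = 2400,
                         condition = "HBT_ingroup", seed) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(halfway < sessionLength, openerFraction >= 0,
              openerFraction <= 1, nDays >= 1, latencyFloor > 0,
              latencyFloor < halfway)
    structure(list(nRats = as.integer(nRats), nDays = as.integer(nDays),
                   openerFraction = openerFraction,
                   acquisitionDays = as.integer(acquisitionDays),
                   latencyFloor = latencyFloor, latencyDecay = latencyDecay,
                   latencyNoiseSd = latencyNoiseSd,
                   sessionLength = sessionLength, halfway = halfway,
                   condition = condition, seed = as.integer(seed)),
              class = "fosmap_behavior_spec")
}

#' Generate synthetic door-opening sessions and movement tracks
#'
#' Each designated opener draws an acquisition day, after which it opens
#' the restrainer every day with latency decaying exponentially toward a
#' floor; before acquisition and for non-openers, sessions are recorded
#' as not opened with latency at the half-way cap. One movement track
#' per rat is generated for the final day.
#'
#' @param spec a \code{\link{behaviorSpec}}
#' @param tracks logical, also generate per-rat final-day tracks
#' @return list with \code{sessions} (data.frame rat_id, condition, day,
#'   opened_by_rat, latency_s), \code{groundTruth} (designated opener
#'   flags and acquisition days) and \code{tracks}
#' @export
simulateBehavior <- function(spec, tracks = FALSE) {
    stopifnot(inherits(spec, "fosmap_behavior_spec"))
    set.seed(spec$seed)
    rats <- sprintf("rat%02d", seq_len(spec$nRats))
    isOpener <- runif(spec$nRats) < spec$openerFraction
    acq <- ifelse(isOpener,
                  spec$acquisitionDays[sample.int(length(spec$acquisitionDays),
                                                  spec$nRats, replace = TRUE)],
                  NA_integer_)
    rows <- vector("list", spec$nRats)
    for (i in seq_len(spec$nRats)) {
        opened <- isOpener[i] & seq_len(spec$nDays) >= acq[i]
        lat <- rep(spec$halfway, spec$nDays)
        if (any(opened)) {
            d <- seq_len(spec$nDays)[opened]
            mu <- spec$latencyFloor + (spec$halfway - spec$latencyFloor) *
                exp(-spec$latencyDecay * (d - acq[i]))
            lat[opened] <- pmin(spec$halfway,
                                pmax(1, mu * exp(rnorm(length(d), 0,
                                                       spec$latencyNoiseSd))))
        }
        rows[[i]] <- data.frame(rat_id = rats[i], condition = spec$condition,
                                day = seq_len(spec$nDays),
                                opened_by_rat = opened, latency_s = lat,
                                stringsAsFactors = FALSE)
    }
    out <- list(sessions = do.call(rbind, rows),
                groundTruth = data.frame(rat_id = rats, opener = isOpener,
                                         acquisition_day = acq),
                tracks = NULL)
    if (tracks) {
        out$tracks <- setNames(lapply(seq_len(spec$nRats), function(i)
            simulateTrack(duration = 600, hz = 10,
                          zoneBias = if (isOpener[i]) 0.15 else 0.03,
                          seed = spec$seed * 1000L + i)), rats)
    }
    out
}

#' Generate a bounded random-walk movement track
#'
#' A reflected Gaussian random walk inside a rectangular arena, with an
#' optional attraction toward the restrainer-zone center controlling
#' zone preference.
#'
#' @param duration seconds
#' @param hz sampling rate
#' @param arena c(x0, y0, x1, y1) in cm
#' @param zone restrainer zone c(x0, y0, x1, y1) in cm
#' @param zoneBias attraction strength toward the zone center (0 = none)
#' @param stepSd per-sample step SD (cm)
#' @param seed mandatory integer seed
#' @return data.frame(t_s, x_cm, y_cm) with the zone as attribute
#'   \code{"zone"}
#' @export
simulateTrack <- function(duration = 600, hz = 10,
                          arena = c(0, 0, 100, 100),
                          zone = c(60, 60, 90, 90), zoneBias = 0,
                          stepSd = 2, seed) {
    if (missing(seed)) stop("seed is mandatory")
    set.seed(seed)
    n <- as.integer(duration * hz)
    x <- numeric(n); y <- numeric(n)
    x[1] <- mean(arena[c(1, 3)]); y[1] <- mean(arena[c(2, 4)])
    zc <- c(mean(zone[c(1, 3)]), mean(zone[c(2, 4)]))
    dx <- rnorm(n, 0, stepSd); dy <- rnorm(n, 0, stepSd)
    for (i in 2:n) {
        x[i] <- x[i - 1] + dx[i] + zoneBias * (zc[1] - x[i - 1]) / hz * 10
        y[i] <- y[i - 1] + dy[i] + zoneBias * (zc[2] - y[i - 1]) / hz * 10
        x[i] <- min(max(x[i], arena[1]), arena[3])
        y[i] <- min(max(y[i], arena[2]), arena[4])
    }
    out <- data.frame(t_s = (seq_len(n) - 1) / hz, x_cm = x, y_cm = y)
    attr(out, "zone") <- zone
    out
}

#' Specification for a synthetic photometry session
#'
#' @param duration seconds
#' @param hz sampling rate (> 0)
#' @param driftAmplitude amplitude of slow shared drift
#' @param artifactAmplitude amplitude of the shared motion artifact
#' @param transientAmplitude peak amplitude of calcium transients, in
#'   the same units as the 470 nm baseline (0 = none)
#' @param riseTau,decayTau transient kernel time constants (s),
#'   decayTau > riseTau > 0
#' @param eventTimes named list of event-time vectors (seconds); a
#'   transient is planted at every \code{zone_entry} and
#'   \code{door_opening} time
#' @param noiseSd per-channel iid noise SD
#' @param baseline470,baseline405 channel baselines
#' @param bleed scaling of the shared drift+artifact into the 470 channel
#' @param sessionKind session label
#' @param seed mandatory integer seed
#' @return a list of class \code{fosmap_photometry_spec}
#' @export
photometrySpec <- function(duration = 600, hz = 20, driftAmplitude = 2,
                           artifactAmplitude = 3, transientAmplitude = 5,
                           riseTau = 0.2, decayTau = 1.5,
                           eventTimes = list(zone_entry = numeric(0)),
                           noiseSd = 0.3, baseline470 = 100,
                           baseline405 = 80, bleed = 1.2,
                           sessionKind = "ingroup", seed) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(hz > 0, decayTau > riseTau, riseTau > 0)
    for (ev in eventTimes)
        if (length(ev) && (min(ev) < 0 || max(ev) > duration))
            stop("event times must lie within [0, duration]")
    structure(list(duration = duration, hz = hz,
                   driftAmplitude = driftAmplitude,
                   artifactAmplitude = artifactAmplitude,
                   transientAmplitude = transientAmplitude,
                   riseTau = riseTau, decayTau = decayTau,
                   eventTimes = eventTimes, noiseSd = noiseSd,
                   baseline470 = baseline470, baseline405 = baseline405,
                   bleed = bleed, sessionKind = sessionKind,
                   seed = as.integer(seed)),
              class = "fosmap_photometry_spec")
}

## double-exponential transient kernel, normalized to unit peak
transientKernel <- function(hz, riseTau, decayTau, lenS = NULL) {
    if (is.null(lenS)) lenS <- riseTau + 6 * decayTau
    tt <- seq(0, lenS, by = 1 / hz)
    k <- exp(-tt / decayTau) - exp(-tt / riseTau)
    k / max(k)
}

#' Generate a synthetic two-channel photometry session
#'
#' The 405 nm control channel carries baseline + drift + motion artifact
#' + noise; the 470 nm channel carries a scaled copy of the same shared
#' component plus calcium transients (double-exponential kernel) at the
#' planted event times. Ground truth is stored in the session's
#' \code{groundTruth} slot for recovery tests. An \code{inZone} mask is
#' set for a few seconds after each zone entry.
#'
#' @param spec a \code{\link{photometrySpec}}
#' @return a \linkS4class{PhotometrySession}
#' @export
simulatePhotometry <- function(spec) {
    stopifnot(inherits(spec, "fosmap_photometry_spec"))
    set.seed(spec$seed)
    n <- as.integer(spec$duration * spec$hz) + 1L
    tt <- (seq_len(n) - 1) / spec$hz
    drift <- spec$driftAmplitude *
        sin(2 * pi * tt / max(spec$duration, 1) * runif(1, 0.5, 1.5) +
                runif(1, 0, 2 * pi))
    raw <- rnorm(n)
    w <- as.integer(max(1, spec$hz))   # ~1 s moving average
    art <- as.numeric(stats::filter(raw, rep(1 / w, w), sides = 2))
    art[is.na(art)] <- 0
    art <- spec$artifactAmplitude * art / max(sd(art), 1e-12)
    shared <- drift + art
    transients <- numeric(n)
    kern <- transientKernel(spec$hz, spec$riseTau, spec$decayTau)
    plantAt <- sort(unlist(spec$eventTimes[
        names(spec$eventTimes) %in% c("zone_entry", "door_opening")]))
    for (te in plantAt) {
        i0 <- round(te * spec$hz) + 1L
        idx <- i0:min(n, i0 + length(kern) - 1L)
        transients[idx] <- transients[idx] +
            spec$transientAmplitude * kern[seq_along(idx)]
    }
    s405 <- spec$baseline405 + shared + rnorm(n, 0, spec$noiseSd)
    s470 <- spec$baseline470 + spec$bleed * shared + transients +
        rnorm(n, 0, spec$noiseSd)
    inZone <- rep(FALSE, n)
    for (te in spec$eventTimes$zone_entry) {
        i0 <- round(te * spec$hz) + 1L
        inZone[i0:min(n, i0 + as.integer(4 * spec$hz))] <- TRUE
    }
    new("PhotometrySession", t = tt, s470 = s470, s405 = s405,
        events = lapply(spec$eventTimes, sort), inZone = inZone,
        sessionKind = spec$sessionKind,
        groundTruth = list(transientAmplitude = spec$transientAmplitude,
                           transientTimes = plantAt,
                           kernelWidth = spec$riseTau + 6 * spec$decayTau,
                           spec = spec))
}

#' Generate a synthetic retrograde-tracing dataset
#'
#' Per (rat, region) Fluoro-Gold, c-Fos and co-label counts, with the
#' target region's co-label percentage tied linearly to each rat's
#' door-opening percentage (slope planted); all other regions
#' uncorrelated.
#'
#' @param nRats number of rats (>= 4)
#' @param targetRegion region id whose co-labeling tracks behavior
#' @param slope co-label percent per door-opening percent
#' @param noiseSd residual SD of the co-label percentage
#' @param regions character vector of sampled region ids
#' @param seed mandatory integer seed
#' @return list with \code{counts} (data.frame rat_id, region_id,
#'   fg_count, cfos_count, colabel_count), \code{behavior} (data.frame
#'   rat_id, pct_door_openings, opener) and \code{groundTruth}
#' @export
simulateTracing <- function(nRats = 13L, targetRegion = "ACC",
                            slope = 0.4, noiseSd = 8,
                            regions = c("ACC", "PrL", "MO", "AI", "R07"),
                            seed) {
    if (missing(seed)) stop("seed is mandatory")
    if (nRats < 4) stop("need at least 4 rats")
    stopifnot(targetRegion %in% regions)
    set.seed(seed)
    rats <- sprintf("rat%02d", seq_len(nRats))
    pctOpen <- round(runif(nRats, 0, 100), 1)
    rows <- list()
    for (r in regions) {
        fg <- rpois(nRats, 120)
        pct <- if (r == targetRegion)
            slope * pctOpen + rnorm(nRats, 20, noiseSd)
        else runif(nRats, 10, 60)
        pct <- pmin(100, pmax(0, pct))
        co <- round(fg * pct / 100)
        cfos <- co + rpois(nRats, 80)
        rows[[r]] <- data.frame(rat_id = rats, region_id = r,
                                fg_count = fg, cfos_count = cfos,
                                colabel_count = co,
                                stringsAsFactors = FALSE)
    }
    list(counts = do.call(rbind, c(rows, make.row.names = FALSE)),
         behavior = data.frame(rat_id = rats, pct_door_openings = pctOpen,
                               opener = pctOpen > 50,
                               stringsAsFactors = FALSE),
         groundTruth = list(targetRegion = targetRegion, slope = slope))
}
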