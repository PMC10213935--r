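#' Construct a TrendSpec
#'
#' @param mediator panel mediator carrying the trend.
#' @param compartments compartments sharing the deterministic trend
#'   (noise stays independent per compartment).
#' @param dayRange numeric \code{c(start, end)} study-day span.
#' @param direction \code{"increasing"} or \code{"decreasing"}.
#' @param slope concentration units per day (> 0; sign comes from
#'   direction).
#' @param baseline concentration at the start of the trend. For a
#'   decreasing trend the baseline must be large enough that the signal
#'   stays non-negative over the span.
#' @return a \linkS4class{TrendSpec}.
#' @examples
#' trendSpec("IL-6", "skin", c(0, 11), "increasing", slope = 10)
#' @export
trendSpec <- function(mediator, compartments, dayRange,
                      direction = c("increasing", "decreasing"),
                      slope = 1, baseline = 100) {
    direction <- match.arg(direction)
    if (direction == "decreasing" &&
        baseline - slope * diff(range(dayRange)) < 0)
        stop("decreasing trend would cross zero: increase baseline or ",
             "reduce slope")
    new("TrendSpec", mediator = as.character(mediator),
        compartments = as.character(compartments),
        dayRange = as.numeric(dayRange), direction = direction,
        slope = as.numeric(slope), baseline = as.numeric(baseline))
}

#' Construct a SimConfig
#'
#' Defines one synthetic multi-compartment Luminex-like study: panel,
#' sampling schedule, per-group planted trends, group size, noise model
#' and master seed. Within a group, at most one TrendSpec may target a
#' given (mediator, compartment) pair.
#'
#' @param groups named list; each element a (possibly empty) list of
#'   \linkS4class{TrendSpec} objects for that experimental group.
#' @param panel a \linkS4class{MediatorPanel}
#'   (default [ratMediatorPanel()]).
#' @param schedule sampling days (default [ratSchedule()]).
#' @param nSubjects subjects per group (default 8).
#' @param noiseFamily \code{"lognormal"} multiplicative (default; keeps
#'   concentrations strictly positive and right-skewed, like real
#'   multiplex data) or \code{"gaussian"} additive (kept for closed-form
#'   checks; negative draws are clamped at 0).
#' @param sigma dispersion: log-sd for lognormal, sd in concentration
#'   units for gaussian; 0 disables noise.
#' @param baseline constant level of mediators without a trend.
#' @param seed master integer seed.
#' @return a \linkS4class{SimConfig}.
#' @seealso [simulateMediators()], [plantedTruth()], [demoSimConfig()]
#' @export
simConfig <- function(groups, panel = ratMediatorPanel(),
                      schedule = ratSchedule(), nSubjects = 8,
                      noiseFamily = c("lognormal", "gaussian"),
                      sigma = 0.3, baseline = 100, seed = 1) {
    noiseFamily <- match.arg(noiseFamily)
    for (g in names(groups)) {
        tgt <- unlist(lapply(groups[[g]], function(ts)
            paste(ts@mediator, ts@compartments, sep = "\r")))
        if (anyDuplicated(tgt))
            stop("group '", g, "': multiple trends target the same ",
                 "(mediator, compartment) pair")
    }
    new("SimConfig", panel = panel, schedule = as.numeric(schedule),
        groups = groups, nSubjects = as.integer(nSubjects),
        noiseFamily = noiseFamily, sigma = as.numeric(sigma),
        baseline = as.numeric(baseline), seed = as.integer(seed))
}

# Deterministic signal level of one trend at given days: baseline before
# the span, linear within, held at the final level after.
.trendSignal <- function(ts, days) {
    sgn <- if (ts@direction == "increasing") 1 else -1
    span <- pmin(pmax(days, ts@dayRange[1]), ts@dayRange[2]) - ts@dayRange[1]
    ts@baseline + sgn * ts@slope * span
}

# Noise-free signal matrix (mediators x days) for one group/compartment.
.signalMatrix <- function(config, group) {
    meds <- panelNames(config@panel)
    comps <- compartmentNames(config@panel)
    days <- config@schedule
    out <- list()
    for (comp in comps) {
        m <- matrix(config@baseline, length(meds), length(days),
                    dimnames = list(meds, as.character(days)))
        for (ts in config@groups[[group]]) {
            if (comp %in% ts@compartments)
                m[ts@mediator, ] <- .trendSignal(ts, days)
        }
        out[[comp]] <- m
    }
    out
}

# Stream seed for one (group index, subject index, compartment index).
# Index-based offsets keep existing groups' draws stable when a new group
# is appended to the config.
.streamSeed <- function(seed, gi, si, ci) {
    (abs(seed) + 1000003 * gi + 101 * si + 7919 * ci) %% 2147483629
}

#' Simulate a multi-compartment mediator study
#'
#' Generates a full synthetic dataset from a \linkS4class{SimConfig}:
#' for every subject, compartment, day and mediator, the deterministic
#' signal (baseline plus any planted linear trend) is perturbed by the
#' configured noise model. Random streams are split per
#' (group, subject, compartment) from the master seed, so the same config
#' always yields the same dataset and appending a group leaves other
#' groups' values untouched.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{experiment}
#'   (a \linkS4class{MediatorExperiment}) and \code{truth} (the
#'   [plantedTruth()] data.frame).
#' @examples
#' cfg <- simConfig(list(g1 = list(trendSpec("IL-6", "skin", c(0, 11),
#'                                           "increasing", slope = 10))),
#'                  nSubjects = 2, sigma = 0, seed = 7)
#' sim <- simulateMediators(cfg)
#' dim(sim$experiment)
#' @export
simulateMediators <- function(config) {
    stopifnot(is(config, "SimConfig"))
    methods::validObject(config)
    meds <- panelNames(config@panel)
    comps <- compartmentNames(config@panel)
    days <- config@schedule
    grps <- names(config@groups)
    nPer <- length(meds) * length(days)

    blocks <- vector("list",
                     length(grps) * config@nSubjects * length(comps))
    b <- 0L
    for (gi in seq_along(grps)) {
        sig <- .signalMatrix(config, grps[gi])
        for (si in seq_len(config@nSubjects)) {
            for (ci in seq_along(comps)) {
                set.seed(.streamSeed(config@seed, gi, si, ci))
                z <- matrix(stats::rnorm(nPer), length(meds), length(days))
                m <- sig[[comps[ci]]]
                vals <- if (config@sigma == 0) m
                        else if (config@noiseFamily == "lognormal")
                            m * exp(config@sigma * z)
                        else pmax(0, m + config@sigma * z)
                b <- b + 1L
                blocks[[b]] <- data.frame(
                    group = grps[gi],
                    subject = sprintf("s%02d", si),
                    compartment = comps[ci],
                    day = rep(days, each = length(meds)),
                    mediator = rep(meds, times = length(days)),
                    concentration = as.vector(vals),
                    stringsAsFactors = FALSE)
            }
        }
    }
    records <- do.call(rbind, blocks)
    exp <- MediatorExperiment(records, config@panel, comps,
                              schedule = days)
    list(experiment = exp, truth = plantedTruth(config))
}

#' Enumerate the ground truth planted by a SimConfig
#'
#' Derives, deterministically and without simulating, the set of
#' (group, mediator, compartment set, window, direction) tuples a
#' sliding-window trend detector must recover under zero noise: for each
#' TrendSpec, every 3-timepoint window lying fully inside its day range.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param width window width in time points (default 3).
#' @return data.frame with columns \code{group}, \code{mediator},
#'   \code{compartments} (labels joined by \code{"+"} in declared order),
#'   \code{windowIndex}, \code{windowDays} (days joined by \code{","}),
#'   \code{direction}; zero rows when nothing was planted.
#' @export
plantedTruth <- function(config, width = 3) {
    stopifnot(is(config, "SimConfig"))
    win <- makeWindows(config@schedule, width)
    comps <- compartmentNames(config@panel)
    rows <- list()
    for (g in names(config@groups)) {
        for (ts in config@groups[[g]]) {
            inside <- which(apply(win, 1, function(d)
                all(d >= ts@dayRange[1] & d <= ts@dayRange[2])))
            cset <- paste(comps[comps %in% ts@compartments],
                          collapse = "+")
            for (w in inside)
                rows[[length(rows) + 1L]] <- data.frame(
                    group = g, mediator = ts@mediator,
                    compartments = cset, windowIndex = w,
                    windowDays = paste(win[w, ], collapse = ","),
                    direction = ts@direction, stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(group = character(), mediator = character(),
                          compartments = character(),
                          windowIndex = integer(),
                          windowDays = character(),
                          direction = character()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Null rate of sliding-window trend edges
#'
#' `nullEdgeRate` estimates by Monte Carlo the probability that 3 iid
#' Gaussian values correlate with the (fixed) window days beyond the
#' trend threshold, i.e. the per-(mediator, compartment, window)
#' false-edge rate of the hypergraph detector on pure noise.
#' `nullEdgeRateExact` is the closed form for 3 points,
#' \deqn{P(|r| > c) = 1 - (2/\pi)\,\arctan\!\big(c/\sqrt{1-c^2}\big),}
#' which does not depend on the day spacing. At the default threshold
#' 0.95 this is about 0.202 — one reason the numeric r cutoff, not a
#' nominal p-value, is the operative criterion with 3 points.
#'
#' @param threshold trend |r| cutoff in (0, 1).
#' @param windowDays 3 distinct day values (spacing does not affect the
#'   rate; the argument documents the geometry being emulated).
#' @param nMc Monte-Carlo replicates (>= 1000).
#' @param seed RNG seed.
#' @return estimated (or exact) probability.
#' @examples
#' nullEdgeRateExact(0.95)
#' nullEdgeRate(0.95, c(0, 3, 5), nMc = 10000, seed = 1)
#' @export
nullEdgeRate <- function(threshold, windowDays = c(0, 3, 5), nMc = 1e5,
                         seed = 1) {
    if (threshold <= 0 || threshold >= 1)
        stop("threshold must lie strictly between 0 and 1")
    if (length(unique(windowDays)) != 3L)
        stop("windowDays must be 3 distinct days")
    if (nMc < 1000)
        stop("nMc must be at least 1000 for a usable estimate")
    set.seed(as.integer(seed))
    x <- as.numeric(windowDays)
    xc <- x - mean(x)
    y <- matrix(stats::rnorm(3 * nMc), nrow = 3)
    yc <- y - rep(colMeans(y), each = 3)
    r <- as.vector(crossprod(yc, xc)) /
        sqrt(sum(xc^2) * colSums(yc^2))
    mean(abs(r) > threshold)
}

#' @rdname nullEdgeRate
#' @export
nullEdgeRateExact <- function(threshold) {
    stopifnot(threshold >= 0, threshold <= 1)
    if (threshold == 1) return(0)
    1 - (2 / pi) * atan(threshold / sqrt(1 - threshold^2))
}

#' Bundled demonstration scenario
#'
#' A four-group rat-style study (syngeneic transplant with and without
#' nerve repair, allogeneic + tacrolimus with and without nerve repair;
#' n = 8 per group, 27-mediator panel, 11-day schedule) with planted
#' trends that qualitatively echo nerve-repair-associated
#' cross-compartment inflammation: early IL-6 in skin, IL-17A spanning
#' muscle and blood late after allogeneic transplant with nerve repair,
#' TNF-a/VEGF in skin and blood, and late IL-10 downregulation. The
#' scenario is illustrative synthetic data, not a reconstruction of any
#' experimental dataset.
#'
#' @param seed master seed (default 1).
#' @param sigma lognormal noise log-sd (default 0.3).
#' @param nSubjects subjects per group (default 8).
#' @return a \linkS4class{SimConfig}.
#' @export
demoSimConfig <- function(seed = 1, sigma = 0.3, nSubjects = 8) {
    simConfig(
        groups = list(
            syn = list(
                trendSpec("IL-6", "skin", c(0, 7), "increasing",
                          slope = 20, baseline = 100)),
            syn_NR = list(
                trendSpec("IL-6", c("skin", "blood"), c(0, 11),
                          "increasing", slope = 30, baseline = 100),
                trendSpec("IL-17A", c("skin", "muscle"), c(20, 31),
                          "decreasing", slope = 15, baseline = 400)),
            allo_TAC = list(
                trendSpec("MCP-1", "muscle", c(0, 9), "increasing",
                          slope = 25, baseline = 150),
                trendSpec("IL-10", "skin", c(20, 31), "decreasing",
                          slope = 10, baseline = 300)),
            allo_TAC_NR = list(
                trendSpec("IP-10", c("skin", "muscle", "blood"),
                          c(20, 27), "increasing", slope = 40,
                          baseline = 120),
                trendSpec("IL-17A", c("muscle", "blood"), c(23, 31),
                          "increasing", slope = 30, baseline = 100),
                trendSpec("TNF-a", c("skin", "blood"), c(23, 31),
                          "increasing", slope = 25, baseline = 100),
                trendSpec("VEGF", c("skin", "blood"), c(23, 31),
                          "increasing", slope = 20, baseline = 100),
                trendSpec("IL-10", c("skin", "muscle", "blood"),
                          c(0, 9), "decreasing", slope = 20,
                          baseline = 400))),
        nSubjects = nSubjects, sigma = sigma, seed = seed)
}
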