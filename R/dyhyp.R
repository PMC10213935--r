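utils::globalVariables(c("windowLabel", "count", "cardinality",
                         "direction"))

#' Sliding windows over a sampling schedule
#'
#' Enumerates all overlapping windows of \code{width} consecutive
#' schedule days, stepping one time point at a time. The 11-day rat-style
#' schedule yields 9 windows, the first (0, 3, 5) and the last
#' (25, 27, 31); windows spanning gaps in the schedule (e.g. day 11 to
#' day 20) are kept, since trend correlations are computed against
#' calendar day.
#'
#' @param schedule strictly increasing numeric sampling days.
#' @param width window width in time points (default 3).
#' @return numeric matrix with one row per window (rownames
#'   \code{"w1"..."wK"}, K = length(schedule) - width + 1) and
#'   \code{width} columns \code{d1..dwidth}.
#' @examples
#' makeWindows(ratSchedule())
#' @export
makeWindows <- function(schedule, width = 3) {
    schedule <- as.numeric(schedule)
    if (is.unsorted(schedule, strictly = TRUE))
        stop("schedule must be strictly increasing")
    if (length(schedule) < width)
        stop("schedule has ", length(schedule),
             " days; at least ", width, " are required")
    k <- length(schedule) - width + 1L
    out <- t(vapply(seq_len(k),
                    function(i) schedule[i:(i + width - 1L)],
                    numeric(width)))
    dimnames(out) <- list(paste0("w", seq_len(k)),
                          paste0("d", seq_len(width)))
    out
}

#' Trend correlation of mediator values against window days
#'
#' Pearson correlation of a mediator's summary values against the
#' calendar days of one window. Returns \code{NA} (no trend assessable)
#' when any value is missing or the values have zero variance.
#'
#' @param values numeric vector of mediator summary values, one per
#'   window day.
#' @param days the window days (same length).
#' @return correlation in [-1, 1], or \code{NA}.
#' @examples
#' trendR(c(1, 2, 3), c(0, 3, 5))  # 0.9934...
#' @export
trendR <- function(values, days) {
    if (length(values) != length(days))
        stop("values and days must have equal length")
    if (anyNA(values)) return(NA_real_)
    if (stats::sd(values) == 0) return(NA_real_)
    stats::cor(values, as.numeric(days))
}

#' Build the dynamic hypergraph of one window
#'
#' For each mediator and each compartment, correlates the per-day summary
#' values against calendar day over the window. Compartments where
#' r > threshold join the mediator's increasing hyperedge; compartments
#' where r < -threshold join its decreasing hyperedge (comparisons are
#' strict). A mediator passing nowhere contributes no edge; a mediator
#' can thus carry at most one edge per direction, and the same
#' compartment never appears in both. (Mediator, compartment) cells that
#' are missing or constant over the window are skipped and logged in the
#' \code{skipped} slot.
#'
#' @param timecourses named list of \linkS4class{TimeCourse}, one per
#'   compartment (names = compartment labels), sharing panel and
#'   schedule.
#' @param window numeric vector of window days (a row of
#'   [makeWindows()]), all present in the shared schedule.
#' @param threshold trend |r| cutoff (default 0.95).
#' @param index window position in its series (bookkeeping; default
#'   \code{NA}).
#' @param timeMode correlate against \code{"day"} (calendar day, default)
#'   or \code{"index"} (time-point rank within the window).
#' @return a \linkS4class{DyHypGraph}.
#' @examples
#' cfg <- simConfig(list(g = list(trendSpec("IL-6", "skin", c(0, 11),
#'                                          "increasing", slope = 10))),
#'                  nSubjects = 2, sigma = 0)
#' sim <- simulateMediators(cfg)
#' tcs <- lapply(setNames(nm = c("skin", "muscle", "blood")),
#'               function(cc) aggregateTimeCourse(sim$experiment, "g", cc))
#' hg <- buildHypergraph(tcs, c(0, 3, 5))
#' hypergraphEdges(hg)
#' @export
buildHypergraph <- function(timecourses, window, threshold = 0.95,
                            index = NA_integer_,
                            timeMode = c("day", "index")) {
    timeMode <- match.arg(timeMode)
    stopifnot(length(timecourses) >= 1,
              all(vapply(timecourses, is, TRUE, "TimeCourse")))
    comps <- names(timecourses)
    if (is.null(comps) || any(!nzchar(comps)))
        stop("timecourses must be a named list (names = compartments)")
    sched <- studySchedule(timecourses[[1]])
    meds <- rownames(timeCourseValues(timecourses[[1]]))
    for (tc in timecourses) {
        if (!identical(studySchedule(tc), sched) ||
            !identical(rownames(timeCourseValues(tc)), meds))
            stop("all time courses must share panel and schedule")
    }
    window <- as.numeric(window)
    if (!all(window %in% sched))
        stop("window days must belong to the shared schedule")
    cols <- match(window, sched)
    xs <- if (timeMode == "day") window else seq_along(window)

    rMat <- matrix(NA_real_, length(meds), length(comps),
                   dimnames = list(meds, comps))
    skipped <- list()
    for (cc in comps) {
        vals <- timeCourseValues(timecourses[[cc]])[, cols, drop = FALSE]
        for (m in meds) {
            v <- vals[m, ]
            if (anyNA(v) || stats::sd(v) == 0) {
                skipped[[length(skipped) + 1L]] <- data.frame(
                    mediator = m, compartment = cc,
                    reason = if (anyNA(v)) "missing value"
                             else "zero variance",
                    stringsAsFactors = FALSE)
                next
            }
            rMat[m, cc] <- stats::cor(v, xs)
        }
    }

    edges <- list()
    for (m in meds) {
        up <- comps[!is.na(rMat[m, ]) & rMat[m, ] > threshold]
        dn <- comps[!is.na(rMat[m, ]) & rMat[m, ] < -threshold]
        if (length(up))
            edges[[length(edges) + 1L]] <- list(
                mediator = m, direction = "increasing",
                compartments = up, r = rMat[m, up])
        if (length(dn))
            edges[[length(edges) + 1L]] <- list(
                mediator = m, direction = "decreasing",
                compartments = dn, r = rMat[m, dn])
    }
    edgeDf <- if (length(edges)) data.frame(
        mediator = vapply(edges, `[[`, "", "mediator"),
        direction = vapply(edges, `[[`, "", "direction"),
        compartments = I(lapply(edges, `[[`, "compartments")),
        r = I(lapply(edges, `[[`, "r")),
        stringsAsFactors = FALSE)
    else data.frame(mediator = character(), direction = character(),
                    compartments = I(list()), r = I(list()))
    skippedDf <- if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(mediator = character(),
                                 compartment = character(),
                                 reason = character())
    new("DyHypGraph", window = window, index = as.integer(index),
        vertices = comps, edges = edgeDf, threshold = threshold,
        skipped = skippedDf)
}

#' Hyperedges of a DyHypGraph as a flat table
#'
#' @param x a \linkS4class{DyHypGraph}.
#' @return data.frame with one row per hyperedge: \code{mediator},
#'   \code{direction}, \code{cardinality}, \code{compartments}
#'   (labels joined by \code{"+"} in vertex order) and \code{rMin}
#'   (weakest per-compartment |r| in the edge).
#' @export
hypergraphEdges <- function(x) {
    stopifnot(is(x, "DyHypGraph"))
    e <- x@edges
    if (!nrow(e))
        return(data.frame(mediator = character(),
                          direction = character(),
                          cardinality = integer(),
                          compartments = character(),
                          rMin = numeric()))
    data.frame(
        mediator = e$mediator, direction = e$direction,
        cardinality = vapply(e$compartments, length, 1L),
        compartments = vapply(e$compartments, function(cc)
            paste(x@vertices[x@vertices %in% cc], collapse = "+"), ""),
        rMin = vapply(e$r, function(r) min(abs(r)), 1),
        stringsAsFactors = FALSE)
}

#' @describeIn edgeDistribution tally of hyperedges by compartment count
#'   and direction, including zero cells, for one window.
#' @export
setMethod("edgeDistribution", "DyHypGraph", function(x) {
    cards <- seq_along(x@vertices)
    grid <- expand.grid(cardinality = cards,
                        direction = c("increasing", "decreasing"),
                        stringsAsFactors = FALSE)
    e <- hypergraphEdges(x)
    grid$count <- vapply(seq_len(nrow(grid)), function(i)
        sum(e$cardinality == grid$cardinality[i] &
            e$direction == grid$direction[i]), 1L)
    grid
})

#' Dynamic hypergraph series over all sliding windows
#'
#' Aggregates one experimental group into per-compartment mean time
#' courses ([aggregateTimeCourse()]), then builds one hypergraph and edge
#' distribution per overlapping 3-point window, in window order.
#'
#' @param x a \linkS4class{MediatorExperiment}.
#' @param group the experimental group to analyze.
#' @param threshold trend |r| cutoff (default 0.95).
#' @param compartments compartments to use as vertices (default: all
#'   present for the group).
#' @param width window width (default 3).
#' @param timeMode passed to [buildHypergraph()].
#' @return list with elements \code{windows} (the [makeWindows()]
#'   matrix), \code{graphs} (list of \linkS4class{DyHypGraph}) and
#'   \code{distribution} (tidy data.frame: window index, first/last day,
#'   cardinality, direction, count).
#' @examples
#' sim <- simulateMediators(demoSimConfig(seed = 1, sigma = 0))
#' ser <- distributionSeries(sim$experiment, "allo_TAC_NR")
#' head(ser$distribution[ser$distribution$count > 0, ])
#' @export
distributionSeries <- function(x, group, threshold = 0.95,
                               compartments = NULL, width = 3,
                               timeMode = c("day", "index")) {
    stopifnot(is(x, "MediatorExperiment"))
    timeMode <- match.arg(timeMode)
    cd <- colData(x)
    if (!group %in% cd$group) stop("group '", group, "' not in data")
    if (is.null(compartments)) {
        present <- unique(cd$compartment[cd$group == group])
        declared <- compartmentNames(mediatorPanelOf(x))
        compartments <- declared[declared %in% present]
    }
    win <- makeWindows(studySchedule(x), width)
    tcs <- lapply(stats::setNames(nm = compartments), function(cc)
        aggregateTimeCourse(x, group, cc, "mean"))
    graphs <- lapply(seq_len(nrow(win)), function(i)
        buildHypergraph(tcs, win[i, ], threshold = threshold,
                        index = i, timeMode = timeMode))
    dist <- do.call(rbind, lapply(seq_along(graphs), function(i) {
        d <- edgeDistribution(graphs[[i]])
        cbind(window = i, dayStart = win[i, 1],
              dayEnd = win[i, ncol(win)], d)
    }))
    rownames(dist) <- NULL
    list(windows = win, graphs = graphs, distribution = dist)
}

#' Bar chart of an edge-distribution series
#'
#' Optional \pkg{ggplot2} rendering of the per-window hyperedge tallies:
#' one panel per direction, bars stacked by the number of compartments
#' each edge spans.
#'
#' @param distribution the tidy distribution data.frame from
#'   [distributionSeries()].
#' @return a ggplot object.
#' @export
plotEdgeDistribution <- function(distribution) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("plotEdgeDistribution requires the 'ggplot2' package")
    distribution$windowLabel <- sprintf("d%g-d%g",
                                        distribution$dayStart,
                                        distribution$dayEnd)
    distribution$windowLabel <- factor(
        distribution$windowLabel,
        levels = unique(distribution$windowLabel[
            order(distribution$window)]))
    ggplot2::ggplot(distribution,
                    ggplot2::aes(x = windowLabel, y = count,
                                 fill = factor(cardinality))) +
        ggplot2::geom_col() +
        ggplot2::facet_wrap(~direction, ncol = 1) +
        ggplot2::labs(x = "dynamic time interval", y = "edges",
                      fill = "compartments\nspanned") +
        ggplot2::theme_minimal()
}

setMethod("show", "DyHypGraph", function(object) {
    cat("DyHypGraph window (",
        paste(object@window, collapse = ", "), "), |r| > ",
        object@threshold, "\n", sep = "")
    e <- hypergraphEdges(object)
    cat("  vertices:", paste(object@vertices, collapse = ", "), "\n")
    cat("  edges:", nrow(e),
        sprintf("(%d increasing, %d decreasing)\n",
                sum(e$direction == "increasing"),
                sum(e$direction == "decreasing")))
    if (nrow(object@skipped))
        cat("  skipped cells:", nrow(object@skipped), "\n")
})
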