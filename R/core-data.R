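#' Construct a MediatorExperiment from long-format records
#'
#' Builds the validated container from a data.frame with one row per
#' measurement, keyed by \code{group}, \code{subject}, \code{compartment},
#' \code{day}, \code{mediator}, with a \code{concentration} column.
#' Validation failures are collected across rows and reported together,
#' citing the offending row numbers; rows are never dropped silently.
#'
#' @param records data.frame with the six canonical columns.
#' @param panel a \linkS4class{MediatorPanel}; every record's mediator
#'   must belong to it.
#' @param compartments compartment labels admitted for this study; must be
#'   a subset of the panel's declared compartments. Default: all declared.
#' @param schedule sampling days; default: sorted unique days observed.
#' @return a \linkS4class{MediatorExperiment}. Mediator/day cells never
#'   measured for a sample are \code{NA}.
#' @examples
#' rec <- data.frame(group = "syn", subject = "r1", compartment = "skin",
#'                   day = c(0, 3, 5), mediator = "IL-6",
#'                   concentration = c(1, 2, 3))
#' me <- MediatorExperiment(rec, ratMediatorPanel())
#' studySchedule(me)
#' @export
MediatorExperiment <- function(records, panel,
                               compartments = compartmentNames(panel),
                               schedule = NULL) {
    stopifnot(is(panel, "MediatorPanel"))
    need <- c("group", "subject", "compartment", "day", "mediator",
              "concentration")
    miss <- setdiff(need, colnames(records))
    if (length(miss))
        stop("records lack column(s): ", paste(miss, collapse = ", "))
    bad <- setdiff(compartments, compartmentNames(panel))
    if (length(bad))
        stop("compartment(s) not declared in panel: ",
             paste(bad, collapse = ", "))
    records$concentration <- as.numeric(records$concentration)
    records$day <- as.numeric(records$day)

    probs <- character()
    rowmsg <- function(i, what)
        sprintf("row %d: %s", i, what)
    badMed <- which(!records$mediator %in% panelNames(panel))
    for (i in badMed)
        probs <- c(probs, rowmsg(i, paste0("unknown mediator '",
                                           records$mediator[i], "'")))
    badComp <- which(!records$compartment %in% compartments)
    for (i in badComp)
        probs <- c(probs, rowmsg(i, paste0("unknown compartment '",
                                           records$compartment[i], "'")))
    badConc <- which(!is.na(records$concentration) &
                     records$concentration < 0)
    for (i in badConc)
        probs <- c(probs, rowmsg(i, "negative concentration"))
    badDay <- which(is.na(records$day) | records$day < 0)
    for (i in badDay)
        probs <- c(probs, rowmsg(i, "day must be a non-negative number"))
    key <- paste(records$group, records$subject, records$compartment,
                 records$day, records$mediator, sep = "\r")
    dup <- which(duplicated(key))
    for (i in dup)
        probs <- c(probs, rowmsg(i, paste0(
            "duplicate {group, subject, compartment, day, mediator} key (",
            records$group[i], ", ", records$subject[i], ", ",
            records$compartment[i], ", ", records$day[i], ", ",
            records$mediator[i], ")")))
    if (length(probs))
        stop("invalid mediator records:\n  ",
             paste(probs, collapse = "\n  "), call. = FALSE)

    if (is.null(schedule))
        schedule <- sort(unique(records$day))
    schedule <- as.numeric(schedule)
    offSched <- which(!records$day %in% schedule)
    if (length(offSched))
        stop("invalid mediator records:\n  ",
             paste(vapply(offSched, function(i)
                 rowmsg(i, paste0("day ", records$day[i],
                                  " not in schedule")), ""),
                 collapse = "\n  "), call. = FALSE)

    skey <- paste(records$group, records$subject, records$compartment,
                  records$day, sep = "\r")
    samples <- !duplicated(skey)
    cd <- DataFrame(group = as.character(records$group[samples]),
                    subject = as.character(records$subject[samples]),
                    compartment = as.character(records$compartment[samples]),
                    day = records$day[samples])
    ord <- order(cd$group, cd$subject, cd$compartment, cd$day)
    cd <- cd[ord, ]
    sampleIds <- paste(cd$group, cd$subject, cd$compartment, cd$day,
                       sep = ".")
    rownames(cd) <- sampleIds

    mat <- matrix(NA_real_, nrow = length(panelNames(panel)),
                  ncol = nrow(cd),
                  dimnames = list(panelNames(panel), sampleIds))
    colIdx <- match(skey, paste(cd$group, cd$subject, cd$compartment,
                                cd$day, sep = "\r"))
    rowIdx <- match(records$mediator, panelNames(panel))
    mat[cbind(rowIdx, colIdx)] <- records$concentration

    new("MediatorExperiment",
        SummarizedExperiment(assays = list(concentration = mat),
                             colData = cd),
        panel = panel, schedule = schedule)
}

#' Read a long-format mediator table from CSV
#'
#' Parses the canonical long/tidy dialect (RFC-4180 CSV, UTF-8, dot
#' decimal separator) with header columns \code{group}, \code{subject},
#' \code{compartment}, \code{day}, \code{mediator}, \code{concentration}.
#' Empty concentration cells are missing values. All validation failures
#' (unknown mediator or compartment, negative concentration, duplicate
#' key) are reported together with their row numbers.
#'
#' @param path path to the CSV file.
#' @inheritParams MediatorExperiment
#' @return a \linkS4class{MediatorExperiment}.
#' @seealso [writeMediatorTable()] for the inverse.
#' @export
readMediatorTable <- function(path, panel,
                              compartments = compartmentNames(panel),
                              schedule = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(concentration = "character"))
    need <- c("group", "subject", "compartment", "day", "mediator",
              "concentration")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("CSV header lacks column(s): ", paste(miss, collapse = ", "))
    conc <- trimws(df$concentration)
    df$concentration <- ifelse(nzchar(conc), suppressWarnings(as.numeric(conc)),
                               NA_real_)
    badNum <- which(nzchar(conc) & is.na(df$concentration))
    if (length(badNum))
        stop("invalid mediator records:\n  ",
             paste(sprintf("row %d: non-numeric concentration '%s'",
                           badNum, conc[badNum]), collapse = "\n  "),
             call. = FALSE)
    MediatorExperiment(df, panel, compartments, schedule)
}

#' Write a MediatorExperiment to the canonical CSV dialect
#'
#' The inverse of [readMediatorTable()]: one row per measured
#' \{group, subject, compartment, day, mediator\} cell, concentrations
#' serialized at full double precision (17 significant digits) so that a
#' write/read round trip reproduces the dataset exactly. Missing cells are
#' not written.
#'
#' @param x a \linkS4class{MediatorExperiment}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeMediatorTable <- function(x, path) {
    stopifnot(is(x, "MediatorExperiment"))
    df <- asLongTable(x)
    df$concentration <- sprintf("%.17g", df$concentration)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Flatten a MediatorExperiment to a long-format data.frame
#'
#' @param x a \linkS4class{MediatorExperiment}.
#' @param keepMissing keep rows for unmeasured (NA) cells? Default drops
#'   them.
#' @return data.frame with the six canonical columns, ordered by
#'   group, subject, compartment, day, then panel order.
#' @export
asLongTable <- function(x, keepMissing = FALSE) {
    stopifnot(is(x, "MediatorExperiment"))
    a <- assay(x, "concentration")
    cd <- colData(x)
    df <- data.frame(
        group = rep(cd$group, each = nrow(a)),
        subject = rep(cd$subject, each = nrow(a)),
        compartment = rep(cd$compartment, each = nrow(a)),
        day = rep(cd$day, each = nrow(a)),
        mediator = rep(rownames(a), times = ncol(a)),
        concentration = as.vector(a),
        stringsAsFactors = FALSE)
    if (!keepMissing) df <- df[!is.na(df$concentration), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Aggregate replicate measurements into a summary time course
#'
#' For one experimental group and one compartment, summarizes all
#' subjects' concentrations per (mediator, day) cell with the mean
#' (default, matching the usual "mean +/- SEM" presentation) or the
#' median. Cells with no measurements are \code{NA} with replicate count
#' 0; no imputation is performed.
#'
#' @param x a \linkS4class{MediatorExperiment}.
#' @param group,compartment the stratum to summarize; both must be present
#'   in the data.
#' @param summaryStat \code{"mean"} (default) or \code{"median"}.
#' @return a \linkS4class{TimeCourse}.
#' @examples
#' rec <- data.frame(group = "syn", subject = c("r1", "r2"),
#'                   compartment = "skin", day = 3, mediator = "IL-6",
#'                   concentration = c(10, 20))
#' tc <- aggregateTimeCourse(MediatorExperiment(rec, ratMediatorPanel()),
#'                           "syn", "skin")
#' timeCourseValues(tc)["IL-6", "3"]  # 15
#' @export
aggregateTimeCourse <- function(x, group, compartment,
                                summaryStat = c("mean", "median")) {
    stopifnot(is(x, "MediatorExperiment"))
    summaryStat <- match.arg(summaryStat)
    cd <- colData(x)
    sel <- cd$group == group & cd$compartment == compartment
    if (!any(sel))
        stop("no samples for group '", group, "' in compartment '",
             compartment, "'")
    a <- assay(x, "concentration")[, sel, drop = FALSE]
    days <- cd$day[sel]
    sched <- studySchedule(x)
    fn <- if (summaryStat == "mean") mean else stats::median
    vals <- matrix(NA_real_, nrow(a), length(sched),
                   dimnames = list(rownames(a), as.character(sched)))
    nrep <- matrix(0L, nrow(a), length(sched),
                   dimnames = dimnames(vals))
    for (j in seq_along(sched)) {
        cols <- which(days == sched[j])
        if (!length(cols)) next
        sub <- a[, cols, drop = FALSE]
        nrep[, j] <- as.integer(rowSums(!is.na(sub)))
        has <- nrep[, j] > 0L
        vals[has, j] <- apply(sub[has, , drop = FALSE], 1, fn,
                              na.rm = TRUE)
    }
    new("TimeCourse", group = as.character(group),
        compartment = as.character(compartment), values = vals,
        nPerCell = nrep, summaryStat = summaryStat, schedule = sched)
}

#' TimeCourse accessors
#'
#' @param x a \linkS4class{TimeCourse}.
#' @return \code{timeCourseValues}: the mediators-by-days summary matrix
#'   (columns named by study day); \code{replicateCounts}: the matching
#'   integer matrix of per-cell replicate counts.
#' @export
timeCourseValues <- function(x) {
    stopifnot(is(x, "TimeCourse"))
    x@values
}

#' @rdname timeCourseValues
#' @export
replicateCounts <- function(x) {
    stopifnot(is(x, "TimeCourse"))
    x@nPerCell
}

#' @rdname accessors
#' @export
setMethod("panelNames", "MediatorExperiment",
          function(x) panelNames(x@panel))

#' @rdname accessors
#' @export
setMethod("compartmentNames", "MediatorExperiment",
          function(x) sort(unique(colData(x)$compartment)))

#' @rdname accessors
#' @export
setMethod("studySchedule", "MediatorExperiment", function(x) x@schedule)

#' @rdname accessors
#' @export
setMethod("studyGroups", "MediatorExperiment",
          function(x) sort(unique(colData(x)$group)))

#' @rdname accessors
#' @export
setMethod("mediatorPanelOf", "MediatorExperiment", function(x) x@panel)

#' @rdname accessors
#' @export
setMethod("studySchedule", "TimeCourse", function(x) x@schedule)

setMethod("show", "MediatorExperiment", function(object) {
    methods::callNextMethod()
    cat("panel:", length(panelNames(object)), "mediators |",
        "groups:", paste(studyGroups(object), collapse = ", "), "|",
        "schedule:", paste(studySchedule(object), collapse = ","), "\n")
})

setMethod("show", "TimeCourse", function(object) {
    cat("TimeCourse (", object@summaryStat, ") for group '",
        object@group, "', compartment '", object@compartment, "'\n",
        sep = "")
    cat("  ", nrow(object@values), " mediators x ",
        length(object@schedule), " days; ",
        sum(object@nPerCell == 0L), " empty cells\n", sep = "")
})
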