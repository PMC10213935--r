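#' Dynamic Network Analysis over consecutive ordinal strata
#'
#' Builds one mediator-mediator correlation network per pair of
#' consecutive strata in an ordinal series (e.g. rejection-severity
#' grades G0-G4, or time bins). Within each interval, all samples whose
#' stratum is one of the two consecutive labels are pooled; an undirected
#' edge joins two mediators when the absolute Pearson correlation of
#' their concentrations across those samples reaches the threshold
#' (default 0.90), operationalizing "trajectories that move in parallel".
#' Mediators with zero variance in an interval carry no edges; mediator
#' pairs with fewer than 3 pairwise-complete observations are skipped and
#' logged. An interval with fewer than 3 samples yields a network flagged
#' unevaluable rather than silently empty.
#'
#' @param x a \linkS4class{MediatorExperiment}.
#' @param strata ordinal stratum label for every sample: either a vector
#'   aligned with \code{colnames(x)} (optionally named by sample id) or a
#'   function of the per-sample colData row returning a label.
#' @param ordering the ordinal labels in order (e.g.
#'   \code{c("G0","G1","G2","G3","G4")}).
#' @param threshold |r| cutoff in (0, 1] (default 0.90; the comparison is
#'   >=).
#' @return list of \linkS4class{DynaNetwork}, one per consecutive pair of
#'   \code{ordering}, named \code{"lower-upper"}.
#' @seealso [complexity()]
#' @export
buildDynaNetworks <- function(x, strata, ordering, threshold = 0.90) {
    stopifnot(is(x, "MediatorExperiment"))
    if (threshold <= 0 || threshold > 1)
        stop("threshold must lie in (0, 1]")
    if (length(ordering) < 2L)
        stop("at least 2 consecutive strata are required")
    cd <- colData(x)
    if (is.function(strata)) {
        strata <- vapply(seq_len(nrow(cd)),
                         function(i) as.character(strata(cd[i, ])), "")
    } else if (!is.null(names(strata))) {
        strata <- as.character(strata[colnames(x)])
    } else {
        if (length(strata) != ncol(x))
            stop("strata must supply one label per sample")
        strata <- as.character(strata)
    }
    unknown <- setdiff(stats::na.omit(unique(strata)), ordering)
    if (length(unknown))
        stop("stratum label(s) not in ordering: ",
             paste(unknown, collapse = ", "))

    a <- assay(x, "concentration")
    meds <- panelNames(x)
    out <- list()
    for (k in seq_len(length(ordering) - 1L)) {
        lower <- ordering[k]
        upper <- ordering[k + 1L]
        sel <- which(!is.na(strata) & strata %in% c(lower, upper))
        net <- .dynaInterval(a[, sel, drop = FALSE], meds, lower, upper,
                             threshold)
        out[[paste(lower, upper, sep = "-")]] <- net
    }
    out
}

# One interval: all-pairs Pearson screen with pairwise-complete deletion.
.dynaInterval <- function(a, meds, lower, upper, threshold) {
    emptyEdges <- data.frame(mediatorA = character(),
                             mediatorB = character(), r = numeric())
    if (ncol(a) < 3L)
        return(new("DynaNetwork", lower = lower, upper = upper,
                   nodes = meds, edges = emptyEdges,
                   threshold = threshold, nSamples = ncol(a),
                   evaluable = FALSE))
    nPair <- crossprod(!is.na(t(a)))
    r <- suppressWarnings(
        stats::cor(t(a), use = "pairwise.complete.obs"))
    ok <- upper.tri(r) & !is.na(r) & nPair >= 3L &
        abs(r) >= threshold - 1e-12
    idx <- which(ok, arr.ind = TRUE)
    edges <- if (nrow(idx)) data.frame(mediatorA = meds[idx[, 1]],
                                       mediatorB = meds[idx[, 2]],
                                       r = r[idx],
                                       stringsAsFactors = FALSE)
             else emptyEdges
    skipped <- which(upper.tri(r) & nPair < 3L, arr.ind = TRUE)
    net <- new("DynaNetwork", lower = lower, upper = upper,
               nodes = meds, edges = edges, threshold = threshold,
               nSamples = ncol(a), evaluable = TRUE)
    attr(net, "skippedPairs") <-
        if (nrow(skipped)) data.frame(mediatorA = meds[skipped[, 1]],
                                      mediatorB = meds[skipped[, 2]])
        else data.frame(mediatorA = character(), mediatorB = character())
    net
}

#' @describeIn complexity degree-sum complexity of one interval network;
#'   errors for fewer than 2 mediators and returns \code{NA} for an
#'   unevaluable interval.
#' @export
setMethod("complexity", "DynaNetwork", function(x) {
    n <- length(x@nodes)
    if (n < 2L) stop("complexity requires at least 2 mediators")
    if (!x@evaluable) return(NA_real_)
    2 * nrow(x@edges) / (n - 1)
})

#' Edge list and per-interval summary of DyNA networks
#'
#' `dynaEdgeTable` binds the edge lists of a network series into one tidy
#' data.frame; `dynaSummary` gives one row per interval with node count,
#' edge count, sample count and complexity.
#'
#' @param networks list of \linkS4class{DynaNetwork} from
#'   [buildDynaNetworks()].
#' @return a data.frame.
#' @export
dynaEdgeTable <- function(networks) {
    rows <- lapply(networks, function(net) {
        if (!nrow(net@edges)) return(NULL)
        cbind(interval = paste(net@lower, net@upper, sep = "-"),
              net@edges, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(interval = character(),
                          mediatorA = character(),
                          mediatorB = character(), r = numeric())
    rownames(out) <- NULL
    out
}

#' @rdname dynaEdgeTable
#' @export
dynaSummary <- function(networks) {
    out <- do.call(rbind, lapply(networks, function(net) data.frame(
        interval = paste(net@lower, net@upper, sep = "-"),
        nMediators = length(net@nodes),
        nSamples = net@nSamples,
        nEdges = nrow(net@edges),
        evaluable = net@evaluable,
        complexity = if (net@evaluable) complexity(net) else NA_real_,
        stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
}

setMethod("show", "DynaNetwork", function(object) {
    cat("DynaNetwork ", object@lower, "-", object@upper, ": ",
        nrow(object@edges), " edges over ", length(object@nodes),
        " mediators (", object@nSamples, " samples, |r| >= ",
        object@threshold, ")\n", sep = "")
    if (!object@evaluable)
        cat("  UNEVALUABLE: fewer than 3 samples in interval\n")
    else
        cat("  complexity:", format(complexity(object), digits = 4), "\n")
})
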