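#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' MediatorPanel: an ordered multiplex analyte panel
#'
#' Describes the set of mediators (cytokines, chemokines, growth factors)
#' quantified by a multiplex immunoassay bead set, together with the
#' measurement unit used in each tissue compartment (typically
#' \code{"pg/mg protein"} for solid tissue homogenates and \code{"pg/ml"}
#' for fluids such as peripheral blood).
#'
#' @slot names character vector of unique, non-empty mediator identifiers,
#'   in panel order.
#' @slot unitsByCompartment named character vector mapping each declared
#'   compartment to its unit string; the names define the compartment set.
#'
#' @seealso [ratMediatorPanel()], [humanMediatorPanel()]
#' @export
setClass("MediatorPanel",
    representation(names = "character", unitsByCompartment = "character"))

setValidity("MediatorPanel", function(object) {
    msg <- character()
    if (length(object@names) == 0L)
        msg <- c(msg, "panel must contain at least one mediator")
    if (anyDuplicated(object@names))
        msg <- c(msg, "mediator names must be unique")
    if (any(!nzchar(object@names)))
        msg <- c(msg, "mediator names must be non-empty")
    if (length(object@unitsByCompartment) == 0L ||
        is.null(names(object@unitsByCompartment)) ||
        any(!nzchar(names(object@unitsByCompartment))))
        msg <- c(msg, "unitsByCompartment must be a named character vector")
    if (anyDuplicated(names(object@unitsByCompartment)))
        msg <- c(msg, "compartment names must be unique")
    if (length(msg)) msg else TRUE
})

#' MediatorExperiment: validated multi-compartment mediator measurements
#'
#' A \linkS4class{SummarizedExperiment} whose rows are panel mediators and
#' whose columns are individual samples, one per
#' \{group, subject, compartment, day\} key. The single assay
#' (\code{"concentration"}) holds non-negative concentrations in panel
#' units, with \code{NA} for missing measurements. Column metadata carries
#' \code{group}, \code{subject}, \code{compartment} and \code{day};
#' \code{day} is calendar study day (the sampling schedule may be unevenly
#' spaced, so day is never treated as an index).
#'
#' @slot panel a \linkS4class{MediatorPanel}; rownames equal
#'   \code{panelNames(panel)}.
#' @slot schedule strictly increasing numeric vector of sampling days;
#'   every sample's day belongs to it.
#'
#' @seealso [MediatorExperiment()], [readMediatorTable()],
#'   [aggregateTimeCourse()]
#' @export
setClass("MediatorExperiment",
    contains = "SummarizedExperiment",
    representation(panel = "MediatorPanel", schedule = "numeric"))

setValidity("MediatorExperiment", function(object) {
    msg <- character()
    if (!"concentration" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'concentration' is required")
    if (!identical(rownames(object), object@panel@names))
        msg <- c(msg, "rownames must equal the panel mediator names")
    cd <- colData(object)
    need <- c("group", "subject", "compartment", "day")
    miss <- setdiff(need, colnames(cd))
    if (length(miss)) {
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
        return(msg)
    }
    if (is.unsorted(object@schedule, strictly = TRUE))
        msg <- c(msg, "schedule must be strictly increasing")
    if (!all(cd$day %in% object@schedule))
        msg <- c(msg, "every sample day must belong to the schedule")
    comps <- names(object@panel@unitsByCompartment)
    if (!all(cd$compartment %in% comps))
        msg <- c(msg, "every sample compartment must be declared in the panel")
    key <- paste(cd$group, cd$subject, cd$compartment, cd$day, sep = "\r")
    if (anyDuplicated(key))
        msg <- c(msg, "duplicate {group, subject, compartment, day} sample key")
    a <- assay(object, "concentration")
    if (any(a < 0, na.rm = TRUE))
        msg <- c(msg, "concentrations must be non-negative or NA")
    if (length(msg)) msg else TRUE
})

#' TimeCourse: per-group, per-compartment summary time course
#'
#' Replicate measurements aggregated (mean or median over subjects) into a
#' mediators-by-days matrix for one experimental group and one tissue
#' compartment. Cells with no replicates are \code{NA} with a replicate
#' count of zero; they are never imputed.
#'
#' @slot group,compartment labels identifying the stratum summarized.
#' @slot values numeric matrix, mediators (rows) by schedule days (columns).
#' @slot nPerCell integer matrix of replicate counts, same dimensions.
#' @slot summaryStat \code{"mean"} or \code{"median"}.
#' @slot schedule the sampling days (column order of \code{values}).
#'
#' @seealso [aggregateTimeCourse()]
#' @export
setClass("TimeCourse",
    representation(group = "character", compartment = "character",
                   values = "matrix", nPerCell = "matrix",
                   summaryStat = "character", schedule = "numeric"))

setValidity("TimeCourse", function(object) {
    msg <- character()
    if (!identical(dim(object@values), dim(object@nPerCell)))
        msg <- c(msg, "values and nPerCell must have identical dimensions")
    if (ncol(object@values) != length(object@schedule))
        msg <- c(msg, "one column per schedule day is required")
    if (!object@summaryStat %in% c("mean", "median"))
        msg <- c(msg, "summaryStat must be 'mean' or 'median'")
    if (any(is.na(object@values) & object@nPerCell > 0L))
        msg <- c(msg, "cells with replicates must not be NA")
    if (any(!is.na(object@values) & object@nPerCell == 0L))
        msg <- c(msg, "cells without replicates must be NA")
    if (length(msg)) msg else TRUE
})

#' CorrResult: Spearman cross-correlation census
#'
#' Symmetric Spearman rank correlation and p-value matrices over
#' mediator-at-compartment variables, with per-pair usable sample counts.
#' Pairs with fewer than 3 paired observations are \code{NA}.
#'
#' @slot labels variable names, \code{"mediator@compartment"}.
#' @slot rho,p,nUsed symmetric matrices (correlation, two-sided p from the
#'   t approximation, pairwise-complete n).
#' @slot meta list of provenance details (groups, compartments, method).
#'
#' @seealso [spearmanCensus()], [significantCount()], [percentSignificant()]
#' @export
setClass("CorrResult",
    representation(labels = "character", rho = "matrix", p = "matrix",
                   nUsed = "matrix", meta = "list"))

setValidity("CorrResult", function(object) {
    msg <- character()
    m <- length(object@labels)
    for (nm in c("rho", "p", "nUsed")) {
        mat <- slot(object, nm)
        if (!identical(dim(mat), c(m, m)))
            msg <- c(msg, paste0(nm, " must be ", m, "x", m))
        else if (!isTRUE(all.equal(mat, t(mat))))
            msg <- c(msg, paste0(nm, " must be symmetric"))
    }
    if (any(abs(object@rho) > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "|rho| must not exceed 1")
    if (any(object@p < 0 | object@p > 1, na.rm = TRUE))
        msg <- c(msg, "p must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' DynaNetwork: one interval of a Dynamic Network Analysis
#'
#' An undirected mediator-mediator correlation network for one pair of
#' consecutive ordinal strata (e.g. rejection-severity grades G0-G1).
#' An edge joins two mediators when the absolute Pearson correlation of
#' their concentrations across all samples in the interval reaches the
#' threshold.
#'
#' @slot lower,upper the consecutive ordinal stratum labels.
#' @slot nodes all panel mediators analyzed (isolated nodes included).
#' @slot edges data.frame with columns \code{mediatorA}, \code{mediatorB},
#'   \code{r}; each unordered pair appears once.
#' @slot threshold the |r| cutoff used (default 0.90).
#' @slot nSamples number of samples pooled in the interval.
#' @slot evaluable \code{FALSE} when the interval held fewer than 3
#'   samples, in which case no edges were assessed.
#'
#' @seealso [buildDynaNetworks()], [complexity()]
#' @export
setClass("DynaNetwork",
    representation(lower = "character", upper = "character",
                   nodes = "character", edges = "data.frame",
                   threshold = "numeric", nSamples = "integer",
                   evaluable = "logical"))

setValidity("DynaNetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("mediatorA", "mediatorB", "r") %in% colnames(e)))
        msg <- c(msg, "edges must have columns mediatorA, mediatorB, r")
    else {
        if (any(e$mediatorA == e$mediatorB))
            msg <- c(msg, "self-edges are not allowed")
        if (nrow(e) && any(abs(e$r) < object@threshold - 1e-12))
            msg <- c(msg, "every edge must satisfy |r| >= threshold")
        if (!all(e$mediatorA %in% object@nodes) ||
            !all(e$mediatorB %in% object@nodes))
            msg <- c(msg, "edge endpoints must be panel mediators")
    }
    if (length(msg)) msg else TRUE
})

#' DyHypGraph: one sliding-window dynamic hypergraph
#'
#' Vertices are tissue compartments; each hyperedge is a mediator whose
#' concentration trend against calendar day passed the correlation
#' threshold (increasing: r > threshold; decreasing: r < -threshold) in the
#' listed compartments over one three-timepoint window. A mediator can
#' carry at most one increasing and one decreasing edge per window, and the
#' two never share a compartment.
#'
#' @slot window ordered numeric triple of consecutive schedule days.
#' @slot index position of the window in the sliding series.
#' @slot vertices the declared compartment set (fixed, even when empty of
#'   edges).
#' @slot edges data.frame with columns \code{mediator}, \code{direction}
#'   (\code{"increasing"}/\code{"decreasing"}), \code{compartments}
#'   (list column of compartment subsets) and \code{r} (list column of
#'   named per-compartment Pearson r).
#' @slot threshold the trend |r| cutoff used (default 0.95, strict).
#' @slot skipped data.frame logging (mediator, compartment) pairs skipped
#'   for missing values or zero variance.
#'
#' @seealso [buildHypergraph()], [edgeDistribution()], [distributionSeries()]
#' @export
setClass("DyHypGraph",
    representation(window = "numeric", index = "integer",
                   vertices = "character", edges = "data.frame",
                   threshold = "numeric", skipped = "data.frame"))

setValidity("DyHypGraph", function(object) {
    msg <- character()
    if (length(object@window) != 3L ||
        is.unsorted(object@window, strictly = TRUE))
        msg <- c(msg, "window must be 3 strictly increasing days")
    e <- object@edges
    need <- c("mediator", "direction", "compartments", "r")
    if (!all(need %in% colnames(e)))
        return(c(msg, "edges must have columns mediator, direction, compartments, r"))
    if (nrow(e)) {
        if (anyDuplicated(paste(e$mediator, e$direction)))
            msg <- c(msg, "at most one edge per mediator and direction")
        if (!all(e$direction %in% c("increasing", "decreasing")))
            msg <- c(msg, "direction must be increasing or decreasing")
        if (!all(unlist(e$compartments) %in% object@vertices))
            msg <- c(msg, "edge compartments must be declared vertices")
        if (any(!vapply(e$compartments, length, 1L)))
            msg <- c(msg, "edges must span at least one compartment")
    }
    if (length(msg)) msg else TRUE
})

#' TrendSpec: one planted monotone trend for the simulator
#'
#' Describes a deterministic linear-in-day signal injected into one
#' mediator in one or more compartments over a span of the sampling
#' schedule. Outside the span the signal stays at baseline (before the
#' start) or holds its final value (after the end), so the trend is
#' monotone but bounded.
#'
#' @slot mediator panel mediator carrying the trend.
#' @slot compartments non-empty subset of the declared compartments;
#'   listing several expresses cross-compartment coupling (shared
#'   deterministic trend, independent noise).
#' @slot dayRange numeric \code{c(start, end)}; must cover at least 3
#'   schedule days.
#' @slot direction \code{"increasing"} or \code{"decreasing"}.
#' @slot slope concentration units per day, > 0 (sign comes from
#'   direction).
#' @slot baseline concentration at the start of the study, >= 0.
#'
#' @seealso [trendSpec()], [simulateMediators()]
#' @export
setClass("TrendSpec",
    representation(mediator = "character", compartments = "character",
                   dayRange = "numeric", direction = "character",
                   slope = "numeric", baseline = "numeric"))

setValidity("TrendSpec", function(object) {
    msg <- character()
    if (length(object@dayRange) != 2L || diff(object@dayRange) <= 0)
        msg <- c(msg, "dayRange must be c(start, end) with start < end")
    if (!object@direction %in% c("increasing", "decreasing"))
        msg <- c(msg, "direction must be increasing or decreasing")
    if (object@slope <= 0) msg <- c(msg, "slope must be > 0")
    if (object@baseline < 0) msg <- c(msg, "baseline must be >= 0")
    if (!length(object@compartments))
        msg <- c(msg, "at least one compartment is required")
    if (length(msg)) msg else TRUE
})

#' SimConfig: full specification of a simulated study
#'
#' Bundles the panel, sampling schedule, per-group planted trends, group
#' size, noise model and master seed that define one synthetic
#' Luminex-like experiment. Identical configs (including seed) simulate to
#' identical datasets.
#'
#' @slot panel a \linkS4class{MediatorPanel}.
#' @slot schedule strictly increasing sampling days.
#' @slot groups named list; each element is a (possibly empty) list of
#'   \linkS4class{TrendSpec} objects for that experimental group.
#' @slot nSubjects subjects (animals) per group, >= 1.
#' @slot noiseFamily \code{"lognormal"} (multiplicative, keeps
#'   concentrations positive) or \code{"gaussian"} (additive, clamped at
#'   zero).
#' @slot sigma dispersion; log-sd for lognormal, sd in concentration units
#'   for gaussian. \code{0} disables noise.
#' @slot baseline default baseline concentration for mediators without a
#'   trend.
#' @slot seed master integer seed; per-(group, subject, compartment)
#'   streams are split from it.
#'
#' @seealso [simConfig()], [simulateMediators()], [plantedTruth()]
#' @export
setClass("SimConfig",
    representation(panel = "MediatorPanel", schedule = "numeric",
                   groups = "list", nSubjects = "integer",
                   noiseFamily = "character", sigma = "numeric",
                   baseline = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
    if (!object@noiseFamily %in% c("lognormal", "gaussian"))
        msg <- c(msg, "noiseFamily must be lognormal or gaussian")
    if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
    if (is.unsorted(object@schedule, strictly = TRUE))
        msg <- c(msg, "schedule must be strictly increasing")
    if (is.null(names(object@groups)) || any(!nzchar(names(object@groups))))
        msg <- c(msg, "groups must be a named list")
    for (g in names(object@groups)) {
        for (ts in object@groups[[g]]) {
            if (!is(ts, "TrendSpec")) {
                msg <- c(msg, "group elements must be TrendSpec lists")
                break
            }
            if (!ts@mediator %in% object@panel@names)
                msg <- c(msg, paste0("trend mediator '", ts@mediator,
                                     "' not in panel"))
            bad <- setdiff(ts@compartments,
                           names(object@panel@unitsByCompartment))
            if (length(bad))
                msg <- c(msg, paste0("trend compartment(s) not declared: ",
                                     paste(bad, collapse = ", ")))
            covered <- sum(object@schedule >= ts@dayRange[1] &
                           object@schedule <= ts@dayRange[2])
            if (covered < 3L)
                msg <- c(msg, paste0("trend dayRange [", ts@dayRange[1], ", ",
                                     ts@dayRange[2],
                                     "] must cover at least 3 schedule days"))
        }
    }
    if (length(msg)) msg else TRUE
})
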