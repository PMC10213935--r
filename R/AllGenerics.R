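#' Panel and experiment accessors
#'
#' @param x a \linkS4class{MediatorPanel}, \linkS4class{MediatorExperiment}
#'   or other package object.
#' @return \code{panelNames}: character vector of mediator names.
#'   \code{compartmentNames}: declared compartment labels.
#'   \code{studySchedule}: numeric sampling days. \code{studyGroups}:
#'   group labels present. \code{mediatorPanelOf}: the
#'   \linkS4class{MediatorPanel}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("panelNames", function(x) standardGeneric("panelNames"))

#' @rdname accessors
#' @export
setGeneric("compartmentNames",
           function(x) standardGeneric("compartmentNames"))

#' @rdname accessors
#' @export
setGeneric("studySchedule", function(x) standardGeneric("studySchedule"))

#' @rdname accessors
#' @export
setGeneric("studyGroups", function(x) standardGeneric("studyGroups"))

#' @rdname accessors
#' @export
setGeneric("mediatorPanelOf", function(x) standardGeneric("mediatorPanelOf"))

#' Network complexity of a DyNA interval network
#'
#' The degree-sum complexity score: with \eqn{N_i} the number of
#' connections of mediator \eqn{i} and \eqn{n} the total number of
#' mediators analyzed (isolated nodes included), complexity is
#' \deqn{(N_1 + N_2 + \dots + N_n)/(n - 1) = 2|E|/(n - 1).}
#' An empty network scores 0; a complete graph on \eqn{n} mediators scores
#' exactly \eqn{n}.
#'
#' @param x a \linkS4class{DynaNetwork}.
#' @return non-negative numeric scalar.
#' @examples
#' net <- new("DynaNetwork", lower = "G0", upper = "G1",
#'            nodes = c("A", "B", "C"),
#'            edges = data.frame(mediatorA = c("A", "B"),
#'                               mediatorB = c("B", "C"), r = c(1, 1)),
#'            threshold = 0.9, nSamples = 5L, evaluable = TRUE)
#' complexity(net)  # (1 + 2 + 1)/2 = 2
#' @export
setGeneric("complexity", function(x) standardGeneric("complexity"))

#' Edge distribution of a dynamic hypergraph
#'
#' Tallies the hyperedges of one window by the number of compartments they
#' span (cardinality 1, 2, ..., number of vertices) and by trend direction.
#' The total over all cells equals the number of hyperedges.
#'
#' @param x a \linkS4class{DyHypGraph}.
#' @return data.frame with columns \code{cardinality}, \code{direction},
#'   \code{count}, one row per (cardinality, direction) cell.
#' @seealso [distributionSeries()]
#' @export
setGeneric("edgeDistribution", function(x) standardGeneric("edgeDistribution"))

#' Count and rate of significant cross-correlations
#'
#' \code{significantCount} counts the unordered off-diagonal variable
#' pairs whose census p-value is below \code{alpha}, each pair once.
#' \code{percentSignificant} divides by the number of evaluable pairs
#' (pairs with fewer than 3 paired observations are excluded from both
#' numerator and denominator), giving the "significant correlations over
#' maximum possible" summary used to compare correlation census panels.
#'
#' @param x a \linkS4class{CorrResult}.
#' @param alpha significance level (default 0.05).
#' @return \code{significantCount}: integer; \code{percentSignificant}:
#'   proportion in [0, 1].
#' @export
setGeneric("significantCount",
           function(x, alpha = 0.05) standardGeneric("significantCount"))

#' @rdname significantCount
#' @export
setGeneric("percentSignificant",
           function(x, alpha = 0.05) standardGeneric("percentSignificant"))
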