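#' Construct a MediatorPanel
#'
#' @param names character vector of unique mediator identifiers, in panel
#'   order.
#' @param unitsByCompartment named character vector mapping each
#'   compartment to its unit string; the names define the compartment set.
#' @return a \linkS4class{MediatorPanel}.
#' @examples
#' mediatorPanel(c("IL-6", "TNF-a"),
#'               c(skin = "pg/mg protein", blood = "pg/ml"))
#' @export
mediatorPanel <- function(names, unitsByCompartment) {
    new("MediatorPanel", names = as.character(names),
        unitsByCompartment = unitsByCompartment)
}

#' Built-in reference mediator panels
#'
#' `ratMediatorPanel()` is the 27-analyte rat multiplex bead set used in
#' rodent limb-transplant studies (skin and muscle homogenates in pg/mg
#' protein, peripheral blood in pg/ml). `humanMediatorPanel()` is the
#' companion 26-analyte human bead set (skin and muscle biopsies).
#' Greek letters are transliterated (\code{IL-1a}, \code{IFN-g},
#' \code{TNF-a}) so identifiers stay plain ASCII.
#'
#' @return a \linkS4class{MediatorPanel}.
#' @examples
#' length(panelNames(ratMediatorPanel()))    # 27
#' length(panelNames(humanMediatorPanel()))  # 26
#' @export
ratMediatorPanel <- function() {
    mediatorPanel(
        c("Eotaxin", "EGF", "Fractalkine", "G-CSF", "GM-CSF", "GRO/KC",
          "IFN-g", "IL-1a", "IL-1b", "IL-2", "IL-4", "IL-5", "IL-6",
          "IL-10", "IL-12p70", "IL-13", "IL-17A", "IL-18", "IP-10",
          "Leptin", "LIX", "MCP-1", "MIP-1a", "MIP-2", "RANTES", "TNF-a",
          "VEGF"),
        c(skin = "pg/mg protein", muscle = "pg/mg protein",
          blood = "pg/ml"))
}

#' @rdname ratMediatorPanel
#' @export
humanMediatorPanel <- function() {
    mediatorPanel(
        c("ENA-78", "Eotaxin", "EGF", "Fractalkine", "G-CSF", "GM-CSF",
          "GRO-a", "GRO-b", "IFN-g", "IL-1a", "IL-1b", "IL-2", "IL-4",
          "IL-6", "IL-10", "IL-12p70", "IL-13", "IL-17A", "IL-18",
          "IP-10", "Leptin", "MCP-1", "MIP-1a", "RANTES", "TNF-a",
          "VEGF-A"),
        c(skin = "pg/mg protein", muscle = "pg/mg protein",
          blood = "pg/ml"))
}

#' The rat study sampling schedule
#'
#' Calendar days on which skin, muscle and peripheral blood samples were
#' collected in the rat hind-limb transplant design: an early dense phase
#' (0-11), a gap, and a late phase (20-31). Sliding 3-point windows over
#' this 11-day schedule give 9 overlapping dynamic time intervals.
#'
#' @return numeric vector of 11 study days.
#' @examples
#' ratSchedule()
#' nrow(makeWindows(ratSchedule()))  # 9
#' @export
ratSchedule <- function() c(0, 3, 5, 7, 9, 11, 20, 23, 25, 27, 31)

#' @rdname accessors
#' @export
setMethod("panelNames", "MediatorPanel", function(x) x@names)

#' @rdname accessors
#' @export
setMethod("compartmentNames", "MediatorPanel",
          function(x) names(x@unitsByCompartment))

#' Measurement units of a panel
#'
#' @param x a \linkS4class{MediatorPanel}.
#' @return named character vector, compartment -> unit string.
#' @export
panelUnits <- function(x) {
    stopifnot(is(x, "MediatorPanel"))
    x@unitsByCompartment
}

setMethod("show", "MediatorPanel", function(object) {
    cat("MediatorPanel with", length(object@names), "mediators\n")
    cat("  mediators:", paste(utils::head(object@names, 6), collapse = ", "),
        if (length(object@names) > 6) "...\n" else "\n")
    cat("  compartments:",
        paste(sprintf("%s [%s]", names(object@unitsByCompartment),
                      object@unitsByCompartment), collapse = ", "), "\n")
})
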