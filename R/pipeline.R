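#' Rebuild a SimConfig from a plain list (YAML/JSON)
#'
#' Inverse of the YAML representation used by [runPipeline()] configs:
#' groups map to lists of trend entries with fields \code{mediator},
#' \code{compartments}, \code{dayRange}, \code{direction}, \code{slope},
#' \code{baseline}.
#'
#' @param lst plain list, e.g. from [yaml::read_yaml()].
#' @param seed master seed overriding any in the list (optional).
#' @return a \linkS4class{SimConfig}.
#' @export
simConfigFromList <- function(lst, seed = NULL) {
    panel <- switch(tolower(lst$panel %||% "rat"),
                    rat = ratMediatorPanel(),
                    human = humanMediatorPanel(),
                    stop("unknown panel '", lst$panel, "'"))
    groups <- lapply(lst$groups, function(trends)
        lapply(trends, function(tr)
            trendSpec(tr$mediator, unlist(tr$compartments),
                      unlist(tr$dayRange), tr$direction,
                      slope = tr$slope %||% 1,
                      baseline = tr$baseline %||% 100)))
    simConfig(groups, panel = panel,
              schedule = unlist(lst$schedule %||% ratSchedule()),
              nSubjects = lst$nSubjects %||% 8,
              noiseFamily = lst$noiseFamily %||% "lognormal",
              sigma = lst$sigma %||% 0.3,
              baseline = lst$baseline %||% 100,
              seed = seed %||% lst$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.knownAnalyses <- c("crosscorr", "dyna", "dyhyp", "screen")

# Default time-bin strata for DyNA on an 11-day rat-style schedule.
.defaultDayBins <- function(schedule) {
    qs <- split(schedule,
                cut(seq_along(schedule), 4, labels = FALSE))
    stats::setNames(qs, paste0("T", seq_along(qs)))
}

.sanitize <- function(s) gsub("[^A-Za-z0-9_.-]", "_", s)

#' Run the full analysis pipeline from a config
#'
#' Config-driven orchestration of simulate/load, the Spearman
#' cross-correlation census, DyNA over time-bin strata, the DyHyp sliding
#' window series, and the two-group screens. Every artifact is written
#' into one results directory together with a JSON manifest recording
#' inputs, parameters, seed and package version. Identical config and
#' seed reproduce identical numeric outputs.
#'
#' The config is a YAML file or an equivalent nested list:
#' \preformatted{
#' seed: 1
#' input:
#'   simulate: demo            # or csv: path (+ panel: rat|human),
#'                             # or a full simulate: spec (see
#'                             # simConfigFromList)
#' analyses: [crosscorr, dyna, dyhyp, screen]
#' crosscorr: {alpha: 0.05}
#' dyna: {threshold: 0.90}     # optional strata: {label: [days], ...}
#' dyhyp: {threshold: 0.95}
#' screen:
#'   comparisons: [[syn, syn_NR], [allo_TAC, allo_TAC_NR]]
#'   fcThreshold: 2.0
#'   alpha: 0.05
#' }
#'
#' @param config path to a YAML config file, or the equivalent list.
#' @param outputDir results directory (created if needed); overrides
#'   \code{config$outputDir}.
#' @param seed overrides \code{config$seed}.
#' @return the manifest, invisibly (also written as
#'   \code{manifest.json}).
#' @examples
#' \donttest{
#' out <- runPipeline(list(seed = 1,
#'                         input = list(simulate = "demo"),
#'                         analyses = c("dyhyp")),
#'                    outputDir = tempfile())
#' names(out$files)
#' }
#' @export
runPipeline <- function(config, outputDir = NULL, seed = NULL) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    seed <- as.integer(seed %||% config$seed %||% 1L)
    outputDir <- outputDir %||% config$outputDir %||%
        stop("an output directory is required")
    analyses <- unlist(config$analyses %||% .knownAnalyses)
    bad <- setdiff(analyses, .knownAnalyses)
    if (length(bad))
        stop("unknown analysis name(s): ", paste(bad, collapse = ", "),
             " (known: ", paste(.knownAnalyses, collapse = ", "), ")")
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)

    manifest <- list(package = "immunodyn",
                     version = as.character(utils::packageVersion("immunodyn")),
                     seed = seed, analyses = as.list(analyses),
                     parameters = list(), files = list(),
                     errors = list())
    addFile <- function(name, path, params = NULL) {
        manifest$files[[name]] <<- basename(path)
        if (!is.null(params)) manifest$parameters[[name]] <<- params
    }
    writeManifest <- function() jsonlite::write_json(
        manifest, file.path(outputDir, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")

    ## --- input stage -------------------------------------------------
    input <- config$input %||% list(simulate = "demo")
    truth <- NULL
    if (!is.null(input$csv)) {
        panel <- switch(tolower(input$panel %||% "rat"),
                        rat = ratMediatorPanel(),
                        human = humanMediatorPanel())
        exp <- readMediatorTable(input$csv, panel)
        manifest$parameters$input <- list(csv = input$csv,
                                          panel = input$panel %||% "rat")
    } else {
        simcfg <- if (identical(input$simulate, "demo"))
            demoSimConfig(seed = seed,
                          sigma = input$sigma %||% 0.3,
                          nSubjects = input$nSubjects %||% 8)
        else simConfigFromList(input$simulate, seed = seed)
        sim <- simulateMediators(simcfg)
        exp <- sim$experiment
        truth <- sim$truth
        manifest$parameters$input <- list(
            simulate = if (identical(input$simulate, "demo")) "demo"
                       else "custom",
            nSubjects = simcfg@nSubjects, sigma = simcfg@sigma,
            noiseFamily = simcfg@noiseFamily, seed = seed)
    }
    p <- file.path(outputDir, "dataset.csv")
    writeMediatorTable(exp, p)
    addFile("dataset", p)
    if (!is.null(truth)) {
        p <- file.path(outputDir, "planted_truth.json")
        jsonlite::write_json(truth, p, auto_unbox = FALSE, digits = NA)
        addFile("planted_truth", p)
    }

    grps <- studyGroups(exp)
    runStage <- function(name, fun) {
        res <- tryCatch(fun(), error = function(e) {
            manifest$errors[[name]] <<- conditionMessage(e)
            NULL
        })
        invisible(res)
    }

    ## --- cross-correlation census ------------------------------------
    if ("crosscorr" %in% analyses) runStage("crosscorr", function() {
        alpha <- config$crosscorr$alpha %||% 0.05
        comps <- unlist(config$crosscorr$compartments) %||%
            compartmentNames(exp)
        summ <- list()
        for (g in grps) {
            res <- spearmanCensus(exp, groups = g, compartments = comps)
            base <- paste0("crosscorr_", .sanitize(g))
            pr <- file.path(outputDir, paste0(base, "_rho.csv"))
            pp <- file.path(outputDir, paste0(base, "_p.csv"))
            utils::write.csv(corrMatrices(res)$rho, pr)
            utils::write.csv(corrMatrices(res)$p, pp)
            addFile(paste0(base, "_rho"), pr)
            addFile(paste0(base, "_p"), pp)
            m <- length(res@labels)
            summ[[g]] <- list(group = g,
                              count = significantCount(res, alpha),
                              maxPairs = m * (m - 1) / 2,
                              percent = percentSignificant(res, alpha))
        }
        ps <- file.path(outputDir, "crosscorr_summary.json")
        jsonlite::write_json(unname(summ), ps, auto_unbox = TRUE,
                             digits = NA)
        addFile("crosscorr_summary", ps,
                params = list(alpha = alpha, compartments = comps))
    })

    ## --- DyNA over time-bin strata -----------------------------------
    if ("dyna" %in% analyses) runStage("dyna", function() {
        thr <- config$dyna$threshold %||% 0.90
        bins <- config$dyna$strata %||%
            .defaultDayBins(studySchedule(exp))
        ordering <- names(bins)
        dayToBin <- function(row) {
            hit <- ordering[vapply(bins, function(d) row$day %in% d,
                                   TRUE)]
            if (length(hit)) hit[1] else NA_character_
        }
        allSumm <- list(); allEdges <- list()
        cd <- colData(exp)
        for (g in grps) for (cc in compartmentNames(exp)) {
            sub <- exp[, cd$group == g & cd$compartment == cc]
            if (ncol(sub) == 0L) next
            nets <- buildDynaNetworks(sub, dayToBin, ordering,
                                      threshold = thr)
            tag <- paste(g, cc, sep = ".")
            es <- dynaEdgeTable(nets)
            if (nrow(es))
                allEdges[[tag]] <- cbind(group = g, compartment = cc, es)
            allSumm[[tag]] <- cbind(group = g, compartment = cc,
                                    dynaSummary(nets))
        }
        pe <- file.path(outputDir, "dyna_edges.csv")
        ed <- do.call(rbind, allEdges)
        if (is.null(ed))
            ed <- data.frame(group = character(),
                             compartment = character(),
                             interval = character(),
                             mediatorA = character(),
                             mediatorB = character(), r = numeric())
        utils::write.csv(ed, pe, row.names = FALSE)
        ps <- file.path(outputDir, "dyna_summary.csv")
        utils::write.csv(do.call(rbind, allSumm), ps, row.names = FALSE)
        addFile("dyna_edges", pe)
        addFile("dyna_summary", ps,
                params = list(threshold = thr,
                              strata = lapply(bins, as.numeric)))
    })

    ## --- DyHyp sliding-window series ---------------------------------
    if ("dyhyp" %in% analyses) runStage("dyhyp", function() {
        thr <- config$dyhyp$threshold %||% 0.95
        allDist <- list(); allEdges <- list()
        for (g in grps) {
            ser <- distributionSeries(exp, g, threshold = thr)
            allDist[[g]] <- cbind(group = g, ser$distribution)
            ee <- do.call(rbind, lapply(ser$graphs, function(hg) {
                e <- hypergraphEdges(hg)
                if (!nrow(e)) return(NULL)
                cbind(group = g, window = hg@index,
                      dayStart = hg@window[1],
                      dayEnd = hg@window[length(hg@window)], e)
            }))
            if (!is.null(ee)) allEdges[[g]] <- ee
        }
        pd <- file.path(outputDir, "dyhyp_distribution.csv")
        utils::write.csv(do.call(rbind, allDist), pd, row.names = FALSE)
        pe <- file.path(outputDir, "dyhyp_edges.csv")
        ed <- do.call(rbind, allEdges)
        if (is.null(ed))
            ed <- data.frame(group = character(), window = integer(),
                             dayStart = numeric(), dayEnd = numeric(),
                             mediator = character(),
                             direction = character(),
                             cardinality = integer(),
                             compartments = character(),
                             rMin = numeric())
        utils::write.csv(ed, pe, row.names = FALSE)
        addFile("dyhyp_distribution", pd)
        addFile("dyhyp_edges", pe, params = list(threshold = thr))
    })

    ## --- group screens -----------------------------------------------
    if ("screen" %in% analyses) runStage("screen", function() {
        comparisons <- config$screen$comparisons
        if (is.null(comparisons) && length(grps) >= 2)
            comparisons <- list(grps[1:2])
        fc <- config$screen$fcThreshold %||% 2.0
        alpha <- config$screen$alpha %||% 0.05
        comps <- unlist(config$screen$compartments) %||%
            compartmentNames(exp)
        for (cmp in comparisons) {
            cmp <- unlist(cmp)
            tag <- paste0(.sanitize(cmp[1]), "_vs_", .sanitize(cmp[2]))
            tw <- do.call(rbind, lapply(comps, function(cc)
                twoWayScreen(exp, cmp[1], cmp[2], cc, alpha = alpha)))
            vo <- do.call(rbind, lapply(comps, function(cc)
                cbind(compartment = cc,
                      volcanoScreen(exp, cmp[1], cmp[2], cc,
                                    fcThreshold = fc, alpha = alpha))))
            pt <- file.path(outputDir,
                            paste0("screen_twoway_", tag, ".csv"))
            pv <- file.path(outputDir,
                            paste0("screen_volcano_", tag, ".csv"))
            utils::write.csv(tw, pt, row.names = FALSE)
            utils::write.csv(vo, pv, row.names = FALSE)
            addFile(paste0("screen_twoway_", tag), pt,
                    params = list(alpha = alpha))
            addFile(paste0("screen_volcano_", tag), pv,
                    params = list(fcThreshold = fc, alpha = alpha))
            grid <- data.frame(
                mediator = tw$mediator, compartment = tw$compartment,
                comparison = paste(cmp[1], "vs", cmp[2]),
                significance = ifelse(is.na(tw$significant), "n.e.",
                                      ifelse(tw$significant,
                                             "p<0.05", "-")))
            pg <- file.path(outputDir,
                            paste0("screen_grid_", tag, ".csv"))
            utils::write.csv(grid, pg, row.names = FALSE)
            addFile(paste0("screen_grid_", tag), pg)
        }
    })

    writeManifest()
    invisible(manifest)
}

#' Extract the rho and p matrices of a census
#'
#' @param x a \linkS4class{CorrResult}.
#' @return list with elements \code{rho}, \code{p}, \code{nUsed}
#'   (labelled symmetric matrices).
#' @export
corrMatrices <- function(x) {
    stopifnot(is(x, "CorrResult"))
    list(rho = x@rho, p = x@p, nUsed = x@nUsed)
}
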