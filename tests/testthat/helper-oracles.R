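# Independent brute-force oracles and tiny fixture builders shared by the
# test files. The oracles deliberately avoid the code paths they check.

# Pearson correlation from explicit sums.
brutePearson <- function(x, y) {
    n <- length(x)
    sx <- x - sum(x) / n
    sy <- y - sum(y) / n
    sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

# Spearman matrix: midrank each column, then Pearson on ranks.
bruteSpearman <- function(mat) {
    ranks <- apply(mat, 2, rank, ties.method = "average")
    m <- ncol(mat)
    out <- diag(1, m)
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
        out[i, j] <- out[j, i] <- brutePearson(ranks[, i], ranks[, j])
    }
    dimnames(out) <- list(colnames(mat), colnames(mat))
    out
}

# All-pairs Pearson edge screen on a mediators x samples matrix.
bruteDynaEdges <- function(a, threshold) {
    meds <- rownames(a)
    hits <- character()
    for (i in seq_len(nrow(a) - 1)) for (j in seq(i + 1, nrow(a))) {
        if (sd(a[i, ]) == 0 || sd(a[j, ]) == 0) next
        r <- brutePearson(a[i, ], a[j, ])
        if (abs(r) >= threshold)
            hits <- c(hits, paste(meds[i], meds[j], sep = "|"))
    }
    sort(hits)
}

# Brute-force hypergraph edges: loop mediator x compartment x window over
# per-compartment group-mean matrices (mediators x schedule days).
bruteHyperEdges <- function(means, schedule, threshold = 0.95) {
    win <- t(vapply(seq_len(length(schedule) - 2),
                    function(i) schedule[i:(i + 2)], numeric(3)))
    comps <- names(means)
    rows <- list()
    for (w in seq_len(nrow(win))) {
        cols <- match(win[w, ], schedule)
        for (m in rownames(means[[1]])) {
            for (dir in c("increasing", "decreasing")) {
                cc <- character()
                for (cmp in comps) {
                    v <- means[[cmp]][m, cols]
                    if (anyNA(v) || sd(v) == 0) next
                    r <- brutePearson(v, win[w, ])
                    if ((dir == "increasing" && r > threshold) ||
                        (dir == "decreasing" && r < -threshold))
                        cc <- c(cc, cmp)
                }
                if (length(cc))
                    rows[[length(rows) + 1]] <- paste(
                        w, m, dir, paste(cc, collapse = "+"))
            }
        }
    }
    sort(unlist(rows))
}

# Small three-mediator panel over the three standard compartments.
tinyPanel <- function(mediators = c("IL-6", "TNF-a", "IL-10")) {
    mediatorPanel(mediators,
                  c(skin = "pg/mg protein", muscle = "pg/mg protein",
                    blood = "pg/ml"))
}

# Long-format record builder with sensible defaults.
rec <- function(group = "g1", subject = "s1", compartment = "skin",
                day = 0, mediator = "IL-6", concentration = 1) {
    data.frame(group = group, subject = subject,
               compartment = compartment, day = day,
               mediator = mediator, concentration = concentration,
               stringsAsFactors = FALSE)
}

# Flatten a hypergraph series into "window mediator direction comps" keys.
hyperKeys <- function(graphs) {
    out <- unlist(lapply(graphs, function(h) {
        e <- hypergraphEdges(h)
        if (!nrow(e)) return(NULL)
        paste(h@index, e$mediator, e$direction, e$compartments)
    }))
    sort(out %||% character())
}

truthKeys <- function(truth) {
    sort(paste(truth$windowIndex, truth$mediator, truth$direction,
               truth$compartments))
}

# Number of planted tuples whose (window, mediator, direction) edge was
# detected over at least the planted compartment set. Noise can add
# spurious compartments at the null edge rate; those are false positives,
# not recovery failures.
countRecovered <- function(graphs, truth) {
    sum(vapply(seq_len(nrow(truth)), function(i) {
        h <- graphs[[truth$windowIndex[i]]]
        e <- h@edges
        sel <- which(e$mediator == truth$mediator[i] &
                     e$direction == truth$direction[i])
        if (!length(sel)) return(FALSE)
        planted <- strsplit(truth$compartments[i], "+", fixed = TRUE)[[1]]
        all(planted %in% e$compartments[[sel]])
    }, TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
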