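# MediatorExperiment with given mediators x samples matrix, one sample per
# subject at day 0, all in one group/compartment, stratified by `strata`.
matrixExperiment <- function(a, strata) {
    meds <- rownames(a)
    df <- do.call(rbind, lapply(seq_len(ncol(a)), function(j)
        data.frame(group = "g1", subject = paste0("s", j),
                   compartment = "skin", day = 0, mediator = meds,
                   concentration = a[, j], stringsAsFactors = FALSE)))
    me <- MediatorExperiment(df, tinyPanel(meds))
    names(strata) <- paste0("g1.s", seq_len(ncol(a)), ".skin.0")
    list(me = me, strata = strata)
}

test_that("exactly proportional mediators are joined with r = 1", {
    a <- rbind("IL-6" = c(1, 2, 3, 4, 5, 6),
               "TNF-a" = 2 * c(1, 2, 3, 4, 5, 6),
               "IL-10" = c(5, 1, 4, 2, 6, 3))
    fx <- matrixExperiment(a, rep(c("G0", "G1"), each = 3))
    nets <- buildDynaNetworks(fx$me, fx$strata, c("G0", "G1"))
    expect_length(nets, 1)
    e <- nets[["G0-G1"]]@edges
    expect_equal(nrow(e), 1)
    expect_equal(e$r, 1, tolerance = 1e-12)
    expect_setequal(c(e$mediatorA, e$mediatorB), c("IL-6", "TNF-a"))
})

test_that("threshold 1 keeps only exactly collinear pairs", {
    set.seed(4)
    a <- matrix(rexp(4 * 6), 4, 6,
                dimnames = list(paste0("M", 1:4), NULL))
    fx <- matrixExperiment(a, rep(c("G0", "G1"), each = 3))
    nets <- buildDynaNetworks(fx$me, fx$strata, c("G0", "G1"),
                              threshold = 1)
    expect_equal(nrow(nets[[1]]@edges), 0)
})

test_that("edge sets equal the brute-force all-pairs Pearson screen", {
    for (s in 1:6) {
        set.seed(s)
        a <- matrix(rexp(4 * 5), 4, 5,
                    dimnames = list(paste0("M", 1:4), NULL))
        fx <- matrixExperiment(a, rep(c("G0", "G1"), c(3, 2)))
        for (thr in c(0.5, 0.9)) {
            nets <- buildDynaNetworks(fx$me, fx$strata, c("G0", "G1"),
                                      threshold = thr)
            e <- nets[[1]]@edges
            got <- sort(paste(e$mediatorA, e$mediatorB, sep = "|"))
            expect_equal(got, bruteDynaEdges(a, thr))
            if (nrow(e))
                for (k in seq_len(nrow(e)))
                    expect_equal(e$r[k],
                                 brutePearson(a[e$mediatorA[k], ],
                                              a[e$mediatorB[k], ]),
                                 tolerance = 1e-12)
        }
    }
})

test_that("complexity follows the degree-sum formula", {
    chain <- new("DynaNetwork", lower = "G0", upper = "G1",
                 nodes = c("A", "B", "C"),
                 edges = data.frame(mediatorA = c("A", "B"),
                                    mediatorB = c("B", "C"),
                                    r = c(0.95, 0.99)),
                 threshold = 0.9, nSamples = 5L, evaluable = TRUE)
    expect_equal(complexity(chain), 2)

    empty <- new("DynaNetwork", lower = "G0", upper = "G1",
                 nodes = c("A", "B", "C"),
                 edges = data.frame(mediatorA = character(),
                                    mediatorB = character(),
                                    r = numeric()),
                 threshold = 0.9, nSamples = 5L, evaluable = TRUE)
    expect_equal(complexity(empty), 0)

    # complete graph on n nodes scores exactly n; each added edge is
    # worth exactly 2/(n-1)
    for (n in c(3, 5, 8)) {
        nodes <- paste0("M", seq_len(n))
        pairs <- t(combn(nodes, 2))
        full <- new("DynaNetwork", lower = "a", upper = "b",
                    nodes = nodes,
                    edges = data.frame(mediatorA = pairs[, 1],
                                       mediatorB = pairs[, 2],
                                       r = 1),
                    threshold = 0.9, nSamples = 5L, evaluable = TRUE)
        expect_equal(complexity(full), n)
        part <- full
        part@edges <- full@edges[-1, ]
        expect_equal(complexity(full) - complexity(part), 2 / (n - 1))
    }
})

test_that("intervals with fewer than 3 samples are flagged unevaluable", {
    a <- rbind("IL-6" = c(1, 2, 3, 4),
               "TNF-a" = c(2, 4, 6, 8))
    fx <- matrixExperiment(a, c("G0", "G0", "G0", "G2"))
    nets <- buildDynaNetworks(fx$me, fx$strata, c("G0", "G1", "G2"))
    expect_true(nets[["G0-G1"]]@evaluable)   # 3 samples
    expect_false(nets[["G1-G2"]]@evaluable)  # 1 sample
    expect_true(is.na(complexity(nets[["G1-G2"]])))
})

test_that("zero-variance mediators carry no edges", {
    a <- rbind("IL-6" = c(1, 2, 3, 4, 5),
               "TNF-a" = c(2, 4, 6, 8, 10),
               "IL-10" = rep(7, 5))
    fx <- matrixExperiment(a, rep(c("G0", "G1"), c(3, 2)))
    nets <- buildDynaNetworks(fx$me, fx$strata, c("G0", "G1"))
    e <- nets[[1]]@edges
    expect_false("IL-10" %in% c(e$mediatorA, e$mediatorB))
})

test_that("edges are invariant under positive affine rescaling", {
    set.seed(12)
    a <- matrix(rexp(4 * 6), 4, 6,
                dimnames = list(paste0("M", 1:4), NULL))
    b <- a * c(3, 0.5, 10, 1) + c(100, 7, 0, 2)
    key <- function(a) {
        fx <- matrixExperiment(a, rep(c("G0", "G1"), each = 3))
        e <- buildDynaNetworks(fx$me, fx$strata, c("G0", "G1"),
                               threshold = 0.5)[[1]]@edges
        sort(paste(e$mediatorA, e$mediatorB))
    }
    expect_equal(key(a), key(b))
})

test_that("lowering the threshold never removes an edge", {
    set.seed(21)
    a <- matrix(rexp(5 * 8), 5, 8,
                dimnames = list(paste0("M", 1:5), NULL))
    fx <- matrixExperiment(a, rep(c("G0", "G1"), each = 4))
    prev <- character()
    for (thr in c(0.95, 0.8, 0.6, 0.4, 0.2)) {
        e <- buildDynaNetworks(fx$me, fx$strata, c("G0", "G1"),
                               threshold = thr)[[1]]@edges
        cur <- paste(e$mediatorA, e$mediatorB)
        expect_true(all(prev %in% cur))
        prev <- cur
    }
})

test_that("summaries expose interval, size and complexity", {
    a <- rbind("IL-6" = c(1, 2, 3, 4, 5, 6),
               "TNF-a" = c(2, 4, 6, 8, 10, 12))
    fx <- matrixExperiment(a, rep(c("G0", "G1", "G2"), each = 2))
    nets <- buildDynaNetworks(fx$me, fx$strata, c("G0", "G1", "G2"))
    s <- dynaSummary(nets)
    expect_equal(s$interval, c("G0-G1", "G1-G2"))
    expect_equal(s$nEdges, c(1, 1))
    expect_equal(s$complexity, c(2, 2))  # 2 edges... 2|E|/(n-1) with n=2
    expect_equal(nrow(dynaEdgeTable(nets)), 2)
})
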