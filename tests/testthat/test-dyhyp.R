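# Per-compartment TimeCourse list from a named list of mediators x days
# matrices (shared schedule).
tcList <- function(mats, schedule) {
    lapply(mats, function(m) {
        n <- matrix(1L, nrow(m), ncol(m), dimnames = dimnames(m))
        n[is.na(m)] <- 0L
        new("TimeCourse", group = "g", compartment = "x", values = m,
            nPerCell = n, summaryStat = "mean", schedule = schedule)
    })
}

mkMat <- function(..., meds, days) {
    matrix(c(...), nrow = length(meds), byrow = TRUE,
           dimnames = list(meds, as.character(days)))
}

test_that("window construction enumerates overlapping 3-point intervals", {
    w <- makeWindows(ratSchedule())
    expect_equal(nrow(w), 9)
    expect_equal(unname(w[1, ]), c(0, 3, 5))
    expect_equal(unname(w[9, ]), c(25, 27, 31))
    # consecutive windows overlap with step 1
    for (i in 2:9) expect_equal(unname(w[i, 1:2]), unname(w[i - 1, 2:3]))

    expect_equal(nrow(makeWindows(c(0, 3, 5))), 1)
    expect_error(makeWindows(c(0, 3)), "at least 3")
    expect_error(makeWindows(c(3, 0, 5)), "strictly increasing")
})

test_that("trend correlation against day matches the closed form", {
    expect_equal(trendR(c(1, 2, 3), c(0, 3, 5)),
                 brutePearson(c(1, 2, 3), c(0, 3, 5)),
                 tolerance = 1e-15)
    expect_equal(round(trendR(c(1, 2, 3), c(0, 3, 5)), 4), 0.9934)
    # exactly linear in day: r = 1
    expect_equal(trendR(7 + 2.5 * c(0, 3, 5), c(0, 3, 5)), 1)
    # zero variance or missing: undefined
    expect_true(is.na(trendR(c(5, 5, 5), c(0, 3, 5))))
    expect_true(is.na(trendR(c(1, NA, 3), c(0, 3, 5))))
})

test_that("single-compartment and multi-compartment trends form edges", {
    meds <- c("IL-6", "IL-17A", "IL-10")
    days <- c(0, 3, 5)
    flat <- mkMat(rep(10, 9), meds = meds, days = days)
    skin <- flat; skin["IL-6", ] <- c(10, 13, 15)
    muscle <- flat; muscle["IL-17A", ] <- c(5, 8, 10)
    blood <- flat; blood["IL-17A", ] <- c(50, 80, 100)
    hg <- buildHypergraph(tcList(list(skin = skin, muscle = muscle,
                                      blood = blood), days), days)
    e <- hypergraphEdges(hg)
    expect_equal(nrow(e), 2)
    expect_equal(e$compartments[e$mediator == "IL-6"], "skin")
    expect_equal(e$cardinality[e$mediator == "IL-17A"], 2)
    expect_equal(e$compartments[e$mediator == "IL-17A"], "muscle+blood")
    expect_true(all(e$direction == "increasing"))
})

test_that("opposite directions in different compartments stay separate", {
    meds <- c("IL-6", "TNF-a")
    days <- c(3, 5, 7)
    skin <- mkMat(c(1, 2, 3), c(9, 9, 9), meds = meds, days = days)
    muscle <- mkMat(c(3, 2, 1), c(9, 9, 9), meds = meds, days = days)
    hg <- buildHypergraph(tcList(list(skin = skin, muscle = muscle),
                                 days), days)
    e <- hypergraphEdges(hg)
    expect_equal(nrow(e), 2)
    expect_true(all(e$mediator == "IL-6"))
    expect_setequal(e$direction, c("increasing", "decreasing"))
    expect_true(all(e$cardinality == 1))
    # a compartment appears in at most one directional edge per mediator
    both <- unlist(hg@edges$compartments)
    expect_false(anyDuplicated(both) > 0)
})

test_that("edge tallies by cardinality and direction are exact", {
    meds <- c("IL-6", "IL-17A", "IL-10")
    days <- c(0, 3, 5)
    skin <- mkMat(c(1, 2, 3), rep(7, 3), c(30, 20, 10),
                  meds = meds, days = days)
    muscle <- mkMat(rep(7, 3), c(1, 2, 3), c(3, 2, 1),
                    meds = meds, days = days)
    blood <- mkMat(rep(7, 3), c(10, 20, 30), c(300, 200, 100),
                   meds = meds, days = days)
    hg <- buildHypergraph(tcList(list(skin = skin, muscle = muscle,
                                      blood = blood), days), days)
    d <- edgeDistribution(hg)
    expect_equal(sum(d$count), nrow(hypergraphEdges(hg)))
    get <- function(k, dir) d$count[d$cardinality == k &
                                    d$direction == dir]
    expect_equal(get(1, "increasing"), 1L)  # IL-6 in skin
    expect_equal(get(2, "increasing"), 1L)  # IL-17A muscle+blood
    expect_equal(get(3, "increasing"), 0L)
    expect_equal(get(3, "decreasing"), 1L)  # IL-10 everywhere
    expect_equal(get(1, "decreasing"), 0L)
    expect_equal(get(2, "decreasing"), 0L)

    # empty graph: all cells zero
    flat <- mkMat(rep(1, 9), meds = meds, days = days)
    hg0 <- buildHypergraph(tcList(list(skin = flat, muscle = flat,
                                       blood = flat), days), days)
    expect_true(all(edgeDistribution(hg0)$count == 0))
})

test_that("missing or constant window cells are skipped and logged", {
    meds <- c("IL-6", "TNF-a")
    days <- c(0, 3, 5)
    skin <- mkMat(c(1, NA, 3), c(4, 4, 4), meds = meds, days = days)
    hg <- buildHypergraph(tcList(list(skin = skin), days), days)
    expect_equal(nrow(hypergraphEdges(hg)), 0)
    expect_setequal(hg@skipped$mediator, meds)
    expect_setequal(hg@skipped$reason, c("missing value", "zero variance"))
})

test_that("negating all values swaps increasing and decreasing exactly", {
    set.seed(31)
    meds <- paste0("M", 1:6)
    days <- c(5, 7, 9)
    mats <- lapply(list(skin = 1, muscle = 2, blood = 3), function(i)
        mkMat(rexp(18), meds = meds, days = days))
    hg <- buildHypergraph(tcList(mats, days), days, threshold = 0.3)
    neg <- lapply(mats, function(m) -m)
    hgN <- buildHypergraph(tcList(neg, days), days, threshold = 0.3)
    e <- hypergraphEdges(hg); eN <- hypergraphEdges(hgN)
    flip <- c(increasing = "decreasing", decreasing = "increasing")
    expect_equal(
        sort(paste(e$mediator, flip[e$direction], e$compartments)),
        sort(paste(eN$mediator, eN$direction, eN$compartments)))
    d <- edgeDistribution(hg); dN <- edgeDistribution(hgN)
    expect_equal(d$count[d$direction == "increasing"],
                 dN$count[dN$direction == "decreasing"])
})

test_that("hypergraphs agree with a brute-force triple loop", {
    for (s in 1:4) {
        set.seed(40 + s)
        sched <- ratSchedule()
        meds <- paste0("M", 1:4)
        means <- lapply(list(skin = 1, muscle = 2, blood = 3),
                        function(i) matrix(
                            rexp(length(meds) * length(sched)),
                            length(meds), length(sched),
                            dimnames = list(meds, as.character(sched))))
        ser <- tcList(means, sched)
        win <- makeWindows(sched)
        got <- hyperKeys(lapply(seq_len(nrow(win)), function(i)
            buildHypergraph(ser, win[i, ], threshold = 0.95, index = i)))
        expect_equal(got, bruteHyperEdges(means, sched, 0.95))
    }
})

test_that("the distribution series recovers noiseless planted truth", {
    cfg <- simConfig(
        list(g1 = list(
            trendSpec("IL-6", c("skin", "blood"), c(0, 11),
                      "increasing", slope = 12),
            trendSpec("IL-10", "muscle", c(20, 31), "decreasing",
                      slope = 8, baseline = 200))),
        panel = tinyPanel(), nSubjects = 4, sigma = 0, seed = 17)
    sim <- simulateMediators(cfg)
    ser <- distributionSeries(sim$experiment, "g1")
    expect_length(ser$graphs, 9)
    expect_equal(hyperKeys(ser$graphs), truthKeys(sim$truth))
    # tidy distribution covers every window x direction x cardinality
    expect_equal(nrow(ser$distribution), 9 * 2 * 3)
    expect_equal(sum(ser$distribution$count), nrow(sim$truth))
})

test_that("index mode ignores the calendar spacing of the window", {
    days <- c(9, 11, 20)
    m <- mkMat(c(1, 2, 2.5), meds = "IL-6", days = days)
    tc <- tcList(list(skin = m), days)
    rDay <- trendR(c(1, 2, 2.5), days)
    hgIdx <- buildHypergraph(tc, days, threshold = 0.95,
                             timeMode = "index")
    rIdx <- brutePearson(c(1, 2, 2.5), 1:3)
    e <- hypergraphEdges(hgIdx)
    if (rIdx > 0.95) expect_equal(nrow(e), 1) else expect_equal(nrow(e), 0)
    expect_false(isTRUE(all.equal(rDay, rIdx)))
})
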