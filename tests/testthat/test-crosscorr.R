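# Build a MediatorExperiment whose variables are two mediators in one
# compartment, measured over `n` days for one subject, from two vectors.
pairExperiment <- function(x, y, mediators = c("IL-6", "TNF-a")) {
    days <- seq(0, by = 3, length.out = length(x))
    df <- rbind(
        do.call(rbind, Map(function(d, v)
            rec(day = d, mediator = mediators[1], concentration = v),
            days, x)),
        do.call(rbind, Map(function(d, v)
            rec(day = d, mediator = mediators[2], concentration = v),
            days, y)))
    MediatorExperiment(df, tinyPanel(mediators))
}

test_that("perfectly concordant and discordant pairs hit rho = +/-1", {
    me <- pairExperiment(c(1, 2, 3, 4, 7), c(2, 4, 9, 11, 30))
    res <- spearmanCensus(me, compartments = "skin")
    expect_equal(res@rho["IL-6@skin", "TNF-a@skin"], 1)
    expect_lt(res@p["IL-6@skin", "TNF-a@skin"], 0.05)

    me2 <- pairExperiment(1:5, 5:1)
    res2 <- spearmanCensus(me2, compartments = "skin")
    expect_equal(res2@rho["IL-6@skin", "TNF-a@skin"], -1)
})

test_that("a hand-ranked example gives rho = 0.6", {
    me <- pairExperiment(c(1, 2, 3, 4), c(2, 1, 4, 3))
    res <- spearmanCensus(me, compartments = "skin")
    expect_equal(res@rho["IL-6@skin", "TNF-a@skin"], 0.6,
                 tolerance = 1e-12)
})

test_that("the census matches a brute-force rank/Pearson oracle", {
    panel <- tinyPanel(c("M1", "M2", "M3"))
    for (s in 1:8) {
        set.seed(s)
        n <- 12
        days <- seq_len(n)
        vals <- matrix(rexp(6 * n), nrow = n)   # 3 mediators x 2 comps
        if (s %% 2 == 0) vals <- round(vals, 1) # force midrank ties
        df <- do.call(rbind, lapply(1:3, function(m)
            do.call(rbind, lapply(c("skin", "muscle"), function(cc)
                data.frame(group = "g1", subject = "s1",
                           compartment = cc, day = days,
                           mediator = paste0("M", m),
                           concentration = vals[, (m - 1) * 2 +
                               (cc == "muscle") + 1])))))
        me <- MediatorExperiment(df, panel)
        res <- spearmanCensus(me, compartments = c("skin", "muscle"))
        wide <- sapply(res@labels, function(lb) {
            parts <- strsplit(lb, "@", fixed = TRUE)[[1]]
            vals[, (as.integer(substring(parts[1], 2)) - 1) * 2 +
                     (parts[2] == "muscle") + 1]
        })
        expect_equal(unname(res@rho), unname(bruteSpearman(wide)),
                     tolerance = 1e-12)
    }
})

test_that("rho is invariant under strictly increasing transforms", {
    set.seed(7)
    me <- pairExperiment(rexp(10), rexp(10))
    res <- spearmanCensus(me, compartments = "skin")
    # exp(x/2) is strictly increasing: ranks, hence rho, are unchanged
    df <- asLongTable(me)
    sel <- df$mediator == "IL-6"
    df$concentration[sel] <- exp(df$concentration[sel] / 2)
    res2 <- spearmanCensus(
        MediatorExperiment(df, tinyPanel(c("IL-6", "TNF-a"))),
        compartments = "skin")
    expect_equal(res@rho, res2@rho, tolerance = 1e-12)
})

test_that("significance counting and the percent summary behave", {
    m <- 4
    labels <- paste0("V", 1:m)
    p <- matrix(1, m, m, dimnames = list(labels, labels))
    rho <- diag(1, m); dimnames(rho) <- dimnames(p)
    n <- matrix(10L, m, m)
    res <- new("CorrResult", labels = labels, rho = rho, p = p,
               nUsed = n, meta = list())
    expect_equal(significantCount(res), 0L)
    expect_equal(percentSignificant(res), 0)

    p[1, 2] <- p[2, 1] <- 0.01
    res2 <- new("CorrResult", labels = labels, rho = rho, p = p,
                nUsed = n, meta = list())
    expect_equal(significantCount(res2, 0.05), 1L)
    expect_equal(percentSignificant(res2, 0.05), 1 / 6)

    p[] <- 0.001; diag(p) <- NA
    res3 <- new("CorrResult", labels = labels, rho = rho, p = p,
                nUsed = n, meta = list())
    expect_equal(percentSignificant(res3), 1)
    # monotone in alpha
    counts <- vapply(c(0.001, 0.01, 0.05, 0.2, 1),
                     function(a) significantCount(res2, a), 1L)
    expect_true(all(diff(counts) >= 0))
})

test_that("pairs with fewer than 3 paired observations are flagged missing", {
    df <- rbind(rec(day = 0, mediator = "IL-6", concentration = 1),
                rec(day = 3, mediator = "IL-6", concentration = 2),
                rec(day = 5, mediator = "IL-6", concentration = 3),
                rec(day = 0, mediator = "TNF-a", concentration = 5),
                rec(day = 3, mediator = "TNF-a", concentration = 4),
                rec(day = 5, mediator = "TNF-a", concentration = 2),
                rec(day = 0, mediator = "IL-10", concentration = 1),
                rec(day = 3, mediator = "IL-10", concentration = 2))
    me <- MediatorExperiment(df, tinyPanel())
    res <- spearmanCensus(me, compartments = "skin")
    expect_true(is.na(res@rho["IL-6@skin", "IL-10@skin"]))
    expect_true(is.na(res@p["IL-6@skin", "IL-10@skin"]))
    # the two missing pairs leave the denominator: 1 evaluable pair,
    # and it is significant at alpha = 1
    expect_equal(percentSignificant(res, 1), 1)
    expect_equal(sum(res@nUsed[upper.tri(res@nUsed)] >= 3), 1)
})

test_that("the null census is calibrated near alpha", {
    nData <- 300
    counts <- numeric(nData)
    panel <- tinyPanel(paste0("M", 1:5))
    for (s in seq_len(nData)) {
        set.seed(20000 + s)
        n <- 20
        df <- do.call(rbind, lapply(paste0("M", 1:5), function(m)
            data.frame(group = "g1", subject = "s1",
                       compartment = "skin", day = seq_len(n),
                       mediator = m, concentration = rexp(n))))
        res <- spearmanCensus(MediatorExperiment(df, panel),
                              compartments = "skin")
        counts[s] <- significantCount(res, 0.05)
    }
    # 10 pairs at alpha 0.05: expect about 0.5 significant per dataset
    expect_gt(mean(counts), 0.3)
    expect_lt(mean(counts), 0.7)
})

test_that("exact permutation p-values agree with enumeration logic", {
    me <- pairExperiment(1:5, c(1, 2, 3, 4, 5))
    res <- spearmanCensus(me, compartments = "skin",
                          pMethod = "permutation")
    # only the identity and the full reversal achieve |rho| = 1
    expect_equal(res@p["IL-6@skin", "TNF-a@skin"], 2 / 120,
                 tolerance = 1e-12)
})

test_that("BH adjustment never decreases census p-values", {
    set.seed(33)
    me <- pairExperiment(rexp(12), rexp(12))
    raw <- spearmanCensus(me, compartments = "skin")
    adj <- spearmanCensus(me, compartments = "skin", adjust = "BH")
    ut <- upper.tri(raw@p)
    expect_true(all(adj@p[ut] >= raw@p[ut] - 1e-15, na.rm = TRUE))
})

test_that("clustering order is a permutation of the variables", {
    set.seed(5)
    me <- pairExperiment(rexp(10), rexp(10))
    res <- spearmanCensus(me, compartments = "skin")
    ord <- corrClusterOrder(res)
    expect_setequal(ord, seq_along(res@labels))
})
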