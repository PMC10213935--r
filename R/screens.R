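#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak multiplicity adjustment: with the m raw p-values in
#' ascending order, the i-th is adjusted to
#' \eqn{1 - (1 - p_{(i)})^{m - i + 1}}, then monotonized by running
#' maximum. Adjusted values are always >= raw and non-decreasing in the
#' raw ordering. Slightly more powerful than Holm's Bonferroni step-down
#' under independence; this is the post hoc family adjustment used with
#' the two-way screen.
#'
#' @param p numeric vector of raw p-values (NAs preserved).
#' @return adjusted p-values in the original order.
#' @examples
#' holmSidak(c(0.01, 0.04, 0.03))
#' @export
holmSidak <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- which(!is.na(p))
    if (!length(ok)) return(out)
    m <- length(ok)
    ord <- ok[order(p[ok])]
    adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
    out[ord] <- pmin(cummax(adj), 1)
    out
}

# Natural-log transform with half-minimum substitution for zeros.
# Multiplex concentrations are positive and right-skewed; analyses run on
# the log scale.
.logConc <- function(v) {
    pos <- v[!is.na(v) & v > 0]
    if (!length(pos)) return(rep(NA_real_, length(v)))
    half <- min(pos) / 2
    log(ifelse(!is.na(v) & v <= 0, half, v))
}

# Long-format selection of one (group(s), compartment) slice.
.screenSlice <- function(x, groups, compartment) {
    cd <- colData(x)
    sel <- cd$group %in% groups & cd$compartment == compartment
    list(a = assay(x, "concentration")[, sel, drop = FALSE],
         group = cd$group[sel], day = cd$day[sel])
}

#' One-way ANOVA of a mediator's time course
#'
#' Tests whether a mediator's (log-transformed) concentration differs
#' across sampling days within one group and compartment, treating day as
#' a categorical factor and samples as independent replicates. Requires
#' at least 2 days carrying at least 2 replicates each; otherwise the
#' mediator is unevaluable and \code{NA} is returned (with attribute
#' \code{reason}).
#'
#' @param x a \linkS4class{MediatorExperiment}.
#' @param group,compartment the stratum to test.
#' @param mediator panel mediator name.
#' @return the ANOVA F-test p-value, or \code{NA} if unevaluable.
#' @export
oneWayTimeAnova <- function(x, group, compartment, mediator) {
    stopifnot(is(x, "MediatorExperiment"))
    if (!mediator %in% panelNames(x))
        stop("unknown mediator '", mediator, "'")
    sl <- .screenSlice(x, group, compartment)
    v <- sl$a[mediator, ]
    keep <- !is.na(v)
    v <- v[keep]; day <- sl$day[keep]
    tab <- table(day)
    if (sum(tab >= 2L) < 2L || length(tab) < 2L)
        return(structure(NA_real_, reason = "insufficient replication"))
    fit <- stats::aov(.logConc(v) ~ factor(day))
    summary(fit)[[1]][["Pr(>F)"]][1]
}

#' Two-way (group x time) ANOVA screen with Holm-Sidak post hoc
#'
#' For every panel mediator, fits a two-way ANOVA of log concentration on
#' experimental group, sampling day (categorical) and their interaction,
#' comparing two groups in one compartment. Per-day pairwise group
#' comparisons (Welch t-tests) are Holm-Sidak adjusted within the
#' mediator. A mediator is flagged significant when its group main effect
#' p-value is below \code{alpha}; mediators with empty group x day cells
#' or cells with fewer than 2 replicates are flagged unevaluable, never
#' dropped silently. Optionally, Benjamini-Hochberg adjustment may be
#' applied across mediators.
#'
#' @param x a \linkS4class{MediatorExperiment}.
#' @param groupA,groupB the two experimental groups.
#' @param compartment the compartment screened.
#' @param alpha significance level (default 0.05).
#' @param adjustAcross \code{"none"} (default, matching raw per-mediator
#'   reporting) or \code{"BH"} across mediators (applied to the group
#'   effect p before flagging).
#' @return data.frame (one row per mediator): \code{mediator},
#'   \code{compartment}, \code{pGroup}, \code{pTime},
#'   \code{pInteraction}, \code{pHolmSidakMin} (smallest adjusted per-day
#'   group comparison), \code{significant}, \code{evaluable}.
#' @export
twoWayScreen <- function(x, groupA, groupB, compartment, alpha = 0.05,
                         adjustAcross = c("none", "BH")) {
    stopifnot(is(x, "MediatorExperiment"))
    adjustAcross <- match.arg(adjustAcross)
    sl <- .screenSlice(x, c(groupA, groupB), compartment)
    if (!any(sl$group == groupA) || !any(sl$group == groupB))
        stop("both groups must have samples in compartment '",
             compartment, "'")
    meds <- panelNames(x)
    rows <- lapply(meds, function(m) {
        v <- sl$a[m, ]
        keep <- !is.na(v)
        v <- v[keep]; g <- sl$group[keep]; d <- sl$day[keep]
        cells <- table(factor(g, levels = c(groupA, groupB)), d)
        if (length(unique(d)) < 2L || any(cells < 2L) ||
            ncol(cells) == 0L)
            return(data.frame(mediator = m, compartment = compartment,
                              pGroup = NA_real_, pTime = NA_real_,
                              pInteraction = NA_real_,
                              pHolmSidakMin = NA_real_,
                              significant = NA, evaluable = FALSE))
        lv <- .logConc(v)
        fit <- stats::lm(lv ~ factor(g) * factor(d))
        an <- stats::anova(fit)
        pd <- vapply(sort(unique(d)), function(dd) {
            stats::t.test(lv[g == groupA & d == dd],
                          lv[g == groupB & d == dd])$p.value
        }, 1)
        pg <- an["factor(g)", "Pr(>F)"]
        data.frame(mediator = m, compartment = compartment,
                   pGroup = pg,
                   pTime = an["factor(d)", "Pr(>F)"],
                   pInteraction = an["factor(g):factor(d)", "Pr(>F)"],
                   pHolmSidakMin = min(holmSidak(pd)),
                   significant = pg < alpha, evaluable = TRUE)
    })
    out <- do.call(rbind, rows)
    if (adjustAcross == "BH") {
        adj <- stats::p.adjust(out$pGroup, method = "BH")
        out$pGroupAdjusted <- adj
        out$significant <- ifelse(out$evaluable, adj < alpha, NA)
    }
    rownames(out) <- NULL
    out
}

#' Volcano-style two-group comparison
#'
#' Per mediator, compares two groups in one compartment pooling all days:
#' fold change is mean(groupB)/mean(groupA) on the raw concentration
#' scale, the p-value a two-sided Welch t-test on log-transformed values.
#' A mediator is a hit when |log2 FC| reaches log2 of the fold-change
#' threshold (default 2) and p < alpha (default 0.05). Groups whose
#' pooled mean is zero get the half-minimum substitution and are flagged
#' in the \code{substituted} column.
#'
#' @param x a \linkS4class{MediatorExperiment}.
#' @param groupA,groupB reference and comparison groups (FC is B over A).
#' @param compartment the compartment compared.
#' @param fcThreshold fold-change gate (default 2.0).
#' @param alpha significance gate (default 0.05).
#' @return data.frame per mediator: \code{mediator}, \code{log2FC},
#'   \code{p}, \code{hit}, \code{substituted}, \code{evaluable}.
#' @export
volcanoScreen <- function(x, groupA, groupB, compartment,
                          fcThreshold = 2.0, alpha = 0.05) {
    stopifnot(is(x, "MediatorExperiment"), fcThreshold > 0)
    sl <- .screenSlice(x, c(groupA, groupB), compartment)
    if (!any(sl$group == groupA) || !any(sl$group == groupB))
        stop("both groups must have samples in compartment '",
             compartment, "'")
    meds <- panelNames(x)
    rows <- lapply(meds, function(m) {
        vA <- sl$a[m, sl$group == groupA]
        vB <- sl$a[m, sl$group == groupB]
        vA <- vA[!is.na(vA)]; vB <- vB[!is.na(vB)]
        if (length(vA) < 2L || length(vB) < 2L)
            return(data.frame(mediator = m, log2FC = NA_real_,
                              p = NA_real_, hit = NA,
                              substituted = FALSE, evaluable = FALSE))
        mA <- mean(vA); mB <- mean(vB)
        subd <- FALSE
        if (mA <= 0 || mB <= 0) {
            pos <- c(vA, vB)[c(vA, vB) > 0]
            if (!length(pos))
                return(data.frame(mediator = m, log2FC = NA_real_,
                                  p = NA_real_, hit = NA,
                                  substituted = TRUE,
                                  evaluable = FALSE))
            half <- min(pos) / 2
            if (mA <= 0) mA <- half
            if (mB <= 0) mB <- half
            subd <- TRUE
        }
        lfc <- log2(mB / mA)
        lAll <- .logConc(c(vA, vB))
        lA <- lAll[seq_along(vA)]
        lB <- lAll[-seq_along(vA)]
        p <- if (stats::sd(lA) == 0 && stats::sd(lB) == 0) {
            if (isTRUE(all.equal(mean(lA), mean(lB)))) 1 else 0
        } else stats::t.test(lA, lB)$p.value
        data.frame(mediator = m, log2FC = lfc, p = p,
                   hit = abs(lfc) >= log2(fcThreshold) & p < alpha,
                   substituted = subd, evaluable = TRUE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
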