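#' Spearman cross-correlation census over mediator-compartment variables
#'
#' Computes the full Spearman rank correlation matrix over all
#' (mediator, compartment) variables in the selected compartments.
#' Observations are individual samples aligned by exact
#' \{group, subject, day\} key across compartments, pooling all time
#' points and subjects of the selected groups; missing values are deleted
#' pairwise. Two-sided p-values come from the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} df (the behaviour of
#' standard census tools); an exact permutation p-value is available for
#' small n. Pairs with fewer than 3 paired observations are flagged
#' missing (\code{NA}).
#'
#' @param x a \linkS4class{MediatorExperiment}.
#' @param groups groups to pool (default: all).
#' @param compartments compartments contributing variables (default: all
#'   present).
#' @param pMethod \code{"t"} (default) or \code{"permutation"} (exact,
#'   only for pairs with n <= 9).
#' @param adjust \code{"none"} (default; census counts use raw p < alpha)
#'   or \code{"BH"} Benjamini-Hochberg across the off-diagonal pairs.
#' @return a \linkS4class{CorrResult}.
#' @seealso [significantCount()], [percentSignificant()],
#'   [corrClusterOrder()]
#' @export
spearmanCensus <- function(x, groups = studyGroups(x),
                           compartments = compartmentNames(x),
                           pMethod = c("t", "permutation"),
                           adjust = c("none", "BH")) {
    stopifnot(is(x, "MediatorExperiment"))
    pMethod <- match.arg(pMethod)
    adjust <- match.arg(adjust)
    cd <- colData(x)
    sel <- cd$group %in% groups & cd$compartment %in% compartments
    if (!any(sel)) stop("no samples match the requested groups/compartments")
    a <- assay(x, "concentration")[, sel, drop = FALSE]
    cd <- cd[sel, ]

    obsKey <- paste(cd$group, cd$subject, cd$day, sep = "\r")
    obs <- unique(obsKey)
    meds <- panelNames(x)
    comps <- compartments[compartments %in% unique(cd$compartment)]
    labels <- as.vector(outer(meds, comps, paste, sep = "@"))
    m <- length(labels)
    if (m < 2) stop("at least 2 variables are required")

    wide <- matrix(NA_real_, nrow = length(obs), ncol = m,
                   dimnames = list(obs, labels))
    for (ci in seq_along(comps)) {
        cols <- which(cd$compartment == comps[ci])
        rows <- match(obsKey[cols], obs)
        wide[rows, (ci - 1L) * length(meds) + seq_along(meds)] <-
            t(a[, cols, drop = FALSE])
    }

    nUsed <- crossprod(!is.na(wide))
    rho <- suppressWarnings(
        stats::cor(wide, method = "spearman",
                   use = "pairwise.complete.obs"))
    rho[nUsed < 3L] <- NA_real_
    diag(rho) <- 1

    p <- matrix(NA_real_, m, m, dimnames = dimnames(rho))
    if (pMethod == "t") {
        r <- rho
        n <- nUsed
        ok <- !is.na(r) & n >= 3L & row(r) != col(r)
        tt <- abs(r[ok]) * sqrt((n[ok] - 2) / pmax(1 - r[ok]^2, 0))
        pv <- 2 * stats::pt(tt, df = n[ok] - 2, lower.tail = FALSE)
        pv[abs(r[ok]) >= 1 - 1e-15] <- 0
        p[ok] <- pmin(pv, 1)
    } else {
        for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
            cc <- stats::complete.cases(wide[, i], wide[, j])
            if (sum(cc) < 3L || is.na(rho[i, j])) next
            p[i, j] <- p[j, i] <-
                .spearmanPermP(wide[cc, i], wide[cc, j])
        }
    }
    if (adjust == "BH") {
        ut <- upper.tri(p)
        p[ut] <- stats::p.adjust(p[ut], method = "BH")
        p[lower.tri(p)] <- t(p)[lower.tri(p)]
    }
    new("CorrResult", labels = labels, rho = rho, p = p,
        nUsed = nUsed,
        meta = list(groups = groups, compartments = comps,
                    pMethod = pMethod, adjust = adjust,
                    pooling = "all samples concatenated within cohort"))
}

# Exact two-sided permutation p-value for Spearman rho (n <= 9).
.spearmanPermP <- function(x, y) {
    n <- length(x)
    if (n > 9L)
        stop("exact permutation p-values are limited to n <= 9; ",
             "use pMethod = 't'")
    rx <- rank(x)
    ry <- rank(y)
    obs <- abs(stats::cor(rx, ry))
    perms <- .permutations(n)
    vals <- apply(perms, 1, function(idx) abs(stats::cor(rx, ry[idx])))
    mean(vals >= obs - 1e-12)
}

# All permutations of 1..n as a (n!, n) matrix.
.permutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- .permutations(n - 1L)
    out <- matrix(0L, n * nrow(sub), n)
    for (i in seq_len(n)) {
        rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
        out[rows, 1L] <- i
        out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
    }
    out
}

#' @describeIn significantCount number of significant unordered pairs.
#' @export
setMethod("significantCount", "CorrResult", function(x, alpha = 0.05) {
    p <- x@p
    sum(p[upper.tri(p)] < alpha, na.rm = TRUE)
})

#' @describeIn significantCount significant pairs over evaluable pairs.
#' @export
setMethod("percentSignificant", "CorrResult", function(x, alpha = 0.05) {
    p <- x@p[upper.tri(x@p)]
    evaluable <- sum(!is.na(p))
    if (evaluable == 0L) return(0)
    sum(p < alpha, na.rm = TRUE) / evaluable
})

#' Variable ordering for correlation heatmaps
#'
#' Average-linkage hierarchical clustering on the 1 - rho distance,
#' giving the row/column order used to display census heatmaps on a
#' colour scale fixed to [-1, 1]. Missing correlations are treated as 0
#' (maximal distance 1) for ordering purposes only.
#'
#' @param x a \linkS4class{CorrResult}.
#' @return integer permutation of the variable indices.
#' @export
corrClusterOrder <- function(x) {
    stopifnot(is(x, "CorrResult"))
    rho <- x@rho
    rho[is.na(rho)] <- 0
    stats::hclust(stats::as.dist(1 - rho), method = "average")$order
}

#' Render a census heatmap
#'
#' Thin optional wrapper around \pkg{pheatmap} with the colour scale
#' fixed to [-1, 1] and rows/columns ordered by [corrClusterOrder()], so
#' census panels from different groups are directly comparable.
#'
#' @param x a \linkS4class{CorrResult}.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plotCorrHeatmap <- function(x, ...) {
    stopifnot(is(x, "CorrResult"))
    if (!requireNamespace("pheatmap", quietly = TRUE))
        stop("plotCorrHeatmap requires the 'pheatmap' package")
    ord <- corrClusterOrder(x)
    rho <- x@rho[ord, ord]
    ph <- pheatmap::pheatmap(
        rho, cluster_rows = FALSE, cluster_cols = FALSE,
        breaks = seq(-1, 1, length.out = 101), ...)
    invisible(ph)
}

setMethod("show", "CorrResult", function(object) {
    m <- length(object@labels)
    cat("CorrResult:", m, "variables,", m * (m - 1) / 2,
        "unordered pairs\n")
    cat("  significant at 0.05:", significantCount(object, 0.05),
        sprintf("(%.1f%%)\n", 100 * percentSignificant(object, 0.05)))
})
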