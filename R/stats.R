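# Pairwise-complete Euclidean distance between rows, scaled by
# sqrt(ncol / #shared) so rows with missing cells stay comparable.
.pcDist <- function(m) {
    n <- nrow(m); p <- ncol(m)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        sh <- which(!is.na(m[i, ]) & !is.na(m[j, ]))
        if (!length(sh))
            stop("rows ", i, " and ", j, " share no observed cells")
        d[i, j] <- d[j, i] <-
            sqrt(sum((m[i, sh] - m[j, sh])^2) * p / length(sh))
    }
    rownames(d) <- colnames(d) <- rownames(m)
    as.dist(d)
}

#' Hierarchical clustering of a log2 fold-change matrix
#'
#' Average-linkage (UPGMA) agglomeration on Euclidean distances, applied
#' independently to the genes (rows) and treatments (columns). Missing cells
#' are handled by pairwise-complete distances scaled by
#' \code{sqrt(ncol / shared)}; all-missing rows or columns are dropped with
#' a warning.
#'
#' @param mat numeric matrix of log2 fold changes, genes x treatments
#'   (NA = missing).
#' @return a \linkS4class{ClusterResult}.
#' @export
clusterLog2FC <- function(mat) {
    stopifnot(is.matrix(mat))
    emptyRow <- rowSums(!is.na(mat)) == 0L
    emptyCol <- colSums(!is.na(mat)) == 0L
    if (any(emptyRow) || any(emptyCol)) {
        warning("dropping ", sum(emptyRow), " all-missing row(s) and ",
                sum(emptyCol), " all-missing column(s)")
        mat <- mat[!emptyRow, !emptyCol, drop = FALSE]
    }
    if (nrow(mat) < 2L || ncol(mat) < 2L)
        stop("need at least 2 rows and 2 columns")
    hr <- hclust(.pcDist(mat), method = "average")
    hc <- hclust(.pcDist(t(mat)), method = "average")
    new("ClusterResult", rowOrder = as.integer(hr$order),
        colOrder = as.integer(hc$order), rowDendrogram = hr,
        colDendrogram = hc, matrix = mat)
}

#' @describeIn clusterLog2FC write the clustered (reordered) matrix as CSV.
#' @param cr a \linkS4class{ClusterResult}.
#' @param path output file.
#' @export
writeClusteredMatrix <- function(cr, path) {
    write.csv(cr@matrix[cr@rowOrder, cr@colOrder, drop = FALSE], path)
    invisible(path)
}

#' @describeIn clusterLog2FC export a dendrogram as Newick text
#'   (heights in Euclidean distance units).
#' @param which \code{"row"} or \code{"col"} dendrogram.
#' @export
exportNewick <- function(cr, path, which = c("row", "col")) {
    which <- match.arg(which)
    hc <- if (which == "row") cr@rowDendrogram else cr@colDendrogram
    ape::write.tree(ape::as.phylo(hc), file = path)
    invisible(path)
}

#' Spearman validation of two fold-change profiles
#'
#' Rank correlation (midranks for ties) between two arms of per-gene mean
#' log2 fold changes — e.g. cytokine treatment versus receptor knock-down —
#' over the genes present (non-missing) in both arms. The two-tailed
#' p-value uses the exact null distribution for small tie-free samples
#' (n <= 10) and the t-approximation
#' \code{t = rs * sqrt((n - 2) / (1 - rs^2))} with n - 2 df otherwise.
#'
#' @param fcA,fcB named numeric vectors of per-gene mean log2 fold changes.
#' @return a \linkS4class{ValidationReport}.
#' @examples
#' spearmanValidation(c(g1 = 1, g2 = 2, g3 = 3), c(g1 = 3, g2 = 1, g3 = 2))
#' @export
spearmanValidation <- function(fcA, fcB) {
    shared <- intersect(names(fcA)[!is.na(fcA)], names(fcB)[!is.na(fcB)])
    n <- length(shared)
    if (n < 3L) stop("need at least 3 genes shared between the arms")
    x <- fcA[shared]; y <- fcB[shared]
    if (sd(x) == 0 || sd(y) == 0)
        stop("zero variance in one arm; Spearman undefined")
    rs <- cor(x, y, method = "spearman")
    noTies <- !anyDuplicated(x) && !anyDuplicated(y)
    if (n <= 10L && noTies) {
        p <- suppressWarnings(
            cor.test(x, y, method = "spearman", exact = TRUE,
                     alternative = "two.sided")$p.value)
    } else if (abs(rs) >= 1) {
        p <- 0
    } else {
        tstat <- rs * sqrt((n - 2) / (1 - rs^2))
        p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    new("ValidationReport", rs = unname(rs), n = as.integer(n),
        p = unname(p),
        pairs = data.frame(gene = shared, meanA = unname(x),
                           meanB = unname(y), stringsAsFactors = FALSE))
}

#' Compare family predictions with normalized data
#'
#' For every (gene, condition): the mean prediction over the family's
#' models, the mean and standard deviation of the normalized measurements
#' across donors, and the absolute deviation between the two means. Rows are
#' sorted by decreasing deviation so systematic misfits surface first.
#'
#' @param family a \linkS4class{ModelFamily}.
#' @param design an \linkS4class{ExperimentDesign}.
#' @param data a \linkS4class{NormalizedSet}.
#' @return data.frame with columns \code{gene}, \code{condition},
#'   \code{prediction}, \code{value}, \code{sd}, \code{absDeviation}.
#' @export
predictionVsData <- function(family, design, data) {
    if (!length(family@models)) stop("empty model family")
    genes <- rownames(assay(data, "norm"))
    pred <- 0
    for (m in family@models)
        pred <- pred + simulateStates(m, design)[genes, , drop = FALSE]
    pred <- pred / length(family@models)
    v <- assay(data, "norm")
    cond <- colData(data)$condition
    out <- do.call(rbind, lapply(design@conditions, function(cd) {
        sub <- v[, cond == cd, drop = FALSE]
        data.frame(gene = genes, condition = cd,
                   prediction = pred[, cd],
                   value = rowMeans(sub, na.rm = TRUE),
                   sd = apply(sub, 1L, sd, na.rm = TRUE),
                   stringsAsFactors = FALSE)
    }))
    out$absDeviation <- abs(out$prediction - out$value)
    out <- out[order(-out$absDeviation), ]
    rownames(out) <- NULL
    out
}

#' Grouped two-sample t-test
#'
#' Pooled-variance (grouped) two-tailed t-test by default, Welch by flag.
#' Significance is flagged at p < 0.05.
#'
#' @param treated,control numeric replicate values (>= 2 each).
#' @param welch if \code{TRUE}, do not pool variances.
#' @return list with \code{statistic}, \code{df}, \code{p}, and
#'   \code{significant}.
#' @examples
#' groupedTTest(c(1, 2, 3), c(4, 5, 6))  # p ~ 0.021
#' @export
groupedTTest <- function(treated, control, welch = FALSE) {
    if (length(treated) < 2L || length(control) < 2L)
        stop("need at least 2 replicates per arm")
    if (sd(treated) == 0 && sd(control) == 0)
        stop("zero pooled variance; t-test undefined")
    tt <- t.test(treated, control, var.equal = !welch,
                 alternative = "two.sided")
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, significant = tt$p.value < 0.05)
}
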