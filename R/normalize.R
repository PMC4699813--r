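#' Fold changes from Ct values (delta-delta-Ct)
#'
#' Per sample, \code{dCt = Ct(gene) - Ct(reference gene)}; per donor,
#' \code{ddCt = dCt(sample) - dCt(calibrator sample)}; the linear fold change
#' is \code{2^(-ddCt)}, so the calibrator condition is 1 for every gene by
#' construction. A sample with a missing reference Ct yields missing fold
#' changes for all its genes (nothing is imputed).
#'
#' @param ct numeric matrix of Ct values (PCR cycles), genes x samples; must
#'   include the reference gene row.
#' @param sampleInfo data.frame with columns \code{sample}, \code{donor},
#'   \code{condition}, one row per column of \code{ct}.
#' @param referenceGene name of the reference (housekeeping) gene row.
#' @param calibratorCondition condition used as calibrator (e.g. the vehicle
#'   control); must be present once per donor.
#' @return a \linkS4class{MeasurementSet} (reference gene dropped).
#' @export
deltaDeltaCt <- function(ct, sampleInfo, referenceGene,
                         calibratorCondition) {
    stopifnot(is.matrix(ct), !is.null(rownames(ct)))
    if (!referenceGene %in% rownames(ct))
        stop("reference gene '", referenceGene, "' not in Ct table")
    sampleInfo <- as.data.frame(sampleInfo, stringsAsFactors = FALSE)
    if (!identical(nrow(sampleInfo), ncol(ct)))
        stop("sampleInfo must have one row per Ct column")
    refCt <- ct[referenceGene, ]
    dct <- sweep(ct[setdiff(rownames(ct), referenceGene), , drop = FALSE],
                 2L, refCt)
    dct[, is.na(refCt)] <- NA_real_
    tables <- list()
    for (d in unique(sampleInfo$donor)) {
        cols <- which(sampleInfo$donor == d)
        cal <- cols[sampleInfo$condition[cols] == calibratorCondition]
        if (length(cal) != 1L)
            stop("donor ", d, " needs exactly one calibrator sample")
        ddct <- sweep(dct[, cols, drop = FALSE], 1L, dct[, cal])
        fc <- 2^(-ddct)
        colnames(fc) <- sampleInfo$condition[cols]
        tables[[as.character(d)]] <- fc
    }
    MeasurementSet(tables)
}

#' Hill normalization of fold changes into [0,1]
#'
#' \code{v = fc^h / (m^h + fc^h)}: strictly increasing in \code{fc}, with
#' \code{v(0) = 0}, \code{v(m) = 0.5} and \code{v -> 1} as
#' \code{fc -> Inf}. With the default scheme (h = 4), a control fold change
#' of 1 maps near 1 for down-regulated genes (m = 0.5) and near 0 for
#' up-regulated genes (m >= 2), anchoring control states at the Boolean
#' extremes the steady-state model produces without stimulus.
#'
#' @param fc linear fold change(s), >= 0 (NA passed through).
#' @param m midpoint in linear fold-change units, > 0.
#' @param h Hill coefficient, >= 1.
#' @return normalized value(s) in [0,1].
#' @examples
#' hillNormalize(1, m = 0.5, h = 4)  # ~0.9412
#' hillNormalize(1, m = 2, h = 4)    # ~0.0588
#' @export
hillNormalize <- function(fc, m, h) {
    if (any(m <= 0)) stop("midpoint m must be positive")
    if (any(h < 1)) stop("Hill coefficient h must be >= 1")
    if (any(fc[!is.na(fc)] < 0)) stop("fold changes must be >= 0")
    fc^h / (m^h + fc^h)
}

#' @rdname hillNormalize
#' @param v normalized value(s) strictly inside (0,1).
#' @details \code{inverseHill} is the algebraic inverse
#'   \code{fc = m * (v / (1 - v))^(1/h)}; it is used to manufacture fold
#'   changes from model states when emitting synthetic data. Values of 0 or
#'   1 map to 0 / infinity and are rejected; clip first.
#' @export
inverseHill <- function(v, m, h) {
    if (any(m <= 0)) stop("midpoint m must be positive")
    if (any(h < 1)) stop("Hill coefficient h must be >= 1")
    if (any(v[!is.na(v)] <= 0 | v[!is.na(v)] >= 1))
        stop("v must lie strictly inside (0,1)")
    m * (v / (1 - v))^(1 / h)
}

#' Assign per-gene normalization midpoints
#'
#' Classifies each gene by its mean IL-6 fold change across donors (missing
#' values excluded): mean < 1 is down-regulated (m = 0.5), mean in
#' [1, strongUpCutoff) weakly induced (m = 2), mean >= strongUpCutoff
#' strongly induced (m = mean / 2). The Hill coefficient is 4 for all genes.
#'
#' @param ms a \linkS4class{MeasurementSet}.
#' @param il6Condition name of the stimulus-alone condition used for
#'   classification (inhibitor conditions are not used).
#' @param strongUpCutoff fold-change cutoff separating weak from strong
#'   induction (default 4).
#' @param overrides optional named numeric vector of per-gene midpoints that
#'   take precedence over the classification.
#' @return a \linkS4class{NormalizationScheme}.
#' @export
assignMidpoints <- function(ms, il6Condition = "IL6", strongUpCutoff = 4,
                            overrides = NULL) {
    cond <- colData(ms)$condition
    if (!il6Condition %in% cond)
        stop("condition '", il6Condition, "' not present")
    fc <- assay(ms, "fc")[, cond == il6Condition, drop = FALSE]
    nObs <- rowSums(!is.na(fc))
    if (any(nObs == 0L))
        stop("gene(s) missing in all donors: ",
             paste(rownames(fc)[nObs == 0L], collapse = ", "))
    meanFC <- rowMeans(fc, na.rm = TRUE)
    m <- ifelse(meanFC < 1, 0.5,
                ifelse(meanFC < strongUpCutoff, 2, meanFC / 2))
    dir <- ifelse(meanFC < 1, "down", "up")
    names(m) <- names(dir) <- rownames(fc)
    if (!is.null(overrides)) {
        bad <- setdiff(names(overrides), names(m))
        if (length(bad))
            stop("override for unknown gene(s): ", paste(bad, collapse = ", "))
        m[names(overrides)] <- overrides
    }
    new("NormalizationScheme", h = 4, midpoints = m, direction = dir)
}

#' Normalize a fold-change table with a midpoint scheme
#'
#' Applies \code{\link{hillNormalize}} gene-wise with the scheme's per-gene
#' midpoint and shared Hill coefficient; missing cells stay missing.
#'
#' @param ms a \linkS4class{MeasurementSet}.
#' @param scheme a \linkS4class{NormalizationScheme} covering all genes of
#'   \code{ms}.
#' @return a \linkS4class{NormalizedSet}.
#' @export
normalizeFoldChanges <- function(ms, scheme) {
    fc <- assay(ms, "fc")
    absent <- setdiff(rownames(fc), names(scheme@midpoints))
    if (length(absent))
        stop("no midpoint for gene(s): ", paste(absent, collapse = ", "))
    m <- scheme@midpoints[rownames(fc)]
    v <- fc^scheme@h / (m^scheme@h + fc^scheme@h)
    se <- SummarizedExperiment(assays = list(norm = v),
                               colData = colData(ms))
    new("NormalizedSet", se, scheme = scheme)
}
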