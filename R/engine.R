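#' Normalized Hill transfer function
#'
#' \code{f(x) = x^n (1 + k^n) / (x^n + k^n)}: strictly increasing on [0,1]
#' with \code{f(0) = 0} and \code{f(1) = 1}, so Boolean inputs propagate
#' exactly. \code{k} is the half-activation gain (in state units), \code{n}
#' the steepness.
#'
#' @param x input state(s) in [0,1].
#' @param k gain in (0,1].
#' @param n Hill exponent >= 1.
#' @return transformed value(s) in [0,1].
#' @examples
#' transferHill(0.5, k = 0.5, n = 4)  # 0.53125
#' @export
transferHill <- function(x, k, n) {
    if (any(x < 0 | x > 1)) stop("transfer input must lie in [0,1]")
    if (k <= 0 || k > 1) stop("k must be in (0,1]")
    if (n < 1) stop("n must be >= 1")
    ifelse(x == 0, 0, x^n * (1 + k^n) / (x^n + k^n))
}

# ---- compilation helpers: turn S4 objects into the integer/double arrays
# ---- the C++ kernel consumes. Species indices are 0-based.

.gateArrays <- function(gatesList, speciesNames) {
    G <- length(gatesList)
    gateTarget <- integer(G)
    inputSrc <- integer(0); inputSign <- integer(0)
    gateOff <- integer(G + 1L)
    for (g in seq_len(G)) {
        gt <- gatesList[[g]]
        gateTarget[g] <- match(gt$target, speciesNames) - 1L
        srcIdx <- match(gt$sources, speciesNames) - 1L
        if (anyNA(gateTarget[g]) || anyNA(srcIdx))
            stop("gate references species absent from the network")
        inputSrc <- c(inputSrc, srcIdx)
        inputSign <- c(inputSign, as.integer(gt$signs))
        gateOff[g + 1L] <- gateOff[g] + length(srcIdx)
    }
    list(gateTarget = gateTarget, gateOff = gateOff,
         inputSrc = inputSrc, inputSign = inputSign)
}

.baselineVector <- function(net) {
    ifelse(net@species$constitutive, 1, 0)
}

.topoIndices <- function(net) {
    match(.topoOrder(net), net@species$name) - 1L
}

.clampMatrix <- function(design, speciesNames) {
    nC <- length(design@conditions)
    clamp <- matrix(NA_real_, nrow = length(speciesNames), ncol = nC,
                    dimnames = list(speciesNames, design@conditions))
    for (i in seq_len(nC)) {
        st <- design@stimuli[[i]]
        for (s in names(st)) {
            if (!s %in% speciesNames)
                stop("stimulus species '", s, "' not in network")
            clamp[s, i] <- st[[s]]
        }
        for (s in design@inhibited[[i]]) {
            if (!s %in% speciesNames)
                stop("inhibited species '", s, "' not in network")
            clamp[s, i] <- 0
        }
    }
    clamp
}

# Sufficient statistics of the normalized data pooled across donors:
# per (gene, condition) the count, sum and sum of squares of non-missing
# donor values, in the design's condition order.
.dataStats <- function(data, speciesNames, conditionNames) {
    v <- assay(data, "norm")
    genes <- rownames(v)
    missingGenes <- setdiff(genes, speciesNames)
    if (length(missingGenes))
        stop("measured gene(s) absent from the model: ",
             paste(missingGenes, collapse = ", "))
    cond <- colData(data)$condition
    nG <- length(genes); nC <- length(conditionNames)
    cnt <- sm <- ssq <- matrix(0, nG, nC)
    for (j in seq_len(nC)) {
        cols <- which(cond == conditionNames[j])
        if (!length(cols)) next
        sub <- v[, cols, drop = FALSE]
        ok <- !is.na(sub)
        cnt[, j] <- rowSums(ok)
        sub[!ok] <- 0
        sm[, j] <- rowSums(sub)
        ssq[, j] <- rowSums(sub^2)
    }
    if (sum(cnt) == 0) stop("no non-missing data cells")
    list(geneSpecies = match(genes, speciesNames) - 1L,
         cnt = cnt, sm = sm, ssq = ssq, genes = genes)
}

# Full compiled problem for a gate space + design + data.
.compileProblem <- function(space, design, data) {
    net <- space@network
    speciesNames <- net@species$name
    ga <- .gateArrays(space@gates, speciesNames)
    st <- .dataStats(data, speciesNames, design@conditions)
    c(ga, st,
      list(speciesNames = speciesNames,
           baseline = .baselineVector(net),
           clamp = .clampMatrix(design, speciesNames),
           topo = .topoIndices(net),
           net = net, gatesList = space@gates,
           conditions = design@conditions))
}

.problemMSE <- function(prob, genomes, kGrid, nGrid) {
    cpp_mse_genomes(genomes, kGrid, nGrid, prob$gateTarget, prob$gateOff,
                    prob$inputSrc, prob$inputSign, prob$baseline, prob$clamp,
                    prob$topo, prob$geneSpecies, prob$cnt, prob$sm, prob$ssq)
}

.problemMSEActive <- function(prob, activeMat, kGate, nGate) {
    cpp_mse_active(activeMat, kGate, nGate, prob$gateTarget, prob$gateOff,
                   prob$inputSrc, prob$inputSign, prob$baseline, prob$clamp,
                   prob$topo, prob$geneSpecies, prob$cnt, prob$sm, prob$ssq)
}

#' Simulate a fuzzy logic model to steady state
#'
#' Species are evaluated in topological order. Clamped species (stimuli,
#' inhibited species) take their clamp value regardless of gates. Each active
#' gate contributes \code{transferHill(state)} for activating inputs and
#' \code{1 - transferHill(state)} for inhibiting inputs, combined by min
#' (AND); a species' state is the max (OR) over its active gates, or its
#' constitutive baseline (1 for constitutive regulators, 0 otherwise) when
#' no gate is active.
#'
#' @param model a \linkS4class{FuzzyModel}.
#' @param design an \linkS4class{ExperimentDesign}.
#' @param ... unused.
#' @return numeric matrix of steady states, species x conditions, all values
#'   in [0,1].
#' @rdname simulateStates
#' @export
setMethod("simulateStates", signature(model = "FuzzyModel",
                                      design = "ExperimentDesign"),
    function(model, design, ...) {
        net <- model@network
        speciesNames <- net@species$name
        ga <- .gateArrays(model@gates, speciesNames)
        kGate <- vapply(model@gates, `[[`, numeric(1), "k")
        nGate <- vapply(model@gates, `[[`, numeric(1), "n")
        states <- cpp_simulate(ga$gateTarget, ga$gateOff, ga$inputSrc,
                               ga$inputSign, kGate, nGate,
                               .baselineVector(net),
                               .clampMatrix(design, speciesNames),
                               .topoIndices(net))
        dimnames(states) <- list(speciesNames, design@conditions)
        states
    })

#' Mean squared error of a model against normalized data
#'
#' The MSE is the mean over all non-missing (gene, condition, donor) cells of
#' the squared difference between the simulated steady state of the gene
#' species and the normalized measurement; missing cells contribute to
#' neither numerator nor denominator.
#'
#' @param model a \linkS4class{FuzzyModel}.
#' @param design an \linkS4class{ExperimentDesign}.
#' @param data a \linkS4class{NormalizedSet} whose row names are model
#'   species.
#' @return a single non-negative number.
#' @export
scoreMSE <- function(model, design, data) {
    states <- simulateStates(model, design)
    st <- .dataStats(data, rownames(states), design@conditions)
    p <- states[st$geneSpecies + 1L, , drop = FALSE]
    num <- sum(st$cnt * p^2 - 2 * p * st$sm + st$ssq)
    num / sum(st$cnt)
}
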