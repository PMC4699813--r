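# Independent oracles used across the suite. These deliberately avoid the
# package's evaluation path (topological C++ loop): the Boolean oracle is a
# recursive memoized evaluator, the clustering oracle an exhaustive
# agglomerator, the Spearman oracle a from-scratch midrank computation.

# Recursive Boolean/fuzzy steady-state evaluation of a model under clamps.
# With binary clamps and any transfer parameters this is exactly the Boolean
# AND/OR/NOT evaluation, since f(0)=0 and f(1)=1.
oracleSteadyState <- function(model, clamps = numeric()) {
    sp <- speciesInfo(network(model))
    base <- stats::setNames(ifelse(sp$constitutive, 1, 0), sp$name)
    gl <- gates(model)
    memo <- new.env(parent = emptyenv())
    evalS <- function(v) {
        if (!is.null(memo[[v]])) return(memo[[v]])
        val <- if (v %in% names(clamps)) {
            clamps[[v]]
        } else {
            gv <- Filter(function(g) g$target == v, gl)
            if (!length(gv)) {
                base[[v]]
            } else {
                outs <- vapply(gv, function(g) {
                    ins <- mapply(function(s, sg) {
                        x <- transferHill(evalS(s), g$k, g$n)
                        if (sg > 0) x else 1 - x
                    }, g$sources, g$signs)
                    min(ins)
                }, numeric(1))
                max(outs)
            }
        }
        memo[[v]] <- val
        val
    }
    vapply(sp$name, evalS, numeric(1))
}

# Random annotated DAG over n species (edges only from lower to higher
# index, so acyclic by construction).
randomDAGNet <- function(n, pEdge = 0.4) {
    nm <- paste0("S", seq_len(n))
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(idx)) < pEdge
    idx <- idx[keep, , drop = FALSE]
    tr <- data.frame(source = nm[idx[, 1L]], target = nm[idx[, 2L]],
                     sign = sample(c(-1L, 1L), nrow(idx), replace = TRUE),
                     stringsAsFactors = FALSE)
    sp <- data.frame(
        name = nm,
        role = c("stimulus", sample(c("signaling", "gene"), n - 1L,
                                    replace = TRUE)),
        measured = c(FALSE, stats::runif(n - 1L) < 0.5),
        perturbable = c(FALSE, stats::runif(n - 1L) < 0.25),
        constitutive = FALSE, stringsAsFactors = FALSE)
    PriorNetwork(sp, unique(tr))
}

# A model over the net with every single-input gate active (flat OR
# semantics) and fixed transfer parameters.
flatModel <- function(net, k = 0.5, n = 10) {
    tr <- transitions(net)
    gl <- lapply(seq_len(nrow(tr)), function(i)
        list(target = tr$target[i], sources = tr$source[i],
             signs = tr$sign[i], kind = "single", k = k, n = n))
    new("FuzzyModel", network = net, gates = gl)
}

# A model with one randomly chosen gate (and grid parameters) per target.
randomModel <- function(net, maxAndSize = 2L, k = 0.5, n = 10) {
    space <- expandGates(net, maxAndSize)
    gl <- list()
    for (tg in unique(vapply(gates(space), `[[`, character(1), "target"))) {
        idx <- which(vapply(gates(space), function(g) g$target == tg,
                            logical(1)))
        g <- gates(space)[[if (length(idx) == 1L) idx else sample(idx, 1L)]]
        g$k <- k; g$n <- n
        gl[[length(gl) + 1L]] <- g
    }
    new("FuzzyModel", network = net, gates = gl)
}

# All 0/1 assignments over the given species names.
allClampPatterns <- function(speciesNames) {
    k <- length(speciesNames)
    if (k == 0L) return(list(numeric()))
    grid <- expand.grid(rep(list(c(0, 1)), k))
    lapply(seq_len(nrow(grid)), function(i)
        stats::setNames(as.numeric(grid[i, ]), speciesNames))
}

# Design whose conditions enumerate the clamp patterns (clamps expressed as
# stimulus levels, which the engine applies to any species).
patternDesign <- function(patterns) {
    ExperimentDesign(paste0("p", seq_along(patterns)),
                     stimuli = patterns,
                     inhibited = rep(list(character()), length(patterns)))
}

# Exhaustive UPGMA agglomeration returning the cophenetic matrix: clusters
# merge at the mean pairwise distance, lowest-index pair first on ties.
oracleUPGMACophenetic <- function(d) {
    d <- as.matrix(d)
    n <- nrow(d)
    clusters <- as.list(seq_len(n))
    coph <- matrix(0, n, n)
    while (length(clusters) > 1L) {
        best <- NULL; bestD <- Inf
        for (a in seq_len(length(clusters) - 1L))
            for (b in seq(a + 1L, length(clusters))) {
                dd <- mean(d[clusters[[a]], clusters[[b]]])
                if (dd < bestD - 1e-12) { bestD <- dd; best <- c(a, b) }
            }
        ia <- clusters[[best[1L]]]; ib <- clusters[[best[2L]]]
        coph[ia, ib] <- coph[ib, ia] <- bestD
        clusters[[best[1L]]] <- c(ia, ib)
        clusters[[best[2L]]] <- NULL
    }
    coph
}

# Midranks computed from first principles.
oracleMidranks <- function(x) {
    vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# Spearman coefficient via explicit Pearson-on-ranks arithmetic.
oracleSpearman <- function(x, y) {
    rx <- oracleMidranks(x); ry <- oracleMidranks(y)
    mx <- mean(rx); my <- mean(ry)
    sum((rx - mx) * (ry - my)) /
        sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Minimal NormalizedSet from per-donor matrices (genes x conditions).
makeNormSet <- function(tables, h = 4, midpoints = NULL) {
    genes <- rownames(tables[[1L]])
    if (is.null(midpoints))
        midpoints <- stats::setNames(rep(0.5, length(genes)), genes)
    sch <- new("NormalizationScheme", h = h, midpoints = midpoints,
               direction = stats::setNames(rep("down", length(genes)),
                                           names(midpoints)))
    conds <- colnames(tables[[1L]])
    v <- do.call(cbind, lapply(tables, unname))
    rownames(v) <- genes
    donor <- rep(names(tables), each = length(conds))
    condition <- rep(conds, times = length(tables))
    colnames(v) <- paste(donor, condition, sep = ".")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(norm = v),
        colData = S4Vectors::DataFrame(condition = condition, donor = donor,
                                       row.names = colnames(v)))
    new("NormalizedSet", se, scheme = sch)
}

# The preprocessed full-scale benchmark shared by the heavier tests.
benchmarkSetup <- function(seed = 7, noiseCV = 0.2, donorSD = 0.25,
                           missingRate = 0.02) {
    net <- compressNetwork(makeBenchmarkPKN("paper"))
    design <- makeBenchmarkDesign(net)
    truth <- sampleTruth(net, seed = seed, design = design,
                         noiseCV = noiseCV, donorSD = donorSD,
                         missingRate = missingRate)
    list(net = net, design = design, truth = truth,
         space = expandGates(net, 2L))
}

# Two graded stimuli driving one measured gene: a small, fully enumerable
# calibration problem.
twoInputProblem <- function() {
    net <- PriorNetwork(
        data.frame(name = c("S1", "S2", "G"),
                   role = c("stimulus", "stimulus", "gene"),
                   measured = c(FALSE, FALSE, TRUE),
                   perturbable = FALSE, constitutive = FALSE),
        data.frame(source = c("S1", "S2"), target = c("G", "G"), sign = 1L))
    lv <- expand.grid(s1 = c(0, 0.5, 1), s2 = c(0, 0.5, 1))
    design <- patternDesign(lapply(seq_len(nrow(lv)), function(i)
        c(S1 = lv$s1[i], S2 = lv$s2[i])))
    space <- expandGates(net, 1L)
    truthGates <- lapply(seq_along(gates(space)), function(i) {
        g <- gates(space)[[i]]
        g$k <- c(0.5, 0.7)[i]; g$n <- c(4, 2)[i]
        g
    })
    truth <- new("FuzzyModel", network = net, gates = truthGates)
    states <- simulateStates(truth, design)
    tab <- states["G", , drop = FALSE]
    rownames(tab) <- "G"
    list(net = net, design = design, space = space, truth = truth,
         data = makeNormSet(list(D1 = tab)))
}

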