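# Run expr with a private RNG stream, restoring the caller's stream after.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    force(expr)
}

.gateKey <- function(g) {
    ord <- order(g$sources)
    paste0(g$target, "<-",
           paste0(ifelse(g$signs[ord] > 0, "", "!"), g$sources[ord],
                  collapse = "&"))
}

.genomeModel <- function(space, genome, kGrid, nGrid) {
    act <- which(genome > 0L)
    gl <- lapply(act, function(i) {
        g <- space@gates[[i]]
        g$k <- kGrid[genome[i]]
        g$n <- nGrid[genome[i]]
        g
    })
    new("FuzzyModel", network = space@network, gates = gl)
}

# GA optimization in genome space. A genome holds, per candidate gate,
# 0 (gate off) or a 1-based index into the flattened (k, n) grid.
.gaRun <- function(prob, control, kFlat, nFlat) {
    G <- length(prob$gateTarget)
    K <- length(kFlat)
    P <- control@populationSize
    pop <- matrix(sample(0:K, P * G, replace = TRUE), nrow = P)
    bestGenome <- NULL
    bestMSE <- Inf
    stall <- 0L
    gen <- 0L
    while (gen < control@maxGenerations && stall < control@stallGenerations) {
        gen <- gen + 1L
        mse <- .problemMSE(prob, pop, kFlat, nFlat)
        ord <- order(mse)
        if (mse[ord[1L]] < bestMSE - 1e-15) {
            bestMSE <- mse[ord[1L]]
            bestGenome <- pop[ord[1L], ]
            stall <- 0L
        } else stall <- stall + 1L
        nChild <- P - control@elitism
        i1 <- sample.int(P, nChild, replace = TRUE)
        i2 <- sample.int(P, nChild, replace = TRUE)
        pa <- ifelse(mse[i1] <= mse[i2], i1, i2)
        j1 <- sample.int(P, nChild, replace = TRUE)
        j2 <- sample.int(P, nChild, replace = TRUE)
        pb <- ifelse(mse[j1] <= mse[j2], j1, j2)
        mask <- matrix(runif(nChild * G) < 0.5, nChild, G)
        children <- pop[pa, , drop = FALSE]
        donors <- pop[pb, , drop = FALSE]
        children[mask] <- donors[mask]
        mut <- matrix(runif(nChild * G) < control@mutationRate, nChild, G)
        nMut <- sum(mut)
        if (nMut) children[mut] <- sample(0:K, nMut, replace = TRUE)
        elite <- pop[ord[seq_len(control@elitism)], , drop = FALSE]
        pop <- rbind(elite, children)
    }
    list(genome = bestGenome, mse = bestMSE, generations = gen)
}

# Greedy reduction in genome space with frozen transfer parameters: while the
# cumulative MSE increase stays within the threshold, switch off the active
# gate whose removal costs least (ties: lowest gate index).
.reduceGenome <- function(prob, genome, kFlat, nFlat, threshold) {
    G <- length(genome)
    kGate <- nGate <- numeric(G)
    on <- genome > 0L
    kGate[on] <- kFlat[genome[on]]
    nGate[on] <- nFlat[genome[on]]
    active <- as.integer(on)
    mse0 <- .problemMSEActive(prob, matrix(active, nrow = 1L), kGate, nGate)[1L]
    mse <- mse0
    repeat {
        idx <- which(active == 1L)
        if (!length(idx)) break
        cand <- matrix(rep(active, length(idx)), nrow = length(idx),
                       byrow = TRUE)
        cand[cbind(seq_along(idx), idx)] <- 0L
        mses <- .problemMSEActive(prob, cand, kGate, nGate)
        best <- which.min(mses)
        if (mses[best] - mse0 <= threshold) {
            active[idx[best]] <- 0L
            mse <- mses[best]
        } else break
    }
    genome[active == 0L] <- 0L
    list(genome = genome, mse = mse, mseOriginal = mse0)
}

.checkIdentifiable <- function(net) {
    pert <- unique(c(net@species$name[net@species$perturbable],
                     net@species$name[net@species$role == "stimulus"]))
    down <- .descendants(net, pert)
    if (!any(net@species$measured[net@species$name %in% down]))
        stop("unidentifiable: no measured species downstream of any ",
             "perturbed species")
    invisible(TRUE)
}

.flatGrid <- function(control) {
    grid <- expand.grid(k = control@kGrid, n = control@nGrid)
    list(k = grid$k, n = grid$n)
}

#' Genetic-algorithm calibration of a fuzzy logic model
#'
#' Selects active gates and their normalized-Hill transfer parameters by
#' minimizing the mean squared error between simulated steady states and the
#' normalized data. The genome assigns each candidate gate either "off" or
#' one cell of the discrete (k, n) grid; identical control settings and seed
#' give identical results.
#'
#' @param space a \linkS4class{GateSpace}.
#' @param design an \linkS4class{ExperimentDesign}.
#' @param data a \linkS4class{NormalizedSet}.
#' @param control a \linkS4class{GAControl}, see \code{\link{gaControl}}.
#' @return list with elements \code{model} (\linkS4class{FuzzyModel}),
#'   \code{mse}, \code{genome} and \code{generations}.
#' @export
gaOptimize <- function(space, design, data, control = gaControl()) {
    if (!length(space@gates)) stop("empty gate space")
    .checkIdentifiable(space@network)
    prob <- .compileProblem(space, design, data)
    grid <- .flatGrid(control)
    res <- .withSeed(control@seed, .gaRun(prob, control, grid$k, grid$n))
    list(model = .genomeModel(space, res$genome, grid$k, grid$n),
         mse = res$mse, genome = res$genome, generations = res$generations)
}

#' Threshold-based model reduction
#'
#' Greedily removes the active gate whose removal increases the MSE least,
#' as long as the cumulative increase over the unreduced model stays within
#' the selection threshold (the maximum tolerated MSE increase). Transfer
#' parameters are frozen; reduction only removes gates, so the reduced MSE
#' is guaranteed to be at most \code{original MSE + threshold}.
#'
#' @param model a calibrated \linkS4class{FuzzyModel}.
#' @param design an \linkS4class{ExperimentDesign}.
#' @param data a \linkS4class{NormalizedSet}.
#' @param threshold maximum tolerated MSE increase (default 0.01).
#' @param report if \code{TRUE}, return
#'   \code{list(model, mse, mseOriginal)}.
#' @return the reduced \linkS4class{FuzzyModel} (or a list, see
#'   \code{report}).
#' @export
reduceModel <- function(model, design, data, threshold = 0.01,
                        report = FALSE) {
    if (threshold < 0) stop("threshold must be >= 0")
    space <- new("GateSpace", network = model@network, gates = lapply(
        model@gates, function(g) g[c("target", "sources", "signs", "kind")]),
        maxAndSize = max(1L, max(vapply(model@gates, function(g)
            length(g$sources), integer(1), USE.NAMES = FALSE), 1L)))
    prob <- .compileProblem(space, design, data)
    kGate <- vapply(model@gates, `[[`, numeric(1), "k")
    nGate <- vapply(model@gates, `[[`, numeric(1), "n")
    genome <- seq_along(model@gates)  # each gate its own grid slot
    red <- .reduceGenome(prob, genome, kGate, nGate, threshold)
    keep <- which(red$genome > 0L)
    out <- new("FuzzyModel", network = model@network,
               gates = model@gates[keep])
    if (report) list(model = out, mse = red$mse,
                     mseOriginal = red$mseOriginal)
    else out
}

#' Fit a family of independently calibrated, reduced models
#'
#' Runs \code{\link{gaOptimize}} followed by reduction \code{nRuns} times
#' (run r uses seed \code{control@seed + r}) and records consensus
#' frequencies: for every transition and every gate, the fraction of runs
#' whose reduced model contains it.
#'
#' @inheritParams gaOptimize
#' @param nRuns number of independent optimization runs (default 100).
#' @param threshold reduction threshold (default 0.01).
#' @return a \linkS4class{ModelFamily}.
#' @export
fitModelFamily <- function(space, design, data, control = gaControl(),
                           nRuns = 100L, threshold = 0.01) {
    stopifnot(nRuns >= 1L)
    if (!length(space@gates)) stop("empty gate space")
    .checkIdentifiable(space@network)
    prob <- .compileProblem(space, design, data)
    grid <- .flatGrid(control)
    seeds <- control@seed + seq_len(nRuns)
    models <- vector("list", nRuns)
    mseRed <- mseOpt <- numeric(nRuns)
    gateKeysPerRun <- vector("list", nRuns)
    trKeysPerRun <- vector("list", nRuns)
    for (r in seq_len(nRuns)) {
        res <- .withSeed(seeds[r], .gaRun(prob, control, grid$k, grid$n))
        red <- .reduceGenome(prob, res$genome, grid$k, grid$n, threshold)
        stopifnot(red$mse - red$mseOriginal <= threshold + 1e-12)
        mseOpt[r] <- red$mseOriginal
        mseRed[r] <- red$mse
        models[[r]] <- .genomeModel(space, red$genome, grid$k, grid$n)
        gl <- models[[r]]@gates
        gateKeysPerRun[[r]] <- unique(vapply(gl, .gateKey, character(1)))
        trKeysPerRun[[r]] <- unique(unlist(lapply(gl, function(g)
            paste(g$sources, g$target, g$signs, sep = "\r"))))
    }
    consensus <- list(
        gates = .frequencyTable(gateKeysPerRun, nRuns),
        transitions = .transitionFrequencies(trKeysPerRun, nRuns))
    new("ModelFamily", models = models, mse = mseRed, mseOptimized = mseOpt,
        nRuns = as.integer(nRuns), threshold = threshold,
        seeds = as.integer(seeds), consensus = consensus)
}

.frequencyTable <- function(keysPerRun, nRuns) {
    all <- sort(unique(unlist(keysPerRun)))
    freq <- vapply(all, function(k)
        sum(vapply(keysPerRun, function(x) k %in% x, logical(1))) / nRuns,
        numeric(1))
    data.frame(key = all, frequency = unname(freq),
               stringsAsFactors = FALSE, row.names = NULL)
}

.transitionFrequencies <- function(trKeysPerRun, nRuns) {
    tab <- .frequencyTable(trKeysPerRun, nRuns)
    parts <- strsplit(tab$key, "\r", fixed = TRUE)
    data.frame(source = vapply(parts, `[`, character(1), 1L),
               target = vapply(parts, `[`, character(1), 2L),
               sign = as.integer(vapply(parts, `[`, character(1), 3L)),
               frequency = tab$frequency, stringsAsFactors = FALSE)
}

#' @rdname fitModelFamily
#' @param object a \linkS4class{ModelFamily}.
#' @export
setMethod("consensus", "ModelFamily", function(object) object@consensus)

#' @rdname fitModelFamily
#' @param reduced if \code{TRUE} (default) the per-run MSEs after reduction,
#'   otherwise before.
#' @export
setMethod("familyMSE", "ModelFamily", function(object, reduced = TRUE)
    if (reduced) object@mse else object@mseOptimized)

#' @rdname fitModelFamily
#' @details \code{meanParameters} counts scalars: each active gate carries
#'   one (k, n) pair, i.e. two parameters.
#' @export
meanParameters <- function(object) {
    mean(vapply(object@models, function(m) 2 * length(m@gates), numeric(1)))
}

#' Consensus network of a model family
#'
#' Keeps the transitions contained in at least \code{minFrequency} of the
#' family's reduced models and annotates each with its frequency (usable as
#' line weight when rendering the network).
#'
#' @param family a \linkS4class{ModelFamily}.
#' @param minFrequency inclusion cutoff (default 0.30; inclusive).
#' @return a \linkS4class{PriorNetwork} whose transitions carry a
#'   \code{frequency} column.
#' @export
consensusNetwork <- function(family, minFrequency = 0.30) {
    if (!length(family@models)) stop("empty model family")
    tr <- family@consensus$transitions
    tr <- tr[tr$frequency >= minFrequency, , drop = FALSE]
    net <- family@models[[1L]]@network
    keep <- net@species$name %in% unique(c(tr$source, tr$target))
    out <- PriorNetwork(net@species[keep, , drop = FALSE],
                        tr[, c("source", "target", "sign")])
    out@transitions$frequency <- tr$frequency
    out
}

#' Reduction curve of a model family
#'
#' Fits the GA runs once, then re-reduces every optimized model at each
#' threshold, reporting the family mean MSE and mean parameter count per
#' threshold. More tolerance removes at least as many gates, so mean
#' parameters are non-increasing and mean MSE non-decreasing along the
#' curve.
#'
#' @inheritParams fitModelFamily
#' @param thresholds increasing numeric vector of selection thresholds.
#' @return data.frame with columns \code{threshold}, \code{meanMSE},
#'   \code{meanParameters}.
#' @export
reductionCurve <- function(space, design, data, control = gaControl(),
                           thresholds = c(0, 0.0005, 0.001, 0.005, 0.01,
                                          0.05, 0.1),
                           nRuns = 10L) {
    if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
    .checkIdentifiable(space@network)
    prob <- .compileProblem(space, design, data)
    grid <- .flatGrid(control)
    genomes <- lapply(seq_len(nRuns), function(r)
        .withSeed(control@seed + r,
                  .gaRun(prob, control, grid$k, grid$n))$genome)
    out <- lapply(thresholds, function(th) {
        reds <- lapply(genomes, function(g)
            .reduceGenome(prob, g, grid$k, grid$n, th))
        data.frame(threshold = th,
                   meanMSE = mean(vapply(reds, `[[`, numeric(1), "mse")),
                   meanParameters = mean(vapply(reds, function(x)
                       2 * sum(x$genome > 0L), numeric(1))))
    })
    do.call(rbind, out)
}
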