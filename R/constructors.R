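#' Construct a PriorNetwork
#'
#' @param species character vector of species names, or a data.frame with
#'   columns \code{name}, \code{role}, \code{measured}, \code{perturbable},
#'   \code{constitutive} (missing columns are filled with defaults:
#'   role "unknown", all flags FALSE).
#' @param transitions data.frame with columns \code{source}, \code{target},
#'   \code{sign}; duplicate rows are collapsed (set semantics).
#'
#' @return a \linkS4class{PriorNetwork}.
#' @examples
#' net <- PriorNetwork(c("IL6", "JAK", "STAT3"),
#'     data.frame(source = c("IL6", "JAK"), target = c("JAK", "STAT3"),
#'                sign = c(1L, 1L)))
#' net
#' @export
PriorNetwork <- function(species,
                         transitions = data.frame(source = character(),
                                                  target = character(),
                                                  sign = integer())) {
    if (is.character(species))
        species <- data.frame(name = species, stringsAsFactors = FALSE)
    species <- as.data.frame(species, stringsAsFactors = FALSE)
    if (is.null(species$role)) species$role <- "unknown"
    for (fl in c("measured", "perturbable", "constitutive"))
        if (is.null(species[[fl]])) species[[fl]] <- FALSE
    species <- species[, c("name", "role", "measured", "perturbable",
                           "constitutive")]
    transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
    transitions$sign <- as.integer(transitions$sign)
    transitions <- unique(transitions[, c("source", "target", "sign")])
    rownames(species) <- NULL
    rownames(transitions) <- NULL
    new("PriorNetwork", species = species, transitions = transitions)
}

#' @rdname PriorNetwork-accessors
#' @name PriorNetwork-accessors
#' @title Accessors for PriorNetwork and derived objects
#' @param object a \linkS4class{PriorNetwork}, \linkS4class{GateSpace},
#'   \linkS4class{FuzzyModel} or \linkS4class{ModelFamily}.
#' @return \code{speciesInfo}: the species annotation data.frame;
#'   \code{transitions}: the signed transition data.frame; \code{network}:
#'   the underlying \linkS4class{PriorNetwork}.
#' @aliases speciesInfo transitions network
#' @export
setMethod("speciesInfo", "PriorNetwork", function(object) object@species)

#' @rdname PriorNetwork-accessors
#' @export
setMethod("transitions", "PriorNetwork", function(object) object@transitions)

#' @rdname PriorNetwork-accessors
#' @export
setMethod("network", "GateSpace", function(object) object@network)

#' @rdname PriorNetwork-accessors
#' @export
setMethod("network", "FuzzyModel", function(object) object@network)

#' @rdname gates
#' @name gates
#' @title Gate lists of gate-bearing objects
#' @param object a \linkS4class{GateSpace} or \linkS4class{FuzzyModel}.
#' @return list of gates (target, sources, signs, kind, and for models k, n).
#' @export
setMethod("gates", "GateSpace", function(object) object@gates)

#' @rdname gates
#' @export
setMethod("gates", "FuzzyModel", function(object) object@gates)

setMethod("show", "PriorNetwork", function(object) {
    cat("PriorNetwork with", nrow(object@species), "species and",
        nrow(object@transitions), "transitions\n")
    cat("  measured:", sum(object@species$measured),
        " perturbable:", sum(object@species$perturbable),
        " constitutive:", sum(object@species$constitutive), "\n")
})

setMethod("show", "GateSpace", function(object) {
    kinds <- vapply(object@gates, `[[`, character(1), "kind")
    cat("GateSpace with", length(object@gates), "candidate gates (",
        sum(kinds == "single"), "single,", sum(kinds == "AND"),
        "AND ), maxAndSize =", object@maxAndSize, "\n")
})

setMethod("show", "FuzzyModel", function(object) {
    cat("FuzzyModel with", length(object@gates), "active gates over",
        nrow(object@network@species), "species\n")
})

setMethod("show", "ModelFamily", function(object) {
    cat("ModelFamily of", object@nRuns, "optimized+reduced models\n")
    cat(sprintf("  mean MSE (reduced): %.4g  mean MSE (optimized): %.4g\n",
                mean(object@mse), mean(object@mseOptimized)))
    cat(sprintf("  mean parameters: %.1f  reduction threshold: %g\n",
                meanParameters(object), object@threshold))
})

setMethod("show", "ValidationReport", function(object) {
    cat(sprintf("Spearman validation: rs = %.3f (N = %d, P = %.3g)\n",
                object@rs, object@n, object@p))
})

setMethod("show", "ExperimentDesign", function(object) {
    cat("ExperimentDesign with", length(object@conditions), "conditions:\n")
    for (i in seq_along(object@conditions)) {
        st <- object@stimuli[[i]]
        cat(sprintf("  %-18s stimuli: %-14s inhibited: %s\n",
                    object@conditions[i],
                    if (length(st)) paste(names(st), st, sep = "=",
                                          collapse = ",") else "-",
                    if (length(object@inhibited[[i]]))
                        paste(object@inhibited[[i]], collapse = ",")
                    else "-"))
    }
})

setMethod("show", "NormalizationScheme", function(object) {
    cat("NormalizationScheme (h =", object@h, ") for",
        length(object@midpoints), "genes;",
        sum(object@direction == "down"), "down,",
        sum(object@direction == "up"), "up\n")
})

#' Construct an ExperimentDesign
#'
#' @param conditions character vector of condition names.
#' @param stimuli list of named numeric stimulus levels, one per condition
#'   (empty numeric for none).
#' @param inhibited list of character vectors of inhibited species, one per
#'   condition.
#'
#' @return an \linkS4class{ExperimentDesign}.
#' @examples
#' ExperimentDesign(c("ctrl", "IL6"),
#'     stimuli = list(numeric(), c(IL6 = 1)),
#'     inhibited = list(character(), character()))
#' @export
ExperimentDesign <- function(conditions, stimuli, inhibited) {
    new("ExperimentDesign", conditions = as.character(conditions),
        stimuli = stimuli, inhibited = inhibited)
}

#' @rdname ExperimentDesign
#' @param object an \linkS4class{ExperimentDesign}.
#' @export
setMethod("conditions", "ExperimentDesign", function(object)
    object@conditions)

#' Genetic algorithm settings
#'
#' Defaults: population 50, at most 500 generations, stop after 100
#' generations without improvement, per-locus mutation rate 0.05, elitism 1.
#' The transfer-parameter grids default to
#' k in \{0.2, ..., 1.0\} and n in \{1, 2, 3, 4, 6\}.
#'
#' @param populationSize,maxGenerations,stallGenerations,mutationRate,elitism
#'   GA hyperparameters, see slots of \linkS4class{GAControl}.
#' @param seed integer seed; identical settings and seed give identical
#'   results.
#' @param kGrid,nGrid discrete grids for the transfer gain and exponent.
#' @return a \linkS4class{GAControl}.
#' @export
gaControl <- function(populationSize = 50L, maxGenerations = 500L,
                      stallGenerations = 100L, mutationRate = 0.05,
                      elitism = 1L, seed = 1L,
                      kGrid = seq(0.2, 1.0, by = 0.1),
                      nGrid = c(1, 2, 3, 4, 6)) {
    new("GAControl", populationSize = as.integer(populationSize),
        maxGenerations = as.integer(maxGenerations),
        stallGenerations = as.integer(stallGenerations),
        mutationRate = mutationRate, elitism = as.integer(elitism),
        seed = as.integer(seed), kGrid = kGrid, nGrid = nGrid)
}

#' Construct a MeasurementSet from per-donor fold-change matrices
#'
#' @param tables named list (names = donor ids) of genes x conditions
#'   matrices of linear fold changes (NA = missing). All matrices must share
#'   row and column names.
#' @return a \linkS4class{MeasurementSet} with one column per
#'   (donor, condition) pair.
#' @export
MeasurementSet <- function(tables) {
    stopifnot(is.list(tables), length(tables) >= 1L,
              !is.null(names(tables)))
    genes <- rownames(tables[[1L]])
    conds <- colnames(tables[[1L]])
    for (tb in tables)
        stopifnot(identical(rownames(tb), genes),
                  identical(colnames(tb), conds))
    fc <- do.call(cbind, lapply(tables, function(tb) unname(tb)))
    donor <- rep(names(tables), each = length(conds))
    condition <- rep(conds, times = length(tables))
    colnames(fc) <- paste(donor, condition, sep = ".")
    rownames(fc) <- genes
    se <- SummarizedExperiment(
        assays = list(fc = fc),
        colData = S4Vectors::DataFrame(condition = condition, donor = donor,
                                       row.names = colnames(fc)))
    new("MeasurementSet", se)
}

#' @describeIn MeasurementSet donors present in the set.
#' @param object a \linkS4class{MeasurementSet}.
#' @export
donors <- function(object) unique(colData(object)$donor)

#' @describeIn MeasurementSet the fold-change (or normalized) matrix of one
#'   donor, genes x conditions.
#' @param donor donor id.
#' @param assayName assay to extract ("fc" or "norm").
#' @export
donorTable <- function(object, donor, assayName = assayNames(object)[1L]) {
    keep <- colData(object)$donor == donor
    m <- assay(object, assayName)[, keep, drop = FALSE]
    colnames(m) <- colData(object)$condition[keep]
    m
}

#' @rdname normalizeFoldChanges
#' @export
setMethod("scheme", "NormalizedSet", function(object) object@scheme)
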