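#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @import SummarizedExperiment
NULL

.SPECIES_ROLES <- c("stimulus", "signaling", "transcription_factor", "gene",
                    "complex", "unknown")

#' Prior knowledge network
#'
#' A signed directed graph of signalling and gene-regulatory influences.
#' Species carry a role (stimulus, signaling, transcription_factor, gene,
#' complex or unknown) and three flags: \code{measured} (readout in the data),
#' \code{perturbable} (can be clamped by an inhibitor) and \code{constitutive}
#' (basal activity 1 in the absence of any active gate, e.g. HNF1A/HNF4A-like
#' regulators). Transitions are (source, target, sign) triples with sign +1
#' (activating) or -1 (inhibiting).
#'
#' @slot species data.frame with columns \code{name}, \code{role},
#'   \code{measured}, \code{perturbable}, \code{constitutive}.
#' @slot transitions data.frame with columns \code{source}, \code{target},
#'   \code{sign}.
#' @aliases PriorNetwork
#' @exportClass PriorNetwork
setClass("PriorNetwork",
    representation(species = "data.frame", transitions = "data.frame"))

setValidity("PriorNetwork", function(object) {
    sp <- object@species
    tr <- object@transitions
    msgs <- character()
    need_sp <- c("name", "role", "measured", "perturbable", "constitutive")
    if (!all(need_sp %in% names(sp)))
        return(paste("species must have columns", paste(need_sp, collapse = ", ")))
    need_tr <- c("source", "target", "sign")
    if (!all(need_tr %in% names(tr)))
        return(paste("transitions must have columns", paste(need_tr, collapse = ", ")))
    if (anyDuplicated(sp$name))
        msgs <- c(msgs, "species names must be unique")
    if (!all(sp$role %in% .SPECIES_ROLES))
        msgs <- c(msgs, "unknown species role")
    if (nrow(tr)) {
        if (!all(tr$sign %in% c(-1L, 1L)))
            msgs <- c(msgs, "transition sign must be +1 or -1")
        if (!all(c(tr$source, tr$target) %in% sp$name))
            msgs <- c(msgs, "transition endpoints must be declared species")
        if (anyDuplicated(tr[, c("source", "target", "sign")]))
            msgs <- c(msgs, "duplicate (source, target, sign) transition")
        if (any(tr$source == tr$target))
            msgs <- c(msgs, "self-loops are not allowed")
    }
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Candidate gate hypothesis space
#'
#' The expansion of a \linkS4class{PriorNetwork} into candidate logic gates:
#' every incoming transition of a target as a one-input gate, plus AND gates
#' over 2..\code{maxAndSize} incoming transitions with distinct sources.
#' Gates on the same target combine by OR (max) during simulation.
#'
#' @slot network the \linkS4class{PriorNetwork} the gates were derived from.
#' @slot gates list of gates; each a list with \code{target}, \code{sources},
#'   \code{signs}, \code{kind} ("single" or "AND").
#' @slot maxAndSize maximum number of inputs of an AND gate.
#' @exportClass GateSpace
setClass("GateSpace",
    representation(network = "PriorNetwork", gates = "list",
                   maxAndSize = "integer"))

setValidity("GateSpace", function(object) {
    for (g in object@gates) {
        if (!all(c("target", "sources", "signs", "kind") %in% names(g)))
            return("each gate needs target, sources, signs, kind")
        if (g$kind == "AND" &&
            (length(g$sources) < 2L || anyDuplicated(g$sources)))
            return("AND gates need >= 2 distinct sources")
        if (g$kind == "single" && length(g$sources) != 1L)
            return("single gates have exactly one input")
        if (length(g$signs) != length(g$sources))
            return("signs and sources must align")
    }
    TRUE
})

#' Fuzzy logic model
#'
#' A selected set of active gates over a \linkS4class{PriorNetwork}, each with
#' normalized-Hill transfer parameters (k, n) applied to its inputs. Species
#' with no active gate fall back to their constitutive baseline (1 for
#' constitutive regulators, 0 otherwise).
#'
#' @slot network the underlying \linkS4class{PriorNetwork}.
#' @slot gates list of active gates: \code{target}, \code{sources},
#'   \code{signs}, \code{kind}, \code{k}, \code{n}.
#' @exportClass FuzzyModel
setClass("FuzzyModel",
    representation(network = "PriorNetwork", gates = "list"))

setValidity("FuzzyModel", function(object) {
    sp <- object@network@species$name
    for (g in object@gates) {
        if (!all(c(g$sources, g$target) %in% sp))
            return("gate references undeclared species")
        if (!is.numeric(g$k) || !is.numeric(g$n) || g$k <= 0 || g$k > 1 ||
            g$n < 1)
            return("transfer parameters need k in (0,1] and n >= 1")
    }
    tgt_and <- vapply(object@gates, function(g) {
        if (g$kind == "AND") g$target else NA_character_
    }, character(1))
    if (anyDuplicated(tgt_and[!is.na(tgt_and)]))
        return("at most one AND gate per target may be active")
    TRUE
})

#' Experimental perturbation design
#'
#' Named treatment conditions, each defined by stimulus clamps (species fixed
#' to a level in [0,1], e.g. IL6 = 1) and inhibitor clamps (species fixed to
#' 0, emulating chemical inhibition).
#'
#' @slot conditions character vector of condition names.
#' @slot stimuli list (one per condition) of named numeric stimulus levels.
#' @slot inhibited list (one per condition) of inhibited species names.
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
    representation(conditions = "character", stimuli = "list",
                   inhibited = "list"))

setValidity("ExperimentDesign", function(object) {
    if (length(object@stimuli) != length(object@conditions) ||
        length(object@inhibited) != length(object@conditions))
        return("stimuli and inhibited must have one entry per condition")
    if (anyDuplicated(object@conditions))
        return("condition names must be unique")
    for (i in seq_along(object@conditions)) {
        st <- object@stimuli[[i]]
        if (length(st) && (is.null(names(st)) || any(st < 0) || any(st > 1)))
            return("stimuli must be named levels in [0,1]")
        if (length(intersect(names(st), object@inhibited[[i]])))
            return("a species cannot be both stimulated and inhibited")
    }
    TRUE
})

#' Hill normalization scheme
#'
#' Per-gene midpoints m and a shared Hill coefficient h for mapping linear
#' fold changes into [0,1] via v = fc^h / (m^h + fc^h). Down-regulated genes
#' get m = 0.5, weakly induced genes m = 2, strongly induced genes m = half
#' their mean IL-6 fold change.
#'
#' @slot h Hill coefficient (>= 1), shared across genes.
#' @slot midpoints named numeric vector of per-gene midpoints (> 0).
#' @slot direction named character vector, "up" or "down" per gene.
#' @exportClass NormalizationScheme
setClass("NormalizationScheme",
    representation(h = "numeric", midpoints = "numeric",
                   direction = "character"))

setValidity("NormalizationScheme", function(object) {
    if (length(object@h) != 1L || object@h < 1)
        return("h must be a single value >= 1")
    if (any(object@midpoints <= 0))
        return("midpoints must be positive")
    if (!identical(names(object@midpoints), names(object@direction)))
        return("midpoints and direction must be named identically")
    if (!all(object@direction %in% c("up", "down")))
        return("direction must be 'up' or 'down'")
    TRUE
})

#' Multi-donor fold-change measurements
#'
#' A \linkS4class{SummarizedExperiment} with a single assay \code{"fc"} of
#' linear fold changes (genes x samples), where each sample is one
#' (donor, condition) pair recorded in \code{colData}. Missing measurements
#' are \code{NA}.
#'
#' @exportClass MeasurementSet
setClass("MeasurementSet", contains = "SummarizedExperiment")

setValidity("MeasurementSet", function(object) {
    if (!"fc" %in% assayNames(object))
        return("MeasurementSet needs an 'fc' assay")
    if (!all(c("condition", "donor") %in% names(colData(object))))
        return("colData needs 'condition' and 'donor'")
    fc <- assay(object, "fc")
    if (any(fc[!is.na(fc)] <= 0))
        return("fold changes must be positive")
    TRUE
})

#' Hill-normalized measurements
#'
#' A \linkS4class{SummarizedExperiment} with assay \code{"norm"} of values in
#' [0,1] (missing cells \code{NA}) plus the \linkS4class{NormalizationScheme}
#' that produced them.
#'
#' @slot scheme the \linkS4class{NormalizationScheme} used.
#' @exportClass NormalizedSet
setClass("NormalizedSet", contains = "SummarizedExperiment",
    representation(scheme = "NormalizationScheme"))

setValidity("NormalizedSet", function(object) {
    if (!"norm" %in% assayNames(object))
        return("NormalizedSet needs a 'norm' assay")
    v <- assay(object, "norm")
    ok <- v[!is.na(v)]
    if (length(ok) && (min(ok) < 0 || max(ok) > 1))
        return("normalized values must lie in [0,1]")
    if (!all(c("condition", "donor") %in% names(colData(object))))
        return("colData needs 'condition' and 'donor'")
    TRUE
})

#' Genetic algorithm control parameters
#'
#' Hyperparameters of the genetic algorithm plus the discrete (k, n) grids the
#' transfer parameters are drawn from. Construct with \code{\link{gaControl}}.
#'
#' @slot populationSize number of genomes per generation (>= 2).
#' @slot maxGenerations hard cap on generations.
#' @slot stallGenerations stop after this many generations without improvement.
#' @slot mutationRate per-locus mutation probability.
#' @slot elitism number of best genomes copied unchanged.
#' @slot seed integer random seed.
#' @slot kGrid,nGrid discrete sets the gain k and exponent n are drawn from.
#' @exportClass GAControl
setClass("GAControl",
    representation(populationSize = "integer", maxGenerations = "integer",
                   stallGenerations = "integer", mutationRate = "numeric",
                   elitism = "integer", seed = "integer",
                   kGrid = "numeric", nGrid = "numeric"))

setValidity("GAControl", function(object) {
    if (object@populationSize < 2L) return("populationSize must be >= 2")
    if (object@mutationRate < 0 || object@mutationRate > 1)
        return("mutationRate must be in [0,1]")
    if (any(object@kGrid <= 0) || any(object@kGrid > 1))
        return("kGrid values must be in (0,1]")
    if (any(object@nGrid < 1)) return("nGrid values must be >= 1")
    if (object@elitism < 0L || object@elitism >= object@populationSize)
        return("elitism must be in [0, populationSize)")
    TRUE
})

#' Family of independently calibrated models
#'
#' The result of running GA optimization plus reduction \code{nRuns} times.
#' Stores each run's reduced model and MSE, the unreduced (optimized) MSEs,
#' and consensus frequencies of transitions and gates across runs.
#'
#' @slot models list of \linkS4class{FuzzyModel}, one per run.
#' @slot mse numeric MSE of each reduced model.
#' @slot mseOptimized numeric MSE of each model before reduction.
#' @slot nRuns number of runs.
#' @slot threshold reduction threshold used (maximum tolerated MSE increase).
#' @slot seeds integer seeds used per run.
#' @slot consensus list with data.frames \code{transitions}
#'   (source, target, sign, frequency) and \code{gates}
#'   (target, key, frequency).
#' @exportClass ModelFamily
setClass("ModelFamily",
    representation(models = "list", mse = "numeric", mseOptimized = "numeric",
                   nRuns = "integer", threshold = "numeric",
                   seeds = "integer", consensus = "list"))

setValidity("ModelFamily", function(object) {
    if (length(object@models) != object@nRuns ||
        length(object@mse) != object@nRuns)
        return("models and mse must have nRuns entries")
    TRUE
})

#' Ground truth for a synthetic benchmark
#'
#' A known fuzzy logic model, the perturbation design, the fold-change
#' midpoint scheme used to emit data from model states, and the noise
#' parameters. Fully regenerable from its seed.
#'
#' @slot model the ground-truth \linkS4class{FuzzyModel}.
#' @slot design the \linkS4class{ExperimentDesign} of the emitted datasets.
#' @slot scheme the \linkS4class{NormalizationScheme} used for emission.
#' @slot noiseCV coefficient of variation of multiplicative lognormal noise.
#' @slot donorSD log2-scale standard deviation of the donor random effect.
#' @slot geneEffect named per-gene log2 effect-size offsets, fixed for the
#'   truth (gene-specific fold-change magnitudes shared across designs).
#' @slot missingRate probability a cell is masked missing.
#' @slot seed integer seed the truth was sampled from.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    representation(model = "FuzzyModel", design = "ExperimentDesign",
                   scheme = "NormalizationScheme", noiseCV = "numeric",
                   donorSD = "numeric", geneEffect = "numeric",
                   missingRate = "numeric", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    if (object@noiseCV < 0) return("noiseCV must be >= 0")
    if (object@missingRate < 0 || object@missingRate >= 1)
        return("missingRate must be in [0,1)")
    TRUE
})

#' Spearman validation report
#'
#' Spearman rank correlation between two arms of per-gene mean log2 fold
#' changes (e.g. IL-6 treatment versus nuclear-receptor knock-down), with a
#' two-tailed p-value and the paired per-gene means.
#'
#' @slot rs Spearman rank correlation coefficient.
#' @slot n number of genes shared (listwise complete) between the arms.
#' @slot p two-tailed p-value.
#' @slot pairs data.frame with columns gene, meanA, meanB.
#' @exportClass ValidationReport
setClass("ValidationReport",
    representation(rs = "numeric", n = "integer", p = "numeric",
                   pairs = "data.frame"))

#' Hierarchical clustering of a fold-change matrix
#'
#' Row (gene) and column (treatment) average-linkage dendrograms on Euclidean
#' distances of log2 fold changes, with the leaf orders.
#'
#' @slot rowOrder,colOrder integer permutations of rows / columns.
#' @slot rowDendrogram,colDendrogram \code{hclust} objects.
#' @slot matrix the (possibly row/column-filtered) input matrix.
#' @exportClass ClusterResult
setClass("ClusterResult",
    representation(rowOrder = "integer", colOrder = "integer",
                   rowDendrogram = "ANY", colDendrogram = "ANY",
                   matrix = "matrix"))
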