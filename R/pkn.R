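#' Read a prior knowledge network from a SIF file
#'
#' Each non-comment line is \code{source relation target}, separated by tabs
#' or whitespace, with relation one of \code{1}, \code{-1}, \code{activates},
#' \code{inhibits}. Lines starting with \code{#} (and inline \code{#}
#' comments) are ignored. Duplicate identical lines collapse to one
#' transition; a duplicated pair carrying both signs is kept in both
#' orientations with a warning (the calibration decides between the
#' contradictory hypotheses).
#'
#' Species enter with role \code{"unknown"} and all flags \code{FALSE};
#' annotate them afterwards with \code{\link{annotateSpecies}}.
#'
#' @param path path to the SIF file.
#' @return a \linkS4class{PriorNetwork}.
#' @examples
#' sif <- tempfile(fileext = ".sif")
#' writeLines(c("IL6\t1\tJAK", "JAK\t1\tSTAT3"), sif)
#' readSIF(sif)
#' @export
readSIF <- function(path) {
    lines <- readLines(path)
    stripped <- sub("#.*$", "", lines)
    src <- tgt <- character(0)
    sgn <- integer(0)
    for (i in seq_along(stripped)) {
        ln <- trimws(stripped[i])
        if (!nzchar(ln)) next
        parts <- strsplit(ln, "[ \t]+")[[1L]]
        if (length(parts) != 3L)
            stop("malformed SIF line ", i, ": expected 'source relation target'")
        rel <- switch(parts[2L],
                      "1" = 1L, "-1" = -1L,
                      "activates" = 1L, "inhibits" = -1L,
                      stop("malformed SIF line ", i, ": invalid relation '",
                           parts[2L], "'"))
        src <- c(src, parts[1L]); tgt <- c(tgt, parts[3L]); sgn <- c(sgn, rel)
    }
    tr <- unique(data.frame(source = src, target = tgt, sign = sgn,
                            stringsAsFactors = FALSE))
    pairs <- paste(tr$source, tr$target)
    if (anyDuplicated(pairs))
        warning("contradictory duplicate transition(s) (both signs) for: ",
                paste(unique(pairs[duplicated(pairs)]), collapse = ", "),
                "; both retained")
    PriorNetwork(unique(c(tr$source, tr$target)), tr)
}

#' Write a network to a SIF file
#'
#' @param net a \linkS4class{PriorNetwork}; if its transitions carry a
#'   \code{frequency} column (see \code{\link{consensusNetwork}}) it is
#'   written as a fourth column.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSIF <- function(net, path) {
    tr <- net@transitions
    lines <- paste(tr$source, tr$sign, tr$target, sep = "\t")
    if (!is.null(tr$frequency))
        lines <- paste(lines, format(tr$frequency, digits = 4), sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

#' Annotate species with roles and flags
#'
#' @param net a \linkS4class{PriorNetwork}.
#' @param annotations data.frame with column \code{name} plus any of
#'   \code{role}, \code{measured}, \code{perturbable}, \code{constitutive}.
#'   Species absent from the table keep their current annotation.
#' @return the annotated \linkS4class{PriorNetwork}.
#' @export
annotateSpecies <- function(net, annotations) {
    sp <- net@species
    ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
    unknown <- setdiff(ann$name, sp$name)
    if (length(unknown))
        stop("annotation for undeclared species: ",
             paste(unknown, collapse = ", "))
    idx <- match(ann$name, sp$name)
    if (!is.null(ann$role)) sp$role[idx] <- ann$role
    for (fl in c("measured", "perturbable", "constitutive"))
        if (!is.null(ann[[fl]])) sp[[fl]][idx] <- as.logical(ann[[fl]])
    PriorNetwork(sp, net@transitions)
}

#' @rdname annotateSpecies
#' @param path CSV file with columns
#'   \code{name,role,measured,perturbable,constitutive}.
#' @export
readSpeciesAnnotations <- function(path) {
    read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' Flatten Boolean gates into signed transitions
#'
#' Converts a gated (Boolean) network description into a flat
#' \linkS4class{PriorNetwork}: every input of every gate becomes one
#' transition to the gate's output, negated inputs with sign -1 and plain
#' inputs with sign +1. The AND/OR structure itself is discarded; candidate
#' gates are re-hypothesized later by \code{\link{expandGates}}.
#'
#' @param gateSpecs list of gates, each a list with elements \code{output}
#'   (species name), \code{inputs} (character vector) and optionally
#'   \code{negated} (logical vector parallel to \code{inputs}, default all
#'   \code{FALSE}).
#' @param species optional character vector of species names to declare in
#'   addition to those appearing in gates.
#' @return a \linkS4class{PriorNetwork}.
#' @examples
#' flattenBooleanGates(list(
#'     list(output = "C", inputs = c("A", "B"), negated = c(FALSE, TRUE))))
#' @export
flattenBooleanGates <- function(gateSpecs, species = character()) {
    src <- tgt <- character(0); sgn <- integer(0)
    for (g in gateSpecs) {
        if (length(g$inputs) == 0L)
            stop("gate with zero inputs for output '", g$output, "'")
        neg <- if (is.null(g$negated)) rep(FALSE, length(g$inputs))
               else g$negated
        src <- c(src, g$inputs)
        tgt <- c(tgt, rep(g$output, length(g$inputs)))
        sgn <- c(sgn, ifelse(neg, -1L, 1L))
    }
    PriorNetwork(unique(c(species, src, tgt)),
                 data.frame(source = src, target = tgt, sign = sgn,
                            stringsAsFactors = FALSE))
}

#' Remove feedback loops
#'
#' Deletes transitions until the network is acyclic, either from an explicit
#' removal list (reproducing a curated simplification) or automatically:
#' repeatedly delete the transition that participates in the largest number
#' of simple cycles, breaking ties by lexicographic (source, target) order.
#'
#' Steady-state logic has no time scale, so feedback loops carry no usable
#' information here and must be cut before simulation.
#'
#' @param net a \linkS4class{PriorNetwork}.
#' @param removals either the string \code{"auto"} (default) or a data.frame
#'   of transitions (\code{source}, \code{target}, optionally \code{sign})
#'   to delete.
#' @param report if \code{TRUE}, return
#'   \code{list(network = , deleted = data.frame)} instead of just the
#'   network.
#' @return the acyclic \linkS4class{PriorNetwork} (or a list, see
#'   \code{report}).
#' @export
removeFeedback <- function(net, removals = "auto", report = FALSE) {
    tr <- net@transitions
    deleted <- tr[0, ]
    if (is.character(removals) && identical(removals, "auto")) {
        while (!.isAcyclic(PriorNetwork(net@species, tr))) {
            cyc <- .simpleCycles(PriorNetwork(net@species, tr))
            edges <- unique(tr[, c("source", "target")])
            counts <- integer(nrow(edges))
            for (nm in cyc) {
                esrc <- nm
                etgt <- c(nm[-1L], nm[1L])
                hit <- paste(edges$source, edges$target) %in%
                       paste(esrc, etgt)
                counts[hit] <- counts[hit] + 1L
            }
            cand <- edges[counts == max(counts), , drop = FALSE]
            cand <- cand[order(cand$source, cand$target), , drop = FALSE]
            pick <- cand[1L, ]
            drop <- tr$source == pick$source & tr$target == pick$target
            deleted <- rbind(deleted, tr[drop, , drop = FALSE])
            tr <- tr[!drop, , drop = FALSE]
        }
    } else {
        removals <- as.data.frame(removals, stringsAsFactors = FALSE)
        for (i in seq_len(nrow(removals))) {
            drop <- tr$source == removals$source[i] &
                    tr$target == removals$target[i]
            if (!is.null(removals$sign))
                drop <- drop & tr$sign == removals$sign[i]
            if (!any(drop))
                stop("transition to remove not found: ",
                     removals$source[i], " -> ", removals$target[i])
            deleted <- rbind(deleted, tr[drop, , drop = FALSE])
            tr <- tr[!drop, , drop = FALSE]
        }
        if (!.isAcyclic(PriorNetwork(net@species, tr)))
            stop("network still cyclic after applying the removal list")
    }
    out <- PriorNetwork(net@species, tr)
    if (report) list(network = out, deleted = deleted) else out
}

# Clampable species for equivalence checks: designated stimuli plus
# perturbable species.
.clampableSpecies <- function(net) {
    sp <- net@species
    sp$name[sp$role == "stimulus" | sp$perturbable]
}

# TRUE if the two networks have identical Boolean steady states at every
# measured species for every 0/1 clamp pattern of the clampable species.
.equivalentAtMeasured <- function(netA, netB, clampable, measured) {
    for (cl in .clampPatterns(clampable)) {
        sa <- .booleanSteadyState(netA, cl)
        sb <- .booleanSteadyState(netB, cl)
        if (!isTRUE(all.equal(sa[measured], sb[measured])))
            return(FALSE)
    }
    TRUE
}

#' Compress a prior knowledge network
#'
#' Removes species that are neither measured nor perturbable (and are not
#' stimuli or constitutive regulators) by pass-through rewiring: every pair
#' of transitions (U -> S, sign s1) and (S -> V, sign s2) becomes
#' (U -> V, sign s1*s2). A species is retained for logical consistency if
#' (i) it has in-degree > 1 and out-degree > 1, (ii) rewiring would create a
#' contradictory duplicate of an existing transition, or (iii) its removal
#' would change any Boolean steady state at a measured species under some
#' clamp pattern of the stimuli/perturbable species (verified exhaustively).
#'
#' @param net an acyclic, annotated \linkS4class{PriorNetwork}.
#' @param report if \code{TRUE}, return
#'   \code{list(network = , removed = character)} instead.
#' @return the compressed \linkS4class{PriorNetwork} (or a list, see
#'   \code{report}).
#' @export
compressNetwork <- function(net, report = FALSE) {
    if (!.isAcyclic(net)) stop("network must be acyclic before compression")
    clampable <- .clampableSpecies(net)
    measured <- net@species$name[net@species$measured]
    removed <- character(0)
    cur <- net
    repeat {
        sp <- cur@species; tr <- cur@transitions
        cand <- sp$name[!sp$measured & !sp$perturbable & !sp$constitutive &
                        sp$role != "stimulus"]
        progress <- FALSE
        for (s in cand) {
            ins <- tr[tr$target == s, , drop = FALSE]
            outs <- tr[tr$source == s, , drop = FALSE]
            if (nrow(ins) == 0L || nrow(outs) == 0L) next
            if (nrow(ins) > 1L && nrow(outs) > 1L) next
            rew <- expand.grid(i = seq_len(nrow(ins)), o = seq_len(nrow(outs)))
            newtr <- data.frame(source = ins$source[rew$i],
                                target = outs$target[rew$o],
                                sign = ins$sign[rew$i] * outs$sign[rew$o],
                                stringsAsFactors = FALSE)
            newtr <- newtr[newtr$source != newtr$target, , drop = FALSE]
            keep <- tr[tr$source != s & tr$target != s, , drop = FALSE]
            merged <- unique(rbind(keep, newtr))
            pairs <- paste(merged$source, merged$target)
            if (anyDuplicated(pairs)) next  # conflicting-sign duplicate path
            trial <- PriorNetwork(sp[sp$name != s, , drop = FALSE], merged)
            if (!.equivalentAtMeasured(cur, trial, clampable, measured)) next
            cur <- trial
            removed <- c(removed, s)
            progress <- TRUE
            break
        }
        if (!progress) break
    }
    if (report) list(network = cur, removed = removed) else cur
}

#' Expand a network into its candidate gate space
#'
#' For each target with d incoming transitions this enumerates d one-input
#' gates plus, for every j in 2..min(d, maxAndSize), all AND gates over j
#' incoming transitions with pairwise distinct sources (each input keeps the
#' sign of its transition). Gates on a target combine by OR during
#' simulation.
#'
#' @param net an acyclic \linkS4class{PriorNetwork}.
#' @param maxAndSize maximum number of AND-gate inputs (default 2, pairwise
#'   ANDs).
#' @return a \linkS4class{GateSpace}.
#' @examples
#' net <- PriorNetwork(c("A", "B", "C"),
#'     data.frame(source = c("A", "B"), target = c("C", "C"),
#'                sign = c(1L, -1L)))
#' expandGates(net)  # 2 singles + 1 AND
#' @export
expandGates <- function(net, maxAndSize = 2L) {
    if (maxAndSize < 1L) stop("maxAndSize must be >= 1")
    if (!.isAcyclic(net)) stop("network must be acyclic")
    tr <- net@transitions
    gates <- list()
    for (target in unique(tr$target)) {
        inc <- tr[tr$target == target, , drop = FALSE]
        inc <- inc[order(inc$source, inc$sign), , drop = FALSE]
        d <- nrow(inc)
        for (i in seq_len(d))
            gates[[length(gates) + 1L]] <- list(
                target = target, sources = inc$source[i],
                signs = inc$sign[i], kind = "single")
        m <- min(d, maxAndSize)
        if (m >= 2L) for (j in 2:m) {
            combos <- combn(seq_len(d), j)
            for (ci in seq_len(ncol(combos))) {
                sel <- combos[, ci]
                if (anyDuplicated(inc$source[sel])) next
                gates[[length(gates) + 1L]] <- list(
                    target = target, sources = inc$source[sel],
                    signs = inc$sign[sel], kind = "AND")
            }
        }
    }
    new("GateSpace", network = net, gates = gates,
        maxAndSize = as.integer(maxAndSize))
}
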