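# Internal graph helpers built on igraph.

.asIgraph <- function(net) {
    graph_from_data_frame(
        unique(net@transitions[, c("source", "target")]),
        directed = TRUE, vertices = net@species$name)
}

.isAcyclic <- function(net) {
    if (nrow(net@transitions) == 0L) return(TRUE)
    is_dag(.asIgraph(net))
}

# Topological order of species names (sources before targets).
.topoOrder <- function(net) {
    if (!.isAcyclic(net))
        stop("network contains a cycle; run removeFeedback() first")
    as_ids(topo_sort(.asIgraph(net), mode = "out"))
}

# Species downstream of (reachable from) any of `from`.
.descendants <- function(net, from) {
    from <- intersect(from, net@species$name)
    if (!length(from)) return(character())
    g <- .asIgraph(net)
    out <- unique(unlist(lapply(from, function(s)
        as_ids(subcomponent(g, s, mode = "out")))))
    setdiff(out, from)
}

# Enumerate all simple directed cycles, each anchored at (and reported
# starting from) its lowest-index vertex. Plain DFS; fine for PKN-sized
# graphs.
.simpleCycles <- function(net) {
    nodes <- net@species$name
    tr <- unique(net@transitions[, c("source", "target")])
    adj <- lapply(nodes, function(v) tr$target[tr$source == v])
    names(adj) <- nodes
    idx <- setNames(seq_along(nodes), nodes)
    cycles <- list()
    path <- character()
    visit <- function(v, start) {
        path <<- c(path, v)
        for (w in adj[[v]]) {
            if (w == start) {
                cycles[[length(cycles) + 1L]] <<- path
            } else if (idx[[w]] > idx[[start]] && !(w %in% path)) {
                visit(w, start)
            }
        }
        path <<- path[-length(path)]
    }
    for (start in nodes) visit(start, start)
    cycles
}

# Boolean steady state of a flat network (every transition its own one-input
# gate, gates OR-combined): used for the compression-equivalence check.
# clamps: named vector of 0/1 clamp values; unclamped species with no inputs
# take their constitutive baseline (1 if constitutive else 0).
.booleanSteadyState <- function(net, clamps = numeric()) {
    ord <- .topoOrder(net)
    tr <- net@transitions
    base <- ifelse(net@species$constitutive, 1, 0)
    names(base) <- net@species$name
    state <- setNames(numeric(length(ord)), ord)
    for (s in ord) {
        if (s %in% names(clamps)) {
            state[s] <- clamps[[s]]
            next
        }
        inc <- tr[tr$target == s, , drop = FALSE]
        if (nrow(inc) == 0L) {
            state[s] <- base[[s]]
        } else {
            contrib <- ifelse(inc$sign > 0, state[inc$source],
                              1 - state[inc$source])
            state[s] <- max(contrib)
        }
    }
    state[net@species$name[net@species$name %in% ord]]
}

# All 0/1 clamp assignments over the given species, as a list of named
# vectors (2^k patterns).
.clampPatterns <- function(speciesNames) {
    k <- length(speciesNames)
    if (k == 0L) return(list(numeric()))
    grid <- expand.grid(rep(list(c(0, 1)), k))
    lapply(seq_len(nrow(grid)), function(i)
        setNames(as.numeric(grid[i, ]), speciesNames))
}
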