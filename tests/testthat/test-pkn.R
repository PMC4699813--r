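test_that("readSIF parses triples, enforces set semantics, flags bad lines", {
    sif <- withr::local_tempfile(fileext = ".sif")
    writeLines(c("IL6\t1\tJAK", "JAK 1 STAT3", "# comment", ""), sif)
    net <- readSIF(sif)
    expect_setequal(speciesInfo(net)$name, c("IL6", "JAK", "STAT3"))
    expect_equal(nrow(transitions(net)), 2L)
    expect_true(all(transitions(net)$sign == 1L))

    writeLines(c("A foo B"), sif)
    expect_error(readSIF(sif), "line 1")

    writeLines(c("A 1 B", "A 1 B"), sif)
    expect_equal(nrow(transitions(readSIF(sif))), 1L)

    writeLines(c("A activates B", "A inhibits B"), sif)
    expect_warning(net2 <- readSIF(sif), "contradictory")
    expect_equal(sort(transitions(net2)$sign), c(-1L, 1L))
})

test_that("flattenBooleanGates turns gated logic into signed transitions", {
    net <- flattenBooleanGates(list(
        list(output = "C", inputs = c("A", "B"),
             negated = c(FALSE, TRUE))))
    tr <- transitions(net)
    expect_equal(tr$sign[tr$source == "A"], 1L)
    expect_equal(tr$sign[tr$source == "B"], -1L)

    orNet <- flattenBooleanGates(list(list(output = "C",
                                           inputs = c("A", "B"))))
    expect_equal(transitions(orNet)$sign, c(1L, 1L))

    notNet <- flattenBooleanGates(list(list(output = "B", inputs = "A",
                                            negated = TRUE)))
    expect_equal(transitions(notNet)$sign, -1L)

    expect_error(flattenBooleanGates(list(list(output = "X",
                                               inputs = character()))),
                 "zero inputs")

    # idempotent on already-flat gate lists
    again <- flattenBooleanGates(list(
        list(output = "C", inputs = "A"),
        list(output = "C", inputs = "B", negated = TRUE)))
    expect_equal(transitions(again)[order(transitions(again)$source), ],
                 transitions(net)[order(transitions(net)$source), ],
                 ignore_attr = TRUE)
})

test_that("removeFeedback yields acyclic networks via list or auto policy", {
    net <- PriorNetwork(c("A", "B"),
        data.frame(source = c("A", "B"), target = c("B", "A"),
                   sign = c(1L, 1L)))
    out <- removeFeedback(net, data.frame(source = "B", target = "A"),
                          report = TRUE)
    expect_equal(nrow(transitions(out$network)), 1L)
    expect_equal(out$deleted$source, "B")

    expect_error(removeFeedback(net, data.frame(source = "X", target = "A")),
                 "not found")

    # acyclic input: identity, empty report
    dag <- PriorNetwork(c("A", "B"),
        data.frame(source = "A", target = "B", sign = 1L))
    outDag <- removeFeedback(dag, "auto", report = TRUE)
    expect_equal(nrow(outDag$deleted), 0L)
    expect_equal(transitions(outDag$network), transitions(dag))

    # 3-cycle: exactly one deletion suffices, whichever edge (verified by
    # enumeration that deleting any single edge yields a DAG)
    cyc <- PriorNetwork(c("A", "B", "C"),
        data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
                   sign = 1L))
    for (i in 1:3) {
        trial <- PriorNetwork(c("A", "B", "C"), transitions(cyc)[-i, ])
        expect_silent(fuzzyhep:::.topoOrder(trial))
    }
    outCyc <- removeFeedback(cyc, "auto", report = TRUE)
    expect_equal(nrow(outCyc$deleted), 1L)
    expect_silent(fuzzyhep:::.topoOrder(outCyc$network))
})

test_that("auto feedback removal prefers the edge breaking most cycles", {
    # B->A closes two cycles (A->B->A and A->C->B->A); the tie-free optimum
    # is to delete B->A alone.
    net <- PriorNetwork(c("A", "B", "C"),
        data.frame(source = c("A", "B", "A", "C"),
                   target = c("B", "A", "C", "B"),
                   sign = 1L))
    out <- removeFeedback(net, "auto", report = TRUE)
    expect_equal(nrow(out$deleted), 1L)
    expect_equal(out$deleted$source, "B")
    expect_equal(out$deleted$target, "A")
})

test_that("compression rewires pass-through species with sign products", {
    net <- annotateSpecies(
        PriorNetwork(c("A", "B", "C"),
            data.frame(source = c("A", "B"), target = c("B", "C"),
                       sign = c(1L, -1L))),
        data.frame(name = c("A", "C"), measured = c(TRUE, TRUE)))
    out <- compressNetwork(net, report = TRUE)
    expect_equal(out$removed, "B")
    tr <- transitions(out$network)
    expect_equal(tr, data.frame(source = "A", target = "C", sign = -1L))

    # measured intermediates are retained
    net2 <- annotateSpecies(net, data.frame(name = "B", measured = TRUE))
    expect_equal(compressNetwork(net2, report = TRUE)$removed, character(0))
})

test_that("compression preserves measured steady states on random DAGs", {
    set.seed(42)
    for (rep in 1:40) {
        net <- randomDAGNet(sample(5:8, 1L))
        if (!any(speciesInfo(net)$measured)) next
        cnet <- compressNetwork(net)
        clampable <- with(speciesInfo(net),
                          name[role == "stimulus" | perturbable])
        measured <- with(speciesInfo(net), name[measured])
        patterns <- allClampPatterns(clampable)
        des <- patternDesign(patterns)
        pre <- simulateStates(flatModel(net), des)
        post <- simulateStates(flatModel(cnet), des)
        expect_equal(pre[measured, , drop = FALSE],
                     post[measured, , drop = FALSE])
    }
})

test_that("gate expansion matches the combinatorial count", {
    mk <- function(d) {
        PriorNetwork(c(paste0("I", seq_len(d)), "T"),
            data.frame(source = paste0("I", seq_len(d)), target = "T",
                       sign = 1L))
    }
    expect_equal(length(gates(expandGates(mk(1L), 2L))), 1L)
    expect_equal(length(gates(expandGates(mk(2L), 2L))), 3L)
    expect_equal(length(gates(expandGates(mk(3L), 2L))), 6L)
    # exact formula d + sum_j C(d, j) for d <= 6, maxAndSize <= 3
    for (d in 1:6) for (mas in 1:3) {
        m <- min(d, mas)
        expected <- d + if (m >= 2) sum(choose(d, 2:m)) else 0
        expect_equal(length(gates(expandGates(mk(d), mas))), expected)
    }
    expect_error(expandGates(mk(2L), 0L), "maxAndSize")
})

test_that("AND gates require distinct sources (contradictory duplicates)", {
    net <- PriorNetwork(c("A", "T"),
        data.frame(source = c("A", "A"), target = c("T", "T"),
                   sign = c(1L, -1L)))
    gs <- gates(expandGates(net, 2L))
    expect_equal(sum(vapply(gs, `[[`, character(1), "kind") == "AND"), 0L)
    expect_equal(length(gs), 2L)  # both contradictory singles hypothesized
})

test_that("the bundled hepatic example network preprocesses end to end", {
    sif <- system.file("extdata", "hepatic_pkn_synthetic.sif",
                       package = "fuzzyhep")
    ann <- system.file("extdata", "hepatic_annotations_synthetic.csv",
                       package = "fuzzyhep")
    rem <- system.file("extdata", "hepatic_feedback_removals.csv",
                       package = "fuzzyhep")
    net <- annotateSpecies(readSIF(sif), readSpeciesAnnotations(ann))
    expect_false(fuzzyhep:::.isAcyclic(net))  # SOCS feedback loops present
    cut <- removeFeedback(net, read.csv(rem), report = TRUE)
    expect_equal(nrow(cut$deleted), 2L)
    expect_silent(fuzzyhep:::.topoOrder(cut$network))
    comp <- compressNetwork(cut$network, report = TRUE)
    # unmeasured, unperturbable pass-through kinases disappear
    expect_true(all(c("gp130", "RAS", "MEK") %in% comp$removed))
    # measured genes and perturbable kinases survive
    kept <- speciesInfo(comp$network)$name
    expect_true(all(c("STAT3", "ERK", "PI3K", "CYP3A4", "CRP") %in% kept))
    space <- expandGates(comp$network, 2L)
    expect_gt(length(gates(space)), 30L)
})
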