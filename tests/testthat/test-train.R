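test_that("GA equals exhaustive search on an enumerable genome space", {
    p <- twoInputProblem()
    ctrl <- gaControl(seed = 3, populationSize = 40, maxGenerations = 300,
                      stallGenerations = 60)
    fit <- gaOptimize(p$space, p$design, p$data, ctrl)

    # brute force over all (off | 45 grid cells)^2 = 46^2 genomes
    grid <- expand.grid(k = ctrl@kGrid, n = ctrl@nGrid)
    opts <- c(list(NULL), lapply(seq_len(nrow(grid)), function(i)
        c(grid$k[i], grid$n[i])))
    best <- Inf
    for (o1 in opts) for (o2 in opts) {
        gl <- list()
        if (!is.null(o1)) {
            g <- gates(p$space)[[1L]]; g$k <- o1[1L]; g$n <- o1[2L]
            gl <- c(gl, list(g))
        }
        if (!is.null(o2)) {
            g <- gates(p$space)[[2L]]; g$k <- o2[1L]; g$n <- o2[2L]
            gl <- c(gl, list(g))
        }
        m <- new("FuzzyModel", network = p$net, gates = gl)
        best <- min(best, scoreMSE(m, p$design, p$data))
    }
    expect_equal(fit$mse, best, tolerance = 1e-12)
    expect_equal(best, 0)  # the grid contains the generating parameters
})

test_that("identical seeds reproduce identical GA results", {
    p <- twoInputProblem()
    ctrl <- gaControl(seed = 9, populationSize = 20, maxGenerations = 50,
                      stallGenerations = 20)
    a <- gaOptimize(p$space, p$design, p$data, ctrl)
    b <- gaOptimize(p$space, p$design, p$data, ctrl)
    expect_identical(a$genome, b$genome)
    expect_identical(a$mse, b$mse)
})

test_that("training errors on unidentifiable layouts and empty data", {
    net <- PriorNetwork(
        data.frame(name = c("IL6", "X", "G"),
                   role = c("stimulus", "signaling", "gene"),
                   measured = c(FALSE, FALSE, TRUE),
                   perturbable = FALSE, constitutive = FALSE),
        data.frame(source = "X", target = "G", sign = 1L))
    space <- expandGates(net, 2L)
    des <- ExperimentDesign("c", list(c(IL6 = 1)), list(character()))
    dat <- makeNormSet(list(D1 = matrix(1, 1, 1,
                                        dimnames = list("G", "c"))))
    expect_error(gaOptimize(space, des, dat), "unidentifiable")
})

test_that("reduction removes duplicates free of charge and respects the bound", {
    net <- PriorNetwork(
        data.frame(name = c("IL6", "G"), role = c("stimulus", "gene"),
                   measured = c(FALSE, TRUE), perturbable = FALSE,
                   constitutive = FALSE),
        data.frame(source = "IL6", target = "G", sign = 1L))
    gate <- list(target = "G", sources = "IL6", signs = 1L,
                 kind = "single", k = 0.5, n = 4)
    dup <- new("FuzzyModel", network = net, gates = list(gate, gate))
    des <- patternDesign(list(c(IL6 = 0.3), c(IL6 = 0.8)))
    tab <- simulateStates(dup, des)["G", , drop = FALSE]
    rownames(tab) <- "G"
    dat <- makeNormSet(list(D1 = tab))

    red <- reduceModel(dup, des, dat, threshold = 0, report = TRUE)
    expect_length(gates(red$model), 1L)
    expect_equal(red$mse, red$mseOriginal)

    # no exactly-redundant gate at threshold 0: unchanged
    single <- new("FuzzyModel", network = net, gates = list(gate))
    expect_length(gates(reduceModel(single, des, dat, threshold = 0)), 1L)

    # infinite tolerance empties the gate set but keeps the MSE finite
    redInf <- reduceModel(single, des, dat, threshold = Inf, report = TRUE)
    expect_length(gates(redInf$model), 0L)
    expect_true(is.finite(redInf$mse))
})

test_that("family fitting asserts the reduction bound and counts frequencies", {
    net <- makeBenchmarkPKN("toy")
    design <- makeBenchmarkDesign(net)
    truth <- sampleTruth(net, seed = 5, design = design,
                         noiseCV = 0.1, donorSD = 0.1, missingRate = 0)
    ms <- emitDataset(truth, nDonors = 3L)
    norm <- normalizeFoldChanges(ms, assignMidpoints(ms, "IL6"))
    ctrl <- gaControl(seed = 21, populationSize = 30, maxGenerations = 150,
                      stallGenerations = 40)
    fam <- fitModelFamily(expandGates(net, 2L), design, norm, ctrl,
                          nRuns = 6L, threshold = 0.01)

    # reduction bound, asserted per run
    expect_true(all(familyMSE(fam) - familyMSE(fam, reduced = FALSE)
                    <= 0.01 + 1e-12))

    # consensus frequencies re-derived from the stored models
    gf <- consensus(fam)$gates
    for (i in seq_len(nrow(gf))) {
        n <- sum(vapply(fam@models, function(m)
            gf$key[i] %in% vapply(gates(m), fuzzyhep:::.gateKey,
                                  character(1)),
            logical(1)))
        expect_equal(gf$frequency[i], n / fam@nRuns)
    }
    expect_equal(meanParameters(fam),
                 mean(vapply(fam@models, function(m) 2 * length(gates(m)),
                             numeric(1))))

    # byte-identical refit with the same configuration
    fam2 <- fitModelFamily(expandGates(net, 2L), design, norm, ctrl,
                           nRuns = 6L, threshold = 0.01)
    expect_identical(familyMSE(fam), familyMSE(fam2))
    expect_identical(consensus(fam), consensus(fam2))
})

test_that("consensus networks apply the display cutoff inclusively", {
    net <- makeBenchmarkPKN("toy")
    design <- makeBenchmarkDesign(net)
    truth <- sampleTruth(net, seed = 5, design = design, noiseCV = 0.1,
                         donorSD = 0.1, missingRate = 0)
    ms <- emitDataset(truth, nDonors = 2L)
    norm <- normalizeFoldChanges(ms, assignMidpoints(ms, "IL6"))
    ctrl <- gaControl(seed = 2, populationSize = 25, maxGenerations = 80,
                      stallGenerations = 30)
    fam <- fitModelFamily(expandGates(net, 2L), design, norm, ctrl,
                          nRuns = 5L)
    cons <- consensusNetwork(fam, minFrequency = 0.30)
    tf <- consensus(fam)$transitions
    expect_setequal(
        paste(transitions(cons)$source, transitions(cons)$target),
        paste(tf$source[tf$frequency >= 0.30],
              tf$target[tf$frequency >= 0.30]))
    expect_true(all(transitions(cons)$frequency >= 0.30))
    # a frequency just below the cutoff is excluded, at the cutoff included
    fake <- fam
    fake@consensus$transitions$frequency[1L] <- 0.29
    cons2 <- consensusNetwork(fake, 0.30)
    expect_false(paste(tf$source[1L], tf$target[1L], tf$sign[1L]) %in%
                 paste(transitions(cons2)$source, transitions(cons2)$target,
                       transitions(cons2)$sign))
})

test_that("the reduction curve is monotone on the toy benchmark", {
    net <- makeBenchmarkPKN("toy")
    design <- makeBenchmarkDesign(net)
    truth <- sampleTruth(net, seed = 13, design = design, noiseCV = 0.15,
                         donorSD = 0.2, missingRate = 0.02)
    ms <- emitDataset(truth, nDonors = 4L)
    norm <- normalizeFoldChanges(ms, assignMidpoints(ms, "IL6"))
    ctrl <- gaControl(seed = 31, populationSize = 30, maxGenerations = 150,
                      stallGenerations = 40)
    curve <- reductionCurve(expandGates(net, 2L), design, norm, ctrl,
                            thresholds = c(0, 0.0005, 0.001, 0.005, 0.01,
                                           0.05, 0.1),
                            nRuns = 4L)
    expect_true(all(diff(curve$meanParameters) <= 0))
    expect_true(all(diff(curve$meanMSE) >= -1e-12))
    expect_error(reductionCurve(expandGates(net, 2L), design, norm, ctrl,
                                thresholds = c(0.1, 0)), "sorted")
})
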