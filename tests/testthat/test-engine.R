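chainModel <- function() {
    net <- annotateSpecies(
        PriorNetwork(
            data.frame(name = c("IL6", "A", "G"),
                       role = c("stimulus", "signaling", "gene"),
                       measured = c(FALSE, FALSE, TRUE),
                       perturbable = c(FALSE, TRUE, FALSE),
                       constitutive = FALSE),
            data.frame(source = c("IL6", "A"), target = c("A", "G"),
                       sign = c(1L, -1L))),
        data.frame(name = "IL6", role = "stimulus"))
    flatModel(net, k = 0.5, n = 10)
}

test_that("transfer function is anchored at 0/1 and matches hand values", {
    expect_identical(transferHill(0, 0.3, 2), 0)
    expect_identical(transferHill(1, 0.3, 2), 1)
    expect_equal(transferHill(0.5, 0.5, 4), 0.53125)
    expect_error(transferHill(1.5, 0.5, 4), "lie in")
    # strictly increasing
    x <- seq(0, 1, by = 0.01)
    expect_true(all(diff(transferHill(x, 0.7, 3)) > 0))
})

test_that("steady states follow clamp/gate semantics on the signalling chain", {
    m <- chainModel()
    des <- ExperimentDesign(
        c("off", "on", "on_Ai"),
        stimuli = list(c(IL6 = 0), c(IL6 = 1), c(IL6 = 1)),
        inhibited = list(character(), character(), "A"))
    st <- simulateStates(m, des)
    # inactive stimulus: inhibitory input gives the gene state exactly 1
    expect_identical(st[, "off"], c(IL6 = 0, A = 0, G = 1))
    # active stimulus with steep transfer: Boolean propagation
    expect_identical(st[, "on"], c(IL6 = 1, A = 1, G = 0))
    # the inhibitor clamp overrides the gate
    expect_identical(st[, "on_Ai"], c(IL6 = 1, A = 0, G = 1))
})

test_that("fuzzy simulation equals the Boolean oracle on random DAG models", {
    set.seed(7)
    for (rep in 1:60) {
        net <- randomDAGNet(sample(4:10, 1L))
        model <- randomModel(net, maxAndSize = 2L, k = 0.5, n = 10)
        clampable <- with(speciesInfo(net),
                          name[role == "stimulus" | perturbable])
        patterns <- allClampPatterns(clampable)
        st <- simulateStates(model, patternDesign(patterns))
        for (i in seq_along(patterns)) {
            expect_identical(st[, i],
                             oracleSteadyState(model, patterns[[i]]))
        }
    }
})

test_that("all states stay in [0,1] for arbitrary parameters and clamps", {
    set.seed(11)
    for (rep in 1:25) {
        net <- randomDAGNet(sample(4:9, 1L))
        model <- randomModel(net, k = runif(1, 0.05, 1),
                             n = runif(1, 1, 8))
        clampable <- with(speciesInfo(net),
                          name[role == "stimulus" | perturbable])
        lv <- stats::setNames(runif(length(clampable)), clampable)
        st <- simulateStates(model, patternDesign(list(lv)))
        expect_true(all(st >= 0 & st <= 1))
    }
})

test_that("monotone response: raising the stimulus never lowers positive-path targets", {
    net <- PriorNetwork(
        data.frame(name = c("S", "A", "G"), role = c("stimulus", "signaling",
                                                     "gene"),
                   measured = c(FALSE, FALSE, TRUE), perturbable = FALSE,
                   constitutive = FALSE),
        data.frame(source = c("S", "A"), target = c("A", "G"), sign = 1L))
    m <- flatModel(net, k = 0.4, n = 3)
    lvls <- seq(0, 1, by = 0.1)
    des <- patternDesign(lapply(lvls, function(x) c(S = x)))
    st <- simulateStates(m, des)
    expect_true(all(diff(st["G", ]) >= 0))
})

test_that("MSE pools non-missing cells only", {
    m <- chainModel()
    des <- ExperimentDesign("on", list(c(IL6 = 1)), list(character()))
    # prediction for G under stimulus is 0
    tab <- matrix(0.5, 1, 1, dimnames = list("G", "on"))
    expect_equal(scoreMSE(m, des, makeNormSet(list(D1 = tab))), 0.25)

    # two cells, one with error 0.1 and one missing: mean over the single
    # observed cell, 0.01
    nsTwoDonor <- makeNormSet(list(
        D1 = matrix(0.1, 1, 1, dimnames = list("G", "on")),
        D2 = matrix(NA_real_, 1, 1, dimnames = list("G", "on"))))
    expect_equal(scoreMSE(m, des, nsTwoDonor), 0.01)

    # prediction equal to data gives exactly zero
    tab0 <- matrix(0, 1, 1, dimnames = list("G", "on"))
    expect_equal(scoreMSE(m, des, makeNormSet(list(D1 = tab0))), 0)

    # unknown genes are refused
    bad <- matrix(0.2, 1, 1, dimnames = list("NOPE", "on"))
    expect_error(scoreMSE(m, des, makeNormSet(list(D1 = bad))), "NOPE")
})

test_that("a gene driven only by an inhibitor rests at 1 (control behaviour)", {
    # the DMET anchor: with the cytokine off, down-regulated genes sit ON
    m <- chainModel()
    des <- ExperimentDesign("ctrl", list(c(IL6 = 0)), list(character()))
    expect_identical(simulateStates(m, des)["G", "ctrl"], 1)
})

test_that("constitutive regulators rest at baseline 1 and drive their targets", {
    net <- PriorNetwork(
        data.frame(name = c("HNF", "G"),
                   role = c("transcription_factor", "gene"),
                   measured = c(FALSE, TRUE), perturbable = FALSE,
                   constitutive = c(TRUE, FALSE)),
        data.frame(source = "HNF", target = "G", sign = 1L))
    m <- flatModel(net, k = 0.5, n = 4)
    des <- ExperimentDesign(c("free", "HNFi"), list(numeric(), numeric()),
                            list(character(), "HNF"))
    st <- simulateStates(m, des)
    expect_identical(st["HNF", "free"], 1)
    expect_identical(st["G", "free"], 1)
    expect_identical(st[, "HNFi"], c(HNF = 0, G = 0))
})
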