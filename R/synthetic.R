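#' Benchmark prior knowledge networks
#'
#' Constructs acyclic benchmark PKNs shaped like a cytokine-driven hepatic
#' gene-regulation network: one stimulus (IL6) feeding three signalling
#' branches (JAK/STAT3, PI3K/AKT/NF-kB, RAF/MAPK), a transcription-factor
#' layer with a nuclear-receptor-complex hub (RXRNR) inhibited by MAPK and
#' NF-kB and a MAPK-inhibited GR-like factor, wired into a measured gene
#' panel dominated by hub targets (fold-change direction mostly down under
#' stimulus, with a few strongly induced acute-phase-like genes under
#' STAT3).
#'
#' The \code{"toy"} scale has 10 species (1 stimulus, 3 perturbable pathway
#' nodes, 2 TFs, 4 genes); the \code{"paper"} scale has 3 perturbable
#' pathway nodes, a 3-species TF layer and 35 genes, with hub out-degree
#' >= 15. Two-regulator genes pair control-ON influences (hub or GR
#' activation, NF-kB repression), so that every candidate gate leaves the
#' gene ON at control and the gate hypotheses keep distinct steady-state
#' signatures under the bundled design — the benchmark stays identifiable
#' and its control fold changes anchor near 1 for every down-class gene.
#'
#' @param scale \code{"toy"} or \code{"paper"}.
#' @return an annotated, acyclic \linkS4class{PriorNetwork}.
#' @export
makeBenchmarkPKN <- function(scale = c("toy", "paper")) {
    scale <- match.arg(scale)
    if (scale == "toy") {
        sp <- data.frame(
            name = c("IL6", "P1", "P2", "P3", "TF1", "TF2",
                     "G1", "G2", "G3", "G4"),
            role = c("stimulus", rep("signaling", 3L),
                     rep("transcription_factor", 2L), rep("gene", 4L)),
            measured = c(rep(FALSE, 6L), rep(TRUE, 4L)),
            perturbable = c(FALSE, TRUE, TRUE, TRUE, rep(FALSE, 6L)),
            constitutive = FALSE, stringsAsFactors = FALSE)
        tr <- data.frame(
            source = c("IL6", "IL6", "IL6", "P1", "P2", "P3",
                       "TF1", "TF1", "TF2", "TF1", "TF2"),
            target = c("P1", "P2", "P3", "TF1", "TF1", "TF2",
                       "G1", "G2", "G3", "G4", "G4"),
            sign = c(1L, 1L, 1L, -1L, -1L, 1L,
                     1L, 1L, 1L, 1L, 1L), stringsAsFactors = FALSE)
        return(PriorNetwork(sp, tr))
    }
    hubGenes <- c("CYP3A4L", "CYP2C8L", "CYP2C9L", "CYP1A2L", "CYP2B6L",
                  "CYP2D6L", "CYP2A6L", "ABCB1L", "ABCC2L", "ABCG2L",
                  "SLCO1B1L", "SLC10A1L", "UGT1A1L", "UGT2B7L", "GSTA1L",
                  "SULT1A1L", "NAT1L", "NAT2L", "CYP2C19L", "CYP3A5L",
                  "ABCB11L", "SLC22A1L", "GSTM1L", "SLCO2B1L", "FMO3L",
                  "CES1L")
    grGenes <- c("PER1L", "TSC22D3L")
    nfkbRepressed <- c("AHRL", "PPARAL")
    statGenes <- c("CRPL", "SAA1L", "SOCS3L")
    dualGenes <- c("ABCC3L", "MT2AL")
    genes <- c(hubGenes, grGenes, nfkbRepressed, statGenes, dualGenes)
    sig <- c("JAK", "STAT3", "PI3K", "AKT", "RAF", "MAPK")
    tfs <- c("NFKB", "RXRNR", "GR")
    sp <- data.frame(
        name = c("IL6", sig, tfs, genes),
        role = c("stimulus", rep("signaling", length(sig)),
                 "transcription_factor", "complex", "transcription_factor",
                 rep("gene", length(genes))),
        measured = c(rep(FALSE, 1L + length(sig) + length(tfs)),
                     rep(TRUE, length(genes))),
        perturbable = FALSE, constitutive = FALSE, stringsAsFactors = FALSE)
    sp$perturbable[sp$name %in% c("STAT3", "PI3K", "MAPK")] <- TRUE
    tr <- rbind(
        data.frame(source = c("IL6", "JAK", "IL6", "PI3K", "AKT",
                              "IL6", "RAF", "MAPK", "NFKB", "MAPK"),
                   target = c("JAK", "STAT3", "PI3K", "AKT", "NFKB",
                              "RAF", "MAPK", "RXRNR", "RXRNR", "GR"),
                   sign = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, -1L, -1L, -1L)),
        data.frame(source = "RXRNR", target = hubGenes, sign = 1L),
        data.frame(source = "GR", target = grGenes, sign = 1L),
        data.frame(source = "NFKB", target = nfkbRepressed, sign = -1L),
        data.frame(source = "STAT3", target = statGenes, sign = 1L),
        data.frame(source = c("RXRNR", "NFKB", "GR", "NFKB"),
                   target = c("ABCC3L", "ABCC3L", "MT2AL", "MT2AL"),
                   sign = c(1L, -1L, 1L, -1L)))
    PriorNetwork(sp, tr)
}

#' Benchmark perturbation design
#'
#' The seven treatment conditions used throughout: vehicle control
#' (stimulus 0), stimulus alone, stimulus plus each single pathway
#' inhibition, and stimulus plus the two tolerated double inhibitions (each
#' non-terminal perturbable node combined with the last one; the remaining
#' double inhibition is deliberately absent, mirroring a co-inhibition that
#' kills the cells).
#'
#' @param net an annotated \linkS4class{PriorNetwork} with a stimulus
#'   species and perturbable species.
#' @param stimulus stimulus species name (default the first role-stimulus
#'   species).
#' @return an \linkS4class{ExperimentDesign}.
#' @export
makeBenchmarkDesign <- function(net, stimulus = NULL) {
    sp <- net@species
    if (is.null(stimulus)) stimulus <- sp$name[sp$role == "stimulus"][1L]
    pert <- sp$name[sp$perturbable]
    stopifnot(length(stimulus) == 1L, length(pert) >= 2L)
    conds <- c("control", stimulus)
    stim <- list(setNames(0, stimulus), setNames(1, stimulus))
    inhib <- list(character(), character())
    for (p in pert) {
        conds <- c(conds, paste0(stimulus, "_", p, "i"))
        stim <- c(stim, list(setNames(1, stimulus)))
        inhib <- c(inhib, list(p))
    }
    last <- pert[length(pert)]
    for (p in pert[-length(pert)]) {
        conds <- c(conds, paste0(stimulus, "_", p, "i_", last, "i"))
        stim <- c(stim, list(setNames(1, stimulus)))
        inhib <- c(inhib, list(c(p, last)))
    }
    ExperimentDesign(conds, stim, inhib)
}

#' Sample a ground-truth model
#'
#' For every species with incoming transitions, one gate is drawn uniformly
#' from its expanded candidate space and one (k, n) pair from the training
#' grids, so the fitter's hypothesis space always covers the truth. The
#' per-gene midpoint scheme used for fold-change emission classifies each
#' measured gene by its simulated stimulus response: genes whose state drops
#' under stimulus (or does not change) are "down" (m = 0.5), induced genes
#' are "up" with midpoint \code{upMidpoint}.
#'
#' @param net an acyclic annotated \linkS4class{PriorNetwork}.
#' @param seed integer seed; the same seed reproduces the identical truth.
#' @param design an \linkS4class{ExperimentDesign}; default
#'   \code{makeBenchmarkDesign(net)}.
#' @param maxAndSize AND-gate size for the sampled space (default 2).
#' @param control a \linkS4class{GAControl} supplying the (k, n) grids.
#' @param noiseCV,donorSD,missingRate noise settings stored with the truth
#'   (defaults 0.2, 0.25, 0.02).
#' @param geneEffectSD log2-scale sd of the fixed per-gene effect-size
#'   offset (default 0.5): genes differ in the magnitude of their
#'   regulation, and this spread is a property of the gene, shared across
#'   designs emitted from the same truth.
#' @param upMidpoint emission midpoint for induced genes (default 10, i.e.
#'   strong acute-phase-like induction).
#' @return a \linkS4class{SyntheticTruth}.
#' @export
sampleTruth <- function(net, seed, design = makeBenchmarkDesign(net),
                        maxAndSize = 2L, control = gaControl(),
                        noiseCV = 0.2, donorSD = 0.25, missingRate = 0.02,
                        geneEffectSD = 0.5, upMidpoint = 10) {
    space <- expandGates(net, maxAndSize)
    grid <- .flatGrid(control)
    targets <- unique(vapply(space@gates, `[[`, character(1), "target"))
    sampled <- .withSeed(seed, {
        gl <- lapply(targets, function(tg) {
            idx <- which(vapply(space@gates, function(g)
                g$target == tg, logical(1)))
            g <- space@gates[[if (length(idx) == 1L) idx
                              else sample(idx, 1L)]]
            ki <- sample.int(length(grid$k), 1L)
            g$k <- grid$k[ki]; g$n <- grid$n[ki]
            g
        })
        nMeas <- sum(net@species$measured)
        list(gl = gl, eff = rnorm(nMeas, 0, geneEffectSD))
    })
    model <- new("FuzzyModel", network = net, gates = sampled$gl)
    states <- simulateStates(model, design)
    measured <- net@species$name[net@species$measured]
    stimCond <- design@conditions[2L]
    up <- states[measured, stimCond] > states[measured, "control"]
    m <- ifelse(up, upMidpoint, 0.5)
    names(m) <- measured
    dir <- ifelse(up, "up", "down"); names(dir) <- measured
    scheme <- new("NormalizationScheme", h = 4, midpoints = m,
                  direction = dir)
    eff <- sampled$eff
    names(eff) <- measured
    new("SyntheticTruth", model = model, design = design, scheme = scheme,
        noiseCV = noiseCV, donorSD = donorSD, geneEffect = eff,
        missingRate = missingRate, seed = as.integer(seed))
}

#' Emit a noisy multi-donor fold-change dataset from a truth model
#'
#' Steady states are clipped to [1e-3, 1 - 1e-3], inverted through the Hill
#' normalization (\code{\link{inverseHill}}) with the truth's per-gene
#' midpoints to produce noise-free linear fold changes (the control column
#' is forced to 1 first), then perturbed multiplicatively: a per-(donor,
#' gene) log2-normal random effect with sd \code{donorSD} and a lognormal
#' measurement error with coefficient of variation \code{noiseCV}. Cells
#' are masked missing independently with probability \code{missingRate}.
#' Before any noise, each non-control fold change is scaled by the truth's
#' fixed per-gene effect-size offset (\code{2^geneEffect}).
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param nDonors number of donors (default 5).
#' @param seed seed of the emission noise stream (default derived from the
#'   truth's seed, so a truth regenerates its dataset identically).
#' @return a \linkS4class{MeasurementSet} with donors \code{D1..Dn}.
#' @export
emitDataset <- function(truth, nDonors = 5L, seed = truth@seed + 1L) {
    states <- simulateStates(truth@model, truth@design)
    genes <- names(truth@scheme@midpoints)
    v <- pmin(pmax(states[genes, , drop = FALSE], 1e-3), 1 - 1e-3)
    fc0 <- v
    for (g in genes)
        fc0[g, ] <- inverseHill(v[g, ], truth@scheme@midpoints[[g]],
                                truth@scheme@h)
    eff <- truth@geneEffect
    if (length(eff)) fc0 <- fc0 * 2^eff[genes]
    if ("control" %in% colnames(fc0)) fc0[, "control"] <- 1
    sigma <- sqrt(log(1 + truth@noiseCV^2))
    tables <- .withSeed(seed, {
        lapply(seq_len(nDonors), function(d) {
            eff <- 2^rnorm(length(genes), 0, truth@donorSD)
            noise <- matrix(rlnorm(length(fc0), 0, sigma), nrow(fc0))
            fc <- fc0 * eff * noise
            if (truth@missingRate > 0)
                fc[matrix(runif(length(fc)) < truth@missingRate,
                          nrow(fc))] <- NA_real_
            fc
        })
    })
    names(tables) <- paste0("D", seq_len(nDonors))
    MeasurementSet(tables)
}

#' Emit a synthetic Ct table from fold changes
#'
#' Inverse of the delta-delta-Ct computation: each gene gets
#' \code{Ct = baselineCt - log2(fc)} and the reference gene a constant Ct.
#' Because the ddCt method rescales every donor by its calibrator sample,
#' \code{\link{deltaDeltaCt}} on the result reproduces
#' \code{fc / fc[calibrator]} per donor — which equals the input fold
#' changes exactly (to floating-point accuracy) whenever the calibrator
#' column of the input is 1, as in noise-free emitted data.
#'
#' @param ms a \linkS4class{MeasurementSet}.
#' @param baselineCt named numeric baseline Ct per gene, or a single value
#'   recycled (default 24).
#' @param refCt constant Ct of the reference gene (default 20).
#' @param referenceGene name of the reference gene row (default "REF").
#' @return list with \code{ct} (matrix genes+reference x samples) and
#'   \code{sampleInfo} (data.frame sample, donor, condition).
#' @export
emitCt <- function(ms, baselineCt = 24, refCt = 20, referenceGene = "REF") {
    fc <- assay(ms, "fc")
    genes <- rownames(fc)
    if (length(baselineCt) == 1L)
        baselineCt <- setNames(rep(baselineCt, length(genes)), genes)
    ct <- baselineCt[genes] - log2(fc)
    ct <- rbind(ct, matrix(refCt, 1L, ncol(fc),
                           dimnames = list(referenceGene, colnames(fc))))
    list(ct = ct,
         sampleInfo = data.frame(sample = colnames(fc),
                                 donor = colData(ms)$donor,
                                 condition = colData(ms)$condition,
                                 stringsAsFactors = FALSE))
}
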