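fastCtrl <- function(...) pipelineControl("fast", nBoot = 5L,
                                          nResample = 10L, ...)

test_that("preprocessing z-scores features and stores a reusable scaler", {
    coh <- smallCohort(seed = 2, nPairs = 0)
    prep <- preprocessFeatures(coh$se)
    expect_equal(unname(colMeans(prep$features)),
                 rep(0, ncol(prep$features)), tolerance = 1e-12)
    expect_equal(unname(apply(prep$features, 2, sd)),
                 rep(1, ncol(prep$features)), tolerance = 1e-12)
    ## reapplying the stored scaler reproduces the table
    m <- log2(SummarizedExperiment::assay(coh$se, "rpkm") + 1)
    z <- (m[colnames(prep$features), ] - prep$scaler$mean) /
        prep$scaler$sd
    expect_equal(t(z), prep$features)
    ## constant gene dropped with a warning
    m2 <- toyMatrix(1, 3, 5)
    m2["g02", ] <- c(1, 2, 3, 4, 5)
    m2["g03", ] <- c(5, 1, 4, 2, 3)
    expect_warning(p2 <- preprocessFeatures(m2), "g01")
    expect_identical(colnames(p2$features), c("g02", "g03"))
})

test_that("correlated pruning drops the lower-expressed pair member", {
    ## duplicated gene: r = 1, lower mean goes
    f <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
               c = c(2, -1, 3, -4, 1))
    keep <- pruneCorrelated(f, c(a = 6, b = 5, c = 4))
    expect_identical(keep, c("a", "c"))
    ## nothing correlated: unchanged
    set.seed(4)
    g <- matrix(rnorm(50 * 4), 50, 4,
                dimnames = list(NULL, letters[1:4]))
    expect_identical(pruneCorrelated(g, setNames(1:4, letters[1:4])),
                     letters[1:4])
    ## chain A~B~C: first pass drops B (lower mean than A), then A~C is
    ## evaluated if still above threshold
    set.seed(5)
    base <- rnorm(200)
    chain <- cbind(A = base + rnorm(200, 0, 0.2),
                   B = base + rnorm(200, 0, 0.2),
                   C = base + rnorm(200, 0, 0.45))
    means <- c(A = 7, B = 5, C = 6)
    keep <- pruneCorrelated(chain, means)
    expect_false("B" %in% keep)
    expect_true("A" %in% keep)
    rAC <- cor(chain[, "A"], chain[, "C"])
    expect_identical("C" %in% keep, rAC < 0.8)
})

test_that("weighted linear SVM matches the independent QP solution", {
    skip_if_not_installed("kernlab")
    set.seed(12)
    for (i in 1:5) {
        X <- matrix(rnorm(12), 6, 2)
        y <- rep(c("responder", "resistant"), 3)
        cR <- sample(c(0.5, 2, 10), 1); cP <- sample(c(0.5, 2, 10), 1)
        fit <- trainWeightedLinearSvm(X, y, cR, cP)
        ref <- qpReferenceSvm(X, y, cR, cP)
        expect_equal(c(unname(fit$w), fit$b), c(ref$w, ref$b),
                     tolerance = 1e-3)
    }
    ## 1-D analytic max-margin case
    f <- trainWeightedLinearSvm(matrix(c(-1, 1), ncol = 1),
                                c("resistant", "responder"), 100, 100)
    expect_equal(unname(f$w), 1, tolerance = 1e-6)
    expect_equal(f$b, 0, tolerance = 1e-6)
    expect_error(trainWeightedLinearSvm(matrix(1:2, ncol = 1),
                                        c("responder", "responder"), 1, 1),
                 "both classes")
})

test_that("duplicating samples at halved costs keeps the solution", {
    set.seed(31)
    X <- matrix(rnorm(16), 8, 2)
    y <- rep(c("responder", "resistant"), 4)
    f1 <- trainWeightedLinearSvm(X, y, 2, 4)
    f2 <- trainWeightedLinearSvm(rbind(X, X), c(y, y), 1, 2)
    expect_equal(f2$w, f1$w, tolerance = 1e-4)
    expect_equal(f2$b, f1$b, tolerance = 1e-4)
})

test_that("raising the responder cost moves the boundary", {
    ## overlapping 1-D classes: higher responder cost must not lower the
    ## decision boundary's responder coverage
    set.seed(7)
    x <- matrix(c(rnorm(20, -0.5), rnorm(20, 0.5)), ncol = 1)
    y <- rep(c("resistant", "responder"), each = 20)
    fLow <- trainWeightedLinearSvm(x, y, 1, 0.1)
    fHigh <- trainWeightedLinearSvm(x, y, 1, 5)
    predLow <- sum(drop(x %*% fLow$w + fLow$b) > 0)
    predHigh <- sum(drop(x %*% fHigh$w + fHigh$b) > 0)
    expect_gte(predHigh, predLow)
})

test_that("cost tuning returns the argmax with deterministic ties", {
    coh <- smallCohort(seed = 3, nResp = 8, nResis = 10, nGenes = 30,
                       nInf = 4, nPairs = 0)
    prep <- preprocessFeatures(coh$se)
    y <- coh$truth$labels
    grid1 <- data.frame(cResis = 0.2, cResp = 0.4)
    t1 <- tuneCosts(prep$features, y, grid1, nBoot = 5, seed = 2)
    expect_equal(c(t1$cResis, t1$cResp), c(0.2, 0.4))
    grid <- expand.grid(cResis = c(0.1, 1), cResp = c(0.1, 1))
    t2 <- tuneCosts(prep$features, y, grid, nBoot = 10, seed = 2)
    t3 <- tuneCosts(prep$features, y, grid, nBoot = 10, seed = 2)
    expect_identical(t2$grid, t3$grid)    # seeded determinism
    expect_equal(t2$meanF1, max(t2$grid$meanF1))
})

test_that("RFE ranks informative features on top and is reproducible", {
    ## 3 informative + 7 noise features at a 3-sd effect
    nOk <- 0
    for (s in 1:5) {
        set.seed(s)
        n <- 48
        y <- rep(c("responder", "resistant"), c(14, 34))
        X <- matrix(rnorm(n * 10), n, 10,
                    dimnames = list(NULL, sprintf("f%02d", 1:10)))
        X[y == "responder", 1:3] <- X[y == "responder", 1:3] + 3
        rk <- svmRfeRank(X, y, fastCtrl(), seed = s)
        if (all(sprintf("f%02d", 1:3) %in% rk$genes[1:3])) nOk <- nOk + 1
    }
    expect_gte(nOk, 4)
    set.seed(1)
    X1 <- matrix(rnorm(20 * 6), 20, 6,
                 dimnames = list(NULL, sprintf("g%d", 1:6)))
    y1 <- rep(c("responder", "resistant"), each = 10)
    r1 <- svmRfeRank(X1, y1, fastCtrl(), seed = 9)
    r2 <- svmRfeRank(X1, y1, fastCtrl(), seed = 9)
    expect_identical(r1, r2)
    ## single feature: trivial ranking
    rs <- svmRfeRank(X1[, 1, drop = FALSE], y1, fastCtrl(), seed = 1)
    expect_identical(rs$genes, colnames(X1[, 1, drop = FALSE]))
})

test_that("the F1-then-sensitivity rule picks the stated candidate", {
    cand <- data.frame(cResis = c(1, 1, 1, 1), cResp = c(1, 1, 1, 1),
                       k = c(8, 12, 16, 20),
                       f1 = c(0.90, 0.89, 0.88, 0.80),
                       sensitivity = c(0.70, 0.85, 0.80, 0.99),
                       specificity = 1)
    win <- PreclinRx:::.pickCandidate(cand, topM = 3)
    expect_equal(win$f1, 0.89)      # highest sensitivity in the top 3
    ## all metrics equal: smallest k wins
    candEq <- transform(cand, f1 = 0.9, sensitivity = 0.8)
    expect_equal(PreclinRx:::.pickCandidate(candEq, 3)$k, 8)
})

test_that("model selection refits the winner on all data", {
    coh <- smallCohort(seed = 5, nResp = 8, nResis = 10, nGenes = 40,
                       nInf = 5, nPairs = 0)
    prep <- preprocessFeatures(coh$se)
    y <- coh$truth$labels
    ctrl <- fastCtrl(costValues = c(0.1, 1))
    rk <- svmRfeRank(prep$features, y, ctrl, seed = 2)
    sel <- selectModel(rk, prep$features, y, ctrl,
                       candidateSizes = c(5, 10), seed = 3)
    expect_true(sel$candidate$k %in% c(5, 10))
    expect_length(sel$fit$w, sel$candidate$k)
    expect_error(selectModel(rk, prep$features, y, ctrl,
                             candidateSizes = 1000, seed = 1),
                 "candidate sizes")
})

test_that("prediction applies the scaler, errors on missing genes", {
    coh <- smallCohort(seed = 8, nResp = 7, nResis = 9, nGenes = 40,
                       nInf = 5, nPairs = 0)
    res <- trainResponseClassifier(coh$se, coh$truth$labels,
                                   control = fastCtrl(candidateSizes =
                                                          c(5, 10)),
                                   seed = 4)
    pred <- predictResponse(res$model, coh$se)
    ## separable training cohort reproduces its own labels
    expect_identical(pred$label, unname(coh$truth$labels))
    ## missing model gene is named in the error
    m <- SummarizedExperiment::assay(coh$se, "rpkm")
    g1 <- signatureGenes(res$model)[1]
    expect_error(predictResponse(res$model, m[setdiff(rownames(m), g1), ]),
                 g1)
    ## a sample at the scaler means with b = 0 ties to resistant
    model0 <- res$model
    model0@b <- 0
    mid <- matrix(2^model0@scalerMean - 1, ncol = 1,
                  dimnames = list(signatureGenes(model0), "mid"))
    p0 <- predictResponse(model0, mid)
    expect_equal(p0$decision, 0)
    expect_identical(p0$label, "resistant")
})

test_that("external z-scoring removes global location/scale shifts", {
    coh <- smallCohort(seed = 9, nResp = 7, nResis = 9, nGenes = 40,
                       nInf = 5, nPairs = 0)
    res <- trainResponseClassifier(coh$se, coh$truth$labels,
                                   control = fastCtrl(candidateSizes =
                                                          c(5, 10)),
                                   seed = 4)
    m <- SummarizedExperiment::assay(coh$se, "rpkm")
    shifted <- 2^(log2(m + 1) + 2) - 1     # global +2 log2 batch offset
    pBase <- predictResponse(res$model, m, mode = "external")
    pShift <- predictResponse(res$model, shifted, mode = "external")
    expect_identical(pBase$label, pShift$label)
    expect_equal(pBase$decision, pShift$decision, tolerance = 1e-9)
})

test_that("mutation-status predictor passes the full truth table", {
    mk <- function(gene, pc) data.frame(model_id = "s", gene = gene,
                                        protein_change = pc)
    cases <- list(
        list(mk("KRAS", "G12D"), "resistant", "resistant"),
        list(mk("KRAS", "G13C"), "resistant", "resistant"),
        list(mk("KRAS", "Q61H"), "responder", "resistant"),
        list(mk("KRAS", "A146T"), "responder", "resistant"),
        list(mk("NRAS", "G12S"), "responder", "resistant"),
        list(mk("NRAS", "Q22K"), "responder", "resistant"),
        list(mk("NRAS", "Q61R"), "responder", "resistant"),
        list(mk("BRAF", "V600E"), "responder", "resistant"),
        list(mk("BRAF", "G466V"), "responder", "responder"),
        list(mk("KRAS", "G60D"), "responder", "responder"))
    for (cs in cases) {
        expect_identical(
            unname(mutationStatusPredictor(cs[[1]], "s",
                                           "kras_codon12_13")), cs[[2]])
        expect_identical(
            unname(mutationStatusPredictor(cs[[1]], "s", "all_ras_raf")),
            cs[[3]])
    }
    ## wild type everywhere
    none <- data.frame(model_id = character(), gene = character(),
                       protein_change = character())
    expect_identical(unname(mutationStatusPredictor(none, c("a", "b"))),
                     c("responder", "responder"))
    ## unparseable call warns and counts as wild type
    expect_warning(
        p <- mutationStatusPredictor(mk("KRAS", "?fs*12"), "s",
                                     "all_ras_raf"),
        "unparseable")
    expect_identical(unname(p), "responder")
})

test_that("the full pipeline is bit-reproducible under one master seed", {
    coh <- smallCohort(seed = 10, nResp = 6, nResis = 8, nGenes = 30,
                       nInf = 4, nPairs = 1)
    ctrl <- fastCtrl(candidateSizes = c(4, 8))
    r1 <- trainResponseClassifier(coh$se, coh$truth$labels,
                                  control = ctrl, seed = 11)
    r2 <- trainResponseClassifier(coh$se, coh$truth$labels,
                                  control = ctrl, seed = 11)
    expect_equal(r1$model, r2$model)
    expect_identical(r1$ranking, r2$ranking)
})
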