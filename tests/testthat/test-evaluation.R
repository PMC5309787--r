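test_that("confusion metrics match the arithmetic definitions", {
    ## tp=13 fn=1 tn=30 fp=4
    yT <- c(rep(TRUE, 14), rep(FALSE, 34))
    yP <- c(rep(TRUE, 13), FALSE, rep(FALSE, 30), rep(TRUE, 4))
    r <- confusionAndMetrics(yT, yP)
    expect_equal(c(r@tp, r@fp, r@tn, r@fn), c(13, 4, 30, 1))
    expect_equal(round(sensitivity(r), 3), 0.929)
    expect_equal(round(specificity(r), 3), 0.882)
    expect_equal(round(balancedAccuracy(r), 3), 0.905)
    ## perfect prediction
    p <- confusionAndMetrics(yT, yT)
    expect_equal(c(sensitivity(p), specificity(p), balancedAccuracy(p)),
                 c(1, 1, 1))
    ## all-responder prediction zeroes specificity
    a <- confusionAndMetrics(yT, rep(TRUE, 48))
    expect_equal(specificity(a), 0)
    ## undefined metrics are NA, not 0
    u <- confusionAndMetrics(rep(FALSE, 5), rep(FALSE, 5))
    expect_true(is.na(sensitivity(u)))
    expect_true(is.na(f1score(u)))
    expect_error(confusionAndMetrics(yT, yP[-1]), "length mismatch")
})

test_that("metric identities hold over random confusion tables", {
    set.seed(99)
    for (i in 1:200) {
        n <- sample(4:60, 1)
        yT <- runif(n) < runif(1, 0.2, 0.8)
        yP <- runif(n) < runif(1, 0.2, 0.8)
        if (!any(yT) || all(yT)) next
        r <- confusionAndMetrics(yT, yP)
        expect_equal(balancedAccuracy(r),
                     (sensitivity(r) + specificity(r)) / 2)
        expect_equal(f1score(r),
                     2 * r@tp / (2 * r@tp + r@fp + r@fn))
        expect_equal(r@tp + r@fp + r@tn + r@fn, n)
        ## permutation of sample order leaves everything unchanged
        o <- sample(n)
        r2 <- confusionAndMetrics(yT[o], yP[o])
        expect_equal(r2, r)
    }
})

test_that("repeated CV averages per-repeat metrics and is seeded", {
    coh <- smallCohort(seed = 13, nResp = 8, nResis = 10, nGenes = 30,
                       nInf = 4, nPairs = 0)
    lab <- coh$truth$labels
    ## degenerate constant trainer: sensitivity 1, specificity 0
    constTrainer <- function(xTr, yTr) function(xTe) rep(TRUE, ncol(xTe))
    r <- repeatedCrossValidation(coh$se, lab, constTrainer, folds = 4,
                                 repeats = 3, seed = 2)
    expect_equal(sensitivity(r), 1)
    expect_equal(specificity(r), 0)
    ## clearly separable cohort with a simple refit trainer scores high
    sep <- smallCohort(seed = 13, nResp = 10, nResis = 10, nGenes = 30,
                       nInf = 5, effect = 3, nPairs = 0)
    sepTrainer <- svmFixedTrainer(1, 1,
                                  genes = sep$truth$informativeGenes)
    r2 <- repeatedCrossValidation(sep$se, sep$truth$labels, sepTrainer,
                                  folds = 5, repeats = 5, seed = 3)
    expect_gte(balancedAccuracy(r2), 0.95)
    r3 <- repeatedCrossValidation(sep$se, sep$truth$labels, sepTrainer,
                                  folds = 5, repeats = 5, seed = 3)
    expect_equal(r2, r3)
    ## fold reduction warning and class-size guard
    expect_warning(repeatedCrossValidation(coh$se, lab,
                                           svmFixedTrainer(1, 1),
                                           folds = 20, repeats = 1,
                                           seed = 1), "reducing folds")
    one <- c("responder", rep("resistant", 17))
    expect_error(repeatedCrossValidation(coh$se, one,
                                         svmFixedTrainer(1, 1)),
                 "class has < 2")
})

test_that("CV on pure-noise features stays at chance (no leakage)", {
    bas <- vapply(1:5, function(s) {
        cfg <- syntheticConfig(nResponders = 30, nResistant = 30,
                               nGenes = 100, nInformative = 0,
                               effectLog2fc = 0, nCorrPairs = 0, seed = s)
        res <- generateExpressionMatrix(cfg)
        r <- repeatedCrossValidation(res$se, res$truth$labels,
                                     svmFixedTrainer(1, 1), folds = 10,
                                     repeats = 10, seed = s)
        balancedAccuracy(r)
    }, numeric(1))
    expect_true(all(bas >= 0.35 & bas <= 0.65))
})

test_that("external validation z-scores per cohort and applies policies", {
    coh <- smallCohort(seed = 14, nResp = 7, nResis = 9, nGenes = 40,
                       nInf = 5, nPairs = 0)
    res <- trainResponseClassifier(
        coh$se, coh$truth$labels,
        control = pipelineControl("fast", nBoot = 5, nResample = 10,
                                  candidateSizes = c(5, 10)), seed = 4)
    m <- SummarizedExperiment::assay(coh$se, "rpkm")
    lab <- coh$truth$labels
    recist <- setNames(ifelse(lab == "responder", "PR", "PD"),
                       colnames(m))
    recist[names(recist)[lab == "resistant"][1:2]] <- "SD"
    cohort <- list(expression = m, response = recist,
                   mutations = coh$mutations)
    rInc <- externalValidation(res$model, cohort,
                               sdPolicy = "include_as_nonresponder")
    rExc <- externalValidation(res$model, cohort, sdPolicy = "exclude")
    expect_equal(rExc@nExcluded, 2)
    expect_equal(rExc@tp + rExc@fp + rExc@tn + rExc@fn + rExc@nExcluded,
                 ncol(m))
    expect_equal(rInc@tp + rInc@fp + rInc@tn + rInc@fn, ncol(m))
    ## a global batch shift does not change external-mode predictions
    shifted <- 2^(log2(m + 1) + 2) - 1
    rShift <- externalValidation(res$model,
                                 list(expression = shifted,
                                      response = recist),
                                 sdPolicy = "exclude")
    expect_equal(rShift@tp, rExc@tp)
    expect_equal(rShift@fn, rExc@fn)
    ## gene mapping below 80% aborts with the unmapped genes named
    k <- length(signatureGenes(res$model))
    dropN <- ceiling(0.3 * k)
    m2 <- m[setdiff(rownames(m),
                    signatureGenes(res$model)[seq_len(dropN)]), ]
    expect_error(externalValidation(res$model,
                                    list(expression = m2,
                                         response = recist)),
                 "validation error")
})

test_that("mutation strata restrict evaluation to wild-type samples", {
    coh <- generateCohort(syntheticConfig(nResponders = 6, nResistant = 8,
                                          nGenes = 40, nInformative = 5,
                                          nCorrPairs = 0, seed = 15),
                          responseLink = "mixed")
    res <- trainResponseClassifier(
        coh$se, coh$truth$labels,
        control = pipelineControl("fast", nBoot = 5, nResample = 10,
                                  candidateSizes = c(5, 10)), seed = 4)
    m <- SummarizedExperiment::assay(coh$se, "rpkm")
    lab <- coh$truth$labels
    recist <- setNames(ifelse(lab == "responder", "PR", "PD"),
                       colnames(m))
    cohort <- list(expression = m, response = recist,
                   mutations = coh$mutations)
    rAll <- externalValidation(res$model, cohort)
    rWt <- externalValidation(res$model, cohort, stratum = "all_ras_raf_wt")
    nMut <- length(unique(coh$mutations$model_id))
    expect_equal(rWt@nExcluded, nMut)
    expect_equal(rWt@tp + rWt@fp + rWt@tn + rWt@fn, ncol(m) - nMut)
    expect_identical(rWt@stratum, "all_ras_raf_wt")
    expect_equal(rAll@tp + rAll@fp + rAll@tn + rAll@fn, ncol(m))
})

test_that("predictor comparison reports deltas and guards sample sets", {
    yT <- c(rep(TRUE, 10), rep(FALSE, 20))
    r1 <- confusionAndMetrics(yT, c(rep(TRUE, 9), FALSE,
                                    rep(FALSE, 16), rep(TRUE, 4)))
    r2 <- confusionAndMetrics(yT, c(rep(TRUE, 10),
                                    rep(FALSE, 8), rep(TRUE, 12)))
    cmp <- comparePredictors(r1, r2)
    expect_equal(cmp$delta[cmp$metric == "sensitivity"],
                 sensitivity(r1) - sensitivity(r2))
    cmp0 <- comparePredictors(r1, r1)
    expect_equal(cmp0$delta, rep(0, 3))
    r3 <- confusionAndMetrics(yT[-1], c(rep(TRUE, 9),
                                        rep(FALSE, 16), rep(TRUE, 4)))
    expect_error(comparePredictors(r1, r3), "different sample sets")
})
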