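test_that("qad matches the enumeration oracle and its invariances", {
    ## deviations of 1:5 from median 3 are {0,1,1,2,2}; interpolated P75 = 2
    expect_equal(qad(1:5), 2)
    expect_equal(qad(rep(4, 10)), 0)
    x <- c(0.3, 2.5, 7, 1, 1, 9)
    expect_equal(qad(x + 10), qad(x))          # translation invariant
    expect_equal(qad(3 * x), 3 * qad(x))       # scale equivariant
    ## independent oracle: sort |x - median| and interpolate by hand
    dev <- sort(abs(x - median(x)))
    h <- (length(dev) - 1) * 0.75 + 1
    expected <- dev[floor(h)] + (h - floor(h)) * (dev[ceiling(h)] -
                                                  dev[floor(h)])
    expect_equal(qad(x), expected)
    expect_error(qad(1), "finite values")
})

test_that("variable-gene selection applies floor and dual QAD ranking", {
    m <- toyMatrix(0, 4, 8)
    m["g01", ] <- 0.4                       # under the 0.5 RPKM floor
    m["g02", ] <- 5                         # expressed but constant
    m["g03", ] <- c(1, 9, 2, 8, 1, 9, 2, 8) # variable
    m["g04", ] <- c(4, 5, 4, 5, 4, 5, 4, 5) # mildly variable
    sel <- selectVariableGenes(m, topFraction = 0.34)
    expect_false("g01" %in% sel)
    expect_true("g03" %in% sel)
    expect_false("g02" %in% sel)
})

test_that("expression filter enforces detection and mean thresholds", {
    m <- toyMatrix(0, 3, 10)
    m["g01", 1:5] <- 1.2; m["g01", 6:10] <- 0.6   # 5 detected, mean 0.9
    m["g02", 1:4] <- 1.2                          # only 4 detected
    m["g03", 1:3] <- 50                           # PDO case: 3 detected
    expect_true("g01" %in% expressionFilter(m, "PDX"))
    expect_false("g02" %in% expressionFilter(m, "PDX"))
    expect_true("g03" %in% expressionFilter(m, "PDO"))
    expect_false("g03" %in% expressionFilter(m, "PDX"))
})

test_that("differential expression nulls behave and power is adequate", {
    set.seed(21)
    ## identical groups: fold changes 0, p near 1
    m <- toyMatrix(rexp(20 * 8, 0.2), 20, 8)
    m2 <- cbind(m, m)
    colnames(m2) <- sprintf("s%02d", 1:16)
    de <- differentialExpression(m2, colnames(m2)[1:8], colnames(m2)[9:16])
    expect_equal(de$log2fc, rep(0, 20))
    expect_true(all(de$p > 0.99))
    expect_error(differentialExpression(m2, colnames(m2)[1:8],
                                        colnames(m2)[8:16]), "overlap")
    ## welch result agrees with stats::t.test per gene
    cohA <- toyMatrix(rexp(10 * 12, 0.1), 10, 12)
    deW <- differentialExpression(cohA, colnames(cohA)[1:6],
                                  colnames(cohA)[7:12])
    pRef <- apply(log2(cohA + 1), 1, function(v)
        t.test(v[1:6], v[7:12])$p.value)
    expect_equal(deW$p, unname(pRef), tolerance = 1e-12)
    ## planted effect: detected at FDR <= 0.01 and |log2fc| >= 1
    hits <- 0
    for (s in 1:5) {
        res <- generateExpressionMatrix(syntheticConfig(
            nResponders = 20, nResistant = 20, nGenes = 200,
            nInformative = 1, effectLog2fc = 2, noiseSd = 1,
            nCorrPairs = 0, seed = s))
        lab <- res$truth$labels
        de <- differentialExpression(res$se,
                                     names(lab)[lab == "responder"],
                                     names(lab)[lab == "resistant"])
        row <- de[de$gene == res$truth$informativeGenes, ]
        if (row$fdr <= 0.01 && abs(row$log2fc) >= 1) hits <- hits + 1
    }
    expect_gte(hits, 4)
})

test_that("fdr adjustment is Benjamini-Hochberg", {
    m <- toyMatrix(rexp(50 * 10, 0.2), 50, 10)
    de <- differentialExpression(m, colnames(m)[1:5], colnames(m)[6:10])
    expect_equal(de$fdr, p.adjust(de$p, "BH"))
    expect_true(all(de$fdr <= 1))
})

test_that("phenotype regression flags perfect fits and controls the null", {
    set.seed(8)
    m <- toyMatrix(runif(40 * 12, 0, 4), 40, 12)
    ph <- setNames(rnorm(12, 50, 20), colnames(m))
    ## plant an exact affine relationship on the log2 scale
    m["g01", ] <- 2^(0.01 * ph + 1) - 1
    ga <- glmAssociation(m, ph)
    expect_identical(ga$gene[which.min(ga$p)], "g01")
    expect_error(glmAssociation(m, setNames(rep(1, 12), colnames(m))),
                 "constant phenotype")
    ## permutation null: about 5% of genes at p < 0.05
    fr <- replicate(10, {
        g2 <- glmAssociation(m[-1, ], sample(ph))
        mean(g2$p < 0.05)
    })
    expect_lt(abs(mean(fr) - 0.05), 0.05)
    ## high-dispersion genes are excluded
    m2 <- m
    m2["g02", ] <- c(rep(0, 6), rep(400, 6))    # var/mean >> 4
    expect_false("g02" %in% glmAssociation(m2, ph)$gene)
})

test_that("signature assembly unions setups, filters and orders genes", {
    coh <- smallCohort(seed = 6, nResp = 20, nResis = 20, nGenes = 80,
                       nInf = 4, nPairs = 0)
    lab <- coh$truth$labels
    de <- differentialExpression(coh$se, names(lab)[lab == "responder"],
                                 names(lab)[lab == "resistant"])
    tc <- setNames(coh$response$tc_percent, coh$response$model_id)
    ga <- glmAssociation(coh$se, tc)
    sig <- assembleSignature(list(a = de, d = ga), coh$se,
                             modelSystem = "PDX", drug = "dx")
    expect_s4_class(sig, "GeneSignature")
    expect_true(all(coh$truth$informativeGenes %in% signatureGenes(sig)))
    expect_true(all(lengths(sig@provenance) >= 1))
    ## invariant to the order in which setups are supplied
    sig2 <- assembleSignature(list(d = ga, a = de), coh$se,
                              modelSystem = "PDX", drug = "dx")
    expect_identical(signatureGenes(sig), signatureGenes(sig2))
    ## low-expressed significant genes are removed by the filter
    expect_true(all(signatureGenes(sig) %in%
                    expressionFilter(coh$se, "PDX")))
})

test_that("mean pattern matrix matches hand computation", {
    m <- toyMatrix(rexp(5 * 3, 0.2), 5, 3)
    z <- t(scale(t(log2(m + 1))))
    mp <- meanPatternMatrix(m, list(sig1 = rownames(m)[1:5],
                                    single = "g03"), trim = 0)
    expect_equal(mp[, "sig1"], colMeans(z), ignore_attr = TRUE)
    expect_equal(mp[, "single"], z["g03", ], ignore_attr = TRUE)
    ## duplicated gene in a signature does not change the column
    mp2 <- meanPatternMatrix(m, list(sig1 = c(rownames(m)[1:5], "g01")),
                             trim = 0)
    expect_equal(mp2[, "sig1"], mp[, "sig1"])
    ## reference-cohort mode reuses stored statistics
    ref <- list(mean = setNames(rowMeans(log2(m + 1)), rownames(m)),
                sd = setNames(apply(log2(m + 1), 1, sd), rownames(m)))
    mp3 <- meanPatternMatrix(m, list(sig1 = rownames(m)[1:5]), trim = 0,
                             referenceStats = ref)
    expect_equal(mp3[, "sig1"], mp[, "sig1"])
})

test_that("pair ranking score is a signed geometric mean with sign rule", {
    x <- c(g1 = 8, g2 = 1, g3 = 3)
    expect_equal(pairRankingScore(x, x)$score, rep(0, 3))
    r1 <- pairRankingScore(c(g1 = 8), c(g1 = 1))
    f <- log2(8.1 / 1.1); d <- log2(9) - log2(2)
    expect_equal(r1$score, sqrt(f * d))
    ## swapping the two profiles negates every score
    r <- pairRankingScore(c(g1 = 8, g2 = 1), c(g1 = 1, g2 = 8))
    expect_equal(r$score[r$gene == "g1"], -r$score[r$gene == "g2"])
})
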