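## Drug-response gene-signature discovery: QAD variable-gene selection,
## expression filters, two-group and phenotype-regression differential
## expression (setups a-d), signature assembly, mean-pattern matrices and
## the PDX/PDO pair ranking score.

#' Quantile absolute deviation (QAD)
#'
#' Robust variability measure: the 75th percentile (linear-interpolation
#' quantile) of the absolute deviations from the median,
#' \eqn{QAD = P_{75}(|x_i - median(x)|)}. Translation-invariant and
#' scale-equivariant.
#'
#' @param values numeric vector with >= 2 finite values.
#' @return Nonnegative scalar; 0 for constant input.
#' @examples
#' qad(1:5)  # 2
#' @export
qad <- function(values) {
    v <- values[is.finite(values)]
    if (length(v) < 2L) stop("qad needs >= 2 finite values")
    unname(stats::quantile(abs(v - stats::median(v)), 0.75, type = 7))
}

#' Select the most variable genes by QAD on raw and log2 scale
#'
#' Genes must pass an expression floor (value > `expressionFloor` RPKM in
#' more than `minSamples` samples) and rank in the top fraction by QAD on
#' both the raw RPKM and the log2(RPKM+1) scale (intersection of the two
#' rankings). Alternatively an absolute number of genes can be requested.
#'
#' @param x SummarizedExperiment (assay "rpkm") or RPKM matrix.
#' @param expressionFloor RPKM floor (default 0.5).
#' @param minSamples the floor must be exceeded in more than this many
#'   samples (default 3).
#' @param topFraction fraction of floor-passing genes kept per ranking.
#' @param nTop absolute number kept per ranking (overrides `topFraction`).
#' @return Character vector of selected gene ids.
#' @examples
#' res <- generateExpressionMatrix(syntheticConfig(nResponders = 10,
#'     nResistant = 10, nGenes = 60, nInformative = 0, nCorrPairs = 0))
#' head(selectVariableGenes(res$se, topFraction = 0.5))
#' @export
selectVariableGenes <- function(x, expressionFloor = 0.5, minSamples = 3L,
                                topFraction = 0.2, nTop = NULL) {
    m <- .rpkm(x)
    pass <- rowSums(m > expressionFloor) > minSamples
    m <- m[pass, , drop = FALSE]
    if (!nrow(m)) {
        warning("no genes pass the expression floor")
        return(character())
    }
    qRaw <- apply(m, 1, qad)
    qLog <- apply(.log2p1(m), 1, qad)
    k <- if (!is.null(nTop)) min(nTop, nrow(m))
         else max(1L, ceiling(topFraction * nrow(m)))
    topRaw <- names(sort(qRaw, decreasing = TRUE))[seq_len(k)]
    topLog <- names(sort(qLog, decreasing = TRUE))[seq_len(k)]
    sel <- intersect(topRaw, topLog)
    if (!length(sel)) warning("variable-gene selection is empty")
    sel
}

#' Low-expression filter for signature genes
#'
#' Keeps genes expressed at >= `minRpkm` in at least `minDetected` samples
#' (5 for PDX, 3 for PDO by default) and with mean expression >=
#' `minMean` RPKM.
#'
#' @param x SummarizedExperiment or RPKM matrix.
#' @param modelSystem "PDX" or "PDO" (sets the default `minDetected`).
#' @param minRpkm detection threshold (RPKM).
#' @param minMean minimum mean RPKM.
#' @param minDetected override for the detection sample count.
#' @return Character vector of genes passing the filter.
#' @export
expressionFilter <- function(x, modelSystem = c("PDX", "PDO"), minRpkm = 1,
                             minMean = 0.8, minDetected = NULL) {
    modelSystem <- match.arg(modelSystem)
    m <- .rpkm(x)
    if (is.null(minDetected))
        minDetected <- if (modelSystem == "PDX") 5L else 3L
    keep <- rowSums(m >= minRpkm) >= minDetected & rowMeans(m) >= minMean
    rownames(m)[keep]
}

## vectorised Welch t-test on rows of a matrix (log2 scale)
.welchRows <- function(logm, ia, ib) {
    na <- length(ia); nb <- length(ib)
    ma <- rowMeans(logm[, ia, drop = FALSE])
    mb <- rowMeans(logm[, ib, drop = FALSE])
    va <- apply(logm[, ia, drop = FALSE], 1, stats::var)
    vb <- apply(logm[, ib, drop = FALSE], 1, stats::var)
    se2 <- va / na + vb / nb
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), df)
    p[!is.finite(t)] <- 1          # constant genes carry no evidence
    p
}

#' Two-group differential expression for signature setups a-c
#'
#' Computes per-gene log2 fold change with a pseudocount
#' (`log2((meanA + eps)/(meanB + eps))`, eps = 0.1 RPKM), the absolute
#' difference of RPKM group means, a p-value from a pluggable two-group
#' test on log2(RPKM+1) (default: Welch t), and Benjamini-Hochberg FDR
#' across tested genes.
#'
#' @param x SummarizedExperiment or RPKM matrix.
#' @param groupA,groupB disjoint sample-id sets, each >= 2 samples.
#' @param test either "welch" or a function(valuesA, valuesB) returning a
#'   p-value, applied per gene to log2(RPKM+1) values.
#' @param pseudocount RPKM pseudocount for fold changes.
#' @return data.frame (one row per gene): gene, log2fc, mean_diff, p, fdr,
#'   dispersion (per-gene RPKM variance/mean).
#' @examples
#' res <- generateExpressionMatrix(syntheticConfig(nResponders = 6,
#'     nResistant = 6, nGenes = 50, nInformative = 5, nCorrPairs = 0))
#' lab <- res$truth$labels
#' de <- differentialExpression(res$se, names(lab)[lab == "responder"],
#'                              names(lab)[lab == "resistant"])
#' @export
differentialExpression <- function(x, groupA, groupB, test = "welch",
                                   pseudocount = 0.1) {
    m <- .rpkm(x)
    if (length(intersect(groupA, groupB)))
        stop("design error: groups overlap")
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("design error: each group needs >= 2 samples")
    missing <- setdiff(c(groupA, groupB), colnames(m))
    if (length(missing))
        stop("samples not in matrix: ", paste(missing, collapse = ", "))
    ia <- match(groupA, colnames(m)); ib <- match(groupB, colnames(m))
    ma <- rowMeans(m[, ia, drop = FALSE])
    mb <- rowMeans(m[, ib, drop = FALSE])
    log2fc <- log2((ma + pseudocount) / (mb + pseudocount))
    meanDiff <- abs(ma - mb)
    logm <- .log2p1(m)
    if (identical(test, "welch")) {
        p <- .welchRows(logm, ia, ib)
    } else if (is.function(test)) {
        p <- vapply(seq_len(nrow(m)), function(i)
            test(logm[i, ia], logm[i, ib]), numeric(1))
    } else stop("'test' must be \"welch\" or a function")
    rm_ <- rowMeans(m)
    disp <- ifelse(rm_ > 0, apply(m, 1, stats::var) / rm_, 0)
    data.frame(gene = rownames(m), log2fc = log2fc, mean_diff = meanDiff,
               p = p, fdr = stats::p.adjust(p, "BH"), dispersion = disp,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Phenotype-regression association for signature setup d
#'
#' Regresses each gene's log2(RPKM+1) values on a continuous phenotype
#' (IC50 or T/C) by least squares and tests the slope (t-test). Genes with
#' RPKM dispersion (variance/mean) >= `dispersionMax` are excluded from
#' the result.
#'
#' @param x SummarizedExperiment or RPKM matrix.
#' @param phenotype named (or matrix-ordered) numeric per-sample value.
#' @param dispersionMax dispersion exclusion threshold (default 4).
#' @return data.frame as in [differentialExpression()] (log2fc is the
#'   regression slope per phenotype unit, mean_diff the fitted range).
#' @export
glmAssociation <- function(x, phenotype, dispersionMax = 4) {
    m <- .rpkm(x)
    if (!is.null(names(phenotype)))
        phenotype <- phenotype[colnames(m)]
    if (length(phenotype) != ncol(m) || any(!is.finite(phenotype)))
        stop("phenotype must be finite for every sample")
    if (ncol(m) < 5L) stop("need >= 5 samples")
    if (stats::var(phenotype) == 0)
        stop("design error: constant phenotype")
    logm <- .log2p1(m)
    ph <- phenotype - mean(phenotype)
    sxx <- sum(ph^2)
    slope <- as.vector(logm %*% ph) / sxx
    fitted <- outer(slope, ph)
    resid <- logm - rowMeans(logm) - fitted
    df <- ncol(m) - 2L
    s2 <- rowSums(resid^2) / df
    seSlope <- sqrt(s2 / sxx)
    t <- slope / seSlope
    p <- 2 * stats::pt(-abs(t), df)
    p[!is.finite(t)] <- 1
    rm_ <- rowMeans(m)
    disp <- ifelse(rm_ > 0, apply(m, 1, stats::var) / rm_, 0)
    keep <- disp < dispersionMax & is.finite(t)
    data.frame(gene = rownames(m), log2fc = slope,
               mean_diff = apply(fitted, 1, function(z) diff(range(z))),
               p = p, fdr = stats::p.adjust(p, "BH"),
               dispersion = disp, row.names = NULL,
               stringsAsFactors = FALSE)[keep, ]
}

#' Assemble a drug-response gene signature from setups a-d
#'
#' Takes the union of genes passing each setup's filters (two-group setups
#' a-c: FDR <= `maxFdr`, |log2FC| >= `minLog2fc`, RPKM group-mean
#' difference >= `minMeanDiff`; phenotype setup d: FDR <= `maxFdr` and
#' dispersion < 4, applied in [glmAssociation()]), intersects it with the
#' low-expression filter, and records per-gene provenance. Gene order is
#' deterministic: descending best |log2fc| across setups, ties by gene id.
#'
#' @param setupResults named list of data.frames from
#'   [differentialExpression()] / [glmAssociation()]; names from
#'   c("a","b","c","d") mark which filter applies ("d" uses the FDR-only
#'   rule).
#' @param x SummarizedExperiment or RPKM matrix (for the expression filter).
#' @param modelSystem "PDX" or "PDO".
#' @param drug drug name stored in the signature.
#' @param maxFdr,minLog2fc,minMeanDiff filter thresholds for setups a-c.
#' @return A [GeneSignature-class].
#' @export
assembleSignature <- function(setupResults, x, modelSystem = "PDX",
                              drug = NA_character_, maxFdr = 0.01,
                              minLog2fc = 1, minMeanDiff = 1) {
    if (!length(setupResults)) stop("at least one setup result is required")
    if (is.null(names(setupResults)))
        names(setupResults) <- letters[seq_along(setupResults)]
    expressed <- expressionFilter(x, modelSystem)
    hits <- list(); bestFc <- numeric(0)
    for (s in names(setupResults)) {
        r <- setupResults[[s]]
        sel <- if (identical(s, "d"))
            r$fdr <= maxFdr
        else
            r$fdr <= maxFdr & abs(r$log2fc) >= minLog2fc &
                r$mean_diff >= minMeanDiff
        sel[is.na(sel)] <- FALSE
        for (g in r$gene[sel]) {
            hits[[g]] <- union(hits[[g]], s)
            fc <- abs(r$log2fc[r$gene == g][1])
            bestFc[g] <- max(bestFc[g], fc, na.rm = TRUE)
        }
    }
    genes <- intersect(names(hits), expressed)
    if (!length(genes)) {
        warning("signature is empty after filtering")
        return(methods::new("GeneSignature", drug = drug,
                            modelSystem = modelSystem))
    }
    ord <- order(-bestFc[genes], genes)
    genes <- genes[ord]
    methods::new("GeneSignature", drug = drug, modelSystem = modelSystem,
                 genes = genes,
                 provenance = stats::setNames(lapply(genes, function(g)
                     sort(hits[[g]])), genes))
}

#' Mean-pattern matrix of signatures across samples
#'
#' Per gene: log2(RPKM+1), then z-score across samples (or with stored
#' reference means/sds); per (sample, signature): trimmed mean over the
#' signature's genes present in the matrix (duplicates deduplicated).
#'
#' @param x SummarizedExperiment or RPKM matrix.
#' @param signatures named list of gene-id vectors (or
#'   [GeneSignature-class] objects).
#' @param trim trimmed-mean fraction (default 0.25).
#' @param referenceStats optional list(mean=, sd=) of named per-gene
#'   statistics from a reference cohort, reused instead of the cohort's own.
#' @return samples x signatures numeric matrix.
#' @export
meanPatternMatrix <- function(x, signatures, trim = 0.25,
                              referenceStats = NULL) {
    m <- .log2p1(.rpkm(x))
    if (is.null(referenceStats)) {
        mu <- rowMeans(m)
        sdv <- apply(m, 1, stats::sd)
    } else {
        mu <- referenceStats$mean[rownames(m)]
        sdv <- referenceStats$sd[rownames(m)]
    }
    sdv[!is.finite(sdv) | sdv == 0] <- NA
    z <- (m - mu) / sdv
    sigGenes <- lapply(signatures, function(s) {
        g <- if (methods::is(s, "GeneSignature")) signatureGenes(s) else s
        unique(g)
    })
    out <- sapply(sigGenes, function(g) {
        g2 <- intersect(g, rownames(z))
        if (!length(g2)) {
            warning("signature with no matching genes")
            return(rep(NA_real_, ncol(z)))
        }
        apply(z[g2, , drop = FALSE], 2, mean, trim = trim, na.rm = TRUE)
    })
    out <- matrix(out, nrow = ncol(z),
                  dimnames = list(colnames(z), names(sigGenes)))
    out
}

#' Pairwise PDX/PDO ranking score
#'
#' For each gene, with `f` the pseudocounted log2 fold change between the
#' PDX and PDO profile and `d` their difference on log2(RPKM+1) scale, the
#' score is the signed geometric mean `sign(f) * sqrt(|f| * |d|)` when `f`
#' and `d` agree in sign, and 0 otherwise. The result is a complete
#' descending ranking usable as pre-ranked enrichment input.
#'
#' @param pdxExpr,pdoExpr named per-gene RPKM vectors over the same genes.
#' @param pseudocount RPKM pseudocount for the fold change.
#' @param rule "zero_discordant" (default) or "signed_product" (keeps
#'   discordant genes with the sign of `f`).
#' @return data.frame (gene, score) sorted by descending score.
#' @examples
#' pairRankingScore(c(g1 = 8, g2 = 1), c(g1 = 1, g2 = 8))
#' @export
pairRankingScore <- function(pdxExpr, pdoExpr, pseudocount = 0.1,
                             rule = c("zero_discordant", "signed_product")) {
    rule <- match.arg(rule)
    if (!identical(names(pdxExpr), names(pdoExpr)))
        pdoExpr <- pdoExpr[names(pdxExpr)]
    if (any(is.na(pdoExpr))) stop("profiles must cover the same genes")
    f <- log2((pdxExpr + pseudocount) / (pdoExpr + pseudocount))
    d <- .log2p1(pdxExpr) - .log2p1(pdoExpr)
    r <- sign(f) * sqrt(abs(f) * abs(d))
    if (rule == "zero_discordant")
        r[sign(f) != sign(d)] <- 0
    out <- data.frame(gene = names(pdxExpr), score = unname(r),
                      stringsAsFactors = FALSE)
    out[order(-out$score, out$gene), , drop = FALSE]
}
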