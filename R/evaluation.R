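## Predictor performance: confusion metrics, repeated stratified k-fold
## cross-validation with in-fold refitting of every trained step,
## external-cohort validation (per-cohort z-scoring, RECIST truth mapping,
## SD policies, mutation strata) and classifier-vs-mutation comparison.

#' Confusion counts and derived performance metrics
#'
#' The responder class is positive. Undefined metrics (e.g. sensitivity
#' with no true responders) are NA, never silently 0.
#'
#' @param yTrue,yPred logical responder flags (equal length) or
#'   "responder"/"resistant" character vectors.
#' @param stratum label recorded in the report.
#' @param nExcluded samples excluded before evaluation.
#' @return A [PerformanceReport-class].
#' @examples
#' confusionAndMetrics(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusionAndMetrics <- function(yTrue, yPred, stratum = "all",
                                nExcluded = 0) {
    toLogical <- function(v)
        if (is.logical(v)) v else as.character(v) == "responder"
    yTrue <- toLogical(yTrue); yPred <- toLogical(yPred)
    if (length(yTrue) != length(yPred))
        stop("data error: prediction/truth length mismatch")
    if (!length(yTrue)) stop("data error: nothing to evaluate")
    tp <- sum(yTrue & yPred); fp <- sum(!yTrue & yPred)
    tn <- sum(!yTrue & !yPred); fn <- sum(yTrue & !yPred)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    ba <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
          else NA_real_
    methods::new("PerformanceReport", tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 balancedAccuracy = ba, f1 = f1,
                 nExcluded = as.numeric(nExcluded), stratum = stratum)
}

## stratified fold assignment: within each class, shuffled samples are
## dealt round-robin over folds
.stratFolds <- function(y, folds) {
    fold <- integer(length(y))
    for (cls in unique(y)) {
        i <- which(y == cls)
        i <- i[sample.int(length(i))]
        fold[i] <- rep_len(seq_len(folds), length(i))
    }
    fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Every trained step lives inside the `trainer`, which is refit from
#' scratch on each training fold -- nothing (scaling, pruning, tuning,
#' feature ranking, selection) leaks from test to training data. Per
#' repeat, test-fold predictions are pooled into one confusion table;
#' metric values (not counts) are then averaged over repeats.
#'
#' @param x SummarizedExperiment or RPKM matrix (genes x samples).
#' @param labels per-sample "responder"/"resistant" (or logical).
#' @param trainer function(xTrain, yTrain) returning a prediction function
#'   f(xTest) -> logical responder flags (xTrain/xTest are genes x samples
#'   RPKM matrices). See [svmPipelineTrainer()].
#' @param folds number of folds (reduced with a warning when a class has
#'   fewer members).
#' @param repeats number of repetitions.
#' @param seed integer seed.
#' @return Averaged [PerformanceReport-class] (counts are per-repeat
#'   means).
#' @export
repeatedCrossValidation <- function(x, labels, trainer, folds = 10L,
                                    repeats = 100L, seed = 1L) {
    m <- .rpkm(x)
    y <- .asLabels(labels, colnames(m))
    minClass <- min(table(y))
    if (minClass < 2L) stop("design error: a class has < 2 members")
    if (minClass < folds) {
        warning("reducing folds from ", folds, " to ", minClass)
        folds <- minClass
    }
    withSeed(seed, {
        mets <- matrix(NA_real_, repeats, 8,
                       dimnames = list(NULL, c("tp", "fp", "tn", "fn",
                                               "sens", "spec", "ba", "f1")))
        for (r in seq_len(repeats)) {
            fold <- .stratFolds(y, folds)
            pred <- logical(length(y))
            for (k in seq_len(folds)) {
                te <- which(fold == k); tr <- which(fold != k)
                predictFun <- trainer(m[, tr, drop = FALSE], y[tr])
                pred[te] <- predictFun(m[, te, drop = FALSE])
            }
            rep_ <- confusionAndMetrics(y == "responder", pred)
            mets[r, ] <- c(rep_@tp, rep_@fp, rep_@tn, rep_@fn,
                           rep_@sensitivity, rep_@specificity,
                           rep_@balancedAccuracy, rep_@f1)
        }
    })
    avg <- colMeans(mets, na.rm = TRUE)
    methods::new("PerformanceReport", tp = avg["tp"], fp = avg["fp"],
                 tn = avg["tn"], fn = avg["fn"],
                 sensitivity = unname(avg["sens"]),
                 specificity = unname(avg["spec"]),
                 balancedAccuracy = unname((avg["sens"] + avg["spec"]) / 2),
                 f1 = unname(avg["f1"]), stratum = "cv")
}

#' Trainer wrapping the full classifier pipeline for cross-validation
#'
#' Returns a trainer (for [repeatedCrossValidation()]) that reruns
#' [trainResponseClassifier()] -- preprocessing, pruning, SVM-RFE, model
#' selection -- on each training fold and predicts held-out samples with
#' the fold's own scaler.
#'
#' @param control a [pipelineControl()]; use the "fast" preset (or
#'   smaller) inside cross-validation, where the pipeline is refit in
#'   every fold.
#' @param genes optional starting gene panel.
#' @param seed seed forwarded to each fold's pipeline run.
#' @return A trainer function.
#' @export
svmPipelineTrainer <- function(control = pipelineControl("fast"),
                               genes = NULL, seed = 1L) {
    force(control); force(genes); force(seed)
    function(xTrain, yTrain) {
        res <- trainResponseClassifier(xTrain, yTrain, genes = genes,
                                       control = control, seed = seed)
        function(xTest)
            predictResponse(res$model, xTest)$label == "responder"
    }
}

#' Trainer fitting a fixed-cost SVM on all supplied genes
#'
#' A lightweight trainer (z-scoring plus one class-weighted linear SVM,
#' both refit per fold) for baselines and permutation controls.
#'
#' @param cResis,cResp per-class costs.
#' @param genes optional gene subset.
#' @return A trainer function for [repeatedCrossValidation()].
#' @export
svmFixedTrainer <- function(cResis = 1, cResp = 1, genes = NULL) {
    force(cResis); force(cResp); force(genes)
    function(xTrain, yTrain) {
        prep <- preprocessFeatures(xTrain, genes)
        fit <- trainWeightedLinearSvm(prep$features, yTrain, cResis, cResp)
        scaler <- prep$scaler
        function(xTest) {
            lm_ <- .log2p1(xTest[names(fit$w), , drop = FALSE])
            z <- (lm_ - scaler$mean[names(fit$w)]) /
                scaler$sd[names(fit$w)]
            .decide(t(z), fit$w, fit$b)
        }
    }
}

#' Validate a classifier on an external cohort
#'
#' Applies the mini-classifier to an independent cohort: expression is
#' log2-transformed (unless already) and z-scored within the cohort
#' (per-cohort means and sds replace the training scaler); RECIST-style
#' truth maps CR/PR to responder and PD to non-responder, with SD handled
#' by `sdPolicy`; an optional mutation stratum restricts evaluation to
#' wild-type samples under the corresponding mutation rule. Gene
#' identifiers can be translated with a two-column mapping; prediction
#' proceeds only if at least 80% of model genes map (missing genes are
#' dropped from the decision function and reported).
#'
#' @param model an [SvmClassifier-class].
#' @param cohort list with `expression` (genes x samples matrix or
#'   SummarizedExperiment), `response` (named per-sample "CR"/"PR"/"SD"/
#'   "PD", or a response category convertible via [binarizeResponse()]),
#'   optional `mutations` (data.frame model_id/gene/protein_change) and
#'   `alreadyLog2` flag.
#' @param sdPolicy "include_as_nonresponder" or "exclude".
#' @param stratum "all", "kras_wt" or "all_ras_raf_wt".
#' @param geneMap optional data.frame (columns from, to) translating model
#'   gene ids to cohort identifiers.
#' @param minMapped minimum fraction of model genes that must map.
#' @return A [PerformanceReport-class] with `nExcluded` set.
#' @export
externalValidation <- function(model, cohort,
                               sdPolicy = c("include_as_nonresponder",
                                            "exclude"),
                               stratum = c("all", "kras_wt",
                                           "all_ras_raf_wt"),
                               geneMap = NULL, minMapped = 0.8) {
    sdPolicy <- match.arg(sdPolicy)
    stratum <- match.arg(stratum)
    m <- .rpkm(cohort$expression)
    genes <- model@genes
    if (!is.null(geneMap)) {
        idx <- match(genes, geneMap$from)
        mapped <- ifelse(is.na(idx), NA_character_, geneMap$to[idx])
    } else mapped <- genes
    present <- !is.na(mapped) & mapped %in% rownames(m)
    if (mean(present) < minMapped)
        stop("validation error: only ", sum(present), "/", length(genes),
             " model genes map to the cohort; unmapped: ",
             paste(genes[!present], collapse = ", "))
    lm_ <- if (isTRUE(cohort$alreadyLog2))
        m[mapped[present], , drop = FALSE]
    else .log2p1(m[mapped[present], , drop = FALSE])
    mu <- rowMeans(lm_); sdv <- apply(lm_, 1, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    z <- (lm_ - mu) / sdv
    w <- model@w[present]
    dv <- drop(crossprod(z, w)) + model@b
    predResp <- dv > 0
    names(predResp) <- colnames(m)

    resp <- cohort$response
    if (is.null(names(resp)) && length(resp) == ncol(m))
        names(resp) <- colnames(m)
    resp <- resp[colnames(m)]
    if (any(is.na(resp)))
        stop("response must be present for every evaluated sample")
    keep <- rep(TRUE, ncol(m))
    nExcluded <- 0L
    if (all(resp %in% c("CR", "PR", "SD", "PD"))) {
        if (sdPolicy == "exclude") {
            nExcluded <- sum(resp == "SD")
            keep <- resp != "SD"
        }
        truth <- resp %in% c("CR", "PR")
    } else {
        truth <- binarizeResponse(resp)
    }
    if (stratum != "all") {
        mode <- if (stratum == "kras_wt") "kras_codon12_13"
                else "all_ras_raf"
        muts <- cohort$mutations
        if (is.null(muts)) stop("stratum filtering needs mutation calls")
        status <- mutationStatusPredictor(muts, colnames(m), mode)
        wt <- status == "responder"
        nExcluded <- nExcluded + sum(keep & !wt)
        keep <- keep & wt
    }
    if (!any(keep)) {
        warning("no samples left to evaluate after exclusions")
        return(methods::new("PerformanceReport", nExcluded = nExcluded,
                            stratum = stratum))
    }
    confusionAndMetrics(truth[keep], predResp[keep], stratum = stratum,
                        nExcluded = nExcluded)
}

#' Side-by-side comparison of two predictors
#'
#' Descriptive comparison (no significance testing) of sensitivity,
#' specificity and balanced accuracy, typically classifier versus
#' mutation status, with deltas (first minus second).
#'
#' @param classifierReport,mutationReport [PerformanceReport-class]
#'   objects over the same evaluated sample set.
#' @return data.frame with rows sensitivity/specificity/balancedAccuracy
#'   and columns classifier, mutation, delta.
#' @export
comparePredictors <- function(classifierReport, mutationReport) {
    nOf <- function(r) r@tp + r@fp + r@tn + r@fn
    if (!isTRUE(all.equal(nOf(classifierReport), nOf(mutationReport))))
        stop("design error: reports cover different sample sets")
    met <- function(r) c(sensitivity = r@sensitivity,
                         specificity = r@specificity,
                         balancedAccuracy = r@balancedAccuracy)
    a <- met(classifierReport); b <- met(mutationReport)
    data.frame(metric = names(a), classifier = unname(a),
               mutation = unname(b), delta = unname(a - b),
               stringsAsFactors = FALSE)
}
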