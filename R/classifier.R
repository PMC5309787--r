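## The mini-classifier: feature preprocessing, correlated-gene pruning,
## class-weighted linear SVM with per-class cost tuning, SVM-RFE with
## resampled weight ranking, feature-size selection and the
## mutation-status comparator.

#' Control parameters for the classifier pipeline
#'
#' Bundles the search settings of cost tuning, SVM-RFE and model
#' selection. The default cost grid covers the span in which the tuned
#' per-class costs of the reference classifiers fall (0.05/0.3 and
#' 0.007/0.02); the "5fu" preset extends it with 0.007 and selects among
#' the top eleven F1 candidates, the "cetuximab" preset among the top
#' three. The "fast" preset shrinks the grid and resampling for use inside
#' cross-validation folds, where the whole pipeline is refit many times.
#'
#' @param preset "cetuximab", "5fu" or "fast".
#' @param costValues cost values per class (Cartesian grid).
#' @param nBoot stratified bootstrap iterations for cost tuning.
#' @param nResample stratified leave-n-out iterations for weight ranking.
#' @param leaveOutFraction fraction of each class left out per resample.
#' @param candidateSizes feature sizes evaluated in model selection
#'   (NULL = a default ladder capped at the feature count).
#' @param topM model selection picks the highest-sensitivity candidate
#'   among the top `topM` by F1.
#' @param pruneThreshold,pruneIterations correlated-gene pruning settings.
#' @param elimFraction,elimThreshold RFE drops the bottom `elimFraction`
#'   of features while more than `elimThreshold` remain, else one at a
#'   time.
#' @return A list of class "PipelineControl".
#' @export
pipelineControl <- function(preset = c("cetuximab", "5fu", "fast"),
                            costValues = NULL, nBoot = NULL,
                            nResample = NULL, leaveOutFraction = 0.2,
                            candidateSizes = NULL, topM = NULL,
                            pruneThreshold = 0.8, pruneIterations = 2L,
                            elimFraction = 0.1, elimThreshold = 50L) {
    preset <- match.arg(preset)
    base <- c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.5,
              1, 2, 5)
    if (is.null(costValues))
        costValues <- switch(preset,
            cetuximab = base,
            "5fu" = sort(c(base, 0.007)),
            fast = c(0.01, 0.1, 1))
    if (is.null(nBoot)) nBoot <- if (preset == "fast") 10L else 100L
    if (is.null(nResample)) nResample <- if (preset == "fast") 20L else 200L
    if (is.null(topM)) topM <- if (preset == "5fu") 11L else 3L
    grid <- expand.grid(cResis = costValues, cResp = costValues,
                        KEEP.OUT.ATTRS = FALSE)
    structure(list(preset = preset, grid = grid, nBoot = nBoot,
                   nResample = nResample,
                   leaveOutFraction = leaveOutFraction,
                   candidateSizes = candidateSizes, topM = topM,
                   pruneThreshold = pruneThreshold,
                   pruneIterations = as.integer(pruneIterations),
                   elimFraction = elimFraction,
                   elimThreshold = as.integer(elimThreshold)),
              class = "PipelineControl")
}

#' Log2 + z-score feature preprocessing
#'
#' Transforms RPKM to log2(RPKM+1) and z-scores each gene across the
#' (training) samples; the per-gene means and sds are stored for reuse on
#' new cohorts. Zero-variance genes are dropped with a warning.
#'
#' @param x SummarizedExperiment or RPKM matrix (genes x samples).
#' @param genes genes to use (default: all).
#' @return list with `features` (samples x genes z-scored matrix),
#'   `scaler` (list of named `mean`, `sd` vectors), `log2Means` (pre-scaling
#'   log2 means, used by pruning) and `dropped` (zero-variance genes).
#' @export
preprocessFeatures <- function(x, genes = NULL) {
    m <- .rpkm(x)
    if (is.null(genes)) genes <- rownames(m)
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
        stop("genes not in matrix: ", paste(missing, collapse = ", "))
    if (ncol(m) < 2L) stop("need >= 2 samples")
    lm_ <- .log2p1(m[genes, , drop = FALSE])
    mu <- rowMeans(lm_)
    sdv <- apply(lm_, 1, stats::sd)
    dropped <- genes[sdv == 0 | !is.finite(sdv)]
    if (length(dropped))
        warning("dropping zero-variance genes: ",
                paste(dropped, collapse = ", "))
    keep <- setdiff(genes, dropped)
    lm_ <- lm_[keep, , drop = FALSE]
    z <- (lm_ - mu[keep]) / sdv[keep]
    list(features = t(z),
         scaler = list(mean = mu[keep], sd = sdv[keep]),
         log2Means = mu[keep], dropped = dropped)
}

#' Prune the lower-expressed member of highly correlated gene pairs
#'
#' Per iteration, gene pairs with Pearson correlation at or above the
#' threshold are visited in descending correlation order (ties broken by
#' gene id); for each pair whose members are both still present, the
#' member with the lower mean expression (pre-scaling log2 mean) is
#' dropped. The procedure is repeated for the stated number of iterations
#' and is fully deterministic.
#'
#' @param features samples x genes matrix.
#' @param log2Means named per-gene pre-scaling log2 mean expression.
#' @param threshold correlation threshold (default 0.8).
#' @param iterations number of pruning passes (default 2).
#' @return Character vector of retained gene ids (input order).
#' @export
pruneCorrelated <- function(features, log2Means, threshold = 0.8,
                            iterations = 2L) {
    genes <- colnames(features)
    if (length(genes) < 2L) return(genes)
    keep <- genes
    for (it in seq_len(iterations)) {
        if (length(keep) < 2L) break
        cm <- stats::cor(features[, keep, drop = FALSE])
        cm[!is.finite(cm)] <- 0
        ut <- which(upper.tri(cm) & cm >= threshold, arr.ind = TRUE)
        if (!nrow(ut)) break
        pairs <- data.frame(a = keep[ut[, 1]], b = keep[ut[, 2]],
                            r = cm[ut], stringsAsFactors = FALSE)
        pairs <- pairs[order(-pairs$r, pairs$a, pairs$b), ]
        alive <- stats::setNames(rep(TRUE, length(keep)), keep)
        for (i in seq_len(nrow(pairs))) {
            a <- pairs$a[i]; b <- pairs$b[i]
            if (alive[a] && alive[b]) {
                ma <- log2Means[a]; mb <- log2Means[b]
                drop <- if (ma < mb) a
                        else if (mb < ma) b
                        else max(a, b)   # tie: drop the later id
                alive[drop] <- FALSE
            }
        }
        keep <- keep[alive[keep]]
    }
    genes[genes %in% keep]
}

#' Train a class-weighted linear SVM
#'
#' Solves the soft-margin linear SVM minimising
#' \eqn{\frac12\|w\|^2 + \sum_i C_{class(i)}\,\xi_i} with per-class costs
#' (resistant: `cResis`, responder: `cResp`), via the libsvm solver. The
#' returned orientation is normalised so that a positive decision value
#' `w . x + b` predicts the responder class.
#'
#' @param X samples x features numeric matrix.
#' @param y character/factor labels, values "responder"/"resistant".
#' @param cResis,cResp per-class misclassification costs (> 0).
#' @return list with `w` (named weights), `b` (bias) and `genes`.
#' @examples
#' X <- matrix(c(-1, 1), ncol = 1)
#' y <- c("resistant", "responder")
#' trainWeightedLinearSvm(X, y, 100, 100)  # w = 1, b = 0
#' @export
trainWeightedLinearSvm <- function(X, y, cResis, cResp) {
    y <- as.character(y)
    if (length(unique(y)) < 2L)
        stop("training error: both classes must be present")
    if (cResis <= 0 || cResp <= 0) stop("costs must be > 0")
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
    yf <- factor(y, levels = c("resistant", "responder"))
    fit <- e1071::svm(X, yf, type = "C-classification", kernel = "linear",
                      cost = 1,
                      class.weights = c(resistant = cResis,
                                        responder = cResp),
                      scale = FALSE, tolerance = 1e-6)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    ## libsvm's decision value is positive for the first training label;
    ## normalise so positive => responder
    firstLabel <- y[!duplicated(y)][1]
    if (firstLabel == "resistant") { w <- -w; b <- -b }
    names(w) <- colnames(X)
    list(w = w, b = b, genes = colnames(X))
}

## F1 with responder as the positive class; NA when no predicted or true
## positives exist at all
.f1 <- function(truePos, predPos) {
    tp <- sum(truePos & predPos)
    fp <- sum(!truePos & predPos)
    fn <- sum(truePos & !predPos)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
}

.decide <- function(X, w, b) drop(X %*% w + b) > 0

## draw a stratified bootstrap (in-bag indices + out-of-bag indices),
## redrawing (bounded) until the out-of-bag set contains both classes
.stratBootstrap <- function(y, maxRetry = 20L) {
    idx <- seq_along(y)
    for (try in seq_len(maxRetry)) {
        inbag <- unlist(lapply(split(idx, y), function(i)
            i[sample.int(length(i), length(i), replace = TRUE)]))
        oob <- setdiff(idx, inbag)
        if (length(unique(y[oob])) == 2L)
            return(list(inbag = inbag, oob = oob))
    }
    stop("could not draw a bootstrap with both classes out of bag")
}

## stratified leave-n-out split: keep (1 - frac) of each class for training
.stratLeaveOut <- function(y, frac) {
    idx <- seq_along(y)
    train <- unlist(lapply(split(idx, y), function(i) {
        nOut <- max(1L, floor(frac * length(i)))
        nOut <- min(nOut, length(i) - 1L)   # keep at least one per class
        if (nOut < 1L) return(i)
        i[-sample.int(length(i), nOut)]
    }))
    sort(train)
}

#' Tune per-class SVM costs by stratified bootstrap
#'
#' For every cost pair on the grid, trains the class-weighted SVM on
#' stratified bootstrap in-bag samples and scores the F1 (responder
#' positive) on the out-of-bag samples; the pair with the highest mean F1
#' wins (ties: smaller total cost, then lexicographic).
#'
#' @param X samples x features matrix.
#' @param y labels ("responder"/"resistant"), both classes >= 2 samples.
#' @param grid data.frame with columns cResis, cResp.
#' @param nBoot bootstrap iterations per grid point.
#' @param seed integer seed.
#' @return list with `cResis`, `cResp`, `meanF1` and the scored `grid`.
#' @export
tuneCosts <- function(X, y, grid, nBoot = 100L, seed = 1L) {
    if (!nrow(grid)) stop("cost grid is empty")
    y <- as.character(y)
    if (min(table(y)) < 2L) stop("both classes need >= 2 samples")
    X <- as.matrix(X)
    withSeed(seed, {
        boots <- lapply(seq_len(nBoot), function(i) .stratBootstrap(y))
        f1s <- vapply(seq_len(nrow(grid)), function(gi) {
            vals <- vapply(boots, function(bs) {
                fit <- trainWeightedLinearSvm(X[bs$inbag, , drop = FALSE],
                                              y[bs$inbag],
                                              grid$cResis[gi],
                                              grid$cResp[gi])
                pred <- .decide(X[bs$oob, , drop = FALSE], fit$w, fit$b)
                .f1(y[bs$oob] == "responder", pred)
            }, numeric(1))
            mean(vals, na.rm = TRUE)
        }, numeric(1))
    })
    scored <- cbind(grid, meanF1 = f1s)
    ord <- order(-scored$meanF1, scored$cResis + scored$cResp,
                 scored$cResis, scored$cResp)
    best <- scored[ord[1], ]
    list(cResis = best$cResis, cResp = best$cResp, meanF1 = best$meanF1,
         grid = scored)
}

#' SVM recursive feature elimination with resampled weight ranking
#'
#' Adapted SVM-RFE: in each recursive step the per-class costs are tuned
#' by stratified bootstrap ([tuneCosts()]); the class-weighted SVM is then
#' fit on stratified leave-n-out training subsets and each remaining
#' feature is scored as the mean of |w| over the resamples (the ranking
#' uses the weight vector w itself, not w^2); the lowest-scoring features
#' are eliminated (the bottom `elimFraction` while more than
#' `elimThreshold` features remain, else one at a time). The elimination
#' order defines the ranking; the whole procedure is seeded.
#'
#' @param X samples x features matrix.
#' @param y labels ("responder"/"resistant").
#' @param control a [pipelineControl()] object.
#' @param seed integer seed.
#' @return list with `genes` (top-ranked first, i.e. last eliminated),
#'   `score` (each feature's mean |w| at its elimination step) and
#'   `steps` (number of recursive steps).
#' @export
svmRfeRank <- function(X, y, control = pipelineControl("fast"), seed = 1L) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
    y <- as.character(y)
    if (ncol(X) < 1L) stop("need >= 1 feature")
    if (length(unique(y)) < 2L) stop("both classes must be present")
    if (ncol(X) == 1L)
        return(list(genes = colnames(X), score = stats::setNames(NA_real_,
               colnames(X)), steps = 0L))
    eliminated <- character(); elimScore <- numeric()
    current <- colnames(X)
    withSeed(seed, {
        step <- 0L
        while (length(current) > 1L) {
            step <- step + 1L
            seeds <- .subSeeds(2L)
            tuned <- tuneCosts(X[, current, drop = FALSE], y,
                               control$grid, control$nBoot, seeds[1])
            wsum <- stats::setNames(numeric(length(current)), current)
            withSeed(seeds[2], {
                for (r in seq_len(control$nResample)) {
                    tr <- .stratLeaveOut(y, control$leaveOutFraction)
                    fit <- trainWeightedLinearSvm(
                        X[tr, current, drop = FALSE], y[tr],
                        tuned$cResis, tuned$cResp)
                    wsum <- wsum + abs(fit$w)
                }
            })
            score <- wsum / control$nResample
            nDrop <- if (length(current) > control$elimThreshold)
                max(1L, floor(control$elimFraction * length(current)))
            else 1L
            ord <- order(score, names(score))   # worst first, ties by id
            drop <- names(score)[ord[seq_len(nDrop)]]
            eliminated <- c(eliminated, drop)
            elimScore <- c(elimScore, score[drop])
            current <- setdiff(current, drop)
        }
    })
    genes <- c(current, rev(eliminated))
    score <- stats::setNames(rep(NA_real_, length(genes)), genes)
    score[names(elimScore)] <- elimScore
    list(genes = genes, score = score, steps = length(eliminated))
}

#' Feature-size and cost selection with the F1-then-sensitivity rule
#'
#' Evaluates every (cost pair, feature size) candidate by resampled F1 and
#' sensitivity of the SVM trained on the top-k ranked features, ranks the
#' candidates by F1, and among the top `topM` returns the one with the
#' highest sensitivity (ties: higher F1, then smaller k, then smaller
#' costs). The final model is refit on all training data with the winning
#' configuration.
#'
#' @param ranking result of [svmRfeRank()] (or a ranked gene vector).
#' @param X samples x features matrix (over all ranked genes).
#' @param y labels.
#' @param control a [pipelineControl()]; its grid and `topM` are used, and
#'   resampled metrics use `nResample`/2 stratified leave-n-out draws.
#' @param candidateSizes feature sizes to evaluate (default: control's, or
#'   a ladder 4, 8, 12, ... capped at the feature count).
#' @param seed integer seed.
#' @return list with `candidate` (chosen cResis/cResp/k/f1/sensitivity/
#'   specificity), `fit` (w, b over the chosen genes), `genes` and the full
#'   `candidates` table.
#' @export
selectModel <- function(ranking, X, y, control = pipelineControl("fast"),
                        candidateSizes = NULL, seed = 1L) {
    genes <- if (is.list(ranking)) ranking$genes else ranking
    X <- as.matrix(X)
    y <- as.character(y)
    if (is.null(candidateSizes)) candidateSizes <- control$candidateSizes
    if (is.null(candidateSizes))
        candidateSizes <- unique(pmin(c(8L, 12L, 16L, 20L, 24L),
                                      length(genes)))
    candidateSizes <- sort(unique(as.integer(candidateSizes)))
    if (!length(candidateSizes) || any(candidateSizes < 1L) ||
        any(candidateSizes > length(genes)))
        stop("design error: candidate sizes must lie in [1, #ranked genes]")
    grid <- control$grid
    nRes <- max(10L, control$nResample %/% 2L)
    truePosAll <- y == "responder"
    withSeed(seed, {
        splits <- lapply(seq_len(nRes), function(i)
            .stratLeaveOut(y, control$leaveOutFraction))
        rows <- list()
        for (k in candidateSizes) {
            gk <- genes[seq_len(k)]
            for (gi in seq_len(nrow(grid))) {
                f1v <- sens <- spec <- numeric(nRes)
                for (r in seq_len(nRes)) {
                    tr <- splits[[r]]; te <- setdiff(seq_along(y), tr)
                    fit <- trainWeightedLinearSvm(
                        X[tr, gk, drop = FALSE], y[tr],
                        grid$cResis[gi], grid$cResp[gi])
                    pred <- .decide(X[te, gk, drop = FALSE], fit$w, fit$b)
                    tp <- truePosAll[te]
                    f1v[r] <- .f1(tp, pred)
                    sens[r] <- if (any(tp)) mean(pred[tp]) else NA
                    spec[r] <- if (any(!tp)) mean(!pred[!tp]) else NA
                }
                rows[[length(rows) + 1L]] <- data.frame(
                    cResis = grid$cResis[gi], cResp = grid$cResp[gi],
                    k = k, f1 = mean(f1v, na.rm = TRUE),
                    sensitivity = mean(sens, na.rm = TRUE),
                    specificity = mean(spec, na.rm = TRUE))
            }
        }
    })
    cand <- do.call(rbind, rows)
    win <- .pickCandidate(cand, control$topM)
    gk <- genes[seq_len(win$k)]
    fit <- trainWeightedLinearSvm(X[, gk, drop = FALSE], y,
                                  win$cResis, win$cResp)
    list(candidate = win, fit = fit, genes = gk, candidates = cand)
}

## the F1-then-sensitivity selection rule: rank candidates by F1, take the
## top m, return the one with the highest sensitivity (ties: higher F1,
## then smaller k, then smaller costs)
.pickCandidate <- function(cand, topM) {
    top <- cand[order(-cand$f1, cand$k, cand$cResis + cand$cResp,
                      cand$cResis), ]
    top <- utils::head(top, topM)
    top[order(-top$sensitivity, -top$f1, top$k, top$cResis + top$cResp,
              top$cResis)[1], ]
}

#' Train the full mini-classifier pipeline
#'
#' Runs preprocessing (log2 + z-score), correlated-gene pruning, SVM-RFE
#' with in-step cost tuning, and feature-size selection, then packages the
#' winning configuration as an [SvmClassifier-class] refit on the full
#' training cohort.
#'
#' @param x SummarizedExperiment or RPKM matrix (genes x samples).
#' @param labels per-sample "responder"/"resistant" (named or in column
#'   order); alternatively a logical responder flag.
#' @param genes starting gene panel (e.g. a signature); default all genes.
#' @param control a [pipelineControl()].
#' @param seed master seed for all stochastic stages.
#' @return list with `model` ([SvmClassifier-class]), `ranking`,
#'   `candidate`, `prunedGenes` (genes removed by pruning) and
#'   `candidates`.
#' @export
trainResponseClassifier <- function(x, labels, genes = NULL,
                                    control = pipelineControl("fast"),
                                    seed = 1L) {
    m <- .rpkm(x)
    labels <- .asLabels(labels, colnames(m))
    prep <- preprocessFeatures(m, genes)
    withSeed(seed, seeds <- .subSeeds(2L))
    kept <- pruneCorrelated(prep$features, prep$log2Means,
                            control$pruneThreshold,
                            control$pruneIterations)
    X <- prep$features[, kept, drop = FALSE]
    ranking <- svmRfeRank(X, labels, control, seed = seeds[1])
    sel <- selectModel(ranking, X, labels, control, seed = seeds[2])
    model <- methods::new("SvmClassifier", genes = sel$genes,
                          w = unname(sel$fit$w), b = sel$fit$b,
                          cResis = sel$candidate$cResis,
                          cResp = sel$candidate$cResp,
                          scalerMean = unname(prep$scaler$mean[sel$genes]),
                          scalerSd = unname(prep$scaler$sd[sel$genes]),
                          positiveClass = "responder")
    list(model = model, ranking = ranking, candidate = sel$candidate,
         prunedGenes = setdiff(colnames(prep$features), kept),
         candidates = sel$candidates)
}

## normalise label input to a character vector over the given samples
.asLabels <- function(labels, samples) {
    if (is.logical(labels))
        labels <- ifelse(labels, "responder", "resistant")
    labels <- as.character(labels)
    if (!is.null(names(labels))) {
        miss <- setdiff(samples, names(labels))
        if (length(miss)) stop("labels missing for: ",
                               paste(miss, collapse = ", "))
        labels <- labels[samples]
    } else if (length(labels) != length(samples))
        stop("labels must cover every sample")
    bad <- setdiff(unique(labels), c("responder", "resistant"))
    if (length(bad)) stop("labels must be responder/resistant, got: ",
                          paste(bad, collapse = ", "))
    unname(labels)
}

#' Predict drug response with a trained mini-classifier
#'
#' Internal mode applies the scaler stored at training time; external mode
#' z-scores each gene within the new cohort instead (per-cohort means and
#' sds replace the training scaler). A decision value of exactly 0 is
#' resolved to resistant (conservative for treatment selection).
#'
#' @param model an [SvmClassifier-class].
#' @param x SummarizedExperiment or RPKM matrix containing all model
#'   genes; values are RPKM unless `alreadyLog2 = TRUE`.
#' @param mode "internal" (training scaler) or "external" (per-cohort
#'   z-scoring).
#' @param alreadyLog2 set TRUE when the matrix is already on log2 scale.
#' @return data.frame with sample, decision (margin) and label.
#' @export
predictResponse <- function(model, x, mode = c("internal", "external"),
                            alreadyLog2 = FALSE) {
    mode <- match.arg(mode)
    m <- if (methods::is(x, "SummarizedExperiment") || is.matrix(x))
        .rpkm(x) else stop("x must be a SummarizedExperiment or matrix")
    missing <- setdiff(model@genes, rownames(m))
    if (length(missing))
        stop("prediction error: matrix lacks model genes: ",
             paste(missing, collapse = ", "))
    lm_ <- if (alreadyLog2) m[model@genes, , drop = FALSE]
           else .log2p1(m[model@genes, , drop = FALSE])
    if (mode == "internal") {
        z <- (lm_ - model@scalerMean) / model@scalerSd
    } else {
        mu <- rowMeans(lm_)
        sdv <- apply(lm_, 1, stats::sd)
        sdv[sdv == 0 | !is.finite(sdv)] <- 1
        z <- (lm_ - mu) / sdv
    }
    dv <- drop(crossprod(z, model@w)) + model@b
    data.frame(sample = colnames(m), decision = unname(dv),
               label = ifelse(dv > 0, "responder", "resistant"),
               stringsAsFactors = FALSE)
}

#' Mutation-status response prediction
#'
#' Predicts resistance from RAS/RAF mutation calls: under mode
#' "kras_codon12_13" a sample is called resistant iff it carries a KRAS
#' mutation at codon 12 or 13; under "all_ras_raf" qualifying events are
#' KRAS/NRAS mutations at G12, G13, Q22, Q61 or A146 and BRAF V600E.
#' All other samples are predicted responders. Protein changes that cannot
#' be parsed raise a warning and count as wild type.
#'
#' @param mutations data.frame with columns model_id, gene,
#'   protein_change (e.g. "G12D").
#' @param samples character vector of sample ids to predict for.
#' @param mode "kras_codon12_13" or "all_ras_raf".
#' @return Named character vector ("responder"/"resistant") over `samples`.
#' @examples
#' muts <- data.frame(model_id = "s1", gene = "KRAS",
#'                    protein_change = "G12D")
#' mutationStatusPredictor(muts, c("s1", "s2"))
#' @export
mutationStatusPredictor <- function(mutations, samples,
                                    mode = c("kras_codon12_13",
                                             "all_ras_raf")) {
    mode <- match.arg(mode)
    pred <- stats::setNames(rep("responder", length(samples)), samples)
    if (!nrow(mutations)) return(pred)
    parsed <- regmatches(mutations$protein_change,
                         regexec("^([A-Za-z])([0-9]+)",
                                 mutations$protein_change))
    for (i in seq_len(nrow(mutations))) {
        p <- parsed[[i]]
        if (length(p) < 3L) {
            warning("unparseable protein change '",
                    mutations$protein_change[i], "', treated as wild type")
            next
        }
        ref <- toupper(p[2]); pos <- as.integer(p[3])
        gene <- toupper(mutations$gene[i])
        hit <- if (mode == "kras_codon12_13") {
            gene == "KRAS" && pos %in% c(12L, 13L)
        } else {
            (gene %in% c("KRAS", "NRAS") &&
                 paste0(ref, pos) %in% c("G12", "G13", "Q22", "Q61",
                                         "A146")) ||
            (gene == "BRAF" &&
                 toupper(mutations$protein_change[i]) == "V600E")
        }
        if (hit && mutations$model_id[i] %in% samples)
            pred[mutations$model_id[i]] <- "resistant"
    }
    pred
}
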