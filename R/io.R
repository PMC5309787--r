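## Shared readers/writers and the top-level pipeline driver. Matrices are
## TSV (genes as rows), sample-level tables CSV, models and reports JSON,
## configuration YAML.

#' Read a genes-x-samples RPKM matrix from TSV
#'
#' First column holds gene ids, header row holds sample ids. Duplicate
#' ids, non-numeric cells and negative values are rejected with
#' coordinates.
#'
#' @param path TSV file path.
#' @param annotations optional data.frame of per-sample annotations
#'   (row names = sample ids) attached as colData.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   "rpkm".
#' @export
readExpressionTsv <- function(path, annotations = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    dup <- unique(genes[duplicated(genes)])
    if (length(dup))
        stop("duplicate gene ids: ", paste(dup, collapse = ", "))
    vals <- tab[, -1, drop = FALSE]
    for (j in seq_along(vals)) {
        v <- suppressWarnings(as.numeric(vals[[j]]))
        bad <- which(is.na(v) & !is.na(vals[[j]]))
        if (length(bad))
            stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                         genes[bad[1]], names(vals)[j]))
        if (anyNA(v))
            stop(sprintf("missing value at gene '%s', sample '%s'",
                         genes[which(is.na(v))[1]], names(vals)[j]))
        neg <- which(v < 0)
        if (length(neg))
            stop(sprintf("negative RPKM at gene '%s', sample '%s'",
                         genes[neg[1]], names(vals)[j]))
        vals[[j]] <- v
    }
    m <- as.matrix(vals)
    rownames(m) <- genes
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample ids in header")
    cd <- if (is.null(annotations))
        S4Vectors::DataFrame(row.names = colnames(m))
    else S4Vectors::DataFrame(annotations[colnames(m), , drop = FALSE])
    SummarizedExperiment::SummarizedExperiment(
        assays = list(rpkm = m), colData = cd)
}

#' Write a genes-x-samples RPKM matrix as TSV
#'
#' @param x SummarizedExperiment or matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionTsv <- function(x, path) {
    m <- .rpkm(x)
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a xenograft growth-series CSV
#'
#' Expected columns: model_id, drug, animal_id, arm, day, length_mm,
#' width_mm. Length/width are swap-normalised so length >= width.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
readGrowthCsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    g <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("model_id", "drug", "animal_id", "arm", "day", "length_mm",
              "width_mm")
    miss <- setdiff(need, names(g))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    if (!all(g$arm %in% c("treated", "control")))
        stop("arm must be treated/control")
    if (any(g$length_mm < 0 | g$width_mm < 0, na.rm = TRUE))
        stop("data error: negative calliper measurement")
    l <- pmax(g$length_mm, g$width_mm); w <- pmin(g$length_mm, g$width_mm)
    g$length_mm <- l; g$width_mm <- w
    g
}

#' Write / read a gene signature as plain text plus a JSON sidecar
#'
#' The text file holds one gene id per line (signature order); the
#' sidecar `<path>.json` records drug, model system, provenance and
#' filter settings.
#'
#' @param signature a [GeneSignature-class].
#' @param path output text file path.
#' @param settings optional list of filter settings stored in the sidecar.
#' @return `path`, invisibly.
#' @export
writeSignature <- function(signature, path, settings = list()) {
    writeLines(signature@genes, path)
    side <- list(drug = signature@drug,
                 model_system = signature@modelSystem,
                 provenance = signature@provenance,
                 settings = settings)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
    genes <- readLines(path)
    genes <- genes[nzchar(genes)]
    sidePath <- paste0(path, ".json")
    if (file.exists(sidePath)) {
        side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
        prov <- lapply(side$provenance, as.character)
        if (is.null(names(prov)) || !length(prov))
            prov <- stats::setNames(rep(list("a"), length(genes)), genes)
        methods::new("GeneSignature",
                     drug = side$drug %||% NA_character_,
                     modelSystem = side$model_system %||% NA_character_,
                     genes = genes, provenance = prov[genes])
    } else {
        methods::new("GeneSignature", genes = genes,
                     provenance = stats::setNames(rep(list("a"),
                         length(genes)), genes))
    }
}

#' Serialize / restore a trained mini-classifier as JSON
#'
#' @param model an [SvmClassifier-class].
#' @param path output JSON path.
#' @param metadata optional list (seed, grid, settings) stored alongside.
#' @return `path` invisibly; `readModelJson()` returns the
#'   [SvmClassifier-class].
#' @export
writeModelJson <- function(model, path, metadata = list()) {
    obj <- list(genes = model@genes, w = model@w, b = model@b,
                c_resis = model@cResis, c_resp = model@cResp,
                scaler = list(mean = as.list(stats::setNames(
                                  model@scalerMean, model@genes)),
                              sd = as.list(stats::setNames(
                                  model@scalerSd, model@genes))),
                positive_class = model@positiveClass,
                metadata = metadata)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    methods::new("SvmClassifier", genes = obj$genes, w = obj$w, b = obj$b,
                 cResis = obj$c_resis, cResp = obj$c_resp,
                 scalerMean = unname(unlist(obj$scaler$mean)[obj$genes]),
                 scalerSd = unname(unlist(obj$scaler$sd)[obj$genes]),
                 positiveClass = obj$positive_class)
}

.pipelineDefaults <- function() {
    list(seed = 1L,
         cohort = list(nResponders = 14L, nResistant = 34L, nGenes = 200L,
                       nInformative = 10L, effectLog2fc = 2,
                       nCorrPairs = 5L, corrTarget = 0.9, noiseSd = 1,
                       fracLowExpressed = 0.1,
                       responseLink = "signature"),
         signature = list(maxFdr = 0.01, minLog2fc = 1, minMeanDiff = 1),
         classifier = list(preset = "fast"),
         cv = list(folds = 10L, repeats = 5L))
}

## recursive merge of a user config into defaults; unknown keys rejected
.mergeConfig <- function(defaults, user, path = "") {
    for (k in names(user)) {
        full <- if (nzchar(path)) paste0(path, ".", k) else k
        if (!k %in% names(defaults))
            stop("unknown configuration key: ", full)
        if (is.list(defaults[[k]]) && is.list(user[[k]]))
            defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]], full)
        else defaults[[k]] <- user[[k]]
    }
    defaults
}

#' Run the full synthetic pipeline and write its artifacts
#'
#' Stages: simulate a cohort, derive the drug-response signature (setups
#' a-d), train the mini-classifier on the signature genes, and estimate
#' performance by repeated stratified cross-validation. All outputs plus a
#' manifest (input checksums, seed, settings, package version) are written
#' to `outDir`; rerunning with an identical configuration reproduces
#' identical artifacts.
#'
#' @param config nested list overriding [.pipelineDefaults()] entries
#'   (unknown keys are rejected), or the path of a YAML file with the same
#'   structure.
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with the cohort, signature, classifier
#'   result and cross-validation report.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("pipeline")) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("missing input: ", config)
        config <- yaml::read_yaml(config)
    }
    cfg <- .mergeConfig(.pipelineDefaults(), config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    cohortArgs <- cfg$cohort
    link <- cohortArgs$responseLink
    cohortArgs$responseLink <- NULL
    scfg <- do.call(syntheticConfig, c(cohortArgs, list(seed = cfg$seed)))
    cohort <- generateCohort(scfg, responseLink = link)

    exprPath <- file.path(outDir, "expression.tsv")
    writeExpressionTsv(cohort$se, exprPath)
    utils::write.csv(cohort$response, file.path(outDir, "response.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$mutations, file.path(outDir, "mutations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(cohort$truth, file.path(outDir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    lab <- cohort$truth$labels
    respSamples <- names(lab)[lab == "responder"]
    resisSamples <- names(lab)[lab == "resistant"]
    tc <- stats::setNames(cohort$response$tc_percent,
                          cohort$response$model_id)
    nc <- min(length(respSamples), length(resisSamples),
              ceiling(length(lab) * 0.4))
    mostSens <- names(sort(tc))[seq_len(nc)]
    leastSens <- names(sort(tc, decreasing = TRUE))[seq_len(nc)]
    setups <- list(
        a = differentialExpression(cohort$se, respSamples, resisSamples),
        c = differentialExpression(cohort$se, mostSens, leastSens),
        d = glmAssociation(cohort$se, tc))
    sig <- assembleSignature(setups, cohort$se, modelSystem = "PDX",
                             drug = "synthetic_drug",
                             maxFdr = cfg$signature$maxFdr,
                             minLog2fc = cfg$signature$minLog2fc,
                             minMeanDiff = cfg$signature$minMeanDiff)
    writeSignature(sig, file.path(outDir, "signature.txt"),
                   settings = cfg$signature)

    ctrl <- pipelineControl(cfg$classifier$preset)
    genes <- if (length(sig@genes) >= 2L) sig@genes else NULL
    trained <- trainResponseClassifier(cohort$se, lab, genes = genes,
                                       control = ctrl, seed = cfg$seed)
    writeModelJson(trained$model, file.path(outDir, "model.json"),
                   metadata = list(seed = cfg$seed,
                                   preset = cfg$classifier$preset))

    cvRep <- repeatedCrossValidation(
        cohort$se, lab,
        svmPipelineTrainer(pipelineControl("fast"), genes = genes,
                           seed = cfg$seed),
        folds = cfg$cv$folds, repeats = cfg$cv$repeats, seed = cfg$seed)
    jsonlite::write_json(
        list(sensitivity = cvRep@sensitivity,
             specificity = cvRep@specificity,
             balanced_accuracy = cvRep@balancedAccuracy, f1 = cvRep@f1,
             folds = cfg$cv$folds, repeats = cfg$cv$repeats),
        file.path(outDir, "cv_report.json"), auto_unbox = TRUE,
        pretty = TRUE)

    arts <- c("expression.tsv", "response.csv", "mutations.csv",
              "truth.json", "signature.txt", "signature.txt.json",
              "model.json", "cv_report.json")
    manifest <- list(
        version = as.character(utils::packageVersion("PreclinRx")),
        seed = cfg$seed, config = cfg,
        checksums = as.list(tools::md5sum(file.path(outDir, arts))))
    names(manifest$checksums) <- arts
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(cohort = cohort, signature = sig, trained = trained,
                   cv = cvRep, outDir = outDir))
}
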