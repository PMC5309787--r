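## S4 classes for the central result objects.

#' @import methods
NULL

#' Ordered response-category levels
#'
#' The four-level drug-response scale used for both PDO (IC50-based) and PDX
#' (T/C-based) calls, ordered from most to least sensitive. Rank distance
#' between two calls is the absolute difference of their integer codes.
#'
#' @return Character vector of the four ordered level names.
#' @examples
#' responseLevels()
#' @export
responseLevels <- function() c("strong", "moderate", "minor", "resistant")

#' Coerce to an ordered response-category factor
#'
#' @param x character vector of category names (case-insensitive).
#' @return Ordered factor with levels `strong < moderate < minor < resistant`.
#' @examples
#' responseCategory(c("strong", "resistant"))
#' @export
responseCategory <- function(x) {
    x <- tolower(as.character(x))
    bad <- setdiff(unique(x[!is.na(x)]), responseLevels())
    if (length(bad))
        stop("unknown response categories: ", paste(bad, collapse = ", "))
    factor(x, levels = responseLevels(), ordered = TRUE)
}

#' DoseResponseFit: four-parameter logistic fit summary
#'
#' Holds the result of fitting the 4PL model
#' \eqn{y(c) = bottom + (top - bottom) / (1 + (IC50/c)^{hill})}
#' to a percent-inhibition dose-response curve, together with the
#' model-free Emax (mean observed inhibition at the highest tested
#' concentration) and censoring information for inflection points falling
#' outside the tested range.
#'
#' @slot drug character, drug name.
#' @slot modelId character, sample/model identifier.
#' @slot ic50 numeric, relative IC50 in uM (the curve inflection); NA when
#'   the fit did not converge.
#' @slot emax numeric, percent inhibition at the maximum tested
#'   concentration (replicate mean), independent of the fit.
#' @slot hill,top,bottom numeric 4PL parameters.
#' @slot converged logical, FALSE for optimizer failure or flat curves
#'   (response span < 10 percentage points).
#' @slot censored character, one of "none", "above_range", "below_range".
#' @slot sse numeric, residual sum of squares of the best fit.
#' @slot concRange numeric length-2, tested concentration range in uM.
#' @export
setClass("DoseResponseFit",
    representation(drug = "character", modelId = "character",
                   ic50 = "numeric", emax = "numeric", hill = "numeric",
                   top = "numeric", bottom = "numeric",
                   converged = "logical", censored = "character",
                   sse = "numeric", concRange = "numeric"),
    prototype(drug = NA_character_, modelId = NA_character_,
              ic50 = NA_real_, emax = NA_real_, hill = NA_real_,
              top = NA_real_, bottom = NA_real_, converged = FALSE,
              censored = "none", sse = NA_real_,
              concRange = c(NA_real_, NA_real_)))

setValidity("DoseResponseFit", function(object) {
    msg <- character()
    if (!object@censored %in% c("none", "above_range", "below_range"))
        msg <- c(msg, "censored must be none/above_range/below_range")
    if (isTRUE(object@converged) && !is.na(object@ic50) &&
        object@censored == "none" && object@ic50 <= 0)
        msg <- c(msg, "uncensored ic50 must be > 0")
    if (!is.na(object@top) && !is.na(object@bottom) &&
        object@bottom > object@top + 1e-8)
        msg <- c(msg, "bottom must not exceed top")
    if (length(msg)) msg else TRUE
})

#' GeneSignature: a drug-response gene signature with provenance
#'
#' @slot drug character, drug name.
#' @slot modelSystem character, "PDO" or "PDX".
#' @slot genes character, ordered gene identifiers (unique).
#' @slot provenance list, for each gene the subset of setups
#'   ("a","b","c","d") that selected it.
#' @export
setClass("GeneSignature",
    representation(drug = "character", modelSystem = "character",
                   genes = "character", provenance = "list"),
    prototype(drug = NA_character_, modelSystem = NA_character_,
              genes = character(), provenance = list()))

setValidity("GeneSignature", function(object) {
    msg <- character()
    if (anyDuplicated(object@genes))
        msg <- c(msg, "signature genes must be unique")
    if (length(object@provenance) != length(object@genes))
        msg <- c(msg, "provenance must have one entry per gene")
    if (length(object@provenance) &&
        any(!vapply(object@provenance, length, 1L)))
        msg <- c(msg, "every gene needs nonempty provenance")
    if (length(msg)) msg else TRUE
})

#' SvmClassifier: the class-weighted linear SVM mini-classifier
#'
#' A trained linear decision rule \eqn{sign(w \cdot x + b)} over z-scored
#' log2 expression of a small gene panel, with per-class misclassification
#' costs (responder class is the positive class). The stored scaler (per-gene
#' mean and sd on log2(RPKM+1) scale, fit on the training cohort) is reused
#' for internal prediction; external cohorts are z-scored per cohort instead.
#'
#' @slot genes character, ordered feature gene ids.
#' @slot w numeric, weight per gene (same length/order as `genes`).
#' @slot b numeric, bias.
#' @slot cResis,cResp numeric, per-class misclassification costs.
#' @slot scalerMean,scalerSd numeric, per-gene mean/sd (log2(RPKM+1) scale).
#' @slot positiveClass character, label treated as positive ("responder").
#' @export
setClass("SvmClassifier",
    representation(genes = "character", w = "numeric", b = "numeric",
                   cResis = "numeric", cResp = "numeric",
                   scalerMean = "numeric", scalerSd = "numeric",
                   positiveClass = "character"),
    prototype(positiveClass = "responder"))

setValidity("SvmClassifier", function(object) {
    msg <- character()
    if (length(object@w) != length(object@genes))
        msg <- c(msg, "need one weight per gene")
    if (length(object@scalerMean) != length(object@genes) ||
        length(object@scalerSd) != length(object@genes))
        msg <- c(msg, "scaler must cover every gene")
    if (length(object@scalerSd) && any(object@scalerSd <= 0))
        msg <- c(msg, "scaler sd must be > 0 for every retained gene")
    if (length(object@b) != 1L) msg <- c(msg, "bias must be scalar")
    if (length(msg)) msg else TRUE
})

#' PerformanceReport: confusion counts and derived metrics
#'
#' Counts are NA (with metrics set directly) for reports averaged over
#' cross-validation repeats, where metric values rather than pooled counts
#' are averaged.
#'
#' @slot tp,fp,tn,fn numeric confusion counts.
#' @slot sensitivity,specificity,balancedAccuracy,f1 numeric metrics in
#'   [0,1]; NA when undefined (e.g. no positives evaluated).
#' @slot nExcluded numeric, samples excluded before evaluation (e.g. SD
#'   samples under the exclusion policy).
#' @slot stratum character, "all", "kras_wt" or "all_ras_raf_wt".
#' @export
setClass("PerformanceReport",
    representation(tp = "numeric", fp = "numeric", tn = "numeric",
                   fn = "numeric", sensitivity = "numeric",
                   specificity = "numeric", balancedAccuracy = "numeric",
                   f1 = "numeric", nExcluded = "numeric",
                   stratum = "character"),
    prototype(tp = NA_real_, fp = NA_real_, tn = NA_real_, fn = NA_real_,
              sensitivity = NA_real_, specificity = NA_real_,
              balancedAccuracy = NA_real_, f1 = NA_real_, nExcluded = 0,
              stratum = "all"))

setValidity("PerformanceReport", function(object) {
    msg <- character()
    for (s in c("sensitivity", "specificity", "balancedAccuracy", "f1")) {
        v <- slot(object, s)
        if (!is.na(v) && (v < -1e-9 || v > 1 + 1e-9))
            msg <- c(msg, paste(s, "must be in [0,1]"))
    }
    if (!is.na(object@sensitivity) && !is.na(object@specificity) &&
        !is.na(object@balancedAccuracy) &&
        abs(object@balancedAccuracy -
            (object@sensitivity + object@specificity) / 2) > 1e-9)
        msg <- c(msg, "balancedAccuracy must equal (sensitivity+specificity)/2")
    if (length(msg)) msg else TRUE
})

setMethod("show", "DoseResponseFit", function(object) {
    cat("DoseResponseFit:", object@modelId, "/", object@drug, "\n")
    cat(sprintf("  IC50 = %s uM  Emax = %.1f%%  hill = %.3g  [%s]\n",
                format(object@ic50, digits = 4), object@emax, object@hill,
                if (object@converged) "converged" else "not converged"))
    if (object@censored != "none")
        cat("  IC50 censored:", object@censored, "\n")
    invisible(NULL)
})

setMethod("show", "GeneSignature", function(object) {
    cat(sprintf("GeneSignature: %s (%s), %d genes\n", object@drug,
                object@modelSystem, length(object@genes)))
    if (length(object@genes))
        cat("  top:", paste(utils::head(object@genes, 5), collapse = ", "),
            if (length(object@genes) > 5) "..." else "", "\n")
    invisible(NULL)
})

setMethod("show", "SvmClassifier", function(object) {
    cat(sprintf("SvmClassifier: %d genes, C_resis = %g, C_resp = %g\n",
                length(object@genes), object@cResis, object@cResp))
    invisible(NULL)
})

setMethod("show", "PerformanceReport", function(object) {
    cat("PerformanceReport [", object@stratum, "]\n", sep = "")
    if (!is.na(object@tp))
        cat(sprintf("  TP=%g FP=%g TN=%g FN=%g (excluded %g)\n", object@tp,
                    object@fp, object@tn, object@fn, object@nExcluded))
    cat(sprintf("  sensitivity=%.3f specificity=%.3f balanced acc=%.3f f1=%.3f\n",
                object@sensitivity, object@specificity,
                object@balancedAccuracy, object@f1))
    invisible(NULL)
})

## ---- accessors ----

#' @describeIn DoseResponseFit relative IC50 in uM.
#' @param object a `DoseResponseFit`.
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))
#' @export
setMethod("ic50", "DoseResponseFit", function(object) object@ic50)

#' @describeIn DoseResponseFit Emax (% inhibition at top concentration).
#' @export
setGeneric("emax", function(object) standardGeneric("emax"))
#' @export
setMethod("emax", "DoseResponseFit", function(object) object@emax)

#' Genes of a signature or classifier
#' @param object a `GeneSignature` or `SvmClassifier`.
#' @return Character vector of gene identifiers, in object order.
#' @export
setGeneric("signatureGenes", function(object) standardGeneric("signatureGenes"))
#' @export
setMethod("signatureGenes", "GeneSignature", function(object) object@genes)
#' @export
setMethod("signatureGenes", "SvmClassifier", function(object) object@genes)

#' Performance metric accessors
#' @param object a `PerformanceReport`.
#' @return Numeric metric value (NA when undefined).
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))
#' @export
setMethod("sensitivity", "PerformanceReport",
          function(object) object@sensitivity)

#' @rdname sensitivity
#' @export
setGeneric("specificity", function(object) standardGeneric("specificity"))
#' @export
setMethod("specificity", "PerformanceReport",
          function(object) object@specificity)

#' @rdname sensitivity
#' @export
setGeneric("balancedAccuracy",
           function(object) standardGeneric("balancedAccuracy"))
#' @export
setMethod("balancedAccuracy", "PerformanceReport",
          function(object) object@balancedAccuracy)

#' @rdname sensitivity
#' @export
setGeneric("f1score", function(object) standardGeneric("f1score"))
#' @export
setMethod("f1score", "PerformanceReport", function(object) object@f1)
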