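## PDO in-vitro sensitivity: plate normalisation, 4PL fitting, relative
## IC50 / Emax and four-level response categories.

#' Percent inhibition from raw luminescence readings
#'
#' Normalises a viability reading against the plate controls: vehicle
#' (maximum-signal) wells map to 0% inhibition and kill-control
#' (staurosporine, minimum-signal) wells to 100%. Values outside [0, 100]
#' are permitted (biological overshoot).
#'
#' @param reading numeric luminescence reading(s).
#' @param maxCtrl mean luminescence of the vehicle (max-signal) wells.
#' @param minCtrl mean luminescence of the kill-control (min-signal) wells.
#' @return Percent inhibition, `100 * (maxCtrl - reading) / (maxCtrl - minCtrl)`.
#' @examples
#' percentInhibition(550, maxCtrl = 1000, minCtrl = 100)  # 50
#' @export
percentInhibition <- function(reading, maxCtrl, minCtrl) {
    if (!is.finite(maxCtrl) || !is.finite(minCtrl) || maxCtrl <= minCtrl)
        stop("plate failure: max control must exceed min control")
    100 * (maxCtrl - reading) / (maxCtrl - minCtrl)
}

#' Serial dilution concentration series
#'
#' @param top highest concentration.
#' @param factor dilution factor between consecutive points (> 1).
#' @param nPoints number of concentrations.
#' @return Strictly decreasing numeric vector
#'   `top, top/factor, ..., top/factor^(nPoints-1)`.
#' @examples
#' serialDilutionSeries(60, 3, 10)  # 60 uM down to ~3.05 nM
#' @export
serialDilutionSeries <- function(top, factor, nPoints) {
    if (!is.numeric(top) || top <= 0) stop("design error: top must be > 0")
    nPoints <- .assertCount(nPoints, "nPoints", min = 1)
    if (nPoints > 1 && (!is.numeric(factor) || factor <= 1))
        stop("design error: dilution factor must be > 1")
    top / factor^(seq_len(nPoints) - 1)
}

## 4PL mean response at concentrations conc
.fourPL <- function(conc, bottom, top, ic50, hill) {
    bottom + (top - bottom) / (1 + (ic50 / conc)^hill)
}

#' Fit the four-parameter logistic dose-response model
#'
#' Least-squares fit of
#' \eqn{y(c) = bottom + (top-bottom)/(1+(IC50/c)^{hill})} to replicate-mean
#' percent inhibition, with the inflection parameterised on the
#' log10-concentration scale. The optimizer starts from a heuristic
#' (bottom = min, top = max, IC50 = geometric mid-concentration, hill = 1)
#' plus jittered restarts, keeping the best residual sum of squares. Emax
#' is always the mean observed inhibition at the maximum tested
#' concentration, regardless of the fit. Curves whose observed response
#' span is below 10 percentage points, or where the optimizer fails, are
#' flagged `converged = FALSE` and censored `above_range` (treated as
#' resistant downstream). A fitted inflection outside the tested range sets
#' `icCensored` accordingly.
#'
#' @param curve a "DoseResponseCurve" (see [generateDoseResponse()] or
#'   [readDoseResponseCsv()]): list with `concentrations` and `inhibition`
#'   (replicate x concentration matrix, equal replicate counts).
#' @param nRestarts jittered restarts after the heuristic start.
#' @param seed seed for the restart jitter.
#' @return A [DoseResponseFit-class] object.
#' @examples
#' crv <- generateDoseResponse(0.1, 95, 1, serialDilutionSeries(60, 3, 10),
#'                             noiseSd = 0, replicates = 2, seed = 1)
#' fit <- fitFourParameterLogistic(crv)
#' ic50(fit)
#' @export
fitFourParameterLogistic <- function(curve, nRestarts = 5L, seed = 1L) {
    conc <- curve$concentrations
    inh <- curve$inhibition
    if (length(unique(conc)) < 4L)
        stop("design error: need >= 4 distinct concentrations")
    if (!all(is.finite(inh))) stop("data error: non-finite inhibition values")
    y <- colMeans(inh)
    emaxObs <- y[which.max(conc)]
    cmin <- min(conc); cmax <- max(conc)

    fit <- methods::new("DoseResponseFit", drug = curve$drug %||% NA_character_,
                        modelId = curve$modelId %||% NA_character_,
                        emax = unname(emaxObs),
                        concRange = c(cmin, cmax))
    span <- max(y) - min(y)
    if (span < 10) {
        fit@converged <- FALSE
        fit@censored <- "above_range"
        fit@bottom <- min(y); fit@top <- max(y)
        return(fit)
    }

    sse <- function(p) {
        ## p = (bottom, top, log10 ic50, hill)
        mu <- .fourPL(conc, p[1], p[2], 10^p[3], p[4])
        sum((y - mu)^2)
    }
    start <- c(min(y), max(y), mean(log10(range(conc))), 1)
    best <- NULL
    starts <- list(start)
    withSeed(seed, {
        for (i in seq_len(nRestarts))
            starts[[i + 1L]] <- start +
                c(stats::rnorm(2, 0, 5), stats::rnorm(1, 0, 0.5),
                  stats::runif(1, -0.5, 1))
    })
    for (s in starts) {
        o <- tryCatch(stats::optim(s, sse, method = "Nelder-Mead",
                                   control = list(maxit = 2000,
                                                  reltol = 1e-12)),
                      error = function(e) NULL)
        if (!is.null(o)) {
            ## polish with BFGS from the Nelder-Mead solution
            o2 <- tryCatch(stats::optim(o$par, sse, method = "BFGS",
                                        control = list(maxit = 500,
                                                       reltol = 1e-14)),
                           error = function(e) o)
            if (o2$value < o$value) o <- o2
            if (is.null(best) || o$value < best$value) best <- o
        }
    }
    if (is.null(best)) {
        fit@converged <- FALSE
        fit@censored <- "above_range"
        return(fit)
    }
    p <- best$par
    if (p[2] < p[1]) { p[c(1, 2)] <- p[c(2, 1)]; p[4] <- -p[4] }
    icFit <- 10^p[3]
    fit@bottom <- p[1]; fit@top <- p[2]; fit@hill <- p[4]
    fit@ic50 <- icFit
    fit@sse <- best$value
    fit@converged <- TRUE
    fit@censored <- if (icFit > cmax) "above_range"
                    else if (icFit < cmin) "below_range" else "none"
    methods::validObject(fit)
    fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Categorise a PDO dose-response fit into the four response levels
#'
#' On the micromolar scale, the relative IC50 is mapped with boundaries
#' 0.0361 / 0.4277 / 5.0656 uM (boundary values assigned to the more
#' sensitive category, matching the "<= 0.0361" anchor): strong
#' (<= 0.0361), moderate ((0.0361, 0.4277]), minor ((0.4277, 5.0656]),
#' resistant (> 5.0656 or censored above range). The log-units scale
#' applies the antibody (cetuximab) boundaries -5.777 / -4.703 / -3.63 /
#' -1.483 on log10(IC50) analogously; the printed gap (-5.777, -4.703] is
#' assigned to the moderate class (see the methods vignette).
#'
#' @param fit a [DoseResponseFit-class], or a bare numeric IC50 value.
#' @param scale "micromolar" (IC50 in uM) or "log_units" (log10 IC50).
#' @return Ordered factor of length 1, see [responseCategory()].
#' @examples
#' categorizePdo(6)      # resistant
#' categorizePdo(0.01)   # strong
#' @export
categorizePdo <- function(fit, scale = c("micromolar", "log_units")) {
    scale <- match.arg(scale)
    if (methods::is(fit, "DoseResponseFit")) {
        if (!fit@converged || fit@censored == "above_range")
            return(responseCategory("resistant"))
        v <- fit@ic50
    } else v <- fit
    if (is.na(v)) return(responseCategory("resistant"))
    if (scale == "micromolar") {
        lev <- if (v <= 0.0361) "strong"
               else if (v <= 0.4277) "moderate"
               else if (v <= 5.0656) "minor"
               else "resistant"
    } else {
        ## boundaries on log10(IC50); the unassigned printed interval
        ## (-5.777, -4.703] goes to moderate
        lev <- if (v <= -5.777) "strong"
               else if (v <= -3.63) "moderate"
               else if (v <= -1.483) "minor"
               else "resistant"
    }
    responseCategory(lev)
}

#' Drug-by-drug Spearman correlation of sensitivity profiles
#'
#' Compares drugs pairwise across models using Spearman's rank correlation
#' on log10 IC50 (PDO) or T/C (PDX) values, pairwise-complete over shared
#' models. Pairs sharing fewer than `minShared` models are flagged missing
#' (NA).
#'
#' @param sensitivities numeric matrix, models x drugs (NA = not tested).
#' @param minShared minimum models shared per drug pair.
#' @return Symmetric drugs x drugs correlation matrix with unit diagonal.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(1.1, 2.1, 3.1, 4.1))
#' drugCorrelationMatrix(m)
#' @export
drugCorrelationMatrix <- function(sensitivities, minShared = 3L) {
    m <- as.matrix(sensitivities)
    d <- ncol(m)
    if (is.null(colnames(m))) colnames(m) <- paste0("drug", seq_len(d))
    out <- matrix(NA_real_, d, d, dimnames = list(colnames(m), colnames(m)))
    diag(out) <- 1
    if (d < 2) return(out)
    for (i in seq_len(d - 1)) for (j in (i + 1):d) {
        ok <- is.finite(m[, i]) & is.finite(m[, j])
        if (sum(ok) >= minShared) {
            r <- stats::cor(m[ok, i], m[ok, j], method = "spearman")
            out[i, j] <- out[j, i] <- r
        }
    }
    out
}

#' Read dose-response plate data from CSV
#'
#' Accepts either pre-normalised data (column `inhibition`) or raw
#' luminescence (`reading`) with control wells flagged by `well_type`
#' ("max_ctrl" for vehicle, "min_ctrl" for the kill control) and a missing
#' concentration; raw plates are normalised per (model, drug) with
#' [percentInhibition()]. Expected columns: model_id, drug, concentration,
#' replicate, and inhibition or reading (+ well_type).
#'
#' @param path CSV file path.
#' @return Long-format data.frame with model_id, drug, concentration,
#'   replicate, inhibition — ready for [scorePdoPlate()].
#' @export
readDoseResponseCsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("model_id", "drug", "concentration", "replicate")
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    if ("inhibition" %in% names(d)) {
        return(d[!is.na(d$concentration),
                 c(need, "inhibition"), drop = FALSE])
    }
    if (!all(c("reading", "well_type") %in% names(d)))
        stop("need either an 'inhibition' column or 'reading' + 'well_type'")
    keys <- unique(d[, c("model_id", "drug")])
    out <- lapply(seq_len(nrow(keys)), function(i) {
        sub <- d[d$model_id == keys$model_id[i] &
                 d$drug == keys$drug[i], ]
        maxC <- mean(sub$reading[sub$well_type == "max_ctrl"], na.rm = TRUE)
        minC <- mean(sub$reading[sub$well_type == "min_ctrl"], na.rm = TRUE)
        if (!is.finite(maxC) || !is.finite(minC))
            stop("plate failure: missing control wells for ",
                 keys$model_id[i], "/", keys$drug[i])
        wells <- sub[!is.na(sub$concentration), ]
        data.frame(model_id = wells$model_id, drug = wells$drug,
                   concentration = wells$concentration,
                   replicate = wells$replicate,
                   inhibition = percentInhibition(wells$reading, maxC,
                                                  minC),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Score a plate of dose-response data
#'
#' Convenience wrapper: fits every (model, drug) curve in a long-format
#' table and returns fits plus category calls.
#'
#' @param plate data.frame with columns model_id, drug, concentration,
#'   replicate, inhibition (pre-normalised percent inhibition).
#' @param scale category scale, see [categorizePdo()].
#' @return data.frame with model_id, drug, ic50_uM, emax_pct, hill,
#'   category, censored.
#' @export
scorePdoPlate <- function(plate, scale = "micromolar") {
    need <- c("model_id", "drug", "concentration", "replicate", "inhibition")
    if (!all(need %in% names(plate)))
        stop("plate must have columns: ", paste(need, collapse = ", "))
    keys <- unique(plate[, c("model_id", "drug")])
    rows <- lapply(seq_len(nrow(keys)), function(i) {
        sub <- plate[plate$model_id == keys$model_id[i] &
                     plate$drug == keys$drug[i], ]
        conc <- sort(unique(sub$concentration), decreasing = TRUE)
        reps <- sort(unique(sub$replicate))
        inh <- sapply(conc, function(cc)
            sapply(reps, function(r)
                sub$inhibition[sub$concentration == cc & sub$replicate == r][1]))
        inh <- matrix(inh, nrow = length(reps))
        crv <- structure(list(drug = keys$drug[i],
                              modelId = keys$model_id[i],
                              concentrations = conc, inhibition = inh),
                         class = "DoseResponseCurve")
        fit <- fitFourParameterLogistic(crv)
        data.frame(model_id = keys$model_id[i], drug = keys$drug[i],
                   ic50_uM = fit@ic50, emax_pct = fit@emax,
                   hill = fit@hill,
                   category = as.character(categorizePdo(fit, scale)),
                   censored = fit@censored, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
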