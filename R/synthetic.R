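## Synthetic-cohort generator: expression matrices with planted
## differential genes and correlated pairs, 4PL dose-response curves,
## exponential tumour-growth series and mutation-linked response labels.
## Everything is seeded so downstream stages are testable end to end.

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates all parameters of the simulated cohort. Defaults
#' mirror the training-cohort structure the classifier assumes: 14
#' responding versus 34 resistant models, a small planted signature with a
#' log2 fold change of 2 against a log2-scale noise sd of 1, and a handful
#' of highly correlated gene pairs (target Pearson r = 0.9) that exercise
#' the correlated-gene pruning step.
#'
#' @param nResponders,nResistant samples per class.
#' @param nGenes total genes simulated.
#' @param nInformative genes carrying the planted responder/resistant shift.
#' @param effectLog2fc log2-scale mean shift of informative genes in
#'   responders (positive = higher in responders).
#' @param nCorrPairs number of planted highly correlated gene pairs
#'   (pair members are additional to the informative genes).
#' @param corrTarget target Pearson correlation of a planted pair, in [0,1).
#' @param baselineLog2MeanRange length-2 numeric, range of per-gene baseline
#'   means on log2(RPKM+1) scale.
#' @param noiseSd per-gene log2-scale noise standard deviation.
#' @param fracLowExpressed fraction of genes forced below 1 RPKM mean.
#' @param seed integer seed.
#' @return A validated list of class "SyntheticConfig".
#' @examples
#' cfg <- syntheticConfig(nResponders = 5, nResistant = 5, nGenes = 50)
#' @export
syntheticConfig <- function(nResponders = 14L, nResistant = 34L,
                            nGenes = 200L, nInformative = 10L,
                            effectLog2fc = 2, nCorrPairs = 5L,
                            corrTarget = 0.9,
                            baselineLog2MeanRange = c(1, 8),
                            noiseSd = 1, fracLowExpressed = 0.1,
                            seed = 1L) {
    nResponders <- .assertCount(nResponders, "nResponders")
    nResistant <- .assertCount(nResistant, "nResistant")
    nGenes <- .assertCount(nGenes, "nGenes")
    nInformative <- .assertCount(nInformative, "nInformative")
    nCorrPairs <- .assertCount(nCorrPairs, "nCorrPairs")
    .assertFraction(corrTarget, "corrTarget", 0, 1, hiOpen = TRUE)
    .assertFraction(fracLowExpressed, "fracLowExpressed")
    if (nInformative > nGenes)
        stop("invalid config: nInformative (", nInformative,
             ") exceeds nGenes (", nGenes, ")")
    if (2L * nCorrPairs > nGenes)
        stop("invalid config: 2*nCorrPairs (", 2L * nCorrPairs,
             ") exceeds nGenes (", nGenes, ")")
    if (nInformative + 2L * nCorrPairs > nGenes)
        stop("invalid config: informative genes plus correlated pairs ",
             "exceed nGenes")
    if (length(baselineLog2MeanRange) != 2L ||
        baselineLog2MeanRange[1] > baselineLog2MeanRange[2])
        stop("invalid config: baselineLog2MeanRange must be (lo, hi)")
    if (!is.numeric(noiseSd) || noiseSd < 0)
        stop("invalid config: noiseSd must be >= 0")
    if (!is.numeric(effectLog2fc) || !is.finite(effectLog2fc))
        stop("invalid config: effectLog2fc must be finite")
    structure(list(nResponders = nResponders, nResistant = nResistant,
                   nGenes = nGenes, nInformative = nInformative,
                   effectLog2fc = effectLog2fc, nCorrPairs = nCorrPairs,
                   corrTarget = corrTarget,
                   baselineLog2MeanRange = as.numeric(baselineLog2MeanRange),
                   noiseSd = as.numeric(noiseSd),
                   fracLowExpressed = fracLowExpressed,
                   seed = as.integer(seed)),
              class = "SyntheticConfig")
}

#' Generate a synthetic RPKM expression matrix with known truth
#'
#' Simulates `nGenes x (nResponders + nResistant)` RPKM values. Each gene's
#' log2(RPKM+1) values are Normal(mu_g, noiseSd) with mu_g drawn uniformly
#' from the configured baseline range; informative genes get their responder
#' group mean shifted by `effectLog2fc`; each planted pair's partner gene is
#' the other member's latent signal plus independent noise sized so the
#' population correlation equals `corrTarget` (the partner is given the
#' lower baseline mean, so the pruning direction is known); a configured
#' fraction of the remaining genes is forced below 1 RPKM mean. RPKM values
#' are clamped at zero.
#'
#' @param config a [syntheticConfig()] object.
#' @return A list with `se`, a [SummarizedExperiment::SummarizedExperiment]
#'   carrying the `rpkm` assay and a `label` column ("responder"/
#'   "resistant") in its colData, and `truth`, a list with `labels`,
#'   `informativeGenes`, `corrPairs` (data.frame gene/partner) and
#'   `lowExpressedGenes`.
#' @examples
#' res <- generateExpressionMatrix(syntheticConfig(nResponders = 4,
#'     nResistant = 4, nGenes = 30, nInformative = 3, nCorrPairs = 2))
#' dim(res$se)
#' @export
generateExpressionMatrix <- function(config) {
    stopifnot(inherits(config, "SyntheticConfig"))
    n <- config$nResponders + config$nResistant
    if (n < 1L) stop("invalid config: no samples requested")
    withSeed(config$seed, {
        g <- config$nGenes
        genes <- sprintf("G%04d", seq_len(g))
        samples <- sprintf("S%03d", seq_len(n))
        labels <- rep(c("responder", "resistant"),
                      c(config$nResponders, config$nResistant))
        idxInf <- seq_len(config$nInformative)
        idxPairA <- config$nInformative + seq_len(config$nCorrPairs)
        idxPairB <- idxPairA + config$nCorrPairs
        free <- setdiff(seq_len(g), c(idxInf, idxPairA, idxPairB))
        nLow <- min(length(free), round(config$fracLowExpressed * g))
        idxLow <- utils::head(free, nLow)

        lo <- config$baselineLog2MeanRange[1]
        hi <- config$baselineLog2MeanRange[2]
        mu <- stats::runif(g, lo, hi)
        ## low-expressed genes: baseline mean below log2(1+1) = 1
        if (nLow) mu[idxLow] <- stats::runif(nLow, 0.05, 0.9)

        noise <- matrix(stats::rnorm(g * n, 0, config$noiseSd), g, n)
        x <- mu + noise
        if (config$nInformative)
            x[idxInf, labels == "responder"] <-
                x[idxInf, labels == "responder"] + config$effectLog2fc
        ## correlated pairs: partner = member's noise + extra noise with
        ## sd solved from the target correlation; partner mean is lower
        if (config$nCorrPairs) {
            rho <- config$corrTarget
            sigmaE <- if (rho > 0) config$noiseSd * sqrt(1 / rho^2 - 1)
                      else Inf
            for (k in seq_len(config$nCorrPairs)) {
                a <- idxPairA[k]; b <- idxPairB[k]
                muB <- max(mu[a] - 1, 0.1)
                eB <- if (is.finite(sigmaE)) stats::rnorm(n, 0, sigmaE)
                      else stats::rnorm(n, 0, config$noiseSd)
                x[b, ] <- muB + (if (rho > 0) noise[a, ] + eB else eB)
            }
        }
        rpkm <- pmax(2^x - 1, 0)
        dimnames(rpkm) <- list(genes, samples)
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(rpkm = rpkm),
            colData = S4Vectors::DataFrame(label = labels,
                                           row.names = samples))
        truth <- list(
            labels = stats::setNames(labels, samples),
            informativeGenes = genes[idxInf],
            corrPairs = data.frame(gene = genes[idxPairA],
                                   partner = genes[idxPairB],
                                   stringsAsFactors = FALSE),
            lowExpressedGenes = genes[idxLow])
        list(se = se, truth = truth)
    })
}

#' Simulate a dose-response curve from a 4PL model
#'
#' Mean percent inhibition at concentration c follows
#' `top / (1 + (ic50True/c)^hill)` (bottom fixed at 0) with `top` chosen so
#' the curve passes through `emaxTrue` at the highest tested concentration;
#' per-replicate additive Gaussian noise is applied.
#'
#' @param ic50True true inflection concentration (uM).
#' @param emaxTrue percent inhibition at the top concentration.
#' @param hill slope parameter.
#' @param concentrations tested concentrations (uM), >= 4 distinct values.
#' @param noiseSd additive noise sd in percentage points.
#' @param replicates replicates per concentration.
#' @param seed integer seed.
#' @param drug,modelId identifiers stored in the result.
#' @return A list of class "DoseResponseCurve" with `concentrations` and an
#'   `inhibition` matrix (replicates x concentrations), plus the true
#'   parameters used.
#' @examples
#' crv <- generateDoseResponse(0.1, 95, 1, serialDilutionSeries(60, 3, 10),
#'                             noiseSd = 0, replicates = 2, seed = 1)
#' @export
generateDoseResponse <- function(ic50True, emaxTrue, hill, concentrations,
                                 noiseSd = 0, replicates = 2L, seed = 1L,
                                 drug = "drug", modelId = "model") {
    if (length(unique(concentrations)) < 4L)
        stop("design error: need >= 4 distinct concentrations")
    if (any(concentrations <= 0))
        stop("design error: concentrations must be strictly positive")
    replicates <- .assertCount(replicates, "replicates", min = 1)
    cmax <- max(concentrations)
    top <- emaxTrue * (1 + (ic50True / cmax)^hill)
    mu <- top / (1 + (ic50True / concentrations)^hill)
    withSeed(seed, {
        inh <- matrix(rep(mu, each = replicates) +
                          stats::rnorm(replicates * length(concentrations),
                                       0, noiseSd),
                      nrow = replicates)
    })
    colnames(inh) <- as.character(concentrations)
    structure(list(drug = drug, modelId = modelId,
                   concentrations = as.numeric(concentrations),
                   inhibition = inh,
                   truth = list(ic50 = ic50True, emax = emaxTrue,
                                hill = hill, top = top, bottom = 0)),
              class = "DoseResponseCurve")
}

#' Simulate xenograft tumour-growth series for a treated and a control arm
#'
#' Control volumes follow `v0 * exp(growthRate * t)`; treated animals grow
#' at `growthRate * (1 - treatmentEffect)`. Multiplicative log-normal noise
#' with coefficient of variation `noiseCv` is applied per measurement.
#' Volumes are emitted as calliper (length, width) pairs consistent with
#' `V = length * width^2 / 2` under the fixed aspect convention
#' `length = 1.2 * width`, so volumes round-trip exactly.
#'
#' @param nAnimals animals per arm.
#' @param v0 starting volume (mm^3).
#' @param growthRate exponential growth rate per day.
#' @param treatmentEffect fraction in [0,1] by which treatment reduces the
#'   growth rate (1 = complete growth arrest).
#' @param days measurement days (ascending, first = treatment start).
#' @param noiseCv multiplicative noise coefficient of variation.
#' @param seed integer seed.
#' @param modelId,drug identifiers for the emitted records.
#' @return data.frame with columns model_id, drug, animal_id, arm, day,
#'   length_mm, width_mm (the growth-series exchange format).
#' @examples
#' g <- generateGrowthSeries(3, 100, 0.1, 0.8, days = seq(0, 28, 7),
#'                           noiseCv = 0, seed = 1)
#' @export
generateGrowthSeries <- function(nAnimals, v0, growthRate, treatmentEffect,
                                 days, noiseCv = 0.1, seed = 1L,
                                 modelId = "model", drug = "drug") {
    nAnimals <- .assertCount(nAnimals, "nAnimals", min = 1)
    if (!is.numeric(v0) || v0 <= 0) stop("v0 must be > 0")
    if (!length(days) || is.unsorted(days, strictly = TRUE))
        stop("days must be nonempty and strictly ascending")
    .assertFraction(treatmentEffect, "treatmentEffect")
    withSeed(seed, {
        rows <- list()
        for (arm in c("control", "treated")) {
            rate <- if (arm == "treated")
                growthRate * (1 - treatmentEffect) else growthRate
            for (a in seq_len(nAnimals)) {
                mu <- v0 * exp(rate * days)
                if (noiseCv > 0) {
                    sdlog <- sqrt(log(1 + noiseCv^2))
                    vol <- mu * stats::rlnorm(length(days),
                                              -sdlog^2 / 2, sdlog)
                } else vol <- mu
                ## invert V = l*w^2/2 with l = 1.2*w  =>  V = 0.6 w^3
                w <- (vol / 0.6)^(1 / 3)
                rows[[length(rows) + 1L]] <- data.frame(
                    model_id = modelId, drug = drug,
                    animal_id = sprintf("%s_%s_%02d", modelId, arm, a),
                    arm = arm, day = days, length_mm = 1.2 * w,
                    width_mm = w, stringsAsFactors = FALSE)
            }
        }
        do.call(rbind, rows)
    })
}

#' Generate a full synthetic cohort: expression, response and mutations
#'
#' Builds the expression matrix via [generateExpressionMatrix()], assigns
#' responder/resistant labels (class sizes exactly as configured) and links
#' them to the molecular data according to `responseLink`:
#' \describe{
#'   \item{signature}{informative genes are shifted in the responder group;
#'     labels are independent of the realized noise, so with
#'     `effectLog2fc = 0` no classifier can beat chance.}
#'   \item{mutation}{resistant samples carry an activating KRAS/NRAS/BRAF
#'     mutation; responders are wild type; no expression shift is planted.}
#'   \item{mixed}{expression shift as in signature mode, and in addition a
#'     random 60% of resistant samples carry a mutation.}
#' }
#' Matched endpoint T/C values are drawn consistently with the labels
#' (responders uniform on (0, 25], resistant uniform on (25, 100]).
#'
#' @param config a [syntheticConfig()].
#' @param responseLink "signature", "mutation" or "mixed".
#' @return list with `se` (expression + colData columns label, tc_percent),
#'   `response` (data.frame model_id, drug, tc_percent, responder),
#'   `mutations` (data.frame model_id, gene, protein_change) and `truth`.
#' @examples
#' coh <- generateCohort(syntheticConfig(nResponders = 4, nResistant = 6,
#'     nGenes = 40, nInformative = 4, nCorrPairs = 0))
#' table(coh$truth$labels)
#' @export
generateCohort <- function(config,
                           responseLink = c("signature", "mutation",
                                            "mixed")) {
    responseLink <- match.arg(responseLink)
    stopifnot(inherits(config, "SyntheticConfig"))
    if (config$nResponders == 0L || config$nResistant == 0L)
        stop("degenerate cohort: both responder and resistant classes ",
             "must be nonempty")
    if (responseLink == "mutation") {
        ## no expression link: remove the planted shift
        config2 <- config
        config2$effectLog2fc <- 0
        gen <- generateExpressionMatrix(config2)
    } else {
        gen <- generateExpressionMatrix(config)
    }
    se <- gen$se
    truth <- gen$truth
    labels <- truth$labels
    samples <- names(labels)

    muts <- data.frame(model_id = character(), gene = character(),
                       protein_change = character(),
                       stringsAsFactors = FALSE)
    withSeed(config$seed + 1L, {
        if (responseLink %in% c("mutation", "mixed")) {
            resis <- samples[labels == "resistant"]
            carriers <- if (responseLink == "mutation") resis
                        else resis[stats::runif(length(resis)) < 0.6]
            if (length(carriers)) {
                pool <- data.frame(
                    gene = c("KRAS", "KRAS", "KRAS", "NRAS", "BRAF"),
                    protein_change = c("G12D", "G13D", "A146T", "Q61K",
                                       "V600E"), stringsAsFactors = FALSE)
                pick <- sample.int(nrow(pool), length(carriers),
                                   replace = TRUE)
                muts <- data.frame(model_id = carriers,
                                   gene = pool$gene[pick],
                                   protein_change = pool$protein_change[pick],
                                   stringsAsFactors = FALSE)
            }
        }
        tc <- ifelse(labels == "responder",
                     stats::runif(length(labels), 0, 25),
                     stats::runif(length(labels), 25.000001, 100))
    })
    response <- data.frame(model_id = samples, drug = "synthetic_drug",
                           tc_percent = as.numeric(tc),
                           responder = labels == "responder",
                           stringsAsFactors = FALSE)
    SummarizedExperiment::colData(se)$tc_percent <- as.numeric(tc)
    truth$mutationTruth <- muts
    list(se = se, response = response, mutations = muts, truth = truth)
}
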