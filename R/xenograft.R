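## PDX in-vivo sensitivity: tumour volumes, endpoint T/C with four
## categories, relative tumour volume (RTV) with RECIST-adapted calls,
## responder binarization and PDO/PDX sibling concordance.

#' Tumour volume from calliper measurements
#'
#' @param length,width tumour dimensions in mm (length >= width; inputs are
#'   swap-normalised).
#' @return Volume in mm^3, `length * width^2 / 2` (vectorised).
#' @examples
#' tumorVolume(10, 6)  # 180
#' @export
tumorVolume <- function(length, width) {
    if (any(length < 0 | width < 0, na.rm = TRUE))
        stop("data error: negative calliper measurement")
    l <- pmax(length, width)
    w <- pmin(length, width)
    l * w^2 / 2
}

## per-animal volume at the arm endpoint day (within tolerance)
.endpointVolumes <- function(growth, day, tol) {
    vapply(split(growth, growth$animal_id), function(a) {
        d <- a$day[which.min(abs(a$day - day))]
        if (abs(d - day) > tol) return(NA_real_)
        i <- which(a$day == d)[1]
        tumorVolume(a$length_mm[i], a$width_mm[i])
    }, numeric(1))
}

#' Endpoint T/C from treated and control growth series
#'
#' The endpoint is the last measurement day present in both arms (nearest
#' match within a +/- `dayTolerance` window). T/C is 100 times the ratio of
#' mean treated to mean control tumour volume at that day.
#'
#' @param growth data.frame with columns animal_id, arm ("treated"/
#'   "control"), day, length_mm, width_mm for one (model, drug).
#' @param dayTolerance allowed day mismatch between arms (days).
#' @param summary arm summary statistic, "mean" (default) or "median".
#' @return T/C in percent.
#' @examples
#' g <- generateGrowthSeries(3, 100, 0.1, 0.9, days = seq(0, 28, 7),
#'                           noiseCv = 0, seed = 1)
#' endpointTC(g)
#' @export
endpointTC <- function(growth, dayTolerance = 2, summary = c("mean",
                                                             "median")) {
    summary <- match.arg(summary)
    stat <- if (summary == "mean") mean else stats::median
    tr <- growth[growth$arm == "treated", ]
    ct <- growth[growth$arm == "control", ]
    if (!nrow(tr) || !nrow(ct))
        stop("both a treated and a control arm are required")
    dayT <- max(tr$day); dayC <- max(ct$day)
    if (abs(dayT - dayC) > dayTolerance)
        stop("alignment error: no common endpoint day within tolerance")
    endday <- min(dayT, dayC)
    vT <- .endpointVolumes(tr, endday, dayTolerance)
    vC <- .endpointVolumes(ct, endday, dayTolerance)
    vT <- vT[is.finite(vT)]; vC <- vC[is.finite(vC)]
    if (!length(vT) || !length(vC))
        stop("alignment error: no endpoint measurements in range")
    mC <- stat(vC)
    if (mC == 0) stop("degenerate control: zero mean control volume")
    100 * stat(vT) / mC
}

#' Categorise an endpoint T/C value
#'
#' Boundaries: strong (<= 10), moderate ((10, 25]), minor ((25, 50]),
#' resistant (> 50), reconciling the printed integer phrasing ("11-25%")
#' with continuous T/C values.
#'
#' @param tcPercent T/C in percent (vectorised).
#' @return Ordered response-category factor.
#' @examples
#' categorizeTC(c(10, 25, 100))
#' @export
categorizeTC <- function(tcPercent) {
    if (any(tcPercent < 0, na.rm = TRUE))
        stop("T/C must be >= 0")
    lev <- ifelse(tcPercent <= 10, "strong",
           ifelse(tcPercent <= 25, "moderate",
           ifelse(tcPercent <= 50, "minor", "resistant")))
    responseCategory(lev)
}

#' Relative tumour volume and RECIST-adapted call
#'
#' RTV is end-of-treatment volume over start-of-treatment volume. The
#' RECIST-adapted mapping is CR (RTV = 0), PR (0 < RTV < 0.7), SD
#' (0.7 <= RTV <= 1.2), PD (RTV > 1.2), partitioning all of [0, Inf).
#'
#' @param start,end tumour volumes in mm^3 (vectorised; start > 0).
#' @return data.frame with columns rtv and recist.
#' @examples
#' rtvRecist(100, c(0, 50, 100, 150))
#' @export
rtvRecist <- function(start, end) {
    if (any(start <= 0, na.rm = TRUE))
        stop("data error: start volume must be > 0")
    if (any(end < 0, na.rm = TRUE))
        stop("data error: end volume must be >= 0")
    rtv <- end / start
    recist <- ifelse(rtv == 0, "CR",
              ifelse(rtv < 0.7, "PR",
              ifelse(rtv <= 1.2, "SD", "PD")))
    data.frame(rtv = rtv, recist = recist, stringsAsFactors = FALSE)
}

#' Responder binarization of a response category
#'
#' A model is a responder iff its category is strong or moderate, i.e.
#' endpoint T/C <= 25% (tumour regression or stable disease).
#'
#' @param category response category (factor or character, vectorised).
#' @return Logical responder flag.
#' @examples
#' binarizeResponse(c("strong", "minor"))
#' @export
binarizeResponse <- function(category) {
    category <- responseCategory(category)
    category %in% c("strong", "moderate")
}

#' PDO/PDX sibling response concordance
#'
#' Siblings are concordant when their four-level response calls differ by
#' at most one rank (e.g. minor versus moderate).
#'
#' @param pdoCat,pdxCat response categories (vectorised).
#' @return Character "concordant"/"discordant".
#' @examples
#' siblingConcordance("minor", "moderate")    # concordant
#' siblingConcordance("strong", "resistant")  # discordant
#' @export
siblingConcordance <- function(pdoCat, pdxCat) {
    a <- as.integer(responseCategory(pdoCat))
    b <- as.integer(responseCategory(pdxCat))
    ifelse(abs(a - b) <= 1L, "concordant", "discordant")
}

#' Score a xenograft growth table into PDX response calls
#'
#' For every (model, drug): endpoint T/C with its category and responder
#' flag, and the treated arm's mean per-animal RTV with its RECIST-adapted
#' call. The arm-level CR call requires every treated animal to reach zero
#' end volume.
#'
#' @param growth data.frame with columns model_id, drug, animal_id, arm,
#'   day, length_mm, width_mm.
#' @param dayTolerance,summary passed to [endpointTC()].
#' @return data.frame with model_id, drug, tc_percent, tc_category, rtv,
#'   recist, responder.
#' @examples
#' g <- generateGrowthSeries(3, 100, 0.1, 0.9, days = seq(0, 28, 7),
#'                           noiseCv = 0, seed = 1)
#' scorePdx(g)
#' @export
scorePdx <- function(growth, dayTolerance = 2, summary = "mean") {
    need <- c("model_id", "drug", "animal_id", "arm", "day", "length_mm",
              "width_mm")
    if (!all(need %in% names(growth)))
        stop("growth table must have columns: ", paste(need, collapse = ", "))
    keys <- unique(growth[, c("model_id", "drug")])
    rows <- lapply(seq_len(nrow(keys)), function(i) {
        sub <- growth[growth$model_id == keys$model_id[i] &
                      growth$drug == keys$drug[i], ]
        tc <- endpointTC(sub, dayTolerance, summary)
        cat4 <- categorizeTC(tc)
        tr <- sub[sub$arm == "treated", ]
        perAnimal <- lapply(split(tr, tr$animal_id), function(a) {
            a <- a[order(a$day), ]
            v0 <- tumorVolume(a$length_mm[1], a$width_mm[1])
            vEnd <- tumorVolume(a$length_mm[nrow(a)], a$width_mm[nrow(a)])
            c(start = v0, end = vEnd)
        })
        st <- vapply(perAnimal, `[[`, numeric(1), "start")
        en <- vapply(perAnimal, `[[`, numeric(1), "end")
        rtvs <- en / st
        armRtv <- mean(rtvs)
        recist <- if (all(en == 0)) "CR" else rtvRecist(1, armRtv)$recist
        data.frame(model_id = keys$model_id[i], drug = keys$drug[i],
                   tc_percent = tc, tc_category = as.character(cat4),
                   rtv = armRtv, recist = recist,
                   responder = binarizeResponse(cat4),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
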