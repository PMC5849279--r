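#' Mean-dosage imputation of missing genotypes
#'
#' Replaces each missing dosage with the mean of the observed dosages at the
#' same marker (additive coding), leaving observed entries untouched, so that
#' per-marker observed means are preserved exactly and every downstream score
#' is finite. A marker with no observed genotypes is an error unless a panel
#' is supplied, in which case its expected dosage under Hardy-Weinberg,
#' 2 x modeled-allele frequency, is used instead (with a message).
#'
#' @param x an [AfCohort-class] or a SNPs x participants numeric matrix.
#' @param panel optional [SnpPanel-class] supplying the fallback frequency
#'   for fully missing markers.
#' @param ... unused.
#' @return object of the same class, with no missing dosages (real-valued
#'   dosages allowed).
#' @examples
#' m <- matrix(c(0, 1, 2, NA), nrow = 1,
#'             dimnames = list("rs2200733", paste0("P", 1:4)))
#' imputeMissing(m)  # NA -> 1
#' @name imputeMissing
NULL

#' @rdname imputeMissing
#' @export
setMethod("imputeMissing", "matrix", function(x, panel = NULL, ...) {
    if (!anyNA(x)) return(x)
    for (i in seq_len(nrow(x))) {
        miss <- is.na(x[i, ])
        if (!any(miss)) next
        if (all(miss)) {
            if (is.null(panel))
                stop("marker '", rownames(x)[i], "' has no observed ",
                     "genotypes and no panel was supplied for a ",
                     "frequency-based fallback")
            f <- panelFreqs(panel)[rownames(x)[i]]
            if (is.na(f))
                stop("marker '", rownames(x)[i], "' not found in panel")
            message("marker '", rownames(x)[i], "' fully missing; ",
                    "imputed as 2 x modeled-allele frequency = ", 2 * f)
            x[i, ] <- 2 * f
        } else {
            x[i, miss] <- mean(x[i, !miss])
        }
    }
    x
})

#' @rdname imputeMissing
#' @export
setMethod("imputeMissing", "AfCohort", function(x, panel = NULL, ...) {
    if (is.null(panel) && all(c("rsid", "weight") %in%
                              colnames(rowData(x))))
        panel <- snpPanel(x)
    d <- imputeMissing(assay(x, "dosage"), panel = panel)
    SummarizedExperiment::assay(x, "dosage", withDimnames = FALSE) <- d
    metadata(x)$imputed <- TRUE
    validObject(x)
    x
})

#' Weighted allele-counting genetic risk score
#'
#' For participant \eqn{j} with dosage \eqn{g_{ij}} of the modeled allele at
#' SNP \eqn{i}, the score is \eqn{s_j = \sum_i w_i g_{ij}} with the panel
#' weights \eqn{w_i} on the log-odds scale. Dosages must be complete; run
#' [imputeMissing()] first.
#'
#' @param x an [AfCohort-class] or a SNPs x participants dosage matrix with
#'   no missing entries.
#' @param panel a [SnpPanel-class]; rsids must match the matrix rows
#'   (any order). For an \code{AfCohort} that carries its panel in
#'   \code{rowData}, \code{panel} may be omitted.
#' @param ... unused.
#' @return a [GrsVector-class] with scores only (quantile labels unassigned).
#' @examples
#' panel <- afPanel("af12")
#' d <- matrix(0, 12, 1, dimnames = list(panel$rsid, "P1"))
#' d["rs2200733", ] <- 2
#' scores(computeGrs(d, panel))  # 2 * 0.54 = 1.08
#' @name computeGrs
NULL

.computeGrsMatrix <- function(d, panel) {
    if (anyNA(d))
        stop("dosage matrix has missing entries; run imputeMissing() first")
    unmatched_m <- setdiff(rownames(d), panel$rsid)
    unmatched_p <- setdiff(panel$rsid, rownames(d))
    if (length(unmatched_m) || length(unmatched_p))
        stop("rsid mismatch between dosage matrix and panel; ",
             "matrix-only: [", paste(unmatched_m, collapse = ", "),
             "]; panel-only: [", paste(unmatched_p, collapse = ", "), "]")
    w <- panelWeights(panel)
    s <- as.numeric(crossprod(d[names(w), , drop = FALSE], w))
    new("GrsVector", participant_ids = colnames(d), score = s,
        quintile = rep(NA_integer_, ncol(d)),
        tertile = rep(NA_integer_, ncol(d)),
        quintile_bounds = numeric(0), tertile_bounds = numeric(0))
}

#' @rdname computeGrs
#' @export
setMethod("computeGrs", signature("matrix", "SnpPanel"),
    function(x, panel, ...) .computeGrsMatrix(x, panel))

#' @rdname computeGrs
#' @export
setMethod("computeGrs", signature("AfCohort", "SnpPanel"),
    function(x, panel, ...) .computeGrsMatrix(assay(x, "dosage"), panel))

#' @rdname computeGrs
#' @export
setMethod("computeGrs", signature("AfCohort", "missing"),
    function(x, panel, ...) .computeGrsMatrix(assay(x, "dosage"), snpPanel(x)))

#' Quantile stratification of risk scores
#'
#' Cuts scores into k near-equal groups at the sample (k-1) quantiles
#' (type-7, linear interpolation). Membership uses closed upper intervals:
#' a score exactly equal to a cut point falls in the lower group. With tied
#' scores the interval rule keeps precedence, so group sizes can be unequal;
#' that is expected, not an error.
#'
#' @param x a [GrsVector-class].
#' @param k 5 (quintiles) or 3 (tertiles).
#' @param ... unused.
#' @return the input with the corresponding labels and cut points filled in.
#' @examples
#' g <- new("GrsVector", participant_ids = letters[1:5], score = 1:5 / 1,
#'          quintile = rep(NA_integer_, 5), tertile = rep(NA_integer_, 5),
#'          quintile_bounds = numeric(0), tertile_bounds = numeric(0))
#' quintiles(assignQuantiles(g, 5))
#' @name assignQuantiles
NULL

#' @rdname assignQuantiles
#' @export
setMethod("assignQuantiles", "GrsVector", function(x, k, ...) {
    k <- as.integer(k)
    if (!(k %in% c(3L, 5L)))
        stop("k must be 3 (tertiles) or 5 (quintiles)")
    s <- x@score
    if (length(unique(s)) < k)
        stop("fewer than ", k, " distinct score values; cannot form ",
             k, " groups")
    bounds <- unname(stats::quantile(s, probs = seq_len(k - 1) / k,
                                     type = 7))
    labels <- vapply(s, function(v) sum(v > bounds), 0L) + 1L
    if (k == 5L) {
        x@quintile <- labels
        x@quintile_bounds <- bounds
    } else {
        x@tertile <- labels
        x@tertile_bounds <- bounds
    }
    validObject(x)
    x
})

#' Accessors for GrsVector objects
#'
#' @param x a [GrsVector-class].
#' @param k 5 for quintile cut points, 3 for tertile cut points.
#' @name GrsVector-accessors
#' @aliases scores quintiles tertiles quantileBounds
NULL

#' @rdname GrsVector-accessors
#' @export
setMethod("scores", "GrsVector", function(x)
    stats::setNames(x@score, x@participant_ids))

#' @rdname GrsVector-accessors
#' @export
setMethod("quintiles", "GrsVector", function(x)
    stats::setNames(x@quintile, x@participant_ids))

#' @rdname GrsVector-accessors
#' @export
setMethod("tertiles", "GrsVector", function(x)
    stats::setNames(x@tertile, x@participant_ids))

#' @rdname GrsVector-accessors
#' @export
setMethod("quantileBounds", "GrsVector", function(x, k = 5L) {
    if (k == 5L) x@quintile_bounds else if (k == 3L) x@tertile_bounds
    else stop("k must be 3 or 5")
})

setMethod("length", "GrsVector", function(x) length(x@score))

setMethod("show", "GrsVector", function(object) {
    cat("GrsVector for", length(object), "participants\n")
    cat(sprintf("  score: mean %.3f, SD %.3f, range [%.3f, %.3f]\n",
                mean(object@score), stats::sd(object@score),
                min(object@score), max(object@score)))
    if (length(object@quintile_bounds))
        cat("  quintile cut points:",
            paste(sprintf("%.3f", object@quintile_bounds), collapse = ", "),
            "\n")
    if (length(object@tertile_bounds))
        cat("  tertile cut points:",
            paste(sprintf("%.3f", object@tertile_bounds), collapse = ", "),
            "\n")
})
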