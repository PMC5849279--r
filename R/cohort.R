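#' Build a cohort from dosages, a panel and covariates
#'
#' @param dosage numeric matrix of modeled-allele dosages. Accepted in either
#'   orientation: SNPs x participants (rownames are rsids) or participants x
#'   SNPs (colnames are rsids); stored internally as SNPs x participants.
#' @param panel optional [SnpPanel-class]; when given, dosage rows are checked
#'   against the panel rsids and reordered to panel order. Unmatched ids on
#'   either side raise an error listing them.
#' @param covariates optional data.frame of per-participant covariates
#'   (one row per participant, in participant order).
#' @param af_event optional binary outcome vector.
#' @param imputed set \code{TRUE} when dosages are already imputed
#'   (real values allowed).
#' @return an [AfCohort-class].
#' @examples
#' panel <- afPanel("af12")
#' d <- matrix(0, nrow = 12, ncol = 2,
#'             dimnames = list(panel$rsid, c("p1", "p2")))
#' AfCohort(d, panel)
#' @export
AfCohort <- function(dosage, panel = NULL, covariates = NULL,
                     af_event = NULL, imputed = FALSE) {
    stopifnot(is.matrix(dosage))
    if (!is.null(panel)) {
        ## accept participants x SNPs input and transpose
        if (!any(rownames(dosage) %in% panel$rsid) &&
            any(colnames(dosage) %in% panel$rsid))
            dosage <- t(dosage)
        unmatched_m <- setdiff(rownames(dosage), panel$rsid)
        unmatched_p <- setdiff(panel$rsid, rownames(dosage))
        if (length(unmatched_m) || length(unmatched_p))
            stop("rsid mismatch between dosage matrix and panel; ",
                 "matrix-only: [", paste(unmatched_m, collapse = ", "),
                 "]; panel-only: [", paste(unmatched_p, collapse = ", "), "]")
        dosage <- dosage[panel$rsid, , drop = FALSE]
        rd <- as(as.data.frame(panel), "DataFrame")
    } else {
        rd <- NULL
    }
    if (is.null(colnames(dosage)))
        colnames(dosage) <- paste0("P", seq_len(ncol(dosage)))
    cd <- DataFrame(row.names = colnames(dosage))
    if (!is.null(covariates)) {
        stopifnot(nrow(covariates) == ncol(dosage))
        cd <- as(as.data.frame(covariates), "DataFrame")
        rownames(cd) <- colnames(dosage)
    }
    if (!is.null(af_event)) {
        stopifnot(length(af_event) == ncol(dosage))
        cd$af_event <- as.integer(af_event)
    }
    se <- SummarizedExperiment(assays = list(dosage = dosage),
                               colData = cd)
    if (!is.null(rd)) rowData(se) <- rd
    obj <- new("AfCohort", se)
    metadata(obj)$imputed <- isTRUE(imputed)
    validObject(obj)
    obj
}

#' Accessors for AfCohort objects
#'
#' \code{dosages} returns the SNPs x participants dosage matrix;
#' \code{snpPanel} rebuilds the [SnpPanel-class] from \code{rowData};
#' \code{covariateTable} returns \code{colData} as a data.frame;
#' \code{afEvents} returns the binary outcome vector.
#'
#' @param x an [AfCohort-class].
#' @name AfCohort-accessors
#' @aliases dosages snpPanel covariateTable afEvents
NULL

#' @rdname AfCohort-accessors
#' @export
setMethod("dosages", "AfCohort", function(x) assay(x, "dosage"))

#' @rdname AfCohort-accessors
#' @export
setMethod("snpPanel", "AfCohort", function(x) {
    rd <- rowData(x)
    if (!all(c("rsid", "weight") %in% colnames(rd)))
        stop("cohort carries no SNP panel in rowData")
    SnpPanel(as.data.frame(rd))
})

#' @rdname AfCohort-accessors
#' @export
setMethod("covariateTable", "AfCohort", function(x)
    as.data.frame(colData(x)))

#' @rdname AfCohort-accessors
#' @export
setMethod("afEvents", "AfCohort", function(x) {
    if (!("af_event" %in% colnames(colData(x))))
        stop("cohort has no af_event outcome")
    stats::setNames(as.integer(x$af_event), colnames(x))
})

setMethod("show", "AfCohort", function(object) {
    d <- assay(object, "dosage")
    cat("AfCohort:", ncol(object), "participants x", nrow(object), "SNPs\n")
    cat("  missing dosages:", sum(is.na(d)),
        sprintf("(%.2f%%)", 100 * mean(is.na(d))),
        if (isTRUE(metadata(object)$imputed)) "[imputed]" else "", "\n")
    cv <- setdiff(colnames(colData(object)), "af_event")
    if (length(cv)) cat("  covariates:", paste(cv, collapse = ", "), "\n")
    if ("af_event" %in% colnames(colData(object)))
        cat("  AF events:", sum(object$af_event), "/", ncol(object), "\n")
})
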