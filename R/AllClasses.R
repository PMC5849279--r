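#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData rowData<- colData colData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.NUCLEOTIDES <- c("A", "C", "G", "T")

#' SNP weight panel for a genetic risk score
#'
#' A \code{SnpPanel} holds, for each SNP in a risk score, its rsid, gene,
#' cytogenetic locus, modeled allele (the allele whose copies are counted),
#' the population frequency of that allele, and its log-odds-scale weight.
#' Weights may be negative: a protective modeled allele keeps its own count
#' and carries a negative weight rather than being re-oriented.
#'
#' @slot .Data inherited \code{DFrame} with columns \code{rsid}, \code{gene},
#'   \code{locus}, \code{modeled_allele}, \code{freq}, \code{weight}.
#' @seealso [afPanel()], [loadPanel()], [subsetOnePerGene()]
#' @exportClass SnpPanel
setClass("SnpPanel", contains = "DFrame")

.validSnpPanel <- function(object) {
    need <- c("rsid", "gene", "locus", "modeled_allele", "freq", "weight")
    msgs <- character()
    missing_cols <- setdiff(need, colnames(object))
    if (length(missing_cols))
        return(paste("missing panel columns:",
                     paste(missing_cols, collapse = ", ")))
    if (anyDuplicated(object$rsid))
        msgs <- c(msgs, paste("duplicate rsid:",
            paste(unique(object$rsid[duplicated(object$rsid)]),
                  collapse = ", ")))
    bad_f <- which(!is.finite(object$freq) |
                   object$freq <= 0 | object$freq >= 1)
    if (length(bad_f))
        msgs <- c(msgs, paste0("freq outside (0,1) in row(s) ",
            paste(bad_f, collapse = ", "), " [",
            paste(object$rsid[bad_f], collapse = ", "), "]"))
    bad_a <- which(!(object$modeled_allele %in% .NUCLEOTIDES))
    if (length(bad_a))
        msgs <- c(msgs, paste0("modeled_allele not a single nucleotide in ",
            "row(s) ", paste(bad_a, collapse = ", "), " [",
            paste(object$rsid[bad_a], collapse = ", "), "]"))
    if (!all(is.finite(object$weight)))
        msgs <- c(msgs, "non-finite weight")
    if (length(msgs)) msgs else TRUE
}
setValidity("SnpPanel", .validSnpPanel)

#' Cohort container: genotype dosages plus clinical covariates
#'
#' \code{AfCohort} extends \linkS4class{SummarizedExperiment}: the
#' \code{"dosage"} assay holds modeled-allele dosages with SNPs as rows and
#' participants as columns (values 0/1/2, \code{NA} for a missing genotype,
#' and real-valued after mean imputation); \code{rowData} carries the SNP
#' panel columns; \code{colData} carries clinical covariates and, when
#' present, the binary \code{af_event} outcome.
#'
#' @seealso [AfCohort()], [simulateCohort()], [imputeMissing()], [computeGrs()]
#' @exportClass AfCohort
setClass("AfCohort", contains = "SummarizedExperiment")

.validAfCohort <- function(object) {
    if (!("dosage" %in% assayNames(object)))
        return("assay 'dosage' is required")
    d <- assay(object, "dosage")
    if (!is.numeric(d))
        return("dosage assay must be numeric")
    obs <- d[!is.na(d)]
    if (length(obs) && (any(obs < 0) || any(obs > 2)))
        return("dosage values must lie in [0, 2]")
    if (!isTRUE(metadata(object)$imputed) &&
        length(obs) && any(obs != round(obs)))
        return("non-imputed dosages must be integers 0/1/2 (or NA)")
    if (is.null(rownames(object)))
        return("rownames (rsids) are required")
    if (is.null(colnames(object)))
        return("colnames (participant ids) are required")
    if ("af_event" %in% colnames(colData(object))) {
        ev <- object$af_event
        if (!all(ev %in% c(0L, 1L)))
            return("af_event must be binary 0/1")
    }
    TRUE
}
setValidity("AfCohort", .validAfCohort)

#' Per-participant genetic risk scores with quantile stratification
#'
#' Holds the weighted allele-counting score for each participant, together
#' with (once assigned) quintile and tertile group labels and the sample
#' quantile cut points that define them. Group membership follows the
#' closed-upper convention: a score equal to a cut point belongs to the
#' lower group.
#'
#' @slot participant_ids character vector of participant identifiers.
#' @slot score numeric score per participant; always finite (imputation
#'   upstream guarantees no missing scores).
#' @slot quintile integer 1-5 per participant, or NA before assignment.
#' @slot tertile integer 1-3 per participant, or NA before assignment.
#' @slot quintile_bounds the 4 sample quintile cut points (length 0 before
#'   assignment).
#' @slot tertile_bounds the 2 sample tertile cut points.
#' @seealso [computeGrs()], [assignQuantiles()]
#' @exportClass GrsVector
setClass("GrsVector",
    representation(participant_ids = "character",
                   score = "numeric",
                   quintile = "integer",
                   tertile = "integer",
                   quintile_bounds = "numeric",
                   tertile_bounds = "numeric"))

.validGrsVector <- function(object) {
    n <- length(object@participant_ids)
    if (length(object@score) != n)
        return("score length must match participant_ids")
    if (!all(is.finite(object@score)))
        return("scores must all be finite")
    if (length(object@quintile) != n || length(object@tertile) != n)
        return("quintile/tertile labels must match participant_ids length")
    if (!all(is.na(object@quintile) | object@quintile %in% 1:5))
        return("quintile labels must be 1..5 or NA")
    if (!all(is.na(object@tertile) | object@tertile %in% 1:3))
        return("tertile labels must be 1..3 or NA")
    if (!(length(object@quintile_bounds) %in% c(0L, 4L)))
        return("quintile_bounds must have length 0 or 4")
    if (!(length(object@tertile_bounds) %in% c(0L, 2L)))
        return("tertile_bounds must have length 0 or 2")
    TRUE
}
setValidity("GrsVector", .validGrsVector)
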