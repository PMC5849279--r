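## The canonical 12-SNP atrial-fibrillation risk panel: modeled allele,
## modeled-allele frequency, and log-odds weight per SNP. Four weights are
## negative (protective modeled alleles).
.AF12 <- data.frame(
    rsid = c("rs13376333", "rs3903239", "rs10033464", "rs17570669",
             "rs2200733", "rs3853445", "rs3807989", "rs10821415",
             "rs10824026", "rs1152591", "rs7164883", "rs2106261"),
    gene = c("KCNN3", "PRRX1", "PITX2", "PITX2", "PITX2", "PITX2",
             "CAV1", "C9orf3", "SYNPO2L", "SYNE2", "HCN4", "ZFHX3"),
    locus = c("1q21", "1q24", "4q25", "4q25", "4q25", "4q25", "7q31",
              "9q22", "10q22", "14q23", "15q24", "16q22"),
    modeled_allele = c("T", "G", "T", "T", "T", "C", "A", "A", "G",
                       "A", "G", "T"),
    freq = c(0.30, 0.40, 0.10, 0.07, 0.13, 0.27, 0.42, 0.40, 0.18,
             0.46, 0.19, 0.19),
    weight = c(0.12, 0.13, 0.33, -0.31, 0.54, -0.15, -0.11, 0.10,
               -0.14, 0.12, 0.17, 0.22),
    stringsAsFactors = FALSE)

#' Construct a SNP weight panel
#'
#' @param rsid,gene,locus,modeled_allele,freq,weight per-SNP fields, either
#'   as parallel vectors or with \code{rsid} a data.frame/DataFrame holding
#'   all six columns.
#' @return a validated [SnpPanel-class].
#' @examples
#' SnpPanel(afPanel("af12"))
#' @export
SnpPanel <- function(rsid, gene = NULL, locus = NULL, modeled_allele = NULL,
                     freq = NULL, weight = NULL) {
    if (is.data.frame(rsid) || is(rsid, "DataFrame")) {
        df <- as(as.data.frame(rsid), "DataFrame")
    } else {
        df <- DataFrame(rsid = as.character(rsid), gene = as.character(gene),
                        locus = as.character(locus),
                        modeled_allele = as.character(modeled_allele),
                        freq = as.numeric(freq), weight = as.numeric(weight))
    }
    rownames(df) <- df$rsid
    new("SnpPanel", df)
}

#' Built-in risk score panels
#'
#' \code{"af12"} is the canonical 12-SNP atrial-fibrillation panel across 9
#' genes (4 SNPs at the PITX2 locus). \code{"af9"} is its one-SNP-per-gene
#' reduction, keeping rs2200733 for PITX2 — the SNP most strongly associated
#' with AF at that locus — with the original weights carried over unchanged.
#'
#' @param name \code{"af12"} or \code{"af9"}.
#' @return a [SnpPanel-class].
#' @examples
#' afPanel("af9")
#' @export
afPanel <- function(name = c("af12", "af9")) {
    name <- match.arg(name)
    p12 <- SnpPanel(.AF12)
    if (name == "af12") return(p12)
    subsetOnePerGene(p12, keep = c(PITX2 = "rs2200733"))
}

#' Load a SNP weight panel from a delimited file or by built-in name
#'
#' @param source either a built-in panel name (\code{"af12"}, \code{"af9"})
#'   or the path to a headered CSV/TSV with columns \code{rsid}, \code{gene},
#'   \code{locus}, \code{modeled_allele}, \code{freq}, \code{weight}.
#' @param col_map optional named character vector remapping non-standard
#'   header names, e.g. \code{c(freq = "MAF")}.
#' @return a validated [SnpPanel-class]; malformed rows (duplicate rsid,
#'   frequency outside (0,1), non-nucleotide allele) raise an error naming
#'   the offending row.
#' @export
loadPanel <- function(source, col_map = NULL) {
    if (source %in% c("af12", "af9")) return(afPanel(source))
    if (!file.exists(source))
        stop("panel source '", source, "' is neither a built-in name ",
             "nor an existing file")
    sep <- if (grepl("\\.tsv$|\\.txt$", source, ignore.case = TRUE)) "\t" else ","
    df <- utils::read.table(source, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    if (!is.null(col_map)) {
        for (std in names(col_map)) {
            i <- match(col_map[[std]], colnames(df))
            if (!is.na(i)) colnames(df)[i] <- std
        }
    }
    SnpPanel(df)
}

#' Reduce a panel to one SNP per gene
#'
#' Drops all but one SNP from every gene represented by multiple panel SNPs.
#' Weights are carried over unchanged from the parent panel (no re-fitting).
#'
#' @param panel a [SnpPanel-class].
#' @param keep named character vector \code{gene -> rsid} choosing the SNP
#'   retained for each multi-SNP gene.
#' @return a [SnpPanel-class] with one SNP per gene.
#' @examples
#' subsetOnePerGene(afPanel("af12"), keep = c(PITX2 = "rs2200733"))
#' @export
subsetOnePerGene <- function(panel, keep = c(PITX2 = "rs2200733")) {
    stopifnot(is(panel, "SnpPanel"))
    bad <- setdiff(keep, panel$rsid)
    if (length(bad))
        stop("keep names rsid(s) not in the panel: ",
             paste(bad, collapse = ", "))
    multi <- names(which(table(panel$gene) > 1L))
    uncovered <- setdiff(multi, names(keep))
    if (length(uncovered))
        stop("multi-SNP gene(s) not covered by keep: ",
             paste(uncovered, collapse = ", "))
    drop <- panel$gene %in% names(keep) & !(panel$rsid %in% keep)
    SnpPanel(panel[!drop, , drop = FALSE])
}

#' @describeIn SnpPanel-class weights, named by rsid.
#' @param object,panel a \code{SnpPanel}.
#' @export
panelWeights <- function(panel) stats::setNames(panel$weight, panel$rsid)

#' @describeIn SnpPanel-class modeled-allele frequencies, named by rsid.
#' @export
panelFreqs <- function(panel) stats::setNames(panel$freq, panel$rsid)

#' @describeIn SnpPanel-class modeled alleles, named by rsid.
#' @export
modeledAlleles <- function(panel) stats::setNames(panel$modeled_allele, panel$rsid)

setMethod("show", "SnpPanel", function(object) {
    cat("SnpPanel with", nrow(object), "SNPs across",
        length(unique(object$gene)), "genes\n")
    cat("  weight range: [", min(object$weight), ", ",
        max(object$weight), "]\n", sep = "")
    show(as(object, "DFrame"))
})
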