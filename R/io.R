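.NA_STRINGS <- c("NA", "", ".")

#' Read a dosage CSV
#'
#' Expects a header row with \code{participant_id} followed by one column
#' per rsid, and values 0/1/2 or missing (spelled \code{NA}, empty, or
#' \code{.}). Orientation is participants as rows.
#'
#' @param path CSV path.
#' @param panel optional [SnpPanel-class]; columns not in the panel trigger
#'   a warning listing them, panel SNPs absent from the file are messaged,
#'   and both matrix and panel are restricted to the common SNPs in panel
#'   order.
#' @return an [AfCohort-class] holding the dosage matrix (with missingness).
#' @export
readDosageCsv <- function(path, panel = NULL) {
    df <- utils::read.csv(path, check.names = FALSE,
                          na.strings = .NA_STRINGS,
                          stringsAsFactors = FALSE)
    if (nrow(df) == 0L || ncol(df) < 2L)
        stop("dosage file '", path, "' is empty or has no SNP columns")
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m))
        m <- matrix(suppressWarnings(as.numeric(m)), nrow = nrow(df),
                    dimnames = list(NULL, colnames(df)[-1L]))
    bad <- which(!is.na(m) & !(m %in% c(0, 1, 2)), arr.ind = TRUE)
    nonnum <- which(is.na(m) & !is.na(df[, -1L, drop = FALSE]),
                    arr.ind = TRUE)
    bad <- rbind(bad, nonnum)
    if (nrow(bad))
        stop("non-dosage value at row ", bad[1, 1], ", column '",
             colnames(m)[bad[1, 2]], "' of ", path)
    rownames(m) <- ids
    d <- t(m)
    if (!is.null(panel)) {
        unknown <- setdiff(rownames(d), panel$rsid)
        if (length(unknown))
            warning("dosage columns not in panel (dropped): ",
                    paste(unknown, collapse = ", "))
        keep <- intersect(panel$rsid, rownames(d))
        absent <- setdiff(panel$rsid, keep)
        if (length(absent))
            message("panel SNP(s) not in dosage file: ",
                    paste(absent, collapse = ", "))
        d <- d[keep, , drop = FALSE]
        panel <- SnpPanel(as.data.frame(panel)[
            match(keep, panel$rsid), , drop = FALSE])
    }
    message("read ", ncol(d), " participants x ", nrow(d), " SNPs from ",
            path, " (", sum(is.na(d)), " missing genotypes)")
    AfCohort(d, panel = panel)
}

#' Write a dosage CSV (participants as rows, NA for missing)
#'
#' @param x an [AfCohort-class] or SNPs x participants matrix.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeDosageCsv <- function(x, path) {
    d <- if (is(x, "AfCohort")) dosages(x) else x
    df <- data.frame(participant_id = colnames(d),
                     t(d), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
    invisible(path)
}

#' Extract modeled-allele dosages from a VCF
#'
#' Records are matched to the panel by the VCF ID column (rsid); for each
#' SNP the modeled allele must equal REF or one of the ALT alleles —
#' anything else is a hard error (no strand inference or flipping). Dosage
#' is the count of the modeled allele in GT; a missing genotype
#' (\code{./.}) becomes a missing dosage.
#'
#' @param path VCF (v4.x) path, plain text or bgzipped.
#' @param panel a [SnpPanel-class].
#' @return an [AfCohort-class] with the panel's SNPs as rows.
#' @export
readVcfDosage <- function(path, panel) {
    stopifnot(is(panel, "SnpPanel"))
    vcf <- VariantAnnotation::readVcf(path)
    ids <- names(SummarizedExperiment::rowRanges(vcf))
    absent <- setdiff(panel$rsid, ids)
    if (length(absent))
        stop("panel SNP(s) absent from VCF: ",
             paste(absent, collapse = ", "))
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT genotype field")
    ref <- as.character(VariantAnnotation::ref(vcf))
    alts <- VariantAnnotation::alt(vcf)
    d <- matrix(NA_real_, nrow = nrow(panel), ncol = ncol(gt),
                dimnames = list(panel$rsid, colnames(gt)))
    for (i in seq_len(nrow(panel))) {
        rs <- panel$rsid[i]
        k <- match(rs, ids)
        allele_set <- c(ref[k], as.character(alts[[k]]))
        idx <- match(panel$modeled_allele[i], allele_set) - 1L
        if (is.na(idx))
            stop("modeled allele ", panel$modeled_allele[i], " for ", rs,
                 " matches neither REF nor ALT (",
                 paste(allele_set, collapse = "/"), ")")
        calls <- strsplit(gt[k, ], "[/|]")
        d[i, ] <- vapply(calls, function(a) {
            if (any(a == ".")) NA_real_ else sum(a == as.character(idx))
        }, numeric(1))
    }
    message("read ", ncol(d), " samples x ", nrow(d), " panel SNPs from ",
            path, " (", sum(is.na(d)), " missing genotypes)")
    AfCohort(d, panel = panel)
}

#' Format an association fit as a display table
#'
#' @param assoc an object from [fitGrsModel()].
#' @return data.frame with columns \code{term}, \code{or_ci} (either
#'   \code{"Reference"} or \code{"OR (lo-hi)"}), \code{p_value}.
#' @export
formatAssociation <- function(assoc) {
    stopifnot(inherits(assoc, "afgrsAssociation"))
    tt <- assoc$terms
    data.frame(term = tt$term,
               or_ci = ifelse(is.na(tt$or), "Reference",
                   sprintf("%.2f (%.2f-%.2f)", tt$or, tt$ci_lower,
                           tt$ci_upper)),
               p_value = ifelse(is.na(tt$p_value), "-",
                                signif(tt$p_value, 2)))
}

#' Write analysis reports to JSON and TSV
#'
#' Writes one machine-readable JSON carrying every report plus the run
#' configuration, seed, and package version, and one TSV per tabular
#' report (baseline table, association tables with a \code{Reference} row
#' for the lowest quantile).
#'
#' @param reports non-empty named list; elements may be data.frames,
#'   \code{afgrsAssociation} objects, or plain lists of values.
#' @param dir output directory (created if needed).
#' @param config optional configuration list echoed into the JSON.
#' @param seed the RNG seed of the run, recorded in every output.
#' @return paths of the written files, invisibly.
#' @export
writeReport <- function(reports, dir, config = NULL, seed = NA_integer_) {
    if (!length(reports))
        stop("empty report list")
    if (is.null(names(reports)) || any(names(reports) == ""))
        stop("reports must be a named list")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop("cannot create output directory ", dir)
    payload <- lapply(reports, function(r) {
        if (inherits(r, "afgrsAssociation"))
            list(coding = r$coding, adjusted = r$adjusted,
                 covariates = r$covariates, terms = r$terms)
        else r
    })
    json_path <- file.path(dir, "report.json")
    jsonlite::write_json(
        list(seed = seed, config = config,
             package_version = as.character(utils::packageVersion("afgrs")),
             reports = payload),
        json_path, auto_unbox = TRUE, digits = NA, na = "null",
        force = TRUE)
    paths <- json_path
    for (nm in names(reports)) {
        r <- reports[[nm]]
        tab <- if (inherits(r, "afgrsAssociation")) formatAssociation(r)
               else if (is.data.frame(r)) r
               else next
        p <- file.path(dir, paste0(nm, ".tsv"))
        con <- file(p, "w")
        writeLines(paste0("# seed: ", seed), con)
        utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        close(con)
        paths <- c(paths, p)
    }
    message("wrote ", length(paths), " report file(s) to ", dir)
    invisible(paths)
}
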