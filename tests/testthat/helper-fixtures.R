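# Brute-force per-cell oracle for the weighted allele-counting score:
# deliberately loop-based and independent of the matrix-algebra path.
grsOracle <- function(dosage, panel) {
    out <- numeric(ncol(dosage))
    for (j in seq_len(ncol(dosage))) {
        s <- 0
        for (rs in rownames(dosage)) {
            w <- panel$weight[match(rs, panel$rsid)]
            s <- s + w * dosage[rs, j]
        }
        out[j] <- s
    }
    out
}

# Small two-SNP panel for IO and scan tests.
miniPanel <- function() {
    SnpPanel(data.frame(
        rsid = c("rs2200733", "rs3807989"),
        gene = c("PITX2", "CAV1"),
        locus = c("4q25", "7q31"),
        modeled_allele = c("T", "A"),
        freq = c(0.13, 0.42),
        weight = c(0.54, -0.11)))
}

# Cohort with explicit dosages/covariates/outcome, bypassing the simulator.
manualCohort <- function(dosage, covariates = NULL, af_event = NULL,
                         panel = NULL, imputed = TRUE) {
    AfCohort(dosage, panel = panel, covariates = covariates,
             af_event = af_event, imputed = imputed)
}

# Plain-text VCF fixture; rows are character lines after the sample header.
writeTestVcf <- function(path, body,
                         samples = c("S1", "S2", "S3")) {
    hdr <- c(
        "##fileformat=VCFv4.2",
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(hdr, body), path)
    path
}

# Random dosage matrix over a panel, optionally with missing entries.
randomDosage <- function(panel, n, miss = 0) {
    d <- matrix(sample(0:2, nrow(panel) * n, replace = TRUE),
                nrow = nrow(panel),
                dimnames = list(panel$rsid, sprintf("P%03d", seq_len(n))))
    if (miss > 0) d[sample(length(d), miss)] <- NA
    d
}
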