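#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-test computed directly from (mean, SD, n) per group,
#' with Welch-Satterthwaite degrees of freedom — so published summary tables
#' can be re-tested without raw data. Agrees with
#' \code{t.test(..., var.equal = FALSE)} on raw data.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @examples
#' welchFromSummary(65.9, 11.8, 819, 68.5, 11.2, 85)$p.value
#' @export
welchFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    stat <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    list(statistic = stat, df = df,
         p.value = 2 * stats::pt(-abs(stat), df))
}

#' Yates-corrected chi-squared test from two binomial counts
#'
#' 2x2 continuity-corrected chi-squared test of equal proportions, taking
#' the per-group event counts and sizes as printed in a baseline table.
#'
#' @param x1,n1 events and size in group 1.
#' @param x2,n2 events and size in group 2.
#' @return the \code{htest} from [stats::chisq.test()] with Yates correction.
#' @examples
#' chisqFromCounts(297, 819, 44, 85)$p.value
#' @export
chisqFromCounts <- function(x1, n1, x2, n2) {
    stats::chisq.test(matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2,
                             byrow = TRUE), correct = TRUE)
}

.BASELINE_QUANT <- c("age", "bmi")

#' Baseline characteristics table by AF status
#'
#' Compares every covariate between participants with and without an AF
#' event: quantitative traits by Welch's unequal-variance t-test with
#' mean (SD) summaries, binary traits by Yates-corrected chi-squared with
#' n (percent) summaries. A quantitative trait with fewer than 2
#' observations in a group is flagged untestable (NA p-value).
#'
#' @param cohort an [AfCohort-class] with \code{af_event}.
#' @param quantitative covariate names treated as quantitative; all other
#'   covariates must be binary 0/1.
#' @return data.frame with columns \code{variable}, \code{summary_no_af},
#'   \code{summary_af}, \code{test}, \code{p_value}.
#' @export
baselineTable <- function(cohort, quantitative = .BASELINE_QUANT) {
    ev <- afEvents(cohort)
    cvt <- covariateTable(cohort)
    vars <- setdiff(colnames(cvt), "af_event")
    rows <- lapply(vars, function(v) {
        x0 <- cvt[[v]][ev == 0L]
        x1 <- cvt[[v]][ev == 1L]
        if (v %in% quantitative) {
            s0 <- sprintf("%.1f (%.1f)", mean(x0), stats::sd(x0))
            s1 <- sprintf("%.1f (%.1f)", mean(x1), stats::sd(x1))
            if (length(x0) < 2L || length(x1) < 2L) {
                p <- NA_real_
            } else if (stats::sd(x0) == 0 && stats::sd(x1) == 0 &&
                       mean(x0) == mean(x1)) {
                p <- 1
            } else {
                p <- welchFromSummary(mean(x0), stats::sd(x0), length(x0),
                                      mean(x1), stats::sd(x1),
                                      length(x1))$p.value
            }
            data.frame(variable = v, summary_no_af = s0, summary_af = s1,
                       test = "welch_t", p_value = p)
        } else {
            if (!all(c(x0, x1) %in% c(0, 1)))
                stop("covariate '", v, "' is neither listed quantitative ",
                     "nor binary 0/1")
            s0 <- sprintf("%d (%.0f%%)", sum(x0), 100 * mean(x0))
            s1 <- sprintf("%d (%.0f%%)", sum(x1), 100 * mean(x1))
            p <- suppressWarnings(
                chisqFromCounts(sum(x0), length(x0),
                                sum(x1), length(x1))$p.value)
            data.frame(variable = v, summary_no_af = s0, summary_af = s1,
                       test = "chi_squared", p_value = p)
        }
    })
    do.call(rbind, rows)
}

.ADJUST_COVARIATES <- c("age", "male", "smoker", "bmi", "diabetes",
                        "hypertension", "prior_mi", "heart_failure")

.safeGlm <- function(formula, data) {
    warned <- NULL
    fit <- withCallingHandlers(
        stats::glm(formula, data = data, family = stats::binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                warned <<- conditionMessage(w)
            invokeRestart("muffleWarning")
        })
    if (!fit$converged)
        stop("logistic regression did not converge")
    if (!is.null(warned) || any(abs(stats::coef(fit)) > 15,
                                na.rm = TRUE))
        stop("(quasi-)complete separation in logistic regression: ",
             "estimates are unstable")
    fit
}

.orTable <- function(fit, keep = NULL) {
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]
    se <- sm[, "Std. Error"]
    out <- data.frame(term = rownames(sm),
                      or = exp(est),
                      ci_lower = exp(est - stats::qnorm(0.975) * se),
                      ci_upper = exp(est + stats::qnorm(0.975) * se),
                      p_value = sm[, "Pr(>|z|)"],
                      row.names = NULL)
    if (!is.null(keep)) out <- out[out$term %in% keep, , drop = FALSE]
    out
}

#' Logistic association of a genetic risk score with AF
#'
#' Fits a maximum-likelihood logistic regression of the AF outcome on the
#' GRS under one of four predictor codings, optionally adjusted for
#' clinical covariates. Odds ratios are exponentiated coefficients with
#' 95\% Wald confidence intervals on the log scale.
#'
#' Codings: \code{"sd"} standardizes the score by its sample SD (odds per
#' SD increase); \code{"quintile"} and \code{"tertile"} use dummy-coded
#' groups with the lowest group as reference; \code{"ordinal"} enters the
#' quintile index 1-5 as a single quantitative trend term.
#'
#' @param cohort an [AfCohort-class] with \code{af_event} and (if
#'   \code{adjusted}) the covariate columns.
#' @param grs a [GrsVector-class] for the same participants; quantile labels
#'   are assigned on the fly if needed.
#' @param coding one of \code{"sd"}, \code{"quintile"}, \code{"ordinal"},
#'   \code{"tertile"}.
#' @param adjusted adjust for \code{covariates}?
#' @param covariates covariate names used when \code{adjusted}.
#' @return list of class \code{"afgrsAssociation"}: \code{coding},
#'   \code{adjusted}, \code{covariates}, \code{terms} (data.frame of GRS
#'   term OR/CI/p, with a \code{"Reference"} row for the lowest group under
#'   categorical codings), \code{all_terms}, and the underlying \code{fit}.
#' @examples
#' ch <- simulateCohort(simConfig(n = 600), seed = 3)
#' grs <- computeGrs(imputeMissing(ch))
#' fitGrsModel(ch, grs, coding = "sd", adjusted = FALSE)$terms
#' @export
fitGrsModel <- function(cohort, grs,
                        coding = c("sd", "quintile", "ordinal", "tertile"),
                        adjusted = TRUE,
                        covariates = .ADJUST_COVARIATES) {
    coding <- match.arg(coding)
    ev <- afEvents(cohort)
    if (length(unique(ev)) < 2L)
        stop("outcome must contain both classes")
    s <- scores(grs)
    stopifnot(length(s) == length(ev))
    df <- data.frame(af_event = ev)
    ref_row <- NULL
    if (coding == "sd") {
        df$grs_sd <- (s - mean(s)) / stats::sd(s)
        term <- "grs_sd"
    } else if (coding == "ordinal") {
        q <- quintiles(grs)
        if (anyNA(q)) q <- quintiles(assignQuantiles(grs, 5L))
        df$grs_quintile <- as.numeric(q)
        term <- "grs_quintile"
    } else if (coding == "quintile") {
        q <- quintiles(grs)
        if (anyNA(q)) q <- quintiles(assignQuantiles(grs, 5L))
        df$grs_q <- factor(q, levels = 1:5)
        term <- paste0("grs_q", 2:5)
        ref_row <- data.frame(term = "grs_q1", or = NA, ci_lower = NA,
                              ci_upper = NA, p_value = NA)
    } else {
        tq <- tertiles(grs)
        if (anyNA(tq)) tq <- tertiles(assignQuantiles(grs, 3L))
        df$grs_t <- factor(tq, levels = 1:3)
        term <- paste0("grs_t", 2:3)
        ref_row <- data.frame(term = "grs_t1", or = NA, ci_lower = NA,
                              ci_upper = NA, p_value = NA)
    }
    rhs <- setdiff(colnames(df), "af_event")
    if (adjusted) {
        cvt <- covariateTable(cohort)
        miss <- setdiff(covariates, colnames(cvt))
        if (length(miss))
            stop("cohort lacks adjustment covariates: ",
                 paste(miss, collapse = ", "))
        if (anyNA(cvt[, covariates]))
            stop("missing covariate values; complete data required")
        df <- cbind(df, cvt[, covariates, drop = FALSE])
        rhs <- c(rhs, covariates)
    }
    fit <- .safeGlm(stats::reformulate(rhs, response = "af_event"), df)
    terms <- .orTable(fit, keep = term)
    if (!is.null(ref_row)) terms <- rbind(ref_row, terms)
    structure(list(coding = coding, adjusted = adjusted,
                   covariates = if (adjusted) covariates else character(0),
                   terms = terms, all_terms = .orTable(fit), fit = fit),
              class = "afgrsAssociation")
}

#' @export
print.afgrsAssociation <- function(x, ...) {
    cat("GRS-AF logistic association (", x$coding, " coding, ",
        if (x$adjusted) "adjusted" else "unadjusted", ")\n", sep = "")
    tt <- x$terms
    tt$or <- ifelse(is.na(tt$or), NA, round(tt$or, 3))
    print(tt, row.names = FALSE)
    invisible(x)
}

#' Concordance statistic of a risk predictor
#'
#' The probability that a randomly chosen case outranks a randomly chosen
#' control — the area under the ROC curve.
#'
#' @param predictor numeric risk predictor (higher = riskier).
#' @param outcome binary 0/1 outcome containing both classes.
#' @return the C-statistic in [0, 1].
#' @examples
#' cStatistic(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
#' @export
cStatistic <- function(predictor, outcome) {
    if (length(unique(outcome)) < 2L)
        stop("outcome is degenerate: both classes required")
    as.numeric(pROC::auc(pROC::roc(outcome, predictor, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
}

#' C-statistic gain from adding the GRS to a clinical model
#'
#' Fits two nested logistic models on identical rows — clinical covariates
#' only, and covariates plus the GRS — and compares their C-statistics
#' (area under the ROC curve of fitted probabilities) with the paired
#' DeLong test.
#'
#' @param cohort an [AfCohort-class] with \code{af_event} and covariates.
#' @param grs a [GrsVector-class].
#' @param covariates clinical covariates of the base model.
#' @return list with \code{c_base}, \code{c_full}, \code{p_value}.
#' @export
compareCStatistics <- function(cohort, grs,
                               covariates = .ADJUST_COVARIATES) {
    ev <- afEvents(cohort)
    if (length(unique(ev)) < 2L)
        stop("outcome must contain both classes")
    cvt <- covariateTable(cohort)
    df <- cbind(data.frame(af_event = ev),
                cvt[, covariates, drop = FALSE])
    df$grs <- scores(grs)
    fit_base <- .safeGlm(
        stats::reformulate(covariates, response = "af_event"), df)
    fit_full <- .safeGlm(
        stats::reformulate(c(covariates, "grs"), response = "af_event"), df)
    roc_base <- pROC::roc(df$af_event, stats::fitted(fit_base),
                          quiet = TRUE, direction = "<", levels = c(0, 1))
    roc_full <- pROC::roc(df$af_event, stats::fitted(fit_full),
                          quiet = TRUE, direction = "<", levels = c(0, 1))
    cmp <- pROC::roc.test(roc_base, roc_full, method = "delong",
                          paired = TRUE)
    list(c_base = as.numeric(pROC::auc(roc_base)),
         c_full = as.numeric(pROC::auc(roc_full)),
         p_value = cmp$p.value)
}

#' Per-SNP association scan
#'
#' One logistic fit per panel SNP with additive dosage coding, unadjusted
#' and adjusted for the clinical covariates. Monomorphic SNPs are flagged
#' and not fit. The dosage correlation of the two PITX2 SNPs rs2200733 and
#' rs10033464 (when both are present) is attached as attribute
#' \code{"pitx2_cor"}.
#'
#' @param cohort an [AfCohort-class] with imputed dosages, covariates and
#'   \code{af_event}.
#' @param panel a [SnpPanel-class]; defaults to the cohort's own panel.
#' @param covariates adjustment covariates.
#' @return data.frame with one row per SNP: gene, OR/CI/p unadjusted and
#'   adjusted, a \code{monomorphic} flag, and a \code{flag} column
#'   (\code{"ok"}, \code{"monomorphic"}, or \code{"unstable"} when a fit
#'   separated or failed to converge; unstable estimates are NA rather than
#'   aborting the scan).
#' @export
perSnpScan <- function(cohort, panel = snpPanel(cohort),
                       covariates = .ADJUST_COVARIATES) {
    ev <- afEvents(cohort)
    d <- dosages(cohort)
    if (anyNA(d))
        stop("dosages contain missing values; run imputeMissing() first")
    cvt <- covariateTable(cohort)
    na_fit <- data.frame(or = NA_real_, ci_lower = NA_real_,
                         ci_upper = NA_real_, p_value = NA_real_)
    rows <- lapply(panel$rsid, function(rs) {
        g <- d[rs, ]
        base <- data.frame(rsid = rs, gene = panel$gene[panel$rsid == rs])
        if (length(unique(g)) < 2L)
            return(cbind(base, data.frame(
                or_unadj = NA, ci_lower_unadj = NA, ci_upper_unadj = NA,
                p_unadj = NA, or_adj = NA, ci_lower_adj = NA,
                ci_upper_adj = NA, p_adj = NA, flag = "monomorphic")))
        df <- cbind(data.frame(af_event = ev, dosage = g),
                    cvt[, covariates, drop = FALSE])
        ## a single unstable marker must not abort the whole scan
        tu <- tryCatch(.orTable(.safeGlm(af_event ~ dosage, df),
                                keep = "dosage"),
                       error = function(e) na_fit)
        ta <- tryCatch(.orTable(.safeGlm(
            stats::reformulate(c("dosage", covariates),
                               response = "af_event"), df),
            keep = "dosage"), error = function(e) na_fit)
        flag <- if (anyNA(c(tu$or, ta$or))) "unstable" else "ok"
        cbind(base, data.frame(
            or_unadj = tu$or, ci_lower_unadj = tu$ci_lower,
            ci_upper_unadj = tu$ci_upper, p_unadj = tu$p_value,
            or_adj = ta$or, ci_lower_adj = ta$ci_lower,
            ci_upper_adj = ta$ci_upper, p_adj = ta$p_value,
            flag = flag))
    })
    out <- do.call(rbind, rows)
    out$monomorphic <- out$flag == "monomorphic"
    pair <- c("rs2200733", "rs10033464")
    if (all(pair %in% rownames(d)))
        attr(out, "pitx2_cor") <- stats::cor(d[pair[1], ], d[pair[2], ])
    out
}
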