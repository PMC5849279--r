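#' Default clinical covariate distribution for the synthetic cohort
#'
#' Marginal distributions emulating a symptomatic AF-screening cohort:
#' age truncated-normal with mean 66.2 years (SD 11.8) and a hard 40-year
#' inclusion floor; 38\% male (341/904); 9.3\% current smokers; BMI normal
#' with mean 29.6 kg/m2 (SD 6.8, floored at 15); prevalences 22.2\% diabetes,
#' 76.7\% hypertension, 8.8\% prior myocardial infarction, 5.4\% heart
#' failure. Covariates are drawn independently (margins only, no copula).
#'
#' @return named list of distribution parameters, editable before passing
#'   to [simConfig()].
#' @export
covariateDefaults <- function() {
    list(age_mean = 66.2, age_sd = 11.8, age_min = 40,
         male = 341 / 904,
         smoker = 84 / 904,
         bmi_mean = 29.6, bmi_sd = 6.8, bmi_min = 15,
         diabetes = 201 / 904,
         hypertension = 693 / 904,
         prior_mi = 80 / 904,
         heart_failure = 49 / 904)
}

#' Simulation configuration
#'
#' Bundles everything the cohort simulator needs: cohort size, SNP panel,
#' an optional linkage-disequilibrium (LD) specification for one SNP pair,
#' covariate margins, and an outcome model.
#'
#' @param n cohort size.
#' @param panel a [SnpPanel-class] (genotypes are drawn at its frequencies
#'   under Hardy-Weinberg equilibrium).
#' @param ld \code{NULL} for fully unlinked SNPs, or a list
#'   \code{list(rsid_a=, rsid_b=, D=)} giving the signed haplotype
#'   covariance D for one pair. The default links the two key PITX2 SNPs
#'   rs2200733 and rs10033464 negatively, at half the most negative
#'   admissible D for their frequencies (the true magnitude is a free
#'   parameter; risk alleles at these markers repel each other).
#' @param covariates covariate margins, see [covariateDefaults()].
#' @param outcome either
#'   \code{list(type = "quintile_rates", rates = c(q1..q5))} — each
#'   participant's event probability is the rate of their GRS quintile — or
#'   \code{list(type = "logistic", beta0 =, beta_grs_per_sd =, beta_cov =,
#'   target_rate =)} — Bernoulli(plogis(beta0 + b_g * standardized GRS +
#'   x' beta_cov)), with \code{beta0 = NULL} auto-calibrated by bisection so
#'   the expected marginal event rate equals \code{target_rate}.
#' @param seed integer used by [simulateCohort()] when no seed argument is
#'   given there.
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n = 904,
                      panel = afPanel("af12"),
                      ld = "default",
                      covariates = covariateDefaults(),
                      outcome = list(type = "logistic", beta0 = NULL,
                                     beta_grs_per_sd = log(1.43),
                                     beta_cov = defaultOutcomeBetas(),
                                     target_rate = 85 / 904),
                      seed = 1L) {
    stopifnot(is(panel, "SnpPanel"), n >= 1)
    if (identical(ld, "default")) {
        ld <- NULL
        if (all(c("rs2200733", "rs10033464") %in% panel$rsid)) {
            f <- panelFreqs(panel)
            lo <- ldBounds(f[["rs2200733"]], f[["rs10033464"]])[["lower"]]
            ld <- list(rsid_a = "rs2200733", rsid_b = "rs10033464",
                       D = 0.5 * lo)
        }
    }
    if (!is.null(ld)) {
        stopifnot(all(c("rsid_a", "rsid_b", "D") %in% names(ld)))
        if (!all(c(ld$rsid_a, ld$rsid_b) %in% panel$rsid))
            stop("ld names rsids not in the panel")
        f <- panelFreqs(panel)
        b <- ldBounds(f[[ld$rsid_a]], f[[ld$rsid_b]])
        if (ld$D < b[["lower"]] || ld$D > b[["upper"]])
            stop(sprintf(
                "requested D = %.4g outside admissible range [%.4g, %.4g]",
                ld$D, b[["lower"]], b[["upper"]]))
    }
    prevs <- covariates[c("male", "smoker", "diabetes", "hypertension",
                          "prior_mi", "heart_failure")]
    stopifnot(all(unlist(prevs) >= 0), all(unlist(prevs) <= 1))
    if (identical(outcome$type, "quintile_rates")) {
        stopifnot(length(outcome$rates) == 5L,
                  all(outcome$rates >= 0), all(outcome$rates <= 1))
    } else if (!identical(outcome$type, "logistic")) {
        stop("outcome$type must be 'quintile_rates' or 'logistic'")
    }
    structure(list(n = as.integer(n), panel = panel, ld = ld,
                   covariates = covariates, outcome = outcome,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

#' Default covariate log-odds effects for the logistic outcome model
#'
#' Modest clinically plausible effects: older age, male sex, higher BMI and
#' heart failure increase AF odds; diabetes is mildly protective in this
#' symptomatic-cohort setting; smoking and prior MI are null.
#'
#' @return named numeric vector of log-odds coefficients.
#' @export
defaultOutcomeBetas <- function() {
    c(age = 0.02, male = 0.65, smoker = 0, bmi = 0.04,
      diabetes = -0.6, hypertension = 0.1, prior_mi = 0,
      heart_failure = 0.5)
}

#' Admissible range of the haplotype covariance D for two biallelic SNPs
#'
#' With modeled-allele frequencies p1, p2 the four haplotype frequencies
#' \eqn{p_1 p_2 + D}, \eqn{p_1 (1-p_2) - D}, \eqn{(1-p_1) p_2 - D},
#' \eqn{(1-p_1)(1-p_2) + D} must all be non-negative, bounding D to
#' \eqn{[\max(-p_1 p_2, -(1-p_1)(1-p_2)),\ \min(p_1(1-p_2), (1-p_1)p_2)]}.
#'
#' @param p1,p2 modeled-allele frequencies in (0,1).
#' @return named numeric vector \code{c(lower=, upper=)}.
#' @export
ldBounds <- function(p1, p2) {
    c(lower = max(-p1 * p2, -(1 - p1) * (1 - p2)),
      upper = min(p1 * (1 - p2), (1 - p1) * p2))
}

.drawLdPair <- function(n, p1, p2, D) {
    h <- c(p1 * p2 + D, p1 * (1 - p2) - D, (1 - p1) * p2 - D,
           (1 - p1) * (1 - p2) + D)   # haplotypes 11, 10, 01, 00
    if (any(h < -1e-12))
        stop("haplotype frequencies negative; D outside admissible range")
    h <- pmax(h, 0); h <- h / sum(h)
    ## two haplotypes per participant; dosage = allele count over the pair
    hap1 <- sample.int(4L, n, replace = TRUE, prob = h)
    hap2 <- sample.int(4L, n, replace = TRUE, prob = h)
    a_of <- c(1L, 1L, 0L, 0L)   # copies of allele at SNP a per haplotype
    b_of <- c(1L, 0L, 1L, 0L)
    cbind(a = a_of[hap1] + a_of[hap2], b = b_of[hap1] + b_of[hap2])
}

#' Simulate Hardy-Weinberg genotypes with optional pairwise LD
#'
#' Each SNP's dosage is Binomial(2, freq) per participant (random mating);
#' the configured LD pair is drawn instead from the two-SNP haplotype
#' distribution with the requested signed D, which preserves both marginal
#' frequencies exactly in expectation.
#'
#' @param config a [simConfig()] object.
#' @return an [AfCohort-class] carrying only genotypes (panel in rowData).
#' @export
simulateGenotypes <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    panel <- config$panel
    n <- config$n
    f <- panelFreqs(panel)
    d <- vapply(f, function(p) stats::rbinom(n, 2L, p), integer(n))
    d <- t(matrix(d, nrow = n, dimnames = list(NULL, names(f))))
    colnames(d) <- sprintf("P%04d", seq_len(n))
    if (!is.null(config$ld)) {
        ab <- .drawLdPair(n, f[[config$ld$rsid_a]], f[[config$ld$rsid_b]],
                          config$ld$D)
        d[config$ld$rsid_a, ] <- ab[, "a"]
        d[config$ld$rsid_b, ] <- ab[, "b"]
    }
    AfCohort(d, panel = panel)
}

.rtruncnorm_low <- function(n, mean, sd, lower) {
    ## rejection sampling at the lower bound; fine for mild truncation
    out <- numeric(0)
    while (length(out) < n) {
        x <- stats::rnorm(2L * (n - length(out)), mean, sd)
        out <- c(out, x[x >= lower])
    }
    out[seq_len(n)]
}

.truncMean <- function(mu, sd, lower) {
    a <- (lower - mu) / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

## shift the pre-truncation location so the truncated mean hits the target
.truncLocation <- function(target_mean, sd, lower) {
    stats::uniroot(function(mu) .truncMean(mu, sd, lower) - target_mean,
                   c(target_mean - 4 * sd, target_mean), tol = 1e-8,
                   extendInt = "upX")$root
}

#' Simulate clinical covariates
#'
#' Age and BMI are truncated-normal; the pre-truncation location is shifted
#' (numerically) so the post-truncation mean equals the configured target
#' mean. Binary covariates are Bernoulli at their configured prevalences,
#' drawn independently.
#'
#' @param config a [simConfig()] object; margins come from
#'   \code{config$covariates}.
#' @return data.frame with columns age, male, smoker, bmi, diabetes,
#'   hypertension, prior_mi, heart_failure.
#' @export
simulateCovariates <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    cv <- config$covariates
    n <- config$n
    mu_age <- .truncLocation(cv$age_mean, cv$age_sd, cv$age_min)
    mu_bmi <- .truncLocation(cv$bmi_mean, cv$bmi_sd, cv$bmi_min)
    data.frame(
        age = .rtruncnorm_low(n, mu_age, cv$age_sd, cv$age_min),
        male = stats::rbinom(n, 1L, cv$male),
        smoker = stats::rbinom(n, 1L, cv$smoker),
        bmi = .rtruncnorm_low(n, mu_bmi, cv$bmi_sd, cv$bmi_min),
        diabetes = stats::rbinom(n, 1L, cv$diabetes),
        hypertension = stats::rbinom(n, 1L, cv$hypertension),
        prior_mi = stats::rbinom(n, 1L, cv$prior_mi),
        heart_failure = stats::rbinom(n, 1L, cv$heart_failure))
}

.calibrateIntercept <- function(eta, target_rate, lo = -25, hi = 25) {
    f <- function(b0) mean(stats::plogis(b0 + eta)) - target_rate
    if (f(lo) > 0 || f(hi) < 0)
        stop("intercept calibration failed to bracket target rate ",
             target_rate)
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Attach a simulated AF outcome to a cohort
#'
#' In \code{quintile_rates} mode, participants are stratified into GRS
#' quintiles (sample quantiles of the simulated scores) and events are drawn
#' Bernoulli at each quintile's configured absolute rate. In \code{logistic}
#' mode events follow Bernoulli(plogis(beta0 + b_g * z + x' beta_cov)) with
#' z the GRS standardized by its sample mean and SD ("per SD"); a NULL
#' beta0 is calibrated by bisection so the expected marginal rate hits
#' \code{target_rate}.
#'
#' @param cohort an [AfCohort-class] with genotypes (and, for logistic mode
#'   with covariate effects, the covariate columns).
#' @param config a [simConfig()] object.
#' @return the cohort with an \code{af_event} column in \code{colData}.
#' @export
simulateOutcome <- function(cohort, config) {
    stopifnot(is(cohort, "AfCohort"), inherits(config, "SimConfig"))
    grs <- computeGrs(imputeMissing(cohort), config$panel)
    s <- scores(grs)
    om <- config$outcome
    if (identical(om$type, "quintile_rates")) {
        q <- quintiles(assignQuantiles(grs, 5L))
        pr <- om$rates[q]
    } else {
        z <- (s - mean(s)) / stats::sd(s)
        eta <- om$beta_grs_per_sd * z
        bc <- om$beta_cov
        if (length(bc)) {
            cvt <- covariateTable(cohort)
            miss <- setdiff(names(bc), colnames(cvt))
            if (length(miss))
                stop("beta_cov names covariates absent from the cohort: ",
                     paste(miss, collapse = ", "))
            eta <- eta + as.numeric(
                as.matrix(cvt[, names(bc), drop = FALSE]) %*% bc)
        }
        b0 <- om$beta0
        if (is.null(b0)) b0 <- .calibrateIntercept(eta, om$target_rate)
        pr <- stats::plogis(b0 + eta)
    }
    colData(cohort)$af_event <- stats::rbinom(ncol(cohort), 1L, pr)
    validObject(cohort)
    cohort
}

#' Simulate a complete synthetic cohort
#'
#' Genotypes (HWE with the configured LD pair), independent clinical
#' covariates, and a binary AF outcome, in one reproducible draw.
#'
#' @param config a [simConfig()] object.
#' @param seed integer RNG seed; defaults to \code{config$seed}.
#' @return an [AfCohort-class] with dosages, covariates and af_event.
#' @examples
#' cohort <- simulateCohort(simConfig(n = 200), seed = 7)
#' cohort
#' @export
simulateCohort <- function(config = simConfig(), seed = config$seed) {
    set.seed(seed)
    geno <- simulateGenotypes(config)
    cvt <- simulateCovariates(config)
    colData(geno) <- cbind(colData(geno),
                           as(cvt, "DataFrame"))
    simulateOutcome(geno, config)
}
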