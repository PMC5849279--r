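#' Quintile-gradient power design
#'
#' The prospective design: n participants split evenly over 5 GRS quintiles,
#' with the absolute AF rate rising by \code{per_quintile_step} per quintile
#' around \code{mean_rate} — so the lowest quintile sits at half the
#' population average and the highest at 1.5 times it under the defaults
#' (rates 4/6/8/10/12\% around 8\%).
#'
#' @param n cohort size (divisible by 5 after rounding; 200/quintile by
#'   default).
#' @param mean_rate population-average event probability.
#' @param per_quintile_step absolute probability increment per quintile.
#' @param alpha two-sided test size.
#' @param n_replicates Monte-Carlo replicates.
#' @param test \code{"ordinal_logistic_wald"} (Wald test on the quintile
#'   index coefficient in a logistic fit) or \code{"chi_squared_trend"}
#'   (Cochran-Armitage style trend test).
#' @return a validated list of class \code{"PowerDesign"}.
#' @export
powerDesign <- function(n = 1000, mean_rate = 0.08,
                        per_quintile_step = 0.02, alpha = 0.05,
                        n_replicates = 2000,
                        test = c("ordinal_logistic_wald",
                                 "chi_squared_trend")) {
    test <- match.arg(test)
    rates <- mean_rate + per_quintile_step * (1:5 - 3)
    if (any(rates < 0) || any(rates > 1))
        stop("quintile rates fall outside [0,1]: ",
             paste(round(rates, 4), collapse = ", "))
    stopifnot(alpha > 0, alpha < 1, n >= 5, n_replicates >= 1)
    structure(list(n = as.integer(n), mean_rate = mean_rate,
                   per_quintile_step = per_quintile_step,
                   rates = rates, alpha = alpha,
                   n_replicates = as.integer(n_replicates), test = test),
              class = "PowerDesign")
}

.quintileTestP <- function(events, n_per, test) {
    if (test == "ordinal_logistic_wald") {
        fit <- suppressWarnings(stats::glm(
            cbind(events, n_per - events) ~ seq_along(events),
            family = stats::binomial()))
        summary(fit)$coefficients[2, "Pr(>|z|)"]
    } else {
        stats::prop.trend.test(events, rep(n_per, length(events)),
                               score = seq_along(events))$p.value
    }
}

#' Monte-Carlo power of the quintile-association test
#'
#' Per replicate: assign \code{n} participants evenly to 5 quintiles, draw
#' event counts Binomial at each quintile's rate, and test the
#' quintile-event association. Power is the fraction of replicates with
#' p below \code{alpha}; a replicate with zero events counts as a
#' non-rejection. The analytic expected event count \code{n * mean_rate}
#' is returned alongside the empirical mean.
#'
#' @param design a [powerDesign()] object.
#' @param seed integer RNG seed.
#' @return list of class \code{"PowerResult"}: \code{power}, binomial
#'   Monte-Carlo standard error \code{mc_se}, \code{mean_events},
#'   \code{expected_events}, \code{per_quintile_rates} (empirical),
#'   \code{n_zero_event_replicates}, plus the design and seed.
#' @examples
#' runPower(powerDesign(n_replicates = 200), seed = 1)$power
#' @export
runPower <- function(design = powerDesign(), seed = 1L) {
    stopifnot(inherits(design, "PowerDesign"))
    set.seed(seed)
    n_per <- round(design$n / 5)
    reps <- design$n_replicates
    reject <- logical(reps)
    total <- numeric(reps)
    qsum <- numeric(5)
    zero <- 0L
    for (r in seq_len(reps)) {
        ev <- stats::rbinom(5L, n_per, design$rates)
        total[r] <- sum(ev)
        qsum <- qsum + ev
        if (total[r] == 0L) {
            zero <- zero + 1L
            reject[r] <- FALSE
            next
        }
        reject[r] <- .quintileTestP(ev, n_per, design$test) < design$alpha
    }
    p_hat <- mean(reject)
    structure(list(power = p_hat,
                   mc_se = sqrt(p_hat * (1 - p_hat) / reps),
                   mean_events = mean(total),
                   expected_events = design$n / 5 * sum(design$rates),
                   per_quintile_rates = qsum / (n_per * reps),
                   n_zero_event_replicates = zero,
                   design = design, seed = as.integer(seed)),
              class = "PowerResult")
}

#' @export
print.PowerResult <- function(x, ...) {
    d <- x$design
    cat(sprintf(
        "Monte-Carlo power (%s), %d replicates, n = %d, alpha = %g\n",
        d$test, d$n_replicates, d$n, d$alpha))
    cat(sprintf("  quintile rates: %s\n",
                paste(sprintf("%.0f%%", 100 * d$rates), collapse = "/")))
    cat(sprintf("  power = %.3f (MC SE %.4f)\n", x$power, x$mc_se))
    cat(sprintf("  events: mean %.1f (analytic expectation %.1f)\n",
                x$mean_events, x$expected_events))
    invisible(x)
}
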