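# Frozen textbook oracle for the 2x2 continuity-corrected statistic:
# N(max(0, |ad-bc|-N/2))^2 / (r1 r2 c1 c2).
yatesOracle <- function(a, b, c, d) {
    a <- as.numeric(a); b <- as.numeric(b)
    c <- as.numeric(c); d <- as.numeric(d)
    N <- a + b + c + d
    num <- N * max(0, abs(a * d - b * c) - N / 2)^2
    den <- (a + b) * (c + d) * (a + c) * (b + d)
    stat <- num / den
    pchisq(stat, df = 1, lower.tail = FALSE)
}

test_that("summary-statistic Welch test agrees with t.test on raw data", {
    set.seed(21)
    for (i in 1:15) {
        x <- rnorm(sample(5:80, 1), mean = runif(1, -2, 2),
                   sd = runif(1, 0.5, 3))
        y <- rnorm(sample(5:80, 1), mean = runif(1, -2, 2),
                   sd = runif(1, 0.5, 3))
        ref <- t.test(x, y, var.equal = FALSE)
        got <- welchFromSummary(mean(x), sd(x), length(x),
                                mean(y), sd(y), length(y))
        expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
        expect_equal(got$df, unname(ref$parameter), tolerance = 1e-8)
    }
})

test_that("corrected chi-squared matches the textbook formula on 2x2 tables", {
    set.seed(22)
    for (i in 1:25) {
        cells <- sample(1:400, 4, replace = TRUE)
        got <- suppressWarnings(
            chisqFromCounts(cells[1], cells[1] + cells[2],
                            cells[3], cells[3] + cells[4])$p.value)
        expect_equal(got, yatesOracle(cells[1], cells[2], cells[3],
                                      cells[4]), tolerance = 1e-10)
    }
})

test_that("baseline table reproduces group comparisons from raw columns", {
    # rebuild the male row of a published-style baseline table: counts
    # 297/819 without AF vs 44/85 with AF
    n0 <- 819; n1 <- 85
    male <- c(rep(c(1, 0), c(297, n0 - 297)), rep(c(1, 0), c(44, n1 - 44)))
    age <- c(rnorm(n0, 66, 12), rnorm(n1, 68, 11))
    ev <- rep(c(0L, 1L), c(n0, n1))
    d <- matrix(rep(0:2, length.out = 2 * (n0 + n1)), nrow = 2,
                dimnames = list(miniPanel()$rsid,
                                sprintf("P%04d", 1:(n0 + n1))))
    ch <- manualCohort(d, covariates = data.frame(age = age, male = male),
                       af_event = ev, panel = miniPanel())
    bt <- baselineTable(ch)
    expect_equal(bt$test, c("welch_t", "chi_squared"))
    expect_equal(bt$p_value[bt$variable == "male"],
                 chisqFromCounts(297, n0, 44, n1)$p.value)
    expect_equal(round(bt$p_value[bt$variable == "male"], 3), 0.007)
    expect_equal(bt$summary_af[bt$variable == "male"], "44 (52%)")
    expect_equal(bt$p_value[bt$variable == "age"],
                 welchFromSummary(mean(age[ev == 0]), sd(age[ev == 0]), n0,
                                  mean(age[ev == 1]), sd(age[ev == 1]),
                                  n1)$p.value)
})

test_that("identical quantitative groups give p = 1", {
    d <- matrix(0:1, nrow = 1, ncol = 8,
                dimnames = list("rs2200733", paste0("P", 1:8)))
    ch <- manualCohort(d, covariates = data.frame(age = rep(50, 8)),
                       af_event = rep(c(0L, 1L), each = 4))
    expect_equal(baselineTable(ch)$p_value, 1)
})

test_that("saturated 2x2 logistic fit recovers the closed-form odds ratio", {
    # binary dosage: a,b = events/non-events at dosage 1; c,d at dosage 0
    a <- 30; b <- 70; c <- 15; d <- 85
    g <- rep(c(1, 1, 0, 0), c(a, b, c, d))
    ev <- rep(c(1L, 0L, 1L, 0L), c(a, b, c, d))
    dm <- matrix(g, nrow = 1,
                 dimnames = list("rs2200733", sprintf("P%03d", seq_along(g))))
    p1 <- SnpPanel(as.data.frame(miniPanel())[1, , drop = FALSE])
    ch <- manualCohort(dm, af_event = ev, panel = p1)
    scan <- perSnpScan(ch, p1, covariates = character(0))
    expect_equal(scan$or_unadj, (a * d) / (b * c), tolerance = 1e-6)
    expect_true(scan$ci_lower_unadj < scan$or_unadj)
    expect_true(scan$ci_upper_unadj > scan$or_unadj)
})

test_that("per-SD and quintile codings behave on an informative cohort", {
    set.seed(23)
    cfg <- simConfig(n = 6000, outcome = list(
        type = "quintile_rates", rates = c(0.03, 0.06, 0.09, 0.12, 0.15)))
    ch <- simulateCohort(cfg, seed = 23)
    grs <- assignQuantiles(assignQuantiles(
        computeGrs(imputeMissing(ch)), 5), 3)
    fq <- fitGrsModel(ch, grs, coding = "quintile", adjusted = FALSE)
    expect_equal(fq$terms$term, paste0("grs_q", 1:5))
    expect_true(is.na(fq$terms$or[1]))             # reference quintile
    ors <- fq$terms$or[-1]
    expect_true(all(diff(ors) > -0.5))             # rising gradient
    expect_gt(ors[4], 2)
    expect_true(all(fq$terms$ci_lower[-1] <= ors &
                    ors <= fq$terms$ci_upper[-1]))
    fs <- fitGrsModel(ch, grs, coding = "sd", adjusted = FALSE)
    expect_gt(fs$terms$or, 1.2)
    ft <- fitGrsModel(ch, grs, coding = "tertile", adjusted = FALSE)
    expect_equal(ft$terms$term, paste0("grs_t", 1:3))
    fo <- fitGrsModel(ch, grs, coding = "ordinal", adjusted = FALSE)
    expect_gt(fo$terms$or, 1)
})

test_that("ordinal and continuous codings coincide when scores are quintile indices", {
    set.seed(24)
    g <- computeGrs(randomDosage(afPanel("af12"), 500), afPanel("af12"))
    g@score <- as.numeric(sample(1:5, 500, replace = TRUE))
    g <- assignQuantiles(g, 5)
    expect_equal(unname(quintiles(g)), as.integer(scores(g)))
    ev <- rbinom(500, 1, plogis(-2.5 + 0.3 * scores(g)))
    d <- matrix(rep(0:1, 500), nrow = 2, ncol = 500,
                dimnames = list(miniPanel()$rsid, g@participant_ids))
    ch <- manualCohort(d, af_event = ev, panel = miniPanel())
    f_sd <- fitGrsModel(ch, g, coding = "sd", adjusted = FALSE)
    f_or <- fitGrsModel(ch, g, coding = "ordinal", adjusted = FALSE)
    # same fit up to an affine predictor rescale: identical z and p
    expect_equal(f_sd$terms$p_value, f_or$terms$p_value, tolerance = 1e-9)
    expect_equal(log(f_sd$terms$or) / sd(scores(g)), log(f_or$terms$or),
                 tolerance = 1e-6)
})

test_that("perfect separation errors in model fits and is flagged in scans", {
    g <- rep(c(2, 0), each = 30)
    ev <- rep(c(1L, 0L), each = 30)
    dm <- matrix(g, nrow = 1,
                 dimnames = list("rs2200733", sprintf("P%02d", 1:60)))
    p1 <- SnpPanel(as.data.frame(miniPanel())[1, , drop = FALSE])
    ch <- manualCohort(dm, af_event = ev, panel = p1)
    # a GRS whose scores separate the outcome: explicit refusal, not a
    # silently huge coefficient
    grs <- computeGrs(dm, p1)
    expect_error(fitGrsModel(ch, grs, coding = "sd", adjusted = FALSE),
                 "separation")
    # the per-SNP scan flags the marker and carries on
    scan <- perSnpScan(ch, p1, covariates = character(0))
    expect_equal(scan$flag, "unstable")
    expect_true(is.na(scan$or_unadj))
})

test_that("C-statistic is 1 for a perfect ranking and ~0.5 for noise", {
    expect_equal(cStatistic(c(9, 8, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0)), 1)
    set.seed(25)
    x <- rnorm(4000)
    y <- rbinom(4000, 1, 0.3)
    expect_lt(abs(cStatistic(x, y) - 0.5), 0.03)
    expect_error(cStatistic(x, rep(0, 4000)), "degenerate")
})

test_that("adding an informative GRS raises the C-statistic", {
    set.seed(26)
    wins <- vapply(1:10, function(i) {
        ch <- simulateCohort(simConfig(n = 904), seed = 300 + i)
        grs <- computeGrs(imputeMissing(ch))
        cs <- compareCStatistics(ch, grs)
        expect_true(cs$c_base >= 0.5 && cs$c_base <= 1)
        expect_true(cs$c_full >= 0.5 && cs$c_full <= 1)
        cs$c_full > cs$c_base
    }, logical(1))
    expect_gte(sum(wins), 8)   # in expectation c_full exceeds c_base
})

test_that("per-SNP scan flags monomorphic markers and reports PITX2 repulsion", {
    set.seed(27)
    ch <- simulateCohort(simConfig(n = 1500), seed = 27)
    d <- dosages(ch)
    d["rs7164883", ] <- 0                     # make one marker monomorphic
    ch2 <- manualCohort(d, covariates = covariateTable(ch)[
        setdiff(colnames(covariateTable(ch)), "af_event")],
        af_event = afEvents(ch), panel = afPanel("af12"))
    scan <- perSnpScan(ch2)
    expect_equal(nrow(scan), 12L)
    expect_true(scan$monomorphic[scan$rsid == "rs7164883"])
    expect_true(is.na(scan$or_adj[scan$rsid == "rs7164883"]))
    expect_false(any(scan$monomorphic[scan$rsid != "rs7164883"]))
    expect_lt(attr(scan, "pitx2_cor"), 0)
    ok <- !scan$monomorphic
    expect_true(all(scan$ci_lower_unadj[ok] <= scan$or_unadj[ok] &
                    scan$or_unadj[ok] <= scan$ci_upper_unadj[ok]))
})

test_that("Wald interval width shrinks roughly like 1/sqrt(n)", {
    set.seed(28)
    width <- vapply(c(500, 2000, 8000), function(n) {
        cfg <- simConfig(n = n)
        ch <- simulateCohort(cfg, seed = n)
        f <- fitGrsModel(ch, computeGrs(imputeMissing(ch)), coding = "sd",
                         adjusted = FALSE)
        log(f$terms$ci_upper) - log(f$terms$ci_lower)
    }, numeric(1))
    expect_true(all(diff(width) < 0))
    expect_lt(width[3], width[1] / 2)   # 16x n -> ~4x narrower
})
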