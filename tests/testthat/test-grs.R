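test_that("score matches the brute-force oracle on small matrices", {
    set.seed(42)
    p12 <- afPanel("af12")
    for (i in 1:20) {
        np <- sample(1:3, 1)
        nj <- sample(1:5, 1)
        sub <- SnpPanel(as.data.frame(p12)[sample(12, np), , drop = FALSE])
        d <- randomDosage(sub, nj)
        expect_equal(unname(scores(computeGrs(d, sub))),
                     grsOracle(d, sub), tolerance = 1e-12)
    }
})

test_that("published single-SNP and all-zero score examples hold", {
    p <- afPanel("af12")
    d <- matrix(0, 12, 3, dimnames = list(p$rsid, c("a", "b", "c")))
    expect_equal(unname(scores(computeGrs(d, p))), c(0, 0, 0))
    d["rs2200733", "b"] <- 2           # two copies of the PITX2 risk allele
    d[, "c"] <- 1                      # heterozygous everywhere
    s <- scores(computeGrs(d, p))
    expect_equal(unname(s["b"]), 1.08)
    expect_equal(unname(s["c"]), grsOracle(d, p)[3])  # = sum of weights
    expect_equal(unname(s["c"]), 1.02, tolerance = 1e-12)
})

test_that("scores are linear in dosage and bounded by the extreme genotypes", {
    set.seed(7)
    p <- afPanel("af12")
    lower <- 2 * sum(p$weight[p$weight < 0])   # -1.42
    upper <- 2 * sum(p$weight[p$weight > 0])   #  3.46
    expect_equal(lower, -1.42)
    expect_equal(upper, 3.46)
    for (i in 1:10) {
        d <- matrix(runif(12 * 8, 0, 2), 12, 8,
                    dimnames = list(p$rsid, paste0("P", 1:8)))
        s <- scores(computeGrs(d, p))
        expect_true(all(s >= lower - 1e-12 & s <= upper + 1e-12))
        a <- runif(1, 0.1, 1)          # scaling keeps dosages in [0,2]
        expect_equal(unname(scores(computeGrs(a * d, p))), unname(a * s),
                     tolerance = 1e-12)
    }
})

test_that("computeGrs rejects missing dosages and unmatched rsids", {
    p <- afPanel("af12")
    d <- randomDosage(p, 4, miss = 2)
    expect_error(computeGrs(d, p), "missing")
    d2 <- randomDosage(p, 4)
    rownames(d2)[1] <- "rs0000001"
    expect_error(computeGrs(d2, p), "rs0000001")
    expect_error(computeGrs(d2, p), "rs13376333")
})

test_that("mean imputation fills gaps without touching observed data", {
    p <- afPanel("af12")
    d <- matrix(c(0, 1, 2, NA), nrow = 1,
                dimnames = list("rs2200733", paste0("P", 1:4)))
    expect_equal(unname(imputeMissing(d)[1, 4]), 1.0)  # mean of 0,1,2

    full <- randomDosage(p, 6)
    expect_identical(imputeMissing(full), full)        # identity case

    set.seed(3)
    holey <- randomDosage(p, 50, miss = 30)
    imp <- imputeMissing(holey)
    expect_false(anyNA(imp))
    obs <- !is.na(holey)
    expect_equal(imp[obs], as.numeric(holey[obs]))
    # observed per-marker means preserved exactly
    for (i in seq_len(nrow(holey)))
        expect_equal(mean(imp[i, ]), mean(holey[i, ], na.rm = TRUE),
                     tolerance = 1e-12)
})

test_that("a fully missing marker errors without a panel, falls back to 2f with one", {
    p <- miniPanel()
    d <- matrix(c(NA, NA, NA, 1, 0, 2), nrow = 2, byrow = TRUE,
                dimnames = list(p$rsid, paste0("P", 1:3)))
    expect_error(imputeMissing(d), "no observed")
    expect_message(imp <- imputeMissing(d, panel = p), "2 x modeled-allele")
    expect_equal(unname(imp[1, ]), rep(2 * 0.13, 3))
})

test_that("imputation through the cohort container marks it imputed", {
    p <- afPanel("af12")
    ch <- AfCohort(randomDosage(p, 20, miss = 5), panel = p)
    imp <- imputeMissing(ch)
    expect_false(anyNA(dosages(imp)))
    expect_true(S4Vectors::metadata(imp)$imputed)
    # 15 missing among 904 x 12 genotypes is a 0.14% missing rate
    expect_equal(round(100 * 15 / (904 * 12), 2), 0.14)
})

test_that("quantile groups use closed-upper intervals and near-equal sizes", {
    g <- computeGrs(matrix(0, 2, 5, dimnames = list(
        miniPanel()$rsid, letters[1:5])), miniPanel())
    g@score <- as.numeric(1:5)
    expect_equal(unname(quintiles(assignQuantiles(g, 5))), 1:5)

    set.seed(11)
    ch <- simulateCohort(simConfig(n = 904), seed = 11)
    grs <- assignQuantiles(computeGrs(imputeMissing(ch)), 5)
    q <- quintiles(grs)
    b <- quantileBounds(grs, 5)
    s <- scores(grs)
    # membership: score <= bound -> lower group; monotone in score
    expect_equal(unname(q),
                 unname(vapply(s, function(v) sum(v > b), 0L)) + 1L)
    expect_true(all(diff(q[order(s)]) >= 0))
    expect_true(all(abs(table(q) - 904 / 5) < 25))  # ties allow imbalance

    # scores sitting exactly on a cut point go to the lower group
    g@score <- c(1, 2, 2, 3, 4)   # with k=3, upper tertile bound region tied
    t3 <- assignQuantiles(g, 3)
    bt <- quantileBounds(t3, 3)
    expect_true(all(scores(t3)[tertiles(t3) == 1] <= bt[1]))
})

test_that("quantile labels are invariant to monotone score transforms", {
    set.seed(5)
    g <- computeGrs(randomDosage(afPanel("af12"), 120), afPanel("af12"))
    q1 <- quintiles(assignQuantiles(g, 5))
    g2 <- g
    g2@score <- exp(3 * g@score) - 1   # strictly increasing transform
    expect_equal(quintiles(assignQuantiles(g2, 5)), q1)
})

test_that("degenerate score vectors cannot be stratified", {
    g <- computeGrs(matrix(1, 2, 6, dimnames = list(
        miniPanel()$rsid, letters[1:6])), miniPanel())
    expect_error(assignQuantiles(g, 5), "distinct")
    g@score <- rep(c(1, 2), 3)
    expect_error(assignQuantiles(g, 3), "distinct")
})
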