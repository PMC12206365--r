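test_that("GISTIC levels classify bijectively with loss/gain flags", {
    cls <- classifyCna(c(-2, -1, 0, 1, 2))
    expect_identical(cls$category,
                     c("deep_deletion", "shallow_deletion", "diploid",
                       "gain", "amplification"))
    expect_identical(cls$loss, c(TRUE, TRUE, FALSE, FALSE, FALSE))
    expect_identical(cls$gain, c(FALSE, FALSE, FALSE, TRUE, TRUE))
    expect_error(classifyCna(3), "GISTIC")
})

test_that("CNA summary reproduces printed-count arithmetic", {
    s <- cnaSummary(list(total = 10712, loss = 3373, gain = 940))
    expect_equal(s$pct_loss, 31.5)
    expect_equal(s$pct_gain, 8.8)
    expect_equal(s$pct_diploid, 59.7)
    expect_equal(s$loss_gain_ratio, 3.6)

    # per-type percentages sum to 100 up to rounding; all-diploid flagged
    set.seed(5)
    cna <- data.frame(sample_id = sprintf("s%03d", 1:300),
                      cancer_type = sample(c("AA", "BB"), 300, TRUE),
                      gistic_level = sample(-2:2, 300, TRUE))
    s2 <- cnaSummary(cna)
    expect_true(all(abs(s2$pct_loss + s2$pct_gain + s2$pct_diploid - 100)
                    <= 0.3))
    dip <- cnaSummary(data.frame(sample_id = "a", cancer_type = "X",
                                 gistic_level = 0))
    expect_equal(dip$pct_loss[1], 0)
    expect_true(is.na(dip$loss_gain_ratio[1]))
})

test_that("co-occurrence fractions hit the degenerate cases", {
    cna <- data.frame(sample_id = c("a", "b", "c"), cancer_type = "X",
                      gistic_level = c(-1, -2, 0))
    arm <- data.frame(sample_id = c("a", "b", "c"), arm = "3p",
                      status = c("loss", "loss", "unchanged"))
    co <- cooccurrenceFraction(cna, arm, "loss", "loss", arm = "3p")
    expect_equal(co$fraction[co$cancer_type == "overall"], 1)
    # no gene-gain samples -> NA
    cog <- cooccurrenceFraction(cna, arm, "gain", "gain", arm = "3p")
    expect_true(is.na(cog$fraction[cog$cancer_type == "overall"]))
    # sample order invariance
    perm <- sample(3)
    co2 <- cooccurrenceFraction(cna[perm, ], arm, "loss", "loss", arm = "3p")
    expect_equal(co2$fraction, co$fraction)
    # samples missing arm status are excluded and tallied
    arm2 <- arm[-1, ]
    co3 <- cooccurrenceFraction(cna, arm2, "loss", "loss", arm = "3p")
    expect_equal(attr(co3, "excluded"), 1L)
})

test_that("planted co-occurrence is recovered within the binomial CI", {
    pt <- data.frame(cancer_type = "SIM", n = 2000L, p_loss = 0.4,
                     p_gain = 0.1, p_arm_loss_given_loss = 0.88,
                     hazard_ratio_loss = 1, censor_rate = 0.02)
    g <- genCnaSurvival(pt, seed = 17)
    co <- cooccurrenceFraction(g$cna, g$armStatus, "loss", "loss",
                               arm = "3p")
    frac <- co$fraction[co$cancer_type == "overall"]
    n_loss <- co$n_gene_event[co$cancer_type == "overall"]
    ci <- 2.576 * sqrt(0.88 * 0.12 / n_loss)   # 99% binomial CI
    expect_lt(abs(frac - 0.88), ci)
    # deterministic degenerate case
    pt2 <- pt; pt2$p_arm_loss_given_loss <- 1
    g2 <- genCnaSurvival(pt2, seed = 1)
    co2 <- cooccurrenceFraction(g2$cna, g2$armStatus, "loss", "loss",
                                arm = "3p")
    expect_equal(co2$fraction[co2$cancer_type == "overall"], 1)
})

test_that("KM estimator matches hand and brute-force computations", {
    # hand-computed: events at 1 and 3, censoring at 2
    km <- kmEstimate(data.frame(time = c(1, 2, 3),
                                event = c(TRUE, FALSE, TRUE)))
    expect_equal(km$survival, c(2 / 3, 2 / 3, 0))
    # no events -> S(t) = 1 throughout
    km0 <- kmEstimate(data.frame(time = 1:4, event = FALSE))
    expect_true(all(km0$survival == 1))
    # S is non-increasing and matches a brute-force product on random data
    set.seed(23)
    for (rep in 1:10) {
        df <- data.frame(time = sample(1:8, 30, TRUE),
                         event = sample(c(TRUE, FALSE), 30, TRUE))
        km2 <- kmEstimate(df)
        expect_true(all(diff(km2$survival) <= 1e-12))
        expect_equal(km2$survival[km2$n_event > 0],
                     bruteKM(df$time, df$event,
                             km2$time[km2$n_event > 0]))
    }
})

test_that("log-rank matches the O-E/V oracle and label swaps", {
    set.seed(7)
    df <- data.frame(time = c(rexp(40, 0.2), rexp(40, 0.4)),
                     event = sample(c(TRUE, FALSE), 80, TRUE, c(0.8, 0.2)),
                     group = rep(c("a", "b"), each = 40))
    lr <- logrankTest(df)
    expect_lt(abs(lr$chi2 - bruteLogrank(df$time, df$event, df$group)),
              1e-10)
    # label swap invariance
    df2 <- df
    df2$group <- ifelse(df$group == "a", "b", "a")
    expect_equal(logrankTest(df2)$chi2, lr$chi2)
    # identical groups -> chi2 0, p 1
    same <- data.frame(time = rep(c(1, 2, 3, 4), 2),
                       event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
                       group = rep(c("a", "b"), each = 4))
    lrs <- logrankTest(same)
    expect_equal(lrs$chi2, 0, tolerance = 1e-12)
    expect_equal(lrs$p, 1, tolerance = 1e-12)
    # no events -> undefined flag
    expect_false(logrankTest(data.frame(time = 1:4, event = FALSE,
                                        group = rep(c("a", "b"), 2)))$defined)
})

test_that("gene-loss stratification follows the two-group design", {
    cna <- data.frame(sample_id = c("a", "b", "c", "d"),
                      gistic_level = c(-2, -1, 0, 1))
    surv <- data.frame(sample_id = c("a", "b", "c", "d", "e"),
                       time = c(1, 2, 3, 4, 5),
                       event = TRUE)
    g <- stratifyByGeneLoss(cna, surv)
    expect_identical(as.character(g$group),
                     c("loss", "loss", "wild_type", "wild_type"))
    expect_equal(unname(attr(g, "excluded")["no_cna"]), 1L)
})

test_that("planted hazard ratios are detected with high power", {
    pt <- data.frame(cancer_type = "SIM", n = 1000L, p_loss = 0.5,
                     p_gain = 0, p_arm_loss_given_loss = 0.5,
                     hazard_ratio_loss = 2, censor_rate = 0.02)
    hits <- 0L
    for (seed in 1:20) {
        g <- genCnaSurvival(pt, baselineHazard = 0.1, seed = seed)
        s <- stratifyByGeneLoss(g$cna, g$survival)
        if (logrankTest(s)$p < 0.05) hits <- hits + 1L
    }
    expect_gte(hits / 20, 0.95)
})
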