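test_that("genomic lambda follows the median chi-square definition", {
  expect_equal(genomic_lambda(rep(0.5, 100)), 1)
  # all p = 0.0455: chi-square quantile about 4.0, lambda about 8.79
  expect_equal(genomic_lambda(rep(0.0455, 10)),
               qchisq(0.0455, 1, lower.tail = FALSE) / qchisq(0.5, 1),
               tolerance = 1e-12)
  set.seed(41)
  expect_true(abs(genomic_lambda(runif(10000)) - 1) < 0.05)
  expect_error(genomic_lambda(c(0.5, 0)), "add-one")
  expect_error(genomic_lambda(numeric(0)), "empty")
})

test_that("QQ tables pair sorted observations with i/(n+1) expectations", {
  tab1 <- qq_table(0.5)
  expect_equal(tab1$expected, 0.5)
  expect_equal(tab1$observed, 0.5)
  tab <- qq_table(c(0.9, 0.1, 0.5))
  expect_equal(tab$observed, c(0.1, 0.5, 0.9))
  expect_equal(tab$expected, (1:3) / 4)
  expect_equal(tab$neglog10_observed, -log10(tab$observed))
  # uniform sample stays inside the 95% beta order-statistic band
  set.seed(42)
  n <- 2000
  tabu <- qq_table(runif(n))
  lo <- qbeta(0.025, 1:n, n:1)
  hi <- qbeta(0.975, 1:n, n:1)
  inside <- mean(tabu$observed >= lo & tabu$observed <= hi)
  expect_gte(inside, 0.9)
})

test_that("power curves count true windows below each cutoff; AUC integrates them", {
  res <- data.frame(group = c("w1", "w2", "w3"),
                    hc_p = c(0.04, 0.2, 0.9),
                    minp_p = c(0.5, 0.6, 0.9))
  pc <- power_curve(res, truth = c("w1", "w2"), cutoffs = c(0.05, 0.5))
  expect_equal(unname(pc$tpr[pc$cutoffs == 0.05, "hc"]), 0.5)
  expect_equal(unname(pc$tpr[pc$cutoffs == 0.5, "hc"]), 1)
  # TPR is monotone in the cutoff
  expect_true(all(diff(pc$tpr[, "hc"]) >= 0))
  # perfect detection: all true-window p at zero -> TPR 1 everywhere, AUC 1
  perfect <- data.frame(group = c("w1", "w2"), hc_p = c(0, 0))
  pcp <- power_curve(perfect, truth = c("w1", "w2"))
  expect_true(all(pcp$tpr[, "hc"] == 1))
  expect_equal(unname(pcp$auc["hc"]), 1)
  # uniform true-window p-values give AUC near 1/2
  set.seed(43)
  unif <- data.frame(group = sprintf("w%d", 1:4000), hc_p = runif(4000))
  pcu <- power_curve(unif, truth = unif$group)
  expect_lt(abs(pcu$auc["hc"] - 0.5), 0.03)
  # AUC is invariant to row order
  pcu2 <- power_curve(unif[sample(4000), ], truth = unif$group)
  expect_equal(pcu$auc, pcu2$auc)
  expect_error(power_curve(res, character(0)), "zero true windows")
  expect_error(power_curve(res, "missing_window"), "cover")
})

test_that("per-window power counts replicates and labels the best method", {
  mk <- function(p_hc, p_minp) data.frame(group = c("w1", "w2"),
                                          hc_p = p_hc, minp_p = p_minp)
  reps <- c(replicate(150, mk(c(0.01, 0.9), c(0.5, 0.9)), simplify = FALSE),
            replicate(50, mk(c(0.9, 0.9), c(0.5, 0.9)), simplify = FALSE))
  tab <- per_window_power(reps, truth = c("w1", "w2"), alpha = 0.05)
  expect_equal(tab$hc[tab$group == "w1"], 0.75)      # 150 of 200 replicates
  expect_identical(tab$best[tab$group == "w1"], "hc")
  # all methods below the floor: the "none" class
  expect_equal(tab$hc[tab$group == "w2"], 0)
  expect_identical(tab$best[tab$group == "w2"], "none")
  expect_identical(attr(tab, "n_replicates"), 200L)
})

test_that("QQ and power-curve plots render without error", {
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f, width = 400, height = 300)
  set.seed(44)
  expect_silent(plot_qq(runif(100)))
  res <- data.frame(group = c("w1", "w2"), hc_p = c(0.01, 0.3),
                    minp_p = c(0.02, 0.5))
  expect_silent(plot_power_curve(power_curve(res, c("w1", "w2"))))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
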