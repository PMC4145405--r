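test_that("empirical p-values count ties as extreme under both rules", {
  B <- 10
  same <- rep(2, B)
  expect_identical(permutation_pvalue(2, same, "large", "proportion"), 1)
  expect_identical(permutation_pvalue(2, same, "large", "add_one"), 1)
  # observed strictly more extreme than every permutation
  expect_identical(permutation_pvalue(9, same, "large", "proportion"), 0)
  expect_equal(permutation_pvalue(9, same, "large", "add_one"), 1 / (B + 1))
  # counting oracle: B = 4, perm (1,2,3,4), observed 2.5 -> 2/4
  expect_equal(permutation_pvalue(2.5, c(1, 2, 3, 4), "large", "proportion"), 0.5)
  # small-is-extreme direction (minP)
  expect_equal(permutation_pvalue(0.1, c(0.05, 0.2, 0.5, 0.9), "small",
                                  "proportion"), 0.25)
  # the Inf sentinel is most extreme and ties with itself
  expect_equal(permutation_pvalue(Inf, c(1, 2, Inf, 3), "large", "proportion"),
               0.25)
  expect_identical(permutation_pvalue(5, c(1, Inf, 2), "large", "proportion"),
                   1 / 3)
})

test_that("scans are deterministic given the seed and invariant to group order", {
  ds <- null_panel(n = 60, m = 60, seed = 21)
  set.seed(22)
  y <- rnorm(60)
  names(y) <- ds$samples
  grp <- assign_variants(ds, make_fixed_windows(ds, 4000))
  cfg <- permutation_config(B = 60, seed = 99)
  r1 <- hc_scan(ds, y, grp, perm_cfg = cfg)
  r2 <- hc_scan(ds, y, grp, perm_cfg = cfg)
  expect_identical(r1, r2)
  r3 <- hc_scan(ds, y, rev(grp), perm_cfg = cfg)
  r3 <- r3[match(r1$group, r3$group), ]
  rownames(r3) <- NULL
  expect_identical(r1, r3)
  # a different seed changes the permutation draws
  r4 <- hc_scan(ds, y, grp, perm_cfg = permutation_config(B = 60, seed = 100))
  expect_false(identical(r1$hc_p, r4$hc_p))
})

test_that("a planted strong causal variant drives minP (and SKAT) to extremes", {
  ds <- null_panel(n = 120, m = 30, seed = 23)
  mafs <- estimate_maf(ds)
  j <- which.max(mafs)                       # a common variant
  set.seed(24)
  y <- 2 * ds$dosage[, j] + rnorm(120, 0, 0.5)
  names(y) <- ds$samples
  grp <- assign_variants(ds, make_fixed_windows(ds, 30 * 400))
  res <- hc_scan(ds, y, grp, perm_cfg = permutation_config(B = 199, seed = 1))
  expect_equal(res$minp_p, 1 / 200)
  expect_lte(res$skat_p, 0.05)
  # the HC formula's p_i >= 1/n guard excludes a solitary extreme p-value,
  # so HC has only the rank-shift signal here: not anti-conservative, but
  # far from the rule minimum
  expect_lte(res$hc_p, 1)
})

test_that("null empirical p-values under the add-one rule are super-uniform", {
  pool <- list()
  for (s in 1:8) {
    ds <- null_panel(n = 60, m = 60, seed = 200 + s)
    set.seed(300 + s)
    y <- rnorm(60)
    names(y) <- ds$samples
    grp <- assign_variants(ds, make_fixed_windows(ds, 3000))
    pool[[s]] <- hc_scan(ds, y, grp,
                         perm_cfg = permutation_config(B = 99, seed = s))
  }
  res <- do.call(rbind, pool)
  for (alpha in c(0.05, 0.1, 0.25)) {
    for (m in c("hc_p", "minp_p", "skat_p")) {
      # 3-SE slack over the pooled windows (independent panels and traits)
      slack <- 3 * sqrt(alpha * (1 - alpha) / nrow(res))
      expect_lte(mean(res[[m]] <= alpha), alpha + slack)
    }
  }
})

test_that("results survive a TSV round trip", {
  ds <- null_panel(n = 40, m = 20, seed = 27)
  set.seed(28)
  y <- rnorm(40)
  names(y) <- ds$samples
  grp <- assign_variants(ds, make_fixed_windows(ds, 4000))
  res <- hc_scan(ds, y, grp, perm_cfg = permutation_config(B = 19, seed = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scan_results(res, f)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_identical(back$group, res$group)
  expect_equal(back$hc_p, res$hc_p)
})
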