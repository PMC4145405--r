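test_that("rare flagging uses a strict MAF threshold", {
  expect_identical(flag_rare(c(0.05, 0.049, 0), 0.05), c(FALSE, TRUE, TRUE))
  expect_true(flag_rare(0, 1e-6))
})

test_that("Madsen-Browning weights use the smoothed minor-allele frequency", {
  # zero minor-allele count over 49 samples: q-hat = 1/100
  g <- matrix(0, 49, 1)
  expect_equal(unname(mb_weights(g)), 1 / sqrt(49 * 0.01 * 0.99))
  # rarer variants get strictly larger weights
  set.seed(3)
  d <- cbind(rbinom(100, 2, 0.01), rbinom(100, 2, 0.1), rbinom(100, 2, 0.4))
  w <- mb_weights(d)
  expect_true(w[1] > w[2] && w[2] > w[3])
  # weights are minor-allele oriented: flipping ref/alt leaves them fixed
  expect_equal(mb_weights(d), mb_weights(2 - d))
  expect_true(all(is.finite(w)) && all(w > 0))
})

test_that("maximal rare runs between adjacent common variants collapse to single columns", {
  # position-ordered flags [r,r,C,r,C,r,r] -> run{1,2}, C3, run{4}, C5, run{6,7}
  set.seed(4)
  d <- matrix(rbinom(6 * 7, 2, 0.2), 6, 7)
  flags <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  des <- collapse_group(d, flags, collapse_config(weight_scheme = "equal"))
  expect_identical(ncol(des$matrix), 5L)
  expect_identical(des$column_kind,
                   c("collapsed_run", "common", "collapsed_run",
                     "common", "collapsed_run"))
  expect_identical(des$column_members,
                   list(1:2, 3L, 4L, 5L, 6:7))
  expect_equal(unname(des$matrix[, 1]), unname(rowSums(d[, 1:2])))
  expect_equal(unname(des$matrix[, 2]), unname(d[, 3]))
})

test_that("all-common groups pass through; all-rare groups collapse to weighted row sums", {
  d <- matrix(c(1, 0, 0, 1, 2, 0), 2, 3)  # rows (1,0,2) and (0,1,0)
  id <- collapse_group(d, rep(FALSE, 3))
  expect_equal(unname(id$matrix), unname(d))
  expect_identical(unique(id$column_kind), "common")
  one <- collapse_group(d, rep(TRUE, 3))
  expect_identical(ncol(one$matrix), 1L)
  expect_equal(unname(one$matrix[, 1]), c(3, 1))   # brute-force row sums
  expect_error(collapse_group(d[, 0], logical(0)), "empty")
})

test_that("equal-weight collapsing conserves dosage mass and obeys the column-count law", {
  set.seed(7)
  for (rep in 1:20) {
    m <- sample(2:15, 1)
    d <- matrix(rbinom(8 * m, 2, 0.3), 8, m)
    flags <- runif(m) < 0.6
    des <- collapse_group(d, flags, collapse_config(weight_scheme = "equal"))
    expect_equal(rowSums(des$matrix), rowSums(d))
    n_runs <- sum(des$column_kind == "collapsed_run")
    expect_identical(ncol(des$matrix), sum(!flags) + n_runs)
    expect_lte(n_runs, max(sum(flags), 0))
    expect_lte(n_runs, sum(!flags) + 1L)
    # every rare variant lands in exactly one run; commons map one-to-one
    covered <- unlist(des$column_members)
    expect_identical(sort(covered), seq_len(m))
  }
})

test_that("MB collapsing with all-equal MAFs is proportional to equal-weight collapsing", {
  set.seed(8)
  base <- rbinom(30, 2, 0.2)
  d <- cbind(base, sample(base), sample(base), sample(base))  # equal colSums
  colnames(d) <- NULL
  flags <- c(TRUE, TRUE, FALSE, TRUE)
  eq <- collapse_group(d, flags, collapse_config(weight_scheme = "equal"))
  mb <- collapse_group(d, flags, collapse_config(weight_scheme = "madsen_browning"))
  w <- mb_weights(d)[1]
  expect_equal(unname(mb$matrix), unname(eq$matrix) *
                 ifelse(eq$column_kind == "collapsed_run", w, 1)[col(eq$matrix)])
})

test_that("collapse_design wires groups, MAFs and manifests together", {
  set.seed(9)
  ds <- null_panel(n = 50, m = 12)
  mafs <- estimate_maf(ds)
  grp <- assign_variants(ds, make_fixed_windows(ds, 400 * 12))[[1]]
  des <- collapse_design(ds, grp, mafs, collapse_config(0.05, "equal"))
  expect_identical(des$n_rare + des$n_common, 12L)
  man <- collapse_manifest(des, ds$variants$vid[grp$member_idx])
  expect_identical(nrow(man), ncol(des$matrix))
  expect_true(all(man$kind %in% c("common", "collapsed_run")))
})
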