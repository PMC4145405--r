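# Independent oracles, written as plain loops / closed forms so they share
# no code path with the package implementation.

# Brute-force Higher Criticism: explicit loop over all eligible indices.
hc_brute <- function(p) {
  p <- sort(p)
  n <- length(p)
  best <- -Inf
  any_eligible <- FALSE
  for (i in seq_len(floor(n / 2))) {
    if (p[i] >= 1 / n) {
      any_eligible <- TRUE
      term <- sqrt(n) * (i / n - p[i]) / sqrt(p[i] * (1 - p[i]))
      if (term > best) best <- term
    }
  }
  if (!any_eligible) Inf else best
}

# Closed-form two-sided slope t-test for simple linear regression.
slope_ttest_p <- function(x, y) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(1)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  2 * stats::pt(abs(b / se), df = n - 2, lower.tail = FALSE)
}

# Closed-form 1-df score test for a single variant against a quantitative
# trait, with the null-model (intercept-only) variance estimate RSS0/(n-1).
score_test_p <- function(g, y) {
  n <- length(y)
  yc <- y - mean(y)
  gc <- g - mean(g)
  sigma2 <- sum(yc^2) / (n - 1)
  chi <- sum(gc * y)^2 / (sigma2 * sum(gc^2))
  stats::pchisq(chi, df = 1, lower.tail = FALSE)
}

# Tiny deterministic dataset builder.
toy_dataset <- function(dosage, pos = NULL, chrom = "chr1",
                        samples = NULL, missing = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(dosage)))
  genotype_dataset(samples,
                   data.frame(chrom = chrom, pos = pos,
                              vid = sprintf("v%d", seq_len(m))),
                   dosage, missing)
}

# Small null panel shared by several tests.
null_panel <- function(n = 60, m = 40, seed = 11) {
  cfg <- sim_config(n_samples = n, n_variants = m, contig_length = m * 400,
                    rho = 0, seed = seed)
  simulate_genotypes(cfg)
}
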