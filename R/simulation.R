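#' Simulation configuration for synthetic genotype panels
#'
#' Defaults describe a desk-scale panel of unrelated individuals with a
#' rare-skewed allele frequency spectrum: 142 samples (a typical
#' complete-case sequencing panel), 5000 variants equally spaced over a
#' 2-Mb contig (25 per 10-kb window, 200 windows), 70\% rare variants with
#' MAF uniform on \[0.002, 0.05) and the rest common with MAF uniform on
#' \[0.05, 0.5\], and exchangeable Gaussian-copula LD (correlation
#' \code{rho}) within blocks of 10 adjacent variants.
#'
#' @param n_samples number of individuals.
#' @param n_variants number of variant sites.
#' @param contig contig label.
#' @param contig_length contig length in bp; positions are equally spaced.
#' @param frac_rare fraction of variants drawn from the rare stratum.
#' @param maf_lo lower bound of the rare MAF stratum (must be > 0).
#' @param rare_threshold boundary between the rare and common strata.
#' @param maf_hi upper bound of the common stratum (<= 0.5).
#' @param ld_block number of adjacent variants per LD block.
#' @param rho within-block latent correlation, in \[0, 1).
#' @param seed integer seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 142L, n_variants = 5000L,
                       contig = "chr1", contig_length = 2e6,
                       frac_rare = 0.7, maf_lo = 0.002,
                       rare_threshold = 0.05, maf_hi = 0.5,
                       ld_block = 10L, rho = 0.2, seed = 1L) {
  stopifnot(maf_lo > 0, maf_lo < rare_threshold, rare_threshold <= maf_hi,
            maf_hi <= 0.5, rho >= 0, rho < 1, frac_rare >= 0, frac_rare <= 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 contig = contig, contig_length = contig_length,
                 frac_rare = frac_rare, maf_lo = maf_lo,
                 rare_threshold = rare_threshold, maf_hi = maf_hi,
                 ld_block = as.integer(ld_block), rho = rho,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype panel with a rare-skewed MAF spectrum and block LD
#'
#' Per variant j a population allele frequency q_j is drawn from the
#' two-stratum spectrum. Each individual carries two haplotypes; each
#' haplotype is a latent standard Gaussian vector with exchangeable
#' correlation \code{rho} inside LD blocks, thresholded at the
#' q_j-quantile to yield one allele per site. Dosage is the sum of the two
#' allele draws, so with \code{rho = 0} each dosage is Binomial(2, q_j)
#' (Hardy-Weinberg). Positions are equally spaced along the contig.
#'
#' @param config a [sim_config()].
#' @return A [genotype_dataset()] with attribute \code{"q"} holding the
#'   simulated population allele frequencies.
#' @export
simulate_genotypes <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_variants
  rare <- stats::runif(m) < config$frac_rare
  q <- ifelse(rare,
              stats::runif(m, config$maf_lo, config$rare_threshold),
              stats::runif(m, config$rare_threshold, config$maf_hi))
  spacing <- max(1L, as.integer(config$contig_length %/% m))
  pos <- (seq_len(m) - 1L) * spacing + 1L
  block <- ceiling(seq_len(m) / config$ld_block)
  nblock <- max(block)
  thr <- matrix(stats::qnorm(q), n, m, byrow = TRUE)
  dosage <- matrix(0L, n, m)
  for (h in 1:2) {
    Bf <- matrix(stats::rnorm(n * nblock), n, nblock)
    Z <- sqrt(config$rho) * Bf[, block, drop = FALSE] +
      sqrt(1 - config$rho) * matrix(stats::rnorm(n * m), n, m)
    dosage <- dosage + (Z < thr)
  }
  variants <- data.frame(chrom = config$contig, pos = pos,
                         vid = sprintf("v%05d", seq_len(m)),
                         stringsAsFactors = FALSE)
  ds <- genotype_dataset(sprintf("s%04d", seq_len(n)), variants, dosage)
  attr(ds, "q") <- q
  ds
}

#' Truth configuration: sparse causal architecture for the trait
#'
#' Defaults plant weak, sparse effects: 5 causal ("true") 10-kb windows,
#' each holding 1-3 causal rare variants with per-allele effects of
#' magnitude uniform on \[0.4, 0.8\] trait SDs and random sign, against
#' unit-SD Gaussian noise — a regime where single-variant power is modest.
#'
#' @param window_width width (bp) of the windows used to define truth.
#' @param n_true_windows number of windows receiving causal variants.
#' @param n_causal_range integer range (min, max) of causal variants drawn
#'   per true window.
#' @param beta_range magnitude range of per-allele effects (trait SD units).
#' @param causal_class which variants may be causal: \code{"rare"}
#'   (MAF < \code{maf_threshold}), \code{"common"}, or \code{"any"}.
#' @param maf_threshold rare/common boundary used by \code{causal_class}.
#' @param sigma residual (noise) standard deviation.
#' @return list of class \code{truth_config}.
#' @export
truth_config <- function(window_width = 1e4, n_true_windows = 5L,
                         n_causal_range = c(1L, 3L),
                         beta_range = c(0.4, 0.8),
                         causal_class = c("rare", "common", "any"),
                         maf_threshold = 0.05, sigma = 1) {
  structure(list(window_width = window_width,
                 n_true_windows = as.integer(n_true_windows),
                 n_causal_range = as.integer(n_causal_range),
                 beta_range = beta_range,
                 causal_class = match.arg(causal_class),
                 maf_threshold = maf_threshold, sigma = sigma),
            class = "truth_config")
}

#' Simulate a quantitative trait with sparse causal variants
#'
#' Draws causal windows and variants per the truth configuration, then
#' \deqn{y_i = \sum_{j \in causal} \beta_j d_{ij} + \varepsilon_i,\quad
#'       \varepsilon_i \sim N(0, \sigma^2).}
#' The returned truth records causal indices, effects, and the derived set
#' of true windows (every window of the configured width containing at
#' least one causal variant) — knowledge meant only for scoring power,
#' never for the tests themselves.
#'
#' @param dataset a [genotype_dataset()].
#' @param config a [truth_config()].
#' @param seed integer seed (independent of the genotype seed).
#' @return list with \code{phenotype} (named numeric) and \code{truth}
#'   (list: \code{causal_idx}, \code{beta}, \code{true_windows},
#'   \code{window_width}).
#' @export
simulate_phenotype <- function(dataset, config = truth_config(), seed = 1L) {
  set.seed(as.integer(seed))
  mafs <- estimate_maf(dataset)
  eligible <- switch(config$causal_class,
                     rare = mafs < config$maf_threshold,
                     common = mafs >= config$maf_threshold,
                     any = rep(TRUE, length(mafs)))
  windows <- make_fixed_windows(dataset, config$window_width)
  groups <- assign_variants(dataset, windows)
  has_elig <- vapply(groups, function(g) any(eligible[g$member_idx]), TRUE)
  candidates <- which(has_elig)
  if (length(candidates) < config$n_true_windows)
    stop("not enough windows with eligible causal variants")
  resample <- function(x, k) x[sample.int(length(x), k)]  # safe for length 1
  chosen <- resample(candidates, config$n_true_windows)
  causal_idx <- integer(0)
  for (g in chosen) {
    elig_idx <- groups[[g]]$member_idx[eligible[groups[[g]]$member_idx]]
    ks <- config$n_causal_range[1L]:config$n_causal_range[2L]
    k <- resample(ks, 1L)
    causal_idx <- c(causal_idx, resample(elig_idx, min(k, length(elig_idx))))
  }
  if (length(causal_idx) > nrow(dataset$variants))
    stop("requested causal count exceeds available variants")
  beta <- stats::runif(length(causal_idx),
                       config$beta_range[1L], config$beta_range[2L]) *
    sample(c(-1, 1), length(causal_idx), replace = TRUE)
  n <- length(dataset$samples)
  y <- as.vector(dataset$dosage[, causal_idx, drop = FALSE] %*% beta) +
    stats::rnorm(n, 0, config$sigma)
  names(y) <- dataset$samples
  truth <- list(causal_idx = causal_idx, beta = beta,
                true_windows = true_windows(dataset, causal_idx,
                                            config$window_width),
                window_width = config$window_width)
  list(phenotype = y, truth = truth)
}

#' Derive the true windows implied by a causal variant set
#'
#' A window is "true" iff it contains at least one causal variant, under
#' the same fixed-window grouping the scan uses.
#'
#' @param dataset a [genotype_dataset()].
#' @param causal_idx indices of causal variants.
#' @param window_width window width in bp.
#' @return character vector of true window names.
#' @export
true_windows <- function(dataset, causal_idx, window_width) {
  windows <- make_fixed_windows(dataset, window_width)
  groups <- assign_variants(dataset, windows)
  hit <- vapply(groups, function(g) any(g$member_idx %in% causal_idx), TRUE)
  names(groups)[hit]
}

#' Write a simulation truth table as TSV
#' @param dataset the simulated [genotype_dataset()].
#' @param truth truth list from [simulate_phenotype()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(dataset, truth, path) {
  utils::write.table(
    data.frame(vid = dataset$variants$vid[truth$causal_idx],
               chrom = dataset$variants$chrom[truth$causal_idx],
               pos = dataset$variants$pos[truth$causal_idx],
               beta = truth$beta),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
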