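#' Permutation configuration
#'
#' @param B number of permutations per group (1000 is the conventional
#'   choice for window scans).
#' @param seed master integer seed; every group derives its own
#'   reproducible stream from it (keyed by group name, so results do not
#'   depend on group processing order or parallel scheduling).
#' @param pvalue_rule \code{"add_one"} (default): empirical p =
#'   (count + 1)/(B + 1), never zero, super-uniform under the null;
#'   \code{"proportion"}: the literal count/B rule.
#' @return list of class \code{permutation_config}.
#' @export
permutation_config <- function(B = 1000L, seed = 1L,
                               pvalue_rule = c("add_one", "proportion")) {
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be >= 1")
  structure(list(B = B, seed = as.integer(seed),
                 pvalue_rule = match.arg(pvalue_rule)),
            class = "permutation_config")
}

#' Empirical p-value from a permutation null
#'
#' Counts permutation statistics at least as extreme as the observed one
#' ("equal or more extreme": ties count). The \code{Inf} sentinel of
#' [hc_statistic()] compares as most extreme under the large-is-extreme
#' direction, and \code{Inf} ties with \code{Inf}, so sentinel-heavy groups
#' calibrate conservatively rather than spuriously.
#'
#' @param observed observed statistic.
#' @param perm_stats vector of B permutation statistics.
#' @param direction \code{"large"} if large values are extreme (HC, SKAT Q),
#'   \code{"small"} if small values are (minP).
#' @param rule \code{"add_one"} for (count + 1)/(B + 1) or
#'   \code{"proportion"} for count/B.
#' @return empirical p-value.
#' @export
permutation_pvalue <- function(observed, perm_stats,
                               direction = c("large", "small"),
                               rule = c("add_one", "proportion")) {
  direction <- match.arg(direction)
  rule <- match.arg(rule)
  B <- length(perm_stats)
  cnt <- if (direction == "large") sum(perm_stats >= observed)
         else sum(perm_stats <= observed)
  if (rule == "add_one") (cnt + 1) / (B + 1) else cnt / B
}

# Deterministic per-group seed from (master seed, group name).
# Name-keyed (not ordinal-keyed) so per-group results are invariant to the
# order in which groups are processed.
.group_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 7919 + 1) %% 2147483647)
}

#' Genome scan: group statistics with permutation calibration
#'
#' For each group: rare variants are flagged from phenotype-free MAFs and
#' collapsed once (the design is frozen before any permutation); HC and
#' minP are computed from the two-tailed per-column p-values of the
#' collapsed design, while SKAT uses the group's original uncollapsed
#' dosages. The phenotype-to-sample alignment is then permuted B times —
#' equivalent, per window, to permuting the genotype rows — and all
#' requested statistics are recomputed on the same shared draws, so methods
#' are compared on identical permutations. Empirical p-values follow the
#' configured counting rule.
#'
#' @param dataset a complete-case [genotype_dataset()].
#' @param phenotype named numeric trait vector aligned to
#'   \code{dataset$samples}.
#' @param groups list of variant groups from [assign_variants()].
#' @param collapse_cfg a [collapse_config()].
#' @param methods subset of \code{c("hc", "minp", "skat")}.
#' @param perm_cfg a [permutation_config()].
#' @param covariates optional covariate matrix, residualised out before
#'   testing (default none).
#' @param verbose log a line every 100 groups.
#' @return data.frame, one row per group: \code{group}, \code{chrom},
#'   \code{start}, \code{end}, \code{n_variants}, \code{n_rare},
#'   \code{n_common}, \code{n_columns}, then \code{<method>_stat} and
#'   \code{<method>_p} per requested method.
#' @export
hc_scan <- function(dataset, phenotype, groups,
                    collapse_cfg = collapse_config(),
                    methods = c("hc", "minp", "skat"),
                    perm_cfg = permutation_config(),
                    covariates = NULL, verbose = FALSE) {
  methods <- match.arg(methods, c("hc", "minp", "skat"), several.ok = TRUE)
  if (!all(names(phenotype) == dataset$samples))
    phenotype <- phenotype[dataset$samples]
  if (anyNA(phenotype)) stop("phenotype missing for some dataset samples")
  if (any(dataset$missing_mask)) stop("run filter_complete_cases() first")
  y <- as.numeric(phenotype)
  n <- length(y)
  B <- perm_cfg$B
  rule <- perm_cfg$pvalue_rule
  mafs <- estimate_maf(dataset)
  if (!is.null(covariates)) {
    qrc <- qr(cbind(1, as.matrix(covariates)))
    df <- n - 1L - qrc$rank
  } else {
    qrc <- NULL
    df <- n - 2L
  }

  rows <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    grp <- groups[[g]]
    des <- collapse_design(dataset, grp, mafs, collapse_cfg)
    G <- dataset$dosage[, grp$member_idx, drop = FALSE]

    set.seed(.group_seed(perm_cfg$seed, grp$name))
    perm <- vapply(seq_len(B), function(b) sample.int(n), integer(n))

    yr <- if (is.null(qrc)) y else qr.resid(qrc, y)
    X <- if (is.null(qrc)) des$matrix else qr.resid(qrc, des$matrix)
    Gr <- if (is.null(qrc)) G else qr.resid(qrc, G)

    # scaled design columns once; permuted traits are column permutations
    # of the one scaled trait vector, so a single crossprod gives all
    # correlations for observed + B permutations
    Xc <- sweep(X, 2L, colMeans(X))
    sx <- sqrt(colSums(Xc^2))
    ok <- sx > 0
    Xs <- Xc
    Xs[, ok] <- sweep(Xc[, ok, drop = FALSE], 2L, sx[ok], "/")
    Xs[, !ok] <- 0
    yc <- yr - mean(yr)
    sy <- sqrt(sum(yc^2))
    ys <- if (sy > 0) yc / sy else yc
    Ys <- cbind(ys, matrix(ys[perm], n, B))
    R <- crossprod(Xs, Ys)                      # m x (B + 1) correlations
    P <- matrix(.r_to_p(R, df), nrow = ncol(X)) # two-tailed p-values

    row <- list(group = grp$name, chrom = grp$chrom,
                start = grp$start, end = grp$end,
                n_variants = length(grp$member_idx),
                n_rare = des$n_rare, n_common = des$n_common,
                n_columns = ncol(des$matrix))
    all_const <- !any(ok)
    if (all_const)
      warning("group '", grp$name, "' has an entirely constant design; p = 1")
    if ("hc" %in% methods) {
      hc <- .hc_columns(P)
      row$hc_stat <- hc[1L]
      row$hc_p <- if (all_const) 1 else
        permutation_pvalue(hc[1L], hc[-1L], "large", rule)
    }
    if ("minp" %in% methods) {
      mp <- do.call(pmin, asplit(P, 1L))
      row$minp_stat <- mp[1L]
      row$minp_p <- if (all_const) 1 else
        permutation_pvalue(mp[1L], mp[-1L], "small", rule)
    }
    if ("skat" %in% methods) {
      ycg <- yr - mean(yr)
      Yq <- cbind(ycg, matrix(ycg[perm], n, B))
      Qs <- colSums(crossprod(Gr, Yq)^2)
      row$skat_stat <- Qs[1L]
      row$skat_p <- if (all(apply(G, 2L, function(col) length(unique(col))) == 1L)) 1 else
        permutation_pvalue(Qs[1L], Qs[-1L], "large", rule)
    }
    rows[[g]] <- row
    if (verbose && g %% 100L == 0L)
      message(sprintf("[hc_scan] %d/%d groups done", g, length(groups)))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Write scan results as TSV
#' @param results data.frame from [hc_scan()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scan_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
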