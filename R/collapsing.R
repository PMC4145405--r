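#' Collapse configuration
#'
#' @param maf_threshold rare/common boundary in (0, 0.5]; a variant is rare
#'   iff its MAF is strictly below this value. Conventional choices are
#'   0.01 and 0.05.
#' @param weight_scheme \code{"equal"} (unit weights) or
#'   \code{"madsen_browning"} (inverse-standard-deviation weights that
#'   emphasise rarer variants).
#' @return list of class \code{collapse_config}.
#' @export
collapse_config <- function(maf_threshold = 0.05,
                            weight_scheme = c("equal", "madsen_browning")) {
  weight_scheme <- match.arg(weight_scheme)
  if (!is.numeric(maf_threshold) || maf_threshold <= 0 || maf_threshold > 0.5)
    stop("maf_threshold must lie in (0, 0.5]")
  structure(list(maf_threshold = maf_threshold, weight_scheme = weight_scheme),
            class = "collapse_config")
}

#' Flag rare variants
#'
#' @param mafs minor allele frequencies in \[0, 0.5\].
#' @param maf_threshold threshold; rare means MAF strictly less than it.
#' @return logical vector, \code{TRUE} for rare.
#' @export
flag_rare <- function(mafs, maf_threshold) {
  stopifnot(all(mafs >= 0 & mafs <= 0.5))
  mafs < maf_threshold
}

#' Madsen-Browning weights
#'
#' Weight for variant j is \code{1 / sqrt(n * q_j * (1 - q_j))} with the
#' smoothed minor-allele frequency estimate \code{q_j = (c_j + 1)/(2n + 2)},
#' where \code{c_j} is the minor-allele dosage total over the n analysis
#' samples. The smoothing keeps every q in (0, 1), so weights are always
#' finite and positive, and rarer variants receive strictly larger weights.
#'
#' @param group_dosage samples x variants dosage matrix (no missing values).
#' @return positive numeric weight per column.
#' @export
mb_weights <- function(group_dosage) {
  n <- nrow(group_dosage)
  stopifnot(n >= 1L)
  s <- colSums(group_dosage)
  c_minor <- ifelse(s / (2 * n) > 0.5, 2 * n - s, s)
  qhat <- (c_minor + 1) / (2 * n + 2)
  1 / sqrt(n * qhat * (1 - qhat))
}

#' Collapse runs of rare variants within a group
#'
#' Walking the group's variants in genomic order, every maximal run of
#' consecutive rare variants — including runs before the first and after the
#' last common variant — is replaced by a single pseudo-variant column equal
#' to the weighted sum of its members' dosages (unit weights for the equal
#' scheme, [mb_weights()] otherwise). Common variants pass through
#' unchanged. Column order follows the genomic position of each common
#' variant or run start, so the output has \code{n_common + n_runs} columns.
#'
#' @param group_dosage samples x variants matrix, columns in position order.
#' @param rare_flags logical vector aligned to the columns.
#' @param config a [collapse_config()].
#' @return list of class \code{collapsed_design} with elements
#'   \code{matrix} (samples x columns), \code{column_kind}
#'   (\code{"common"} or \code{"collapsed_run"} per column), and
#'   \code{column_members} (list of source column indices per column).
#' @export
collapse_group <- function(group_dosage, rare_flags,
                           config = collapse_config()) {
  group_dosage <- as.matrix(group_dosage)
  m <- ncol(group_dosage)
  if (m == 0L) stop("cannot collapse an empty group")
  stopifnot(length(rare_flags) == m)
  w <- if (config$weight_scheme == "madsen_browning")
    mb_weights(group_dosage) else rep(1, m)
  r <- rle(rare_flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cols <- vector("list", 0L)
  kinds <- character(0)
  members <- list()
  for (seg in seq_along(r$values)) {
    idx <- starts[seg]:ends[seg]
    if (r$values[seg]) {  # one pseudo-variant per maximal rare run
      run <- group_dosage[, idx, drop = FALSE] %*% w[idx]
      cols <- c(cols, list(drop(run)))
      kinds <- c(kinds, "collapsed_run")
      members <- c(members, list(idx))
    } else {            # common variants pass through one by one
      for (j in idx) {
        cols <- c(cols, list(group_dosage[, j]))
        kinds <- c(kinds, "common")
        members <- c(members, list(j))
      }
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- rownames(group_dosage)
  colnames(mat) <- vapply(seq_along(kinds), function(k) {
    if (kinds[k] == "common") colnames(group_dosage)[members[[k]]] %||%
      sprintf("v%d", members[[k]])
    else sprintf("run_%d_%d", members[[k]][1L],
                 members[[k]][length(members[[k]])])
  }, "")
  structure(list(matrix = mat, column_kind = kinds, column_members = members,
                 weight_scheme = config$weight_scheme,
                 maf_threshold = config$maf_threshold),
            class = "collapsed_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the collapsed design for one variant group
#'
#' Convenience wrapper: extracts the group's dosage columns, flags rare
#' variants from precomputed MAFs, and collapses per the configuration.
#'
#' @param dataset a [genotype_dataset()] (complete cases).
#' @param group a \code{variant_group} from [assign_variants()].
#' @param mafs per-variant MAFs from [estimate_maf()] for the whole dataset.
#' @param config a [collapse_config()].
#' @return a \code{collapsed_design}, with an extra element
#'   \code{n_rare}/\code{n_common} recording the member split.
#' @export
collapse_design <- function(dataset, group, mafs, config = collapse_config()) {
  idx <- group$member_idx
  gd <- dataset$dosage[, idx, drop = FALSE]
  flags <- flag_rare(mafs[idx], config$maf_threshold)
  des <- collapse_group(gd, flags, config)
  des$n_rare <- sum(flags)
  des$n_common <- sum(!flags)
  des$group <- group$name
  des
}

#' Collapse manifest for a design
#' @param design a \code{collapsed_design}.
#' @param variant_ids IDs of the group's member variants, in column order of
#'   the pre-collapse matrix.
#' @return data.frame: column id, kind, member variant IDs (comma-joined),
#'   weight scheme and threshold.
#' @export
collapse_manifest <- function(design, variant_ids) {
  data.frame(
    column = colnames(design$matrix),
    kind = design$column_kind,
    members = vapply(design$column_members,
                     function(ix) paste(variant_ids[ix], collapse = ","), ""),
    weight_scheme = design$weight_scheme,
    maf_threshold = design$maf_threshold,
    stringsAsFactors = FALSE)
}
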