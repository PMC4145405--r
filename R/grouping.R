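#' Tile each contig with fixed-width windows
#'
#' Windows are 1-based inclusive, anchored at position 1 per contig:
#' \code{[kW + 1, (k + 1)W]} for k = 0, 1, ... up to the largest observed
#' variant position. Windows never overlap and jointly cover every variant
#' on the contig; windows that contain no variant are dropped later by
#' [assign_variants()].
#'
#' @param dataset a [genotype_dataset()].
#' @param width_bp window width in base pairs (>= 1).
#' @return An [interval_set()] with names \code{chrom:start-end}.
#' @export
make_fixed_windows <- function(dataset, width_bp) {
  width_bp <- as.integer(width_bp)
  if (is.na(width_bp) || width_bp < 1L) stop("window width must be >= 1 bp")
  out <- lapply(unique(dataset$variants$chrom), function(ch) {
    maxpos <- max(dataset$variants$pos[dataset$variants$chrom == ch])
    k <- seq_len(ceiling(maxpos / width_bp)) - 1L
    data.frame(chrom = ch, start = k * width_bp + 1L,
               end = (k + 1L) * width_bp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  interval_set(sprintf("%s:%d-%d", out$chrom, out$start, out$end),
               out$chrom, out$start, out$end)
}

#' Assign variants to intervals, forming variant groups
#'
#' A variant belongs to every interval whose span contains its position, so
#' overlapping gene intervals yield overlapping groups (fixed windows never
#' overlap). Intervals containing no variant are not emitted. Members are
#' ordered by position.
#'
#' @param dataset a [genotype_dataset()].
#' @param intervals an [interval_set()].
#' @return Named list of \code{variant_group} objects; each is a list with
#'   \code{name}, \code{chrom}, \code{start}, \code{end}, and
#'   \code{member_idx} (indices into \code{dataset$variants}).
#' @export
assign_variants <- function(dataset, intervals) {
  v <- dataset$variants
  groups <- lapply(seq_len(nrow(intervals)), function(i) {
    hit <- which(v$chrom == intervals$chrom[i] &
                   v$pos >= intervals$start[i] & v$pos <= intervals$end[i])
    if (length(hit) == 0L) return(NULL)
    structure(list(name = intervals$name[i], chrom = intervals$chrom[i],
                   start = intervals$start[i], end = intervals$end[i],
                   member_idx = hit[order(v$pos[hit])]),
              class = "variant_group")
  })
  groups <- groups[!vapply(groups, is.null, TRUE)]
  names(groups) <- vapply(groups, `[[`, "", "name")
  groups
}

#' Summarise a list of variant groups as a window manifest
#' @param groups result of [assign_variants()].
#' @return data.frame with columns name, chrom, start, end, n_variants.
#' @export
group_manifest <- function(groups) {
  data.frame(name = vapply(groups, `[[`, "", "name"),
             chrom = vapply(groups, `[[`, "", "chrom"),
             start = vapply(groups, function(g) as.integer(g$start), 1L),
             end = vapply(groups, function(g) as.integer(g$end), 1L),
             n_variants = vapply(groups, function(g) length(g$member_idx), 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}
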