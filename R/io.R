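#' Construct a genotype dataset
#'
#' The central container: a sample-by-variant dosage matrix in \[0, 2\]
#' together with variant coordinates and a missingness mask. Variants are
#' stored sorted by (chromosome, position); ties keep their input order.
#'
#' @param samples character vector of unique sample IDs.
#' @param variants data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{vid}, and optionally \code{ref}, \code{alt}.
#' @param dosage numeric matrix, \code{length(samples)} rows by
#'   \code{nrow(variants)} columns, values in \[0, 2\] where not missing.
#' @param missing_mask logical matrix of the same shape as \code{dosage};
#'   \code{TRUE} marks a missing genotype. Defaults to all observed.
#' @return An object of class \code{genotype_dataset}: a list with elements
#'   \code{samples}, \code{variants}, \code{dosage}, \code{missing_mask}.
#' @export
genotype_dataset <- function(samples, variants, dosage, missing_mask = NULL) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample IDs")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "vid") %in% names(variants)))
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(samples) || ncol(dosage) != nrow(variants))
    stop("dosage matrix shape does not match samples x variants")
  if (is.null(missing_mask)) {
    missing_mask <- is.na(dosage)
  } else {
    missing_mask <- as.matrix(missing_mask)
    stopifnot(identical(dim(missing_mask), dim(dosage)))
  }
  obs <- !missing_mask
  bad <- obs & (!is.finite(dosage) | dosage < 0 | dosage > 2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("dosage outside [0,2] at sample '%s', variant '%s'",
                 samples[idx[1L]], variants$vid[idx[2L]]))
  }
  ord <- order(variants$chrom, variants$pos)  # stable for ties
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  missing_mask <- missing_mask[, ord, drop = FALSE]
  dimnames(dosage) <- list(samples, variants$vid)
  dimnames(missing_mask) <- dimnames(dosage)
  structure(list(samples = samples, variants = variants,
                 dosage = dosage, missing_mask = missing_mask),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d variants (%d contig%s), %d missing cells\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$chrom)),
              if (length(unique(x$variants$chrom)) == 1L) "" else "s",
              sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosage)

.parse_variant_tokens <- function(tokens) {
  parts <- strsplit(tokens, ":", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("malformed variant header token(s): expected 'chrom:pos[:vid]', got e.g. '",
         tokens[which(nf < 2L)[1L]], "'")
  chrom <- vapply(parts, `[[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(pos)) stop("malformed variant header token(s): non-integer position")
  vid <- ifelse(nf >= 3L, vapply(parts, function(p) p[3L], ""), tokens)
  data.frame(chrom = chrom, pos = pos, vid = vid, stringsAsFactors = FALSE)
}

#' Read a dosage matrix from a "dose" TSV file
#'
#' Dialect: tab-separated, header \code{sample_id} followed by one
#' \code{chrom:pos[:vid]} token per variant; one row per sample; cells are
#' numeric dosages in \[0, 2\] or the missing token \code{NA}.
#'
#' @param path path to the TSV file.
#' @return A [genotype_dataset()] with variants sorted by (chrom, pos).
#' @seealso [write_dose_matrix()]
#' @export
read_dose_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "sample_id")
    stop("malformed dose header: first column must be 'sample_id'")
  variants <- .parse_variant_tokens(header[-1L])
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           na.strings = "NA", colClasses = "character",
                           stringsAsFactors = FALSE)
  samples <- tab[[1L]]
  dosage <- suppressWarnings(
    vapply(seq_len(nrow(variants)),
           function(j) as.numeric(tab[[j + 1L]]), numeric(nrow(tab))))
  dosage <- matrix(dosage, nrow = nrow(tab))
  missing_mask <- is.na(dosage)
  nonnum <- missing_mask & !is.na(tab[, -1L, drop = FALSE])
  if (any(nonnum)) {
    idx <- which(as.matrix(nonnum), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric dosage cell at sample '%s', variant '%s'",
                 samples[idx[1L]], header[idx[2L] + 1L]))
  }
  genotype_dataset(samples, variants, dosage, missing_mask)
}

#' Write a dosage matrix as a "dose" TSV file
#'
#' Inverse of [read_dose_matrix()]; finite dosages are written with
#' \code{\%.17g} so the numeric content round-trips bit-exactly.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dose_matrix <- function(dataset, path) {
  v <- dataset$variants
  tokens <- sprintf("%s:%d:%s", v$chrom, v$pos, v$vid)
  cells <- sprintf("%.17g", dataset$dosage)
  cells[as.vector(dataset$missing_mask)] <- "NA"
  cells <- matrix(cells, nrow = nrow(dataset$dosage))
  lines <- c(paste(c("sample_id", tokens), collapse = "\t"),
             vapply(seq_along(dataset$samples), function(i)
               paste(c(dataset$samples[i], cells[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotype dosages from a VCF file
#'
#' Uses the \code{DS} FORMAT field when present, otherwise counts alternate
#' alleles in \code{GT}. Missing genotypes (\code{./.} or \code{.}) set the
#' missing mask. Multi-allelic records are rejected: the collapsing model
#' assumes one dosage per site.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @return A [genotype_dataset()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic VCF record(s) found; split them (e.g. 'bcftools norm -m-') before import")
  vid <- fix[, "ID"]
  vid[is.na(vid) | vid == "."] <-
    sprintf("%s:%s", fix[is.na(vid) | vid == ".", "CHROM"],
            fix[is.na(vid) | vid == ".", "POS"])
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         vid = vid,
                         ref = fix[, "REF"], alt = alt,
                         stringsAsFactors = FALSE)
  has_ds <- any(grepl("(^|:)DS(:|$)", vcf@gt[, "FORMAT"]))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dosage <- t(ds)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    count_alt <- function(g) {
      if (is.na(g)) return(NA_real_)
      al <- strsplit(g, "[/|]")[[1L]]
      if (any(al == ".")) return(NA_real_)
      sum(al != "0")
    }
    dosage <- t(apply(gt, c(1L, 2L), count_alt))
  }
  samples <- rownames(dosage)
  genotype_dataset(samples, variants, dosage, is.na(dosage))
}

#' Read a phenotype table
#'
#' @param path TSV with columns \code{sample_id} and \code{trait}.
#' @param trait name of the trait column (default \code{"trait"}).
#' @return Named numeric vector of trait values, names = sample IDs.
#' @export
read_phenotype <- function(path, trait = "trait") {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", trait) %in% names(tab)))
    stop("phenotype file must have columns 'sample_id' and '", trait, "'")
  stats::setNames(as.numeric(tab[[trait]]), as.character(tab$sample_id))
}

#' Write a phenotype table
#' @param phenotype named numeric vector.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_phenotype <- function(phenotype, path) {
  utils::write.table(
    data.frame(sample_id = names(phenotype), trait = unname(phenotype)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention on read. A fourth column supplies interval
#' names; unnamed intervals get \code{chrom:start-end} labels.
#'
#' @param path BED path (3 or more columns, tab-separated, no header).
#' @return An interval set: data.frame with columns \code{name},
#'   \code{chrom}, \code{start}, \code{end} (1-based inclusive).
#' @export
read_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  chrom <- as.character(tab[[1L]])
  start <- as.integer(tab[[2L]]) + 1L
  end <- as.integer(tab[[3L]])
  name <- if (ncol(tab) >= 4L) as.character(tab[[4L]])
          else sprintf("%s:%d-%d", chrom, start, end)
  interval_set(name, chrom, start, end)
}

#' Construct an interval set (1-based inclusive coordinates)
#' @param name unique interval names.
#' @param chrom contig labels.
#' @param start,end 1-based inclusive bounds, \code{start <= end}.
#' @return data.frame of class \code{interval_set}.
#' @export
interval_set <- function(name, chrom, start, end) {
  name <- as.character(name); chrom <- as.character(chrom)
  start <- as.integer(start); end <- as.integer(end)
  if (anyDuplicated(name)) stop("interval names must be unique")
  if (any(start > end)) stop("interval start > end")
  if (any(start < 1L)) stop("interval start must be >= 1")
  structure(data.frame(name = name, chrom = chrom, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("interval_set", "data.frame"))
}

#' Restrict to the complete-case analysis sample
#'
#' Keeps exactly the samples that appear in both the genotype dataset and
#' the phenotype, have no missing genotype at any variant, and have a
#' non-missing finite trait value. Sample order of the dataset is preserved.
#' This mirrors the standard population-based setup of analysing only
#' independent individuals with fully observed dosages.
#'
#' @param dataset a [genotype_dataset()].
#' @param phenotype named numeric vector (names = sample IDs).
#' @return list with elements \code{dataset} (filtered) and
#'   \code{phenotype} (aligned named vector).
#' @export
filter_complete_cases <- function(dataset, phenotype) {
  ph <- phenotype[!is.na(phenotype) & is.finite(phenotype)]
  keep <- dataset$samples %in% names(ph) &
    rowSums(dataset$missing_mask) == 0L
  if (!any(keep)) stop("no samples remain after complete-case filtering")
  samples <- dataset$samples[keep]
  out <- genotype_dataset(samples, dataset$variants,
                          dataset$dosage[keep, , drop = FALSE],
                          dataset$missing_mask[keep, , drop = FALSE])
  list(dataset = out, phenotype = ph[samples])
}

#' Estimate per-variant minor allele frequencies
#'
#' The alternate-allele frequency of variant j is the sum of its non-missing
#' dosages divided by twice the number of non-missing samples; the MAF folds
#' it at 0.5: \code{min(f, 1 - f)}. Fractional (imputed) dosages contribute
#' directly, so no hard genotype calls are made.
#'
#' @param dataset a [genotype_dataset()].
#' @return numeric vector of MAFs in \[0, 0.5\], one per variant, named by
#'   variant ID.
#' @export
estimate_maf <- function(dataset) {
  obs <- !dataset$missing_mask
  n_obs <- colSums(obs)
  if (any(n_obs == 0L))
    stop("variant(s) with all genotypes missing: ",
         paste(dataset$variants$vid[n_obs == 0L], collapse = ", "))
  d <- dataset$dosage
  d[!obs] <- 0
  f <- colSums(d) / (2 * n_obs)
  maf <- pmin(f, 1 - f)
  names(maf) <- dataset$variants$vid
  maf
}
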