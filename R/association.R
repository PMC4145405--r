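#' Two-tailed per-column association p-values for a quantitative trait
#'
#' Each design column is tested by simple linear regression of the trait on
#' that column (with intercept); the two-sided p-value comes from the t
#' statistic of the slope, accommodating effects in either direction. A
#' constant column carries no information and gets p = 1 by convention.
#' Optional covariates are residualised out of both the trait and every
#' column before testing, with the degrees of freedom reduced accordingly.
#'
#' @param design a \code{collapsed_design} or a plain samples x columns
#'   numeric matrix.
#' @param phenotype numeric trait vector aligned to the design's rows.
#' @param covariates optional samples x q numeric covariate matrix.
#' @return Object of class \code{pvalue_set}: list with \code{p} (sorted
#'   ascending), \code{column} (design column index of each sorted p),
#'   \code{p_raw} (p-values in design column order), and \code{n}.
#' @export
single_variant_pvalues <- function(design, phenotype, covariates = NULL) {
  X <- if (inherits(design, "collapsed_design")) design$matrix else as.matrix(design)
  y <- as.numeric(phenotype)
  n <- length(y)
  if (nrow(X) != n) stop("design rows and phenotype length differ")
  if (n < 3L) stop("need at least 3 samples for the slope t-test")
  df <- n - 2L
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    qrc <- qr(cbind(1, C))
    y <- qr.resid(qrc, y)
    X <- qr.resid(qrc, X)
    df <- n - 2L - qrc$rank + 1L  # intercept already counted in the 2
  }
  p <- .column_pvalues(X, y, df)
  o <- order(p)
  structure(list(p = p[o], column = o, p_raw = p, n = length(p)),
            class = "pvalue_set")
}

# Vectorised slope t-test p-values via Pearson correlation.
# X: n x m (already residualised if needed), y: length n, df: residual df.
# Constant columns (or constant y) give r = 0 -> p = 1.
.column_pvalues <- function(X, y, df) {
  n <- length(y)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  Xc <- sweep(X, 2L, colMeans(X))
  sx <- sqrt(colSums(Xc^2))
  denom <- sx * sy
  r <- as.vector(crossprod(Xc, yc))
  r <- ifelse(denom > 0, r / denom, 0)
  r <- pmin(1, pmax(-1, r))
  .r_to_p(r, df)
}

# Map correlations to two-sided p-values, clamped into (0, 1].
# r^2 = 1 (perfect fit) gives t = Inf, pt tail 0, then the clamp floor.
.r_to_p <- function(r, df) {
  t2 <- r^2 * df / pmax(1 - r^2, 0)
  p <- 2 * stats::pt(sqrt(t2), df = df, lower.tail = FALSE)
  p[!is.finite(t2)] <- 0
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' @export
print.pvalue_set <- function(x, ...) {
  cat(sprintf("pvalue_set: %d ordered p-values, min %.3g\n", x$n, x$p[1L]))
  invisible(x)
}
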