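#' Higher Criticism statistic over ordered p-values
#'
#' With ordered p-values p_1 <= ... <= p_n, the statistic is
#' \deqn{HC_n = \max_{1 \le i \le n/2,\; p_i \ge 1/n}
#'       \sqrt{n}\,\frac{i/n - p_i}{\sqrt{p_i (1 - p_i)}},}
#' the maximal normalised departure of the empirical p-value distribution
#' from uniform — sensitive to sparse, weak signals. The index bound n/2 is
#' taken as floor(n/2). When no index satisfies both constraints (every
#' usable p-value lies below 1/n — an extreme departure), the function
#' returns \code{Inf} as a sentinel; permutation calibration treats the
#' sentinel as most extreme, with ties counted conservatively.
#'
#' @param pvals a [single_variant_pvalues()] result or a numeric vector of
#'   p-values (sorted internally).
#' @return HC value (larger = more significant), or \code{Inf} (sentinel).
#' @export
hc_statistic <- function(pvals) {
  p <- if (inherits(pvals, "pvalue_set")) pvals$p else sort(as.numeric(pvals))
  n <- length(p)
  if (n == 0L) stop("empty p-value set")
  imax <- n %/% 2L
  if (imax < 1L) return(Inf)
  i <- seq_len(imax)
  keep <- p[i] >= 1 / n
  if (!any(keep)) return(Inf)
  i <- i[keep]
  pi <- p[i]
  max(sqrt(n) * (i / n - pi) / sqrt(pi * (1 - pi)))
}

# HC for every column of an m x K matrix of (unsorted) p-values at once.
# Used by the permutation scan; semantics identical to hc_statistic().
.hc_columns <- function(P) {
  m <- nrow(P)
  K <- ncol(P)
  imax <- m %/% 2L
  if (imax < 1L) return(rep(Inf, K))
  Ps <- apply(P, 2L, sort.int, method = "quick")
  Ps <- matrix(Ps, nrow = m)
  Ps <- Ps[seq_len(imax), , drop = FALSE]
  I <- matrix(seq_len(imax) / m, nrow = imax, ncol = K)
  terms <- sqrt(m) * (I - Ps) / sqrt(Ps * (1 - Ps))
  eligible <- Ps >= 1 / m
  terms[!eligible] <- -Inf
  out <- do.call(pmax, asplit(terms, 1L))
  out[colSums(eligible) == 0L] <- Inf   # empty eligible set -> sentinel
  out
}

#' Minimum p-value (minP) group statistic
#'
#' The smallest per-column p-value in the group; smaller = more significant.
#' Its null distribution depends on the number and correlation of columns,
#' hence the permutation calibration.
#'
#' @inheritParams hc_statistic
#' @return the minimum p-value.
#' @export
minp_statistic <- function(pvals) {
  p <- if (inherits(pvals, "pvalue_set")) pvals$p else as.numeric(pvals)
  if (length(p) == 0L) stop("empty p-value set")
  min(p)
}

#' Flat-weight SKAT statistic and analytic p-value
#'
#' Variance-component score test for a quantitative trait: with null-model
#' residuals r (trait regressed on intercept and optional covariates) and
#' the group's original uncollapsed dosage matrix G (rare and common
#' variants alike, unweighted linear kernel), the statistic is
#' \deqn{Q = r^\top G G^\top r.}
#' Under the null, Q is distributed as a mixture of 1-df chi-squares with
#' weights \eqn{\hat\sigma^2 \lambda_k}, the eigenvalues of the projected
#' kernel; the analytic tail probability is evaluated by exact numerical
#' inversion of the characteristic function (Imhof's method) with a
#' Liu-type four-moment approximation as fallback. A rank-one kernel
#' reduces exactly to the 1-df chi-square of the per-variant score test.
#'
#' @param G samples x variants dosage matrix (original, uncollapsed).
#' @param phenotype numeric trait vector.
#' @param covariates optional covariate matrix (intercept always included).
#' @param method \code{"davies"} (Imhof-type exact inversion, default) or
#'   \code{"liu"} (moment matching).
#' @return list with \code{Q}, \code{p} (analytic), \code{lambda} (mixture
#'   weights), and \code{method} actually used.
#' @export
skat_statistic <- function(G, phenotype, covariates = NULL,
                           method = c("davies", "liu")) {
  method <- match.arg(method)
  G <- as.matrix(G)
  y <- as.numeric(phenotype)
  n <- length(y)
  stopifnot(nrow(G) == n)
  X0 <- if (is.null(covariates)) matrix(1, n, 1L) else cbind(1, as.matrix(covariates))
  qr0 <- qr(X0)
  if (n <= qr0$rank + 1L) stop("too few samples for the null model")
  r <- qr.resid(qr0, y)
  sigma2 <- sum(r^2) / (n - qr0$rank)
  score <- crossprod(G, r)
  Q <- sum(score^2)
  PG <- qr.resid(qr0, G)
  A <- crossprod(PG)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  # rank cut relative to the unprojected kernel scale, so columns that are
  # numerically constant (zero residual variance) drop out
  tol <- max(sum(G * G), 1) * 1e-12
  lambda <- sigma2 * ev[ev > tol]
  if (length(lambda) == 0L || sigma2 == 0)
    return(list(Q = 0, p = 1, lambda = numeric(0), method = "degenerate"))
  if (length(lambda) == 1L) {
    p <- stats::pchisq(Q / lambda, df = 1, lower.tail = FALSE)
    return(list(Q = Q, p = p, lambda = lambda, method = "exact_1df"))
  }
  p <- if (method == "davies") .imhof_tail(Q, lambda) else NA_real_
  used <- method
  if (!is.finite(p) || p < 0 || p > 1) {
    p <- .liu_tail(Q, lambda)
    used <- "liu"
  }
  list(Q = Q, p = min(max(p, 0), 1), lambda = lambda, method = used)
}

# Imhof (1961) numerical inversion of the characteristic function of a
# positively weighted chi-square mixture: P(T > q). The integrand
# oscillates with period about 4*pi/q, so the half-line is integrated one
# period at a time (each segment is smooth for the adaptive quadrature)
# and the alternating segment sums are accumulated until they vanish.
.imhof_tail <- function(q, lambda) {
  theta <- function(u) 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
  rho <- function(u) exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
  f <- function(u) {
    out <- sin(theta(u)) / (u * rho(u))
    out[u == 0] <- 0.5 * (sum(lambda) - q)
    out
  }
  L <- 4 * pi / max(q, sum(lambda) / 10, 1e-3)
  total <- 0
  small <- 0L
  for (seg in 0:4999) {
    val <- tryCatch(
      stats::integrate(f, seg * L, (seg + 1) * L, subdivisions = 1000L,
                       rel.tol = 1e-10, abs.tol = 1e-13,
                       stop.on.error = FALSE),
      error = function(e) NULL)
    if (is.null(val) || !is.finite(val$value)) return(NA_real_)
    total <- total + val$value
    small <- if (abs(val$value) < 1e-12 * max(1, abs(total))) small + 1L else 0L
    if (small >= 3L) break
  }
  0.5 + total / pi
}

# Liu-Tang-Zhang four-moment chi-square approximation: P(T > q).
.liu_tail <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- c2^3 / c3^2
  }
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  muX <- l + delta; sigmaX <- sqrt(2) * sqrt(l + 2 * delta)
  stats::pchisq((q - muQ) / sigmaQ * sigmaX + muX, df = l, ncp = delta,
                lower.tail = FALSE)
}
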