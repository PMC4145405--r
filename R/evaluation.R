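#' Genomic inflation factor lambda
#'
#' Each p-value is mapped to its 1-df chi-square upper-tail quantile;
#' lambda is the median of those chi-squares divided by the null median
#' (\code{qchisq(0.5, 1)} = 0.4549364). Lambda near 1 indicates correct
#' type-I calibration; lambda > 1, inflation.
#'
#' @param pvalues numeric p-values in (0, 1\].
#' @return lambda.
#' @export
genomic_lambda <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (any(pvalues <= 0))
    stop("p-values of 0 are not admissible; use the add-one permutation rule")
  chi <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Quantile-quantile table for p-values
#'
#' Expected i-th quantile is i/(n + 1); observed p-values are sorted
#' ascending. Both are also reported on the -log10 scale for plotting.
#'
#' @param pvalues numeric p-values in (0, 1\].
#' @return data.frame with columns \code{expected}, \code{observed},
#'   \code{neglog10_expected}, \code{neglog10_observed}.
#' @export
qq_table <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  n <- length(pvalues)
  obs <- sort(pvalues)
  exp_q <- seq_len(n) / (n + 1)
  data.frame(expected = exp_q, observed = obs,
             neglog10_expected = -log10(exp_q),
             neglog10_observed = -log10(obs))
}

#' Power curve: true-positive rate of true windows over p-value cutoffs
#'
#' Power at cutoff alpha is the fraction of true windows whose empirical
#' p-value is <= alpha. Evaluated over the full (0, 1) range of cutoffs the
#' curve is a receiver-operating-characteristic-style curve; its AUC is the
#' trapezoidal integral over the empirical step function, evaluated at
#' every distinct p-value plus the endpoints 0 and 1.
#'
#' @param results scan results data.frame (from [hc_scan()], possibly
#'   row-bound over replicates) with a \code{group} column and
#'   \code{<method>_p} columns.
#' @param truth character vector of true window names.
#' @param methods methods to score (default: all \code{*_p} columns found).
#' @param cutoffs optional cutoff grid; default is every distinct p-value
#'   among true windows plus the endpoints.
#' @return list of class \code{power_curve}: \code{cutoffs}, \code{tpr}
#'   (matrix cutoffs x methods), \code{auc} (named vector),
#'   \code{n_true} (number of scored true-window results).
#' @export
power_curve <- function(results, truth, methods = NULL, cutoffs = NULL) {
  if (length(truth) == 0L) stop("zero true windows: power is undefined")
  if (!all(truth %in% results$group))
    stop("results do not cover all true windows")
  sub <- results[results$group %in% truth, , drop = FALSE]
  pcols <- grep("_p$", names(results), value = TRUE)
  if (is.null(methods)) methods <- sub("_p$", "", pcols)
  if (is.null(cutoffs)) {
    cutoffs <- sort(unique(c(0, 1, unlist(sub[paste0(methods, "_p")]))))
  } else {
    cutoffs <- sort(unique(c(cutoffs)))
  }
  tpr <- vapply(methods, function(m) {
    p <- sub[[paste0(m, "_p")]]
    vapply(cutoffs, function(a) mean(p <= a), 0)
  }, numeric(length(cutoffs)))
  tpr <- matrix(tpr, ncol = length(methods),
                dimnames = list(NULL, methods))
  auc <- apply(tpr, 2L, function(v)
    sum(diff(cutoffs) * (v[-1L] + v[-length(v)]) / 2))
  structure(list(cutoffs = cutoffs, tpr = tpr, auc = auc,
                 n_true = nrow(sub)),
            class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("power_curve over %d true-window results; AUC: %s\n",
              x$n_true,
              paste(sprintf("%s=%.4f", names(x$auc), x$auc), collapse = ", ")))
  invisible(x)
}

#' Per-window power over simulation replicates
#'
#' For each true window and method, power is the fraction of replicates in
#' which the window's empirical p-value is <= alpha. Each window also gets
#' a categorical label: the method with the highest power, or
#' \code{"none"} when every method's power falls below the floor (the
#' "no power for any test" class).
#'
#' @param results_list list of scan-result data.frames, one per replicate
#'   of the same truth.
#' @param truth character vector of true window names.
#' @param alpha significance cutoff (default 0.05).
#' @param methods methods to score (default: all \code{*_p} columns).
#' @param power_floor floor below which a window is labelled "none"
#'   (default 0.1).
#' @return data.frame: \code{group}, one power column per method,
#'   \code{best} label.
#' @export
per_window_power <- function(results_list, truth, alpha = 0.05,
                             methods = NULL, power_floor = 0.1) {
  stopifnot(length(results_list) >= 1L)
  pcols <- grep("_p$", names(results_list[[1L]]), value = TRUE)
  if (is.null(methods)) methods <- sub("_p$", "", pcols)
  R <- length(results_list)
  pow <- vapply(methods, function(m) {
    vapply(truth, function(w) {
      mean(vapply(results_list, function(res)
        res[[paste0(m, "_p")]][match(w, res$group)] <= alpha, TRUE))
    }, 0)
  }, numeric(length(truth)))
  pow <- matrix(pow, ncol = length(methods),
                dimnames = list(truth, methods))
  best <- apply(pow, 1L, function(v)
    if (max(v) < power_floor) "none" else methods[which.max(v)])
  out <- data.frame(group = truth, pow, best = best,
                    row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  attr(out, "n_replicates") <- R
  out
}

#' Base-graphics QQ plot of p-values
#' @param pvalues numeric p-values in (0, 1].
#' @param ... passed to [graphics::plot()].
#' @return the [qq_table()], invisibly.
#' @export
plot_qq <- function(pvalues, ...) {
  tab <- qq_table(pvalues)
  graphics::plot(tab$neglog10_expected, tab$neglog10_observed,
                 xlab = expression(-log[10] ~ "expected p"),
                 ylab = expression(-log[10] ~ "observed p"), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(tab)
}

#' Base-graphics power curves per method
#' @param pc a [power_curve()].
#' @param ... passed to [graphics::matplot()].
#' @return \code{pc}, invisibly.
#' @export
plot_power_curve <- function(pc, ...) {
  graphics::matplot(pc$cutoffs, pc$tpr, type = "s", lty = 1,
                    xlab = "p-value cutoff", ylab = "power (TPR)", ...)
  graphics::legend("bottomright", legend = colnames(pc$tpr),
                   col = seq_len(ncol(pc$tpr)), lty = 1, bty = "n")
  invisible(pc)
}
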