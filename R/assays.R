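# Statistics for replicate assay readouts (LDH cytotoxicity, ELISA, qPCR):
# fold change of means, single-outlier Grubbs screen, Welch two-sample t,
# delta-delta-Ct relative quantification, platform correlation.

.assay_values <- function(x) {
  if (is.data.frame(x)) {
    if (!"value" %in% names(x)) stop("assay data frame needs a 'value' column",
                                     call. = FALSE)
    x$value
  } else {
    as.numeric(x)
  }
}

#' Assay fold change
#'
#' Mean of the treated replicates divided by the mean of the control
#' replicates (the plain, unsigned ratio used for assay readouts such as LDH
#' activity or ELISA absorbance).
#'
#' @param treated,control numeric vectors or assay-series data frames (see
#'   [read_assay_series()]).
#' @return a positive ratio.
#' @export
assay_fold_change <- function(treated, control) {
  t_vals <- .assay_values(treated); c_vals <- .assay_values(control)
  if (!length(t_vals) || !length(c_vals)) stop("both series must be non-empty",
                                               call. = FALSE)
  mc <- mean(c_vals)
  if (mc <= 0) stop("control mean must be > 0", call. = FALSE)
  mean(t_vals) / mc
}

#' Grubbs single-outlier test
#'
#' Two-sided single-outlier Grubbs test: `G = max|x - mean| / sd`, compared
#' with the closed-form critical value
#' `G_crit = ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` where `t` is the
#' upper `alpha / (2n)` quantile of the t-distribution with `n - 2` degrees of
#' freedom. At most one point is flagged per call; to screen for several
#' outliers, remove the flagged value and call again.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha significance level (default 0.05).
#' @return a list of class `"grubbs_result"`: `flagged_index` (index of the
#'   outlier, or `NA` if none), `G`, `critical`, `alpha`, `n`.
#' @examples
#' grubbs_test(c(1, 2, 3, 100))
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  values <- .assay_values(values)
  n <- length(values)
  if (n < 3) stop("Grubbs test needs n >= 3", call. = FALSE)
  s <- stats::sd(values)
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  if (s == 0) {
    res <- list(flagged_index = NA_integer_, G = 0, critical = crit,
                alpha = alpha, n = n)
  } else {
    dev <- abs(values - mean(values))
    G <- max(dev) / s
    idx <- which.max(dev)
    res <- list(flagged_index = if (G > crit) idx else NA_integer_,
                G = G, critical = crit, alpha = alpha, n = n)
  }
  class(res) <- "grubbs_result"
  res
}

#' @export
print.grubbs_result <- function(x, ...) {
  cat(sprintf("Grubbs test (n = %d, alpha = %.3g): G = %.4f, critical = %.4f -> %s\n",
              x$n, x$alpha, x$G, x$critical,
              if (is.na(x$flagged_index)) "no outlier"
              else sprintf("value %d flagged", x$flagged_index)))
  invisible(x)
}

#' Iteratively remove Grubbs outliers
#'
#' Applies [grubbs_test()] repeatedly, removing the flagged value each round,
#' until no outlier remains (or fewer than 3 values are left).
#'
#' @param values numeric vector.
#' @param alpha significance level per round.
#' @param max_iter safety cap on removals.
#' @return a list with `values` (cleaned), `removed_index` (indices into the
#'   original vector, in removal order) and `tests` (the per-round results).
#' @export
grubbs_screen <- function(values, alpha = 0.05, max_iter = length(values)) {
  values <- .assay_values(values)
  keep <- seq_along(values)
  removed <- integer(0)
  tests <- list()
  while (length(keep) >= 3 && length(removed) < max_iter) {
    g <- grubbs_test(values[keep], alpha)
    tests[[length(tests) + 1]] <- g
    if (is.na(g$flagged_index)) break
    removed <- c(removed, keep[g$flagged_index])
    keep <- keep[-g$flagged_index]
  }
  list(values = values[keep], removed_index = removed, tests = tests)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value, plus the treated/control fold change of means.
#' Degenerate input (both groups with zero variance) yields `t = 0, p = 1`
#' when the means are equal and `t = +/-Inf, p = 0` otherwise.
#'
#' @param treated,control numeric vectors (>= 2 each) or assay-series data
#'   frames.
#' @return a list of class `"two_sample_result"`: `fold_change`,
#'   `t_statistic`, `degrees_of_freedom`, `p_value`, `mean_treated`,
#'   `mean_control`.
#' @examples
#' welch_t_test(c(20, 22, 24), c(10, 12, 14))
#' @export
welch_t_test <- function(treated, control) {
  t_vals <- .assay_values(treated); c_vals <- .assay_values(control)
  if (length(t_vals) < 2 || length(c_vals) < 2) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  mt <- mean(t_vals); mc <- mean(c_vals)
  if (stats::sd(t_vals) == 0 && stats::sd(c_vals) == 0) {
    res <- list(fold_change = if (mc > 0) mt / mc else NA_real_,
                t_statistic = if (mt == mc) 0 else sign(mt - mc) * Inf,
                degrees_of_freedom = length(t_vals) + length(c_vals) - 2,
                p_value = if (mt == mc) 1 else 0,
                mean_treated = mt, mean_control = mc)
  } else {
    ht <- stats::t.test(t_vals, c_vals, var.equal = FALSE)
    res <- list(fold_change = if (mc > 0) mt / mc else NA_real_,
                t_statistic = unname(ht$statistic),
                degrees_of_freedom = unname(ht$parameter),
                p_value = ht$p.value,
                mean_treated = mt, mean_control = mc)
  }
  class(res) <- "two_sample_result"
  res
}

#' @export
print.two_sample_result <- function(x, ...) {
  cat(sprintf("Welch t-test: FC = %.4g, t = %.4g, df = %.3f, p = %.4g\n",
              x$fold_change, x$t_statistic, x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' Relative quantification of qPCR expression (delta-delta-Ct)
#'
#' Computes `2^-ddCt` from mean cycle thresholds, where
#' `ddCt = (Ct_target - Ct_reference)_treated - (Ct_target - Ct_reference)_control`,
#' then converts the ratio to the signed fold-change convention of
#' [signed_fold_change()]. The reference (normalizer) assay must be supplied
#' explicitly — there is no defensible default.
#'
#' @param ct_target_treated,ct_target_control Ct values of the target assay.
#' @param ct_ref_treated,ct_ref_control Ct values of the reference assay.
#' @return signed fold change of the target's relative abundance.
#' @examples
#' # target one cycle later in treated (ddCt = +1): ratio 0.5 -> signed FC -2
#' relative_quantification(21, 20, 15, 15)
#' @export
relative_quantification <- function(ct_target_treated, ct_target_control,
                                    ct_ref_treated, ct_ref_control) {
  cts <- c(ct_target_treated, ct_target_control, ct_ref_treated, ct_ref_control)
  if (any(!is.finite(cts))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (mean(ct_target_treated) - mean(ct_ref_treated)) -
    (mean(ct_target_control) - mean(ct_ref_control))
  ratio <- 2^(-ddct)
  if (ratio >= 1) ratio else -1 / ratio
}

#' Cross-platform abundance correlation
#'
#' Pearson correlation of paired per-item abundances measured on two
#' platforms (e.g. mean qPCR-derived abundance vs mean array intensity per
#' miRNA).
#'
#' @param series_a,series_b paired numeric vectors, >= 3 items.
#' @return the Pearson correlation coefficient; `NA` (with a warning) when
#'   either series has zero variance.
#' @export
platform_correlation <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) {
    stop("series must be paired (equal length)", call. = FALSE)
  }
  if (length(series_a) < 3) stop("need >= 3 paired items", call. = FALSE)
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0) {
    warning("correlation undefined: a series has zero variance", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(series_a, series_b, method = "pearson")
}
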