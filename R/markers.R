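# Differential-expression core: signed fold change, SNR statistic,
# permutation null, pooled ("smoothed") empirical p-values, BH FDR and the
# three-criterion significance call.

#' Signed fold change
#'
#' Ratio of treated to control group means, reported on the signed
#' convention customary for array studies: the plain ratio `r` when `r >= 1`
#' and `-1/r` when `r < 1` (so a halving is `-2`, never `0.5`). By
#' construction `|fc| >= 1`; negative values mean lower expression in the
#' treated group.
#'
#' @param mean_treated,mean_control positive group means (linear scale);
#'   vectorized.
#' @return signed fold change(s).
#' @examples
#' signed_fold_change(15, 10)  # 1.5
#' signed_fold_change(2, 10)   # -5
#' @export
signed_fold_change <- function(mean_treated, mean_control) {
  if (any(mean_treated <= 0) || any(mean_control <= 0)) {
    stop("group means must be > 0 for a fold change", call. = FALSE)
  }
  r <- mean_treated / mean_control
  ifelse(r >= 1, r, -1 / r)
}

# row-wise sample sd (denominator n - 1)
.row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1))
}

# vectorized SNR over rows of a (log-scale) matrix for one labeling
.snr_rows <- function(logm, treated_cols, control_cols,
                      sigma_floor = 1e-8, relative_floor = FALSE) {
  a <- logm[, treated_cols, drop = FALSE]
  b <- logm[, control_cols, drop = FALSE]
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  sd_a <- pmax(.row_sds(a), sigma_floor)
  sd_b <- pmax(.row_sds(b), sigma_floor)
  if (relative_floor) {
    sd_a <- pmax(sd_a, 0.2 * abs(mu_a))
    sd_b <- pmax(sd_b, 0.2 * abs(mu_b))
  }
  list(snr = (mu_a - mu_b) / (sd_a + sd_b),
       mu_a = mu_a, mu_b = mu_b, sd_a = sd_a, sd_b = sd_b)
}

#' Signal-to-noise-ratio statistic
#'
#' `SNR = (mu_A - mu_B) / (sigma_A + sigma_B)` with A = treated, B = control,
#' using sample (n-1) standard deviations. Each sigma is floored at
#' `sigma_floor` to avoid division by zero; with `relative_floor = TRUE` it
#' is additionally floored at `0.2 * |mu|` of its group, the classic
#' variance-regularized convention of SNR-based marker selection (at the
#' cost of losing invariance to additive shifts).
#'
#' @param treated_values,control_values numeric vectors, >= 2 values each.
#' @param sigma_floor absolute lower bound on each group sd.
#' @param relative_floor apply the `0.2 * |mu|` relative floor as well.
#' @return a list with `snr` and `summary` (mu/sigma per group, the sigmas
#'   after flooring).
#' @examples
#' snr_statistic(c(4, 6), c(1, 3))$snr  # 3 / (2 * sqrt(2)) ~ 1.0607
#' @export
snr_statistic <- function(treated_values, control_values,
                          sigma_floor = 1e-8, relative_floor = FALSE) {
  if (length(treated_values) < 2 || length(control_values) < 2) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  m <- rbind(c(treated_values, control_values))
  r <- .snr_rows(m, seq_along(treated_values),
                 length(treated_values) + seq_along(control_values),
                 sigma_floor, relative_floor)
  list(snr = unname(r$snr),
       summary = list(mu_treated = unname(r$mu_a), mu_control = unname(r$mu_b),
                      sigma_treated = unname(r$sd_a), sigma_control = unname(r$sd_b)))
}

#' Enumerate or sample group relabelings
#'
#' A relabeling assigns `n_treated` of the `n` samples to the treated group.
#' When the number of distinct relabelings `choose(n, n_treated)` does not
#' exceed `n_perm`, all of them are enumerated once (exhaustive mode,
#' seed-independent); otherwise `n_perm` distinct relabelings are sampled
#' without replacement (seeded).
#'
#' @param n total number of samples.
#' @param n_treated samples assigned to the treated group.
#' @param n_perm requested number of permutations (>= 1).
#' @param seed integer seed (required in sampled mode).
#' @return a list with `labelings` (matrix, one column per relabeling, rows =
#'   treated column indices) and `mode` (`"exhaustive"` or `"sampled"`).
#' @export
permutation_relabelings <- function(n, n_treated, n_perm = 2000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  total <- choose(n, n_treated)
  if (total <= n_perm) {
    return(list(labelings = utils::combn(n, n_treated), mode = "exhaustive"))
  }
  .local_seed(seed, {
    if (total <= 1e5) {
      all <- utils::combn(n, n_treated)
      list(labelings = all[, sample(ncol(all), n_perm), drop = FALSE],
           mode = "sampled")
    } else {
      seen <- new.env(hash = TRUE)
      out <- matrix(0L, n_treated, n_perm)
      k <- 0L
      while (k < n_perm) {
        cand <- sort(sample.int(n, n_treated))
        key <- paste(cand, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          k <- k + 1L
          out[, k] <- cand
        }
      }
      list(labelings = out, mode = "sampled")
    }
  })
}

#' Permutation null distribution of the SNR statistic
#'
#' Recomputes the per-miRNA SNR under every relabeling of samples to groups
#' (group sizes preserved) and pools the statistics across miRNAs and
#' relabelings. In a 3-vs-3 design there are exactly `choose(6, 3) = 20`
#' distinct relabelings, so exhaustive enumeration applies whenever more than
#' 20 permutations are requested, and the pool has `20 x n_mirnas` entries.
#'
#' With `drop_observed = TRUE` the observed assignment — and, for balanced
#' designs, its label-swap mirror, which reproduces the observed statistic
#' with the opposite sign — is excluded for every miRNA, so the pool contains
#' only relabelings that genuinely mix the two groups. This is the pool the
#' [mirna_markers()] fit uses: leaving each marker's own observed statistic
#' (and every other true marker's) in the pool places a floor under the
#' attainable pooled p-values that defeats FDR control in small designs.
#'
#' @param logm numeric matrix of (log-scale) values, rows = miRNAs, columns =
#'   samples.
#' @param group factor/character of `"treated"`/`"control"` per column.
#' @param n_perm requested permutations (default 2000).
#' @param seed integer seed (used only in sampled mode).
#' @param sigma_floor,relative_floor passed to the SNR computation.
#' @param drop_observed exclude the observed assignment (and its mirror) from
#'   the pool.
#' @return a list with `pool` (numeric vector of pooled null SNRs), `stats`
#'   (matrix miRNAs x relabelings), `mode`, and `labelings`.
#' @export
permutation_null <- function(logm, group, n_perm = 2000, seed = 1,
                             sigma_floor = 1e-8, relative_floor = FALSE,
                             drop_observed = FALSE) {
  group <- as.character(group)
  treated_obs <- which(group == "treated")
  n <- length(group)
  rel <- permutation_relabelings(n, length(treated_obs), n_perm, seed)
  lab <- rel$labelings
  if (drop_observed) {
    obs_key <- paste(sort(treated_obs), collapse = ",")
    keys <- apply(lab, 2, function(cols) paste(sort(cols), collapse = ","))
    drop <- keys == obs_key
    if (length(treated_obs) == n - length(treated_obs)) {
      mirror_key <- paste(sort(setdiff(seq_len(n), treated_obs)), collapse = ",")
      drop <- drop | keys == mirror_key
    }
    lab <- lab[, !drop, drop = FALSE]
    if (ncol(lab) == 0) stop("no mixing relabelings left after dropping the observed assignment",
                             call. = FALSE)
  }
  stats <- vapply(seq_len(ncol(lab)), function(j) {
    a <- lab[, j]
    .snr_rows(logm, a, setdiff(seq_len(n), a), sigma_floor, relative_floor)$snr
  }, numeric(nrow(logm)))
  if (is.null(dim(stats))) stats <- matrix(stats, nrow = nrow(logm))
  rownames(stats) <- rownames(logm)
  list(pool = as.vector(stats), stats = stats, mode = rel$mode, labelings = lab)
}

#' Pooled ("smoothed") empirical p-value
#'
#' Two-sided empirical p-value against a pooled permutation null with
#' add-one smoothing: `p = (b + 1) / (N + 1)` where `b` counts pooled null
#' statistics with `|null| >= |observed|` and `N` is the pool size. Pooling
#' the null across miRNAs gives resolution far below the 1/20 granularity of
#' a single miRNA's 3-vs-3 permutation distribution, which is how p-values
#' under 0.005 are attainable in such designs.
#'
#' @param observed_snr numeric vector of observed statistics.
#' @param null_pool non-empty numeric vector of pooled null statistics.
#' @return p-values in (0, 1\], one per observed statistic.
#' @examples
#' smoothed_p(0.75, c(-1, -0.5, 0.5, 1))  # (2 + 1) / (4 + 1) = 0.6
#' @export
smoothed_p <- function(observed_snr, null_pool) {
  if (!length(null_pool)) stop("null pool is empty", call. = FALSE)
  sorted <- sort(abs(null_pool))
  n <- length(sorted)
  below <- findInterval(abs(observed_snr), sorted, left.open = TRUE)
  (n - below + 1) / (n + 1)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment (sort ascending, `q_i = p_i * m / i`, cumulative
#' minimum from the largest rank, cap at 1), returned in input order.
#' Delegates to [stats::p.adjust()] after validating that every p lies in
#' (0, 1\].
#'
#' @param p_values numeric vector of raw p-values in (0, 1\].
#' @return adjusted values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Three-criterion differential-expression call
#'
#' A miRNA is called significant when all of (a) `|fc| >= fc_cut` (boundary
#' inclusive, matching the convention "FC >= 1.5 or <= -1.5"), (b)
#' `p < p_cut` (strict) and (c) `fdr < fdr_cut` (strict) hold. Results are
#' ranked by `|fc|` descending, then p ascending, then miRNA id — a
#' deterministic ordering for identical inputs.
#'
#' @param results data frame with columns `mirna_id`, `fc`, `p_value`, `fdr`.
#' @param fc_cut,p_cut,fdr_cut the three thresholds (defaults 1.5, 0.005,
#'   0.005).
#' @return the data frame with `significant` (logical) and `rank` columns,
#'   ordered by rank.
#' @export
call_differential <- function(results, fc_cut = 1.5, p_cut = 0.005,
                              fdr_cut = 0.005) {
  stopifnot(all(c("mirna_id", "fc", "p_value", "fdr") %in% names(results)))
  results$significant <- abs(results$fc) >= fc_cut &
    results$p_value < p_cut & results$fdr < fdr_cut
  ord <- order(-abs(results$fc), results$p_value, results$mirna_id)
  results <- results[ord, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  rownames(results) <- NULL
  results
}

#' Fit permutation-SNR markers to a two-group expression matrix
#'
#' The package's central fit. For every miRNA it computes the signed fold
#' change of linear-scale group means, the SNR statistic on
#' `log2(intensity + 1)` (log transform stabilizes multiplicative array
#' noise; linear means match the conventional fold-change definition), a
#' pooled-permutation smoothed p-value, a Benjamini-Hochberg FDR across all
#' fitted miRNAs, and the three-criterion significance call.
#'
#' The null pool is built from relabelings that mix the two groups (the
#' observed assignment and its label-swap mirror are excluded; see
#' [permutation_null()]) and, by default, only from miRNAs whose observed
#' fold change lies below `fc_cut` — candidate markers do not inform the
#' null, so strong true signal cannot fatten the pooled tail and mask weaker
#' markers. The SNR uses the `0.2 * |mu|` relative sigma floor by default,
#' the variance-regularized convention that keeps the pooled null's tails
#' comparable across miRNAs.
#'
#' Note an inherent granularity of the pooled add-one estimator: with `R`
#' mixing relabelings per miRNA (18 in a 3-vs-3 design) the smallest
#' attainable BH-adjusted value when `k` markers tie at the minimal p is
#' about `1 / (R * k)`, so an FDR threshold of 0.005 can only be cleared
#' when at least 12 markers are significant together.
#'
#' @param x a miRNA-level `mir_expr` object (linear intensities), e.g. the
#'   output of [collapse_to_mirna()]; or a plain named numeric matrix if
#'   `group` is supplied.
#' @param group group labels per column, only when `x` is a plain matrix.
#' @param n_perm requested permutation count (default 2000; collapses to
#'   exhaustive enumeration whenever fewer distinct relabelings exist).
#' @param fc_cut,p_cut,fdr_cut significance thresholds (defaults 1.5, 0.005,
#'   0.005).
#' @param sigma_floor absolute sd floor.
#' @param relative_floor apply the `0.2 * |mu|` floor (default `TRUE` here,
#'   unlike the raw [snr_statistic()]).
#' @param pool one of `"mixing"` (default: observed assignment and mirror
#'   excluded from the null pool) or `"all"` (every relabeling pooled).
#' @param exclude_candidates exclude rows with `|fc| >= fc_cut` from null-pool
#'   construction (default `TRUE`; falls back to all rows when nothing would
#'   remain).
#' @param seed integer seed (consumed only if relabelings must be sampled).
#' @return an object of class `"mirna_markers"`: list with `results` (the
#'   ranked marker table), `cuts`, `permutation` (mode, counts, pool size),
#'   `design` (group sizes), `sigma` (floor settings), `seed` and `call`.
#'   Methods: `print`, `summary`, `coef` (named SNR vector),
#'   `as.data.frame`, `plot` (clustered heat map of significant miRNAs).
#' @examples
#' sim <- simulate_expression(sim_config(
#'   n_probes = 200, n_mirnas = 50, detectable_fraction = 1,
#'   spiked_mirnas = c("mir-0001" = -4), seed = 5))
#' mirna <- collapse_to_mirna(sim$expr, sim$annotation)
#' fit <- mirna_markers(mirna, seed = 5)
#' head(as.data.frame(fit))
#' @export
mirna_markers <- function(x, group = NULL, n_perm = 2000,
                          fc_cut = 1.5, p_cut = 0.005, fdr_cut = 0.005,
                          sigma_floor = 1e-8, relative_floor = TRUE,
                          pool = c("mixing", "all"),
                          exclude_candidates = TRUE, seed = 1) {
  pool <- match.arg(pool)
  if (!inherits(x, "mir_expr")) {
    if (is.null(group)) stop("supply a mir_expr object or a matrix plus 'group'",
                             call. = FALSE)
    x <- expression_matrix(x, group)
  }
  cols <- .group_cols(x)
  if (length(cols$treated) < 2 || length(cols$control) < 2) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  linear <- x$values
  logm <- log2(linear + 1)
  obs <- .snr_rows(logm, cols$treated, cols$control, sigma_floor, relative_floor)
  fc <- signed_fold_change(rowMeans(linear[, cols$treated, drop = FALSE]),
                           rowMeans(linear[, cols$control, drop = FALSE]))
  # The pooled null must estimate the *null*: rows that look like candidate
  # markers (|fc| beyond the cut) are excluded from pool construction, so
  # true signal does not fatten the pooled tail and mask weaker markers.
  # Falls back to all rows if the exclusion would empty the pool.
  null_rows <- if (isTRUE(exclude_candidates)) which(abs(fc) < fc_cut) else
    seq_len(nrow(logm))
  if (!length(null_rows)) null_rows <- seq_len(nrow(logm))
  null <- permutation_null(logm[null_rows, , drop = FALSE], x$group,
                           n_perm = n_perm, seed = seed,
                           sigma_floor = sigma_floor,
                           relative_floor = relative_floor,
                           drop_observed = (pool == "mixing"))
  p <- smoothed_p(obs$snr, null$pool)
  fdr <- benjamini_hochberg(p)
  results <- data.frame(
    mirna_id = rownames(linear),
    mu_treated = obs$mu_a, mu_control = obs$mu_b,
    sigma_treated = obs$sd_a, sigma_control = obs$sd_b,
    fc = unname(fc), snr = obs$snr, p_value = p, fdr = fdr,
    stringsAsFactors = FALSE)
  results <- call_differential(results, fc_cut, p_cut, fdr_cut)
  structure(list(
    results = results,
    cuts = c(fc = fc_cut, p = p_cut, fdr = fdr_cut),
    permutation = list(mode = null$mode, n_relabelings = ncol(null$labelings),
                       pool_size = length(null$pool), pool = pool,
                       n_perm_requested = n_perm),
    design = c(treated = length(cols$treated), control = length(cols$control)),
    sigma = list(floor = sigma_floor, relative = relative_floor),
    seed = seed,
    data = x,
    call = match.call()),
    class = "mirna_markers")
}

#' @export
print.mirna_markers <- function(x, ...) {
  r <- x$results
  cat(sprintf("Permutation-SNR marker fit: %d miRNAs, %d treated vs %d control\n",
              nrow(r), x$design["treated"], x$design["control"]))
  cat(sprintf("  %s permutations: %d relabelings, pooled null of %d statistics (%s pool)\n",
              x$permutation$mode, x$permutation$n_relabelings,
              x$permutation$pool_size, x$permutation$pool))
  cat(sprintf("  significant (|FC| >= %.3g, p < %.3g, FDR < %.3g): %d down, %d up\n",
              x$cuts["fc"], x$cuts["p"], x$cuts["fdr"],
              sum(r$significant & r$fc < 0), sum(r$significant & r$fc > 0)))
  invisible(x)
}

#' @export
summary.mirna_markers <- function(object, n = 10, ...) {
  r <- object$results
  out <- list(n_mirnas = nrow(r),
              n_significant = sum(r$significant),
              n_down = sum(r$significant & r$fc < 0),
              n_up = sum(r$significant & r$fc > 0),
              cuts = object$cuts,
              top = utils::head(r[, c("mirna_id", "fc", "snr", "p_value",
                                      "fdr", "significant")], n))
  class(out) <- "summary.mirna_markers"
  out
}

#' @export
print.summary.mirna_markers <- function(x, ...) {
  cat(sprintf("%d miRNAs tested; %d significant (%d down, %d up) at |FC| >= %.3g, p < %.3g, FDR < %.3g\n",
              x$n_mirnas, x$n_significant, x$n_down, x$n_up,
              x$cuts["fc"], x$cuts["p"], x$cuts["fdr"]))
  cat("Top-ranked markers:\n")
  print(x$top, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mirna_markers <- function(object, ...) {
  stats::setNames(object$results$snr, object$results$mirna_id)
}

#' @export
as.data.frame.mirna_markers <- function(x, ...) x$results

#' Significant markers of a fit
#'
#' @param object a `mirna_markers` fit.
#' @return the rows of the result table passing all three criteria.
#' @export
significant_markers <- function(object) {
  stopifnot(inherits(object, "mirna_markers"))
  object$results[object$results$significant, , drop = FALSE]
}

#' Mean-standardize rows and cluster them
#'
#' Reproduces the usual heat-map preprocessing: each miRNA row is z-scored
#' (row mean subtracted, divided by the row sd; constant rows become all
#' zeros), then rows are clustered agglomeratively with average linkage on
#' the `1 - Pearson correlation` distance. Pairs involving a constant row
#' have undefined correlation and are assigned the neutral distance 1.
#'
#' @param x a miRNA-level `mir_expr` object.
#' @param mirna_subset non-empty character vector of miRNA ids to include.
#' @return a list with `standardized` (matrix, rows in input-subset order),
#'   `order` (leaf order of the clustering, as row indices into
#'   `standardized`), and `hclust` (the tree, `NULL` for a single row).
#' @export
standardize_and_cluster <- function(x, mirna_subset) {
  stopifnot(inherits(x, "mir_expr"))
  if (!length(mirna_subset)) stop("subset is empty", call. = FALSE)
  unknown <- setdiff(mirna_subset, rownames(x$values))
  if (length(unknown)) {
    stop("unknown miRNA(s): ", paste(utils::head(unknown, 5), collapse = ", "),
         call. = FALSE)
  }
  m <- log2(x$values[mirna_subset, , drop = FALSE] + 1)
  mu <- rowMeans(m)
  sdv <- .row_sds(m)
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  if (nrow(z) < 2) {
    return(list(standardized = z, order = seq_len(nrow(z)), hclust = NULL))
  }
  cc <- suppressWarnings(stats::cor(t(z)))
  cc[!is.finite(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  list(standardized = z, order = hc$order, hclust = hc)
}

#' @describeIn mirna_markers heat map of the significant (or top-ranked)
#'   miRNAs after mean standardization and average-linkage correlation
#'   clustering.
#' @param y ignored.
#' @param top_n fall back to this many top-ranked miRNAs when fewer than two
#'   are significant.
#' @param ... further arguments passed to [graphics::image()].
#' @export
plot.mirna_markers <- function(x, y, top_n = 25, ...) {
  r <- x$results
  ids <- r$mirna_id[r$significant]
  if (length(ids) < 2) ids <- utils::head(r$mirna_id, top_n)
  sc <- standardize_and_cluster(x$data, ids)
  z <- sc$standardized[sc$order, , drop = FALSE]
  graphics::image(seq_len(ncol(z)), seq_len(nrow(z)), t(z),
                  col = grDevices::hcl.colors(51, "Blue-Red 2"),
                  xlab = "sample", ylab = "", axes = FALSE, ...)
  graphics::axis(1, at = seq_len(ncol(z)), labels = colnames(z), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(z)), labels = rownames(z), las = 2,
                 cex.axis = 0.6)
  graphics::box()
  invisible(sc)
}
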