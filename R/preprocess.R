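# Background filtering of probe-level records and probe -> miRNA collapse.

#' Default background threshold
#'
#' The median over arrays of each array's median signal: the conventional
#' "background approximating the median signal per array" rule. On typical
#' miRNA arrays, where roughly half the probes interrogate unexpressed
#' species, this lands near the detection floor (about 30 intensity units on
#' the platform this package emulates).
#'
#' @param x a `mir_expr` object (probe level, linear intensities).
#' @return a single intensity value.
#' @export
default_threshold <- function(x) {
  stopifnot(inherits(x, "mir_expr"))
  if (nrow(x$values) == 0) stop("empty matrix", call. = FALSE)
  stats::median(apply(x$values, 2, stats::median))
}

#' Filter probes below a background intensity
#'
#' Retains exactly the probes whose mean intensity across all samples is
#' strictly greater than `threshold`. The strict inequality makes behaviour
#' at the threshold deterministic (a probe averaging exactly the background
#' is treated as undetectable).
#'
#' @param x a probe-level `mir_expr` object.
#' @param threshold positive intensity; use [default_threshold()] for the
#'   median-of-medians rule.
#' @param annotation optional probe annotation (data frame `probe_id`,
#'   `mirna_id`); when supplied the report also counts the miRNAs with at
#'   least one retained probe.
#' @return a list with `expr` (the filtered matrix) and `report` (a
#'   `filter_report`: `n_input_records`, `n_retained_records`,
#'   `background_threshold`, `n_detectable_mirnas` — `NA` without annotation).
#' @examples
#' sim <- simulate_expression(sim_config(n_probes = 60, n_mirnas = 12, seed = 3))
#' filt <- filter_background(sim$expr, 30, sim$annotation)
#' filt$report
#' @export
filter_background <- function(x, threshold, annotation = NULL) {
  stopifnot(inherits(x, "mir_expr"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("threshold must be a single value > 0", call. = FALSE)
  }
  keep <- rowMeans(x$values) > threshold
  out <- expression_matrix(x$values[keep, , drop = FALSE], x$group)
  n_detect <- NA_integer_
  if (!is.null(annotation)) {
    n_detect <- length(unique(
      annotation$mirna_id[annotation$probe_id %in% rownames(out$values)]))
  }
  report <- structure(
    list(n_input_records = nrow(x$values),
         n_retained_records = sum(keep),
         background_threshold = threshold,
         n_detectable_mirnas = n_detect),
    class = "filter_report")
  list(expr = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("background filter at %.4g: %d of %d probe records retained",
              x$background_threshold, x$n_retained_records, x$n_input_records))
  if (!is.na(x$n_detectable_mirnas)) {
    cat(sprintf("; %d detectable miRNAs", x$n_detectable_mirnas))
  }
  cat("\n")
  invisible(x)
}

#' Collapse probe-level intensities to one row per miRNA
#'
#' Per sample, each miRNA's value is the median of its retained probes'
#' intensities — robust to a single aberrant probe. Every probe present in
#' the matrix must be annotated.
#'
#' @param x a probe-level `mir_expr` object (typically the output of
#'   [filter_background()]).
#' @param annotation data frame with columns `probe_id`, `mirna_id`.
#' @return a miRNA-level `mir_expr` object, rows ordered by miRNA id.
#' @export
collapse_to_mirna <- function(x, annotation) {
  stopifnot(inherits(x, "mir_expr"))
  probes <- rownames(x$values)
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx)) {
    stop("probe(s) without annotation: ",
         paste(probes[is.na(idx)][seq_len(min(5, sum(is.na(idx))))],
               collapse = ", "), call. = FALSE)
  }
  mir <- annotation$mirna_id[idx]
  groups <- split(seq_along(probes), mir)
  vals <- t(vapply(groups, function(rows) {
    apply(x$values[rows, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(x$values))))
  colnames(vals) <- colnames(x$values)
  expression_matrix(vals[order(rownames(vals)), , drop = FALSE], x$group)
}
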