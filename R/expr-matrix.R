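#' Expression matrix with sample group labels
#'
#' The pipeline's central container: a non-negative linear-scale intensity
#' matrix (rows = probes or miRNAs, columns = samples) together with a
#' treated/control label for every sample. Validation is strict: duplicate
#' identifiers, unlabeled samples, non-finite or negative intensities and
#' single-group designs are rejected, because every downstream statistic
#' assumes a clean two-group layout.
#'
#' @param values numeric matrix with unique row names (feature identifiers)
#'   and unique column names (sample identifiers); linear-scale intensities.
#' @param group character or factor vector, one entry per column of `values`,
#'   each `"treated"` or `"control"`. May be named by sample identifier; if
#'   unnamed it is taken in column order.
#' @return An object of class `"mir_expr"`: a list with elements `values`
#'   (the matrix) and `group` (factor with levels `control`, `treated`,
#'   named by sample).
#' @examples
#' m <- matrix(c(10, 20, 30, 40), 2, 2,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' x <- expression_matrix(m, c(s1 = "treated", s2 = "control"))
#' n_features(x)
#' @export
expression_matrix <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have row and column names", call. = FALSE)
  }
  dup_r <- duplicated(rownames(values))
  if (any(dup_r)) {
    stop("duplicate feature identifier(s): ",
         paste(unique(rownames(values)[dup_r]), collapse = ", "), call. = FALSE)
  }
  dup_c <- duplicated(colnames(values))
  if (any(dup_c)) {
    stop("duplicate sample identifier(s): ",
         paste(unique(colnames(values)[dup_c]), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "intensities must be finite and >= 0; first offender at probe '%s', sample '%s'",
      rownames(values)[i[1]], colnames(values)[i[2]]), call. = FALSE)
  }
  group <- stats::setNames(as.character(group), names(group))
  if (!is.null(names(group)) && all(nzchar(names(group)))) {
    missing <- setdiff(colnames(values), names(group))
    if (length(missing)) {
      stop("no group label for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    group <- group[colnames(values)]
  } else {
    if (length(group) != ncol(values)) {
      stop("'group' must have one entry per sample column", call. = FALSE)
    }
    names(group) <- colnames(values)
  }
  bad_lab <- setdiff(unique(group), c("treated", "control"))
  if (length(bad_lab)) {
    stop("unknown group label(s): ", paste(bad_lab, collapse = ", "),
         " (expected 'treated' or 'control')", call. = FALSE)
  }
  group <- factor(group, levels = c("control", "treated"))
  if (any(table(group) == 0)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  structure(list(values = values, group = group), class = "mir_expr")
}

#' @rdname expression_matrix
#' @param x a `mir_expr` object.
#' @export
n_features <- function(x) nrow(x$values)

#' @rdname expression_matrix
#' @export
n_samples <- function(x) ncol(x$values)

#' @rdname expression_matrix
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.mir_expr <- function(x, ...) {
  cat(sprintf("<mir_expr> %d features x %d samples (%d treated, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "treated"), sum(x$group == "control")))
  invisible(x)
}

#' @export
dim.mir_expr <- function(x) dim(x$values)

# internal: column indices of each group
.group_cols <- function(x) {
  list(treated = which(x$group == "treated"),
       control = which(x$group == "control"))
}
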