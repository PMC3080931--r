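# On-disk formats: TSV matrices and tables, GMT gene sets, GEO series-matrix.
# Dialect: UTF-8, tab-separated, first column = identifier, '#' comment lines
# ignored. Writers put one provenance comment line at the top; readers skip it.

.provenance_line <- function(extra = NULL) {
  v <- tryCatch(as.character(utils::packageVersion("mirperm")),
                error = function(e) "dev")
  paste0("# mirperm ", v, if (!is.null(extra)) paste0(" ", extra) else "")
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

.write_tsv <- function(df, path, extra = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance_line(extra), con)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write expression matrices
#'
#' `read_expression()` loads a tab-separated intensity matrix (first column =
#' probe identifier, remaining columns = samples) plus a sample sheet
#' (columns `sample_id`, `group`) and validates the pair into a
#' [expression_matrix()]. `write_expression()` is its inverse; a write/read
#' round trip reproduces the matrix to 12 significant digits.
#'
#' @param matrix_path path to the intensity TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @return `read_expression()`: a `mir_expr` object with file column order
#'   preserved. `write_expression()`: the paths, invisibly.
#' @export
read_expression <- function(matrix_path, sample_sheet_path) {
  tab <- .read_tsv(matrix_path, colClasses = NA)
  if (ncol(tab) < 2) stop("expression matrix needs an id column plus >= 1 sample column",
                          call. = FALSE)
  ids <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        row <- which(is.na(vn))[1]
        stop(sprintf("non-numeric cell in column '%s', row %d (probe '%s'): '%s'",
                     names(vals)[j], row, ids[row], v[row]), call. = FALSE)
      }
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  sheet <- .read_tsv(sample_sheet_path)
  need <- c("sample_id", "group")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns 'sample_id' and 'group'", call. = FALSE)
  }
  missing <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing)) {
    stop("sample sheet is missing matrix column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  grp <- stats::setNames(as.character(sheet$group), sheet$sample_id)
  expression_matrix(m, grp[colnames(m)])
}

#' @rdname read_expression
#' @param x a `mir_expr` object.
#' @param extra optional provenance string appended to the header comment
#'   (e.g. `"seed=11"`).
#' @export
write_expression <- function(x, matrix_path, sample_sheet_path, extra = NULL) {
  stopifnot(inherits(x, "mir_expr"))
  df <- data.frame(probe_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, matrix_path, extra)
  sheet <- data.frame(sample_id = names(x$group),
                      group = as.character(x$group),
                      stringsAsFactors = FALSE)
  .write_tsv(sheet, sample_sheet_path, extra)
  invisible(c(matrix_path, sample_sheet_path))
}

#' Read and write probe-to-miRNA annotation
#'
#' A two-column TSV (`probe_id`, `mirna_id`); every probe maps to exactly one
#' miRNA.
#'
#' @param path file path.
#' @return a data frame with columns `probe_id`, `mirna_id`.
#' @export
read_probe_annotation <- function(path) {
  ann <- .read_tsv(path)
  if (!all(c("probe_id", "mirna_id") %in% names(ann))) {
    stop("annotation must have columns 'probe_id' and 'mirna_id'", call. = FALSE)
  }
  dup <- duplicated(ann$probe_id)
  if (any(dup)) {
    stop("probe(s) annotated more than once: ",
         paste(unique(ann$probe_id[dup]), collapse = ", "), call. = FALSE)
  }
  ann[, c("probe_id", "mirna_id")]
}

#' @rdname read_probe_annotation
#' @param annotation data frame with columns `probe_id`, `mirna_id`.
#' @param extra optional provenance string for the header comment.
#' @export
write_probe_annotation <- function(annotation, path, extra = NULL) {
  .write_tsv(annotation[, c("probe_id", "mirna_id")], path, extra)
}

#' Read and write GMT gene-set collections
#'
#' One set per line: `set_name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Genes outside the supplied universe are dropped (with a message reporting
#' the count), sets left empty after filtering are dropped, and a duplicated
#' set name keeps the last definition with a warning.
#'
#' @param gmt_path path to the GMT file.
#' @param universe character vector of admissible gene identifiers.
#' @return a list of class `"gene_set_collection"` with elements `sets`
#'   (named list of character vectors), `descriptions` (named character) and
#'   `universe`.
#' @export
read_gene_sets <- function(gmt_path, universe) {
  universe <- unique(as.character(universe))
  lines <- readLines(gmt_path, encoding = "UTF-8")
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  sets <- list(); desc <- character(0)
  n_dropped_genes <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                   line_no[i]), call. = FALSE)
    }
    nm <- f[1]
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    in_univ <- genes %in% universe
    n_dropped_genes <- n_dropped_genes + sum(!in_univ)
    genes <- genes[in_univ]
    if (!length(genes)) {
      message(sprintf("gene set '%s' dropped: no genes in universe", nm))
      next
    }
    if (nm %in% names(sets)) {
      warning(sprintf("duplicate gene set name '%s': last definition wins", nm),
              call. = FALSE)
    }
    sets[[nm]] <- genes
    desc[nm] <- f[2]
  }
  if (n_dropped_genes > 0) {
    message(sprintf("dropped %d gene(s) outside the universe", n_dropped_genes))
  }
  structure(list(sets = sets, descriptions = desc, universe = universe),
            class = "gene_set_collection")
}

#' @rdname read_gene_sets
#' @param collection a `gene_set_collection` (or plain named list of character
#'   vectors).
#' @param extra optional provenance string for the header comment.
#' @export
write_gene_sets <- function(collection, gmt_path, extra = NULL) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets else collection
  desc <- if (inherits(collection, "gene_set_collection")) collection$descriptions else NULL
  con <- file(gmt_path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance_line(extra), con)
  for (nm in names(sets)) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    writeLines(paste(c(nm, d, sets[[nm]]), collapse = "\t"), con)
  }
  invisible(gmt_path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read and write miRNA target-score tables
#'
#' Three-column TSV (`mirna_id`, `gene_id`, `score`), scores in \[0, 100\]
#' (miRDB-style confidence scores). Duplicate (miRNA, gene) pairs are
#' rejected.
#'
#' @param path file path.
#' @return a data frame with columns `mirna_id`, `gene_id`, `score`.
#' @export
read_target_table <- function(path) {
  tab <- .read_tsv(path)
  need <- c("mirna_id", "gene_id", "score")
  if (!all(need %in% names(tab))) {
    stop("target table must have columns mirna_id, gene_id, score", call. = FALSE)
  }
  tab <- tab[, need]
  validate_target_table(tab)
}

#' @rdname read_target_table
#' @param table data frame with columns `mirna_id`, `gene_id`, `score`.
#' @param extra optional provenance string for the header comment.
#' @export
write_target_table <- function(table, path, extra = NULL) {
  .write_tsv(validate_target_table(table), path, extra)
}

#' @rdname read_target_table
#' @export
validate_target_table <- function(table) {
  if (!is.numeric(table$score) || any(!is.finite(table$score)) ||
      any(table$score < 0 | table$score > 100)) {
    stop("target scores must be finite and within [0, 100]", call. = FALSE)
  }
  key <- paste(table$mirna_id, table$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (mirna_id, gene_id) pair(s) in target table", call. = FALSE)
  }
  table
}

#' Read and write replicate assay series
#'
#' TSV with columns `condition` (`treated`/`control`), `replicate_id`,
#' `value`: scalar replicate measurements such as LDH activity, ELISA
#' absorbance or qPCR Ct values.
#'
#' @param path file path.
#' @return a data frame with columns `condition`, `replicate_id`, `value`.
#' @export
read_assay_series <- function(path) {
  tab <- .read_tsv(path)
  need <- c("condition", "replicate_id", "value")
  if (!all(need %in% names(tab))) {
    stop("assay series must have columns condition, replicate_id, value",
         call. = FALSE)
  }
  bad <- setdiff(unique(tab$condition), c("treated", "control"))
  if (length(bad)) {
    stop("unknown assay condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(tab$value) || any(!is.finite(tab$value))) {
    stop("assay values must be finite numerics", call. = FALSE)
  }
  tab[, need]
}

#' @rdname read_assay_series
#' @param series data frame with columns `condition`, `replicate_id`, `value`.
#' @param extra optional provenance string for the header comment.
#' @export
write_assay_series <- function(series, path, extra = NULL) {
  .write_tsv(series[, c("condition", "replicate_id", "value")], path, extra)
}

#' Read a GEO series-matrix file
#'
#' Minimal reader for the GEO series-matrix text layout: metadata lines are
#' prefixed with `!`, and the expression table sits between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`. Quoted
#' identifiers and values are unquoted before parsing. Sample groups are
#' taken from a caller-supplied mapping (GEO characteristics parsing is
#' deliberately not attempted).
#'
#' @param path path to an (uncompressed) series-matrix text file.
#' @param group_map named character vector mapping every sample column to
#'   `"treated"` or `"control"`.
#' @return a `mir_expr` object.
#' @export
read_series_matrix <- function(path, group_map) {
  lines <- readLines(path, encoding = "UTF-8")
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
    stop("series-matrix table markers not found (need one table_begin and one table_end)",
         call. = FALSE)
  }
  tab_lines <- gsub('"', "", lines[(begin + 1):(end - 1)], fixed = TRUE)
  fields <- strsplit(tab_lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  ids <- vapply(body, `[`, character(1), 1)
  vals <- t(vapply(body, function(f) {
    suppressWarnings(v <- as.numeric(f[-1]))
    if (anyNA(v)) stop("non-numeric value in series-matrix table", call. = FALSE)
    v
  }, numeric(length(header) - 1)))
  # single-row edge: vapply returns a vector
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(ids))
  colnames(vals) <- header[-1]
  rownames(vals) <- ids
  expression_matrix(vals, group_map)
}
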