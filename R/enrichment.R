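# Score-thresholded target mapping, overlap accounting and Fisher-exact
# gene-set enrichment.

#' Select predicted targets of one miRNA above a confidence score
#'
#' Returns the unique genes whose prediction score for `mirna_id` is strictly
#' greater than `score_cut` (the conventional "score > 70" rule; a score of
#' exactly 70 is excluded). A miRNA absent from the table yields an empty
#' set.
#'
#' @param table target table (`mirna_id`, `gene_id`, `score`).
#' @param mirna_id single miRNA identifier.
#' @param score_cut confidence threshold (default 70).
#' @return character vector of gene identifiers.
#' @export
select_targets <- function(table, mirna_id, score_cut = 70) {
  stopifnot(length(mirna_id) == 1)
  rows <- table$mirna_id == mirna_id & table$score > score_cut
  unique(table$gene_id[rows])
}

#' Overlap summary across per-miRNA target sets
#'
#' @param target_sets named list of gene-id vectors (one per miRNA).
#' @return a list with `total_unique` (union size), `shared` (named integer:
#'   per-gene multiplicity, genes in >= 2 sets only) and `n_shared_ge2`.
#' @examples
#' overlap_summary(list(a = c("g1", "g2"), b = c("g2", "g3"), c = "g2"))
#' @export
overlap_summary <- function(target_sets) {
  if (!length(target_sets)) stop("need >= 1 target set", call. = FALSE)
  target_sets <- lapply(target_sets, unique)
  all_genes <- unlist(target_sets, use.names = FALSE)
  mult <- table(all_genes)
  shared <- mult[mult >= 2]
  list(total_unique = length(mult),
       shared = stats::setNames(as.integer(shared), names(shared)),
       n_shared_ge2 = length(shared))
}

#' One-sided Fisher exact enrichment p-value
#'
#' Probability, under the hypergeometric null of drawing `|target_set|` genes
#' from the universe, of an overlap with `gene_set` at least as large as
#' observed — the one-sided (enrichment) Fisher exact test on the 2x2 table
#' of target membership vs set membership.
#'
#' @param target_set,gene_set character vectors, subsets of `universe`.
#' @param universe character vector of all genes under consideration
#'   (length >= 2).
#' @return a p-value in (0, 1\].
#' @examples
#' u <- paste0("g", 1:10)
#' fisher_enrichment(u[1:5], u[1:5], u)  # 1 / choose(10, 5)
#' @export
fisher_enrichment <- function(target_set, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) < 2) stop("universe must have >= 2 genes", call. = FALSE)
  target_set <- unique(target_set); gene_set <- unique(gene_set)
  if (length(setdiff(target_set, universe)) ||
      length(setdiff(gene_set, universe))) {
    stop("target_set and gene_set must be subsets of the universe", call. = FALSE)
  }
  n_univ <- length(universe)
  n_tgt <- length(target_set)
  n_set <- length(gene_set)
  k <- length(intersect(target_set, gene_set))
  # upper hypergeometric tail: P(X >= k)
  stats::phyper(k - 1, n_set, n_univ - n_set, n_tgt, lower.tail = FALSE)
}

#' Fisher enrichment of gene sets across several miRNA target sets
#'
#' For every gene set in the collection, computes the one-sided Fisher exact
#' p-value against each miRNA's target set and summarizes them as their
#' arithmetic mean ("average p-value"). A set is flagged `enriched` when its
#' average p is below `p_cut`, and `enriched_all` when additionally every
#' per-miRNA p is below `p_cut` (significant association with *all* target
#' sets). Results are sorted by average p ascending.
#'
#' @param target_sets named list of gene-id vectors (one per miRNA), each a
#'   subset of the collection's universe.
#' @param collection a `gene_set_collection` (see [read_gene_sets()]).
#' @param p_cut enrichment threshold (default 0.005).
#' @return a data frame with one row per gene set: `set_name`, one `p_<mirna>`
#'   column per miRNA, `average_p`, `enriched`, `enriched_all`.
#' @export
enrich_across_mirnas <- function(target_sets, collection, p_cut = 0.005) {
  stopifnot(inherits(collection, "gene_set_collection"), length(target_sets) >= 1)
  universe <- collection$universe
  for (nm in names(target_sets)) {
    outside <- setdiff(target_sets[[nm]], universe)
    if (length(outside)) {
      stop(sprintf("target set '%s' contains gene(s) outside the universe: %s",
                   nm, paste(utils::head(outside, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  pm <- vapply(collection$sets, function(gs) {
    vapply(target_sets, fisher_enrichment, numeric(1),
           gene_set = gs, universe = universe)
  }, numeric(length(target_sets)))
  pm <- matrix(pm, nrow = length(target_sets),
               dimnames = list(names(target_sets), names(collection$sets)))
  avg <- colMeans(pm)
  out <- data.frame(set_name = names(collection$sets),
                    t(pm), check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("p_", rownames(pm))
  out$average_p <- avg
  out$enriched <- avg < p_cut
  out$enriched_all <- apply(pm < p_cut, 2, all)
  out <- out[order(out$average_p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
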