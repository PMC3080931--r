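# End-to-end orchestration: simulate a study bundle to disk, or run the
# filter -> collapse -> markers -> targets -> enrichment -> assays pipeline
# over on-disk inputs, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Paths to the pipeline inputs plus every analysis threshold. Defaults are
#' the conventional printed values for this kind of study: background 30,
#' 2000 permutations, |FC| >= 1.5, p < 0.005, FDR < 0.005, target score > 70,
#' enrichment p < 0.005, Grubbs alpha 0.05.
#'
#' @param expression,samples,annotation paths to the expression matrix TSV,
#'   sample sheet TSV and probe annotation TSV (required).
#' @param targets optional path to a target-score TSV.
#' @param gene_sets optional path to a GMT file.
#' @param assays optional named character vector/list of assay-series TSV
#'   paths.
#' @param out_dir output directory (created if missing).
#' @param background_threshold intensity threshold, or `"auto"` for the
#'   median-of-medians rule of [default_threshold()].
#' @param n_permutations,fc_cut,p_cut,fdr_cut marker-selection settings.
#' @param score_cut,enrichment_p_cut,n_top_targets target/enrichment settings
#'   (`n_top_targets`: how many top-ranked significant miRNAs get target
#'   mapping).
#' @param grubbs_alpha outlier-screen level for the assay stage.
#' @param seed master seed; stage seeds are derived from it.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expression, samples, annotation,
                            targets = NULL, gene_sets = NULL, assays = NULL,
                            out_dir = tempfile("mirperm_run_"),
                            background_threshold = 30,
                            n_permutations = 2000,
                            fc_cut = 1.5, p_cut = 0.005, fdr_cut = 0.005,
                            score_cut = 70, enrichment_p_cut = 0.005,
                            grubbs_alpha = 0.05, n_top_targets = 4,
                            seed = 1) {
  cfg <- list(expression = expression, samples = samples,
              annotation = annotation, targets = targets,
              gene_sets = gene_sets, assays = assays, out_dir = out_dir,
              background_threshold = background_threshold,
              n_permutations = n_permutations, fc_cut = fc_cut,
              p_cut = p_cut, fdr_cut = fdr_cut, score_cut = score_cut,
              enrichment_p_cut = enrichment_p_cut,
              grubbs_alpha = grubbs_alpha, n_top_targets = n_top_targets,
              seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

# flat key=value echo of the effective configuration. out_dir is omitted so
# that reruns of one configuration into different directories stay
# bit-identical.
.write_config_echo <- function(cfg, path) {
  scalar <- function(v) if (is.null(v)) "" else paste(as.character(v), collapse = ",")
  keys <- setdiff(names(cfg), c("assays", "out_dir"))
  lines <- vapply(keys, function(k) paste0(k, "=", scalar(cfg[[k]])), character(1))
  if (!is.null(cfg$assays)) {
    lines <- c(lines, vapply(names(cfg$assays), function(a) {
      paste0("assay.", a, "=", cfg$assays[[a]])
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete synthetic study bundle to disk
#'
#' Generates every input the pipeline consumes — probe-level expression and
#' sample sheet, probe annotation, a target-score table, a GMT gene-set
#' collection, replicate assay series and the simulation ground truth — as
#' mutually consistent TSV/GMT files with known truth, so the full pipeline
#' can be exercised without any external data.
#'
#' @param dir writable output directory (created if missing).
#' @param config a [sim_config()] describing the expression study.
#' @param n_genes size of the simulated gene universe.
#' @param n_targets,n_decoys per-miRNA target-table composition (see
#'   [simulate_target_table()]); recycled over miRNAs.
#' @param n_sets,set_size,enriched_set gene-set collection settings (see
#'   [simulate_gene_sets()]).
#' @param assay_specs named list of `list(n_treated=, n_control=,
#'   true_ratio=, cv=)` entries, one per assay readout. Defaults emulate an
#'   LDH cytotoxicity readout (6 replicates per arm, true ratio 6.68) and an
#'   ELISA cytokine readout (12 replicates per arm, true ratio 16.9).
#' @return (invisibly) a named character vector of the written file paths,
#'   plus the simulation truth under attribute `"truth"`.
#' @export
simulate_study <- function(dir, config = sim_config(),
                           n_genes = 3000, n_targets = 50, n_decoys = 50,
                           n_sets = 20, set_size = c(10, 50),
                           enriched_set = NULL,
                           assay_specs = list(
                             ldh = list(n_treated = 6, n_control = 6,
                                        true_ratio = 6.68, cv = 0.1),
                             il8 = list(n_treated = 12, n_control = 12,
                                        true_ratio = 16.9, cv = 0.1))) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  if (file.access(dir, 2) != 0) stop("output directory is not writable: ", dir,
                                     call. = FALSE)
  seed <- config$seed
  tag <- sprintf("seed=%d", seed)
  sim <- simulate_expression(config)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             annotation = file.path(dir, "probe_annotation.tsv"),
             targets = file.path(dir, "targets.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "ground_truth.tsv"))
  write_expression(sim$expr, paths["expression"], paths["samples"], extra = tag)
  write_probe_annotation(sim$annotation, paths["annotation"], extra = tag)
  genes <- sprintf("gene-%05d", seq_len(n_genes))
  tt <- simulate_target_table(sim$truth$mirna_id, genes,
                              n_targets = n_targets, n_decoys = n_decoys,
                              seed = seed + 1)
  write_target_table(tt, paths["targets"], extra = tag)
  gs <- simulate_gene_sets(genes, n_sets = n_sets, set_size = set_size,
                           enriched_set = enriched_set, seed = seed + 2)
  write_gene_sets(gs, paths["gene_sets"], extra = tag)
  .write_tsv(sim$truth, paths["truth"], tag)
  for (i in seq_along(assay_specs)) {
    nm <- names(assay_specs)[i]
    sp <- assay_specs[[i]]
    rep <- simulate_assay_replicates(
      n_treated = sp$n_treated, n_control = sp$n_control,
      true_ratio = sp$true_ratio,
      cv = if (is.null(sp$cv)) 0.1 else sp$cv,
      n_outliers = if (is.null(sp$n_outliers)) 0 else sp$n_outliers,
      seed = seed + 2 + i)
    p <- file.path(dir, sprintf("assay_%s.tsv", nm))
    write_assay_series(rbind(rep$treated, rep$control), p, extra = tag)
    paths[paste0("assay_", nm)] <- p
  }
  attr(paths, "truth") <- sim$truth
  invisible(paths)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: ingest, background filter, probe-to-miRNA collapse,
#' permutation-SNR marker selection, target mapping for the top-ranked
#' significant miRNAs, gene-set enrichment, and assay statistics — writing
#' every stage's outputs under `config$out_dir` together with a manifest
#' (`manifest.tsv`) listing stage record counts and an MD5 hash of every
#' output file. Identical configuration and seed give bit-identical outputs
#' and manifest; wall-clock timestamps go to `run.log` only, never into
#' hashed files.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the manifest: a list with `version`, `seed`, `config`,
#'   `stages` (named list of per-stage counts) and `files` (named MD5
#'   vector).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time()),
                                        sprintf(...)),
                                file = log_path, append = TRUE)
  tag <- sprintf("seed=%d", config$seed)
  stages <- list()
  outputs <- character(0)
  emit <- function(name, path) outputs[[name]] <<- path

  log_line("pipeline started")
  expr <- .stage("ingest", {
    x <- read_expression(config$expression, config$samples)
    ann <- read_probe_annotation(config$annotation)
    list(x = x, ann = ann)
  })
  stages$ingest <- list(n_probes = n_features(expr$x),
                        n_samples = n_samples(expr$x))
  log_line("ingest: %d probes x %d samples", n_features(expr$x),
           n_samples(expr$x))

  filt <- .stage("filter", {
    thr <- config$background_threshold
    if (identical(thr, "auto")) thr <- default_threshold(expr$x)
    filter_background(expr$x, thr, expr$ann)
  })
  .stage("filter", {
    write_expression(filt$expr, file.path(config$out_dir, "filtered_expression.tsv"),
                     file.path(config$out_dir, "filtered_samples.tsv"), extra = tag)
    .write_tsv(data.frame(n_input_records = filt$report$n_input_records,
                          n_retained_records = filt$report$n_retained_records,
                          background_threshold = filt$report$background_threshold,
                          n_detectable_mirnas = filt$report$n_detectable_mirnas),
               file.path(config$out_dir, "filter_report.tsv"), tag)
  })
  emit("filtered_expression", file.path(config$out_dir, "filtered_expression.tsv"))
  emit("filtered_samples", file.path(config$out_dir, "filtered_samples.tsv"))
  emit("filter_report", file.path(config$out_dir, "filter_report.tsv"))
  stages$filter <- unclass(filt$report)
  log_line("filter: %d -> %d records at threshold %.4g",
           filt$report$n_input_records, filt$report$n_retained_records,
           filt$report$background_threshold)

  mirna <- .stage("collapse", collapse_to_mirna(filt$expr, expr$ann))
  .stage("collapse", write_expression(
    mirna, file.path(config$out_dir, "mirna_expression.tsv"),
    file.path(config$out_dir, "mirna_samples.tsv"), extra = tag))
  emit("mirna_expression", file.path(config$out_dir, "mirna_expression.tsv"))
  emit("mirna_samples", file.path(config$out_dir, "mirna_samples.tsv"))
  stages$collapse <- list(n_mirnas = n_features(mirna))
  log_line("collapse: %d miRNAs", n_features(mirna))

  fit <- .stage("markers", mirna_markers(
    mirna, n_perm = config$n_permutations, fc_cut = config$fc_cut,
    p_cut = config$p_cut, fdr_cut = config$fdr_cut, seed = config$seed))
  res <- fit$results
  sig <- significant_markers(fit)
  .stage("markers", {
    .write_tsv(res, file.path(config$out_dir, "marker_results.tsv"), tag)
    .write_tsv(sig, file.path(config$out_dir, "significant_markers.tsv"), tag)
    if (nrow(sig) >= 2) {
      sc <- standardize_and_cluster(mirna, sig$mirna_id)
      std <- data.frame(mirna_id = rownames(sc$standardized),
                        sc$standardized, check.names = FALSE)
      .write_tsv(std, file.path(config$out_dir, "standardized_matrix.tsv"), tag)
      .write_tsv(data.frame(position = seq_along(sc$order),
                            mirna_id = rownames(sc$standardized)[sc$order]),
                 file.path(config$out_dir, "cluster_leaf_order.tsv"), tag)
      emit("standardized_matrix", file.path(config$out_dir, "standardized_matrix.tsv"))
      emit("cluster_leaf_order", file.path(config$out_dir, "cluster_leaf_order.tsv"))
    }
  })
  emit("marker_results", file.path(config$out_dir, "marker_results.tsv"))
  emit("significant_markers", file.path(config$out_dir, "significant_markers.tsv"))
  stages$markers <- list(n_tested = nrow(res),
                         n_significant = nrow(sig),
                         n_down = sum(sig$fc < 0), n_up = sum(sig$fc > 0),
                         permutation_mode = fit$permutation$mode,
                         n_relabelings = fit$permutation$n_relabelings,
                         pool_size = fit$permutation$pool_size)
  log_line("markers: %d significant (%d down, %d up) of %d",
           nrow(sig), sum(sig$fc < 0), sum(sig$fc > 0), nrow(res))

  target_sets <- NULL
  target_table <- NULL
  if (!is.null(config$targets)) {
    target_sets <- .stage("targets", {
      target_table <- read_target_table(config$targets)
      top <- utils::head(sig$mirna_id, config$n_top_targets)
      sets <- lapply(top, select_targets, table = target_table,
                     score_cut = config$score_cut)
      names(sets) <- top
      sets
    })
    .stage("targets", {
      if (length(target_sets)) {
        long <- do.call(rbind, lapply(names(target_sets), function(m) {
          if (!length(target_sets[[m]])) return(NULL)
          data.frame(mirna_id = m, gene_id = target_sets[[m]],
                     stringsAsFactors = FALSE)
        }))
        if (is.null(long)) long <- data.frame(mirna_id = character(0),
                                              gene_id = character(0))
        .write_tsv(long, file.path(config$out_dir, "target_sets.tsv"), tag)
        ov <- overlap_summary(target_sets)
        .write_tsv(data.frame(total_unique = ov$total_unique,
                              n_shared_ge2 = ov$n_shared_ge2),
                   file.path(config$out_dir, "overlap_summary.tsv"), tag)
        shared <- data.frame(gene_id = names(ov$shared),
                             n_mirnas = unname(ov$shared))
        .write_tsv(shared, file.path(config$out_dir, "shared_targets.tsv"), tag)
        emit("target_sets", file.path(config$out_dir, "target_sets.tsv"))
        emit("overlap_summary", file.path(config$out_dir, "overlap_summary.tsv"))
        emit("shared_targets", file.path(config$out_dir, "shared_targets.tsv"))
        stages$targets <- list(n_mirnas_mapped = length(target_sets),
                               sizes = vapply(target_sets, length, integer(1)),
                               total_unique = ov$total_unique,
                               n_shared_ge2 = ov$n_shared_ge2)
        log_line("targets: %d sets, %d unique genes, %d shared by >= 2",
                 length(target_sets), ov$total_unique, ov$n_shared_ge2)
      } else {
        stages$targets <- list(n_mirnas_mapped = 0L)
        log_line("targets: no significant miRNAs to map")
      }
    })
  }

  if (!is.null(config$gene_sets) && length(target_sets) > 0) {
    enr <- .stage("enrichment", {
      universe <- unique(target_table$gene_id)
      coll <- read_gene_sets(config$gene_sets, universe)
      enrich_across_mirnas(target_sets, coll, p_cut = config$enrichment_p_cut)
    })
    .stage("enrichment", .write_tsv(
      enr, file.path(config$out_dir, "enrichment_results.tsv"), tag))
    emit("enrichment_results", file.path(config$out_dir, "enrichment_results.tsv"))
    stages$enrichment <- list(n_sets_tested = nrow(enr),
                              n_enriched = sum(enr$enriched),
                              n_enriched_all = sum(enr$enriched_all))
    log_line("enrichment: %d of %d sets below average p %.4g",
             sum(enr$enriched), nrow(enr), config$enrichment_p_cut)
  }

  if (!is.null(config$assays)) {
    assay_rows <- .stage("assays", {
      rows <- lapply(names(config$assays), function(nm) {
        series <- read_assay_series(config$assays[[nm]])
        tr <- series$value[series$condition == "treated"]
        ct <- series$value[series$condition == "control"]
        scr_t <- grubbs_screen(tr, config$grubbs_alpha)
        scr_c <- grubbs_screen(ct, config$grubbs_alpha)
        tt <- welch_t_test(scr_t$values, scr_c$values)
        data.frame(assay = nm,
                   n_treated = length(scr_t$values),
                   n_control = length(scr_c$values),
                   n_outliers_removed = length(scr_t$removed_index) +
                     length(scr_c$removed_index),
                   fold_change = tt$fold_change,
                   t_statistic = tt$t_statistic,
                   degrees_of_freedom = tt$degrees_of_freedom,
                   p_value = tt$p_value,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    .stage("assays", .write_tsv(
      assay_rows, file.path(config$out_dir, "assay_results.tsv"), tag))
    emit("assay_results", file.path(config$out_dir, "assay_results.tsv"))
    stages$assays <- assay_rows
    log_line("assays: %d readouts analysed", nrow(assay_rows))
  }

  cfg_path <- file.path(config$out_dir, "config.txt")
  .write_config_echo(config, cfg_path)
  emit("config", cfg_path)

  files <- vapply(outputs, function(p) unname(tools::md5sum(p)), character(1))
  manifest <- list(version = as.character(utils::packageVersion("mirperm")),
                   seed = config$seed, config = config,
                   stages = stages, files = files)
  # flat, timestamp-free manifest: (section, key, value) rows
  rows <- list(data.frame(section = "run", key = c("version", "seed"),
                          value = c(manifest$version, as.character(config$seed))))
  for (st in names(stages)) {
    rec <- stages[[st]]
    if (is.data.frame(rec)) {
      for (i in seq_len(nrow(rec))) {
        for (k in names(rec)) {
          rows[[length(rows) + 1]] <- data.frame(
            section = paste0("stage.", st, ".", rec$assay[i]), key = k,
            value = as.character(rec[[k]][i]))
        }
      }
    } else {
      flat <- unlist(rec)
      rows[[length(rows) + 1]] <- data.frame(
        section = paste0("stage.", st), key = names(flat),
        value = as.character(flat))
    }
  }
  rows[[length(rows) + 1]] <- data.frame(section = "file.md5",
                                         key = names(files),
                                         value = unname(files))
  man_df <- do.call(rbind, rows)
  utils::write.table(man_df, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("pipeline finished")
  invisible(manifest)
}
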