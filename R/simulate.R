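# Synthetic-data generators. Every generator runs in its own RNG scope: the
# caller's .Random.seed is saved and restored, so a (config, seed) pair fully
# determines the output and no global RNG state leaks.

.local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulation configuration for a synthetic two-group miRNA array study
#'
#' Describes a probe-level microarray experiment: `n_probes` probes mapping
#' many-to-one onto `n_mirnas` miRNAs, measured on `n_treated` + `n_control`
#' arrays. A `detectable_fraction` of miRNAs get baseline intensities above
#' `background_level` (log-uniform between 2x and 100x background); the rest
#' sit below background and should be removed by the background filter.
#' miRNAs named in `spiked_mirnas` have their treated-group signal shifted by
#' a signed linear fold change (negative = down-regulated in treated
#' samples). Probe intensities are miRNA signal x a per-probe multiplicative
#' effect (shared across samples, log2-normal with sd `probe_effect_sd`) x
#' multiplicative log2-normal noise with sd `noise_sd`.
#'
#' Defaults mirror a 534-miRNA human array hybridized with three treated and
#' three control samples, 12,033 probes, background at 30 and roughly 64% of
#' miRNAs detectable.
#'
#' @param n_probes,n_mirnas,n_treated,n_control design counts.
#' @param background_level linear-scale background intensity.
#' @param detectable_fraction proportion of miRNAs simulated above background.
#' @param spiked_mirnas named numeric vector: `mirna_id -> true signed fold
#'   change` with `|fc| >= 1` (may be empty). Spiked miRNAs are always
#'   simulated as detectable.
#' @param noise_sd log2-scale sd of the per-measurement multiplicative noise.
#' @param probe_effect_sd log2-scale sd of the per-probe effect.
#' @param seed integer; fully determines the generator output.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_probes = 12033, n_mirnas = 534,
                       n_treated = 3, n_control = 3,
                       background_level = 30,
                       detectable_fraction = 343 / 534,
                       spiked_mirnas = numeric(0),
                       noise_sd = 0.25, probe_effect_sd = 0.25,
                       seed = 1) {
  cfg <- list(n_probes = n_probes, n_mirnas = n_mirnas,
              n_treated = n_treated, n_control = n_control,
              background_level = background_level,
              detectable_fraction = detectable_fraction,
              spiked_mirnas = spiked_mirnas,
              noise_sd = noise_sd, probe_effect_sd = probe_effect_sd,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config a `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    counts <- c(n_probes, n_mirnas, n_treated, n_control)
    if (any(counts < 1) || any(counts != round(counts))) {
      stop("counts must be positive integers", call. = FALSE)
    }
    if (n_treated < 2 || n_control < 2) {
      stop("need >= 2 samples per group for group statistics", call. = FALSE)
    }
    if (detectable_fraction < 0 || detectable_fraction > 1) {
      stop("detectable_fraction must lie in [0, 1]", call. = FALSE)
    }
    if (background_level <= 0) stop("background_level must be > 0", call. = FALSE)
    if (noise_sd < 0 || probe_effect_sd < 0) {
      stop("noise sds must be >= 0", call. = FALSE)
    }
    n_spiked <- length(spiked_mirnas)
    if (n_probes < n_mirnas || n_mirnas < n_spiked) {
      stop("need n_probes >= n_mirnas >= number of spiked miRNAs", call. = FALSE)
    }
    if (n_spiked > 0) {
      if (is.null(names(spiked_mirnas)) || any(!nzchar(names(spiked_mirnas)))) {
        stop("spiked_mirnas must be a named vector (mirna_id -> fold change)",
             call. = FALSE)
      }
      if (any(abs(spiked_mirnas) < 1)) {
        stop("every spiked fold change must satisfy |fc| >= 1", call. = FALSE)
      }
    }
  })
  config
}

# signed fold change -> multiplicative factor on the treated-group mean
.fc_to_mult <- function(fc) ifelse(fc >= 1, fc, -1 / fc)

#' Generate a synthetic probe-level expression study
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   * `expr`: probe-level [expression_matrix()] (linear intensities),
#'   * `annotation`: data frame `probe_id`, `mirna_id`,
#'   * `truth`: data frame `mirna_id`, `is_differential`, `true_fc`,
#'     `detectable` (the simulated ground truth).
#' @examples
#' sim <- simulate_expression(sim_config(n_probes = 40, n_mirnas = 10, seed = 7))
#' dim(sim$expr)
#' @export
simulate_expression <- function(config) {
  config <- validate_sim_config(config)
  .local_seed(config$seed, {
    n_m <- config$n_mirnas
    mirna_ids <- sprintf("mir-%04d", seq_len(n_m))
    spikes <- config$spiked_mirnas
    if (length(spikes) > 0 && is.null(names(spikes))) names(spikes) <- character(0)
    spike_ids <- names(spikes)
    unknown <- setdiff(spike_ids, mirna_ids)
    if (length(unknown)) {
      stop("spiked miRNA(s) not in the simulated id space: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    n_detect <- round(config$detectable_fraction * n_m)
    n_detect <- max(n_detect, length(spike_ids))
    # spiked miRNAs are always detectable; fill the rest at random
    detectable <- mirna_ids %in% spike_ids
    pool <- which(!detectable)
    extra <- n_detect - sum(detectable)
    if (extra > 0 && length(pool) > 0) {
      detectable[sample(pool, min(extra, length(pool)))] <- TRUE
    }
    base <- numeric(n_m)
    bg <- config$background_level
    base[detectable] <- bg * 10^stats::runif(sum(detectable), 0.3, 2)
    base[!detectable] <- bg * 10^stats::runif(sum(!detectable), -1, -0.25)

    true_fc <- rep(1, n_m)
    names(true_fc) <- mirna_ids
    true_fc[spike_ids] <- spikes
    mult <- .fc_to_mult(true_fc)

    n_t <- config$n_treated; n_c <- config$n_control
    # per-miRNA group means on the linear scale
    mean_control <- base
    mean_treated <- base * mult

    # probes assigned round-robin so per-miRNA counts differ by at most one
    probe_mirna <- rep(seq_len(n_m), length.out = config$n_probes)
    probe_mirna <- sort(probe_mirna)
    probe_ids <- sprintf("probe-%05d", seq_len(config$n_probes))
    probe_effect <- 2^stats::rnorm(config$n_probes, 0, config$probe_effect_sd)

    signal <- cbind(
      matrix(mean_treated[probe_mirna] * probe_effect, config$n_probes, n_t),
      matrix(mean_control[probe_mirna] * probe_effect, config$n_probes, n_c)
    )
    noise <- 2^matrix(stats::rnorm(config$n_probes * (n_t + n_c), 0, config$noise_sd),
                      config$n_probes, n_t + n_c)
    vals <- signal * noise
    colnames(vals) <- c(sprintf("treated_%d", seq_len(n_t)),
                        sprintf("control_%d", seq_len(n_c)))
    rownames(vals) <- probe_ids
    grp <- c(rep("treated", n_t), rep("control", n_c))
    expr <- expression_matrix(vals, stats::setNames(grp, colnames(vals)))
    annotation <- data.frame(probe_id = probe_ids,
                             mirna_id = mirna_ids[probe_mirna],
                             stringsAsFactors = FALSE)
    truth <- data.frame(mirna_id = mirna_ids,
                        is_differential = mirna_ids %in% spike_ids,
                        true_fc = unname(true_fc),
                        detectable = detectable,
                        stringsAsFactors = FALSE)
    list(expr = expr, annotation = annotation, truth = truth)
  })
}

#' Generate a synthetic miRNA-to-gene target-score table
#'
#' Emulates a miRDB-style prediction table. By default each miRNA receives
#' `n_targets` "true" target genes with scores drawn above 70 (so the
#' standard score > 70 filter recovers exactly these) plus `n_decoys`
#' low-confidence pairs scored in (0, 70). Supplying `score_fun` overrides
#' this and scores every sampled pair with `score_fun(n)` instead.
#'
#' @param mirnas,genes non-empty character vectors of identifiers.
#' @param n_targets scalar or per-miRNA vector: number of high-score pairs.
#' @param n_decoys scalar or per-miRNA vector: number of sub-threshold pairs.
#' @param seed integer seed.
#' @param score_fun optional `function(n)` returning `n` scores in \[0, 100\].
#' @return a data frame `mirna_id`, `gene_id`, `score` with unique pairs.
#' @export
simulate_target_table <- function(mirnas, genes, n_targets = 50, n_decoys = 50,
                                  seed = 1, score_fun = NULL) {
  if (!length(mirnas) || !length(genes)) {
    stop("'mirnas' and 'genes' must be non-empty", call. = FALSE)
  }
  n_targets <- rep_len(n_targets, length(mirnas))
  n_decoys <- rep_len(n_decoys, length(mirnas))
  if (any(n_targets + n_decoys > length(genes))) {
    stop("n_targets + n_decoys exceeds the size of the gene universe", call. = FALSE)
  }
  .local_seed(seed, {
    rows <- lapply(seq_along(mirnas), function(i) {
      k <- n_targets[i] + n_decoys[i]
      g <- sample(genes, k)
      score <- if (is.null(score_fun)) {
        c(stats::runif(n_targets[i], 70 + 1e-6, 100),
          stats::runif(n_decoys[i], 0, 70))
      } else {
        s <- score_fun(k)
        if (any(s < 0 | s > 100)) stop("score_fun produced scores outside [0, 100]",
                                       call. = FALSE)
        s
      }
      data.frame(mirna_id = mirnas[i], gene_id = g, score = score,
                 stringsAsFactors = FALSE)
    })
    validate_target_table(do.call(rbind, rows))
  })
}

#' Generate a synthetic gene-set collection
#'
#' Draws `n_sets` random gene sets from the universe (sizes uniform within
#' `set_size`). When `enriched_set` is supplied, one additional set is built
#' that contains the listed genes plus random fill up to `enriched_size`,
#' guaranteeing a detectable over-representation signal for any target list
#' that includes those genes.
#'
#' @param genes gene universe (character).
#' @param n_sets number of random sets (>= 1).
#' @param set_size length-2 integer range of random set sizes.
#' @param enriched_set optional `list(name =, genes =)`; `genes` must lie in
#'   the universe.
#' @param enriched_size total size of the enriched set (>= length of its gene
#'   list); default twice the list length.
#' @param seed integer seed.
#' @return a `gene_set_collection` (see [read_gene_sets()]).
#' @export
simulate_gene_sets <- function(genes, n_sets, set_size = c(10, 50),
                               enriched_set = NULL, enriched_size = NULL,
                               seed = 1) {
  if (n_sets < 1) stop("n_sets must be >= 1", call. = FALSE)
  genes <- unique(as.character(genes))
  if (!is.null(enriched_set)) {
    stopifnot(is.list(enriched_set), !is.null(enriched_set$name),
              length(enriched_set$genes) >= 1)
    outside <- setdiff(enriched_set$genes, genes)
    if (length(outside)) {
      stop("enriched_set names gene(s) outside the universe: ",
           paste(outside, collapse = ", "), call. = FALSE)
    }
  }
  set_size <- pmin(pmax(round(set_size), 1), length(genes))
  .local_seed(seed, {
    size_range <- seq(set_size[1], set_size[2])
    sizes <- if (length(size_range) == 1) rep(size_range, n_sets) else
      sample(size_range, n_sets, replace = TRUE)
    sets <- lapply(sizes, function(k) sample(genes, k))
    names(sets) <- sprintf("set_%03d", seq_len(n_sets))
    desc <- stats::setNames(rep("random", n_sets), names(sets))
    if (!is.null(enriched_set)) {
      core <- unique(as.character(enriched_set$genes))
      k <- if (is.null(enriched_size)) 2 * length(core) else enriched_size
      k <- min(max(k, length(core)), length(genes))
      fill <- sample(setdiff(genes, core), k - length(core))
      sets[[enriched_set$name]] <- c(core, fill)
      desc[enriched_set$name] <- "enriched"
    }
    structure(list(sets = sets, descriptions = desc, universe = genes),
              class = "gene_set_collection")
  })
}

#' Generate replicate assay measurements with known truth
#'
#' Control replicates are drawn Normal(`baseline`, `cv * baseline`); treated
#' replicates Normal(`baseline * true_ratio`, `cv * baseline * true_ratio`).
#' `n_outliers` randomly chosen replicates are replaced by gross deviations
#' (10x the maximum of their arm) and flagged in the returned truth table.
#'
#' @param n_treated,n_control replicate counts (>= 2).
#' @param true_ratio true treated/control ratio of means (> 0).
#' @param cv coefficient of variation (> 0).
#' @param n_outliers number of injected outliers (must be < min arm size).
#' @param baseline control-arm mean, arbitrary units.
#' @param seed integer seed.
#' @return a list with `treated` and `control` assay-series data frames
#'   (columns `condition`, `replicate_id`, `value`) and `truth` (columns
#'   `condition`, `replicate_id`, `is_outlier`).
#' @export
simulate_assay_replicates <- function(n_treated, n_control, true_ratio,
                                      cv = 0.1, n_outliers = 0,
                                      baseline = 100, seed = 1) {
  if (n_treated < 2 || n_control < 2) stop("counts must be >= 2", call. = FALSE)
  if (cv <= 0) stop("cv must be > 0", call. = FALSE)
  if (true_ratio <= 0) stop("true_ratio must be > 0", call. = FALSE)
  if (n_outliers >= min(n_treated, n_control)) {
    stop("n_outliers must be smaller than the smallest replicate count",
         call. = FALSE)
  }
  .local_seed(seed, {
    mk <- function(n, mu, condition) {
      data.frame(condition = condition,
                 replicate_id = sprintf("%s_%02d", condition, seq_len(n)),
                 value = abs(stats::rnorm(n, mu, cv * mu)),
                 stringsAsFactors = FALSE)
    }
    treated <- mk(n_treated, baseline * true_ratio, "treated")
    control <- mk(n_control, baseline, "control")
    truth <- rbind(
      data.frame(condition = "treated", replicate_id = treated$replicate_id,
                 is_outlier = FALSE, stringsAsFactors = FALSE),
      data.frame(condition = "control", replicate_id = control$replicate_id,
                 is_outlier = FALSE, stringsAsFactors = FALSE))
    if (n_outliers > 0) {
      all_idx <- seq_len(n_treated + n_control)
      pick <- sample(all_idx, n_outliers)
      for (i in pick) {
        if (i <= n_treated) {
          treated$value[i] <- 10 * max(treated$value)
          truth$is_outlier[truth$condition == "treated"][i] <- TRUE
        } else {
          j <- i - n_treated
          control$value[j] <- 10 * max(control$value)
          truth$is_outlier[truth$condition == "control"][j] <- TRUE
        }
      }
    }
    list(treated = treated, control = control, truth = truth)
  })
}
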