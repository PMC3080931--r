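# Shared fixture builders. Everything is generated in code; nothing binary.

# small expression matrix with explicit values
toy_expr <- function(values, treated = NULL) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("p%d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  }
  if (is.null(treated)) treated <- seq_len(ceiling(ncol(values) / 2))
  grp <- rep("control", ncol(values))
  grp[treated] <- "treated"
  expression_matrix(values, stats::setNames(grp, colnames(values)))
}

# small simulated study, collapsed to miRNA level
toy_study <- function(n_mirnas = 50, n_probes = 4 * n_mirnas,
                      spiked = numeric(0), noise_sd = 0.25, seed = 1,
                      detectable_fraction = 1) {
  sim <- simulate_expression(sim_config(
    n_probes = n_probes, n_mirnas = n_mirnas,
    detectable_fraction = detectable_fraction,
    spiked_mirnas = spiked, noise_sd = noise_sd, seed = seed))
  sim$mirna <- collapse_to_mirna(sim$expr, sim$annotation)
  sim
}

# independent brute-force BH oracle: q_i = min_{p_(j) >= p_i} m * p_(j) / j
bh_brute_force <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    cand <- vapply(seq_len(m), function(j) {
      if (ps[j] >= pi) m * ps[j] / j else Inf
    }, numeric(1))
    min(min(cand), 1)
  }, numeric(1))
}

# independent hypergeometric-tail oracle via choose(): P(overlap >= k)
fisher_enumeration <- function(k, n_set, n_univ, n_tgt) {
  kk <- max(0, n_tgt + n_set - n_univ):min(n_set, n_tgt)
  pmf <- choose(n_set, kk) * choose(n_univ - n_set, n_tgt - kk) /
    choose(n_univ, n_tgt)
  sum(pmf[kk >= k])
}

# write a minimal GEO series-matrix text fixture; returns the path
write_series_matrix_fixture <- function(path, drop_end_marker = FALSE) {
  lines <- c(
    '!Series_title\t"synthetic miniature series"',
    '!Sample_geo_accession\t"S1"\t"S2"',
    "!series_matrix_table_begin",
    '"ID_REF"\t"S1"\t"S2"',
    '"probe-1"\t"10.5"\t12',
    '"probe-2"\t30\t"31.5"',
    '"probe-3"\t5\t4',
    if (!drop_end_marker) "!series_matrix_table_end")
  writeLines(lines, path)
  path
}
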