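test_that("simulation config enforces its invariants", {
  expect_error(sim_config(n_probes = 10, n_mirnas = 20), "n_probes >= n_mirnas")
  expect_error(sim_config(detectable_fraction = 1.5), "detectable_fraction")
  expect_error(sim_config(n_treated = 1), ">= 2 samples")
  expect_error(sim_config(n_probes = -5), "positive integers")
  expect_error(sim_config(spiked_mirnas = c("mir-0001" = -0.5)), "\\|fc\\| >= 1")
  expect_error(sim_config(spiked_mirnas = -2), "named")
})

test_that("generators are seed-deterministic and leave global RNG alone", {
  cfg <- sim_config(n_probes = 60, n_mirnas = 20, seed = 42,
                    spiked_mirnas = c("mir-0003" = -3))
  a <- simulate_expression(cfg)
  set.seed(7); before <- runif(3)
  set.seed(7)
  b <- simulate_expression(cfg)
  after <- runif(3)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  expect_identical(before, after)  # no global RNG state consumed

  t1 <- simulate_target_table(c("m1", "m2"), paste0("g", 1:50),
                              n_targets = 10, n_decoys = 10, seed = 9)
  t2 <- simulate_target_table(c("m1", "m2"), paste0("g", 1:50),
                              n_targets = 10, n_decoys = 10, seed = 9)
  expect_identical(t1, t2)
  g1 <- simulate_gene_sets(paste0("g", 1:100), n_sets = 5, seed = 3)
  g2 <- simulate_gene_sets(paste0("g", 1:100), n_sets = 5, seed = 3)
  expect_identical(g1$sets, g2$sets)
  a1 <- simulate_assay_replicates(4, 4, 2, seed = 5)
  a2 <- simulate_assay_replicates(4, 4, 2, seed = 5)
  expect_identical(a1, a2)
  # different seeds give different draws
  expect_false(identical(a1$treated$value,
                         simulate_assay_replicates(4, 4, 2, seed = 6)$treated$value))
})

test_that("ground truth records spike status and detectability", {
  none <- simulate_expression(sim_config(n_probes = 40, n_mirnas = 10, seed = 2))
  expect_false(any(none$truth$is_differential))
  expect_true(all(none$truth$true_fc == 1))

  spiked <- simulate_expression(sim_config(
    n_probes = 40, n_mirnas = 10, detectable_fraction = 0.3,
    spiked_mirnas = c("mir-0002" = -4, "mir-0009" = 2), seed = 2))
  tr <- spiked$truth
  expect_setequal(tr$mirna_id[tr$is_differential], c("mir-0002", "mir-0009"))
  expect_equal(tr$true_fc[tr$mirna_id == "mir-0002"], -4)
  # spiked miRNAs are always simulated as detectable
  expect_true(all(tr$detectable[tr$is_differential]))
})

test_that("simulated group-mean ratios match the spiked fold changes", {
  # truth-consistency: with many probes and tiny noise the linear-scale
  # treated/control mean ratio converges to the configured fold change
  cfg <- sim_config(n_probes = 600, n_mirnas = 3, detectable_fraction = 1,
                    noise_sd = 0.01,
                    spiked_mirnas = c("mir-0001" = -5.5, "mir-0002" = 2), seed = 8)
  sim <- simulate_expression(cfg)
  m <- collapse_to_mirna(sim$expr, sim$annotation)
  cols <- split(seq_len(ncol(m$values)), m$group)
  ratio <- rowMeans(m$values[, cols$treated]) / rowMeans(m$values[, cols$control])
  expect_equal(unname(ratio["mir-0001"]), 1 / 5.5, tolerance = 0.02)
  expect_equal(unname(ratio["mir-0002"]), 2, tolerance = 0.02)
  expect_equal(unname(ratio["mir-0003"]), 1, tolerance = 0.02)
})

test_that("target-table generator honours score control and uniqueness", {
  genes <- paste0("g", 1:200)
  tt <- simulate_target_table(c("m1", "m2"), genes, n_targets = 15,
                              n_decoys = 25, seed = 4)
  expect_false(anyDuplicated(paste(tt$mirna_id, tt$gene_id)) > 0)
  expect_true(all(tt$score >= 0 & tt$score <= 100))
  # default bands make the >70 filter recover exactly n_targets genes
  expect_length(select_targets(tt, "m1", 70), 15)

  sat <- simulate_target_table("m1", genes, n_targets = 5, n_decoys = 5,
                               seed = 4, score_fun = function(n) rep(100, n))
  expect_length(select_targets(sat, "m1", 70), 10)   # all pairs pass
  bound <- simulate_target_table("m1", genes, n_targets = 5, n_decoys = 5,
                                 seed = 4, score_fun = function(n) rep(70, n))
  expect_length(select_targets(bound, "m1", 70), 0)  # strict inequality
  expect_error(simulate_target_table(character(0), genes), "non-empty")
  expect_error(simulate_target_table("m1", genes, n_targets = 150,
                                     n_decoys = 100), "exceeds")
})

test_that("gene-set generator plants a detectable enrichment signal", {
  genes <- paste0("g", 1:500)
  targets <- paste0("g", 1:10)
  cc <- simulate_gene_sets(genes, n_sets = 5,
                           enriched_set = list(name = "hot", genes = targets),
                           enriched_size = 20, seed = 6)
  expect_true(all(targets %in% cc$sets$hot))
  expect_length(cc$sets$hot, 20)
  # hypergeometric-tail oracle: all 10 targets inside a 20-gene set
  p <- fisher_enrichment(targets, cc$sets$hot, genes)
  expect_lt(p, 1e-6)
  expect_equal(p, fisher_enumeration(10, 20, 500, 10), tolerance = 1e-12)

  # degenerate margin: the whole universe as one set
  whole <- simulate_gene_sets(genes, n_sets = 1, set_size = c(500, 500), seed = 6)
  expect_equal(fisher_enrichment(targets, whole$sets$set_001, genes), 1)
  expect_error(simulate_gene_sets(genes, 2,
                                  enriched_set = list(name = "x", genes = "nope")),
               "outside the universe")
})

test_that("null gene-set enrichment p-values are roughly uniform", {
  set.seed(5)
  genes <- paste0("g", 1:500)
  target <- sample(genes, 60)
  ps <- vapply(1:100, function(s) {
    cc <- simulate_gene_sets(genes, n_sets = 1, set_size = c(60, 60), seed = s)
    fisher_enrichment(target, cc$sets$set_001, genes)
  }, numeric(1))
  # coarse K-S check against U(0,1); discreteness keeps this from being tight
  ks <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(ks, 0.2)
})

test_that("assay replicate generator matches its declared truth", {
  expect_error(simulate_assay_replicates(1, 4, 2), ">= 2")
  expect_error(simulate_assay_replicates(4, 4, 2, n_outliers = 4),
               "smaller than")
  expect_error(simulate_assay_replicates(4, 4, 2, cv = 0), "cv")

  # null case: estimated fold change concentrates on 1
  fcs <- vapply(1:50, function(s) {
    r <- simulate_assay_replicates(12, 12, 1, cv = 0.1, seed = s)
    assay_fold_change(r$treated, r$control)
  }, numeric(1))
  expect_lt(abs(mean(fcs) - 1), 0.05)

  # strong-effect case: FC within 20% of 16.9 in >= 95% of 200 seeds
  hits <- vapply(1:200, function(s) {
    r <- simulate_assay_replicates(12, 12, 16.9, cv = 0.1, seed = s)
    abs(assay_fold_change(r$treated, r$control) / 16.9 - 1) <= 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # injected gross outlier is flagged by the Grubbs screen, exactly once
  r <- simulate_assay_replicates(8, 8, 2, cv = 0.05, n_outliers = 1, seed = 3)
  truth <- r$truth[r$truth$is_outlier, ]
  arm <- r[[truth$condition]]
  g <- grubbs_test(arm$value)
  expect_identical(arm$replicate_id[g$flagged_index], truth$replicate_id)
  other <- r[[setdiff(c("treated", "control"), truth$condition)]]
  expect_true(is.na(grubbs_test(other$value)$flagged_index))
})
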