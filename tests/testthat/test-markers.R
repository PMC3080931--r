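test_that("signed fold change follows the negative-reciprocal convention", {
  expect_equal(signed_fold_change(10, 10), 1)
  expect_equal(signed_fold_change(15, 10), 1.5)
  expect_equal(signed_fold_change(2, 10), -5)
  expect_error(signed_fold_change(0, 10), "> 0")
  # |fc| >= 1 for any positive pair of means
  set.seed(1)
  a <- runif(200, 0.01, 50); b <- runif(200, 0.01, 50)
  expect_true(all(abs(signed_fold_change(a, b)) >= 1))
})

test_that("SNR matches its hand oracle and symmetries", {
  r <- snr_statistic(c(4, 6), c(1, 3))
  expect_equal(r$snr, 3 / (2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(r$summary$mu_treated, 5)
  expect_equal(r$summary$sigma_control, sqrt(2))

  expect_equal(snr_statistic(c(2, 4), c(4, 2))$snr, 0)  # equal means
  # antisymmetry under group swap
  x <- rnorm(5, 10); y <- rnorm(4, 8)
  expect_equal(snr_statistic(x, y)$snr, -snr_statistic(y, x)$snr)
  # invariance: additive shift and positive scaling (default floors)
  s0 <- snr_statistic(x, y)$snr
  expect_equal(snr_statistic(x + 7, y + 7)$snr, s0, tolerance = 1e-9)
  expect_equal(snr_statistic(3.2 * x, 3.2 * y)$snr, s0, tolerance = 1e-9)
  expect_error(snr_statistic(1, c(1, 2)), ">= 2 values")

  # relative floor: sd replaced by 0.2|mu| when smaller
  rf <- snr_statistic(c(10, 10.1), c(5, 4.9), relative_floor = TRUE)
  expect_equal(rf$summary$sigma_treated, 0.2 * 10.05)
  expect_equal(rf$snr, (10.05 - 4.95) / (0.2 * 10.05 + 0.2 * 4.95))
})

test_that("3-vs-3 relabelings are exhaustive, 20-deep and seed-free", {
  r <- permutation_relabelings(6, 3, n_perm = 2000)
  expect_identical(r$mode, "exhaustive")
  expect_equal(ncol(r$labelings), 20)  # C(6, 3)
  expect_identical(r$labelings, permutation_relabelings(6, 3, 2000, seed = 99)$labelings)
  expect_error(permutation_relabelings(6, 3, n_perm = 0), ">= 1")

  s <- permutation_relabelings(12, 6, n_perm = 50, seed = 4)
  expect_identical(s$mode, "sampled")
  expect_equal(ncol(s$labelings), 50)
  keys <- apply(s$labelings, 2, paste, collapse = ",")
  expect_false(anyDuplicated(keys) > 0)  # without replacement
  expect_identical(s$labelings, permutation_relabelings(12, 6, 50, seed = 4)$labelings)
})

test_that("permutation null pools 20 x n_mirnas statistics in 3-vs-3", {
  sim <- toy_study(n_mirnas = 15, seed = 3)
  logm <- log2(sim$mirna$values + 1)
  null <- permutation_null(logm, sim$mirna$group, n_perm = 2000)
  expect_equal(length(null$pool), 20 * 15)
  expect_identical(null$mode, "exhaustive")
  # exhaustive pool is seed-independent
  null2 <- permutation_null(logm, sim$mirna$group, n_perm = 2000, seed = 77)
  expect_identical(null$pool, null2$pool)
  # constant matrix: every null statistic is exactly zero
  const <- matrix(5, 4, 6, dimnames = list(paste0("m", 1:4), paste0("s", 1:6)))
  nc <- permutation_null(const, rep(c("treated", "control"), each = 3))
  expect_true(all(nc$pool == 0))
  # mixing pool drops the observed assignment and its mirror
  mix <- permutation_null(logm, sim$mirna$group, drop_observed = TRUE)
  expect_equal(length(mix$pool), 18 * 15)
})

test_that("smoothed p-values follow the add-one pooled formula", {
  expect_equal(smoothed_p(0.75, c(-1, -0.5, 0.5, 1)), 0.6)  # (2+1)/(4+1)
  expect_equal(smoothed_p(0, c(-1, -0.5, 0.5, 1)), 1)       # all nulls qualify
  expect_equal(smoothed_p(99, rep(0.5, 9)), 1 / 10)         # exceeds the pool
  expect_error(smoothed_p(1, numeric(0)), "empty")
  # tie handling: |null| == |obs| counts toward b
  expect_equal(smoothed_p(0.5, c(-1, -0.5, 0.5, 1)), 1)
})

test_that("per-miRNA unpooled permutation p cannot fall below 1/20", {
  sim <- toy_study(n_mirnas = 10, seed = 13,
                   spiked = c("mir-0001" = -6))
  logm <- log2(sim$mirna$values + 1)
  null <- permutation_null(logm, sim$mirna$group)  # all 20 relabelings
  obs <- null$stats[, which(apply(null$labelings, 2, identical,
                                  y = which(sim$mirna$group == "treated")))]
  p_unpooled <- vapply(seq_len(nrow(logm)), function(i) {
    smoothed_p(obs[i], null$stats[i, ])
  }, numeric(1))
  expect_true(all(p_unpooled >= 1 / 20))
})

test_that("BH adjustment matches a brute-force oracle", {
  expect_equal(benjamini_hochberg(0.37), 0.37)                   # m = 1
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))                                     # hand oracle
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(42)
  for (m in c(2, 5, 8)) {
    for (rep in 1:20) {
      p <- runif(m)
      if (rep %% 3 == 0) p[1:2] <- p[1]  # exercise ties
      expect_equal(benjamini_hochberg(p), bh_brute_force(p), tolerance = 1e-12)
    }
  }
})

test_that("three-criterion call applies the printed boundary logic", {
  res <- data.frame(
    mirna_id = c("a", "b", "c", "d"),
    fc = c(1.0, -1.5, -5.0, -2.0),
    p_value = c(0.0001, 0.004, 0.005, 0.004),
    fdr = c(0.0001, 0.004, 0.004, 0.005))
  out <- call_differential(res)
  sig <- setNames(out$significant, out$mirna_id)
  expect_false(sig[["a"]])  # |fc| < 1.5 regardless of p/fdr
  expect_true(sig[["b"]])   # FC boundary inclusive
  expect_false(sig[["c"]])  # p boundary strict
  expect_false(sig[["d"]])  # fdr boundary strict
  # ranking: |fc| desc, then p asc, then id
  expect_identical(out$mirna_id, c("c", "d", "b", "a"))
  expect_identical(out$rank, 1:4)
})

test_that("row standardization and clustering behave on edge cases", {
  vals <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(5, 5, 5, 5), c(8, 6, 4, 2))
  dimnames(vals) <- list(paste0("m", 1:4), paste0("s", 1:4))
  x <- toy_expr(vals, treated = 1:2)
  sc <- standardize_and_cluster(x, paste0("m", 1:4))
  z <- sc$standardized
  expect_equal(unname(z["m3", ]), rep(0, 4))           # constant row -> zeros
  nz <- z[c("m1", "m2", "m4"), ]
  expect_equal(unname(rowMeans(nz)), rep(0, 3))
  expect_equal(unname(apply(nz, 1, sd)), rep(1, 3))
  # m1 and m2 are perfectly correlated on the log scale: adjacent leaves
  o <- sc$order
  expect_equal(abs(which(o == 1) - which(o == 2)), 1)
  expect_error(standardize_and_cluster(x, c("m1", "zz")), "unknown miRNA")
  expect_error(standardize_and_cluster(x, character(0)), "empty")
})

test_that("marker fit recovers strong down-regulated spikes, down-only", {
  spikes <- setNames(runif(20, 4, 5.5) * -1, sprintf("mir-%04d", 1:20))
  sim <- toy_study(n_mirnas = 120, spiked = spikes, noise_sd = 0.25, seed = 17)
  fit <- mirna_markers(sim$mirna, seed = 17)
  r <- fit$results
  sig <- r[r$significant, ]
  # power: >= 90% of |fc| >= 4 spikes flagged
  expect_gte(sum(sig$mirna_id %in% names(spikes)), 18)
  # with down-only truth every flagged miRNA is down-regulated
  expect_true(all(sig$fc < 0))
  # flagged spikes outrank every null miRNA
  spiked_rank <- r$rank[r$mirna_id %in% names(spikes)]
  null_rank <- r$rank[!r$mirna_id %in% names(spikes)]
  expect_true(max(spiked_rank) < min(null_rank))
  # p/fdr land in (0, 1]
  expect_true(all(r$p_value > 0 & r$p_value <= 1))
  expect_true(all(r$fdr > 0 & r$fdr <= 1))
})

test_that("marker fit object supports the usual model-object verbs", {
  sim <- toy_study(n_mirnas = 30, spiked = c("mir-0001" = -5), seed = 23)
  fit <- mirna_markers(sim$mirna, seed = 23)
  expect_s3_class(fit, "mirna_markers")
  expect_output(print(fit), "Permutation-SNR marker fit")
  s <- summary(fit)
  expect_output(print(s), "Top-ranked markers")
  expect_named(coef(fit)[1], as.data.frame(fit)$mirna_id[1])
  expect_identical(nrow(as.data.frame(fit)), 30L)
  pdf(NULL)
  on.exit(dev.off())
  sc <- plot(fit, top_n = 10)
  expect_true(all(sc$order %in% seq_len(nrow(sc$standardized))))
  # a plain matrix plus group labels is accepted too
  fit2 <- mirna_markers(sim$mirna$values, group = as.character(sim$mirna$group),
                        seed = 23)
  expect_equal(fit2$results$p_value, fit$results$p_value)
})

test_that("fit reproduces: spiked example recovers 9/10 with calibrated nulls", {
  # 500 miRNAs, 10 spiked at -5.5: the ten spikes dominate the ranking and
  # reach p < 0.005, and null miRNAs stay calibrated at nominal p < 0.05.
  # (With only 10 co-significant markers the pooled estimator's FDR floor
  # ~1/(18k) sits just above 0.005, so the FDR criterion is not asserted
  # here; the 89-spike acceptance test covers the full call.)
  spikes <- setNames(rep(-5.5, 10), sprintf("mir-%04d", 1:10))
  sim <- toy_study(n_mirnas = 500, n_probes = 1500, spiked = spikes,
                   noise_sd = 0.25, seed = 31)
  fit <- mirna_markers(sim$mirna, seed = 31)
  r <- fit$results
  spiked <- r$mirna_id %in% names(spikes)
  hits <- sum(abs(r$fc[spiked]) >= 1.5 & r$p_value[spiked] < 0.005)
  expect_gte(hits, 9)
  expect_lt(max(r$rank[spiked]), min(r$rank[!spiked]) + 2)
  expect_lte(mean(r$p_value[!spiked] < 0.05), 0.05 + 0.03)
})
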