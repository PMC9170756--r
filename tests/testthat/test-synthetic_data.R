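test_that("zero-noise simulation reproduces planted folds exactly", {
  p6_mix <- stats::setNames(c(0, 0, 0, 0, 0, 1, 0, 0, 0), paste0("P", 1:9))
  spec <- simulation_spec(n_proteins = 20, pattern_mix = p6_mix,
                          log2_noise_sd = 0, missing_prob = 0, seed = 3)
  sim <- simulate_dataset(spec)
  h <- harmonize_ratios(sim$quant, sim$design)
  expect_equal(unique(h$pa_over_control), 4.0)
  expect_equal(unique(h$combined_over_control), 1.0)
  # full-pipeline recovery is perfect without noise
  a <- classify_proteins(filter_min_quantified(aggregate_proteins(h), 2))
  expect_equal(unique(a$pattern), "P6")
})

test_that("simulation is deterministic and stable under n growth", {
  spec <- simulation_spec(n_proteins = 50, seed = 19)
  s1 <- simulate_dataset(spec)
  s2 <- simulate_dataset(spec)
  expect_identical(s1, s2)
  # byte-identical files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulated_dataset(s1, d1); write_simulated_dataset(s2, d2)
  for (f in c("quant.tsv", "design.yaml", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # growing n_proteins never reshuffles earlier proteins
  big <- simulate_dataset(simulation_spec(n_proteins = 80, seed = 19))
  expect_identical(big$truth[1:50, ], s1$truth)
  expect_identical(big$quant[big$quant$protein_id %in% s1$truth$protein_id, ],
                   s1$quant)
})

test_that("infeasible fold specifications are rejected", {
  expect_error(simulation_spec(fold_up = 1.5), "no-change band")
  expect_error(simulation_spec(fold_down = 0.6), "no-change band")
  expect_error(simulation_spec(enhancement_fold = 1.2), "threshold")
  expect_error(simulation_spec(missing_prob = 1), "missing_prob")
  expect_error(simulation_spec(pattern_mix = c(P1 = 1)), "named over")
})

test_that("null non-P1 fraction matches an independently coded generator", {
  # oracle: direct matrix simulation of 3 complete replicates of null
  # ratios, classified by plain arithmetic, no shared code path
  oracle_frac <- function(n, sd, seed) {
    set.seed(seed)
    pa <- matrix(2^rnorm(n * 3, 0, sd), n, 3)
    cb <- matrix(2^rnorm(n * 3, 0, sd), n, 3)
    m_pa <- rowMeans(pa); m_cb <- rowMeans(cb)
    mean(m_pa >= 2 | m_pa <= 0.5 | m_cb >= 2 | m_cb <= 0.5)
  }
  null_mix <- stats::setNames(c(1, rep(0, 8)), paste0("P", 1:9))
  n <- 20000
  for (sd in c(0.2, 0.5)) {
    spec <- simulation_spec(n_proteins = n, pattern_mix = null_mix,
                            log2_noise_sd = sd, missing_prob = 0, seed = 61)
    sim <- simulate_dataset(spec)
    kept <- filter_min_quantified(
      aggregate_proteins(harmonize_ratios(sim$quant, sim$design)), 2)
    got <- mean(classify_proteins(kept)$pattern != "P1")
    ref <- oracle_frac(n, sd, seed = 62)
    se <- sqrt(max(ref * (1 - ref), 1 / n) / n)
    expect_lt(abs(got - ref), 4 * se + 1e-9)
  }
})

test_that("annotation generator plants enrichment only when odds > 1", {
  spec <- simulation_spec(n_proteins = 1500, seed = 71)
  sim <- simulate_dataset(spec)
  query <- sim$truth$gene_symbol[sim$truth$true_pattern == "P6"]
  factor_at <- function(odds, seed) {
    ann <- simulate_annotations(
      sim$truth, seed = seed,
      planted_set = list(name = "PL", target_pattern = "P6",
                         enrichment_odds = odds, size = 50))
    background <- unique(c(toupper(unlist(ann$gene_sets, use.names = FALSE)),
                           sim$truth$gene_symbol))
    res <- enrich(intersect(query, background), ann$gene_sets, background)
    res$enrichment_factor[res$set_name == "PL"]
  }
  null_factors <- vapply(1:15, function(s) factor_at(1, 100 + s), numeric(1))
  expect_gt(median(null_factors), 0.5)
  expect_lt(median(null_factors), 1.7)  # odds 1 ~ background behaviour
  planted_factors <- vapply(1:5, function(s) factor_at(8, 200 + s),
                            numeric(1))
  expect_true(all(planted_factors > 2))
})

test_that("TF flags concentrate in the configured patterns", {
  spec <- simulation_spec(n_proteins = 2000, seed = 83)
  sim <- simulate_dataset(spec)
  ann <- simulate_annotations(sim$truth, seed = 84, tf_prob_in = 0.5,
                              tf_prob_out = 0.05)
  in_pat <- sim$truth$true_pattern %in% c("P6", "P8")
  rate_in <- mean(ann$is_tf_target[in_pat])
  rate_out <- mean(ann$is_tf_target[!in_pat])
  expect_gt(rate_in, 4 * rate_out)
})
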