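test_that("harmonization maps channels per orientation", {
  # forward: light = PA, heavy = combined; reverse swaps
  f <- harmonize_orientation(ratio_hm = 1.0, ratio_lm = 2.0, "forward")
  expect_equal(f$pa_over_control, 2.0)
  expect_equal(f$combined_over_control, 1.0)
  r <- harmonize_orientation(ratio_hm = 1.0, ratio_lm = 2.0, "reverse")
  expect_equal(r$pa_over_control, 1.0)
  expect_equal(r$combined_over_control, 2.0)
  id <- harmonize_orientation(1, 1, c("forward", "reverse"))
  expect_equal(id$pa_over_control, c(1, 1))
  expect_equal(id$combined_over_control, c(1, 1))
  expect_error(harmonize_orientation(1, 1, "sideways"), "forward")
  # missing channels propagate
  m <- harmonize_orientation(NA, 2.0, "forward")
  expect_equal(m$pa_over_control, 2.0)
  expect_true(is.na(m$combined_over_control))
})

test_that("orientation involution: forward equals channel-swapped reverse", {
  set.seed(7)
  for (i in 1:50) {
    hm <- exp(rnorm(1)); lm <- exp(rnorm(1))
    f <- harmonize_orientation(hm, lm, "forward")
    r <- harmonize_orientation(lm, hm, "reverse")
    expect_identical(f, r)
  }
})

test_that("aggregation matches hand arithmetic and degenerate cases", {
  # mean/sd of {1.0, 1.2, 1.1}: sample SD 0.1
  s <- aggregate_protein(ratios_df(pa = c(1.0, 1.2, 1.1),
                                   combined = c(2, 2, 2)))
  expect_equal(s$pa_mean, 1.1)
  expect_equal(s$pa_sd, 0.1)
  expect_equal(s$n_quantified, 3L)
  expect_equal(s$log2_pa[[1]], log2(c(1.0, 1.2, 1.1)))

  one <- aggregate_protein(ratios_df(2.0, 1.0))
  expect_equal(one$pa_mean, 2.0)
  expect_equal(one$pa_sd, 0.0)
  expect_equal(one$n_quantified, 1L)

  cp <- aggregate_protein(ratios_df(c(2, 2, 2), c(1, 1, 1)))
  expect_equal(cp$combined_over_pa_mean, 0.5)

  expect_error(aggregate_protein(ratios_df(1, 1)[0, ]), "empty")
  expect_error(aggregate_protein(
    rbind(ratios_df(1, 1, "A"), ratios_df(1, 1, "B"))), "one protein_id")
})

test_that("a replicate counts only when both ratios are present", {
  df <- ratios_df(pa = c(1.0, NA, 1.2), combined = c(1.1, 2.0, NA))
  s <- aggregate_protein(df)
  expect_equal(s$n_quantified, 1L)
  expect_equal(s$pa_mean, 1.0)
  expect_length(s$log2_pa[[1]], 1L)
})

test_that("aggregation is permutation-invariant in replicate order", {
  set.seed(11)
  base <- ratios_df(pa = exp(rnorm(4)), combined = exp(rnorm(4)))
  ref <- aggregate_protein(base)
  for (i in 1:10) {
    perm <- base[sample(nrow(base)), ]
    got <- aggregate_protein(perm)
    expect_equal(got$pa_mean, ref$pa_mean)
    expect_equal(got$pa_sd, ref$pa_sd)
    expect_equal(got$combined_over_pa_mean, ref$combined_over_pa_mean)
    expect_equal(sort(got$log2_pa[[1]]), sort(ref$log2_pa[[1]]))
  }
})

test_that("aggregate_proteins agrees with per-protein aggregation", {
  design <- toy_design()
  quant <- random_quant_df(n_proteins = 30, seed = 3)
  h <- harmonize_ratios(quant, design)
  all <- aggregate_proteins(h)
  for (pid in sample(unique(h$protein_id), 5)) {
    single <- aggregate_protein(h[h$protein_id == pid, ])
    row <- all[all$protein_id == pid, ]
    expect_equal(row$pa_mean, single$pa_mean)
    expect_equal(row$combined_sd, single$combined_sd)
    expect_equal(row$n_quantified, single$n_quantified)
    expect_equal(row$log2_combined[[1]], single$log2_combined[[1]])
  }
})

test_that("min-quantified filter implements the quantified-at-least-twice rule", {
  h <- rbind(ratios_df(c(1.1, NA), c(1.0, NA), "ONLY_F1"),
             ratios_df(c(1.1, 1.2), c(1.0, 1.0), "F1_R1"))
  s <- aggregate_proteins(h)
  kept <- filter_min_quantified(s, 2)
  expect_equal(kept$protein_id, "F1_R1")   # single-replicate protein dropped
  expect_equal(filter_min_quantified(s, 1)$protein_id, s$protein_id)
  expect_error(filter_min_quantified(s, 0), ">= 1")
})

test_that("noise-free folds survive harmonization exactly under any design mix", {
  for (orientations in list(c("forward", "forward", "reverse"),
                            rep("forward", 3), rep("reverse", 3))) {
    design <- experiment_design("x", sprintf("R%d", 1:3), orientations)
    f <- 3.7; g <- 0.31
    fwd <- orientations == "forward"
    quant <- data.frame(protein_id = "P1", gene_symbol = "G1",
                        replicate_id = design$replicates$replicate_id,
                        ratio_hm = ifelse(fwd, g, f),
                        ratio_lm = ifelse(fwd, f, g),
                        stringsAsFactors = FALSE)
    s <- aggregate_proteins(harmonize_ratios(quant, design))
    expect_equal(s$pa_mean, f)
    expect_equal(s$combined_mean, g)
  }
})
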