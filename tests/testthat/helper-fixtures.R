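# Shared fixtures, all built in code at test time.

toy_design <- function() {
  experiment_design("PA+OA", c("F1", "F2", "R1"),
                    c("forward", "forward", "reverse"))
}

# Random quantification table for round-trip / property tests.
random_quant_df <- function(n_proteins = 20, design = toy_design(),
                            missing_prob = 0.2, seed = 1) {
  set.seed(seed)
  reps <- design$replicates$replicate_id
  grid <- expand.grid(p = seq_len(n_proteins), r = reps,
                      stringsAsFactors = FALSE)
  maybe_na <- function(x) ifelse(runif(length(x)) < missing_prob, NA, x)
  data.frame(protein_id = sprintf("P%03d", grid$p),
             gene_symbol = sprintf("GENE%03d", grid$p),
             replicate_id = grid$r,
             ratio_hm = maybe_na(exp(rnorm(nrow(grid), 0, 0.5))),
             ratio_lm = maybe_na(exp(rnorm(nrow(grid), 0, 0.5))),
             stringsAsFactors = FALSE)
}

write_tsv_lines <- function(lines, path = withr::local_tempfile(
                              fileext = ".tsv", .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# One-row-per-replicate harmonized data frame for a single protein.
ratios_df <- function(pa, combined, protein_id = "P1") {
  data.frame(protein_id = protein_id, gene_symbol = "G1",
             replicate_id = sprintf("R%d", seq_along(pa)),
             pa_over_control = pa, combined_over_control = combined,
             stringsAsFactors = FALSE)
}

# Independent closed-form hypergeometric upper tail via binomial coefficients
# (the enumeration oracle; deliberately avoids dhyper/phyper).
hyper_tail_enum <- function(observed, query, set, background) {
  if (observed == 0) return(1)
  k <- observed:min(query, set)
  sum(choose(set, k) * choose(background - set, query - k)) /
    choose(background, query)
}
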