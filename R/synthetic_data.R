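# Seeded generator for triple-SILAC quantification tables with known truth.
#
# Each protein draws a response pattern, gets deterministic true fold changes
# for PA and the combined treatment, and emits one observation per replicate:
# treatment/control ratios perturbed by i.i.d. multiplicative log-normal
# noise, converted to heavy/medium and light/medium channel ratios according
# to that replicate's labeling orientation, and dropped completely at random
# with probability missing_prob. Noise is drawn on the treatment-ratio scale
# BEFORE orientation mapping, so the same truth and seed give identical
# harmonized data under any forward/reverse mix.
#
# Seeding contract: one master seed; protein i uses a substream seeded by
# stable arithmetic on (seed, i), so growing n_proteins never reshuffles
# earlier proteins.

#' Specify a synthetic triple-SILAC experiment
#'
#' Defaults state a realistic experiment: the nine-pattern mix observed in
#' the PA+EPA comparison, 4-fold planted effects (0.25 for down), another
#' 4-fold enhancement on top for P4, log2 noise SD 0.2 (linear-ratio SD near
#' 0.14-0.16 around ratio 1, the scale reported for real triple-SILAC
#' replicates), 10% missingness per protein x replicate, and the 2 forward +
#' 1 reverse triplicate design.
#'
#' @param n_proteins number of proteins to simulate.
#' @param pattern_mix probability vector over P1-P9 (normalized internally).
#' @param fold_up true fold for up-responses (>= threshold).
#' @param fold_down true fold for down-responses (<= 1/threshold).
#' @param enhancement_fold extra fold applied on top for P4 (>= threshold).
#' @param log2_noise_sd SD of the log2-scale multiplicative noise.
#' @param missing_prob per-observation dropout probability in [0, 1).
#' @param design an \code{ffa_design}.
#' @param seed master integer seed.
#' @param threshold category boundary the folds must respect (default 2).
#' @return object of class \code{sim_spec}.
#' @export
simulation_spec <- function(n_proteins = 1000L,
                            pattern_mix = NULL,
                            fold_up = 4.0,
                            fold_down = 0.25,
                            enhancement_fold = 4.0,
                            log2_noise_sd = 0.2,
                            missing_prob = 0.1,
                            design = NULL,
                            seed = 1L,
                            threshold = 2.0) {
  if (is.null(pattern_mix)) {
    counts <- reference_pattern_counts("pa_epa")$counts
    pattern_mix <- counts / sum(counts)
  }
  if (is.null(names(pattern_mix))) names(pattern_mix) <- PATTERN_LEVELS
  if (!setequal(names(pattern_mix), PATTERN_LEVELS))
    stop("pattern_mix must be named over P1-P9")
  pattern_mix <- pattern_mix[PATTERN_LEVELS]
  if (any(pattern_mix < 0) || sum(pattern_mix) <= 0)
    stop("pattern_mix must be non-negative with positive sum")
  pattern_mix <- pattern_mix / sum(pattern_mix)
  if (is.null(design))
    design <- experiment_design("synthetic", c("F1", "F2", "R1"),
                                c("forward", "forward", "reverse"))
  if (fold_up < threshold)
    stop("infeasible spec: fold_up lies inside the no-change band")
  if (fold_down > 1 / threshold)
    stop("infeasible spec: fold_down lies inside the no-change band")
  if (enhancement_fold < threshold)
    stop("infeasible spec: enhancement_fold below the category threshold")
  if (missing_prob < 0 || missing_prob >= 1)
    stop("missing_prob must be in [0, 1)")
  if (log2_noise_sd < 0) stop("log2_noise_sd must be >= 0")
  structure(list(n_proteins = as.integer(n_proteins),
                 pattern_mix = pattern_mix,
                 fold_up = fold_up, fold_down = fold_down,
                 enhancement_fold = enhancement_fold,
                 log2_noise_sd = log2_noise_sd,
                 missing_prob = missing_prob,
                 design = design,
                 seed = as.integer(seed),
                 threshold = threshold),
            class = "sim_spec")
}

# True (PA fold, combined fold) per pattern.
pattern_true_folds <- function(pattern, spec) {
  up <- spec$fold_up; dn <- spec$fold_down; en <- spec$enhancement_fold
  folds <- list(P1 = c(1, 1), P2 = c(1, up), P3 = c(1, dn),
                P4 = c(up, up * en), P5 = c(up, up), P6 = c(up, 1),
                P7 = c(dn, dn), P8 = c(dn, 1), P9 = c(dn, up))
  folds[[pattern]]
}

# Stable per-protein substream seed; stays within 32-bit integer range.
protein_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483647 + i * 7919) %% 2147483647)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a triple-SILAC quantification table with known truth
#'
#' @param spec a \code{sim_spec} from \code{\link{simulation_spec}}.
#' @return list with \code{quant} (quantification-table data frame in the
#'   \code{\link{read_quant_table}} schema), \code{truth} (per-protein
#'   data frame: \code{protein_id}, \code{gene_symbol}, \code{true_pattern},
#'   \code{true_pa_fold}, \code{true_combined_fold}) and \code{design}.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  reps <- spec$design$replicates
  R <- nrow(reps)
  n <- spec$n_proteins
  cum <- cumsum(spec$pattern_mix)
  pat <- character(n)
  pa_fold <- numeric(n); cb_fold <- numeric(n)
  # per-protein x replicate noisy treatment ratios, pre-orientation
  pa_obs <- matrix(NA_real_, n, R)
  cb_obs <- matrix(NA_real_, n, R)
  keep <- matrix(TRUE, n, R)
  for (i in seq_len(n)) {
    with_local_seed(protein_seed(spec$seed, i), {
      p <- PATTERN_LEVELS[min(findInterval(stats::runif(1), cum) + 1L, 9L)]
      pat[i] <- p
      f <- pattern_true_folds(p, spec)
      pa_fold[i] <- f[1]; cb_fold[i] <- f[2]
      for (r in seq_len(R)) {
        z <- stats::rnorm(2, 0, spec$log2_noise_sd)
        pa_obs[i, r] <- f[1] * 2^z[1]
        cb_obs[i, r] <- f[2] * 2^z[2]
        keep[i, r] <- stats::runif(1) >= spec$missing_prob
      }
    })
  }
  ids <- sprintf("PROT%06d", seq_len(n))
  genes <- sprintf("G%06d", seq_len(n))
  rows <- which(keep, arr.ind = TRUE)
  rows <- rows[order(rows[, 1], rows[, 2]), , drop = FALSE]
  i <- rows[, 1]; r <- rows[, 2]
  fwd <- reps$orientation[r] == "forward"
  pa <- pa_obs[cbind(i, r)]; cb <- cb_obs[cbind(i, r)]
  quant <- data.frame(protein_id = ids[i],
                      gene_symbol = genes[i],
                      replicate_id = reps$replicate_id[r],
                      ratio_hm = ifelse(fwd, cb, pa),
                      ratio_lm = ifelse(fwd, pa, cb),
                      stringsAsFactors = FALSE)
  truth <- data.frame(protein_id = ids, gene_symbol = genes,
                      true_pattern = pat,
                      true_pa_fold = pa_fold,
                      true_combined_fold = cb_fold,
                      stringsAsFactors = FALSE)
  list(quant = quant, truth = truth, design = spec$design)
}

#' Simulate gene-set and TF-target annotations for a synthetic truth table
#'
#' Background gene sets are drawn uniformly from the simulated genes; one
#' planted set over-samples genes of a target pattern at the stated odds
#' (odds 1 reduces to a background set). TF-target flags are drawn with
#' elevated probability inside the configured patterns, and a configurable
#' fraction of flagged targets receives score/TSS values that fail the
#' canonical filters (a zero binding score or a binding site beyond the TSS
#' window).
#'
#' @param truth truth data frame from \code{\link{simulate_dataset}}.
#' @param n_sets number of background gene sets.
#' @param set_size_range integer range for background set sizes.
#' @param planted_set list with \code{name}, \code{target_pattern},
#'   \code{enrichment_odds} and optionally \code{size} (default 50).
#' @param tf_patterns patterns whose genes are preferential TF targets.
#' @param tf_prob_in,tf_prob_out target-flag probability inside/outside
#'   \code{tf_patterns}.
#' @param frac_filter_fail fraction of flagged targets given filter-failing
#'   scores or TSS distances.
#' @param seed integer seed.
#' @return list with \code{gene_sets} (named list incl. the planted set),
#'   \code{tf_table} (data frame in the \code{\link{read_tf_targets}}
#'   schema), \code{is_tf_target} (logical per truth row) and
#'   \code{planted_name}.
#' @export
simulate_annotations <- function(truth,
                                 n_sets = 25L,
                                 set_size_range = c(10L, 40L),
                                 planted_set = list(name = "PLANTED_SET",
                                                    target_pattern = "P6",
                                                    enrichment_odds = 8,
                                                    size = 50L),
                                 tf_patterns = c("P6", "P8"),
                                 tf_prob_in = 0.5,
                                 tf_prob_out = 0.05,
                                 frac_filter_fail = 0.3,
                                 seed = 1L) {
  if (nrow(truth) == 0L) stop("truth must be non-empty")
  with_local_seed(seed, {
    genes <- truth$gene_symbol
    sets <- list()
    for (s in seq_len(n_sets)) {
      size <- sample(set_size_range[1]:set_size_range[2], 1)
      nm <- sprintf("BG_SET_%03d", s)
      sets[[nm]] <- structure(sort(sample(genes, size)),
                              description = "background set")
    }
    odds <- planted_set$enrichment_odds %||% 1
    psize <- planted_set$size %||% 50L
    w <- ifelse(truth$true_pattern == planted_set$target_pattern, odds, 1)
    planted <- sort(sample(genes, min(psize, length(genes)), prob = w))
    sets[[planted_set$name]] <- structure(
      planted, description = sprintf("planted toward %s at odds %s",
                                     planted_set$target_pattern, odds))
    p_flag <- ifelse(truth$true_pattern %in% tf_patterns, tf_prob_in,
                     tf_prob_out)
    flagged <- stats::runif(nrow(truth)) < p_flag
    tf_genes <- genes[flagged]
    n_tf <- length(tf_genes)
    fail <- stats::runif(n_tf) < frac_filter_fail
    score_macs2 <- stats::runif(n_tf, 1, 100)
    score_string <- stats::runif(n_tf, 1, 10)
    tss <- stats::runif(n_tf, 0, 1)
    # failing targets miss on a random one of the three filter axes
    mode <- sample(1:3, n_tf, replace = TRUE)
    score_macs2[fail & mode == 1] <- 0
    score_string[fail & mode == 2] <- 0
    tss[fail & mode == 3] <- stats::runif(sum(fail & mode == 3), 1.001, 50)
    list(gene_sets = sets,
         tf_table = data.frame(gene_symbol = tf_genes,
                               score_macs2 = score_macs2,
                               score_string = score_string,
                               tss_distance_kb = tss,
                               stringsAsFactors = FALSE),
         is_tf_target = flagged,
         planted_name = planted_set$name)
  })
}

#' Write a simulated dataset to disk in the pipeline's file dialects
#'
#' @param sim result of \code{\link{simulate_dataset}}.
#' @param dir output directory (created if needed).
#' @return named vector of the file paths written (quant, design, truth).
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(quant = file.path(dir, "quant.tsv"),
             design = file.path(dir, "design.yaml"),
             truth = file.path(dir, "truth.tsv"))
  write_quant_table(sim$quant, paths[["quant"]])
  write_design(sim$design, paths[["design"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
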