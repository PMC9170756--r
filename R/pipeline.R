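# End-to-end orchestration: harmonize -> filter -> aggregate -> volcano ->
# classify -> summarize -> (enrich) -> (TF overlap), with every applied
# threshold echoed into a machine-readable run report.

#' Run the full analysis pipeline
#'
#' Reads a quantification table, design and optional config / gene sets /
#' TF-target table, executes every stage, writes all output TSVs plus a JSON
#' run report to \code{out_dir}, and returns the report invisibly. The
#' pipeline is a pure function of its inputs: rerunning with the same files
#' gives byte-identical outputs.
#'
#' The enrichment stage takes the non-P1 proteins (the treatment responders)
#' as query. The background is the annotation universe (union of all gene-set
#' members plus the quantified genes) or, in \code{quantified_only} mode,
#' just the quantified genes. When a TF-target table is supplied its filtered
#' targets are intersected with the pattern groups, and each non-empty
#' overlap set is itself passed through enrichment when gene sets are
#' available.
#'
#' @param quant_path quantification TSV.
#' @param design_path design YAML or TSV.
#' @param config_path optional config YAML (defaults apply otherwise).
#' @param gmt_path optional GMT file enabling the enrichment stage.
#' @param tf_path optional TF-target TSV enabling the overlap stage.
#' @param out_dir output directory, created if needed.
#' @param median_center apply global median-centering of ratios (off by
#'   default; see \code{\link{median_center_ratios}}).
#' @return the run report (list), invisibly.
#' @export
run_pipeline <- function(quant_path, design_path, config_path = NULL,
                         gmt_path = NULL, tf_path = NULL, out_dir,
                         median_center = FALSE) {
  config <- if (is.null(config_path)) pipeline_config()
            else read_config(config_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  design <- stage("read_design", read_design(design_path))
  quant <- stage("read_quant", read_quant_table(quant_path, design))
  harmonized <- stage("harmonize", harmonize_ratios(quant, design))
  if (median_center) harmonized <- median_center_ratios(harmonized)
  summaries <- stage("aggregate", aggregate_proteins(harmonized))
  kept <- stage("filter",
                filter_min_quantified(summaries, config$min_quantified))
  volcano <- stage("volcano", volcano_table(kept, config))
  assignments <- stage("classify", classify_proteins(kept, config))
  psummary <- stage("summarize", summarize_patterns(assignments))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_protein_summary(kept, file.path(out_dir, "protein_summary.tsv"))
  write_volcano(volcano, file.path(out_dir, "volcano.tsv"))
  write_assignments(assignments, file.path(out_dir, "assignments.tsv"))
  write_pattern_summary(psummary, file.path(out_dir, "pattern_summary.tsv"))
  writeLines(render_summary(psummary),
             file.path(out_dir, "pattern_summary.txt"))

  report <- list(
    config = unclass(config),
    design = list(experiment_label = design$experiment_label,
                  replicates = design$replicates),
    stages = list(
      n_quant_records = nrow(quant),
      n_proteins_observed = nrow(summaries),
      n_passed_filter = nrow(kept),
      n_classified = nrow(assignments),
      n_dep_pa = sum(volcano$dep_flag[volcano$contrast == "PA_vs_control"]),
      n_dep_combined =
        sum(volcano$dep_flag[volcano$contrast == "combined_vs_control"])),
    pattern_counts = as.list(psummary$counts),
    reversed_count = psummary$reversed_count)

  gene_sets <- NULL
  if (!is.null(gmt_path)) {
    gene_sets <- stage("read_gmt", read_gmt(gmt_path))
    universe <- unique(toupper(unlist(gene_sets, use.names = FALSE)))
    quantified <- unique(assignments$gene_symbol)
    background <- if (config$background_mode == "quantified_only") quantified
                  else union(universe, quantified)
    query <- intersect(unique(
      assignments$gene_symbol[assignments$pattern != "P1"]), background)
    enr <- stage("enrich", enrich(query, gene_sets, background, config))
    write_enrichment(enr, file.path(out_dir, "enrichment.tsv"))
    report$stages$n_sets_tested <- nrow(enr)
    report$stages$n_sets_passing <- sum(enr$passes_filters)
  }
  if (!is.null(tf_path)) {
    tf <- stage("read_tf_targets", read_tf_targets(tf_path))
    targets <- filter_tf_targets(tf, config$tf_score_min,
                                 config$tf_tss_max_kb)
    overlap <- stage("tf_overlap",
                     intersect_targets_with_patterns(targets, assignments))
    write_tf_overlap(overlap, file.path(out_dir, "tf_overlap.tsv"))
    report$stages$n_tf_targets_filtered <- length(targets)
    report$tf_overlap_counts <-
      stats::setNames(as.list(overlap$counts$n_overlap),
                      overlap$counts$pattern)
    report$tf_responders_total <- overlap$responders_total
    if (!is.null(gene_sets)) {
      background <- unique(c(toupper(unlist(gene_sets, use.names = FALSE)),
                             assignments$gene_symbol))
      per_pat <- Filter(length, overlap$per_pattern)
      tf_enr <- do.call(rbind, lapply(names(per_pat), function(p) {
        e <- enrich(intersect(per_pat[[p]], background), gene_sets,
                    background, config)
        if (nrow(e)) cbind(pattern = p, e) else NULL
      }))
      if (!is.null(tf_enr))
        write_enrichment(tf_enr, file.path(out_dir, "tf_enrichment.tsv"))
    }
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Render a pattern summary as fixed-format text
#'
#' One row per pattern with its count and proportion printed to one decimal
#' percent, followed by totals and the reversed (P6+P8) count. An empty
#' summary renders a warning line and no pattern rows.
#'
#' @param summary a \code{pattern_summary}.
#' @return character vector of lines.
#' @export
render_summary <- function(summary) {
  stopifnot(inherits(summary, "pattern_summary"))
  if (summary$degenerate)
    return(c("pattern\tcount\tproportion",
             "WARNING: no classified proteins; proportions undefined"))
  lines <- c("pattern\tcount\tproportion",
             sprintf("%s\t%d\t%.1f%%", names(summary$counts),
                     summary$counts, 100 * summary$proportions),
             sprintf("total\t%d\t(divisor %d)", summary$count_sum,
                     summary$total_classified),
             sprintf("reversed (P6+P8)\t%d", summary$reversed_count))
  lines
}
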