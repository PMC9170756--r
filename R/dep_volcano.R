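# Differential-expression calls and volcano statistics.
#
# DEP status is decided by fold change alone: mean treatment/control ratio
# >= threshold (up) or <= 1/threshold (down), boundaries inclusive, among
# proteins passing the min-quantified filter. One-sample t-tests on the
# per-replicate log2 ratios annotate the volcano output but never gate calls.

#' Call regulation direction from a mean ratio
#'
#' Boundaries are inclusive: ratio >= threshold is \code{up}, ratio <=
#' 1/threshold is \code{down}, the open interval between is \code{none}.
#'
#' @param mean_ratio positive ratio(s).
#' @param threshold fold-change threshold, > 1 (default 2).
#' @return character vector in \code{c("up", "down", "none")}.
#' @examples
#' call_direction(c(2, 0.5, 1.99), 2)  # "up" "down" "none"
#' @export
call_direction <- function(mean_ratio, threshold = 2) {
  if (threshold <= 1) stop("threshold must be > 1")
  if (any(!is.finite(mean_ratio) | mean_ratio <= 0))
    stop("mean_ratio must be finite and > 0")
  ifelse(mean_ratio >= threshold, "up",
         ifelse(mean_ratio <= 1 / threshold, "down", "none"))
}

#' Two-sided one-sample t-test of log2 ratios against zero
#'
#' Degenerate inputs are flagged rather than erroring: fewer than two values
#' gives flag \code{"insufficient_replicates"}; zero variance with nonzero
#' mean gives flag \code{"degenerate"} (t infinite in the limit, p undefined);
#' an all-zero vector is the exact null, t = 0 and p = 1.
#'
#' @param log2_ratios numeric vector of per-replicate log2 ratios.
#' @return list with \code{t}, \code{p}, \code{flag} (\code{"ok"} or one of
#'   the degenerate flags above).
#' @examples
#' one_sample_t(c(0.9, 1.0, 1.1))  # t = 17.32, p ~ 0.0033
#' @export
one_sample_t <- function(log2_ratios) {
  x <- log2_ratios[is.finite(log2_ratios)]
  n <- length(x)
  if (n < 2L)
    return(list(t = NA_real_, p = NA_real_, flag = "insufficient_replicates"))
  s <- stats::sd(x)
  m <- mean(x)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, flag = "ok"))
    return(list(t = NA_real_, p = NA_real_, flag = "degenerate"))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1L), flag = "ok")
}

#' Build the volcano/DEP table
#'
#' One row per protein per contrast (\code{PA_vs_control} and
#' \code{combined_vs_control}) with the log2 mean ratio, t statistic, raw p,
#' -log10 p, direction and the DEP flag (direction != none). Input summaries
#' are expected to have passed \code{\link{filter_min_quantified}}.
#'
#' @param summaries protein-summary data frame.
#' @param config an \code{ffa_config}; only \code{fold_change_threshold} is
#'   used.
#' @param adjust add a Benjamini-Hochberg \code{p_adj} column (off by
#'   default; the canonical analysis reports raw volcano p-values).
#' @return volcano data frame.
#' @export
volcano_table <- function(summaries, config = pipeline_config(),
                          adjust = FALSE) {
  stopifnot(inherits(config, "ffa_config"))
  one_contrast <- function(contrast, mean_col, log2_col) {
    tt <- lapply(summaries[[log2_col]], one_sample_t)
    mean_ratio <- summaries[[mean_col]]
    direction <- call_direction(mean_ratio, config$fold_change_threshold)
    data.frame(protein_id = summaries$protein_id,
               gene_symbol = summaries$gene_symbol,
               contrast = contrast,
               mean_ratio = mean_ratio,
               log2_ratio = log2(mean_ratio),
               t = vapply(tt, `[[`, numeric(1), "t"),
               p = vapply(tt, `[[`, numeric(1), "p"),
               flag = vapply(tt, `[[`, character(1), "flag"),
               direction = direction,
               dep_flag = direction != "none",
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_contrast("PA_vs_control", "pa_mean", "log2_pa"),
               one_contrast("combined_vs_control", "combined_mean",
                            "log2_combined"))
  out$minus_log10_p <- -log10(out$p)
  if (adjust)
    out$p_adj <- stats::ave(out$p, out$contrast,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  rownames(out) <- NULL
  out
}

#' Write the volcano TSV
#'
#' @param volcano data frame from \code{\link{volcano_table}}.
#' @param path output path.
#' @export
write_volcano <- function(volcano, path) {
  cols <- c("protein_id", "gene_symbol", "contrast", "log2_ratio", "t", "p",
            "minus_log10_p", "dep_flag", "direction")
  if ("p_adj" %in% names(volcano)) cols <- c(cols, "p_adj")
  utils::write.table(volcano[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
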