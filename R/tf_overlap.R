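# Transcription-factor target / pattern-group intersection ("responder"
# analysis): predicted TF targets are filtered on two binding scores and the
# TSS distance window, then intersected with the pattern groups; the union
# over all responding (non-P1) patterns is the responder total.

#' Filter predicted TF targets by binding score and TSS distance
#'
#' Keeps genes where BOTH binding scores are strictly above \code{score_min}
#' and the binding site lies within \code{tss_max_kb} of the transcription
#' start site (inclusive). Defaults reproduce the canonical filter: scores
#' > 0 and a 1 kb window.
#'
#' @param targets data frame from \code{\link{read_tf_targets}}.
#' @param score_min exclusive lower bound for both scores (default 0).
#' @param tss_max_kb inclusive TSS-distance bound in kb (default 1).
#' @return character vector of unique retained gene symbols.
#' @export
filter_tf_targets <- function(targets, score_min = 0, tss_max_kb = 1) {
  stopifnot(is.finite(score_min), is.finite(tss_max_kb))
  keep <- targets$score_macs2 > score_min &
          targets$score_string > score_min &
          targets$tss_distance_kb <= tss_max_kb
  unique(targets$gene_symbol[keep])
}

#' Intersect TF targets with pattern groups
#'
#' For each requested pattern, returns the genes assigned to it that are in
#' the target set; also reports the responder total, i.e. targets among the
#' union of all non-P1 patterns (proteins whose expression responded to at
#' least one treatment).
#'
#' @param targets character vector of TF target genes.
#' @param assignments pattern-assignment data frame (needs
#'   \code{gene_symbol} and \code{pattern}).
#' @param patterns pattern labels to report (default P2-P9).
#' @return list with \code{per_pattern} (named list of gene vectors),
#'   \code{counts} (data frame pattern / n_overlap), and
#'   \code{responders_total} (targets in any non-P1 pattern).
#' @export
intersect_targets_with_patterns <- function(targets, assignments,
                                            patterns = paste0("P", 2:9)) {
  bad <- setdiff(patterns, PATTERN_LEVELS)
  if (length(bad))
    stop("unknown pattern label(s): ", paste(bad, collapse = ", "))
  targets <- unique(toupper(targets))
  per_pattern <- lapply(patterns, function(p) {
    genes <- unique(assignments$gene_symbol[assignments$pattern == p])
    sort(intersect(targets, genes))
  })
  names(per_pattern) <- patterns
  responders <- unique(
    assignments$gene_symbol[assignments$pattern != "P1"])
  list(per_pattern = per_pattern,
       counts = data.frame(pattern = patterns,
                           n_overlap = lengths(per_pattern),
                           stringsAsFactors = FALSE),
       responders_total = length(intersect(targets, responders)))
}

#' Write the TF-overlap TSV
#'
#' @param overlap result of \code{\link{intersect_targets_with_patterns}}.
#' @param path output path.
#' @export
write_tf_overlap <- function(overlap, path) {
  df <- overlap$counts
  df$genes <- vapply(overlap$per_pattern, paste, character(1),
                     collapse = ";")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
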