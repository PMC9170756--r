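# Nine-pattern classification of fatty-acid responses.
#
# Each quantified protein gets a category (down / none / up, two-fold
# boundaries inclusive) for the PA treatment and for the combined treatment,
# and a pattern label P1-P9 from the canonical 3x3 grid plus an "enhanced"
# subcell:
#
#   PA \ combined |  none |  up  | down
#   --------------+-------+------+------
#   none          |  P1   |  P2  |  P3
#   up            |  P6   | P5*  |  P6
#   down          |  P8   |  P9  |  P7
#
# (*) an up-regulated protein whose combined/PA mean ratio crosses the same
# threshold again (>= threshold) is "enhanced" and labeled P4 instead of P5;
# symmetrically a down-regulated protein with combined/PA <= 1/threshold folds
# into P7. P6 and P8 are the "reversed" patterns (PA effect cancelled by the
# combined treatment); P9 is over-reversal (down under PA, up under combined).

PATTERN_LEVELS <- paste0("P", 1:9)

#' Categorize a mean ratio (alias of call_direction)
#'
#' Shared contract with \code{\link{call_direction}}: >= threshold is
#' \code{up}, <= 1/threshold is \code{down}, otherwise \code{none}.
#'
#' @inheritParams call_direction
#' @export
categorize <- call_direction

#' Classify one or more proteins into patterns P1-P9
#'
#' @param pa_category,combined_category character vectors in
#'   \code{c("down", "none", "up")}.
#' @param combined_over_pa mean per-replicate combined/PA ratio(s), > 0;
#'   decides enhancement for proteins responding to PA.
#' @param threshold fold-change threshold (> 1, default 2); enhancement uses
#'   the same threshold.
#' @return character vector of pattern labels.
#' @examples
#' classify_pattern("none", "none", 1.0)   # "P1"
#' classify_pattern("up",   "none", 0.6)   # "P6" (reversed)
#' classify_pattern("up",   "up",   2.4)   # "P4" (enhanced)
#' @export
classify_pattern <- function(pa_category, combined_category, combined_over_pa,
                             threshold = 2) {
  cats <- c("down", "none", "up")
  if (any(!pa_category %in% cats) || any(!combined_category %in% cats))
    stop("categories must be one of 'down', 'none', 'up'")
  if (any(!is.finite(combined_over_pa) | combined_over_pa <= 0))
    stop("combined_over_pa must be finite and > 0")
  n <- max(length(pa_category), length(combined_category),
           length(combined_over_pa))
  pa <- rep_len(pa_category, n)
  cb <- rep_len(combined_category, n)
  cp <- rep_len(combined_over_pa, n)
  out <- character(n)
  none <- pa == "none"
  out[none & cb == "none"] <- "P1"
  out[none & cb == "up"] <- "P2"
  out[none & cb == "down"] <- "P3"
  up <- pa == "up"
  out[up & cp >= threshold] <- "P4"
  out[up & cp < threshold & cb == "up"] <- "P5"
  out[up & cp < threshold & cb != "up"] <- "P6"
  dn <- pa == "down"
  enh_dn <- dn & cp <= 1 / threshold
  out[dn & (cb == "down" | enh_dn)] <- "P7"
  out[dn & !enh_dn & cb == "none"] <- "P8"
  out[dn & !enh_dn & cb == "up"] <- "P9"
  out
}

#' Assign patterns to a protein-summary table
#'
#' @param summaries protein-summary data frame (post min-quantified filter).
#' @param config an \code{ffa_config}; \code{fold_change_threshold} drives
#'   both categorization and enhancement.
#' @return pattern-assignment data frame: \code{protein_id},
#'   \code{gene_symbol}, \code{pa_category}, \code{combined_category},
#'   \code{combined_over_pa}, \code{enhanced}, \code{pattern}.
#' @export
classify_proteins <- function(summaries, config = pipeline_config()) {
  stopifnot(inherits(config, "ffa_config"))
  thr <- config$fold_change_threshold
  pa_cat <- call_direction(summaries$pa_mean, thr)
  cb_cat <- call_direction(summaries$combined_mean, thr)
  cp <- summaries$combined_over_pa_mean
  pattern <- classify_pattern(pa_cat, cb_cat, cp, thr)
  data.frame(protein_id = summaries$protein_id,
             gene_symbol = summaries$gene_symbol,
             pa_category = pa_cat,
             combined_category = cb_cat,
             combined_over_pa = cp,
             enhanced = (pa_cat == "up" & cp >= thr) |
                        (pa_cat == "down" & cp <= 1 / thr),
             pattern = pattern,
             stringsAsFactors = FALSE)
}

#' Summarize pattern counts and proportions
#'
#' Counts per pattern, proportions, and the reversed-protein total
#' (P6 + P8). Proportions divide by \code{total}, defaulting to the number of
#' classified proteins; a published analysis total may be supplied instead
#' (the original tables' per-pattern counts do not sum exactly to the printed
#' quantified-protein totals, so both the count sum and the divisor are
#' reported).
#'
#' @param assignments pattern-assignment data frame (or any data frame with a
#'   \code{pattern} column).
#' @param total divisor for proportions; default \code{nrow(assignments)}.
#' @return object of class \code{pattern_summary}: list with \code{counts}
#'   (named integer vector P1-P9), \code{count_sum}, \code{total_classified},
#'   \code{proportions}, \code{reversed_count}, \code{degenerate} (TRUE when
#'   empty input makes proportions undefined).
#' @export
summarize_patterns <- function(assignments, total = NULL) {
  counts <- table(factor(assignments$pattern, levels = PATTERN_LEVELS))
  counts <- stats::setNames(as.integer(counts), PATTERN_LEVELS)
  if (is.null(total)) total <- nrow(assignments)
  degenerate <- total == 0L
  props <- if (degenerate) stats::setNames(rep(NA_real_, 9L), PATTERN_LEVELS)
           else counts / total
  structure(list(counts = counts,
                 count_sum = sum(counts),
                 total_classified = as.integer(total),
                 proportions = props,
                 reversed_count = counts[["P6"]] + counts[["P8"]],
                 degenerate = degenerate),
            class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  writeLines(render_summary(x))
  invisible(x)
}

#' Write pattern assignments and summary TSVs
#'
#' @param assignments pattern-assignment data frame.
#' @param path output path.
#' @export
write_assignments <- function(assignments, path) {
  cols <- c("protein_id", "gene_symbol", "pa_category", "combined_category",
            "combined_over_pa", "pattern")
  utils::write.table(assignments[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignments
#' @param summary a \code{pattern_summary}.
#' @export
write_pattern_summary <- function(summary, path) {
  df <- data.frame(pattern = PATTERN_LEVELS,
                   count = summary$counts,
                   proportion = summary$proportions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published reference pattern tables
#'
#' Per-pattern protein counts reported for the two HepG2 free-fatty-acid
#' triple-SILAC experiments, together with the number of proteins that passed
#' the quantified-at-least-twice filter (the divisor used for the published
#' proportions). These printed tables serve as worked-example inputs; note
#' the per-pattern counts do not sum exactly to the published totals, an
#' inconsistency of the source tables that this package reports rather than
#' resolves.
#'
#' @param experiment \code{"pa_oa"} (eight patterns, P9 empty) or
#'   \code{"pa_epa"} (nine patterns).
#' @return list with \code{counts} (named integer vector P1-P9) and
#'   \code{total_quantified}.
#' @examples
#' ref <- reference_pattern_counts("pa_oa")
#' sum(ref$counts)      # 4803
#' ref$total_quantified # 4633
#' @export
reference_pattern_counts <- function(experiment = c("pa_oa", "pa_epa")) {
  experiment <- match.arg(experiment)
  if (experiment == "pa_oa")
    list(counts = stats::setNames(c(4399L, 40L, 15L, 2L, 143L, 8L, 188L, 8L,
                                    0L), PATTERN_LEVELS),
         total_quantified = 4633L)
  else
    list(counts = stats::setNames(c(3200L, 282L, 8L, 66L, 379L, 913L, 19L,
                                    413L, 1L), PATTERN_LEVELS),
         total_quantified = 5471L)
}

#' Build representative pattern assignments from per-pattern counts
#'
#' Expands a named count vector into a pattern-assignment table by giving
#' every protein a representative (PA mean, combined mean) ratio pair for its
#' pattern and running it through the classifier — so summaries of published
#' count tables exercise the same code path as real data.
#'
#' @param counts named integer vector over P1-P9 (missing names count 0).
#' @param config an \code{ffa_config}.
#' @return pattern-assignment data frame with \code{sum(counts)} rows.
#' @export
assignments_from_counts <- function(counts, config = pipeline_config()) {
  thr <- config$fold_change_threshold
  up <- thr * 2; dn <- 1 / up
  rep_ratios <- list(P1 = c(1, 1), P2 = c(1, up), P3 = c(1, dn),
                     P4 = c(up, up * thr * 2), P5 = c(up, up), P6 = c(up, 1),
                     P7 = c(dn, dn), P8 = c(dn, 1), P9 = c(dn, up))
  counts <- counts[intersect(PATTERN_LEVELS, names(counts))]
  counts <- counts[counts > 0]
  rows <- lapply(names(counts), function(p) {
    r <- rep_ratios[[p]]
    data.frame(protein_id = sprintf("%s_%06d", p, seq_len(counts[[p]])),
               gene_symbol = "",
               n_quantified = 3L,
               pa_mean = r[1], pa_sd = 0,
               combined_mean = r[2], combined_sd = 0,
               combined_over_pa_mean = r[2] / r[1],
               stringsAsFactors = FALSE)
  })
  summaries <- do.call(rbind, rows)
  summaries$log2_pa <- I(rep(list(numeric(0)), nrow(summaries)))
  summaries$log2_combined <- I(rep(list(numeric(0)), nrow(summaries)))
  out <- classify_proteins(summaries, config)
  stopifnot(identical(
    as.integer(table(factor(out$pattern, levels = names(counts)))),
    as.integer(counts)))
  out
}
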