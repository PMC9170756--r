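# Readers/writers for every external table the pipeline touches, plus the
# experiment design and run configuration. All files are UTF-8, tab-separated
# with a mandatory header row and "." as decimal point (the dialect quant
# software exports). Gene symbols are uppercased at ingestion so protein-style
# and gene-style symbols (Jun vs JUN) match case-insensitively.

MISSING_TOKENS <- c("", "NA", "NaN", "nan")

#' Construct an experiment design
#'
#' A triple-SILAC experiment is described by its label (e.g. \code{"PA+OA"})
#' and an ordered set of replicates, each run in \code{forward} orientation
#' (light channel = PA, heavy channel = combined treatment) or \code{reverse}
#' orientation (channels swapped). The medium channel always carries the
#' vehicle control.
#'
#' @param experiment_label single string naming the experiment.
#' @param replicate_id character vector of unique replicate identifiers.
#' @param orientation character vector, one of \code{"forward"} or
#'   \code{"reverse"} per replicate.
#' @return An object of class \code{ffa_design}: a list with
#'   \code{experiment_label} and a \code{replicates} data frame.
#' @examples
#' experiment_design("PA+OA", c("F1", "F2", "R1"),
#'                   c("forward", "forward", "reverse"))
#' @export
experiment_design <- function(experiment_label, replicate_id, orientation) {
  stopifnot(is.character(experiment_label), length(experiment_label) == 1L)
  replicate_id <- as.character(replicate_id)
  orientation <- as.character(orientation)
  if (length(replicate_id) < 1L)
    stop("design must declare at least one replicate")
  if (length(orientation) != length(replicate_id))
    stop("orientation must have one entry per replicate")
  if (anyDuplicated(replicate_id))
    stop("replicate_ids must be unique: ",
         paste(unique(replicate_id[duplicated(replicate_id)]), collapse = ", "))
  bad <- !orientation %in% c("forward", "reverse")
  if (any(bad))
    stop("orientation must be 'forward' or 'reverse', got: ",
         paste(unique(orientation[bad]), collapse = ", "))
  structure(
    list(experiment_label = experiment_label,
         replicates = data.frame(replicate_id = replicate_id,
                                 orientation = orientation,
                                 stringsAsFactors = FALSE)),
    class = "ffa_design")
}

#' @export
print.ffa_design <- function(x, ...) {
  cat("Triple-SILAC design:", x$experiment_label, "\n")
  cat(sprintf("  %s (%s)\n", x$replicates$replicate_id,
              x$replicates$orientation), sep = "")
  invisible(x)
}

#' Read / write an experiment design
#'
#' Designs are stored either as YAML (keys \code{experiment_label} and
#' \code{replicates}, the latter a list of \code{id}/\code{orientation} pairs)
#' or as TSV with columns \code{replicate_id}, \code{orientation}; the format
#' is chosen by file extension (\code{.yaml}/\code{.yml} vs anything else).
#'
#' @param path file path.
#' @param design an \code{ffa_design} object (for writing).
#' @return \code{read_design} returns an \code{ffa_design}.
#' @export
read_design <- function(path) {
  if (tolower(tools::file_ext(path)) %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    if (is.null(y$replicates)) stop("design YAML lacks a 'replicates' key")
    ids <- vapply(y$replicates, function(r) as.character(r$id), character(1))
    ori <- vapply(y$replicates, function(r) as.character(r$orientation),
                  character(1))
    experiment_design(y$experiment_label %||% "unnamed", ids, ori)
  } else {
    df <- read_tsv_checked(path, c("replicate_id", "orientation"))
    lab <- attr(df, "experiment_label") %||% "unnamed"
    experiment_design(lab, df$replicate_id, df$orientation)
  }
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "ffa_design"))
  if (tolower(tools::file_ext(path)) %in% c("yaml", "yml")) {
    reps <- lapply(seq_len(nrow(design$replicates)), function(i)
      list(id = design$replicates$replicate_id[i],
           orientation = design$replicates$orientation[i]))
    yaml::write_yaml(list(experiment_label = design$experiment_label,
                          replicates = reps), path)
  } else {
    utils::write.table(design$replicates, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every threshold the pipeline applies. Defaults are the values the
#' analysis is defined with: two-fold expression change, quantified in at
#' least 2 of 3 replicates, enrichment filters p < 0.01 / count >= 3 /
#' factor > 1.5, and TF-target filters binding scores > 0 within 1 kb of the
#' transcription start site.
#'
#' @param fold_change_threshold ratio threshold for up/down calls (> 1).
#' @param min_quantified minimum complete replicates per protein (>= 1).
#' @param enrich_p_max strict upper bound on the enrichment p-value.
#' @param enrich_min_count minimum observed overlap (inclusive).
#' @param enrich_min_factor strict lower bound on the enrichment factor.
#' @param tf_score_min exclusive lower bound on both TF binding scores.
#' @param tf_tss_max_kb inclusive upper bound on TSS distance, kilobases.
#' @param random_seed integer seed echoed into run reports.
#' @param background_mode enrichment background: the full annotation universe
#'   or only quantified proteins.
#' @return An object of class \code{ffa_config} (a validated list).
#' @export
pipeline_config <- function(fold_change_threshold = 2.0,
                            min_quantified = 2L,
                            enrich_p_max = 0.01,
                            enrich_min_count = 3L,
                            enrich_min_factor = 1.5,
                            tf_score_min = 0,
                            tf_tss_max_kb = 1.0,
                            random_seed = 1L,
                            background_mode = c("annotation_universe",
                                                "quantified_only")) {
  background_mode <- match.arg(background_mode)
  if (!is.numeric(fold_change_threshold) || fold_change_threshold <= 1)
    stop("fold_change_threshold must be > 1")
  if (min_quantified < 1) stop("min_quantified must be >= 1")
  if (enrich_p_max <= 0 || enrich_p_max > 1)
    stop("enrich_p_max must be in (0, 1]")
  if (tf_tss_max_kb < 0) stop("tf_tss_max_kb must be >= 0")
  structure(
    list(fold_change_threshold = as.numeric(fold_change_threshold),
         min_quantified = as.integer(min_quantified),
         enrich_p_max = as.numeric(enrich_p_max),
         enrich_min_count = as.integer(enrich_min_count),
         enrich_min_factor = as.numeric(enrich_min_factor),
         tf_score_min = as.numeric(tf_score_min),
         tf_tss_max_kb = as.numeric(tf_tss_max_kb),
         random_seed = as.integer(random_seed),
         background_mode = background_mode),
    class = "ffa_config")
}

#' @rdname pipeline_config
#' @param path YAML file holding any subset of the configuration keys;
#'   unstated keys keep their defaults.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

#' @rdname pipeline_config
#' @param config an \code{ffa_config} to serialize.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ffa_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Shared TSV reader: checks the header, keeps everything character for
# controlled coercion by the caller.
read_tsv_checked <- function(path, required_cols) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "",
                          fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  df
}

parse_ratio <- function(x, col, path) {
  out <- rep(NA_real_, length(x))
  present <- !(x %in% MISSING_TOKENS)
  vals <- suppressWarnings(as.numeric(x[present]))
  bad_num <- is.na(vals) | !is.finite(vals)
  if (any(bad_num))
    stop(sprintf("%s: column %s, row %d: not a number: '%s'", path, col,
                 which(present)[which(bad_num)[1]],
                 x[present][which(bad_num)[1]]))
  if (any(vals <= 0))
    stop(sprintf("%s: column %s, row %d: ratio must be > 0, got %s", path,
                 col, which(present)[which(vals <= 0)[1]],
                 vals[which(vals <= 0)[1]]))
  out[present] <- vals
  out
}

#' Read a protein quantification table
#'
#' Expects a TSV with header columns \code{protein_id}, \code{gene_symbol},
#' \code{replicate_id}, \code{ratio_hm} (heavy/medium) and \code{ratio_lm}
#' (light/medium), one row per protein per replicate. Missing-value tokens
#' (empty, \code{NA}, \code{NaN}) become missing ratios; present ratios must
#' be finite and strictly positive. Every \code{replicate_id} must be declared
#' in the design.
#'
#' @param path TSV file path.
#' @param design an \code{ffa_design}; rows referencing undeclared replicates
#'   are a design-mismatch error.
#' @return data frame with columns \code{protein_id}, \code{gene_symbol}
#'   (uppercased), \code{replicate_id}, \code{ratio_hm}, \code{ratio_lm}.
#' @export
read_quant_table <- function(path, design) {
  stopifnot(inherits(design, "ffa_design"))
  df <- read_tsv_checked(path, c("protein_id", "gene_symbol", "replicate_id",
                                 "ratio_hm", "ratio_lm"))
  unknown <- setdiff(unique(df$replicate_id), design$replicates$replicate_id)
  if (length(unknown))
    stop(sprintf("%s: replicate_id(s) not declared in design: %s", path,
                 paste(unknown, collapse = ", ")))
  dup <- duplicated(df[c("protein_id", "replicate_id")])
  if (any(dup))
    stop(sprintf("%s: row %d: duplicate (protein_id, replicate_id) = (%s, %s)",
                 path, which(dup)[1], df$protein_id[which(dup)[1]],
                 df$replicate_id[which(dup)[1]]))
  data.frame(protein_id = df$protein_id,
             gene_symbol = toupper(df$gene_symbol),
             replicate_id = df$replicate_id,
             ratio_hm = parse_ratio(df$ratio_hm, "ratio_hm", path),
             ratio_lm = parse_ratio(df$ratio_lm, "ratio_lm", path),
             stringsAsFactors = FALSE)
}

#' @rdname read_quant_table
#' @param quant data frame as returned by \code{read_quant_table}.
#' @export
write_quant_table <- function(quant, path) {
  out <- quant
  out$ratio_hm <- ifelse(is.na(out$ratio_hm), "NA",
                         format(out$ratio_hm, digits = 15, scientific = FALSE,
                                trim = TRUE))
  out$ratio_lm <- ifelse(is.na(out$ratio_lm), "NA",
                         format(out$ratio_lm, digits = 15, scientific = FALSE,
                                trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one gene set per line, fields
#' \code{name TAB description TAB gene1 TAB gene2 ...}. Duplicate genes within
#' a line are deduplicated; symbols are uppercased.
#'
#' @param path GMT file path.
#' @return named list of gene sets; each element is a character vector of
#'   genes with a \code{description} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("%s: line %d: GMT line needs name, description and >= 1 gene",
                   path, i))
    genes <- unique(toupper(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("%s: line %d: gene set '%s' is empty", path, i, fields[1]))
    sets[[fields[1]]] <- structure(genes, description = fields[2])
  }
  sets
}

#' @rdname read_gmt
#' @param gene_sets named list as returned by \code{read_gmt}.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, attr(gene_sets[[nm]], "description") %||% "", gene_sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a transcription-factor target table
#'
#' TSV with header \code{gene_symbol}, \code{score_macs2}, \code{score_string},
#' \code{tss_distance_kb}, as exported from ChIP-seq target predictions (two
#' binding scores and the distance of the binding site from the transcription
#' start site). No filtering happens at read time; see
#' \code{\link{filter_tf_targets}}.
#'
#' @param path TSV file path.
#' @return data frame with uppercased gene symbols and numeric scores.
#' @export
read_tf_targets <- function(path) {
  df <- read_tsv_checked(path, c("gene_symbol", "score_macs2", "score_string",
                                 "tss_distance_kb"))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) | !is.finite(v)
    if (any(bad))
      stop(sprintf("%s: column %s, row %d: not a finite number: '%s'", path,
                   col, which(bad)[1], df[[col]][which(bad)[1]]))
    v
  }
  tss <- num("tss_distance_kb")
  if (any(tss < 0))
    stop(sprintf("%s: row %d: tss_distance_kb must be >= 0, got %s", path,
                 which(tss < 0)[1], tss[which(tss < 0)[1]]))
  data.frame(gene_symbol = toupper(df$gene_symbol),
             score_macs2 = num("score_macs2"),
             score_string = num("score_string"),
             tss_distance_kb = tss,
             stringsAsFactors = FALSE)
}

#' @rdname read_tf_targets
#' @param targets data frame as returned by \code{read_tf_targets}.
#' @export
write_tf_targets <- function(targets, path) {
  utils::write.table(targets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
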