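# Gene-set over-representation analysis.
#
# The statistic is the exact hypergeometric upper tail: drawing query_size
# genes from a background of background_size containing set_size members of
# the set, the p-value is P(X >= observed). A term passes when p < 0.01 AND
# observed >= 3 AND enrichment factor > 1.5 (strict/strict/non-strict exactly
# as those filters are conventionally printed). Enrichment factor = observed /
# expected, expected = query_size * set_size / background_size.

#' Exact hypergeometric upper-tail probability
#'
#' P(X >= observed) for X ~ Hypergeometric(N = background_size,
#' K = set_size, n = query_size), computed by exact summation of the
#' probability mass over the upper tail.
#'
#' @param observed observed overlap count.
#' @param query_size number of genes in the query.
#' @param set_size number of set members in the background.
#' @param background_size background universe size.
#' @return upper-tail probability in [0, 1].
#' @examples
#' hypergeom_upper_tail(3, 5, 5, 20)  # 1126/15504
#' @export
hypergeom_upper_tail <- function(observed, query_size, set_size,
                                 background_size) {
  if (observed < 0 || query_size < 0 || set_size < 0 || background_size < 0)
    stop("all sizes must be non-negative")
  if (set_size > background_size || query_size > background_size)
    stop("set_size and query_size cannot exceed background_size")
  if (observed > min(query_size, set_size))
    stop("observed cannot exceed min(query_size, set_size)")
  if (observed == 0) return(1)
  k <- observed:min(query_size, set_size)
  sum(stats::dhyper(k, m = set_size, n = background_size - set_size,
                    k = query_size))
}

#' Over-representation analysis of a query gene set
#'
#' Each gene set is intersected with the background before counting; sets
#' with empty background intersection are dropped. The three filters come
#' from \code{config}: \code{p < enrich_p_max} (strict),
#' \code{observed >= enrich_min_count}, \code{factor > enrich_min_factor}
#' (strict).
#'
#' @param query character vector of query genes (must lie in the background).
#' @param gene_sets named list of gene sets (see \code{\link{read_gmt}}).
#' @param background character vector: the gene universe.
#' @param config an \code{ffa_config}.
#' @return data frame sorted by p-value with columns \code{set_name},
#'   \code{observed_count}, \code{query_size}, \code{set_size_in_background},
#'   \code{background_size}, \code{expected_count}, \code{enrichment_factor},
#'   \code{p_value}, \code{passes_filters}, plus a list column \code{overlap}
#'   holding the member genes (used by \code{\link{cluster_terms}}).
#' @export
enrich <- function(query, gene_sets, background, config = pipeline_config()) {
  stopifnot(inherits(config, "ffa_config"))
  background <- unique(toupper(background))
  if (!length(background)) stop("empty background")
  query <- unique(toupper(query))
  stray <- setdiff(query, background)
  if (length(stray))
    stop("query genes outside the background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(toupper(gene_sets[[nm]])), background)
    K <- length(members)
    if (K == 0L) return(NULL)
    overlap <- intersect(query, members)
    k <- length(overlap)
    expected <- n * K / N
    factor <- if (expected > 0) k / expected else NA_real_
    p <- hypergeom_upper_tail(k, n, K, N)
    data.frame(set_name = nm, observed_count = k, query_size = n,
               set_size_in_background = K, background_size = N,
               expected_count = expected, enrichment_factor = factor,
               p_value = p,
               passes_filters = (p < config$enrich_p_max) &&
                 (k >= config$enrich_min_count) &&
                 (factor > config$enrich_min_factor),
               overlap = I(list(overlap)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_name = character(), observed_count = integer(),
                      query_size = integer(),
                      set_size_in_background = integer(),
                      background_size = integer(), expected_count = numeric(),
                      enrichment_factor = numeric(), p_value = numeric(),
                      passes_filters = logical(), overlap = I(list())))
  out <- out[order(out$p_value, -out$enrichment_factor, out$set_name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-linkage clustering of enriched terms by membership similarity
#'
#' Terms are linked when the Jaccard similarity of their member (overlap)
#' genes reaches \code{similarity_threshold}; connected components under that
#' relation form clusters (an approximation of kappa-statistic term
#' clustering). Each cluster is labeled by its lowest-p member term.
#'
#' @param results enrichment data frame from \code{\link{enrich}} (needs the
#'   \code{overlap} list column).
#' @param similarity_threshold Jaccard threshold in [0, 1], default 0.5.
#' @return \code{results} with added \code{cluster} (integer id) and
#'   \code{cluster_label} columns; cluster ids are ordered by their
#'   representative's p-value.
#' @export
cluster_terms <- function(results, similarity_threshold = 0.5) {
  m <- nrow(results)
  if (m == 0L) {
    results$cluster <- integer(0)
    results$cluster_label <- character(0)
    return(results)
  }
  sets <- lapply(results$overlap, unique)
  # union-find over term pairs with Jaccard >= threshold
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (m > 1L) for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
    u <- length(union(sets[[i]], sets[[j]]))
    jac <- if (u == 0L) 0 else length(intersect(sets[[i]], sets[[j]])) / u
    if (jac >= similarity_threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  # label clusters by lowest-p member; order cluster ids the same way
  # (results are already sorted by p, so first occurrence is representative)
  ids <- match(roots, unique(roots))
  reps <- vapply(unique(roots), function(r) which(roots == r)[1], integer(1))
  results$cluster <- ids
  results$cluster_label <- results$set_name[reps][ids]
  results
}

#' Write the enrichment TSV
#'
#' @param results enrichment data frame.
#' @param path output path.
#' @export
write_enrichment <- function(results, path) {
  out <- results[setdiff(names(results), "overlap")]
  out$genes <- vapply(results$overlap, paste, character(1), collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
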