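test_that("hypergeometric upper tail matches exact enumeration", {
  expect_equal(hypergeom_upper_tail(0, 5, 5, 20), 1)
  # frozen worked example: C(5,3)C(15,2)+C(5,4)C(15,1)+C(5,5) over C(20,5)
  expect_equal(hypergeom_upper_tail(3, 5, 5, 20), 1126 / 15504,
               tolerance = 1e-12)
  # query = background: overlap is certain
  expect_equal(hypergeom_upper_tail(4, 10, 4, 10), 1)
  expect_error(hypergeom_upper_tail(6, 5, 5, 20), "observed")
  expect_error(hypergeom_upper_tail(3, 5, 25, 20), "exceed")
  set.seed(13)
  for (i in 1:50) {
    N <- sample(5:50, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper_tail(k, n, K, N),
                 hyper_tail_enum(k, n, K, N), tolerance = 1e-10)
  }
})

test_that("p is monotone non-increasing in observed for fixed margins", {
  for (margins in list(c(30, 10, 8), c(50, 25, 12), c(12, 6, 6))) {
    N <- margins[1]; n <- margins[2]; K <- margins[3]
    p <- vapply(0:min(n, K), hypergeom_upper_tail, numeric(1),
                query_size = n, set_size = K, background_size = N)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("enrich applies the three printed filters exactly", {
  background <- sprintf("G%02d", 1:20)
  sets <- list(TOY = background[1:5])
  query <- c(background[1:3], background[10:11])  # overlap 3 of query 5
  res <- enrich(query, sets, background)
  expect_equal(res$observed_count, 3L)
  expect_equal(res$expected_count, 1.25)
  expect_equal(res$enrichment_factor, 2.4)
  expect_equal(res$p_value, 1126 / 15504, tolerance = 1e-12)
  expect_false(res$passes_filters)  # p = 0.073 fails the p < 0.01 filter

  # query = background: factor 1 everywhere, nothing passes
  full <- enrich(background, sets, background)
  expect_equal(full$enrichment_factor, 1)
  expect_false(any(full$passes_filters))

  # tiny overlap with tiny p still fails on minimum count
  bg2 <- sprintf("H%03d", 1:400)
  sets2 <- list(SMALL = bg2[1:2])
  res2 <- enrich(bg2[1:2], sets2, bg2)
  expect_lt(res2$p_value, 0.01)
  expect_equal(res2$observed_count, 2L)
  expect_false(res2$passes_filters)

  expect_error(enrich("X", list(S = "X"), character(0)), "background")
  expect_error(enrich("ZZZ", sets, background), "outside the background")
})

test_that("exact tail agrees with a Monte-Carlo resampling oracle", {
  set.seed(29)
  B <- 4000
  for (i in 1:5) {
    N <- sample(20:50, 1); K <- sample(3:(N - 2), 1)
    n <- sample(3:(N - 2), 1); k <- sample(0:min(K, n), 1)
    draws <- replicate(B, sum(sample(N, n) <= K))  # first K items = the set
    mc <- mean(draws >= k)
    p <- hypergeom_upper_tail(k, n, K, N)
    se <- sqrt(max(p * (1 - p), 1 / B) / B)
    expect_lt(abs(mc - p), 3 * se + 1e-9)
  }
})

test_that("term clustering is single-linkage over Jaccard similarity", {
  mk <- function(names, overlaps, ps) {
    data.frame(set_name = names, p_value = ps,
               observed_count = lengths(overlaps),
               enrichment_factor = 2, passes_filters = TRUE,
               overlap = I(overlaps), stringsAsFactors = FALSE)
  }
  # identical memberships collapse; disjoint stay apart
  res <- mk(c("A", "B", "C"),
            list(c("X", "Y"), c("X", "Y"), c("Q", "R")),
            c(0.001, 0.002, 0.003))
  cl <- cluster_terms(res)
  expect_equal(cl$cluster, c(1L, 1L, 2L))
  expect_equal(cl$cluster_label, c("A", "A", "C"))

  # chain closure: A~B and B~C at Jaccard 0.6, A~C only 1/3; single linkage
  # at threshold 0.5 still joins all three
  g <- sprintf("g%02d", 1:12)
  chain <- mk(c("A", "B", "C"),
              list(g[1:8], g[3:10], g[5:12]),
              c(1e-4, 1e-3, 1e-2))
  ja <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  expect_equal(ja(chain$overlap[[1]], chain$overlap[[2]]), 0.6)
  expect_equal(ja(chain$overlap[[2]], chain$overlap[[3]]), 0.6)
  expect_equal(ja(chain$overlap[[1]], chain$overlap[[3]]), 1 / 3)
  cl2 <- cluster_terms(chain, similarity_threshold = 0.5)
  expect_equal(cl2$cluster, c(1L, 1L, 1L))
  expect_equal(unique(cl2$cluster_label), "A")  # lowest-p representative
})

test_that("a planted enriched set passes filters and ranks first by p", {
  spec <- simulation_spec(n_proteins = 2000, seed = 47)
  sim <- simulate_dataset(spec)
  ann <- simulate_annotations(sim$truth, seed = 48,
                              planted_set = list(name = "PLANTED_MITO",
                                                 target_pattern = "P6",
                                                 enrichment_odds = 8,
                                                 size = 50))
  background <- unique(c(toupper(unlist(ann$gene_sets, use.names = FALSE)),
                         sim$truth$gene_symbol))
  query <- sim$truth$gene_symbol[sim$truth$true_pattern == "P6"]
  res <- enrich(query, ann$gene_sets, background)
  expect_equal(res$set_name[1], "PLANTED_MITO")
  expect_true(res$passes_filters[1])
})
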