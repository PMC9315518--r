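ranked4 <- rank_edges(c(e1 = 4, e2 = 3, e3 = 2, e4 = 1))

test_that("rank_edges orders by score then canonical id and validates", {
  r <- rank_edges(c(e1 = 4, e3 = 3, e2 = 2))
  expect_equal(r$edge, c("e1", "e3", "e2"))
  tie <- rank_edges(c(`A|C` = 1, `A|B` = 1))
  expect_equal(tie$edge, c("A|B", "A|C"))
  all_eq <- rank_edges(c(b = 0, a = 0, c = 0))
  expect_equal(all_eq$edge, c("a", "b", "c"))
  expect_error(rank_edges(numeric()), "empty")
  expect_error(rank_edges(c(a = Inf)), "finite")
})

test_that("enrichment score reproduces hand-enumerated cases", {
  one_top <- enrichment_score(ranked4, "e1")
  expect_equal(one_top$es, 1.0)
  expect_equal(one_top$peak, 1L)

  one_bottom <- enrichment_score(ranked4, "e4")
  expect_equal(one_bottom$es, -1.0)
  expect_equal(one_bottom$peak, 3L)

  split <- enrichment_score(ranked4, c("e1", "e4"))
  expect_equal(split$es, 0.8)
  expect_equal(split$peak, 1L)
  expect_equal(split$running, c(4 / 5, 3 / 10, -1 / 5, 0))

  expect_error(enrichment_score(ranked4, "nope"), "intersect")
  expect_error(enrichment_score(ranked4, c("e1", "e2", "e3", "e4")), "whole")
})

test_that("enrichment score equals exhaustive enumeration on all subsets", {
  set.seed(81)
  for (N in c(4, 6, 8)) {
    scores <- sort(rnorm(N), decreasing = TRUE)
    ids <- sprintf("e%02d", seq_len(N))
    ranked <- rank_edges(setNames(scores, ids))
    for (mask in seq_len(2^N - 2)) {
      hits <- as.logical(bitwAnd(mask, 2^(seq_len(N) - 1)))
      for (p in c(0, 1, 2)) {
        oracle <- es_oracle(ranked$score, hits, p)
        got <- enrichment_score(ranked, ids[hits], p)
        expect_equal(abs(got$es), abs(oracle$es), tolerance = 1e-12)
        # the sign is well-defined whenever the extreme deviation is unique
        r <- abs(oracle$running)
        if (sum(abs(r - max(r)) < 1e-9) == 1L) {
          expect_equal(got$es, oracle$es, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("top/bottom prefix sets reach ES of exactly +1 / -1", {
  set.seed(82)
  scores <- sort(rnorm(30), decreasing = TRUE)
  ids <- sprintf("e%02d", 1:30)
  ranked <- rank_edges(setNames(scores, ids))
  for (p in c(0, 1, 2)) {
    for (m in c(1, 5, 10)) {
      expect_equal(enrichment_score(ranked, ids[1:m], p)$es, 1)
      expect_equal(enrichment_score(ranked, ids[(30 - m + 1):30], p)$es, -1)
    }
  }
})

test_that("exponent zero reduces to the classical KS statistic", {
  set.seed(83)
  for (i in 1:20) {
    N <- sample(10:40, 1)
    ranked <- rank_edges(setNames(rnorm(N), sprintf("e%03d", seq_len(N))))
    hits <- ranked$edge %in% sample(ranked$edge, sample(2:(N - 2), 1))
    # ties in |deviation| make the sign convention-dependent; the magnitude
    # is the KS statistic
    expect_equal(abs(enrichment_score(ranked, ranked$edge[hits], 0)$es),
                 abs(ks_oracle(hits)), tolerance = 1e-12)
  }
})

test_that("reversing the ranked list negates the unweighted ES", {
  set.seed(84)
  for (i in 1:10) {
    N <- 20
    scores <- rnorm(N)
    ids <- sprintf("e%02d", seq_len(N))
    ranked <- rank_edges(setNames(scores, ids))
    set <- sample(ids, 6)
    fwd <- enrichment_score(ranked, set, 0)$es
    rev_ranked <- ranked[rev(seq_len(N)), ]
    oracle <- es_oracle(rev_ranked$score, rev_ranked$edge %in% set, 0)
    # the reversed running sum is the forward one mirrored and negated, so
    # the extreme deviation flips sign (compare magnitudes; exact ties in
    # |deviation| leave the reported sign convention-dependent)
    expect_equal(abs(oracle$es), abs(fwd), tolerance = 1e-12)
  }
})

test_that("fast null ES computation agrees with the full running sum", {
  set.seed(85)
  N <- 60
  ranked <- rank_edges(setNames(rnorm(N), sprintf("e%03d", seq_len(N))))
  w <- abs(ranked$score)^1
  for (i in 1:50) {
    m <- sample(3:20, 1)
    pos <- sort(sample.int(N, m))
    hits <- seq_len(N) %in% pos
    expect_equal(subpathx:::.es_from_positions(pos, w, N),
                 es_oracle(ranked$score, hits, 1)$es,
                 tolerance = 1e-12)
  }
})

test_that("permutation p-values are deterministic, bounded, and sharp for a top prefix", {
  set.seed(86)
  N <- 1000
  ranked <- rank_edges(setNames(rnorm(N), sprintf("e%04d", seq_len(N))))
  top10 <- ranked$edge[1:10]
  r1 <- permutation_pvalue(ranked, top10, n_perm = 999, seed = 11)
  r2 <- permutation_pvalue(ranked, top10, n_perm = 999, seed = 11)
  expect_identical(r1$p, r2$p)
  expect_equal(r1$p, 1 / 1000)  # no random 10-set matches a perfect prefix
  some <- permutation_pvalue(ranked, sample(ranked$edge, 15), n_perm = 199,
                             seed = 12)
  expect_gte(some$p, 1 / 200)
  expect_lte(some$p, 1)
  expect_error(permutation_pvalue(ranked, top10, n_perm = 10), ">= 100")
})

test_that("BH adjustment matches the hand-coded step-up and is order invariant", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(1, 1)), c(1, 1))
  set.seed(87)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))^2
    expect_equal(fdr_adjust(p), bh_oracle(p))
    perm <- sample(seq_along(p))
    expect_equal(fdr_adjust(p[perm]), fdr_adjust(p)[perm])
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("leading edge extracts members at the correct side of the peak", {
  expect_equal(leading_edge(ranked4, c("e1", "e2"), es = 1, peak = 2),
               c("e1", "e2"))
  expect_equal(leading_edge(ranked4, "e4", es = -1, peak = 3), "e4")
  split <- enrichment_score(ranked4, c("e1", "e4"))
  expect_equal(leading_edge(ranked4, c("e1", "e4"), split$es, split$peak),
               "e1")
})

test_that("sample_gsea assembles per-sample tables with within-sample FDR", {
  set.seed(88)
  genes <- sprintf("G%02d", 1:12)
  edges <- make_edges(list(
    P1 = edge_id(genes[1:6], genes[c(2:6, 1)]),
    P2 = edge_id(genes[7:12], genes[c(8:12, 7)])
  ))
  scores <- tibble::tibble(edge = sort(unique(edges$edge)))
  scores$S1 <- rnorm(nrow(scores))
  scores$S2 <- rnorm(nrow(scores))
  enr <- sample_gsea(scores, edges, n_perm = 199, min_set_size = 3, seed = 4)
  expect_setequal(enr$sample, c("S1", "S2"))
  expect_setequal(enr$pathway, c("P1", "P2"))
  for (s in c("S1", "S2")) {
    sub <- enr[enr$sample == s, ]
    expect_equal(sub$q, fdr_adjust(sub$p))
  }
  expect_true(all(enr$direction %in% c("up", "down")))
  expect_true(all((enr$es >= 0) == (enr$direction == "up")))
  # determinism under seed
  enr2 <- sample_gsea(scores, edges, n_perm = 199, min_set_size = 3, seed = 4)
  expect_equal(dplyr::select(enr, -"core_edges"),
               dplyr::select(enr2, -"core_edges"))

  skipped <- suppressMessages(
    sample_gsea(scores, edges, n_perm = 199, min_set_size = 10)
  )
  expect_equal(nrow(skipped), 0L)
})

test_that("subpathway extraction respects alpha, min_edges, and pathway identity", {
  enr <- tibble::tibble(
    sample = "S1", pathway = c("P1", "P2", "P3"), size = 5L,
    es = c(0.9, -0.8, 0.7), peak = c(2L, 8L, 3L),
    p = c(0.001, 0.002, 0.2), q = c(0.003, 0.003, 0.2),
    direction = c("up", "down", "up"), n_core = c(2L, 1L, 3L),
    core_edges = list(c("A|B", "A|C"), "A|B", c("D|E", "E|F", "F|G"))
  )
  sub <- extract_subpathways(enr, alpha = 0.05, min_edges = 1)
  # the shared edge appears once per significant pathway, never merged
  expect_equal(sub$pathway[sub$edge == "A|B"], c("P1", "P2"))
  expect_false("P3" %in% sub$pathway)
  expect_equal(sub$gene_a[sub$edge == "A|C"], "A")

  sub2 <- extract_subpathways(enr, alpha = 0.05, min_edges = 2)
  expect_false("P2" %in% sub2$pathway)

  none <- extract_subpathways(enr, alpha = 0.0001)
  expect_equal(nrow(none), 0L)
  expect_named(none, c("sample", "pathway", "edge", "gene_a", "gene_b",
                       "direction", "es", "q"))
})
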