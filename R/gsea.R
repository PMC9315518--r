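#' Rank a sample's edges by perturbation score
#'
#' Produces the descending ranked edge list used by the enrichment statistic.
#' Ties are broken deterministically by canonical edge id (ascending), so
#' ranking is a stable permutation of the edge universe.
#'
#' @param scores A named numeric vector (names = edge ids), or a two-column
#'   data frame / tibble with columns `edge` and `score`.
#' @return A tibble with columns `edge`, `score`, ordered by decreasing
#'   score then edge id.
#' @export
rank_edges <- function(scores) {
  if (is.data.frame(scores)) {
    tbl <- tibble(edge = as.character(scores$edge), score = as.numeric(scores$score))
  } else {
    if (length(scores) == 0L) abort("empty score vector")
    if (is.null(names(scores))) abort("scores must be named by edge id")
    tbl <- tibble(edge = names(scores), score = as.numeric(scores))
  }
  if (nrow(tbl) == 0L) abort("empty score vector")
  if (any(!is.finite(tbl$score))) abort("scores must be finite")
  if (anyDuplicated(tbl$edge)) abort("duplicate edge ids in score vector")
  arrange(tbl, desc(.data$score), .data$edge)
}

#' Weighted Kolmogorov-Smirnov enrichment score over a ranked edge list
#'
#' Walks the ranked list; at an edge belonging to `edge_set` the running sum
#' rises by that edge's weight `|score|^exponent` (normalized over the set),
#' at any other edge it falls by `1/(N - m)` where `m` is the effective set
#' size. The enrichment score (ES) is the running-sum value of maximum
#' absolute deviation; its sign says whether set members concentrate at the
#' top (positive) or bottom (negative) of the list. `exponent = 0` recovers
#' the classical unweighted KS statistic.
#'
#' @param ranked Ranked tibble from [rank_edges()].
#' @param edge_set Character vector of edge ids forming the set.
#' @param exponent Weighting exponent `p >= 0` (default 1).
#' @return A list: `es`, `peak` (1-based position of the extreme deviation;
#'   first such position on ties), `running` (the full running sum),
#'   `hits` (logical membership along the list), `size` (effective set size).
#' @export
enrichment_score <- function(ranked, edge_set, exponent = 1) {
  if (exponent < 0) abort("exponent must be >= 0")
  hits <- ranked$edge %in% edge_set
  m <- sum(hits)
  N <- nrow(ranked)
  if (m == 0L) abort("edge set does not intersect the ranked universe")
  if (m == N) abort("edge set covers the whole ranked universe")
  w <- abs(ranked$score)^exponent
  wsum <- sum(w[hits])
  step_hit <- if (wsum > 0) w / wsum else rep(1 / m, N)
  steps <- ifelse(hits, step_hit, -1 / (N - m))
  running <- cumsum(steps)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak, running = running,
       hits = hits, size = m)
}

# Fast signed ES from sorted hit positions (same statistic as
# enrichment_score, without materializing the full running sum).
# pos: sorted hit positions; w_all: |score|^p along the ranked list.
.es_from_positions <- function(pos, w_all, N) {
  m <- length(pos)
  w <- w_all[pos]
  tot <- sum(w)
  cw <- if (tot > 0) cumsum(w) / tot else seq_len(m) / m
  j <- seq_len(m)
  miss <- 1 / (N - m)
  at_hit <- cw - (pos - j) * miss          # running sum at each hit
  before <- c(0, cw[-m]) - (pos - j) * miss # value just before each hit
  cand <- c(at_hit, before)
  cand[which.max(abs(cand))]
}

#' Permutation p-value for one enrichment score
#'
#' Single-sample enrichment cannot permute phenotypes, so the null is
#' same-size random edge sets drawn (without replacement) from the ranked
#' universe. The p-value is two-sided on `|ES|` with the add-one estimator
#' `p = (1 + #\{|ES_null| >= |ES_obs|\}) / (n_perm + 1)`; enrichment
#' direction is reported separately by [sample_gsea()].
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of random sets (>= 100).
#' @param seed Optional integer; when given, the null draw is reproducible
#'   and the caller's RNG state is untouched.
#' @param null_es Optional precomputed null ES vector (see
#'   [null_enrichment_scores()]); overrides `n_perm`/`seed`.
#' @return A list: `p`, `es`, `peak`, `size`, `null_es`.
#' @export
permutation_pvalue <- function(ranked, edge_set, exponent = 1, n_perm = 1000,
                               seed = NULL, null_es = NULL) {
  obs <- enrichment_score(ranked, edge_set, exponent)
  if (is.null(null_es)) {
    if (n_perm < 100L) abort("n_perm must be >= 100")
    null_es <- null_enrichment_scores(ranked, obs$size, exponent, n_perm, seed)
  }
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (length(null_es) + 1)
  list(p = p, es = obs$es, peak = obs$peak, size = obs$size, null_es = null_es)
}

#' Null enrichment scores for random same-size edge sets
#'
#' Draws `n_perm` random sets of `size` positions from the ranked universe
#' and returns their enrichment scores. Because the null depends on the
#' ranked scores only through the weights and on the set only through its
#' size, one null vector serves every pathway of the same effective size
#' within a sample.
#'
#' @inheritParams permutation_pvalue
#' @param size Effective set size to draw.
#' @return Numeric vector of length `n_perm`.
#' @export
null_enrichment_scores <- function(ranked, size, exponent = 1, n_perm = 1000,
                                   seed = NULL) {
  N <- nrow(ranked)
  if (size <= 0L || size >= N) abort("size must be in [1, N - 1]")
  w_all <- abs(ranked$score)^exponent
  draw <- function() {
    vapply(seq_len(n_perm), function(i) {
      pos <- sort.int(sample.int(N, size))
      .es_from_positions(pos, w_all, N)
    }, numeric(1))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Benjamini-Hochberg FDR within one sample
#'
#' Step-up adjustment of the nominal enrichment p-values across all pathways
#' tested in a single sample (the grain at which subpathways are selected).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Leading-edge (core-enrichment) edges
#'
#' The set members that drive the enrichment score: for positive ES, members
#' at or before the running-sum peak; for negative ES, members at or after
#' it. These are the edges reported as a sample's core enrichment and
#' assembled into its subpathway.
#'
#' @inheritParams enrichment_score
#' @param es,peak Enrichment score and peak position from
#'   [enrichment_score()] on the same inputs.
#' @return Character vector of core edge ids, in ranked order.
#' @export
leading_edge <- function(ranked, edge_set, es, peak) {
  hits <- ranked$edge %in% edge_set
  idx <- which(hits)
  core <- if (es >= 0) idx[idx <= peak] else idx[idx >= peak]
  ranked$edge[core]
}

#' Per-sample edge-set enrichment across all pathways
#'
#' For each tumor sample: rank the edge universe by perturbation score, test
#' every pathway's edge set with the weighted KS statistic, compute
#' permutation p-values (null sets shared across pathways of equal effective
#' size within the sample), adjust by Benjamini-Hochberg within the sample,
#' and extract leading-edge core edges. Pathways whose effective set (edges
#' present in the scored universe) is smaller than `min_set_size` are
#' skipped.
#'
#' @param score_matrix Edge-score tibble from [edge_score_matrix()] (column
#'   `edge` + one column per sample).
#' @param pathway_edges Pathway edge tibble.
#' @param exponent Weighting exponent (default 1).
#' @param n_perm Permutations per null distribution (default 1000).
#' @param min_set_size Minimum effective pathway size (default 5).
#' @param seed Optional integer seed making the whole run reproducible.
#' @return A tibble with one row per (sample, pathway): `sample`, `pathway`,
#'   `size`, `es`, `peak`, `p`, `q`, `direction` (`"up"`/`"down"`),
#'   `n_core`, and list-column `core_edges`.
#' @export
sample_gsea <- function(score_matrix, pathway_edges, exponent = 1,
                        n_perm = 1000, min_set_size = 5, seed = NULL) {
  samples <- setdiff(names(score_matrix), "edge")
  if (length(samples) == 0L) abort("score matrix has no sample columns")
  sets <- split(pathway_edges$edge, pathway_edges$pathway)
  run <- function() {
    purrr::map(samples, function(s) {
      ranked <- rank_edges(setNames(score_matrix[[s]], score_matrix$edge))
      eff <- purrr::map(sets, ~ intersect(.x, ranked$edge))
      sizes <- lengths(eff)
      keep <- sizes >= min_set_size & sizes < nrow(ranked)
      if (any(!keep)) {
        inform(sprintf("sample %s: skipped %d pathway(s) below min_set_size or spanning the universe",
                       s, sum(!keep)))
      }
      if (!any(keep)) return(NULL)
      null_cache <- lapply(
        setNames(nm = unique(sizes[keep])),
        function(m) null_enrichment_scores(ranked, as.integer(m), exponent, n_perm)
      )
      rows <- purrr::map(names(sets)[keep], function(pw) {
        obs <- enrichment_score(ranked, eff[[pw]], exponent)
        nulls <- null_cache[[as.character(obs$size)]]
        p <- (1 + sum(abs(nulls) >= abs(obs$es))) / (n_perm + 1)
        core <- leading_edge(ranked, eff[[pw]], obs$es, obs$peak)
        tibble(sample = s, pathway = pw, size = obs$size, es = obs$es,
               peak = obs$peak, p = p,
               direction = if (obs$es >= 0) "up" else "down",
               n_core = length(core), core_edges = list(core))
      })
      bind_rows(rows) |> mutate(q = fdr_adjust(.data$p), .after = "p")
    }) |> bind_rows()
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (nrow(out) == 0L) return(out)
  arrange(out, .data$sample, .data$pathway)
}

#' Assemble per-sample subpathways from enrichment results
#'
#' Selects, within each sample, the pathways with FDR `q < alpha` and at
#' least `min_edges` core edges, and expands their core-enrichment edges into
#' a long edge table: the sample's subpathway in each significant pathway.
#' A shared edge significant in two pathways appears once per pathway;
#' subpathways are never merged across pathways.
#'
#' @param enrichment Result of [sample_gsea()].
#' @param alpha FDR threshold (default 0.05).
#' @param min_edges Minimum core-edge count for a reported subpathway
#'   (default 1).
#' @return A tibble with columns `sample`, `pathway`, `edge`, `gene_a`,
#'   `gene_b`, `direction`, `es`, `q`. Empty (zero rows) when nothing is
#'   significant.
#' @export
extract_subpathways <- function(enrichment, alpha = 0.05, min_edges = 1) {
  empty <- tibble(sample = character(), pathway = character(),
                  edge = character(), gene_a = character(),
                  gene_b = character(), direction = character(),
                  es = numeric(), q = numeric())
  if (nrow(enrichment) == 0L) return(empty)
  sig <- enrichment |> filter(.data$q < alpha, .data$n_core >= min_edges)
  if (nrow(sig) == 0L) return(empty)
  sig |>
    select("sample", "pathway", "direction", "es", "q", "core_edges") |>
    tidyr::unnest_longer(col = "core_edges", values_to = "edge") |>
    mutate(edge_genes(.data$edge)[c("gene_a", "gene_b")]) |>
    select("sample", "pathway", "edge", "gene_a", "gene_b",
           "direction", "es", "q") |>
    arrange(.data$sample, .data$pathway, .data$edge)
}
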