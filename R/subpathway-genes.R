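#' Gene degrees within each sample's subpathway union
#'
#' Degrees are computed on the union of all of a sample's subpathway edges:
#' each distinct gene pair counts once even when it belongs to several
#' significant pathways. High-degree genes are the candidate drivers of the
#' sample's perturbation.
#'
#' @param subpathways Long subpathway edge tibble from
#'   [extract_subpathways()].
#' @return A tibble `sample`, `gene`, `degree`, ordered within sample by
#'   decreasing degree then gene symbol. Samples without subpathway edges are
#'   absent (a warning is raised if the input is empty).
#' @export
node_degrees <- function(subpathways) {
  if (nrow(subpathways) == 0L) {
    warn("no subpathway edges; empty degree profile")
    return(tibble(sample = character(), gene = character(), degree = integer()))
  }
  subpathways |>
    distinct(.data$sample, .data$edge, .data$gene_a, .data$gene_b) |>
    tidyr::pivot_longer(c("gene_a", "gene_b"), values_to = "gene") |>
    count(.data$sample, .data$gene, name = "degree") |>
    arrange(.data$sample, desc(.data$degree), .data$gene)
}

#' Top-k highest-degree genes per sample
#'
#' @param degrees Degree tibble from [node_degrees()].
#' @param k Number of genes to keep per sample (ties broken by gene symbol
#'   ascending; all genes returned when fewer than `k` exist).
#' @return A tibble `sample`, `gene`, `degree`, `rank` (1..<=k per sample).
#' @export
top_k_genes <- function(degrees, k) {
  if (k < 1L) abort("k must be >= 1")
  degrees |>
    group_by(.data$sample) |>
    arrange(desc(.data$degree), .data$gene, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    filter(.data$rank <= k) |>
    ungroup()
}

#' Overlap of high-degree subpathway genes with a gene set
#'
#' For each sample and each `k`, the fraction of the sample's top-k
#' highest-degree genes that belong to a target set. The target is the
#' sample's own somatic-mutation gene set when `mutations` is supplied, or a
#' fixed list (`gene_list`, e.g. immune-related genes) otherwise. An optional
#' `conditioning` list restricts the numerator further (e.g. genes that are
#' both mutated and known drivers). The denominator is the number of top
#' genes actually available (= `min(k, genes in profile)`).
#'
#' @param degrees Degree tibble from [node_degrees()].
#' @param k Integer vector of list sizes (default `c(5, 10, 20, 30)`).
#' @param mutations Optional mutation tibble (`sample`, `gene`).
#' @param gene_list Optional character vector of target genes.
#' @param conditioning Optional character vector intersected with the target.
#' @return A tibble `k`, `sample`, `n_top`, `n_hit`, `rate`, plus the cohort
#'   `mean_rate` per `k` merged on (constant within `k`).
#' @export
overlap_rate <- function(degrees, k = c(5, 10, 20, 30), mutations = NULL,
                         gene_list = NULL, conditioning = NULL) {
  if (is.null(mutations) && is.null(gene_list)) {
    abort("supply `mutations` (per-sample target) or `gene_list` (fixed target)")
  }
  mut_sets <- if (!is.null(mutations)) mutated_gene_sets(mutations)
  per_k <- purrr::map(sort(unique(as.integer(k))), function(kk) {
    top_k_genes(degrees, kk) |>
      group_by(.data$sample) |>
      summarise(n_top = n(), genes = list(.data$gene), .groups = "drop") |>
      mutate(
        n_hit = purrr::map2_int(.data$genes, .data$sample, function(g, s) {
          target <- if (!is.null(mut_sets)) mut_sets[[s]] %||% character() else gene_list
          if (!is.null(gene_list) && !is.null(mut_sets)) {
            target <- intersect(target, gene_list)
          }
          if (!is.null(conditioning)) target <- intersect(target, conditioning)
          length(intersect(g, target))
        }),
        k = kk, rate = .data$n_hit / .data$n_top
      ) |>
      select("k", "sample", "n_top", "n_hit", "rate")
  })
  out <- bind_rows(per_k)
  out |>
    group_by(.data$k) |>
    mutate(mean_rate = mean(.data$rate)) |>
    ungroup()
}

#' Recurrently mutated high-degree genes ("potential disease genes")
#'
#' Collects, per sample, the somatically mutated genes among the sample's
#' top-`k` highest-degree subpathway genes, then keeps the genes recurring in
#' at least `min_samples` samples.
#'
#' @param degrees Degree tibble from [node_degrees()].
#' @param mutations Mutation tibble (`sample`, `gene`).
#' @param k Top-degree list size per sample (default 5).
#' @param min_samples Minimum number of supporting samples (default 10).
#' @return A tibble `gene`, `n_samples` (support count), sorted by decreasing
#'   support; only genes with `n_samples >= min_samples`.
#' @export
potential_disease_genes <- function(degrees, mutations, k = 5,
                                    min_samples = 10) {
  mut <- distinct(mutations, .data$sample, .data$gene)
  top_k_genes(degrees, k) |>
    inner_join(mut, by = c("sample", "gene")) |>
    distinct(.data$sample, .data$gene) |>
    count(.data$gene, name = "n_samples") |>
    filter(.data$n_samples >= min_samples) |>
    arrange(desc(.data$n_samples), .data$gene)
}

#' Mean cohort mutation ratio of a gene set
#'
#' For each gene, the fraction of the cohort's samples carrying a mutation in
#' it; the statistic is the mean of these fractions over the set (genes never
#' mutated contribute 0).
#'
#' @param genes Non-empty character vector of gene symbols.
#' @param mutations Mutation tibble (`sample`, `gene`).
#' @param n_samples Cohort size used as the denominator.
#' @return A single number in \[0, 1\].
#' @export
mutation_ratio <- function(genes, mutations, n_samples) {
  if (length(genes) == 0L) abort("gene set is empty")
  if (n_samples <= 0L) abort("n_samples must be positive")
  freq <- mutations |>
    distinct(.data$sample, .data$gene) |>
    count(.data$gene, name = "n_mut")
  freq_map <- setNames(freq$n_mut, freq$gene)
  counts <- freq_map[genes]
  counts[is.na(counts)] <- 0
  mean(counts / n_samples)
}

#' Random-gene permutation test of a mutation ratio
#'
#' Tests whether an observed gene set's mean mutation ratio exceeds that of
#' random gene sets of the same size drawn (without replacement) from a
#' universe of genes — by default all genes somatically mutated anywhere in
#' the cohort. The empirical p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (R + 1)`.
#'
#' @param observed_genes Character vector, the set under test.
#' @param mutations Mutation tibble (`sample`, `gene`).
#' @param n_samples Cohort size.
#' @param universe Character vector to draw from; default all mutated genes.
#' @param n_perm Number of random draws `R` (default 1000).
#' @param seed Optional integer seed (caller RNG untouched when given).
#' @return An object of class `subpathx_permtest` with elements `statistic`
#'   (observed ratio), `null` (length-`R` null vector), `p_value`, `n_perm`,
#'   `set_size`, `seed`. Has [tidy()] and [glance()] methods.
#' @export
random_gene_test <- function(observed_genes, mutations, n_samples,
                             universe = NULL, n_perm = 1000, seed = NULL) {
  universe <- universe %||% unique(mutations$gene)
  m <- length(observed_genes)
  if (m == 0L) abort("observed gene set is empty")
  if (length(universe) <= m) {
    abort("universe must be larger than the observed set")
  }
  freq <- mutations |>
    distinct(.data$sample, .data$gene) |>
    count(.data$gene, name = "n_mut")
  freq_map <- setNames(freq$n_mut, freq$gene)
  ratio_of <- function(gs) {
    cnt <- freq_map[gs]
    cnt[is.na(cnt)] <- 0
    mean(cnt / n_samples)
  }
  observed <- ratio_of(observed_genes)
  draw <- function() {
    vapply(seq_len(n_perm), function(i) ratio_of(sample(universe, m)), numeric(1))
  }
  null <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(
    list(statistic = observed, null = null,
         p_value = (1 + sum(null >= observed)) / (n_perm + 1),
         n_perm = n_perm, set_size = m, seed = seed),
    class = "subpathx_permtest"
  )
}

#' @export
print.subpathx_permtest <- function(x, ...) {
  cat("Random-gene mutation-ratio permutation test\n")
  cat(sprintf("  set size: %d genes; permutations: %d\n", x$set_size, x$n_perm))
  cat(sprintf("  observed mean mutation ratio: %.4f (null mean %.4f)\n",
              x$statistic, mean(x$null)))
  cat(sprintf("  empirical p-value: %.4g\n", x$p_value))
  invisible(x)
}

#' @method tidy subpathx_permtest
#' @export
tidy.subpathx_permtest <- function(x, ...) {
  tibble(statistic = x$statistic, null_mean = mean(x$null),
         null_sd = sd(x$null), p_value = x$p_value,
         n_perm = x$n_perm, set_size = x$set_size)
}

#' @method glance subpathx_permtest
#' @export
glance.subpathx_permtest <- function(x, ...) tidy(x)

#' @method autoplot subpathx_permtest
#' @export
autoplot.subpathx_permtest <- function(object, ...) {
  df <- tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(x = "null mean mutation ratio", y = "count",
                  title = sprintf("Permutation null (R = %d), p = %.3g",
                                  object$n_perm, object$p_value))
}
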