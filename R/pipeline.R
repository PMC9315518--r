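#' Per-sample subpathway identification, end to end
#'
#' Convenience wrapper running the single-sample chain: reference edge
#' correlations, per-sample edge perturbation scores, per-sample edge-set
#' enrichment, and subpathway extraction at `q < alpha`.
#'
#' @inheritParams reference_edge_stats
#' @inheritParams sample_gsea
#' @inheritParams extract_subpathways
#' @param tumor Tumor sample ids; defaults to roles attached to `expr`.
#' @return A list: `ref_stats`, `scores` (edge-score matrix tibble),
#'   `enrichment` ([sample_gsea()] tibble), `subpathways`
#'   ([extract_subpathways()] tibble).
#' @export
identify_subpathways <- function(expr, pathway_edges, reference = NULL,
                                 tumor = NULL, exponent = 1, n_perm = 1000,
                                 min_set_size = 5, alpha = 0.05,
                                 min_edges = 1, eps = 1e-8, seed = NULL) {
  ref_stats <- reference_edge_stats(expr, pathway_edges, reference, eps = eps)
  scores <- edge_score_matrix(expr, ref_stats, tumor = tumor,
                              reference = reference)
  enrichment <- sample_gsea(scores, pathway_edges, exponent = exponent,
                            n_perm = n_perm, min_set_size = min_set_size,
                            seed = seed)
  subpaths <- extract_subpathways(enrichment, alpha = alpha,
                                  min_edges = min_edges)
  list(ref_stats = ref_stats, scores = scores, enrichment = enrichment,
       subpathways = subpaths)
}

#' Edge-score feature table for survival modeling
#'
#' Transposes selected rows of the edge-score matrix into the samples-by-
#' features layout consumed by [univariate_cox()] / [fit_risk_model()]: one
#' row per tumor sample, one column per edge (named by canonical edge id).
#'
#' @param score_matrix Edge-score tibble ([edge_score_matrix()]).
#' @param edges Edge ids to keep (default: all rows).
#' @return A tibble `sample` + one numeric column per edge.
#' @export
edge_score_features <- function(score_matrix, edges = NULL) {
  edges <- edges %||% score_matrix$edge
  missing <- setdiff(edges, score_matrix$edge)
  if (length(missing) > 0L) {
    abort(paste0("edge(s) absent from score matrix: ",
                 paste(missing, collapse = ", ")))
  }
  sub <- score_matrix[match(edges, score_matrix$edge), , drop = FALSE]
  samples <- setdiff(names(score_matrix), "edge")
  mat <- t(as.matrix(sub[samples]))
  colnames(mat) <- sub$edge
  bind_cols(tibble(sample = samples), as_tibble(mat))
}

#' Expression feature table for a gene signature
#'
#' Per-sample expression values of the given genes, in the samples-by-
#' features layout of [fit_risk_model()].
#'
#' @param expr Expression tibble.
#' @param genes Gene symbols (must exist in `expr`).
#' @param samples Sample ids to keep (default: tumor role of `expr`).
#' @return A tibble `sample` + one numeric column per gene.
#' @export
gene_expression_features <- function(expr, genes, samples = NULL) {
  samples <- samples %||% sample_roles(expr)$tumor
  missing <- setdiff(genes, expr$gene)
  if (length(missing) > 0L) {
    abort(paste0("gene(s) absent from expression table: ",
                 paste(missing, collapse = ", ")))
  }
  sub <- expr[match(genes, expr$gene), , drop = FALSE]
  mat <- t(as.matrix(sub[samples]))
  colnames(mat) <- sub$gene
  bind_cols(tibble(sample = samples), as_tibble(mat))
}

#' Cohort edge-signature survival analysis
#'
#' The cohort-level chain from per-sample subpathways to a prognostic edge
#' signature: (1) count edge recurrence across samples and keep edges
#' recurrent in more than `p0` of the cohort with binomial `p < 0.05`;
#' (2) keep recurrent edges touching a high-frequency mutation gene
#' (mutated in more than `hf_threshold` of samples); (3) screen the
#' surviving edges' perturbation scores by univariate Cox regression at
#' `p < p_cutoff` and build the median-split risk model.
#'
#' @param scores Edge-score matrix tibble.
#' @param subpathways Long subpathway tibble.
#' @param mutations Mutation tibble.
#' @param clinical Clinical tibble.
#' @param n_samples Number of tumor samples analyzed (defaults to the score
#'   matrix's sample columns).
#' @param hf_threshold High-frequency mutation cut-off (default 0.05).
#' @param p0 Recurrence null proportion (default 0.5).
#' @param p_cutoff Cox screening threshold (default 0.05).
#' @param eval_samples Optional hold-out sample ids for unbiased evaluation
#'   (see [fit_risk_model()]).
#' @return A list: `recurrence` (edge recurrence table), `hf_genes`,
#'   `candidate_edges` (recurrent + mutation-linked), `model`
#'   (`subpathx_risk_model`, or `NULL` when no candidate edge remains).
#' @export
cohort_edge_signature <- function(scores, subpathways, mutations, clinical,
                                  n_samples = NULL, hf_threshold = 0.05,
                                  p0 = 0.5, p_cutoff = 0.05,
                                  eval_samples = NULL) {
  n_samples <- n_samples %||% length(setdiff(names(scores), "edge"))
  recurrence <- recurrence_counts(subpathways, n_samples, unit = "edge",
                                  p0 = p0)
  sig_edges <- recurrence |> filter(.data$significant) |> pull("unit_id")
  hf <- high_frequency_mutations(mutations, n_samples,
                                 threshold = hf_threshold)
  candidates <- mutated_edge_filter(sig_edges, hf$gene)
  model <- NULL
  if (length(candidates) > 0L) {
    feats <- edge_score_features(scores, candidates)
    model <- fit_risk_model(feats, clinical, p_cutoff = p_cutoff,
                            eval_samples = eval_samples)
  }
  list(recurrence = recurrence, hf_genes = hf, candidate_edges = candidates,
       model = model)
}
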