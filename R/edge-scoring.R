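#' Pearson correlation with validity checks
#'
#' Plain product-moment correlation (sample, n - 1 convention), erroring on
#' the degenerate inputs the edge score cannot use: fewer than three pairs or
#' a constant vector.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation, in \[-1, 1\].
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3L) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for a constant vector")
  cor(x, y)
}

#' Single-sample edge perturbation score
#'
#' The perturbation z-score for one pathway edge: the change in Pearson
#' correlation when one sample is added to a reference cohort of `n` samples,
#' scaled by the sampling variability of the reference correlation,
#'
#' \deqn{score = \frac{PCC_{n+1} - PCC_n}{(1 - PCC_n^2)/(n - 1)}.}
#'
#' Under a stable reference correlation the score is approximately standard
#' normal, so it is comparable across edges with different baseline
#' correlations. Vectorized over edges.
#'
#' @param pcc_n Reference correlation(s) over the `n` reference samples.
#' @param pcc_n1 Correlation(s) over reference plus the one added sample.
#' @param n Number of reference samples (>= 3).
#' @param eps Singularity guard: `|pcc_n| >= 1 - eps` is an error (the scale
#'   factor degenerates); such edges are excluded upstream, not clipped.
#' @return Numeric score(s), sign matching `pcc_n1 - pcc_n`.
#' @export
edge_score <- function(pcc_n, pcc_n1, n, eps = 1e-8) {
  if (n < 3L) abort("edge score needs n >= 3 reference samples")
  if (any(abs(pcc_n) >= 1 - eps)) {
    abort("|reference correlation| too close to 1; edge must be excluded")
  }
  (pcc_n1 - pcc_n) / ((1 - pcc_n^2) / (n - 1))
}

# Sufficient statistics for fast correlation updates.
# X: genes x samples matrix; edges: tibble with gene_a/gene_b present in X.
.edge_suffstats <- function(X, gene_a, gene_b) {
  n <- ncol(X)
  sx <- rowSums(X)
  sxx <- rowSums(X^2)
  sxy <- rowSums(X[gene_a, , drop = FALSE] * X[gene_b, , drop = FALSE])
  list(n = n, sx = sx, sxx = sxx, sxy = sxy)
}

.pcc_from_suffstats <- function(n, sxa, sxb, sxxa, sxxb, sxy) {
  va <- n * sxxa - sxa^2
  vb <- n * sxxb - sxb^2
  num <- n * sxy - sxa * sxb
  denom <- sqrt(pmax(va, 0) * pmax(vb, 0))
  out <- rep(NA_real_, length(num))
  ok <- denom > 0
  out[ok] <- num[ok] / denom[ok]
  # guard rounding just past +-1
  pmin(pmax(out, -1), 1)
}

#' Reference correlations for the pathway edge universe
#'
#' Computes, once per unique edge across all pathways, the Pearson
#' correlation of the two genes over the reference (normal) samples, and
#' flags edges the perturbation score cannot use: a gene missing from the
#' expression table (`"missing gene"`), a zero-variance reference profile
#' (`"zero variance"`), or a reference correlation within `eps` of +-1
#' (`"near singular"`). Invalid edges are excluded from the score matrix, not
#' clipped, so the edge universe is reproducible.
#'
#' @param expr Expression tibble from [read_expression()] /
#'   [simulate_cohort()].
#' @param pathway_edges Pathway edge tibble ([read_pathway_edges()]).
#' @param reference Reference sample ids; defaults to the roles attached to
#'   `expr`.
#' @param eps Singularity guard for `|PCC|` near 1.
#' @return A tibble with one row per unique edge: `edge`, `gene_a`, `gene_b`,
#'   `pcc_ref`, `valid`, `reason`; attributes `n_ref` and `eps`.
#' @export
reference_edge_stats <- function(expr, pathway_edges, reference = NULL,
                                 eps = 1e-8) {
  reference <- reference %||% sample_roles(expr)$reference
  if (length(reference) < 3L) abort("need at least 3 reference samples")
  uni <- pathway_edges |> distinct(.data$edge, .data$gene_a, .data$gene_b) |>
    arrange(.data$edge)
  if (nrow(uni) == 0L) abort("no edges in pathway table")

  genes <- expr$gene
  X <- as.matrix(expr[reference])
  rownames(X) <- genes
  present <- uni$gene_a %in% genes & uni$gene_b %in% genes

  out <- uni |> mutate(pcc_ref = NA_real_, valid = FALSE, reason = NA_character_)
  out$reason[!present] <- "missing gene"

  if (any(present)) {
    sub <- uni[present, , drop = FALSE]
    ss <- .edge_suffstats(X, sub$gene_a, sub$gene_b)
    pcc <- .pcc_from_suffstats(ss$n, ss$sx[sub$gene_a], ss$sx[sub$gene_b],
                               ss$sxx[sub$gene_a], ss$sxx[sub$gene_b], ss$sxy)
    zero_var <- is.na(pcc)
    singular <- !zero_var & abs(pcc) >= 1 - eps
    ok <- !zero_var & !singular
    out$pcc_ref[present] <- pcc
    out$valid[present] <- ok
    out$reason[present][zero_var] <- "zero variance"
    out$reason[present][singular] <- "near singular"
  }
  n_bad <- sum(!out$valid)
  if (n_bad > 0L) {
    inform(sprintf("excluded %d invalid edge(s) (%s)", n_bad,
                   paste(unique(stats::na.omit(out$reason)), collapse = ", ")))
  }
  if (!any(out$valid)) abort("no usable edges after validity filtering")
  structure(out, n_ref = length(reference), eps = eps)
}

#' Per-sample edge perturbation score matrix
#'
#' For every valid edge and every tumor sample, adds that single sample to
#' the fixed reference cohort, recomputes the edge's Pearson correlation, and
#' converts the change into the perturbation z-score of [edge_score()]. This
#' is the edges-by-samples matrix that drives per-sample enrichment.
#'
#' @inheritParams reference_edge_stats
#' @param ref_stats Output of [reference_edge_stats()].
#' @param tumor Tumor sample ids; defaults to the roles attached to `expr`.
#' @return A tibble with column `edge` (valid edges only, sorted) followed by
#'   one numeric score column per tumor sample; attributes `n_ref` and `eps`.
#' @export
edge_score_matrix <- function(expr, ref_stats, tumor = NULL, reference = NULL) {
  roles <- tryCatch(sample_roles(expr), error = function(e) NULL)
  tumor <- tumor %||% roles$tumor
  ref_ids <- reference %||% roles$reference
  if (is.null(tumor)) abort("no tumor samples given and none attached to `expr`")
  if (is.null(ref_ids)) abort("no reference samples given and none attached to `expr`")
  if (length(intersect(tumor, ref_ids)) > 0L) {
    abort("tumor samples must be disjoint from the reference cohort")
  }
  valid <- ref_stats |> filter(.data$valid)
  genes <- expr$gene

  X <- as.matrix(expr[ref_ids])
  rownames(X) <- genes
  n <- ncol(X)
  if (!identical(as.integer(attr(ref_stats, "n_ref")), as.integer(n))) {
    abort("reference cohort size differs from the one used for ref_stats")
  }
  ss <- .edge_suffstats(X, valid$gene_a, valid$gene_b)
  sxa <- ss$sx[valid$gene_a]; sxb <- ss$sx[valid$gene_b]
  sxxa <- ss$sxx[valid$gene_a]; sxxb <- ss$sxx[valid$gene_b]
  sxy <- ss$sxy
  denom_scale <- (1 - valid$pcc_ref^2) / (n - 1)

  tum_mat <- as.matrix(expr[tumor])
  rownames(tum_mat) <- genes
  scores <- matrix(NA_real_, nrow(valid), length(tumor),
                   dimnames = list(valid$edge, tumor))
  for (j in seq_along(tumor)) {
    xa <- tum_mat[valid$gene_a, j]
    xb <- tum_mat[valid$gene_b, j]
    pcc1 <- .pcc_from_suffstats(n + 1, sxa + xa, sxb + xb,
                                sxxa + xa^2, sxxb + xb^2, sxy + xa * xb)
    scores[, j] <- (pcc1 - valid$pcc_ref) / denom_scale
  }
  if (anyNA(scores)) {
    # a degenerate augmented correlation cannot occur for valid edges, but a
    # non-finite expression value could propagate; refuse rather than emit NA
    abort("non-finite edge score produced; check expression values")
  }
  out <- bind_cols(tibble(edge = valid$edge), as_tibble(scores))
  structure(out, n_ref = n, eps = attr(ref_stats, "eps"))
}
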