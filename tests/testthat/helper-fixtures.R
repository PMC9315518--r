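# Shared fixture builders. Everything is generated in code at test time.

write_tsv_lines <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

# A 4-gene x 6-sample expression file with a duplicated symbol and an
# all-zero gene; samples N1-N3 reference, T1-T3 tumor.
expression_fixture_file <- function() {
  write_tsv_lines(c(
    "gene\tN1\tN2\tN3\tT1\tT2\tT3",
    "TP53\t2\t1\t4\t3\t3\t2",
    "tp53\t4\t3\t6\t5\t7\t2",
    "EGFR\t1\t2\t3\t1\t7\t9",
    "ZERO\t0\t0\t0\t0\t0\t0",
    "KRAS\t5\t4\t3\t2\t2\t8"
  ))
}

pathway_fixture_file <- function() {
  write_tsv_lines(c(
    "pathway\tgeneA\tgeneB",
    "P1\tB\tA",
    "P1\tA\tB",
    "P2\tA\tB",
    "P1\tC\tD"
  ))
}

# A deterministic expression tibble with roles, built from given matrices.
make_expr <- function(ref_mat, tum_mat, genes = rownames(ref_mat)) {
  ref_ids <- sprintf("N%02d", seq_len(ncol(ref_mat)))
  tum_ids <- sprintf("T%02d", seq_len(ncol(tum_mat)))
  vals <- cbind(ref_mat, tum_mat)
  colnames(vals) <- c(ref_ids, tum_ids)
  out <- dplyr::bind_cols(tibble::tibble(gene = genes),
                          tibble::as_tibble(vals))
  attr(out, "reference") <- ref_ids
  attr(out, "tumor") <- tum_ids
  out
}

# pathway edge tibble from a named list pathway -> character edges "A|B"
make_edges <- function(sets) {
  rows <- lapply(names(sets), function(p) {
    eg <- subpathx::edge_genes(sets[[p]])
    tibble::tibble(pathway = p, gene_a = eg$gene_a, gene_b = eg$gene_b,
                   edge = eg$edge)
  })
  dplyr::bind_rows(rows)
}

# Independent brute-force enrichment oracle: walk the full running sum with
# an explicit loop and return the signed maximum-|deviation| value and its
# position.
es_oracle <- function(scores, hits, p = 1) {
  N <- length(scores)
  m <- sum(hits)
  w <- abs(scores)^p
  tot <- sum(w[hits])
  run <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- if (hits[i]) {
      acc + (if (tot > 0) w[i] / tot else 1 / m)
    } else {
      acc - 1 / (N - m)
    }
    run[i] <- acc
  }
  peak <- which.max(abs(run))
  list(es = run[peak], peak = peak, running = run)
}

# Independent classical two-sample KS-style statistic for the unweighted
# (p = 0) case: signed maximum difference between the hit CDF and miss CDF
# along the ranked list.
ks_oracle <- function(hits) {
  N <- length(hits)
  m <- sum(hits)
  f_hit <- cumsum(hits) / m
  f_miss <- cumsum(!hits) / (N - m)
  d <- f_hit - f_miss
  d[which.max(abs(d))]
}

# Hand-coded Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Hand-coded Cox negative log partial likelihood (no ties in the fixtures).
cox_nll <- function(beta, time, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  -ll
}

# Hand-coded Kaplan-Meier product-limit on event/censor data.
km_oracle <- function(time, status) {
  tt <- sort(unique(time))
  s <- 1
  out <- data.frame(time = tt, survival = NA_real_)
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & status == 1)
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
  }
  out
}

# A tiny deterministic mutation table.
mutation_fixture <- function() {
  tibble::tibble(
    sample = c("S1", "S1", "S2", "S3", "S3", "S3"),
    gene = c("KRAS", "TP53", "KRAS", "EGFR", "KRAS", "TP53")
  )
}

cox_fixture <- function() {
  tibble::tibble(
    sample = sprintf("P%d", 1:8),
    time = c(3, 5, 7, 11, 2, 9, 13, 6),
    status = c(1, 1, 0, 1, 1, 0, 1, 1),
    x = c(1.2, 0.4, -0.3, -1.1, 2.0, 0.1, -0.8, 0.6)
  )
}
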