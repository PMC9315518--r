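test_that("binomial enrichment matches exact pmf summation", {
  expect_equal(binomial_enrichment(10, 10), 2^-10)
  expect_equal(binomial_enrichment(60, 100), sum(dbinom(60:100, 100, 0.5)),
               tolerance = 1e-12)
  expect_equal(binomial_enrichment(50, 100), sum(dbinom(50:100, 100, 0.5)),
               tolerance = 1e-12)
  set.seed(91)
  for (N in c(17, 250, 1000)) {
    ks <- sort(sample(0:N, 5))
    expect_equal(binomial_enrichment(ks, N),
                 vapply(ks, function(k) sum(dbinom(k:N, N, 0.5)), numeric(1)),
                 tolerance = 1e-12)
  }
  expect_error(binomial_enrichment(11, 10), "0, N")
})

test_that("recurrence counts units across samples, order independent", {
  mk <- function(s, edges, pw = "P1") {
    eg <- edge_genes(edges)
    tibble::tibble(sample = s, pathway = pw, edge = eg$edge,
                   gene_a = eg$gene_a, gene_b = eg$gene_b,
                   direction = "up", es = 1, q = 0.01)
  }
  sub <- dplyr::bind_rows(mk("S1", c("A|B", "A|C")), mk("S2", "A|C"),
                          mk("S3", c("A|B", "A|C"), pw = "P2"))
  rec <- recurrence_counts(sub, n_samples = 3, unit = "edge")
  expect_equal(rec$count[rec$unit_id == "A|B"], 2L)
  expect_equal(rec$count[rec$unit_id == "A|C"], 3L)
  expect_equal(rec$p_value, binomial_enrichment(rec$count, 3))
  # at N = 3 even 3/3 recurrence is not significant (p = 1/8)
  expect_false(any(rec$significant))
  big <- recurrence_counts(
    dplyr::bind_rows(lapply(sprintf("T%02d", 1:20), mk, edges = "A|B")), 20)
  expect_true(big$significant[big$unit_id == "A|B"])
  rec_rev <- recurrence_counts(sub[rev(seq_len(nrow(sub))), ], 3, "edge")
  expect_equal(rec_rev, rec)
  pw <- recurrence_counts(sub, 3, unit = "pathway")
  expect_equal(pw$count[pw$unit_id == "P1"], 2L)
  expect_equal(pw$count[pw$unit_id == "P2"], 1L)
})

test_that("high-frequency mutation filter applies the strict threshold", {
  muts <- tibble::tibble(
    sample = c(sprintf("S%03d", 1:6), sprintf("S%03d", 1:5), "S001"),
    gene = c(rep("KEPT", 6), rep("DROPPED", 5), "RARE")
  )
  hf <- high_frequency_mutations(muts, n_samples = 100, threshold = 0.05)
  expect_equal(hf$gene, "KEPT")   # 6 > 5 kept, 5 of 100 dropped
  expect_equal(hf$freq, 0.06)
  all_g <- high_frequency_mutations(muts, 100, threshold = 0)
  expect_setequal(all_g$gene, c("KEPT", "DROPPED", "RARE"))
})

test_that("mutated-edge filter keeps edges touching the gene set", {
  edges <- c("KRAS|X", "A|B", "KRAS|TP53")
  expect_equal(mutated_edge_filter(edges, "KRAS"), c("KRAS|X", "KRAS|TP53"))
  tbl <- tibble::tibble(edge = edges, extra = 1:3)
  kept <- mutated_edge_filter(tbl, c("KRAS", "TP53"))
  expect_equal(kept$extra, c(1L, 3L))
  expect_length(mutated_edge_filter(edges, "NOPE"), 0L)
})

test_that("univariate Cox matches a grid-search partial-likelihood oracle", {
  fx <- cox_fixture()
  res <- univariate_cox(fx[c("sample", "x")], fx[c("sample", "time", "status")])
  oracle <- optimize(cox_nll, c(-5, 5), time = fx$time, status = fx$status,
                     x = fx$x)$minimum
  expect_equal(res$beta, oracle, tolerance = 1e-4)
  expect_equal(res$hr, exp(res$beta))
  expect_true(res$converged)
})

test_that("Cox screening is sign-symmetric and flags degenerate features", {
  fx <- cox_fixture()
  feats <- tibble::tibble(sample = fx$sample, pos = fx$x, neg = -fx$x,
                          flat = 1)
  clin <- fx[c("sample", "time", "status")]
  res <- suppressWarnings(univariate_cox(feats, clin))
  expect_equal(res$beta[res$feature == "neg"],
               -res$beta[res$feature == "pos"], tolerance = 1e-8)
  expect_equal(res$p_value[res$feature == "neg"],
               res$p_value[res$feature == "pos"], tolerance = 1e-8)
  expect_false(res$converged[res$feature == "flat"])
  expect_true(is.na(res$beta[res$feature == "flat"]))
})

test_that("risk scores are the beta-weighted feature sums", {
  feats <- tibble::tibble(sample = c("a", "b"), f1 = c(2, 1), f2 = c(1, 2))
  expect_equal(risk_score(feats, c(f1 = 0.5, f2 = -1))$risk_score, c(0, -1.5))
  expect_equal(risk_score(feats, setNames(numeric(), character()))$risk_score,
               c(0, 0))
  expect_equal(risk_score(feats, c(f1 = 1, f2 = 1))$risk_score, c(3, 3))
  expect_error(risk_score(feats, c(nope = 1)), "absent")
})

test_that("median split sends the median sample low and rejects constants", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_split(c(1, 2, 3))), c("low", "low", "high"))
  expect_error(median_split(c(5, 5, 5)), "identical")
  expect_error(median_split(1), "at least 2")
})

test_that("Kaplan-Meier matches the hand product-limit oracle", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)
  set.seed(92)
  time <- sample(1:8, 12, replace = TRUE)
  status <- rbinom(12, 1, 0.7)
  km2 <- kaplan_meier(time, status)
  oracle <- km_oracle(time, status)
  expect_equal(km2$survival, oracle$survival[match(km2$time, oracle$time)])
  expect_true(all(diff(km2$survival) <= 1e-12))
  # no events: survival stays at 1
  flat <- kaplan_meier(c(2, 4), c(0, 0))
  expect_true(all(flat$survival == 1))
})

test_that("log-rank is zero for identical groups and errors without events", {
  time <- c(1, 2, 3, 4, 1, 2, 3, 4)
  status <- c(1, 0, 1, 1, 1, 0, 1, 1)
  grp <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(time, status, grp)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-6)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "event")
  expect_error(logrank_test(time, status, rep("a", 8)), "2 non-empty")
})

test_that("risk model selects, scores, splits, and reports; holdout respected", {
  set.seed(93)
  n <- 80
  ids <- sprintf("S%03d", seq_len(n))
  signal <- rnorm(n)
  feats <- tibble::tibble(sample = ids, good = signal, junk = rnorm(n))
  clin <- simulate_survival(ids, load = 5 * signal, baseline_hazard = 0.01,
                            gamma = 0.3, censoring_rate = 0.1)
  m <- fit_risk_model(feats, clin)
  expect_s3_class(m, "subpathx_risk_model")
  expect_true("good" %in% m$selected)
  expect_equal(sort(table(m$scores$group), decreasing = TRUE)[[1]], n / 2)
  expect_lt(m$logrank$p_value, 0.01)
  td <- tidy(m)
  expect_true(td$selected[td$feature == "good"])
  gl <- glance(m)
  expect_equal(gl$logrank_p, m$logrank$p_value)
  expect_s3_class(autoplot(m), "ggplot")

  eval_ids <- ids[1:30]
  mh <- fit_risk_model(feats, clin, eval_samples = eval_ids)
  expect_equal(sort(mh$scores$sample), sort(eval_ids))
  expect_equal(mh$n_eval, 30L)

  # no feature passing the screen yields an empty, printable model
  m0 <- fit_risk_model(feats["sample"] |> dplyr::mutate(noise = rnorm(n)),
                       clin, p_cutoff = 1e-12)
  expect_length(m0$selected, 0L)
  expect_null(m0$logrank)
  expect_true(is.na(glance(m0)$logrank_p))
})
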