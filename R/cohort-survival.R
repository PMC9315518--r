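#' Cohort recurrence of subpathway edges or pathways
#'
#' Counts, for each edge (or pathway), the number of samples whose subpathway
#' output contains it, and attaches the one-sided exact binomial p-value for
#' recurrence above the null proportion `p0`. A unit is flagged significant
#' when `p < 0.05` and its recurrence proportion strictly exceeds `p0`
#' ("more than half the cohort").
#'
#' @param subpathways Long subpathway tibble ([extract_subpathways()]).
#' @param n_samples Total number of tumor samples analyzed (the denominator;
#'   may exceed the number of samples with any significant subpathway).
#' @param unit `"edge"` or `"pathway"`.
#' @param p0 Null recurrence proportion (default 0.5).
#' @return A tibble `unit_id`, `count`, `n`, `prop`, `p_value`,
#'   `significant`, sorted by decreasing count.
#' @export
recurrence_counts <- function(subpathways, n_samples,
                              unit = c("edge", "pathway"), p0 = 0.5) {
  unit <- match.arg(unit)
  key <- if (unit == "edge") "edge" else "pathway"
  counts <- subpathways |>
    distinct(.data$sample, .data[[key]]) |>
    count(.data[[key]], name = "count") |>
    rename(unit_id = all_of(key))
  counts |>
    mutate(
      n = n_samples,
      prop = .data$count / n_samples,
      p_value = binomial_enrichment(.data$count, n_samples, p0),
      significant = .data$p_value < 0.05 & .data$prop > p0
    ) |>
    arrange(desc(.data$count), .data$unit_id)
}

#' One-sided exact binomial recurrence p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(N, p0)`: the chance
#' that a unit recurs in at least `k` of `N` samples when each sample
#' includes it independently with probability `p0`. Vectorized over `k`.
#'
#' @param k Observed recurrence count(s), `0 <= k <= N`.
#' @param N Number of samples.
#' @param p0 Null inclusion probability (default 0.5).
#' @return Upper-tail p-value(s).
#' @export
binomial_enrichment <- function(k, N, p0 = 0.5) {
  if (any(k < 0 | k > N)) abort("k must lie in [0, N]")
  pbinom(k - 1, N, p0, lower.tail = FALSE)
}

#' High-frequency mutation genes
#'
#' Genes mutated in strictly more than `threshold` of the cohort's samples
#' (the ">5% of samples" rule at the default).
#'
#' @param mutations Mutation tibble (`sample`, `gene`).
#' @param n_samples Cohort size.
#' @param threshold Frequency cut-off, exclusive (default 0.05).
#' @return A tibble `gene`, `n_mut`, `freq` for qualifying genes, sorted by
#'   decreasing frequency.
#' @export
high_frequency_mutations <- function(mutations, n_samples, threshold = 0.05) {
  if (n_samples <= 0L) abort("n_samples must be positive")
  mutations |>
    distinct(.data$sample, .data$gene) |>
    count(.data$gene, name = "n_mut") |>
    mutate(freq = .data$n_mut / n_samples) |>
    filter(.data$n_mut > threshold * n_samples) |>
    arrange(desc(.data$freq), .data$gene)
}

#' Edges touching high-frequency mutation genes
#'
#' Keeps the edges with at least one endpoint in the given gene set (used to
#' intersect recurrent subpathway edges with high-frequency mutation genes
#' before survival modeling).
#'
#' @param edges Character vector of canonical edge ids, or a tibble with an
#'   `edge` column (extra columns preserved).
#' @param genes Character vector of gene symbols.
#' @return Same shape as `edges`, filtered.
#' @export
mutated_edge_filter <- function(edges, genes) {
  ids <- if (is.data.frame(edges)) edges$edge else edges
  gg <- edge_genes(ids)
  keep <- gg$gene_a %in% genes | gg$gene_b %in% genes
  if (is.data.frame(edges)) edges[keep, , drop = FALSE] else edges[keep]
}

#' Univariate Cox screening of candidate features
#'
#' Fits one Cox proportional-hazards model per feature column (Efron tie
#' handling) against overall survival and reports the coefficient, hazard
#' ratio and Wald p-value. Constant features and non-convergent fits are
#' flagged (`converged = FALSE`, a warning) and carry `NA` estimates; they
#' are dropped from downstream signatures rather than aborting the run.
#'
#' @param features A tibble with a `sample` column plus one numeric column
#'   per feature (edge scores for an edge signature, or per-sample expression
#'   of signature genes for a gene signature).
#' @param clinical Clinical tibble (`sample`, `time`, `status`).
#' @return A tibble `feature`, `beta`, `hr`, `se`, `p_value`, `n`,
#'   `converged`.
#' @export
univariate_cox <- function(features, clinical) {
  feats <- setdiff(names(features), "sample")
  if (length(feats) == 0L) abort("no feature columns")
  dat <- inner_join(features, clinical, by = "sample")
  if (nrow(dat) < 3L) abort("fewer than 3 samples with both features and survival")
  if (sum(dat$status) < 2L) abort("need at least 2 events")
  surv <- survival::Surv(dat$time, dat$status)
  rows <- purrr::map(feats, function(f) {
    x <- dat[[f]]
    bad_row <- tibble(feature = f, beta = NA_real_, hr = NA_real_,
                      se = NA_real_, p_value = NA_real_, n = nrow(dat),
                      converged = FALSE)
    if (sd(x) == 0) {
      warn(sprintf("feature %s is constant; skipped", f))
      return(bad_row)
    }
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(surv ~ x, ties = "efron"),
        warning = function(w) {
          if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warn(sprintf("feature %s: Cox fit failed; skipped", f))
      return(bad_row)
    }
    beta <- unname(fit$coefficients[1])
    se <- sqrt(diag(fit$var))[1]
    ok <- is.finite(beta) && is.finite(se) && se < 50 && abs(beta) < 50
    if (!ok) {
      warn(sprintf("feature %s: Cox fit did not converge; skipped", f))
      return(bad_row)
    }
    z <- beta / se
    tibble(feature = f, beta = beta, hr = exp(beta), se = se,
           p_value = 2 * stats::pnorm(-abs(z)), n = nrow(dat),
           converged = TRUE)
  })
  bind_rows(rows)
}

#' Risk score from Cox coefficients
#'
#' The per-sample weighted sum of feature values with the univariate Cox
#' coefficients as weights: `risk = sum_i beta_i * x_i`.
#'
#' @param features Feature tibble (`sample` + feature columns).
#' @param betas Named numeric vector of coefficients; names must all be
#'   feature columns of `features`. A zero-length `betas` yields all-zero
#'   scores.
#' @return A tibble `sample`, `risk_score`.
#' @export
risk_score <- function(features, betas) {
  missing <- setdiff(names(betas), names(features))
  if (length(missing) > 0L) {
    abort(paste0("coefficients name feature(s) absent from the table: ",
                 paste(missing, collapse = ", ")))
  }
  score <- if (length(betas) == 0L) {
    rep(0, nrow(features))
  } else {
    as.numeric(as.matrix(features[names(betas)]) %*% unname(betas))
  }
  tibble(sample = features$sample, risk_score = score)
}

#' Median split into high- and low-risk groups
#'
#' Samples strictly above the median score are `"high"`, the rest `"low"`
#' (the median-valued sample falls in the low group). All-identical scores
#' admit no split and are an error.
#'
#' @param scores Numeric vector of risk scores (length >= 2).
#' @return A factor with levels `c("low", "high")`, same length as `scores`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) abort("need at least 2 samples to split")
  if (length(unique(scores)) == 1L) abort("all risk scores identical; degenerate split")
  factor(if_else(scores > median(scores), "high", "low"),
         levels = c("low", "high"))
}

#' Kaplan-Meier product-limit curve
#'
#' @param time Survival times (> 0).
#' @param status Event indicators (1 = death, 0 = censored).
#' @return A tibble `time`, `n_risk`, `n_event`, `n_censor`, `survival`, one
#'   row per distinct observed time.
#' @export
kaplan_meier <- function(time, status) {
  if (length(time) == 0L) abort("no subjects")
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' @param time,status Survival data.
#' @param group Factor/vector with exactly two non-empty levels.
#' @return A list `statistic` (chi-square, 1 df), `p_value`, `n` (per-group
#'   sizes).
#' @export
logrank_test <- function(time, status, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) abort("log-rank test needs exactly 2 non-empty groups")
  if (sum(status) < 1L) abort("log-rank test needs at least one event")
  sd_fit <- survival::survdiff(survival::Surv(time, status) ~ group)
  stat <- sd_fit$chisq
  list(statistic = unname(stat),
       p_value = pchisq(unname(stat), df = 1, lower.tail = FALSE),
       n = as.integer(table(group)))
}

#' Fit a Cox risk-score stratification model
#'
#' The survival-stratification pipeline over a set of candidate features
#' (edge scores or signature-gene expression values): screen each feature by
#' univariate Cox regression, keep those with Wald `p < p_cutoff` (no
#' multiple-testing correction at this step), form the per-sample risk score
#' `sum beta_i x_i`, split at the median, and compare the two groups by
#' Kaplan-Meier curves and a log-rank test.
#'
#' When `eval_samples` is given, the Cox screening and coefficients are
#' estimated on the remaining (training) samples only, and the median split
#' and log-rank test are evaluated on `eval_samples` — an internal hold-out
#' mirroring validation on an independent cohort and giving an unbiased
#' group comparison. By default everything uses the full cohort (the
#' in-sample procedure).
#'
#' @inheritParams univariate_cox
#' @param p_cutoff Wald p-value threshold for keeping a feature (default
#'   0.05).
#' @param eval_samples Optional character vector of sample ids reserved for
#'   evaluation.
#' @return An object of class `subpathx_risk_model`: list with `cox`
#'   (screening table), `selected` (kept feature names), `betas`, `scores`
#'   (tibble `sample`, `risk_score`, `group`, `time`, `status`), `cutoff`
#'   (median), `logrank`, `km` (per-group curves), `n_eval`. When no feature
#'   passes the screen, `selected` is empty and `logrank` is `NULL`. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_risk_model <- function(features, clinical, p_cutoff = 0.05,
                           eval_samples = NULL) {
  train <- features
  if (!is.null(eval_samples)) {
    train <- filter(features, !(.data$sample %in% eval_samples))
    eval_feat <- filter(features, .data$sample %in% eval_samples)
    if (nrow(eval_feat) == 0L) abort("no evaluation samples found in feature table")
  } else {
    eval_feat <- features
  }
  cox <- univariate_cox(train, clinical)
  kept <- cox |> filter(.data$converged, .data$p_value < p_cutoff)
  model <- list(cox = cox, selected = kept$feature,
                betas = setNames(kept$beta, kept$feature),
                p_cutoff = p_cutoff,
                holdout = !is.null(eval_samples))
  if (nrow(kept) == 0L) {
    model <- c(model, list(scores = NULL, cutoff = NA_real_, logrank = NULL,
                           km = NULL, n_eval = 0L))
    return(structure(model, class = "subpathx_risk_model"))
  }
  sc <- risk_score(eval_feat, model$betas) |>
    inner_join(clinical, by = "sample")
  grp <- median_split(sc$risk_score)
  sc$group <- grp
  lr <- logrank_test(sc$time, sc$status, sc$group)
  km <- sc |>
    group_by(.data$group) |>
    summarise(curve = list(kaplan_meier(.data$time, .data$status)),
              .groups = "drop") |>
    tidyr::unnest(col = "curve")
  model <- c(model, list(scores = sc, cutoff = median(sc$risk_score),
                         logrank = lr, km = km, n_eval = nrow(sc)))
  structure(model, class = "subpathx_risk_model")
}

#' @export
print.subpathx_risk_model <- function(x, ...) {
  cat("Cox risk-score stratification model\n")
  cat(sprintf("  screened %d feature(s); %d kept at p < %g%s\n",
              nrow(x$cox), length(x$selected), x$p_cutoff,
              if (x$holdout) " (hold-out evaluation)" else ""))
  if (is.null(x$logrank)) {
    cat("  no feature passed the screen; no risk groups formed\n")
  } else {
    cat(sprintf("  %d evaluated samples; median cut-off %.4f\n",
                x$n_eval, x$cutoff))
    cat(sprintf("  log-rank chi-square %.3f, p = %.4g\n",
                x$logrank$statistic, x$logrank$p_value))
  }
  invisible(x)
}

#' @method tidy subpathx_risk_model
#' @export
tidy.subpathx_risk_model <- function(x, ...) {
  x$cox |> mutate(selected = .data$feature %in% x$selected)
}

#' @method glance subpathx_risk_model
#' @export
glance.subpathx_risk_model <- function(x, ...) {
  tibble(
    n_features = nrow(x$cox),
    n_selected = length(x$selected),
    n_eval = x$n_eval,
    cutoff = x$cutoff,
    logrank_statistic = if (is.null(x$logrank)) NA_real_ else x$logrank$statistic,
    logrank_p = if (is.null(x$logrank)) NA_real_ else x$logrank$p_value
  )
}

#' @method autoplot subpathx_risk_model
#' @export
autoplot.subpathx_risk_model <- function(object, ...) {
  if (is.null(object$km)) abort("model has no risk groups to plot")
  steps <- object$km |>
    group_by(.data$group) |>
    group_modify(~ bind_rows(tibble(time = 0, survival = 1),
                             .x[c("time", "survival")])) |>
    ungroup()
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival,
                                      colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability", colour = "risk group",
                  title = sprintf("Kaplan-Meier by risk group (log-rank p = %.3g)",
                                  object$logrank$p_value))
}
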