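#' Generate random pathway graphs
#'
#' Builds `n_pathways` connected random graphs over disjoint gene universes
#' and returns their edges in the canonical three-column form. Models:
#' `"pa"` (preferential attachment, hub-rich degree distribution — the
#' default, since curated signaling pathways are hub-dominated), `"gnp"`
#' (Erdős–Rényi conditioned on connectivity), `"tree"` (uniform random
#' spanning tree).
#'
#' @param n_pathways Number of pathways.
#' @param n_nodes Genes per pathway (>= 4).
#' @param model Graph model, one of `"pa"`, `"gnp"`, `"tree"`.
#' @param pa_m Edges added per vertex under `"pa"` (default 2).
#' @param gnp_p Edge probability under `"gnp"` (default 0.3).
#' @return A pathway edge tibble (`pathway`, `gene_a`, `gene_b`, `edge`)
#'   with pathway ids `P01..` and gene symbols `P01G01..`.
#' @export
generate_pathways <- function(n_pathways, n_nodes,
                              model = c("pa", "gnp", "tree"),
                              pa_m = 2, gnp_p = 0.3) {
  model <- match.arg(model)
  if (n_nodes < 4L) abort("pathways need at least 4 nodes")
  rows <- purrr::map(seq_len(n_pathways), function(i) {
    g <- switch(model,
      pa = igraph::sample_pa(n_nodes, m = pa_m, directed = FALSE),
      tree = igraph::sample_tree(n_nodes),
      gnp = {
        repeat {
          g <- igraph::sample_gnp(n_nodes, gnp_p)
          if (igraph::is_connected(g)) break
        }
        g
      }
    )
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    genes <- sprintf("P%02dG%02d", i, seq_len(n_nodes))
    tibble(pathway = sprintf("P%02d", i),
           gene_a = genes[el[, 1]], gene_b = genes[el[, 2]])
  })
  canonicalize_edges(bind_rows(rows))
}

# Choose the gene subset whose perturbation realizes an edge fraction
# closest to `fraction` for the given mode. Under "sign_flip" the perturbed
# edges are those crossing the subset boundary (loading sign flip changes
# exactly the crossing correlations); under "decorrelate" they are the edges
# incident to the subset (zeroed loadings kill every correlation touching
# it). Randomized search over subset sizes; deterministic under the caller's
# RNG state.
.pick_perturb_genes <- function(block_edges, genes, fraction, mode,
                                n_try = 400L) {
  n_edge <- nrow(block_edges)
  if (fraction == 0) {
    # no perturbation: planted and reference distributions coincide
    return(list(genes = character(), edge_hit = rep(FALSE, n_edge)))
  }
  best <- NULL
  best_gap <- Inf
  sizes <- seq.int(1L, length(genes) - 1L)
  for (i in seq_len(n_try)) {
    s <- sample(genes, sample(sizes, 1))
    in_a <- block_edges$gene_a %in% s
    in_b <- block_edges$gene_b %in% s
    hit <- if (mode == "sign_flip") xor(in_a, in_b) else (in_a | in_b)
    gap <- abs(sum(hit) / n_edge - fraction)
    if (gap < best_gap) {
      best <- list(genes = sort(s), edge_hit = hit)
      best_gap <- gap
      if (gap == 0) break
    }
  }
  best
}

#' Simulation settings for a synthetic cohort
#'
#' Returns the default simulation configuration, optionally overridden.
#' Defaults describe a modest desk-scale cohort: 8 preferential-attachment
#' tree pathways of 30 genes (hub-rich like curated signaling pathways),
#' 100 reference and 130 tumor samples (a 1:4 scale-down of a typical
#' tumor-atlas cohort), reference edge correlation 0.8
#' (tightly co-regulated interacting pairs — the stable-reference regime
#' the perturbation score presumes), one designated driver pathway with 60%
#' of its edges sign-flipped in planted tumor samples (each tumor is planted
#' with probability 0.7), mutations at 2% background enriched 10-fold on the
#' driver pathway's hubs in planted samples, and exponential survival whose
#' log-hazard increases by `gamma` per perturbed edge carried (defaults give
#' a planted-vs-unplanted hazard ratio around 4.5).
#'
#' @param ... Named overrides of the defaults listed above (see
#'   [simulate_cohort()] for the full field list).
#' @return A named list of settings.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    n_pathways = 8L, n_nodes = 30L, graph_model = "pa", pa_m = 1, gnp_p = 0.3,
    n_reference = 100L, n_tumor = 130L,
    rho = 0.8, perturb_fraction = 0.6,
    perturb_mode = "sign_flip", p_plant = 0.5, planted_pathway = NULL,
    background_mutation_rate = 0.02, hub_multiplier = 10, hub_top_frac = 0.2,
    baseline_hazard = 0.002, gamma = 0.1, censoring_rate = 0.2,
    baseline_min = 2, baseline_max = 8
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    abort(paste0("unknown simulation setting(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(cfg, over)
  if (cfg$rho < 0 || cfg$rho > 0.8) abort("rho must lie in [0, 0.8]")
  for (f in c("perturb_fraction", "p_plant", "background_mutation_rate",
              "censoring_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0(f, " must lie in [0, 1]"))
  }
  cfg
}

#' Simulate a full synthetic cohort with recorded ground truth
#'
#' Generates pathway graphs, correlated reference expression, tumor samples
#' with planted edge-correlation perturbations, somatic mutations enriched
#' on perturbed-pathway hub genes, and survival times whose hazard grows
#' with the planted perturbation load. Every piece of ground truth needed to
#' evaluate recovery is recorded.
#'
#' Mechanics: each pathway's genes follow a Gaussian Markov field on a
#' spanning tree of the pathway graph (child = `rho` * parent + noise, unit
#' marginal variances), so spanning-tree edges carry correlation exactly
#' `rho`, a chord at tree distance d carries `rho^d`, and the covariance is
#' positive definite by construction — co-expression is strong between
#' direct interactors and decays with network distance. With the default
#' preferential-attachment trees every pathway edge carries exactly `rho`.
#' One pathway (`planted_pathway`, default the first) is the driver: a fixed
#' gene subset — chosen once so that the affected edges are as close as
#' possible to `perturb_fraction` of the pathway's edges, and shared by all
#' planted samples so perturbed edges can recur across the cohort — has its
#' deviates negated (`"sign_flip"`: edges crossing the subset boundary get
#' their correlation exactly negated) or redrawn independently
#' (`"decorrelate"`: edges touching the subset drop to correlation 0) in
#' planted tumor samples. The realized perturbed-edge list and fraction are
#' recorded in the ground truth. Each tumor sample is planted independently with
#' probability `p_plant`; its perturbation load is the number of perturbed
#' edges it carries (0 when unplanted). Genes mutate independently at
#' `background_mutation_rate`, multiplied by `hub_multiplier` on the driver
#' pathway's hub genes (top `hub_top_frac` by degree) in planted samples.
#' Survival is exponential with hazard `baseline_hazard * exp(gamma * load)`;
#' a sample is censored with probability `censoring_rate`, uniformly before
#' its event time. Expression values sit on a log2-like scale: per-gene
#' baselines drawn uniformly in `[baseline_min, baseline_max]` plus the
#' unit-variance correlated deviations.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @param seed Mandatory integer seed; the whole cohort is a deterministic
#'   function of (config, seed).
#' @return A list of class `subpathx_cohort`: `expression` (tibble with
#'   roles attached, as [read_expression()] returns), `pathways`,
#'   `mutations`, `clinical`, and `truth` — a list with `planted`
#'   (tibble `sample`, `planted`, `pathway`, `load`), `perturbed_edges`,
#'   `hub_genes`, `achieved` (per-edge achieved reference and perturbed
#'   correlations), and `config`.
#' @export
simulate_cohort <- function(..., seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  cfg <- simulation_config(...)
  withr::with_seed(seed, .simulate_cohort_impl(cfg))
}

.simulate_cohort_impl <- function(cfg) {
  pathways <- generate_pathways(cfg$n_pathways, cfg$n_nodes,
                                model = cfg$graph_model,
                                pa_m = cfg$pa_m, gnp_p = cfg$gnp_p)
  pw_ids <- unique(pathways$pathway)
  driver <- cfg$planted_pathway %||% pw_ids[1]
  if (!driver %in% pw_ids) abort("planted_pathway not among generated pathways")

  if (!cfg$perturb_mode %in% c("sign_flip", "decorrelate")) {
    abort("perturb_mode must be 'sign_flip' or 'decorrelate'")
  }

  # fixed perturbed gene subset of the driver pathway, chosen so the
  # affected edge fraction is as close as possible to the requested one
  driver_edges <- filter(pathways, .data$pathway == driver)
  flip <- .pick_perturb_genes(driver_edges,
                              sort(unique(c(driver_edges$gene_a,
                                            driver_edges$gene_b))),
                              cfg$perturb_fraction, cfg$perturb_mode)
  perturbed <- driver_edges[flip$edge_hit,
                            c("pathway", "edge", "gene_a", "gene_b")]
  n_pert <- nrow(perturbed)
  pert_rho <- if (cfg$perturb_mode == "sign_flip") -cfg$rho else 0

  # per-pathway Gaussian Markov field on a spanning tree of the pathway
  # graph: spanning-tree edges carry correlation exactly rho, a chord at
  # tree distance d carries rho^d, and the joint covariance is positive
  # definite by construction (unit marginal variances)
  blocks <- purrr::map(pw_ids, function(pw) {
    be <- filter(pathways, .data$pathway == pw)
    genes <- sort(unique(c(be$gene_a, be$gene_b)))
    g <- igraph::graph_from_data_frame(be[c("gene_a", "gene_b")],
                                       directed = FALSE, vertices = genes)
    st <- igraph::mst(g)
    b <- igraph::bfs(st, root = 1, father = TRUE)
    ord <- as.integer(b$order)
    father <- as.integer(b$father)
    d <- igraph::distances(st)
    tree_dist <- d[cbind(match(be$gene_a, genes), match(be$gene_b, genes))]
    list(pathway = pw, genes = genes, edges = be, order = ord,
         father = father, tree_dist = tree_dist)
  })
  all_genes <- unlist(purrr::map(blocks, "genes"))

  ref_ids <- sprintf("N%03d", seq_len(cfg$n_reference))
  tum_ids <- sprintf("T%03d", seq_len(cfg$n_tumor))
  planted <- runif(cfg$n_tumor) < cfg$p_plant

  # n x k draws: root ~ N(0,1), child = rho * parent + sqrt(1-rho^2) * eps
  draw_block <- function(b, n) {
    k <- length(b$genes)
    X <- matrix(NA_real_, n, k)
    noise_sd <- sqrt(1 - cfg$rho^2)
    for (v in b$order) {
      p <- b$father[v]
      X[, v] <- if (is.na(p)) rnorm(n) else cfg$rho * X[, p] + noise_sd * rnorm(n)
    }
    colnames(X) <- b$genes
    X
  }
  # the planted perturbation acts on the drawn deviates: sign_flip negates
  # the chosen genes (crossing-edge correlations become exactly -rho^d);
  # decorrelate redraws them independently (touching edges drop to 0)
  perturb_rows <- function(X, rows) {
    if (length(rows) == 0L) return(X)
    cols <- intersect(colnames(X), flip$genes)
    if (length(cols) == 0L) return(X)
    if (cfg$perturb_mode == "sign_flip") {
      X[rows, cols] <- -X[rows, cols]
    } else {
      X[rows, cols] <- matrix(rnorm(length(rows) * length(cols)),
                              length(rows), length(cols))
    }
    X
  }
  # samples x genes deviations
  ref_dev <- do.call(cbind, purrr::map(blocks, ~ draw_block(.x, cfg$n_reference)))
  tum_dev <- do.call(cbind, purrr::map(blocks, function(b) {
    X <- draw_block(b, cfg$n_tumor)
    if (b$pathway == driver) X <- perturb_rows(X, which(planted))
    X
  }))
  baseline <- runif(length(all_genes), cfg$baseline_min, cfg$baseline_max)
  vals <- t(rbind(ref_dev, tum_dev)) + baseline  # genes x samples
  dimnames(vals) <- list(all_genes, c(ref_ids, tum_ids))

  expression <- bind_cols(tibble(gene = all_genes), as_tibble(vals)) |>
    arrange(.data$gene)
  attr(expression, "reference") <- ref_ids
  attr(expression, "tumor") <- tum_ids
  attr(expression, "log_transformed") <- TRUE

  # hub genes of the driver pathway (top fraction by degree)
  deg <- driver_edges |>
    tidyr::pivot_longer(c("gene_a", "gene_b"), values_to = "gene") |>
    count(.data$gene, name = "degree") |>
    arrange(desc(.data$degree), .data$gene)
  n_hub <- max(1L, ceiling(cfg$hub_top_frac * nrow(deg)))
  hub_genes <- tibble(pathway = driver, gene = deg$gene[seq_len(n_hub)])

  # mutations: background everywhere, hub-enriched in planted samples
  rate <- matrix(cfg$background_mutation_rate, cfg$n_tumor, length(all_genes),
                 dimnames = list(tum_ids, all_genes))
  hub_rate <- min(0.95, cfg$background_mutation_rate * cfg$hub_multiplier)
  if (any(planted)) rate[planted, hub_genes$gene] <- hub_rate
  mut_flag <- matrix(rbinom(length(rate), 1, as.vector(rate)),
                     nrow = cfg$n_tumor, dimnames = dimnames(rate))
  hits <- which(mut_flag == 1, arr.ind = TRUE)
  mutations <- tibble(sample = tum_ids[hits[, 1]],
                      gene = all_genes[hits[, 2]]) |>
    arrange(.data$sample, .data$gene)

  # survival: exponential hazard increasing with perturbation load
  load <- if_else(planted, n_pert, 0L)
  clinical <- simulate_survival(tum_ids, load,
                                baseline_hazard = cfg$baseline_hazard,
                                gamma = cfg$gamma,
                                censoring_rate = cfg$censoring_rate)

  # exact generating correlations per edge (rho^tree-distance, flipped or
  # zeroed for the driver pathway's perturbed edges)
  achieved <- bind_rows(purrr::map(blocks, function(b) {
    rr <- cfg$rho^b$tree_dist
    rp <- rr
    if (b$pathway == driver) {
      if (cfg$perturb_mode == "sign_flip") {
        rp <- if_else(flip$edge_hit, -rr, rr)
      } else {
        touching <- b$edges$gene_a %in% flip$genes |
          b$edges$gene_b %in% flip$genes
        rp <- if_else(touching, 0, rr)
      }
    }
    tibble(pathway = b$pathway, edge = b$edges$edge,
           rho_ref = rr, rho_perturbed = rp)
  }))

  truth <- list(
    planted = tibble(sample = tum_ids, planted = planted,
                     pathway = if_else(planted, driver, NA_character_),
                     load = load),
    perturbed_edges = perturbed,
    perturbed_genes = flip$genes,
    hub_genes = hub_genes,
    achieved = achieved,
    config = cfg
  )
  structure(list(expression = expression, pathways = pathways,
                 mutations = mutations, clinical = clinical, truth = truth),
            class = "subpathx_cohort")
}

#' Simulate survival outcomes for a given perturbation load
#'
#' Draws exponential survival times with hazard
#' `baseline_hazard * exp(gamma * load)` and independent censoring: each
#' subject is censored with probability `censoring_rate`, at a uniform time
#' before its event. Used internally by [simulate_cohort()] and exported so
#' survival can be re-drawn on a fixed cohort (e.g. null calibration of the
#' risk pipeline with `gamma = 0`).
#'
#' @param samples Character vector of sample ids.
#' @param load Numeric perturbation load per sample (same length).
#' @param baseline_hazard Hazard at load 0 (events per time unit).
#' @param gamma Log-hazard increase per unit load; 0 severs the
#'   survival-perturbation link.
#' @param censoring_rate Probability a subject is censored.
#' @return A clinical tibble `sample`, `time`, `status`.
#' @export
simulate_survival <- function(samples, load, baseline_hazard = 0.002,
                              gamma = 0.1, censoring_rate = 0.2) {
  n <- length(samples)
  if (length(load) != n) abort("`load` must match `samples` in length")
  hazard <- baseline_hazard * exp(gamma * load)
  t_event <- rexp(n, rate = hazard)
  censored <- runif(n) < censoring_rate
  time <- if_else(censored, runif(n) * t_event, t_event)
  tibble(sample = samples, time = pmax(time, 1e-6),
         status = as.integer(!censored))
}

#' @export
print.subpathx_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic subpathway cohort\n")
  cat(sprintf("  %d pathways (%s, %d nodes), %d edges total\n",
              cfg$n_pathways, cfg$graph_model, cfg$n_nodes, nrow(x$pathways)))
  cat(sprintf("  %d reference + %d tumor samples; rho = %.2f\n",
              cfg$n_reference, cfg$n_tumor, cfg$rho))
  cat(sprintf("  driver pathway %s: %d perturbed edge(s) (%s), %d/%d samples planted\n",
              x$truth$perturbed_edges$pathway[1],
              nrow(x$truth$perturbed_edges), cfg$perturb_mode,
              sum(x$truth$planted$planted), cfg$n_tumor))
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `expression.tsv`, `samples.tsv` (sample roles), `pathways.tsv`,
#' `mutations.tsv` (MAF-like column names), `clinical.tsv` and `truth.json`
#' into `dir`. All files round-trip through the package readers.
#'
#' @param cohort A `subpathx_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  roles <- sample_roles(cohort$expression)
  readr::write_tsv(
    tibble(sample = c(roles$reference, roles$tumor),
           role = rep(c("reference", "tumor"),
                      c(length(roles$reference), length(roles$tumor)))),
    file.path(dir, "samples.tsv"), progress = FALSE)
  write_pathway_edges(cohort$pathways, file.path(dir, "pathways.tsv"))
  readr::write_tsv(
    tibble(Tumor_Sample_Barcode = cohort$mutations$sample,
           Hugo_Symbol = cohort$mutations$gene,
           Variant_Classification = "Missense_Mutation"),
    file.path(dir, "mutations.tsv"), progress = FALSE)
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"),
                   progress = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(planted = truth$planted, perturbed_edges = truth$perturbed_edges,
         perturbed_genes = truth$perturbed_genes,
         hub_genes = truth$hub_genes, achieved = truth$achieved,
         config = truth$config),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
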