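#' Read a genes-by-samples expression table
#'
#' Reads a tab-separated expression matrix whose first column holds gene
#' symbols and whose header names the samples, attaches sample roles
#' (reference/normal vs tumor), and applies the standard preprocessing:
#' duplicate gene symbols are merged by averaging their rows, genes with zero
#' expression in every retained sample are removed, and (optionally) values
#' are log2(x + 1)-transformed.
#'
#' Only the columns named in `reference` and `tumor` are retained, so the
#' sample-role labelling is total. Gene symbols are uppercased.
#'
#' @param path Path to a TSV file (first column gene symbol, one column per
#'   sample).
#' @param reference,tumor Character vectors of sample ids taking the
#'   reference (normal) and tumor roles. Must be disjoint, non-empty, and
#'   present in the file header.
#' @param log_transform If `TRUE`, values are transformed to `log2(x + 1)`
#'   after merging and zero-filtering.
#' @return A tibble with column `gene` followed by one numeric column per
#'   sample, carrying attributes `reference` and `tumor` (the role vectors)
#'   and `log_transformed`. Retrieve roles with [sample_roles()].
#' @seealso [write_expression()], [read_pathway_edges()]
#' @export
read_expression <- function(path, reference, tumor, log_transform = FALSE) {
  reference <- as.character(reference)
  tumor <- as.character(tumor)
  if (length(reference) == 0L || length(tumor) == 0L) {
    abort("`reference` and `tumor` must both be non-empty")
  }
  if (length(intersect(reference, tumor)) > 0L) {
    abort(paste0(
      "reference and tumor sample lists overlap: ",
      paste(intersect(reference, tumor), collapse = ", ")
    ))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2L) abort("expression file needs a gene column plus sample columns")
  names(raw)[1] <- "gene"
  wanted <- c(reference, tumor)
  missing <- setdiff(wanted, names(raw)[-1])
  if (length(missing) > 0L) {
    abort(paste0("sample id(s) absent from expression header: ",
                 paste(missing, collapse = ", ")))
  }
  raw <- raw[, c("gene", wanted)]
  bad <- wanted[!vapply(raw[wanted], is.numeric, logical(1))]
  if (length(bad) > 0L) {
    abort(paste0("non-numeric expression values in column(s): ",
                 paste(bad, collapse = ", ")))
  }
  raw$gene <- toupper(trimws(as.character(raw$gene)))

  merged <- raw |>
    group_by(.data$gene) |>
    summarise(across(all_of(wanted), mean), .groups = "drop")

  vals <- as.matrix(merged[wanted])
  keep <- rowSums(vals != 0, na.rm = TRUE) > 0
  if (any(!keep)) {
    inform(sprintf("removed %d gene(s) with all-zero expression", sum(!keep)))
  }
  merged <- merged[keep, , drop = FALSE]
  if (log_transform) {
    merged <- merged |> mutate(across(all_of(wanted), ~ log2(.x + 1)))
  }
  merged <- arrange(merged, .data$gene)
  structure(merged,
            reference = reference, tumor = tumor,
            log_transformed = isTRUE(log_transform))
}

#' Sample roles of an expression table
#'
#' @param expr An expression tibble from [read_expression()] or
#'   [simulate_cohort()].
#' @return A list with character vectors `reference` and `tumor`.
#' @export
sample_roles <- function(expr) {
  ref <- attr(expr, "reference")
  tum <- attr(expr, "tumor")
  if (is.null(ref) || is.null(tum)) {
    abort("expression table carries no sample roles; pass `reference`/`tumor` explicitly")
  }
  list(reference = ref, tumor = tum)
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression()] up to preprocessing already applied; a
#' write/read round trip reproduces the same tibble.
#'
#' @param expr Expression tibble (`gene` column plus sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read pathway edges from a three-column table
#'
#' Pathway topology is consumed as a flat edge list: a TSV whose first column
#' is the pathway id and whose next two columns are the two gene symbols
#' joined by an edge in that pathway. Edges are canonicalized (uppercased,
#' lexicographically ordered pair), self-loops are dropped with a warning,
#' and duplicate edges within a pathway are collapsed. The same edge may
#' appear in several pathways; pathway edge sets are independent.
#'
#' @param path Path to a TSV file with at least three columns
#'   (pathway, geneA, geneB); extra columns are ignored.
#' @return A tibble with columns `pathway`, `gene_a`, `gene_b`, `edge`
#'   (canonical id), one row per (pathway, edge).
#' @export
read_pathway_edges <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 3L) abort("pathway edge file must have >= 3 columns (pathway, geneA, geneB)")
  tbl <- tibble(pathway = as.character(raw[[1]]),
                gene_a = as.character(raw[[2]]),
                gene_b = as.character(raw[[3]]))
  canonicalize_edges(tbl)
}

#' @rdname read_pathway_edges
#' @param edges Pathway edge tibble as returned by [read_pathway_edges()].
#' @export
write_pathway_edges <- function(edges, path) {
  readr::write_tsv(edges[c("pathway", "gene_a", "gene_b")], path, progress = FALSE)
  invisible(path)
}

#' Read a somatic mutation table (MAF-like)
#'
#' Reads a mutation table with at least a sample-id and a gene-symbol column
#' (MAF defaults `Tumor_Sample_Barcode` / `Hugo_Symbol`; override for generic
#' tables). Duplicate (sample, gene) records collapse to one row: downstream
#' analyses use mutated-gene membership, not counts. No variant-consequence
#' filter is applied.
#'
#' @param path Path to a TSV; lines starting with `#` are skipped.
#' @param sample_col,gene_col Column names holding the sample id and gene
#'   symbol.
#' @return A tibble with columns `sample`, `gene` (uppercased), one row per
#'   mutated (sample, gene) pair.
#' @export
read_mutations <- function(path, sample_col = "Tumor_Sample_Barcode",
                           gene_col = "Hugo_Symbol") {
  raw <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(c(sample_col, gene_col), names(raw))
  if (length(missing) > 0L) {
    abort(paste0("mutation table lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tibble(sample = as.character(raw[[sample_col]]),
         gene = toupper(trimws(as.character(raw[[gene_col]])))) |>
    filter(!is.na(.data$sample), !is.na(.data$gene), .data$gene != "") |>
    distinct(.data$sample, .data$gene) |>
    arrange(.data$sample, .data$gene)
}

#' Per-sample mutated-gene sets
#'
#' @param mutations Mutation tibble from [read_mutations()].
#' @return A named list mapping each sample id to its character vector of
#'   mutated genes.
#' @export
mutated_gene_sets <- function(mutations) {
  split(mutations$gene, mutations$sample)
}

#' Read a clinical survival table
#'
#' Expects columns for sample id, survival time, and vital status. Textual
#' status values are mapped through `status_map` (defaults cover common
#' dialects: Dead/DECEASED/1 are events, Alive/LIVING/0 censored). Rows with
#' missing time or status are dropped with a message; non-positive times are
#' an error.
#'
#' @param path Path to a TSV file.
#' @param sample_col,time_col,status_col Column names.
#' @param status_map Named numeric vector mapping status strings (matched
#'   case-insensitively) to 0/1.
#' @return A tibble with columns `sample`, `time` (numeric, > 0), `status`
#'   (integer 0/1).
#' @export
read_clinical <- function(path, sample_col = "sample", time_col = "time",
                          status_col = "status",
                          status_map = c(DEAD = 1, DECEASED = 1, `1` = 1,
                                         ALIVE = 0, LIVING = 0, `0` = 0)) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(c(sample_col, time_col, status_col), names(raw))
  if (length(missing) > 0L) {
    abort(paste0("clinical table lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl <- tibble(sample = as.character(raw[[sample_col]]),
                time_raw = trimws(as.character(raw[[time_col]])),
                status_raw = trimws(as.character(raw[[status_col]])))
  n0 <- nrow(tbl)
  tbl <- filter(tbl, !is.na(.data$time_raw), .data$time_raw != "",
                !is.na(.data$status_raw), .data$status_raw != "")
  dropped <- n0 - nrow(tbl)
  if (dropped > 0L) {
    inform(sprintf("dropped %d patient(s) with unspecified survival time or vital status", dropped))
  }
  time <- suppressWarnings(as.numeric(tbl$time_raw))
  if (anyNA(time)) abort("non-numeric survival time value(s)")
  if (any(time <= 0)) abort("survival times must be positive")
  status_key <- toupper(tbl$status_raw)
  status <- unname(status_map[status_key])
  if (anyNA(status)) {
    abort(paste0("unmapped vital status value(s): ",
                 paste(unique(tbl$status_raw[is.na(status)]), collapse = ", ")))
  }
  tibble(sample = tbl$sample, time = time, status = as.integer(status))
}

#' Read a plain gene list
#'
#' One symbol per line; `#` starts a comment; blank lines ignored; symbols
#' are whitespace-trimmed and uppercased; duplicates collapse.
#'
#' @param path Path to the list file.
#' @return A character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  genes <- toupper(trimws(lines))
  genes <- unique(genes[genes != ""])
  if (length(genes) == 0L) abort("gene list is empty")
  genes
}
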