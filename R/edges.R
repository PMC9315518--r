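#' Canonical edge identifiers
#'
#' Pathway edges are unordered gene pairs. Throughout the package an edge is
#' keyed by its canonical id: the two (uppercased) gene symbols joined by
#' `"|"` with the lexicographically smaller symbol first, so `("TP53",
#' "EGFR")` and `("EGFR", "TP53")` map to the same id `"EGFR|TP53"`.
#'
#' @param gene_a,gene_b Character vectors of gene symbols (recycled to a
#'   common length).
#' @return `edge_id()` returns a character vector of canonical ids;
#'   `edge_genes()` returns a tibble with columns `edge`, `gene_a`, `gene_b`
#'   (`gene_a < gene_b`).
#' @examples
#' edge_id(c("TP53", "EGFR"), c("EGFR", "TP53"))
#' edge_genes("EGFR|TP53")
#' @export
edge_id <- function(gene_a, gene_b) {
  a <- toupper(trimws(as.character(gene_a)))
  b <- toupper(trimws(as.character(gene_b)))
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' @param edge Character vector of canonical edge ids (`"GENEA|GENEB"`).
#' @rdname edge_id
#' @export
edge_genes <- function(edge) {
  parts <- stringr::str_split_fixed(edge, stringr::fixed("|"), 2)
  tibble(edge = edge, gene_a = parts[, 1], gene_b = parts[, 2])
}

# Internal: canonicalize a pathway edge table (pathway, gene_a, gene_b),
# dropping self-loops (with a warning) and within-pathway duplicates.
canonicalize_edges <- function(tbl) {
  tbl <- tbl |>
    mutate(
      gene_a = toupper(trimws(.data$gene_a)),
      gene_b = toupper(trimws(.data$gene_b))
    )
  loops <- tbl$gene_a == tbl$gene_b
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop edge(s)", sum(loops)))
    tbl <- tbl[!loops, , drop = FALSE]
  }
  tbl |>
    mutate(
      a = pmin(.data$gene_a, .data$gene_b),
      b = pmax(.data$gene_a, .data$gene_b),
      gene_a = .data$a, gene_b = .data$b,
      edge = paste(.data$a, .data$b, sep = "|")
    ) |>
    select(-"a", -"b") |>
    distinct(.data$pathway, .data$edge, .keep_all = TRUE) |>
    arrange(.data$pathway, .data$edge)
}
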