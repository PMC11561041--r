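#' Load a weighted gene interaction network from an edge list
#'
#' Reads a STRING-style whitespace- or tab-delimited edge list with columns
#' `gene1, gene2[, confidence]` and returns a tidy undirected network.
#' Confidence scores given on the common 0-1000 integer scale are rescaled to
#' 0-1 automatically (any value above 1 triggers the rescale). Edges at or
#' below `min_confidence` are removed (strict `>` filtering, matching the
#' convention of keeping STRING edges with confidence greater than 0.700),
#' self-loops are dropped, duplicated pairs keep the maximum confidence and
#' genes left without any edge are discarded so that every retained gene
#' participates in message passing.
#'
#' @param path Path to a 2- or 3-column delimited edge list. A header line is
#'   auto-detected and skipped. A missing third column means confidence 1.
#' @param min_confidence Keep edges with confidence strictly greater than
#'   this value (on the 0-1 scale). Default 0 keeps everything.
#' @return A `gene_network`: a tibble with columns `from`, `to`, `confidence`
#'   (one row per undirected edge, `from < to` lexicographically).
#' @examples
#' f <- tempfile()
#' writeLines(c("a b 900", "b c 650", "a a 999"), f)
#' net <- load_edge_list(f, min_confidence = 0.7)
#' net
#' @export
load_edge_list <- function(path, min_confidence = 0) {
  assert_scalar_number(min_confidence, "min_confidence", 0, 1)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("empty edge list file")
  fields <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    abort(sprintf("malformed edge list line %d: %s", bad[1], lines[bad[1]]))
  }
  g1 <- vapply(fields, `[[`, "", 1L)
  g2 <- vapply(fields, `[[`, "", 2L)
  cf <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else "1", "")
  conf <- suppressWarnings(as.numeric(cf))
  # header detection: first line with a non-numeric third column, or 2-col
  # file whose first line repeats known column names
  start <- 1L
  if (is.na(conf[1]) ||
      (nf[1] == 2L && tolower(g1[1]) %in% c("gene1", "from", "protein1", "source"))) {
    start <- 2L
    if (length(lines) < 2L) abort("edge list contains only a header")
  }
  if (anyNA(conf[start:length(conf)])) {
    bad <- start - 1L + which(is.na(conf[start:length(conf)]))[1]
    abort(sprintf("malformed edge list line %d: non-numeric confidence", bad))
  }
  edges <- tibble(
    from = g1[start:length(g1)],
    to = g2[start:length(g2)],
    confidence = conf[start:length(conf)]
  )
  as_gene_network(edges, min_confidence = min_confidence)
}

#' Build a gene network from an edge data frame
#'
#' Applies the normalization rules of [load_edge_list()] (0-1000 rescale,
#' strict confidence filter, self-loop and duplicate removal) to an in-memory
#' edge table.
#'
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `confidence` (default 1).
#' @inheritParams load_edge_list
#' @return A `gene_network` tibble.
#' @export
as_gene_network <- function(edges, min_confidence = 0) {
  edges <- as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` needs columns from, to")
  }
  if (!"confidence" %in% names(edges)) edges$confidence <- 1
  if (any(edges$confidence < 0)) abort("negative confidence score")
  if (any(edges$confidence > 1)) edges$confidence <- edges$confidence / 1000
  if (any(edges$confidence > 1)) abort("confidence above 1000; unknown scale")
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  net <- tibble(from = a, to = b, confidence = edges$confidence) |>
    filter(.data$from != .data$to) |>
    arrange(desc(.data$confidence)) |>
    distinct(.data$from, .data$to, .keep_all = TRUE) |>
    filter(.data$confidence > min_confidence) |>
    arrange(.data$from, .data$to)
  if (nrow(net) == 0L) {
    abort("network is empty after confidence filtering")
  }
  tibble::new_tibble(net, class = "gene_network")
}

#' Genes present in a network
#'
#' @param network A `gene_network`.
#' @return Sorted character vector of gene identifiers (every gene has at
#'   least one edge; isolated genes are dropped at load time).
#' @export
network_genes <- function(network) {
  sort(unique(c(network$from, network$to)))
}

# igraph view of a gene_network; vertex order = network_genes(network)
network_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = network_genes(network))
  )
  igraph::E(g)$weight <- network$confidence
  g
}

#' Load a plain-text gene list
#'
#' One identifier per line; blank lines and `#` comments are ignored and
#' surrounding whitespace is trimmed.
#'
#' @param path File path.
#' @return Character vector of unique gene identifiers, in first-seen order.
#' @export
load_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genes <- unique(lines)
  if (length(genes) == 0L) abort(sprintf("no gene identifiers in '%s'", path))
  genes
}

#' Read and write gene rankings
#'
#' Rankings are TSV files with columns `rank`, `gene`, `score`; writing then
#' reading is the identity.
#'
#' @param ranking A `gene_ranking` tibble (columns `rank`, `gene`, `score`).
#' @param path File path.
#' @return `write_ranking()` returns `path` invisibly; `read_ranking()`
#'   returns a `gene_ranking` tibble.
#' @export
write_ranking <- function(ranking, path) {
  validate_ranking(ranking)
  readr::write_tsv(as_tibble(ranking)[, c("rank", "gene", "score")], path)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    rank = readr::col_integer(),
    gene = readr::col_character(),
    score = readr::col_double()
  ))
  out <- tibble::new_tibble(
    list(rank = x$rank, gene = x$gene, score = x$score),
    nrow = nrow(x), class = "gene_ranking"
  )
  validate_ranking(out)
  out
}

#' Read a differential-expression table
#'
#' Expects a TSV with header `gene, log2FC, pvalue, padj` (case-insensitive;
#' `log2FoldChange` accepted for `log2FC`).
#'
#' @param path File path.
#' @return Tibble with columns `gene`, `log2fc`, `pvalue`, `padj`.
#' @export
read_deg_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols())
  nm <- tolower(names(x))
  nm[nm == "log2foldchange"] <- "log2fc"
  names(x) <- nm
  need <- c("gene", "log2fc", "pvalue", "padj")
  if (!all(need %in% nm)) {
    abort(sprintf(
      "DEG table must have columns gene, log2FC, pvalue, padj (found: %s)",
      paste(names(x), collapse = ", ")
    ))
  }
  if (anyDuplicated(x$gene)) abort("duplicated gene identifiers in DEG table")
  as_tibble(x[, need])
}
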