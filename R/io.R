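#' Read an expression intensity matrix from TSV
#'
#' First column = probe ids, remaining columns = patients, as written by
#' [write_matrix_tsv()].
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with probe rownames.
#' @export
read_expression_matrix <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a matrix as TSV with an id column
#'
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id_name Header of the id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-entity map from TSV
#'
#' Columns `probe_id`, `entity_id`, `entity_class`.
#'
#' @param path Path to the TSV file.
#' @return Validated probe map data frame.
#' @export
read_probe_map <- function(path) {
  validate_probe_map(read.delim(path, stringsAsFactors = FALSE))
}

#' Export a network in GraphML format
#'
#' @param net A `grn` or `core_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- if (inherits(net, "grn") || inherits(net, "core_network")) net$graph else net
  stopifnot(igraph::is_igraph(g))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
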