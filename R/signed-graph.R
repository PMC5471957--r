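#' Construct a signed weighted graph
#'
#' A signed graph is an undirected [igraph::igraph] object whose vertices are
#' named by unique, non-empty strings and whose edges carry a numeric
#' `weight` attribute with `0 < |weight| <= 1`.  Positive weights model
#' cooperation (e.g. positive co-occurrence correlation between two bacterial
#' taxa), negative weights competition.  Self-loops, parallel edges and
#' zero weights are rejected so that data errors surface instead of being
#' silently dropped.
#'
#' @param edges a data frame (or coercible) whose first three columns are
#'   source node, target node and weight.
#' @param nodes optional character vector of node identifiers; nodes that
#'   appear in `edges` are added automatically, so this is only needed for
#'   isolated nodes.
#' @return a validated undirected igraph object with a `weight` edge
#'   attribute ("signed graph").
#' @examples
#' g <- signed_graph(data.frame(from = c("A", "A"), to = c("B", "C"),
#'                              weight = c(0.2, -0.8)))
#' igraph::E(g)$weight
#' @export
signed_graph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 3L)
    stop("`edges` needs at least three columns: source, target, weight")
  df <- data.frame(from = as.character(edges[[1L]]),
                   to = as.character(edges[[2L]]),
                   weight = as.numeric(edges[[3L]]),
                   stringsAsFactors = FALSE)
  vertices <- unique(c(df$from, df$to, as.character(nodes)))
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = if (length(vertices)) vertices)
  validate_signed_graph(g)
}

#' Coerce to a signed graph
#'
#' @param x an igraph object (undirected, named vertices, `weight` edge
#'   attribute) or an edge data frame.
#' @return a validated signed graph.
#' @export
as_signed_graph <- function(x) {
  if (igraph::is_igraph(x)) return(validate_signed_graph(x))
  signed_graph(x)
}

#' Validate the signed-graph invariants
#'
#' Checks that `g` is undirected, has unique non-empty vertex names, no
#' self-loops, no parallel edges, and weights `w` with `0 < |w| <= 1`.
#' The closed endpoints `|w| = 1` are admitted (correlation networks reach
#' them); path products then need not strictly shrink with length.
#'
#' @param g an igraph object.
#' @return `g`, invisibly usable, on success; otherwise an error.
#' @export
validate_signed_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop("not an igraph object")
  if (igraph::is_directed(g))
    stop("signed graphs are undirected; got a directed graph")
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm)))
    stop("every node needs a non-empty string identifier")
  if (anyDuplicated(nm)) stop("duplicate node identifiers: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(igraph::which_loop(g))) stop("self-loops are not allowed")
  if (igraph::any_multiple(g)) stop("duplicate edges for the same node pair")
  if (igraph::ecount(g) > 0L) {
    w <- igraph::E(g)$weight
    if (is.null(w)) stop("edges need a numeric 'weight' attribute")
    if (!is.numeric(w) || anyNA(w) || any(!is.finite(w)))
      stop("edge weights must be finite numbers")
    if (any(w == 0)) stop("zero edge weights are not allowed")
    if (any(abs(w) > 1)) stop("edge weights must satisfy |w| <= 1")
  }
  g
}

#' Read a signed graph from a delimited edge list
#'
#' Each non-comment line holds at least three fields: source, target,
#' weight.  Lines whose first non-blank character is `#` and blank lines are
#' skipped.  Duplicate undirected pairs and self-loops are errors.
#'
#' @param path file path.
#' @param delimiter field separator, tab by default (use `","` for CSV).
#' @return a signed graph.
#' @export
read_edge_list <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no edges found in ", path)
  parts <- strsplit(lines[idx], delimiter, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed line ", idx[which(nf < 3L)[1L]], " in ", path,
         ": expected at least 3 fields (source, target, weight)")
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(w))
    stop("malformed line ", idx[which(is.na(w))[1L]], " in ", path,
         ": weight is not a number")
  key <- paste(pmin(from, to), pmax(from, to))
  if (anyDuplicated(key))
    stop("duplicate edge for pair (",
         sub(" ", ", ", key[duplicated(key)][1L]), ") in ", path)
  signed_graph(data.frame(from = from, to = to, weight = w))
}

#' Write a signed graph as a tab-separated edge list
#'
#' Weights are printed with full double precision so that
#' `read_edge_list(write_edge_list(g))` round-trips exactly.
#'
#' @param graph a signed graph.
#' @param path output file path.
#' @param delimiter field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path, delimiter = "\t") {
  g <- as_signed_graph(graph)
  el <- igraph::as_edgelist(g, names = TRUE)
  header <- paste("# source", "target", "weight", sep = delimiter)
  if (nrow(el)) {
    body <- paste(el[, 1L], el[, 2L],
                  sprintf("%.17g", igraph::E(g)$weight), sep = delimiter)
    writeLines(c(header, body), path)
  } else {
    writeLines(header, path)
  }
  invisible(path)
}

#' Read a signed graph from GraphML
#'
#' The file must describe an undirected graph with a real-valued edge
#' attribute named `weight`; this is the format exchanged with Cytoscape.
#'
#' @param path GraphML file path.
#' @return a signed graph.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g))
    stop("GraphML file declares a directed graph; signed graphs are undirected")
  if (igraph::ecount(g) > 0L && is.null(igraph::E(g)$weight))
    stop("GraphML file lacks an edge attribute named 'weight'")
  if (is.null(igraph::V(g)$name)) {
    id <- igraph::vertex_attr(g, "id")
    igraph::V(g)$name <- if (!is.null(id)) id else as.character(seq_len(igraph::vcount(g)))
  }
  validate_signed_graph(g)
}

#' Write a signed graph to GraphML
#'
#' @param graph a signed graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  g <- as_signed_graph(graph)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# radix (code-point) order, independent of locale; used for every tie-break
lex_order <- function(x) order(x, method = "radix")

lex_sort <- function(x) sort(x, method = "radix")
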