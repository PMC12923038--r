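#' Weighted undirected network
#'
#' Light container used for every network layer in the pipeline (disease
#' similarity network, shared-gene enhancer network, sequence-similarity
#' enhancer network).  Holds a symmetric, non-negative adjacency matrix with
#' a zero diagonal over a fixed, named node set; isolated nodes are kept.
#'
#' @param nodes character vector of unique node identifiers.
#' @param adj numeric matrix, `length(nodes)` square; symmetrized dimnames
#'   are set from `nodes`.  Must be symmetric and non-negative with zero
#'   diagonal.
#' @param layer short label naming the layer (e.g. `"gEnhNet"`).
#' @param edge_data optional data.frame of per-edge annotations (audit
#'   trail, e.g. hypergeometric p-values).
#' @return an object of class `weighted_network`.
#' @export
weighted_network <- function(nodes, adj, layer = "network", edge_data = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids in network")
  adj <- as.matrix(adj)
  if (nrow(adj) != length(nodes) || ncol(adj) != length(nodes))
    stop("adjacency dimensions do not match node set")
  if (any(adj < 0)) stop("negative edge weights are not allowed")
  if (length(nodes) && max(abs(adj - t(adj))) > 1e-9)
    stop("adjacency matrix must be symmetric")
  adj <- (adj + t(adj)) / 2
  diag(adj) <- 0
  dimnames(adj) <- list(nodes, nodes)
  structure(list(nodes = nodes, adj = adj, layer = layer,
                 edge_data = edge_data),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<%s> %d nodes, %d edges\n", x$layer, length(x$nodes),
              network_edge_count(x)))
  invisible(x)
}

#' Number of (undirected) edges with positive weight
#' @param net a [weighted_network()].
#' @return integer edge count.
#' @export
network_edge_count <- function(net) {
  sum(net$adj[upper.tri(net$adj)] > 0)
}

#' Edge list of a network
#'
#' @param net a [weighted_network()].
#' @return data.frame with columns `from`, `to`, `weight`, one row per
#'   undirected edge (from < to lexicographically).
#' @export
network_edges <- function(net) {
  ut <- which(upper.tri(net$adj) & net$adj > 0, arr.ind = TRUE)
  data.frame(from = net$nodes[ut[, 1L]], to = net$nodes[ut[, 2L]],
             weight = net$adj[ut], stringsAsFactors = FALSE)
}

#' Write a network as a headered edge-list TSV
#'
#' The node universe (including isolated nodes) is preserved in a
#' `# nodes:` comment line so that [read_network()] round-trips exactly.
#'
#' @param net a [weighted_network()].
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# layer: ", net$layer), con)
  writeLines(paste0("# nodes: ", paste(net$nodes, collapse = "\t")), con)
  ed <- network_edges(net)
  writeLines("from\tto\tweight", con)
  if (nrow(ed))
    writeLines(sprintf("%s\t%s\t%.10g", ed$from, ed$to, ed$weight), con)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path edge-list TSV path.
#' @return a [weighted_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  layer <- "network"
  nodes <- NULL
  hdr <- grep("^#", lines)
  for (i in hdr) {
    if (grepl("^# layer: ", lines[i]))
      layer <- sub("^# layer: ", "", lines[i])
    if (grepl("^# nodes: ", lines[i]))
      nodes <- strsplit(sub("^# nodes: ", "", lines[i]), "\t", fixed = TRUE)[[1L]]
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  ed <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses =
                            c("character", "character", "numeric"))
  if (is.null(nodes)) nodes <- sort(unique(c(ed$from, ed$to)))
  adj <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(ed)) {
    adj[cbind(ed$from, ed$to)] <- ed$weight
    adj[cbind(ed$to, ed$from)] <- ed$weight
  }
  weighted_network(nodes, adj, layer = layer)
}
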