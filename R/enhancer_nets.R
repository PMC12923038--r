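#' Enhancer catalog
#'
#' Enhancer identifiers with their target-gene sets (and optionally
#' genomic intervals).  The gene universe defaults to all genes annotated
#' to any enhancer in the catalog; it is the background for the
#' hypergeometric overlap tests.
#'
#' @param targets named list: enhancer id -> character vector of target
#'   genes (may be empty).
#' @param intervals optional [genomic_intervals()] data.frame whose `id`
#'   column matches enhancer ids.
#' @param gene_universe optional character vector; default is the union of
#'   all target sets.
#' @return object of class `enhancer_catalog`.
#' @export
enhancer_catalog <- function(targets, intervals = NULL, gene_universe = NULL) {
  ids <- names(targets)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("targets must be a named list with unique enhancer ids")
  targets <- lapply(targets, function(g) unique(as.character(g)))
  if (is.null(gene_universe))
    gene_universe <- sort(unique(unlist(targets, use.names = FALSE)))
  stray <- setdiff(unlist(targets, use.names = FALSE), gene_universe)
  if (length(stray))
    stop("target genes outside the gene universe: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  structure(list(ids = ids, targets = targets, intervals = intervals,
                 gene_universe = gene_universe),
            class = "enhancer_catalog")
}

#' @export
print.enhancer_catalog <- function(x, ...) {
  cat(sprintf("<enhancer_catalog> %d enhancers, %d genes in universe\n",
              length(x$ids), length(x$gene_universe)))
  invisible(x)
}

#' Hypergeometric overlap p-value for two gene sets
#'
#' Upper-tail probability of observing at least `k` shared genes between
#' target sets of sizes `n_i` and `n_j` drawn from a universe of
#' `n_universe` genes:
#' `p = sum_{i=k}^{min(n_i, n_j)} C(n_j, i) C(n - n_j, n_i - i) / C(n, n_i)`.
#'
#' @param n_universe gene universe size.
#' @param n_i,n_j target-set sizes.
#' @param k observed overlap.
#' @return p-value in `[0, 1]`; exactly 1 when `k = 0`.
#' @export
hypergeometric_overlap_pvalue <- function(n_universe, n_i, n_j, k) {
  n_universe <- as.integer(n_universe); n_i <- as.integer(n_i)
  n_j <- as.integer(n_j); k <- as.integer(k)
  if (n_i > n_universe || n_j > n_universe)
    stop("target-set size exceeds the gene universe")
  if (k < 0L || k > min(n_i, n_j))
    stop("overlap k must lie in [0, min(n_i, n_j)]")
  if (k < n_i + n_j - n_universe)
    stop("infeasible configuration: overlap below the forced minimum ",
         n_i + n_j - n_universe)
  if (k == 0L) return(1)
  # upper tail P(X >= k) with X ~ Hypergeometric(n_j successes, n_i draws)
  stats::phyper(k - 1L, m = n_j, n = n_universe - n_j, k = n_i,
                lower.tail = FALSE)
}

#' Build the shared-gene enhancer network (gEnhNet)
#'
#' Connects every unordered enhancer pair whose target-gene overlap is
#' hypergeometrically significant at level `alpha` (raw p-values by
#' default, the convention of the underlying method; Benjamini-Hochberg
#' correction can be switched on).  Edges are unweighted (weight 1); the
#' p-values are retained in the edge data for audit.  Enhancers with
#' empty target sets become isolated nodes.
#'
#' @param catalog an [enhancer_catalog()].
#' @param alpha significance cutoff, default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a [weighted_network()] with layer `"gEnhNet"`.
#' @export
build_shared_gene_network <- function(catalog, alpha = 0.05,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha < 1)
  ids <- catalog$ids
  n <- length(catalog$gene_universe)
  sizes <- lengths(catalog$targets[ids])
  np <- length(ids)
  pairs <- if (np >= 2L) utils::combn(np, 2L) else matrix(integer(), 2L, 0L)
  pv <- numeric(ncol(pairs)); kk <- integer(ncol(pairs))
  for (c_ in seq_len(ncol(pairs))) {
    a <- pairs[1L, c_]; b <- pairs[2L, c_]
    if (sizes[a] == 0L || sizes[b] == 0L) { pv[c_] <- 1; next }
    k <- length(intersect(catalog$targets[[ids[a]]], catalog$targets[[ids[b]]]))
    kk[c_] <- k
    pv[c_] <- hypergeometric_overlap_pvalue(n, sizes[a], sizes[b], k)
  }
  p_eff <- if (adjust == "BH") stats::p.adjust(pv, "BH") else pv
  keep <- p_eff <= alpha
  adj <- matrix(0, np, np, dimnames = list(ids, ids))
  if (any(keep)) {
    sel <- pairs[, keep, drop = FALSE]
    adj[cbind(sel[1L, ], sel[2L, ])] <- 1
    adj[cbind(sel[2L, ], sel[1L, ])] <- 1
  }
  edge_data <- data.frame(from = ids[pairs[1L, keep]],
                          to = ids[pairs[2L, keep]],
                          shared = kk[keep], p = pv[keep],
                          stringsAsFactors = FALSE)
  weighted_network(ids, adj, layer = "gEnhNet", edge_data = edge_data)
}

#' Surrogate pairwise sequence similarity (percent identity)
#'
#' Global-alignment percent identity under unit match and zero
#' mismatch/indel scoring, with diagonal-preferring traceback: the score
#' is the maximal number of matched columns, divided by the alignment
#' length.  This is a deterministic, symmetric stand-in for an external
#' aligner's percent-identity output, used by the fixture generator and
#' tests; real analyses ingest a similarity matrix file instead.
#'
#' @param seq_a,seq_b non-empty nucleotide strings over ACGTN (case
#'   insensitive; `N` matches nothing).
#' @return similarity score in `[0, 100]`.
#' @export
surrogate_sequence_similarity <- function(seq_a, seq_b) {
  nw_percent_identity(toupper(seq_a), toupper(seq_b))
}

#' All-pairs surrogate similarity matrix
#' @param seqs named character vector of sequences.
#' @return symmetric numeric matrix (diagonal 100) with sequence names.
#' @export
sequence_similarity_matrix <- function(seqs) {
  mat <- nw_identity_matrix(toupper(unname(seqs)))
  dimnames(mat) <- list(names(seqs), names(seqs))
  mat
}

#' Build the sequence-similarity enhancer network (sEnhNet)
#'
#' The diagonal is discarded, enhancers whose similarity to every other
#' enhancer is zero are pruned, and the remaining strictly positive
#' scores become weighted edges (used as-is: downstream column
#' normalization makes within-layer scale irrelevant).
#'
#' @param simmat symmetric non-negative labelled similarity matrix.
#' @return a [weighted_network()] with layer `"sEnhNet"`; pruned ids are
#'   attached as attribute `"pruned"`.
#' @export
build_sequence_network <- function(simmat) {
  if (is.null(rownames(simmat))) stop("similarity matrix must be labelled")
  if (any(simmat < 0)) stop("negative similarity entries are not allowed")
  if (max(abs(simmat - t(simmat))) > 1e-9)
    stop("similarity matrix must be symmetric")
  diag(simmat) <- 0
  keep <- rowSums(simmat) > 0
  pruned <- rownames(simmat)[!keep]
  simmat <- simmat[keep, keep, drop = FALSE]
  net <- weighted_network(rownames(simmat), simmat, layer = "sEnhNet")
  attr(net, "pruned") <- pruned
  net
}
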