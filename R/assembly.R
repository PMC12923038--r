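#' Align two enhancer layers onto a shared node universe
#'
#' The multiplex node universe is the (sorted) union of both layers'
#' enhancers; enhancers absent from a layer are added to it as isolated
#' nodes (zero rows/columns) so both layers are indexed identically.
#'
#' @param layer_g,layer_s [weighted_network()] objects.
#' @return list with `nodes` (shared universe) and padded adjacency
#'   matrices `A_g`, `A_s`.
#' @export
align_layers <- function(layer_g, layer_s) {
  nodes <- sort(union(layer_g$nodes, layer_s$nodes))
  pad <- function(net) {
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    A[net$nodes, net$nodes] <- net$adj
    A
  }
  list(nodes = nodes, A_g = pad(layer_g), A_s = pad(layer_s))
}

bipartite_matrix <- function(associations, enhancers, diseases) {
  B <- matrix(0, length(enhancers), length(diseases),
              dimnames = list(enhancers, diseases))
  if (!is.null(associations) && nrow(associations)) {
    keep <- associations$enhancer %in% enhancers &
      associations$disease %in% diseases
    a <- associations[keep, , drop = FALSE]
    B[cbind(a$enhancer, a$disease)] <- 1
  }
  B
}

#' Assemble a (multiplex-)heterogeneous supra system
#'
#' Builds the node-aligned layer adjacencies, the multiplex
#' supra-adjacency `A^M = [[(1-delta) A_g, delta I], [delta I,
#' (1-delta) A_s]]`, the bipartite coupling `B` from the association
#' table (replicated over layers), and the disease block, according to
#' `mode`:
#' \describe{
#'   \item{`"mulhet"`}{both enhancer layers + disease network (full model)}
#'   \item{`"het"`}{gene layer + disease network (heterogeneous baseline)}
#'   \item{`"mul"`}{both enhancer layers, no disease block}
#'   \item{`"gene"`, `"seq"`}{a single enhancer layer alone}
#' }
#'
#' @param associations data.frame with columns `disease`, `enhancer`
#'   (ignored by modes without a disease block).
#' @param gene_net,seq_net,disease_net [weighted_network()] layers as
#'   required by `mode`.
#' @param delta inter-layer jump probability in `[0, 1]` (two-layer
#'   modes only).
#' @param mode network configuration, see above.
#' @return object of class `supra_system`.
#' @export
build_supra_system <- function(associations = NULL, gene_net = NULL,
                               seq_net = NULL, disease_net = NULL,
                               delta = 0.5,
                               mode = c("mulhet", "het", "mul", "gene", "seq")) {
  mode <- match.arg(mode)
  stopifnot(delta >= 0, delta <= 1)
  two_layer <- mode %in% c("mulhet", "mul")
  has_disease <- mode %in% c("mulhet", "het")

  if (two_layer) {
    if (is.null(gene_net) || is.null(seq_net))
      stop("mode ", mode, " needs both gene_net and seq_net")
    al <- align_layers(gene_net, seq_net)
    nodes <- al$nodes
    layers <- list(gene = al$A_g, seq = al$A_s)
    n <- length(nodes)
    I <- diag(n)
    A_M <- rbind(cbind((1 - delta) * al$A_g, delta * I),
                 cbind(delta * I, (1 - delta) * al$A_s))
  } else {
    layer_net <- switch(mode, het = gene_net, gene = gene_net, seq = seq_net)
    if (is.null(layer_net))
      stop("mode ", mode, " needs the corresponding layer network")
    nodes <- layer_net$nodes
    n <- length(nodes)
    layers <- stats::setNames(list(layer_net$adj),
                              if (mode == "seq") "seq" else "gene")
    A_M <- layer_net$adj
  }
  k <- length(layers)
  layer_names <- names(layers)
  supra_enh_names <- as.vector(vapply(layer_names, function(l)
    paste0(l, "::", nodes), character(n)))
  dimnames(A_M) <- list(supra_enh_names, supra_enh_names)

  if (has_disease) {
    if (is.null(disease_net)) stop("mode ", mode, " needs disease_net")
    diseases <- disease_net$nodes
    A_D <- disease_net$adj
    B <- bipartite_matrix(associations, nodes, diseases)
  } else {
    diseases <- character(0)
    A_D <- NULL
    B <- NULL
  }

  structure(list(mode = mode, nodes = nodes, n = n, k = k,
                 layer_names = layer_names, layers = layers,
                 delta = delta, A_M = A_M,
                 diseases = diseases, m = length(diseases),
                 A_D = A_D, B = B,
                 node_names = c(supra_enh_names, diseases)),
            class = "supra_system")
}

#' @export
print.supra_system <- function(x, ...) {
  cat(sprintf("<supra_system mode=%s> %d enhancers x %d layer(s), %d disease(s); delta=%g\n",
              x$mode, x$n, x$k, x$m, x$delta))
  invisible(x)
}

#' Replace the bipartite coupling of a supra system
#'
#' Rebuilds `B` from a (possibly pruned) association table without
#' touching the layer adjacencies; used by cross-validation to exclude
#' held-out associations.
#'
#' @param sys a [build_supra_system()] object.
#' @param associations association data.frame.
#' @return the updated system.
#' @export
set_associations <- function(sys, associations) {
  if (sys$m == 0L) return(sys)
  sys$B <- bipartite_matrix(associations, sys$nodes, sys$diseases)
  sys
}

#' Full supra-adjacency matrix A^MH
#'
#' `[[A^M, B^MH], [(B^MH)^T, A^D]]` where `B^MH` stacks one copy of the
#' bipartite matrix per enhancer layer (the couplings to both layers come
#' from the same association set).  Symmetric by construction.
#'
#' @param sys a [build_supra_system()] object.
#' @return numeric matrix of size `(k n + m)` with node-name dimnames.
#' @export
build_supra_adjacency <- function(sys) {
  if (sys$m == 0L) return(sys$A_M)
  BMH <- do.call(rbind, rep(list(sys$B), sys$k))
  A <- rbind(cbind(sys$A_M, BMH),
             cbind(t(BMH), sys$A_D))
  dimnames(A) <- list(sys$node_names, sys$node_names)
  A
}

#' Column-stochastic transition operator
#'
#' Two conventions are available.  `"jump"` (default): from an
#' enhancer-side node carrying at least one bipartite link, the walker
#' moves to the disease side with probability `lambda` (proportionally to
#' its bipartite column) and stays within the multiplex with probability
#' `1 - lambda` (proportionally to its supra-adjacency column); a node
#' with no bipartite link keeps all its mass within the multiplex, and a
#' node connected only through the bipartite graph sends all its mass
#' across (provided `lambda > 0`; at `lambda = 0` the blocks are fully
#' decoupled and such a node is dangling).  The symmetric rule applies
#' on the disease side.
#' `"literal"`: the assembled supra-adjacency is column-normalized
#' directly and `lambda` is ignored.  In both conventions the multiplex
#' block is normalized as assembled, so `delta` interacts with node
#' degree.  Columns that are zero everywhere (fully isolated nodes) are
#' flagged as dangling and are resolved against the restart vector by the
#' walk itself (equivalent to an immediate restart).
#'
#' @param sys a [build_supra_system()] object.
#' @param lambda bipartite jump probability in `[0, 1]`.
#' @param normalization `"jump"` or `"literal"`.
#' @return object of class `transition_op`: list with the matrix `M`,
#'   logical `dangling`, and the node names.
#' @export
build_transition <- function(sys, lambda = 0.5,
                             normalization = c("jump", "literal")) {
  normalization <- match.arg(normalization)
  stopifnot(lambda >= 0, lambda <= 1)
  kn <- sys$k * sys$n
  m <- sys$m
  N <- kn + m
  M <- matrix(0, N, N, dimnames = list(sys$node_names, sys$node_names))
  dangling <- logical(N)

  if (m == 0L) {
    cs <- colSums(sys$A_M)
    pos <- cs > 0
    M[, pos] <- sweep(sys$A_M[, pos, drop = FALSE], 2L, cs[pos], "/")
    dangling[!pos] <- TRUE
  } else if (normalization == "literal") {
    A <- build_supra_adjacency(sys)
    cs <- colSums(A)
    pos <- cs > 0
    M[, pos] <- sweep(A[, pos, drop = FALSE], 2L, cs[pos], "/")
    dangling[!pos] <- TRUE
  } else {
    BMH <- do.call(rbind, rep(list(sys$B), sys$k))   # kn x m
    am_cs <- colSums(sys$A_M)                        # within-multiplex mass
    b_rs <- rowSums(BMH)                             # enhancer-side bipartite
    for (j in seq_len(kn)) {
      w_within <- (1 - lambda) * (am_cs[j] > 0)
      w_cross <- lambda * (b_rs[j] > 0)
      if (w_within + w_cross == 0) { dangling[j] <- TRUE; next }
      if (w_within > 0)
        M[seq_len(kn), j] <- w_within / (w_within + w_cross) *
          sys$A_M[, j] / am_cs[j]
      if (w_cross > 0)
        M[kn + seq_len(m), j] <- w_cross / (w_within + w_cross) *
          BMH[j, ] / b_rs[j]
    }
    ad_cs <- colSums(sys$A_D)
    b_cs <- colSums(BMH)                             # disease-side bipartite
    for (jd in seq_len(m)) {
      j <- kn + jd
      w_within <- (1 - lambda) * (ad_cs[jd] > 0)
      w_cross <- lambda * (b_cs[jd] > 0)
      if (w_within + w_cross == 0) { dangling[j] <- TRUE; next }
      if (w_within > 0)
        M[kn + seq_len(m), j] <- w_within / (w_within + w_cross) *
          sys$A_D[, jd] / ad_cs[jd]
      if (w_cross > 0)
        M[seq_len(kn), j] <- w_cross / (w_within + w_cross) *
          BMH[, jd] / b_cs[jd]
    }
  }
  structure(list(M = M, dangling = dangling, node_names = sys$node_names,
                 normalization = normalization, lambda = lambda),
            class = "transition_op")
}

#' Restart (initial probability) vector
#'
#' Seed enhancers receive a uniform distribution replicated in every
#' enhancer layer, weighted `tau` (gene layer) and `1 - tau` (sequence
#' layer) and scaled by `1 - eta`; seed diseases receive a uniform
#' distribution scaled by `eta`.  If one seed side is empty, its mass is
#' renormalized onto the other side; both sides empty is an error.
#' Single-layer systems ignore `tau`; systems without a disease block
#' ignore `eta`.
#'
#' @param sys a [build_supra_system()] object.
#' @param seed_enhancers character vector of seed enhancer ids.
#' @param seed_diseases character vector of seed disease ids.
#' @param tau gene-layer restart weight in `[0, 1]`.
#' @param eta disease-side restart weight in `[0, 1]`.
#' @return named probability vector of length `k n + m` summing to 1.
#' @export
build_restart_vector <- function(sys, seed_enhancers,
                                 seed_diseases = character(0),
                                 tau = 0.5, eta = 0.5) {
  stopifnot(tau >= 0, tau <= 1, eta >= 0, eta <= 1)
  seed_enhancers <- unique(as.character(seed_enhancers))
  seed_diseases <- unique(as.character(seed_diseases))
  drop_e <- setdiff(seed_enhancers, sys$nodes)
  if (length(drop_e)) {
    warning("seed enhancer(s) not in node universe dropped: ",
            paste(drop_e, collapse = ", "))
    seed_enhancers <- intersect(seed_enhancers, sys$nodes)
  }
  drop_d <- setdiff(seed_diseases, sys$diseases)
  if (length(drop_d)) {
    if (sys$m > 0L)
      warning("seed disease(s) not in disease network dropped: ",
              paste(drop_d, collapse = ", "))
    seed_diseases <- intersect(seed_diseases, sys$diseases)
  }
  ne <- length(seed_enhancers); nd <- length(seed_diseases)
  if (ne == 0L && nd == 0L) stop("no usable seeds (both seed sets empty)")

  w_enh <- if (sys$m == 0L || nd == 0L) 1 else if (ne == 0L) 0 else 1 - eta
  w_dis <- 1 - w_enh
  kn <- sys$k * sys$n
  p0 <- stats::setNames(numeric(kn + sys$m), sys$node_names)
  if (ne > 0L && w_enh > 0) {
    idx <- match(seed_enhancers, sys$nodes)
    if (sys$k == 2L) {
      p0[idx] <- w_enh * tau / ne
      p0[sys$n + idx] <- w_enh * (1 - tau) / ne
    } else {
      p0[idx] <- w_enh / ne
    }
  }
  if (nd > 0L && w_dis > 0)
    p0[kn + match(seed_diseases, sys$diseases)] <- w_dis / nd
  if (sum(p0) == 0) stop("restart vector has no mass (check tau/eta)")
  p0 / sum(p0)
}
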