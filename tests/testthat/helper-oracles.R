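# Independent brute-force oracles and tiny generators used across tests.
# Each oracle re-derives the quantity from first principles, sharing no
# code path with the implementation it checks.

# --- ontology oracles -------------------------------------------------

oracle_descendants <- function(dag, term) {
  seen <- character(0)
  queue <- term
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    queue <- c(queue, dag$children[[t]])
  }
  seen
}

oracle_ancestors <- function(dag, term) {
  seen <- character(0)
  queue <- term
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    queue <- c(queue, dag$parents[[t]])
  }
  seen
}

oracle_cum_count <- function(dag, annotations, term) {
  desc <- oracle_descendants(dag, term)
  length(unique(annotations$gene[annotations$term %in% desc]))
}

oracle_ic <- function(dag, annotations, term) {
  f <- oracle_cum_count(dag, annotations, term)
  froot <- oracle_cum_count(dag, annotations, dag$root)
  if (f == 0) Inf else -log(f / froot)
}

oracle_resnik <- function(dag, annotations, ti, tj) {
  if (!is.finite(oracle_ic(dag, annotations, ti)) ||
      !is.finite(oracle_ic(dag, annotations, tj))) return(NA_real_)
  common <- intersect(oracle_ancestors(dag, ti), oracle_ancestors(dag, tj))
  if (!length(common)) return(0)
  max(vapply(common, oracle_ic, 0, dag = dag, annotations = annotations))
}

# random rooted DAG: term i (i >= 2) draws 1-2 parents among earlier terms
random_dag <- function(n_terms, seed) {
  withr::with_seed(seed, {
    terms <- sprintf("t%02d", seq_len(n_terms))
    parents <- c(list(character(0)), lapply(seq_len(n_terms)[-1L], function(i) {
      np <- sample(1:min(2L, i - 1L), 1L)
      terms[sample(i - 1L, np)]
    }))
    names(parents) <- terms
    dag <- ontology_dag(terms, parents)
    n_ann <- sample(seq_len(n_terms), 1L)
    ann <- data.frame(
      term = sample(terms, n_ann, replace = TRUE),
      gene = sprintf("g%02d", sample(2L * n_terms, n_ann, replace = TRUE)),
      stringsAsFactors = FALSE)
    # guarantee the root closure is annotated
    ann <- rbind(ann, data.frame(term = terms[n_terms], gene = "g_anchor"))
    list(dag = dag, annotations = unique(ann))
  })
}

# diamond: root -> a, root -> b, both -> x
diamond_dag <- function() {
  ontology_dag(c("root", "a", "b", "x"),
               list(root = character(0), a = "root", b = "root",
                    x = c("a", "b")))
}

# --- hypergeometric enumeration oracle --------------------------------

# tail P(overlap >= k) by enumerating all C(n, n_i) equally likely draws
oracle_hypergeom_tail <- function(n, n_i, n_j, k) {
  if (k == 0L) return(1)
  cmb <- utils::combn(n, n_i)
  ov <- colSums(cmb <= n_j)       # genes 1..n_j are the second target set
  mean(ov >= k)
}

# --- AUC oracle -------------------------------------------------------

oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# --- random multiplex-heterogeneous systems ---------------------------

random_sym_adj <- function(nodes, density, seed_offset = 0) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (n >= 2L) {
    ut <- upper.tri(A)
    w <- stats::runif(sum(ut))
    on <- stats::runif(sum(ut)) < density
    A[ut] <- w * on
    A <- A + t(A)
  }
  A
}

random_system <- function(n, m, seed, delta = NULL) {
  withr::with_seed(seed, {
    enh <- sprintf("e%02d", seq_len(n))
    dis <- sprintf("d%02d", seq_len(m))
    gene_net <- weighted_network(enh, random_sym_adj(enh, 0.2), "gEnhNet")
    seq_net <- weighted_network(enh, random_sym_adj(enh, 0.3), "sEnhNet")
    disease_net <- weighted_network(dis, random_sym_adj(dis, 0.5), "disease")
    n_assoc <- max(1L, round(0.4 * n))
    assoc <- unique(data.frame(
      disease = sample(dis, n_assoc, replace = TRUE),
      enhancer = sample(enh, n_assoc, replace = TRUE),
      stringsAsFactors = FALSE))
    if (is.null(delta)) delta <- stats::runif(1)
    sys <- build_supra_system(assoc, gene_net = gene_net, seq_net = seq_net,
                              disease_net = disease_net, delta = delta,
                              mode = "mulhet")
    seeds_e <- sample(enh, max(1L, n %/% 10L))
    seeds_d <- sample(dis, 1L)
    list(sys = sys, assoc = assoc, gene_net = gene_net, seq_net = seq_net,
         disease_net = disease_net, seeds_e = seeds_e, seeds_d = seeds_d)
  })
}

# effective transition with dangling columns resolved against p0
resolved_matrix <- function(trans, p0) {
  M <- trans$M
  if (any(trans$dangling)) M[, trans$dangling] <- p0
  M
}

# tiny deterministic fixture for fast end-to-end tests
small_spec <- function(seed = 1L, regime = "A") {
  fixture_spec(n_terms = 15L, n_enhancers = 24L, n_modules = 4L,
               module_gene_pool = 12L, n_diseases = 4L,
               assoc_per_disease = 4L, base_seq_length = 40L,
               seq_length_step = 30L, regime = regime, seed = seed)
}
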