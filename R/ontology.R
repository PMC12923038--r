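#' Ontology DAG
#'
#' Rooted directed acyclic graph of ontology terms connected by is_a
#' relations, optionally carrying per-term gene annotations.  This is the
#' substrate for information-content (IC) and Resnik semantic similarity
#' computations used to build the disease similarity network.
#'
#' @param terms character vector of term ids.
#' @param parents named list mapping each term to the character vector of
#'   its is_a parents (empty for roots).
#' @param root optional root term id; required when the graph has more
#'   than one parentless term.
#' @return object of class `ontology_dag` with fields `terms`, `parents`,
#'   `children`, `root` and `topo` (topological order, parents first).
#' @export
ontology_dag <- function(terms, parents, root = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate term ids")
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) as.character(p[!is.na(p)]))
  unknown <- setdiff(unlist(parents), terms)
  if (length(unknown))
    stop("is_a parent(s) not defined as terms: ",
         paste(unknown, collapse = ", "))

  # Kahn's algorithm: detect cycles, produce parents-first order
  indeg <- vapply(parents, length, 1L)
  children <- lapply(terms, function(t) character())
  names(children) <- terms
  for (t in terms) for (p in parents[[t]])
    children[[p]] <- c(children[[p]], t)
  queue <- terms[indeg == 0L]
  topo <- character(0)
  indeg_work <- indeg
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      indeg_work[[ch]] <- indeg_work[[ch]] - 1L
      if (indeg_work[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < length(terms)) {
    cyc <- setdiff(terms, topo)
    edges <- unlist(lapply(cyc, function(t)
      paste(t, "is_a", intersect(parents[[t]], cyc))))
    stop("cycle detected among is_a relations:\n  ",
         paste(edges, collapse = "\n  "))
  }

  roots <- terms[indeg == 0L]
  if (is.null(root)) {
    if (length(roots) != 1L)
      stop("ontology has ", length(roots),
           " roots (", paste(roots, collapse = ", "),
           "); supply `root` explicitly")
    root <- roots
  } else if (!root %in% terms) {
    stop("designated root ", root, " is not a term")
  }

  structure(list(terms = terms, parents = parents, children = children,
                 root = root, topo = topo),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  n_edges <- sum(vapply(x$parents, length, 1L))
  cat(sprintf("<ontology_dag> %d terms, %d is_a edges, root = %s%s\n",
              length(x$terms), n_edges, x$root,
              if (is.null(x$ic)) "" else " (annotated)"))
  invisible(x)
}

#' Read an OBO file into an ontology DAG
#'
#' Parses `[Term]` stanzas, keeping only `id`, `is_a` and `is_obsolete`
#' tags; obsolete terms are dropped, as are is_a references to undefined
#' or obsolete terms (with a warning).  Cycles are rejected with the
#' offending edges listed.
#'
#' @param path OBO 1.2/1.4 file path.
#' @param root optional root term id (required for multi-rooted files).
#' @return an [ontology_dag()].
#' @export
read_obo <- function(path, root = NULL) {
  lines <- readLines(path)
  lines <- sub("\\s*!.*$", "", lines)      # strip trailing comments
  term_rows <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur) {
    if (!is.null(cur) && !is.null(cur$id) && !isTRUE(cur$obsolete))
      term_rows[[length(term_rows) + 1L]] <<- cur
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(cur); cur <- list(is_a = character()); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(cur); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^is_a:", ln))
      cur$is_a <- c(cur$is_a, trimws(sub("^is_a:", "", ln)))
    else if (grepl("^is_obsolete:", ln) &&
             grepl("true", ln, fixed = TRUE)) cur$obsolete <- TRUE
  }
  flush(cur)
  if (!length(term_rows)) stop("no usable [Term] stanzas in ", path)
  ids <- vapply(term_rows, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate term ids in ", path)
  parents <- lapply(term_rows, `[[`, "is_a")
  names(parents) <- ids
  dangling <- setdiff(unlist(parents), ids)
  if (length(dangling)) {
    warning("dropping is_a references to missing/obsolete terms: ",
            paste(dangling, collapse = ", "))
    parents <- lapply(parents, setdiff, y = dangling)
  }
  ontology_dag(ids, parents, root = root)
}

#' Write an ontology DAG as a minimal OBO file
#' @param dag an [ontology_dag()].
#' @param path output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    for (p in dag$parents[[t]]) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Attach gene annotations and compute IC
#'
#' Computes, for every term `t`, the cumulative annotation count `f(t)`:
#' the number of *distinct* genes annotated to `t` or any of its
#' descendants (a gene annotated to several descendants counts once,
#' keeping `p(t) = f(t)/f(root) <= 1`).  The information content is
#' `IC(t) = -log(p(t))` (natural log by default); terms with `f(t) = 0`
#' get an infinite IC sentinel and are excluded from similarity.
#'
#' @param dag an [ontology_dag()].
#' @param annotations data.frame with columns `term`, `gene`.
#' @param log_base base of the logarithm (default `exp(1)`; downstream
#'   rankings are invariant to this monotone rescaling).
#' @return the DAG with `direct_genes`, `cum_genes`, `f`, `ic` fields.
#' @export
annotate_dag <- function(dag, annotations, log_base = exp(1)) {
  stopifnot(all(c("term", "gene") %in% names(annotations)))
  unknown <- setdiff(unique(annotations$term), dag$terms)
  if (length(unknown)) {
    warning("dropping annotations to unknown terms: ",
            paste(unknown, collapse = ", "))
    annotations <- annotations[!annotations$term %in% unknown, , drop = FALSE]
  }
  direct <- split(as.character(annotations$gene),
                  factor(annotations$term, levels = dag$terms))
  direct <- lapply(direct, unique)

  cum <- vector("list", length(dag$terms))
  names(cum) <- dag$terms
  for (t in rev(dag$topo)) {                       # children before parents
    gs <- direct[[t]]
    for (ch in dag$children[[t]]) gs <- c(gs, cum[[ch]])
    cum[[t]] <- unique(gs)
  }
  f <- vapply(cum, length, 1L)
  if (f[[dag$root]] == 0L)
    stop("no gene annotations reach the root; cannot define IC")
  ic <- ifelse(f > 0L, -log(f / f[[dag$root]]) / log(log_base), Inf)
  names(ic) <- dag$terms
  dag$direct_genes <- direct
  dag$cum_genes <- cum
  dag$f <- f
  dag$ic <- ic
  dag
}

#' Cumulative annotation count f(t)
#' @param dag an annotated [ontology_dag()].
#' @param term term id.
#' @return number of distinct genes annotated to `term` or a descendant.
#' @export
cumulative_annotation_count <- function(dag, term) {
  if (is.null(dag$f)) stop("DAG is not annotated; call annotate_dag() first")
  if (!term %in% dag$terms) stop("unknown term: ", term)
  dag$f[[term]]
}

#' Information content IC(t) = -log(f(t)/f(root))
#' @inheritParams cumulative_annotation_count
#' @return non-negative real; `Inf` for unannotated terms.
#' @export
information_content <- function(dag, term) {
  if (is.null(dag$ic)) stop("DAG is not annotated; call annotate_dag() first")
  if (!term %in% dag$terms) stop("unknown term: ", term)
  dag$ic[[term]]
}

#' Ancestor closure of a term (including the term itself)
#' @inheritParams cumulative_annotation_count
#' @return character vector of ancestor term ids.
#' @export
term_ancestors <- function(dag, term) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
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

#' Resnik semantic similarity between two terms
#'
#' The similarity is the maximum IC over the shared ancestors of the two
#' terms (each term counting as its own ancestor), i.e. the IC of their
#' most informative common ancestor (MICA).  Unannotated terms (infinite
#' IC) have no defined similarity and return `NA`.
#'
#' @param dag an annotated [ontology_dag()].
#' @param t_i,t_j term ids.
#' @return non-negative real, or `NA` if either term is unannotated.
#' @export
resnik_similarity <- function(dag, t_i, t_j) {
  if (is.null(dag$ic)) stop("DAG is not annotated; call annotate_dag() first")
  ic_i <- information_content(dag, t_i)
  ic_j <- information_content(dag, t_j)
  if (!is.finite(ic_i) || !is.finite(ic_j)) return(NA_real_)
  common <- intersect(term_ancestors(dag, t_i), term_ancestors(dag, t_j))
  if (!length(common)) return(0)
  max(dag$ic[common][is.finite(dag$ic[common])], 0)
}

#' Build the disease similarity network
#'
#' Each disease maps to one ontology term; the edge weight between two
#' diseases is the Resnik similarity of their terms, and only pairs with
#' strictly positive similarity are connected.  Distinct diseases mapping
#' to the same term are allowed (identical similarity profiles).
#'
#' @param dag an annotated [ontology_dag()].
#' @param disease_map data.frame with columns `disease`, `term`.
#' @return a [weighted_network()] with layer `"disease"`.
#' @export
build_disease_network <- function(dag, disease_map) {
  stopifnot(all(c("disease", "term") %in% names(disease_map)))
  disease_map <- unique(disease_map[, c("disease", "term")])
  if (anyDuplicated(disease_map$disease))
    stop("a disease maps to more than one term")
  known <- disease_map$term %in% dag$terms
  annotated <- known & is.finite(dag$ic[disease_map$term])
  if (any(!annotated))
    warning("dropping disease(s) mapped to unknown or unannotated terms: ",
            paste(disease_map$disease[!annotated], collapse = ", "))
  disease_map <- disease_map[annotated, , drop = FALSE]
  dis <- disease_map$disease
  terms <- disease_map$term
  m <- length(dis)
  anc <- lapply(unique(terms), term_ancestors, dag = dag)
  names(anc) <- unique(terms)
  adj <- matrix(0, m, m, dimnames = list(dis, dis))
  if (m >= 2L) {
    for (a in seq_len(m - 1L)) for (b in seq(a + 1L, m)) {
      common <- intersect(anc[[terms[a]]], anc[[terms[b]]])
      w <- if (length(common)) max(dag$ic[common], 0) else 0
      adj[a, b] <- adj[b, a] <- w
    }
  }
  weighted_network(dis, adj, layer = "disease")
}
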