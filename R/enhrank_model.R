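#' Fit a disease-enhancer propagation model
#'
#' Assembles the requested network configuration — disease similarity
#' network, shared-gene enhancer layer, sequence-similarity enhancer
#' layer, and the bipartite coupling from known disease-enhancer
#' associations — into a multiplex-heterogeneous system and precomputes
#' its transition operator.  The fitted object ranks candidate enhancers
#' for a query disease via [predict.enhrank()], running a random walk
#' with restart from the disease's known enhancers (and the disease
#' itself) and scoring every other enhancer by its steady-state
#' probability.
#'
#' Parameter roles (all default 0.5, the setting under which the method
#' is stable): `gamma` — restart probability of the walk; `delta` —
#' probability of jumping between the two enhancer layers; `tau` —
#' restart weight of the gene layer versus the sequence layer; `lambda`
#' — probability of crossing the bipartite disease-enhancer coupling;
#' `eta` — restart weight of the disease side versus the enhancer side.
#'
#' @param associations data.frame with columns `disease`, `enhancer`.
#' @param gene_net shared-gene enhancer [weighted_network()].
#' @param seq_net sequence-similarity enhancer [weighted_network()].
#' @param disease_net disease similarity [weighted_network()].
#' @param gamma,delta,tau,lambda,eta walk parameters in `[0, 1]`
#'   (`gamma` in `(0, 1]`).
#' @param mode network configuration; see [build_supra_system()].
#' @param normalization transition convention; see [build_transition()].
#' @param combine replica score combination; see [score_candidates()].
#' @param tol,max_iter power-iteration controls.
#' @return object of class `enhrank`.
#' @seealso [cross_validate()], [rank_novel()], [sweep_parameters()]
#' @examples
#' fix <- generate_fixture(fixture_spec(seed = 1))
#' nets <- fixture_networks(fix)
#' fit <- enhrank(fix$associations, gene_net = nets$gene_net,
#'                seq_net = nets$seq_net, disease_net = nets$disease_net)
#' head(predict(fit, disease = fix$associations$disease[1]), 3)
#' @export
enhrank <- function(associations, gene_net = NULL, seq_net = NULL,
                    disease_net = NULL,
                    gamma = 0.5, delta = 0.5, tau = 0.5, lambda = 0.5,
                    eta = 0.5,
                    mode = c("mulhet", "het", "mul", "gene", "seq"),
                    normalization = c("jump", "literal"),
                    combine = c("sum", "mean", "max"),
                    tol = 1e-10, max_iter = 1000L) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  combine <- match.arg(combine)
  stopifnot(gamma > 0, gamma <= 1)
  sys <- build_supra_system(associations, gene_net = gene_net,
                            seq_net = seq_net, disease_net = disease_net,
                            delta = delta, mode = mode)
  trans <- build_transition(sys, lambda = lambda,
                            normalization = normalization)
  structure(list(system = sys, transition = trans,
                 associations = associations,
                 params = list(gamma = gamma, delta = delta, tau = tau,
                               lambda = lambda, eta = eta),
                 mode = mode, normalization = normalization,
                 combine = combine, tol = tol, max_iter = max_iter,
                 call = match.call()),
            class = "enhrank")
}

#' Rank candidate enhancers for a query disease
#'
#' Runs the random walk with restart seeded at the disease's known
#' enhancers (taken from the fitted association table unless
#' `seed_enhancers` is supplied) and, in modes with a disease block, at
#' the query disease itself.  Seeds are excluded from the returned
#' ranking.
#'
#' @param object an [enhrank()] fit.
#' @param disease query disease id (optional in modes without a disease
#'   block if `seed_enhancers` is given).
#' @param seed_enhancers optional explicit seed set overriding the known
#'   associations.
#' @param top optional row cap on the returned ranking.
#' @param method `"iterate"` (power iteration, default) or `"solve"`
#'   (exact linear solve).
#' @param ... unused.
#' @return an `enh_ranking` data.frame; see [score_candidates()].
#' @export
predict.enhrank <- function(object, disease = NULL, seed_enhancers = NULL,
                            top = NULL, method = c("iterate", "solve"), ...) {
  method <- match.arg(method)
  if (is.null(seed_enhancers)) {
    if (is.null(disease)) stop("supply `disease` or `seed_enhancers`")
    seed_enhancers <-
      object$associations$enhancer[object$associations$disease == disease]
  }
  seed_diseases <- if (object$system$m > 0L && !is.null(disease))
    disease else character(0)
  p0 <- build_restart_vector(object$system, seed_enhancers, seed_diseases,
                             tau = object$params$tau, eta = object$params$eta)
  steady <- if (method == "iterate")
    rwr_iterate(object$transition, p0, object$params$gamma,
                tol = object$tol, max_iter = object$max_iter)
  else rwr_solve(object$transition, p0, object$params$gamma)
  ranking <- score_candidates(steady, object$system,
                              seeds = intersect(seed_enhancers,
                                                object$system$nodes),
                              combine = object$combine)
  if (!is.null(top)) ranking <- ranking[seq_len(min(top, nrow(ranking))), ]
  attr(ranking, "steady") <- steady
  ranking
}

#' @export
print.enhrank <- function(x, ...) {
  cat("Disease-enhancer propagation model\n")
  cat(sprintf("  mode: %s (%s normalization, %s replica combination)\n",
              x$mode, x$normalization, x$combine))
  cat(sprintf("  enhancers: %d in %d layer(s); diseases: %d; associations: %d\n",
              x$system$n, x$system$k, x$system$m, nrow(x$associations)))
  p <- x$params
  cat(sprintf("  gamma=%g delta=%g tau=%g lambda=%g eta=%g\n",
              p$gamma, p$delta, p$tau, p$lambda, p$eta))
  invisible(x)
}

#' @export
summary.enhrank <- function(object, ...) {
  sys <- object$system
  layer_edges <- vapply(sys$layers, function(A)
    sum(A[upper.tri(A)] > 0), 1)
  out <- list(mode = object$mode, params = object$params,
              n_enhancers = sys$n, n_diseases = sys$m,
              layer_edges = layer_edges,
              n_associations = if (is.null(sys$B)) nrow(object$associations)
                               else sum(sys$B),
              disease_edges = if (is.null(sys$A_D)) NA_integer_
                              else sum(sys$A_D[upper.tri(sys$A_D)] > 0),
              dangling = sum(object$transition$dangling))
  class(out) <- "summary.enhrank"
  out
}

#' @export
print.summary.enhrank <- function(x, ...) {
  cat(sprintf("Disease-enhancer propagation model (mode %s)\n", x$mode))
  cat(sprintf("  enhancer universe: %d nodes\n", x$n_enhancers))
  for (l in names(x$layer_edges))
    cat(sprintf("  %s layer: %d edges\n", l, x$layer_edges[[l]]))
  if (!is.na(x$disease_edges))
    cat(sprintf("  disease network: %d nodes, %d edges\n",
                x$n_diseases, x$disease_edges))
  cat(sprintf("  bipartite associations in coupling: %d\n", x$n_associations))
  cat(sprintf("  dangling transition columns: %d\n", x$dangling))
  p <- x$params
  cat(sprintf("  gamma=%g delta=%g tau=%g lambda=%g eta=%g\n",
              p$gamma, p$delta, p$tau, p$lambda, p$eta))
  invisible(x)
}
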