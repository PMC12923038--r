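#' Deterministic sub-seed derived from a master seed and a string key
#'
#' Used so that per-disease fold assignments depend only on the master
#' seed and the disease id, which makes folds reusable across parameter
#' settings (paired comparisons) and runs byte-reproducible.
#'
#' @param master integer master seed.
#' @param key character key (e.g. a disease id).
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, key) {
  h <- 0
  for (b in utf8ToInt(as.character(key)))
    h <- (h * 31 + b) %% 2147483647
  as.integer((h + as.numeric(master) * 7919) %% 2147483647)
}

#' Random k-fold partition of a disease's enhancer set
#'
#' Folds are disjoint, cover `S`, and differ in size by at most one
#' (e.g. sizes 1-1-2 for four enhancers at k = 3).  Deterministic given
#' the seed.
#'
#' @param S character vector of known enhancers (`length(S) >= k`).
#' @param k number of folds (default 3).
#' @param seed integer RNG seed.
#' @return object of class `fold_plan`: list of `k` character vectors.
#' @export
make_folds <- function(S, k = 3L, seed = 1L) {
  S <- unique(as.character(S))
  if (length(S) < k)
    stop("need at least ", k, " enhancers to form ", k, " folds")
  perm <- withr::with_seed(seed, sample(S))
  base <- length(S) %/% k
  extra <- length(S) %% k
  sizes <- base + (seq_len(k) <= extra)
  folds <- split(perm, rep(seq_len(k), times = sizes))
  structure(unname(folds), class = "fold_plan", seed = seed)
}

#' ROC AUC from positive and negative score sets
#'
#' Mann-Whitney form: the fraction of (positive, negative) pairs where
#' the positive scores higher, ties counting one half.  Equals the area
#' under the empirical ROC curve.
#'
#' @param pos,neg numeric score vectors (each non-empty).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(pos, neg) {
  if (!length(pos) || !length(neg))
    stop("need at least one positive and one negative score")
  r <- rank(c(pos, neg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

#' Per-disease k-fold cross-validation of enhancer ranking
#'
#' For every disease with at least `k` known enhancers (inside the
#' system's node universe), the known set `S` is partitioned into `k`
#' folds.  In each round the held-out fold's associations are removed
#' from the bipartite coupling, the training enhancers (plus the query
#' disease, in modes with a disease block) seed the walk, and the
#' held-out enhancers are scored against all universe enhancers outside
#' `S`.  AUCs are averaged over folds per disease, then unweighted over
#' diseases.
#'
#' @param associations data.frame with columns `disease`, `enhancer`.
#' @param gene_net,seq_net,disease_net network layers as required by
#'   `mode`; see [build_supra_system()].
#' @param k number of folds (default 3).
#' @param seed master seed; per-disease fold seeds are derived from it
#'   with [derive_seed()].
#' @param gamma,delta,tau,lambda,eta walk parameters.
#' @param mode,normalization,combine see [enhrank()].
#' @param tol,max_iter power-iteration controls.
#' @param details if `TRUE`, attach per-fold seed/positive/negative sets
#'   and the pruned association tables (leakage audit).
#' @return object of class `cv_report` with elements `per_fold`,
#'   `per_disease`, `grand_mean`, `config` (and `details`).
#' @export
cross_validate <- function(associations, gene_net = NULL, seq_net = NULL,
                           disease_net = NULL, k = 3L, seed = 1L,
                           gamma = 0.5, delta = 0.5, tau = 0.5,
                           lambda = 0.5, eta = 0.5,
                           mode = c("mulhet", "het", "mul", "gene", "seq"),
                           normalization = c("jump", "literal"),
                           combine = c("sum", "mean", "max"),
                           tol = 1e-10, max_iter = 1000L, details = FALSE) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  combine <- match.arg(combine)
  sys0 <- build_supra_system(associations, gene_net = gene_net,
                             seq_net = seq_net, disease_net = disease_net,
                             delta = delta, mode = mode)
  universe <- sys0$nodes
  assoc <- unique(associations[, c("disease", "enhancer")])
  assoc <- assoc[assoc$enhancer %in% universe, , drop = FALSE]
  if (sys0$m > 0L)
    assoc <- assoc[assoc$disease %in% sys0$diseases, , drop = FALSE]
  known <- split(assoc$enhancer, assoc$disease)
  eligible <- names(known)[lengths(known) >= k]
  if (!length(eligible)) {
    warning("no disease has >= ", k, " known enhancers; empty report")
    return(empty_cv_report(k, seed, mode, gamma, delta, tau, lambda, eta,
                           normalization))
  }

  rows <- list()
  detail_list <- list()
  for (d in sort(eligible)) {
    S <- sort(unique(known[[d]]))
    folds <- make_folds(S, k = k, seed = derive_seed(seed, d))
    negatives <- setdiff(universe, S)
    for (f in seq_len(k)) {
      held <- folds[[f]]
      train <- setdiff(S, held)
      pruned <- assoc[!(assoc$disease == d & assoc$enhancer %in% held), ,
                      drop = FALSE]
      sys <- set_associations(sys0, pruned)
      trans <- build_transition(sys, lambda = lambda,
                                normalization = normalization)
      p0 <- build_restart_vector(
        sys, train,
        if (sys$m > 0L) d else character(0),
        tau = tau, eta = eta)
      steady <- rwr_iterate(trans, p0, gamma, tol = tol,
                            max_iter = max_iter)
      ranking <- score_candidates(steady, sys, seeds = train,
                                  combine = combine)
      sc <- stats::setNames(ranking$score, ranking$enhancer)
      if (!length(held) || !length(negatives)) {
        message("skipping ", d, " fold ", f, ": empty positive or ",
                "negative side")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        disease = d, fold = f, auc = roc_auc(sc[held], sc[negatives]),
        n_pos = length(held), n_neg = length(negatives),
        stringsAsFactors = FALSE)
      if (details)
        detail_list[[length(detail_list) + 1L]] <- list(
          disease = d, fold = f, seeds = train, positives = held,
          negatives = negatives, coupling = pruned)
    }
  }
  per_fold <- do.call(rbind, rows)
  per_disease <- stats::aggregate(auc ~ disease, per_fold, mean)
  out <- list(per_fold = per_fold, per_disease = per_disease,
              grand_mean = mean(per_disease$auc),
              n_excluded = length(known) - length(eligible),
              config = list(k = k, seed = seed, mode = mode, gamma = gamma,
                            delta = delta, tau = tau, lambda = lambda,
                            eta = eta, normalization = normalization,
                            combine = combine))
  if (details) out$details <- detail_list
  class(out) <- "cv_report"
  out
}

empty_cv_report <- function(k, seed, mode, gamma, delta, tau, lambda, eta,
                            normalization) {
  structure(list(per_fold = data.frame(), per_disease = data.frame(),
                 grand_mean = NA_real_, n_excluded = 0L,
                 config = list(k = k, seed = seed, mode = mode,
                               gamma = gamma, delta = delta, tau = tau,
                               lambda = lambda, eta = eta,
                               normalization = normalization)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%d-fold cross-validation (mode %s)\n", cfg$k, cfg$mode))
  cat(sprintf("  gamma=%g delta=%g tau=%g lambda=%g eta=%g seed=%s\n",
              cfg$gamma, cfg$delta, cfg$tau, cfg$lambda, cfg$eta,
              format(cfg$seed)))
  if (nrow(x$per_disease)) {
    cat(sprintf("  %d disease(s) evaluated, %d excluded (< %d enhancers)\n",
                nrow(x$per_disease), x$n_excluded, cfg$k))
    cat(sprintf("  grand-mean AUC: %.4f\n", x$grand_mean))
  } else cat("  no eligible diseases\n")
  invisible(x)
}

#' Write a CV report as TSV with a config header
#' @param report a [cross_validate()] result.
#' @param path output path.
#' @export
write_cv_report <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  cfg <- report$config
  writeLines(sprintf("# %s", paste(names(cfg), unlist(cfg), sep = "=",
                                   collapse = " ")), con)
  writeLines(sprintf("# grand_mean_auc\t%.10g", report$grand_mean), con)
  writeLines("disease\tfold\tauc\tn_pos\tn_neg", con)
  pf <- report$per_fold
  if (!is.null(pf) && nrow(pf))
    writeLines(sprintf("%s\t%d\t%.10g\t%d\t%d", pf$disease, pf$fold,
                       pf$auc, pf$n_pos, pf$n_neg), con)
  invisible(path)
}

#' Grand-mean AUC over a parameter grid
#'
#' Re-runs [cross_validate()] for each grid value of one walk parameter,
#' holding the others fixed.  Because fold seeds derive from the master
#' seed and the disease id only, every setting reuses identical folds
#' (a paired design).
#'
#' @param associations,gene_net,seq_net,disease_net,k,seed,mode,normalization
#'   passed to [cross_validate()].
#' @param param one of `"gamma"`, `"delta"`, `"tau"`, `"lambda"`, `"eta"`.
#' @param grid numeric grid, default `c(0.1, 0.3, 0.5, 0.7, 0.9)`.
#' @param fixed named list of values for the non-swept parameters
#'   (default 0.5 each).
#' @param ... further arguments for [cross_validate()].
#' @return data.frame with columns `param`, `value`, `grand_mean_auc`.
#' @export
sweep_parameters <- function(associations, gene_net = NULL, seq_net = NULL,
                             disease_net = NULL,
                             param = c("gamma", "delta", "tau", "lambda",
                                       "eta"),
                             grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                             fixed = list(), k = 3L, seed = 1L,
                             mode = "mulhet", normalization = "jump", ...) {
  param <- match.arg(param)
  base <- list(gamma = 0.5, delta = 0.5, tau = 0.5, lambda = 0.5, eta = 0.5)
  base[names(fixed)] <- fixed
  rows <- lapply(grid, function(v) {
    pars <- base
    pars[[param]] <- v
    rep_ <- cross_validate(associations, gene_net = gene_net,
                           seq_net = seq_net, disease_net = disease_net,
                           k = k, seed = seed, gamma = pars$gamma,
                           delta = pars$delta, tau = pars$tau,
                           lambda = pars$lambda, eta = pars$eta,
                           mode = mode, normalization = normalization, ...)
    data.frame(param = param, value = v, grand_mean_auc = rep_$grand_mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Top-k novel candidate enhancers for a disease
#'
#' Seeds the walk with all of the disease's known enhancers and returns
#' the `k_top` best-scoring enhancers not already associated with it,
#' together with their target genes (for downstream evidence lookup)
#' when a catalog is supplied.
#'
#' @param fit an [enhrank()] fit.
#' @param disease query disease id.
#' @param k_top number of candidates (default 10); silently truncated to
#'   the candidate pool.
#' @param catalog optional [enhancer_catalog()] supplying target genes.
#' @return data.frame with columns `rank`, `enhancer`, `score` (+
#'   per-layer scores and `target_genes`).
#' @export
rank_novel <- function(fit, disease, k_top = 10L, catalog = NULL) {
  known <- fit$associations$enhancer[fit$associations$disease == disease]
  if (!length(known))
    stop("disease ", disease, " has no known enhancer to seed from")
  ranking <- predict(fit, disease = disease)
  ranking <- ranking[!ranking$enhancer %in% known, , drop = FALSE]
  ranking <- ranking[seq_len(min(k_top, nrow(ranking))), , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  if (!is.null(catalog))
    ranking$target_genes <- vapply(ranking$enhancer, function(e)
      paste(catalog$targets[[e]], collapse = ","), "")
  rownames(ranking) <- NULL
  ranking
}
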