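#' Random walk with restart by power iteration
#'
#' Iterates `P_{t+1} = (1 - gamma) M P_t + gamma P0` from `P0` until the
#' L1 change drops below `tol` or `max_iter` is reached.  Mass sitting on
#' dangling nodes (flagged zero columns) is redirected to the restart
#' distribution at every step, which keeps the iteration on the
#' probability simplex.
#'
#' @param trans a [build_transition()] object, or a bare column-stochastic
#'   matrix (zero columns are then treated as dangling).
#' @param p0 restart probability vector (sums to 1).
#' @param gamma restart probability in `(0, 1]`.
#' @param tol L1 convergence tolerance (default `1e-10`).
#' @param max_iter iteration cap (default 1000); non-convergence is
#'   flagged and the best iterate returned.
#' @return object of class `rwr_steady`: list with `p` (steady-state
#'   probabilities), `iterations`, `residual`, `converged`.
#' @export
rwr_iterate <- function(trans, p0, gamma, tol = 1e-10, max_iter = 1000L) {
  tr <- as_transition(trans)
  check_rwr_inputs(tr, p0, gamma)
  p <- p0
  it <- 0L
  res <- Inf
  while (it < max_iter) {
    it <- it + 1L
    q <- drop(tr$M %*% p)
    dm <- sum(p[tr$dangling])
    if (dm > 0) q <- q + dm * p0
    p_new <- (1 - gamma) * q + gamma * p0
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) break
  }
  converged <- res < tol
  if (!converged)
    warning("RWR did not converge within ", max_iter,
            " iterations (residual ", format(res), ")")
  structure(list(p = p, iterations = it, residual = res,
                 converged = converged),
            class = "rwr_steady")
}

#' Random walk with restart by exact linear solve
#'
#' Solves the fixed point `(I - (1 - gamma) M') P = gamma P0` directly,
#' where `M'` is the transition operator with dangling columns replaced
#' by the restart distribution.  Serves as the exact oracle for
#' [rwr_iterate()] on systems small enough for a dense solve.
#'
#' @inheritParams rwr_iterate
#' @return an `rwr_steady` object (`iterations = 0`).
#' @export
rwr_solve <- function(trans, p0, gamma) {
  tr <- as_transition(trans)
  check_rwr_inputs(tr, p0, gamma)
  if (gamma == 1) {
    return(structure(list(p = p0, iterations = 0L, residual = 0,
                          converged = TRUE), class = "rwr_steady"))
  }
  M <- tr$M
  if (any(tr$dangling))
    M[, tr$dangling] <- p0          # restart-only resolution
  A <- diag(length(p0)) - (1 - gamma) * M
  p <- drop(solve(A, gamma * p0))
  names(p) <- names(p0)
  structure(list(p = p, iterations = 0L,
                 residual = sum(abs(drop(A %*% p) - gamma * p0)),
                 converged = TRUE),
            class = "rwr_steady")
}

as_transition <- function(trans) {
  if (inherits(trans, "transition_op")) return(trans)
  M <- as.matrix(trans)
  list(M = M, dangling = colSums(M) == 0,
       node_names = colnames(M))
}

check_rwr_inputs <- function(tr, p0, gamma) {
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  if (length(p0) != ncol(tr$M)) stop("restart vector length mismatch")
  if (abs(sum(p0) - 1) > 1e-9) stop("restart vector must sum to 1")
  if (any(p0 < 0)) stop("restart vector must be non-negative")
  cs <- colSums(tr$M)[!tr$dangling]
  if (length(cs) && max(abs(cs - 1)) > 1e-8)
    stop("transition matrix is not column-stochastic")
  invisible(TRUE)
}

#' @export
print.rwr_steady <- function(x, ...) {
  cat(sprintf("<rwr_steady> %d nodes, %s after %d iteration(s), residual %.3g\n",
              length(x$p), if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  invisible(x)
}

#' Score and rank candidate enhancers from a steady state
#'
#' Each enhancer's score combines its per-layer replica probabilities
#' (sum by default; an enhancer isolated in one layer still scores
#' through the other).  Seed enhancers are excluded from the candidate
#' list; ties are broken lexicographically by enhancer id.
#'
#' @param steady an `rwr_steady` object over the system's node order.
#' @param sys the [build_supra_system()] the walk ran on.
#' @param seeds character vector of seed enhancer ids to exclude.
#' @param combine `"sum"` (default), `"mean"` or `"max"` across replicas.
#' @return data.frame of class `enh_ranking` with columns `rank`,
#'   `enhancer`, `score` and one `score_<layer>` column per layer;
#'   disease probabilities (if any) are attached as attribute
#'   `"disease_scores"`.
#' @export
score_candidates <- function(steady, sys, seeds = character(0),
                             combine = c("sum", "mean", "max")) {
  combine <- match.arg(combine)
  p <- steady$p
  kn <- sys$k * sys$n
  rep_mat <- matrix(p[seq_len(kn)], nrow = sys$n, ncol = sys$k,
                    dimnames = list(sys$nodes, sys$layer_names))
  score <- switch(combine,
                  sum = rowSums(rep_mat),
                  mean = rowMeans(rep_mat),
                  max = apply(rep_mat, 1L, max))
  out <- data.frame(enhancer = sys$nodes, score = unname(score),
                    stringsAsFactors = FALSE)
  for (l in sys$layer_names)
    out[[paste0("score_", l)]] <- unname(rep_mat[, l])
  out <- out[!out$enhancer %in% seeds, , drop = FALSE]
  out <- out[order(-out$score, out$enhancer), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("enh_ranking", "data.frame")
  if (sys$m > 0L)
    attr(out, "disease_scores") <-
      stats::setNames(p[kn + seq_len(sys$m)], sys$diseases)
  out
}

#' @export
plot.enh_ranking <- function(x, top = 20L, ...) {
  top <- min(top, nrow(x))
  d <- x[seq_len(top), , drop = FALSE]
  op <- graphics::par(mar = c(5, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(d$score), names.arg = rev(d$enhancer), horiz = TRUE,
                    las = 1, xlab = "steady-state score",
                    main = sprintf("top %d candidate enhancers", top), ...)
  invisible(x)
}

#' Write a ranking as TSV
#' @param ranking an [score_candidates()] result.
#' @param path output path.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
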