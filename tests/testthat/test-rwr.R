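# Power iteration vs exact solve, mass conservation, locality, scoring.

test_that("gamma = 1 returns the restart vector", {
  M <- matrix(c(0, 1, 1, 0), 2)
  p0 <- c(0.7, 0.3)
  expect_equal(rwr_iterate(M, p0, gamma = 1)$p, p0)
  expect_equal(rwr_solve(M, p0, gamma = 1)$p, p0)
})

test_that("two-node closed form is recovered", {
  # gamma (I - (1-gamma) M)^{-1} p0 with M the swap gives (2/3, 1/3)
  M <- matrix(c(0, 1, 1, 0), 2)
  p0 <- c(1, 0)
  st <- rwr_iterate(M, p0, gamma = 0.5)
  expect_equal(st$p, c(2 / 3, 1 / 3), tolerance = 1e-9)
  expect_true(st$converged)
  expect_equal(rwr_solve(M, p0, gamma = 0.5)$p, c(2 / 3, 1 / 3),
               tolerance = 1e-12)
})

test_that("probability mass is conserved at every iterate", {
  rs <- random_system(n = 20, m = 5, seed = 314)
  tr <- build_transition(rs$sys)
  p0 <- build_restart_vector(rs$sys, rs$seeds_e, rs$seeds_d)
  for (t_ in c(1L, 2L, 3L, 5L, 10L, 25L)) {
    st <- suppressWarnings(rwr_iterate(tr, p0, gamma = 0.5, max_iter = t_))
    expect_equal(sum(st$p), 1, tolerance = 1e-9)
    expect_true(all(st$p >= 0))
  }
})

test_that("iterate and solve agree across gamma on random systems", {
  for (r in 1:12) {
    rs <- random_system(n = sample(10:50, 1), m = sample(2:10, 1),
                        seed = 8200 + r)
    tr <- build_transition(rs$sys)
    p0 <- build_restart_vector(rs$sys, rs$seeds_e, rs$seeds_d)
    for (g in c(0.1, 0.5, 0.9)) {
      pi_ <- rwr_iterate(tr, p0, g)$p
      ps <- rwr_solve(tr, p0, g)$p
      expect_lt(max(abs(pi_ - ps)), 1e-8)
    }
  }
})

test_that("uniform restart on a regular graph stays uniform", {
  n <- 6L
  ring <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ring[i, i %% n + 1L] <- 1
    ring[i %% n + 1L, i] <- 1
  }
  M <- sweep(ring, 2, colSums(ring), "/")
  p0 <- rep(1 / n, n)
  expect_equal(rwr_solve(M, p0, gamma = 0.3)$p, p0, tolerance = 1e-12)
})

test_that("steady-state probability decays with hop distance on a chain", {
  n <- 9L
  chain <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) chain[i, i + 1L] <- chain[i + 1L, i] <- 1
  M <- sweep(chain, 2, colSums(chain), "/")
  p0 <- c(1, rep(0, n - 1L))
  p <- rwr_solve(M, p0, gamma = 0.4)$p
  expect_true(all(diff(p) < 0))
})

test_that("the steady state approaches the restart vector as gamma -> 1", {
  rs <- random_system(n = 15, m = 4, seed = 2718)
  tr <- build_transition(rs$sys)
  p0 <- build_restart_vector(rs$sys, rs$seeds_e, rs$seeds_d)
  gaps <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.95, 0.999), function(g)
    sum(abs(rwr_solve(tr, p0, g)$p - p0)), 0)
  expect_true(all(diff(gaps) < 1e-12))
  expect_lt(gaps[length(gaps)], 1e-2)
})

test_that("rwr rejects malformed inputs", {
  M <- matrix(c(0.5, 0.2, 0.5, 0.8), 2)   # second column ok, first not
  expect_error(rwr_iterate(matrix(c(0.5, 0.2, 0, 1), 2), c(1, 0), 0.5),
               "not column-stochastic")
  expect_error(rwr_iterate(matrix(c(0, 1, 1, 0), 2), c(0.5, 0.4), 0.5),
               "sum to 1")
  expect_error(rwr_iterate(matrix(c(0, 1, 1, 0), 2), c(1, 0), 0), "gamma")
})

test_that("candidate scores sum layer replicas and exclude seeds", {
  sys <- build_supra_system(
    data.frame(disease = "d", enhancer = "a"),
    gene_net = weighted_network(c("a", "b"), matrix(c(0, 1, 1, 0), 2), "g"),
    seq_net = weighted_network(c("a", "b"), matrix(c(0, 1, 1, 0), 2), "s"),
    disease_net = weighted_network("d", matrix(0, 1, 1), "disease"),
    delta = 0.5, mode = "mulhet")
  steady <- structure(list(p = c(0.1, 0.02, 0.2, 0.03, 0.65)),
                      class = "rwr_steady")
  sc <- score_candidates(steady, sys, seeds = "a")
  expect_identical(sc$enhancer, "b")
  expect_equal(sc$score, 0.05)
  expect_equal(sc$score_gene, 0.02)
  expect_equal(sc$score_seq, 0.03)
  expect_equal(unname(attr(sc, "disease_scores")), 0.65)

  # single-layer mode: score equals the lone replica probability
  sys1 <- build_supra_system(NULL, gene_net = weighted_network(
    c("a", "b"), matrix(c(0, 1, 1, 0), 2), "g"), mode = "gene")
  sc1 <- score_candidates(structure(list(p = c(0.6, 0.4)),
                                    class = "rwr_steady"), sys1)
  expect_equal(sc1$score, c(0.6, 0.4))
})

test_that("scores are invariant to node relabelling/permutation", {
  rs <- random_system(n = 12, m = 3, seed = 555)
  tr <- build_transition(rs$sys)
  p0 <- build_restart_vector(rs$sys, rs$seeds_e, rs$seeds_d)
  sc <- score_candidates(rwr_solve(tr, p0, 0.5), rs$sys, seeds = rs$seeds_e)

  # rebuild with nodes supplied in a different order; same seeds
  perm <- withr::with_seed(1, sample(length(rs$gene_net$nodes)))
  reorder <- function(net) weighted_network(
    net$nodes[perm], net$adj[perm, perm], net$layer)
  sys2 <- build_supra_system(rs$assoc, gene_net = reorder(rs$gene_net),
                             seq_net = reorder(rs$seq_net),
                             disease_net = rs$disease_net,
                             delta = rs$sys$delta, mode = "mulhet")
  tr2 <- build_transition(sys2)
  p02 <- build_restart_vector(sys2, rs$seeds_e, rs$seeds_d)
  sc2 <- score_candidates(rwr_solve(tr2, p02, 0.5), sys2,
                          seeds = rs$seeds_e)
  m1 <- stats::setNames(sc$score, sc$enhancer)
  m2 <- stats::setNames(sc2$score, sc2$enhancer)
  expect_equal(m2[names(m1)], m1, tolerance = 1e-12)
})

test_that("ties are broken lexicographically by enhancer id", {
  sys1 <- build_supra_system(NULL, gene_net = weighted_network(
    c("b", "a", "c"), matrix(0, 3, 3), "g"), mode = "gene")
  sc <- score_candidates(structure(list(p = c(0.3, 0.3, 0.4)),
                                   class = "rwr_steady"), sys1)
  expect_identical(sc$enhancer, c("c", "a", "b"))
})
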