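# Layer alignment, supra-adjacency assembly, transition operator,
# restart vector.

two_layer_toy <- function(delta = 0.4, assoc = data.frame(
                            disease = "d", enhancer = "a")) {
  enh <- c("a", "b")
  Ag <- matrix(c(0, 2, 2, 0), 2, dimnames = list(enh, enh))
  As <- matrix(c(0, 3, 3, 0), 2, dimnames = list(enh, enh))
  gene_net <- weighted_network(enh, Ag, "gEnhNet")
  seq_net <- weighted_network(enh, As, "sEnhNet")
  disease_net <- weighted_network("d", matrix(0, 1, 1), "disease")
  build_supra_system(assoc, gene_net = gene_net, seq_net = seq_net,
                     disease_net = disease_net, delta = delta,
                     mode = "mulhet")
}

test_that("align_layers pads the union universe with isolated nodes", {
  g <- weighted_network(c("a", "b"), matrix(c(0, 1, 1, 0), 2), "gEnhNet")
  s <- weighted_network(c("b", "c"), matrix(c(0, 2, 2, 0), 2), "sEnhNet")
  al <- align_layers(g, s)
  expect_identical(al$nodes, c("a", "b", "c"))
  expect_equal(length(al$nodes),
               length(g$nodes) + length(s$nodes) -
                 length(intersect(g$nodes, s$nodes)))
  expect_equal(sum(al$A_s["a", ]), 0)       # a isolated in the s layer
  expect_equal(sum(al$A_g["c", ]), 0)       # c isolated in the g layer
  expect_equal(al$A_g["a", "b"], 1)
  expect_equal(al$A_s["b", "c"], 2)

  # identical node sets: padding is a no-op
  al2 <- align_layers(g, weighted_network(c("a", "b"),
                                          matrix(c(0, 5, 5, 0), 2), "s"))
  expect_equal(al2$A_g, g$adj)
})

test_that("supra-adjacency matches the hand-assembled block formula", {
  sys <- two_layer_toy(delta = 0.4)
  A <- build_supra_adjacency(sys)
  want <- matrix(c(
    0,   1.2, 0.4, 0,   1,
    1.2, 0,   0,   0.4, 0,
    0.4, 0,   0,   1.8, 1,
    0,   0.4, 1.8, 0,   0,
    1,   0,   1,   0,   0), 5, 5, byrow = TRUE)
  dimnames(want) <- list(rownames(A), rownames(A))
  expect_equal(A, want)
  expect_identical(A, t(A))
})

test_that("delta = 0 block-diagonalizes the multiplex", {
  sys <- two_layer_toy(delta = 0)
  expect_equal(sys$A_M[1:2, 3:4], matrix(0, 2, 2,
               dimnames = dimnames(sys$A_M[1:2, 3:4])))
  expect_equal(sys$A_M[3:4, 1:2], matrix(0, 2, 2,
               dimnames = dimnames(sys$A_M[3:4, 1:2])))
})

test_that("empty association table decouples enhancers from diseases", {
  sys <- two_layer_toy(assoc = data.frame(disease = character(),
                                          enhancer = character()))
  A <- build_supra_adjacency(sys)
  expect_equal(sum(A[1:4, 5]), 0)
  expect_equal(sum(A[5, 1:4]), 0)
})

test_that("transition columns are stochastic in both modes on random systems", {
  for (r in 1:30) {
    rs <- random_system(n = sample(5:25, 1), m = sample(2:6, 1),
                        seed = 700 + r)
    for (nm in c("jump", "literal")) {
      tr <- build_transition(rs$sys, lambda = stats::runif(1),
                             normalization = nm)
      p0 <- build_restart_vector(rs$sys, rs$seeds_e, rs$seeds_d)
      Meff <- resolved_matrix(tr, p0)
      expect_lt(max(abs(colSums(Meff) - 1)), 1e-12)
    }
  }
})

test_that("a node isolated in one layer transitions to its replica", {
  enh <- c("a", "b")
  Ag <- matrix(0, 2, 2, dimnames = list(enh, enh))   # a,b isolated in g
  As <- matrix(c(0, 1, 1, 0), 2, dimnames = list(enh, enh))
  sys <- build_supra_system(NULL,
                            gene_net = weighted_network(enh, Ag, "g"),
                            seq_net = weighted_network(enh, As, "s"),
                            delta = 0.3, mode = "mul")
  tr <- build_transition(sys)
  # gene::a column has only its delta*I entry -> all mass on seq::a
  expect_equal(unname(tr$M[, "gene::a"]), c(0, 0, 1, 0))
})

test_that("lambda = 0 decouples diseases from enhancers in jump mode", {
  sys <- two_layer_toy()
  tr <- build_transition(sys, lambda = 0, normalization = "jump")
  expect_equal(sum(tr$M[5, 1:4]), 0)
  expect_equal(sum(tr$M[1:4, 5]), 0)
})

test_that("restart vector follows the layer/eta/tau weighting", {
  sys <- two_layer_toy()
  # 1 seed enhancer + 1 seed disease at tau = eta = 0.5
  p0 <- build_restart_vector(sys, "a", "d", tau = 0.5, eta = 0.5)
  expect_equal(unname(p0), c(0.25, 0, 0.25, 0, 0.5))
  expect_equal(sum(p0), 1)
  # tau = 1: all enhancer mass in the gene layer
  p1 <- build_restart_vector(sys, "a", "d", tau = 1, eta = 0.5)
  expect_equal(unname(p1[3]), 0)
  expect_equal(unname(p1[1]), 0.5)
  # two seed enhancers split uniformly
  p2 <- build_restart_vector(sys, c("a", "b"), "d", tau = 0.5, eta = 0.5)
  expect_equal(unname(p2), c(0.125, 0.125, 0.125, 0.125, 0.5))
  # empty enhancer side renormalizes onto the disease block
  p3 <- build_restart_vector(sys, character(0), "d")
  expect_equal(unname(p3), c(0, 0, 0, 0, 1))
  p4 <- build_restart_vector(sys, "a", character(0), tau = 0.5)
  expect_equal(sum(p4[1:4]), 1)
  expect_error(build_restart_vector(sys, character(0), character(0)),
               "both seed sets empty")
  expect_warning(build_restart_vector(sys, c("a", "zz"), "d"),
                 "not in node universe")
})

test_that("fully isolated nodes resolve to the restart distribution", {
  enh <- c("a", "b", "c")
  Ag <- matrix(0, 3, 3, dimnames = list(enh, enh))
  Ag["a", "b"] <- Ag["b", "a"] <- 1
  sys <- build_supra_system(NULL,
                            gene_net = weighted_network(enh, Ag, "g"),
                            mode = "gene")
  tr <- build_transition(sys)
  expect_true(tr$dangling[3])
  p0 <- build_restart_vector(sys, "a")
  st <- rwr_solve(tr, p0, gamma = 0.5)
  expect_equal(sum(st$p), 1, tolerance = 1e-12)
  Meff <- resolved_matrix(tr, p0)
  expect_lt(max(abs(colSums(Meff) - 1)), 1e-12)
})

test_that("a duplicated gene layer at delta = 0 reduces to the het system", {
  # with both layers identical and no inter-layer jumps, the replica-summed
  # multiplex-heterogeneous walk equals the single-layer heterogeneous walk
  fix <- generate_fixture(small_spec(seed = 21))
  nets <- fixture_networks(fix)
  dup <- weighted_network(nets$gene_net$nodes, nets$gene_net$adj, "sEnhNet")
  fit_mh <- enhrank(fix$associations, gene_net = nets$gene_net,
                    seq_net = dup, disease_net = nets$disease_net,
                    delta = 0, tau = 0.3, mode = "mulhet")
  fit_h <- enhrank(fix$associations, gene_net = nets$gene_net,
                   disease_net = nets$disease_net, mode = "het")
  d <- fix$associations$disease[1]
  r_mh <- predict(fit_mh, disease = d, method = "solve")
  r_h <- predict(fit_h, disease = d, method = "solve")
  sc_mh <- stats::setNames(r_mh$score, r_mh$enhancer)
  sc_h <- stats::setNames(r_h$score, r_h$enhancer)
  expect_equal(sc_mh[names(sc_h)], sc_h, tolerance = 1e-10)
})
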