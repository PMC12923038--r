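# Fold construction, AUC, cross-validation protocol, sweeps, novel ranking.

test_that("folds are balanced, disjoint, covering and deterministic", {
  f4 <- make_folds(sprintf("e%d", 1:4), k = 3, seed = 7)
  expect_equal(sort(lengths(f4)), c(1L, 1L, 2L))       # the 1-1-2 split
  f3 <- make_folds(sprintf("e%d", 1:3), k = 3, seed = 7)
  expect_equal(lengths(f3), c(1L, 1L, 1L))
  f7 <- make_folds(sprintf("e%d", 1:7), k = 3, seed = 7)
  expect_equal(sort(lengths(f7)), c(2L, 2L, 3L))
  expect_setequal(unlist(f7), sprintf("e%d", 1:7))
  expect_equal(sum(lengths(f7)), 7L)
  expect_identical(make_folds(sprintf("e%d", 1:7), 3, 7), f7)
  expect_false(identical(make_folds(sprintf("e%d", 1:7), 3, 8), f7))
  expect_error(make_folds(c("e1", "e2"), k = 3), "at least 3")
})

test_that("roc_auc matches the pairwise count with half credit for ties", {
  expect_equal(roc_auc(c(3, 4), c(1, 2)), 1)
  expect_equal(roc_auc(0.5, 0.5), 0.5)
  expect_equal(roc_auc(0.3, c(0.1, 0.5)), 0.5)
  expect_error(roc_auc(numeric(0), 1), "at least one")

  withr::with_seed(31, {
    for (i in 1:200) {
      pos <- sample(0:10, sample(1:8, 1), replace = TRUE) / 10
      neg <- sample(0:10, sample(1:8, 1), replace = TRUE) / 10
      expect_equal(roc_auc(pos, neg), oracle_auc(pos, neg),
                   tolerance = 1e-14)
      expect_equal(roc_auc(pos, neg) + roc_auc(neg, pos), 1)
    }
  })
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    pos <- stats::rnorm(25, 1)
    neg <- stats::rnorm(40)
    want <- as.numeric(pROC::auc(pROC::roc(
      response = c(rep(1, 25), rep(0, 40)), predictor = c(pos, neg),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(pos, neg), want, tolerance = 1e-12)
  })
})

test_that("cross-validation excludes small diseases and never leaks held-out links", {
  fix <- generate_fixture(small_spec(seed = 5))
  nets <- fixture_networks(fix)
  # keep only 2 associations for D04: below the k = 3 eligibility cutoff
  assoc <- fix$associations
  drop <- utils::tail(which(assoc$disease == "D04"), -2)
  assoc_small <- assoc[-drop, ]
  cv <- cross_validate(assoc_small, gene_net = nets$gene_net,
                       seq_net = nets$seq_net,
                       disease_net = nets$disease_net, seed = 5,
                       details = TRUE)
  expect_false("D04" %in% cv$per_fold$disease)
  expect_equal(cv$n_excluded, 1L)
  expect_true(all(cv$per_fold$auc >= 0 & cv$per_fold$auc <= 1))

  S_by_disease <- split(assoc_small$enhancer, assoc_small$disease)
  for (det in cv$details) {
    S <- S_by_disease[[det$disease]]
    # folds partition S: seeds + positives = S, disjoint
    expect_setequal(c(det$seeds, det$positives), S)
    expect_length(intersect(det$seeds, det$positives), 0L)
    # negatives exclude every known enhancer of the disease
    expect_length(intersect(det$negatives, S), 0L)
    # held-out links are absent from the bipartite coupling
    coupled <- det$coupling[det$coupling$disease == det$disease, "enhancer"]
    expect_length(intersect(coupled, det$positives), 0L)
    expect_setequal(coupled, det$seeds)
  }
})

test_that("cross-validation is deterministic given the master seed", {
  fix <- generate_fixture(small_spec(seed = 6))
  nets <- fixture_networks(fix)
  run <- function() cross_validate(fix$associations,
                                   gene_net = nets$gene_net,
                                   seq_net = nets$seq_net,
                                   disease_net = nets$disease_net,
                                   seed = 123)
  cv1 <- run(); cv2 <- run()
  expect_identical(cv1$per_fold, cv2$per_fold)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_cv_report(cv1, f1); write_cv_report(cv2, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical report
})

test_that("parameter sweeps reuse identical folds across settings", {
  fix <- generate_fixture(small_spec(seed = 9))
  nets <- fixture_networks(fix)
  tab <- sweep_parameters(fix$associations, gene_net = nets$gene_net,
                          seq_net = nets$seq_net,
                          disease_net = nets$disease_net,
                          param = "gamma", grid = c(0.3, 0.7), seed = 4)
  expect_equal(nrow(tab), 2L)
  expect_true(all(is.finite(tab$grand_mean_auc)))
  # folds derive from (seed, disease) only, hence identical across settings
  for (d in unique(fix$associations$disease)) {
    S <- fix$associations$enhancer[fix$associations$disease == d]
    expect_identical(make_folds(S, 3, derive_seed(4, d)),
                     make_folds(S, 3, derive_seed(4, d)))
  }
  # lambda is inert in a decoupled multiplex-only system
  tab2 <- sweep_parameters(fix$associations, gene_net = nets$gene_net,
                           seq_net = nets$seq_net,
                           disease_net = nets$disease_net,
                           param = "lambda", grid = c(0.1, 0.9),
                           seed = 4, mode = "mul")
  expect_equal(tab2$grand_mean_auc[1], tab2$grand_mean_auc[2],
               tolerance = 1e-12)
})

test_that("rank_novel returns top candidates disjoint from known associations", {
  fix <- generate_fixture(small_spec(seed = 10))
  nets <- fixture_networks(fix)
  fit <- enhrank(fix$associations, gene_net = nets$gene_net,
                 seq_net = nets$seq_net, disease_net = nets$disease_net)
  d <- "D01"
  known <- fix$associations$enhancer[fix$associations$disease == d]
  tab <- rank_novel(fit, d, k_top = 10, catalog = fix$catalog)
  expect_lte(nrow(tab), 10L)
  expect_length(intersect(tab$enhancer, known), 0L)
  expect_true(all(diff(tab$score) <= 0))
  expect_true(all(nzchar(tab$target_genes)))
  # k_top beyond the candidate pool truncates
  big <- rank_novel(fit, d, k_top = 10000)
  universe <- union(nets$gene_net$nodes, nets$seq_net$nodes)
  expect_equal(nrow(big), length(universe) - length(known))
  expect_error(rank_novel(fit, "nosuch"), "no known enhancer")
})
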