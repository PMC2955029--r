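test_that("AU test is degenerate-safe and internally consistent", {
  ds <- simulate_cophylo_dataset(n_hosts = 6, seed = 101,
                                 seq_length = c(300, 300),
                                 model = subst_model("JC"))
  aln <- ds$aln_host
  model <- subst_model("JC")
  ml <- ml_search(aln, model, seed = 1)

  # identical topologies -> warning and p = 1 everywhere
  expect_warning(
    same <- au_test(list(ml$tree, ml$tree), aln, model, n_rell = 200,
                    seed = 2),
    "degenerate")
  expect_equal(same$table$au_p, c(1, 1))

  # against a genuinely different topology: the ML topology never has the
  # smaller AU p, and the scale-1 win frequency matches an independently
  # coded naive RELL bootstrap
  alt <- ml$tree
  alt$tip.label <- alt$tip.label[c(2, 1, 3:6)]
  res <- au_test(list(ml$tree, alt), aln, model, n_rell = 2000, seed = 3)
  expect_gte(res$table$au_p[1], res$table$au_p[2])
  expect_true(all(res$table$au_p >= 0 & res$table$au_p <= 1))

  S <- cbind(optimize_phylo(ml$tree, aln, model)$sitewise,
             optimize_phylo(alt, aln, model)$sitewise)
  wins <- 0
  set.seed(99)
  for (i in 1:2000) {
    idx <- sample.int(nrow(S), nrow(S), replace = TRUE)
    wins <- wins + (which.max(colSums(S[idx, ])) == 1)
  }
  expect_lt(abs(res$table$bp[1] - wins / 2000),
            4 * sqrt(0.25 / 2000) + 0.02)
  expect_error(au_test(list(ml$tree), aln, model), "at least two")
})

test_that("one-tree and two-tree likelihoods nest correctly", {
  ds <- simulate_cophylo_dataset(n_hosts = 6, seed = 102,
                                 seq_length = c(250, 250),
                                 model = subst_model("JC"))
  m <- subst_model("JC")
  one <- one_tree_loglik(ds$aln_host, ds$aln_parasite, m, seed = 1)
  two <- two_tree_loglik(ds$aln_host, ds$aln_parasite, m, seed = 1)
  expect_lte(one$loglik0, two$loglik1 + 1e-3)

  # identical partitions: trees agree and d ~ 0
  one_i <- one_tree_loglik(ds$aln_host, ds$aln_host, m, seed = 2)
  two_i <- two_tree_loglik(ds$aln_host, ds$aln_host, m, seed = 2)
  expect_equal(phangorn::RF.dist(two_i$tree_A, two_i$tree_B), 0)
  expect_lt(abs(2 * (one_i$loglik0 - two_i$loglik1)), 0.5)

  # concatenation ML topology equals the exhaustive best at 5 taxa
  ds5 <- simulate_cophylo_dataset(n_hosts = 5, seed = 103,
                                  seq_length = c(300, 300),
                                  model = subst_model("JC"))
  one5 <- one_tree_loglik(ds5$aln_host, ds5$aln_parasite, m, seed = 3)
  concat <- cbind(ds5$aln_host, ds5$aln_parasite)
  best <- max(vapply(seq_len(15), function(i) {
    tr <- phangorn::allTrees(5, tip.label = rownames(concat))[[i]]
    tr$edge.length <- rep(0.1, nrow(tr$edge))
    optimize_phylo(tr, concat, m, free = "branch_lengths",
                   sitewise = FALSE)$loglik
  }, numeric(1)))
  concat_fit <- ml_search(concat, m, seed = 4)
  expect_equal(concat_fit$loglik, best, tolerance = 1e-3)

  # guards
  expect_error(one_tree_loglik(ds$aln_host,
                               ds$aln_parasite[1:4, , drop = FALSE], m),
               "taxon set")
  expect_error(one_tree_loglik(ds$aln_host,
                               ds$aln_parasite[, 0, drop = FALSE], m),
               "non-empty")
})

test_that("partitions on very different trees give a large two-tree gain", {
  m <- subst_model("JC")
  ds <- simulate_cophylo_dataset(n_hosts = 8, n_switches = 4, seed = 109,
                                 seq_length = c(800, 800), model = m)
  d <- cophylointron:::.hb_d(ds$aln_host, ds$aln_parasite, m, m,
                             list(), 7)$d
  expect_lt(d, -20)
  # d is invariant to swapping the partition labels
  d_swap <- cophylointron:::.hb_d(ds$aln_parasite, ds$aln_host, m, m,
                                  list(), 7)$d
  expect_lt(abs(d - d_swap) / abs(d), 0.2)
})

test_that("hb_lrt is deterministic given a seed and directional", {
  m <- subst_model("JC")
  ds <- simulate_cophylo_dataset(n_hosts = 6, seed = 105,
                                 seq_length = c(200, 200), model = m)
  r1 <- hb_lrt(ds$aln_host, ds$aln_parasite, m, replicates = 15, seed = 5,
               null_args = fast_null_args)
  r2 <- hb_lrt(ds$aln_host, ds$aln_parasite, m, replicates = 15, seed = 5,
               null_args = fast_null_args)
  expect_identical(r1$null_d, r2$null_d)
  expect_identical(r1$p, r2$p)
  expect_lte(r1$d, 1e-3)  # nesting: d <= 0 up to tolerance
  expect_equal(r1$p, mean(r1$null_d < r1$d))

  # strong horizontal transfer rejects the one-tree hypothesis
  dsw <- simulate_cophylo_dataset(n_hosts = 8, n_switches = 3, seed = 106,
                                  seq_length = c(700, 700), model = m)
  rs <- hb_lrt(dsw$aln_host, dsw$aln_parasite, m, replicates = 29,
               seed = 6, null_args = fast_null_args)
  expect_lt(rs$p, 0.05)

  # the pair-shuffle alternative null is exposed
  rp <- hb_lrt(ds$aln_host, ds$aln_parasite, m, replicates = 5, seed = 7,
               null = "pair-shuffle", null_args = fast_null_args)
  expect_true(is.finite(rp$p))
  expect_error(hb_lrt(ds$aln_host, ds$aln_parasite, m, replicates = 0),
               "replicates")
})
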