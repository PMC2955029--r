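test_that("two-taxon JC likelihood matches the closed form", {
  tr <- ape::read.tree(text = "(a:0.05,b:0.1);")
  aln <- as_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAG"))
  ll <- tree_loglik(tr, aln, subst_model("JC"))$total
  t <- 0.15
  p_same <- 0.25 * (0.25 + 0.75 * exp(-4 * t / 3))
  p_diff <- 0.25 * (0.25 - 0.25 * exp(-4 * t / 3))
  expect_equal(ll, 9 * log(p_same) + log(p_diff), tolerance = 1e-10)
})

test_that("pruning equals brute-force state enumeration (<= 5 taxa)", {
  set.seed(11)
  for (n in 4:5) {
    tr <- ape::rtree(n)
    tr$edge.length <- tr$edge.length * 0.3
    aln <- random_aln(n, 40, labels = tr$tip.label, seed = n)
    for (model in list(
      subst_model("JC"),
      subst_model("GTR", rates = c(1, 3, 0.5, 0.8, 4, 1),
                  base_freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 0.5,
                  p_inv = 0.2, n_cat = 3))) {
      mine <- tree_loglik(tr, aln, model)$total
      oracle <- brute_force_loglik(tr, aln, model)
      expect_equal(mine, oracle, tolerance = 1e-8)
    }
  }
})

test_that("likelihood is invariant to rerooting and leaf order", {
  set.seed(12)
  tr <- ape::unroot(ape::rtree(7))
  aln <- random_aln(7, 60, labels = tr$tip.label, seed = 3)
  model <- subst_model("HKY", rates = 3, base_freqs = c(0.3, 0.2, 0.3, 0.2),
                       alpha = 0.7)
  base <- tree_loglik(tr, aln, model)$sitewise
  for (og in tr$tip.label[c(1, 4)]) {
    rr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(tree_loglik(rr, aln, model)$sitewise, base,
                 tolerance = 1e-9)
  }
  expect_equal(tree_loglik(tr, aln[sample(7), ], model)$total,
               sum(base), tolerance = 1e-9)
})

test_that("GTR+G+I with p_inv = 0 and one category reduces to plain GTR", {
  set.seed(13)
  tr <- ape::rtree(6)
  aln <- random_aln(6, 50, labels = tr$tip.label, seed = 4)
  bf <- c(0.28, 0.22, 0.24, 0.26)
  rates <- c(1.2, 3, 0.7, 1.1, 4, 1)
  plain <- subst_model("GTR", rates = rates, base_freqs = bf)
  degen <- subst_model("GTR", rates = rates, base_freqs = bf, alpha = 1e8,
                       n_cat = 1, p_inv = 0)
  expect_equal(tree_loglik(tr, aln, degen)$sitewise,
               tree_loglik(tr, aln, plain)$sitewise, tolerance = 1e-6)
})

test_that("ambiguity codes act as partial missing data", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  model <- subst_model("JC")
  full <- tree_loglik(tr, as_alignment(c(a = "A", b = "A", c = "A",
                                         d = "N")), model)$total
  # N sums over the four states; must equal the sum of the four resolved
  # likelihoods
  parts <- vapply(c("A", "C", "G", "T"), function(x)
    exp(tree_loglik(tr, as_alignment(c(a = "A", b = "A", c = "A", d = x)),
                    model)$total), numeric(1))
  expect_equal(exp(full), sum(parts), tolerance = 1e-12)
  # R = A or G
  partial <- tree_loglik(tr, as_alignment(c(a = "A", b = "A", c = "A",
                                            d = "R")), model)$total
  expect_equal(exp(partial), parts[["A"]] + parts[["G"]], tolerance = 1e-12)
})

test_that("likelihood agrees with an independent engine on larger trees", {
  set.seed(14)
  tr <- ape::rtree(9)
  aln <- random_aln(9, 120, labels = tr$tip.label, seed = 5)
  bf <- c(0.3, 0.2, 0.3, 0.2)
  rates <- c(1.5, 4, 0.8, 1.2, 5, 1)
  mine <- tree_loglik(tr, aln, subst_model("GTR", rates = rates,
                                           base_freqs = bf,
                                           p_inv = 0.25))$total
  fit <- phangorn::pml(tr, phangorn::phyDat(aln), bf = bf, Q = rates,
                       inv = 0.25)
  expect_equal(mine, fit$logLik, tolerance = 1e-6)
})

test_that("branch-length optimisation is a fixed point at the optimum and
           unimodal around it", {
  set.seed(15)
  tr <- ape::rtree(6)
  aln <- random_aln(6, 150, labels = tr$tip.label, seed = 6)
  model <- subst_model("JC")
  fit <- optimize_phylo(tr, aln, model, free = "branch_lengths")
  refit <- optimize_phylo(fit$tree, aln, model, free = "branch_lengths")
  expect_lt(abs(refit$loglik - fit$loglik), 1e-3)
  # moving one branch off its optimum decreases the likelihood both ways
  e <- which.max(fit$tree$edge.length)
  for (f in c(0.5, 2)) {
    tr2 <- fit$tree
    tr2$edge.length[e] <- max(tr2$edge.length[e], 1e-4) * f
    expect_lt(tree_loglik(tr2, aln, model)$total, fit$loglik + 1e-9)
  }
  # the message-passing optimizer reaches at least as good an optimum as
  # the simple full-recomputation reference (different coordinate-ascent
  # paths may end at different, equally valid, local optima)
  cache <- cophylointron:::.make_cache(aln)
  mp <- cophylointron:::.model_pieces(
    cophylointron:::.resolve_model(model, aln))
  pt <- cophylointron:::.prep_tree(tr, cache)
  args <- list(pt$tree$edge, 6L, 6L + pt$tree$Nnode, pt$tree$edge.length,
               pt$tip_pat, cache$enc$weights, mp$eig$U1, mp$eig$U2,
               mp$eig$lam, mp$eig$pi, mp$rc$rates, mp$rc$weights,
               10L, 1e-4, 1e-8, 20, 1e-4)
  expect_gte(do.call(cophylointron:::optimize_edges_cpp, args)$loglik,
             do.call(cophylointron:::optimize_edges_ref_cpp, args)$loglik -
               1e-6)
})

test_that("model parameters are recovered in the right order", {
  # alpha ordering: data simulated with strong vs weak rate variation
  tr <- simulate_host_tree(8, seed = 31)
  tr$edge.length <- tr$edge.length * 0.3
  gen <- function(alpha, seed)
    simulate_alignment(tr, subst_model("JC", alpha = alpha), 3000,
                       seed = seed)
  fit_a <- function(aln) {
    m <- subst_model("JC", alpha = 1)
    optimize_phylo(tr, aln, m, sitewise = FALSE)$model$alpha
  }
  a_low <- fit_a(gen(0.5, 41))
  a_high <- fit_a(gen(5, 42))
  expect_lt(a_low, a_high)
})

test_that("branch lengths are recovered from simulated data", {
  # compare patristic distances: individual root-adjacent branches of a
  # rooted tree are not identifiable under a reversible model
  tr <- ape::unroot(simulate_host_tree(5, seed = 77))
  tr$edge.length <- pmax(tr$edge.length * 0.2, 0.02)
  aln <- simulate_alignment(tr, subst_model("JC"), 5000, seed = 78)
  fit <- optimize_phylo(tr, aln, subst_model("JC"),
                        free = "branch_lengths", sitewise = FALSE)
  d_true <- patristic(tr)
  d_hat <- patristic(fit$tree)[rownames(d_true), colnames(d_true)]
  off <- upper.tri(d_true)
  expect_true(all(abs(d_hat[off] - d_true[off]) / d_true[off] < 0.15))
})

test_that("taxon mismatches and degenerate inputs raise errors", {
  tr <- ape::rtree(4)
  aln <- random_aln(4, 10, labels = c("x1", "x2", "x3", "x4"))
  expect_error(tree_loglik(tr, aln, subst_model("JC")), "taxon mismatch")
  tr2 <- ape::rtree(4); tr2$edge.length <- NULL
  expect_error(patristic(tr2), "branch lengths")
})
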