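test_that("PCoA reproduces Euclidean configurations exactly", {
  pts <- matrix(c(0, 0, 3, 0, 0, 4, 3, 4), 4, 2, byrow = TRUE)
  d <- as.matrix(stats::dist(pts))
  rownames(d) <- colnames(d) <- paste0("p", 1:4)
  pc <- pcoa(d)
  expect_equal(pc$correction_constant, 0)
  expect_equal(as.matrix(stats::dist(pc$coordinates)), unname(d),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Lingoes correction removes negative eigenvalues", {
  d <- matrix(c(0, 1, 1, 1, 0, 3, 1, 3, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  # direct eigendecomposition shows this matrix is non-Euclidean
  g <- -0.5 * d^2
  g <- sweep(sweep(g, 1, rowMeans(g)), 2, colMeans(g)) + mean(g)
  expect_lt(min(eigen(g, symmetric = TRUE)$values), -1e-8)
  un <- pcoa(d, correction = "none")
  expect_lt(min(un$all_eigenvalues), -1e-8)
  co <- pcoa(d, correction = "lingoes")
  expect_gt(co$correction_constant, 0)
  expect_gt(min(co$all_eigenvalues), -1e-6 * max(co$all_eigenvalues))
  # corrected coordinates reproduce the corrected distances
  d2 <- sqrt(d^2 + 2 * co$correction_constant); diag(d2) <- 0
  expect_equal(as.matrix(stats::dist(co$coordinates)), unname(d2),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("patristic distances need no correction after sqrt transform", {
  tr <- simulate_host_tree(10, seed = 71)
  d <- patristic(tr)
  sq <- pcoa(sqrt(d), correction = "none")
  expect_gt(min(sq$all_eigenvalues), -1e-8 * max(sq$all_eigenvalues))
  raw <- pcoa(d, correction = "lingoes")
  expect_gte(raw$correction_constant, 0)
})

test_that("ParaFit statistics obey their algebraic identities", {
  set.seed(72)
  ht <- simulate_host_tree(7, seed = 73)
  pt <- simulate_host_tree(7, seed = 74,
                           labels = paste0("q", 1:7))
  links <- data.frame(host = ht$tip.label, parasite = pt$tip.label)
  res <- parafit_test(patristic(ht), patristic(pt), links, n_perm = 99,
                      seed = 1)
  expect_gte(res$global_stat, 0)
  # defining identity: link stat + statistic-without-link = global
  A <- association_matrix(links, rownames(patristic(ht)),
                          rownames(patristic(pt)))
  hp0 <- pcoa(patristic(ht)); pp0 <- pcoa(patristic(pt))
  for (k in c(1, 4)) {
    Ak <- A; Ak[links$host[k], links$parasite[k]] <- 0L
    without <- sum((t(hp0$coordinates) %*% Ak %*% pp0$coordinates)^2)
    expect_equal(res$links$stat[k], res$global_stat - without,
                 tolerance = 1e-9)
  }
  expect_true(all(res$links$stat <= res$global_stat + 1e-9))
  expect_true(all(res$links$p > 0 & res$links$p <= 1))

  # single-link system: the link statistic is the global statistic
  one <- parafit_test(patristic(ht)[1:2, 1:2], patristic(pt)[1:2, 1:2],
                      links[1, ], n_perm = 49, seed = 2)
  expect_equal(one$links$stat[1], one$global_stat, tolerance = 1e-12)

  # invariance under host/parasite reordering
  sh <- sample(7)
  res2 <- parafit_test(patristic(ht)[sh, sh], patristic(pt), links,
                       n_perm = 9, seed = 3)
  expect_equal(res2$global_stat, res$global_stat, tolerance = 1e-9)
  # invariance under orthogonal rotation of one coordinate set
  hp <- pcoa(patristic(ht)); pp <- pcoa(patristic(pt))
  A <- association_matrix(links, rownames(patristic(ht)),
                          rownames(patristic(pt)))
  k <- ncol(hp$coordinates)
  qr_rot <- qr.Q(qr(matrix(stats::rnorm(k * k), k)))
  rot <- hp
  rot$coordinates <- hp$coordinates %*% qr_rot
  expect_equal(parafit_global(rot, pp, A, n_perm = 0)$global_stat,
               parafit_global(hp, pp, A, n_perm = 0)$global_stat,
               tolerance = 1e-9)
})

test_that("permutation p-values are reproducible and match ape's parafit", {
  ht <- simulate_host_tree(8, seed = 75)
  sc <- simulate_cophylogeny(ht, seed = 76)
  links <- sc$association
  hd <- patristic(sc$host_tree); pd <- patristic(sc$parasite_tree)
  r1 <- parafit_test(hd, pd, links, n_perm = 99, seed = 9)
  r2 <- parafit_test(hd, pd, links, n_perm = 99, seed = 9)
  expect_identical(r1$global_p, r2$global_p)
  expect_identical(r1$links$p, r2$links$p)
  # same statistic as the independent implementation in ape
  A <- association_matrix(links, rownames(hd), rownames(pd))
  suppressWarnings(
    ape_res <- ape::parafit(hd, pd, t(t(A)), nperm = 0, silent = TRUE))
  expect_equal(r1$global_stat, ape_res$ParaFitGlobal, tolerance = 1e-6)
  # co-divergent scenario: strongly significant
  expect_lt(r1$global_p, 0.05)
})

test_that("Monte-Carlo global p matches the exhaustive permutation null", {
  ht <- simulate_host_tree(5, seed = 81)
  pt <- simulate_host_tree(5, seed = 82, labels = paste0("q", 1:5))
  links <- data.frame(host = ht$tip.label, parasite = pt$tip.label)
  hd <- patristic(ht); pd <- patristic(pt)
  hp <- pcoa(hd); pp <- pcoa(pd)
  A <- association_matrix(links, rownames(hd), rownames(pd))
  exact <- parafit_exact_p(hp, pp, A)
  mc <- parafit_global(hp, pp, A, n_perm = 999, seed = 5)$global_p
  se <- sqrt(exact * (1 - exact) / 999)
  expect_lt(abs(mc - exact), 4 * se + 2 / 999)
})

test_that("dropping hosts re-runs the test on the reduced system", {
  ht <- simulate_host_tree(8, seed = 83)
  sc <- simulate_cophylogeny(ht, seed = 84)
  full <- parafit_test(patristic(ht), patristic(sc$parasite_tree),
                       sc$association, n_perm = 19, seed = 1)
  drop3 <- parafit_test(patristic(ht), patristic(sc$parasite_tree),
                        sc$association, n_perm = 19, seed = 1,
                        drop_hosts = ht$tip.label[1:3])
  expect_equal(nrow(drop3$links), nrow(full$links) - 3L)
  expect_false(any(ht$tip.label[1:3] %in% drop3$links$host))
  # zero links after dropping everything is an error
  expect_error(parafit_test(patristic(ht), patristic(sc$parasite_tree),
                            sc$association, drop_hosts = ht$tip.label),
               "no links")
})
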