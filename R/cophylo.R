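#' Approximately unbiased (AU) topology test
#'
#' Tests each candidate topology against the maximum-likelihood topology
#' of a dataset by Shimodaira's multiscale bootstrap.  For each topology
#' the branch lengths and free model parameters are re-optimised on the
#' alignment to obtain site-wise log-likelihoods; RELL resampling
#' (resampling estimated log-likelihoods, i.e. site contributions are
#' resampled without re-optimisation) at a ladder of bootstrap sizes
#' yields per-scale win frequencies, and the signed distance `d` and
#' curvature `c` of the likelihood-surface boundary are fitted by weighted
#' least squares of `qnorm(1 - BP)` on `sqrt(r)` and `1/sqrt(r)`.  The AU
#' p-value is `1 - pnorm(d - c)`.
#'
#' @param topologies List of `phylo` trees over the alignment's taxa
#'   (at least two).
#' @param aln Alignment matrix.
#' @param model A [subst_model()]; re-optimised per topology.
#' @param scales Bootstrap scale factors `r` (replicate length =
#'   `round(r * n_sites)`).
#' @param n_rell RELL replicates per scale.
#' @param seed Optional integer seed.
#' @param optim_args Extra arguments passed to [optimize_phylo()].
#' @return Object of class `au_result`: data frame `table` with one row
#'   per topology (`loglik`, `bp` -- the naive RELL proportion at scale 1
#'   -- and `au_p`), plus the scales and replicate count used.
#' @export
au_test <- function(topologies, aln, model, scales = seq(0.5, 1.4, by = 0.1),
                    n_rell = 10000, seed = NULL, optim_args = list()) {
  if (length(topologies) < 2)
    stop("need at least two candidate topologies")
  fits <- lapply(topologies, function(tr)
    do.call(optimize_phylo, c(list(tr, aln, model), optim_args)))
  S <- vapply(fits, `[[`, numeric(ncol(aln)), "sitewise")  # n x K
  K <- ncol(S); n <- nrow(S)
  centred <- S - S[, 1]
  degenerate <- max(abs(sweep(centred, 1,
                              apply(centred, 1, mean)))) < 1e-10
  if (degenerate) {
    warning("identical site log-likelihood vectors; AU test degenerate, ",
            "p = 1 for all topologies")
    tab <- data.frame(topology = seq_len(K),
                      loglik = vapply(fits, `[[`, 0, "loglik"),
                      bp = rep(1 / K, K), au_p = rep(1, K))
    return(structure(list(table = tab, scales = scales, n_rell = n_rell,
                          degenerate = TRUE), class = "au_result"))
  }
  seeds <- derive_seeds(seed, length(scales))
  bp <- matrix(NA_real_, length(scales), K)
  for (si in seq_along(scales)) {
    m <- max(1L, round(scales[si] * n))
    wins <- numeric(K)
    with_seed(seeds[[si]], {
      done <- 0L
      while (done < n_rell) {
        b <- min(2000L, n_rell - done)
        cnt <- stats::rmultinom(b, m, rep(1 / n, n))  # n x b
        rep_ll <- crossprod(cnt, S)                   # b x K
        best <- max.col(rep_ll, ties.method = "first")
        wins <- wins + tabulate(best, K)
        done <- done + b
      }
    })
    bp[si, ] <- wins / n_rell
  }
  r_eff <- pmax(1, round(scales * n)) / n
  au_p <- vapply(seq_len(K), function(k) {
    raw <- bp[, k]
    # a topology that never (always) wins at any scale is decisively
    # rejected (accepted); the signed-distance fit needs interior points
    if (all(raw == 0)) return(0)
    if (all(raw == 1)) return(1)
    interior <- raw > 0 & raw < 1
    if (sum(interior) < 2) return(raw[which.min(abs(scales - 1))])
    p <- pmin(pmax(raw[interior], 0.5 / n_rell), 1 - 0.5 / n_rell)
    z <- stats::qnorm(1 - p)
    r <- r_eff[interior]
    X <- cbind(sqrt(r), 1 / sqrt(r))
    w <- n_rell * stats::dnorm(z)^2 / (p * (1 - p))
    dc <- qr.coef(qr(X * sqrt(w)), z * sqrt(w))
    min(max(1 - stats::pnorm(dc[1] - dc[2]), 0), 1)
  }, numeric(1))
  tab <- data.frame(topology = seq_len(K),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    bp = bp[which.min(abs(scales - 1)), ], au_p = au_p)
  structure(list(table = tab, scales = scales, n_rell = n_rell,
                 bp_by_scale = bp, degenerate = FALSE),
            class = "au_result")
}

#' @export
print.au_result <- function(x, ...) {
  cat("AU test (", x$n_rell, "RELL replicates x", length(x$scales),
      "scales )\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

.check_same_taxa <- function(aln_A, aln_B) {
  if (!setequal(rownames(aln_A), rownames(aln_B)))
    stop("partitions must share one taxon set; differ by: ",
         paste(union(setdiff(rownames(aln_A), rownames(aln_B)),
                     setdiff(rownames(aln_B), rownames(aln_A))),
               collapse = ", "))
  if (ncol(aln_A) < 1 || ncol(aln_B) < 1)
    stop("both partitions must be non-empty")
}

#' One-tree and two-tree log-likelihoods for two partitions
#'
#' `one_tree_loglik()` estimates a single ML topology from the
#' concatenation of the two partitions, then optimises each partition's
#' own model and branch lengths on that fixed topology; its `loglik0` is
#' the sum.  `two_tree_loglik()` runs an independent tree search per
#' partition; its `loglik1` is the sum.  The two-tree model nests the
#' one-tree model, so `loglik1 >= loglik0` up to optimisation tolerance.
#'
#' @param aln_A,aln_B Alignment matrices over the same taxon set.
#' @param model_A,model_B [subst_model()]s for each partition (the
#'   concatenation search uses `model_A`'s family).
#' @param search_args Arguments passed to [ml_search()].
#' @param seed Optional integer seed for the searches.
#' @return `one_tree_loglik()`: list with `loglik0`, `tree`, `fit_A`,
#'   `fit_B`.  `two_tree_loglik()`: list with `loglik1`, `tree_A`,
#'   `tree_B`, `fit_A`, `fit_B`.
#' @export
one_tree_loglik <- function(aln_A, aln_B, model_A, model_B = model_A,
                            search_args = list(), seed = NULL) {
  .check_same_taxa(aln_A, aln_B)
  concat <- cbind(aln_A, aln_B[rownames(aln_A), , drop = FALSE])
  sh <- do.call(ml_search, c(list(concat, model_A, seed = seed),
                             search_args))
  opt_args <- search_args[intersect(names(search_args),
                                    c("optim_rounds", "optim_maxit",
                                      "edge_sweeps", "brent_tol",
                                      "sitewise"))]
  names(opt_args)[names(opt_args) == "optim_rounds"] <- "max_rounds"
  fit_A <- do.call(optimize_phylo,
                   c(list(sh$tree, aln_A, model_A), opt_args))
  fit_B <- do.call(optimize_phylo,
                   c(list(sh$tree, aln_B, model_B), opt_args))
  list(loglik0 = fit_A$loglik + fit_B$loglik, tree = sh$tree,
       fit_A = fit_A, fit_B = fit_B)
}

#' @rdname one_tree_loglik
#' @export
two_tree_loglik <- function(aln_A, aln_B, model_A, model_B = model_A,
                            search_args = list(), seed = NULL) {
  .check_same_taxa(aln_A, aln_B)
  seeds <- derive_seeds(seed, 2)
  fit_A <- do.call(ml_search, c(list(aln_A, model_A, seed = seeds[[1]]),
                                search_args))
  fit_B <- do.call(ml_search, c(list(aln_B, model_B, seed = seeds[[2]]),
                                search_args))
  list(loglik1 = fit_A$loglik + fit_B$loglik, tree_A = fit_A$tree,
       tree_B = fit_B$tree, fit_A = fit_A, fit_B = fit_B)
}

# d = 2(lnL0 - lnL1) for a pair of partitions, at a given search effort.
.hb_d <- function(aln_A, aln_B, model_A, model_B, search_args, seed) {
  seeds <- derive_seeds(seed, 2)
  one <- one_tree_loglik(aln_A, aln_B, model_A, model_B,
                         search_args = search_args, seed = seeds[[1]])
  two <- two_tree_loglik(aln_A, aln_B, model_A, model_B,
                         search_args = search_args, seed = seeds[[2]])
  list(d = 2 * (one$loglik0 - two$loglik1), one = one, two = two)
}

#' Non-parametric Huelsenbeck-Bull likelihood-ratio test of congruence
#'
#' Tests whether two data partitions (here, a cox1 "host" partition and an
#' intron "parasite" partition over the same individuals) support a shared
#' topology.  The statistic is `d = 2 * (lnL0 - lnL1)`, where `lnL0`
#' constrains both partitions to one topology (each with its own model and
#' branch lengths) and `lnL1` lets each partition have its own topology;
#' `d <= 0` by construction.  The null distribution is built by
#' non-parametric bootstrap: each replicate resamples the columns of each
#' partition independently, concatenates them, and randomises which
#' columns belong to which partition (`null = "site-shuffle"`, the
#' default).  Both pseudo-partitions of a replicate then carry the same
#' blended signal, which is exactly the one-tree null hypothesis, so the
#' null `d` captures the incongruence expected from sampling noise alone;
#' an observed `d` deep in its left tail indicates real topological
#' conflict.  `null = "pair-shuffle"` instead randomises the
#' taxon-to-taxon association between the partitions (the ParaFit-style
#' randomisation); it destroys co-ancestry entirely and therefore
#' calibrates against maximal incongruence rather than against the
#' one-tree hypothesis -- exposed for comparison, not recommended for
#' testing H0.  The p-value is the plain proportion of null statistics
#' smaller (more incongruent) than the observed one, with no continuity
#' correction.
#'
#' Null-replicate tree searches use a reduced search effort
#' (`null_args`); the observed statistic uses the full configured search.
#'
#' @inheritParams one_tree_loglik
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed (controls bootstraps, shuffles and searches).
#' @param null Randomisation scheme, see Details.
#' @param null_args Reduced [ml_search()] settings for null replicates.
#' @return Object of class `hb_lrt`: `loglik0`, `loglik1`, `d`, `null_d`,
#'   `p`, `replicates`, `null`, plus the fitted trees.
#' @export
hb_lrt <- function(aln_A, aln_B, model_A, model_B = model_A,
                   replicates = 500, seed = NULL,
                   null = c("site-shuffle", "pair-shuffle"),
                   search_args = list(),
                   null_args = list(max_rounds = 1, optim_rounds = 1,
                                    screen_top = 1, optim_maxit = 40,
                                    edge_sweeps = 3, brent_tol = 1e-3,
                                    sitewise = FALSE)) {
  null <- match.arg(null)
  if (replicates < 1) stop("replicates must be >= 1")
  .check_same_taxa(aln_A, aln_B)
  seeds <- derive_seeds(seed, replicates + 1)
  obs <- .hb_d(aln_A, aln_B, model_A, model_B, search_args,
               seeds[[replicates + 1]])
  null_d <- vapply(seq_len(replicates), function(i) {
    draw <- with_seed(seeds[[i]], list(
      ia = sample.int(ncol(aln_A), ncol(aln_A), replace = TRUE),
      ib = sample.int(ncol(aln_B), ncol(aln_B), replace = TRUE),
      perm = sample(nrow(aln_B)),
      cols = sample(ncol(aln_A) + ncol(aln_B)),
      s1 = sample.int(.Machine$integer.max - 1L, 1),
      s2 = sample.int(.Machine$integer.max - 1L, 1)))
    ba <- aln_A[, draw$ia, drop = FALSE]
    bb <- aln_B[, draw$ib, drop = FALSE]
    if (null == "pair-shuffle") {
      rownames(bb) <- rownames(bb)[draw$perm]
    } else {
      conc <- cbind(ba, bb[rownames(ba), , drop = FALSE])
      conc <- conc[, draw$cols, drop = FALSE]
      ba <- conc[, seq_len(ncol(aln_A)), drop = FALSE]
      bb <- conc[, ncol(aln_A) + seq_len(ncol(aln_B)), drop = FALSE]
    }
    .hb_d(ba, bb, model_A, model_B, null_args, draw$s1)$d
  }, numeric(1))
  p <- mean(null_d < obs$d)
  structure(list(loglik0 = obs$one$loglik0, loglik1 = obs$two$loglik1,
                 d = obs$d, null_d = null_d, p = p,
                 replicates = replicates, null = null,
                 tree_shared = obs$one$tree, tree_A = obs$two$tree_A,
                 tree_B = obs$two$tree_B, seed = seed),
            class = "hb_lrt")
}

#' @export
print.hb_lrt <- function(x, ...) {
  cat("Huelsenbeck-Bull likelihood-ratio test (", x$null, "null )\n")
  cat(sprintf("  lnL0 = %.3f (one tree), lnL1 = %.3f (two trees)\n",
              x$loglik0, x$loglik1))
  cat(sprintf("  d = 2(lnL0 - lnL1) = %.3f\n", x$d))
  cat(sprintf("  p = %d/%d = %.4g  (proportion of null d below observed)\n",
              sum(x$null_d < x$d), x$replicates, x$p))
  invisible(x)
}
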