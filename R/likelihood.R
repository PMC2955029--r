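#' @useDynLib cophylointron, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.check_taxa <- function(tree, aln) {
  extra <- setdiff(tree$tip.label, rownames(aln))
  miss <- setdiff(rownames(aln), tree$tip.label)
  if (length(extra) || length(miss))
    stop("taxon mismatch between tree and alignment; ",
         if (length(extra)) paste0("in tree only: ",
                                   paste(extra, collapse = ", "), "; "),
         if (length(miss)) paste0("in alignment only: ",
                                  paste(miss, collapse = ", ")))
}

# Resolve a model's base frequencies against the data (empirical if NULL).
.resolve_model <- function(model, aln) {
  if (is.null(model$base_freqs))
    model$base_freqs <- empirical_base_freqs(aln)
  model
}

# Pattern cache: encode the alignment once per analysis; per-tree tip
# reordering is a cheap column permutation of the pattern matrix.
.make_cache <- function(aln) {
  enc <- encode_patterns(aln, rownames(aln))
  list(enc = enc, taxa = rownames(aln), n_cols = ncol(aln))
}

.model_pieces <- function(model) {
  list(eig = model_eigen(model), rc = rate_classes(model))
}

.prep_tree <- function(tree, cache) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  tree <- ape::reorder.phylo(tree, "postorder")
  ord <- match(tree$tip.label, cache$taxa)
  if (anyNA(ord))
    stop("taxa missing from alignment: ",
         paste(tree$tip.label[is.na(ord)], collapse = ", "))
  list(tree = tree, tip_pat = cache$enc$tip_pat[, ord, drop = FALSE])
}

# Per-pattern log-likelihoods for a prepared tree.
.cached_patterns_ll <- function(pt, cache, mp) {
  site_loglik_cpp(pt$tree$edge, length(pt$tree$tip.label),
                  length(pt$tree$tip.label) + pt$tree$Nnode,
                  pt$tree$edge.length, pt$tip_pat,
                  mp$eig$U1, mp$eig$U2, mp$eig$lam, mp$eig$pi,
                  mp$rc$rates, mp$rc$weights)
}

.cached_total <- function(tree, cache, mp) {
  pt <- .prep_tree(tree, cache)
  sum(cache$enc$weights * .cached_patterns_ll(pt, cache, mp))
}

.cached_opt_edges <- function(tree, cache, mp, max_sweeps = 10, tol = 1e-4,
                              brent_tol = 1e-4) {
  pt <- .prep_tree(tree, cache)
  res <- optimize_edges_cpp(pt$tree$edge, length(pt$tree$tip.label),
                            length(pt$tree$tip.label) + pt$tree$Nnode,
                            pmax(pt$tree$edge.length, 1e-8), pt$tip_pat,
                            cache$enc$weights, mp$eig$U1, mp$eig$U2,
                            mp$eig$lam, mp$eig$pi, mp$rc$rates,
                            mp$rc$weights, max_sweeps, tol, 1e-8, 20,
                            brent_tol)
  tr <- pt$tree
  tr$edge.length <- res$lens
  list(tree = tr, loglik = res$loglik)
}

#' Site-wise log-likelihood under a substitution model
#'
#' Computes per-column log-likelihoods of an alignment on a tree by
#' Felsenstein pruning, summing over discrete-gamma rate categories and an
#' invariant-sites class.  Ambiguous or missing states contribute a partial
#' likelihood of 1 over their compatible nucleotides.
#'
#' @param tree An `ape::phylo` tree with branch lengths in expected
#'   substitutions per site; may be rooted or unrooted (the model is
#'   time-reversible, so the root placement is immaterial).
#' @param aln Alignment matrix (see [as_alignment()]).
#' @param model A [subst_model()].
#' @return List with `sitewise` (per-column log-likelihoods) and `total`.
#' @export
tree_loglik <- function(tree, aln, model) {
  .check_taxa(tree, aln)
  model <- .resolve_model(model, aln)
  cache <- .make_cache(aln)
  mp <- .model_pieces(model)
  pt <- .prep_tree(tree, cache)
  sl <- .cached_patterns_ll(pt, cache, mp)
  if (any(!is.finite(sl)))
    stop("non-finite site log-likelihood (degenerate model or data)")
  sitewise <- sl[cache$enc$index]
  list(sitewise = sitewise, total = sum(sitewise))
}

# Shared core for optimize_phylo/ml_search working on a prebuilt cache.
.optimize_core <- function(tree, cache, model, free, max_rounds, tol,
                           edge_sweeps, optim_maxit, brent_tol = 1e-4) {
  mp <- .model_pieces(model)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  ll <- .cached_total(tree, cache, mp)
  pack <- model_pack(model)
  for (round in seq_len(max_rounds)) {
    ll_prev <- ll
    if ("branch_lengths" %in% free) {
      oe <- .cached_opt_edges(tree, cache, mp, max_sweeps = edge_sweeps,
                              tol = tol, brent_tol = brent_tol)
      tree <- oe$tree
      ll <- oe$loglik
    }
    if ("model" %in% free && length(pack)) {
      obj <- function(p) {
        m <- model_unpack(model, p)
        lt <- tryCatch(.cached_total(tree, cache, .model_pieces(m)),
                       error = function(e) -Inf)
        if (!is.finite(lt)) 1e10 else -lt
      }
      opt <- if (length(pack) == 1L)
        stats::optim(pack, obj, method = "Brent", lower = pack - 8,
                     upper = pack + 8)
      else
        stats::optim(pack, obj, method = "Nelder-Mead",
                     control = list(maxit = optim_maxit))
      if (-opt$value > ll) {
        pack <- opt$par
        model <- model_unpack(model, pack)
        mp <- .model_pieces(model)
        ll <- -opt$value
      }
    }
    if (ll - ll_prev < tol) break
  }
  if (!is.finite(ll)) stop("non-finite likelihood after optimisation")
  list(tree = tree, model = model, loglik = ll)
}

#' Optimize branch lengths and model parameters on a fixed topology
#'
#' Coordinate-ascent maximum likelihood: sweeps of per-branch Brent line
#' searches (bounded to `[1e-8, 20]` substitutions/site) alternate with
#' numerical optimisation of the free model parameters
#' (exchangeabilities, gamma shape, invariant proportion), until the
#' log-likelihood improves by less than `tol` between rounds.  Base
#' frequencies are fixed at their empirical values when the model leaves
#' them unspecified.
#'
#' @inheritParams tree_loglik
#' @param free Which parameter blocks to optimise: any of
#'   `"branch_lengths"`, `"model"`.
#' @param max_rounds Maximum coordinate-ascent rounds.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param edge_sweeps Brent sweeps per branch-length round.
#' @param optim_maxit Iterations for the model-parameter optimiser.
#' @param brent_tol Relative x-tolerance of the per-branch Brent search.
#' @param sitewise Also return per-column log-likelihoods.
#' @return List with elements `tree`, `model`, `loglik` and (when
#'   requested) `sitewise`.
#' @export
optimize_phylo <- function(tree, aln, model,
                           free = c("branch_lengths", "model"),
                           max_rounds = 20, tol = 1e-4, edge_sweeps = 10,
                           optim_maxit = 200, brent_tol = 1e-4,
                           sitewise = TRUE) {
  free <- match.arg(free, several.ok = TRUE)
  .check_taxa(tree, aln)
  model <- .resolve_model(model, aln)
  cache <- .make_cache(aln)
  fit <- .optimize_core(tree, cache, model, free, max_rounds, tol,
                        edge_sweeps, optim_maxit, brent_tol)
  if (sitewise)
    fit$sitewise <- tree_loglik(fit$tree, aln, fit$model)$sitewise
  fit
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (via `ape::nj`) with negative branch-length
#' estimates clamped to zero.
#'
#' @param d Symmetric distance matrix with labelled rows/columns.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Patristic distance matrix
#'
#' Sums of branch lengths along the tree path between every pair of leaves.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Symmetric labelled distance matrix.
#' @export
patristic <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  m <- stats::cophenetic(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Bootstrap alignment columns
#'
#' Draws `ncol(aln)` columns i.i.d. with replacement; reproducible given a
#' seed.
#'
#' @param aln Alignment matrix.
#' @param seed Optional integer seed.
#' @return Alignment matrix of the same dimensions.
#' @export
bootstrap_columns <- function(aln, seed = NULL) {
  idx <- with_seed(seed, sample.int(ncol(aln), ncol(aln), replace = TRUE))
  aln[, idx, drop = FALSE]
}

# NJ starting tree from model-corrected distances, with saturated pairs
# (non-finite JC distances) replaced by a large finite value.
.nj_start <- function(aln) {
  dna <- ape::as.DNAbin(tolower(aln))
  d <- tryCatch(
    as.matrix(ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE)),
    error = function(e) NULL)
  if (is.null(d) || any(!is.finite(d))) {
    draw <- as.matrix(ape::dist.dna(dna, model = "raw",
                                    pairwise.deletion = TRUE))
    if (is.null(d)) d <- draw
    big <- max(d[is.finite(d)], 1)
    d[!is.finite(d)] <- 1.25 * big + 1
  }
  nj_tree(d)
}

#' Heuristic maximum-likelihood tree search
#'
#' Hill climbing from a neighbor-joining start: each round every
#' nearest-neighbor-interchange move (and, optionally, a batch of random
#' subtree-prune-and-regraft moves) is screened at the current branch
#' lengths, the most promising candidates get their branch lengths
#' re-optimised, and the best strictly improving rearrangement is
#' accepted, followed by re-optimisation of the model parameters.  The
#' search stops when no move improves the log-likelihood, so on a flat
#' surface (for example, identical sequences) it returns the optimised
#' starting tree.  Deterministic given `seed`.
#'
#' @inheritParams tree_loglik
#' @param moves Rearrangement moves: `"NNI"` or `c("NNI", "SPR")`.
#' @param seed Integer seed controlling the SPR proposals (and nothing
#'   else; NNI enumeration is deterministic).
#' @param max_rounds Maximum move rounds.
#' @param screen_top Number of screened candidates promoted to
#'   branch-length re-optimisation each round.
#' @param spr_per_round Number of random SPR proposals per round.
#' @param optim_rounds Coordinate rounds in the full optimisations.
#' @param optim_maxit Iterations for the model-parameter optimiser.
#' @param edge_sweeps,brent_tol,sitewise As in [optimize_phylo()].
#' @return List with `tree`, `model`, `loglik` and (when requested)
#'   `sitewise`.
#' @export
ml_search <- function(aln, model, moves = "NNI", seed = NULL,
                      max_rounds = 20, screen_top = 3, spr_per_round = 10,
                      optim_rounds = 20, optim_maxit = 200,
                      edge_sweeps = 10, brent_tol = 1e-4,
                      sitewise = TRUE) {
  moves <- match.arg(moves, c("NNI", "SPR"), several.ok = TRUE)
  if (nrow(aln) < 4) stop("tree search needs at least 4 taxa")
  model <- .resolve_model(model, aln)
  cache <- .make_cache(aln)
  start <- .nj_start(aln)
  fit <- .optimize_core(start, cache, model,
                        free = c("branch_lengths", "model"),
                        max_rounds = optim_rounds, tol = 1e-4,
                        edge_sweeps = edge_sweeps,
                        optim_maxit = optim_maxit, brent_tol = brent_tol)
  tree <- fit$tree; model <- fit$model; ll <- fit$loglik
  mp <- .model_pieces(model)
  for (round in seq_len(max_rounds)) {
    cands <- tryCatch(phangorn::nni(tree), error = function(e) list())
    # multiPhylo stores tip labels compressed; expand before iteration
    cands <- lapply(seq_along(cands), function(i) cands[[i]])
    if ("SPR" %in% moves && length(tree$tip.label) >= 5) {
      sprs <- with_seed(if (is.null(seed)) NULL else seed + round,
                        replicate(spr_per_round,
                                  tryCatch(phangorn::rSPR(tree, moves = 1),
                                           error = function(e) NULL),
                                  simplify = FALSE))
      cands <- c(cands, Filter(Negate(is.null), sprs))
    }
    if (!length(cands)) break
    # cheap screen: one likelihood evaluation per candidate
    screen <- vapply(cands, function(cand) {
      if (is.null(cand$edge.length) || anyNA(cand$edge.length) ||
          any(cand$edge.length < 0))
        cand$edge.length <- rep(0.1, nrow(cand$edge))
      tryCatch(.cached_total(cand, cache, mp), error = function(e) -Inf)
    }, numeric(1))
    ord <- order(screen, decreasing = TRUE)[seq_len(min(screen_top,
                                                        length(cands)))]
    best_ll <- ll; best_tree <- NULL
    for (i in ord) {
      cand <- cands[[i]]
      if (is.null(cand$edge.length) || anyNA(cand$edge.length) ||
          any(cand$edge.length < 0))
        cand$edge.length <- rep(0.1, nrow(cand$edge))
      sc <- .cached_opt_edges(cand, cache, mp, max_sweeps = 2,
                              brent_tol = 1e-3)
      if (sc$loglik > best_ll + 1e-6) {
        best_ll <- sc$loglik
        best_tree <- sc$tree
      }
    }
    if (is.null(best_tree)) break
    fit <- .optimize_core(best_tree, cache, model,
                          free = c("branch_lengths", "model"),
                          max_rounds = min(3, optim_rounds), tol = 1e-4,
                          edge_sweeps = min(5, edge_sweeps),
                          optim_maxit = optim_maxit, brent_tol = brent_tol)
    tree <- fit$tree; model <- fit$model; ll <- fit$loglik
    mp <- .model_pieces(model)
  }
  out <- list(tree = tree, model = model, loglik = ll)
  if (sitewise) out$sitewise <- tree_loglik(tree, aln, model)$sitewise
  out
}
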