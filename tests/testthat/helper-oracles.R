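# Independent oracles and small fixture builders used across the suite.

# Brute-force tree likelihood by explicit summation over all internal-state
# assignments, with transition matrices from ape::matexpo -- an independent
# path from the pruning engine's eigendecomposition.  Tips must be
# unambiguous A/C/G/T.
brute_force_loglik <- function(tree, aln, model) {
  if (is.null(model$base_freqs)) model$base_freqs <- rep(0.25, 4)
  Q <- cophylointron:::model_Q(model)
  rc <- cophylointron:::rate_classes(model)
  nuc <- c("A", "C", "G", "T")
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  n_int <- tree$Nnode
  root <- ntip + 1L
  aln <- aln[tree$tip.label, , drop = FALSE]
  tip_state <- matrix(match(aln, nuc), nrow = ntip)
  stopifnot(!anyNA(tip_state))
  assigns <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  site_ll <- numeric(ncol(aln))
  for (ci in seq_along(rc$rates)) {
    P <- lapply(tree$edge.length, function(t)
      ape::matexpo(Q * rc$rates[ci] * t))
    for (s in seq_len(ncol(aln))) {
      lik <- 0
      for (a in seq_len(nrow(assigns))) {
        state <- c(tip_state[, s], assigns[a, ])
        term <- model$base_freqs[state[root]]
        for (e in seq_len(nrow(tree$edge)))
          term <- term * P[[e]][state[tree$edge[e, 1]],
                                state[tree$edge[e, 2]]]
        lik <- lik + term
      }
      site_ll[s] <- site_ll[s] + rc$weights[ci] * lik
    }
  }
  sum(log(site_ll))
}

# Random alignment of pure A/C/G/T columns.
random_aln <- function(n_taxa, n_cols, labels = paste0("t", seq_len(n_taxa)),
                       seed = NULL) {
  cophylointron:::with_seed(seed, {
    m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * n_cols,
                       replace = TRUE), n_taxa)
    rownames(m) <- labels
    m
  })
}

# Random coding-style reference sequence (no length-3 structure needed for
# insertion-detection tests, just nucleotides).
random_dna <- function(n, seed = NULL) {
  cophylointron:::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# Reverse-translate a protein into nucleotides under table 4, using a fixed
# codon per amino acid ('#' marks a TGA-encoded tryptophan).
codon_for <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
               M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT",
               "#" = "TGA", "*" = "TAA")
protein_to_dna <- function(protein) {
  paste(codon_for[strsplit(protein, "")[[1]]], collapse = "")
}

# An intron carrying a single LAGLIDADG ORF with one internal TGA
# tryptophan, padded with ORF-free flanks.
laglidadg_intron <- function(flank5 = 40, flank3 = 40, seed = 1) {
  orf <- protein_to_dna(paste0(
    "M", strrep("S", 20), "LAGLIDADG", strrep("T", 20), "#",
    strrep("K", 15), "*"))
  pad <- function(n, sd) paste(rep("C", n), collapse = "")
  paste0(pad(flank5), orf, pad(flank3))
}

# Exact ParaFit global null by enumerating every independent host
# assignment (columns carry a single 1, so a column permutation is a
# uniform host choice).
parafit_exact_p <- function(host_pc, para_pc, A) {
  B <- host_pc$coordinates; C <- para_pc$coordinates
  obs <- sum((t(B) %*% A %*% C)^2)
  h <- nrow(A); p <- ncol(A)
  grids <- as.matrix(expand.grid(rep(list(seq_len(h)), p)))
  stats <- apply(grids, 1, function(assign) {
    Ap <- matrix(0L, h, p)
    Ap[cbind(assign, seq_len(p))] <- 1L
    sum((t(B) %*% Ap %*% C)^2)
  })
  mean(stats >= obs - 1e-12)
}

fast_null_args <- list(max_rounds = 1, optim_rounds = 1, screen_top = 1,
                       optim_maxit = 40, edge_sweeps = 3, brent_tol = 1e-3,
                       sitewise = FALSE)
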