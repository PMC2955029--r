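#' Principal coordinates analysis with Lingoes correction
#'
#' Embeds a distance matrix in Euclidean axes: Gower double-centering of
#' `-0.5 * d^2`, eigendecomposition, coordinates scaled by the square root
#' of the eigenvalues.  If the matrix is non-Euclidean (negative
#' eigenvalues) and `correction = "lingoes"`, the constant
#' `c1 = |lambda_min|` is added to all squared off-diagonal distances
#' (`d'^2 = d^2 + 2 c1`) and the decomposition is repeated, after which no
#' retained eigenvalue is negative beyond tolerance.  Axes with
#' eigenvalues below `eig_tol * lambda_max` are dropped; axes with
#' negative eigenvalues are never retained.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param correction `"lingoes"` or `"none"`.
#' @param eig_tol Relative eigenvalue tolerance for retaining axes.
#' @return Object of class `pcoa_result`: `coordinates` (points x axes),
#'   `eigenvalues` (retained), `all_eigenvalues` (of the corrected
#'   matrix), and `correction_constant` (0 when no correction applied).
#' @export
pcoa <- function(d, correction = c("lingoes", "none"), eig_tol = 1e-8) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
  n <- nrow(d)
  gower <- function(d2) {
    g <- -0.5 * d2
    rm <- rowMeans(g)
    g - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(g)
  }
  eig <- eigen(gower(d^2), symmetric = TRUE)
  cc <- 0
  tol_neg <- eig_tol * max(abs(eig$values), 1e-300)
  if (correction == "lingoes" && min(eig$values) < -tol_neg) {
    cc <- abs(min(eig$values))
    d2 <- d^2 + 2 * cc
    diag(d2) <- 0
    eig <- eigen(gower(d2), symmetric = TRUE)
  }
  keep <- eig$values > eig_tol * max(eig$values, 1e-300)
  coords <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), sum(keep))
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords, eigenvalues = eig$values[keep],
                 all_eigenvalues = eig$values, correction_constant = cc),
            class = "pcoa_result")
}

#' Build a binary host-parasite association matrix
#'
#' @param links Data frame with columns `host`, `parasite`.
#' @param hosts,parasites Row/column universes (default: the values seen
#'   in `links`).
#' @return Binary matrix, rows = hosts, columns = parasites.
#' @export
association_matrix <- function(links, hosts = unique(links$host),
                               parasites = unique(links$parasite)) {
  if (anyDuplicated(links[c("host", "parasite")]))
    stop("duplicate host-parasite links")
  A <- matrix(0L, length(hosts), length(parasites),
              dimnames = list(hosts, parasites))
  miss_h <- setdiff(links$host, hosts)
  miss_p <- setdiff(links$parasite, parasites)
  if (length(miss_h) || length(miss_p))
    stop("links refer to unknown taxa: ",
         paste(c(miss_h, miss_p), collapse = ", "))
  A[cbind(match(links$host, hosts), match(links$parasite, parasites))] <- 1L
  if (any(colSums(A) == 0))
    stop("every parasite must be linked to at least one host")
  A
}

# Fourth-corner cross-statistic: sum of squares of B' A C with B = host
# coordinates, C = parasite coordinates, A hosts x parasites.
.parafit_stat <- function(host_coords, para_coords, A) {
  sum((t(host_coords) %*% A %*% para_coords)^2)
}

# One null draw: permute each parasite's host assignment independently.
.permute_assoc <- function(A) apply(A, 2, sample)

#' ParaFit test of host-parasite co-speciation
#'
#' Reimplementation of Legendre's ParaFit: the global statistic is the
#' sum of squared entries of the fourth-corner matrix `B' A C`, where `B`
#' and `C` are principal coordinates of the host and parasite patristic
#' distance matrices (Lingoes-corrected where needed) and `A` is the
#' binary host x parasite association matrix.  Under the null hypothesis
#' host and parasite phylogenies are randomly associated; the null
#' distribution permutes, independently for each parasite, which host it
#' attaches to.  The per-link ParaFitLink1 statistic is the drop in the
#' global statistic when the link is removed, tested against the same
#' permutation stream.  P-values use the add-one permutation estimate
#' `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param host_d,parasite_d Patristic (or other) distance matrices with
#'   labelled rows; typically from [patristic()].
#' @param links Data frame with columns `host`, `parasite`, one row per
#'   association link.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed (fixed seed gives bit-identical
#'   p-values).
#' @param correction PCoA correction, passed to [pcoa()].
#' @param sqrt_dist Square-root transform the distances before embedding
#'   (tree metrics become exactly Euclidean); default `FALSE`, matching
#'   the DistPCoA-plus-Lingoes usage on raw patristic distances.
#' @param test_links Compute per-link statistics and p-values.
#' @param drop_hosts Hosts to exclude (with their links) before testing;
#'   supports leave-taxa-out sensitivity re-runs.
#' @return Object of class `parafit_result`: `global_stat`, `global_p`,
#'   `links` (data frame with per-link `stat` and `p` when
#'   `test_links = TRUE`), `n_perm`, PCoA metadata.
#' @export
parafit_test <- function(host_d, parasite_d, links, n_perm = 999,
                         seed = NULL, correction = "lingoes",
                         sqrt_dist = FALSE, test_links = TRUE,
                         drop_hosts = character(0)) {
  if (length(drop_hosts)) {
    links <- links[!(links$host %in% drop_hosts), , drop = FALSE]
    if (!nrow(links)) stop("no links left after dropping hosts")
  }
  hosts <- intersect(rownames(as.matrix(host_d)), unique(links$host))
  paras <- intersect(rownames(as.matrix(parasite_d)),
                     unique(links$parasite))
  bad <- setdiff(unique(c(links$host, links$parasite)), c(hosts, paras))
  if (length(bad))
    stop("links refer to taxa absent from the distance matrices: ",
         paste(bad, collapse = ", "))
  hd <- as.matrix(host_d)[hosts, hosts]
  pd <- as.matrix(parasite_d)[paras, paras]
  if (sqrt_dist) { hd <- sqrt(hd); pd <- sqrt(pd) }
  A <- association_matrix(links, hosts, paras)
  host_pc <- pcoa(hd, correction = correction)
  para_pc <- pcoa(pd, correction = correction)
  B <- host_pc$coordinates; C <- para_pc$coordinates
  global <- .parafit_stat(B, C, A)

  link_idx <- which(A > 0, arr.ind = TRUE)
  link_stat <- rep(NA_real_, nrow(link_idx))
  A_minus <- vector("list", nrow(link_idx))
  for (k in seq_len(nrow(link_idx))) {
    Ak <- A; Ak[link_idx[k, 1], link_idx[k, 2]] <- 0L
    A_minus[[k]] <- Ak
    link_stat[k] <- global - .parafit_stat(B, C, Ak)
  }

  n_ge_global <- 0L
  n_ge_link <- integer(nrow(link_idx))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      perm_cols <- lapply(seq_len(ncol(A)), function(j) sample(nrow(A)))
      Ap <- A
      for (j in seq_len(ncol(A))) Ap[, j] <- A[perm_cols[[j]], j]
      g_perm <- .parafit_stat(B, C, Ap)
      if (g_perm >= global) n_ge_global <- n_ge_global + 1L
      if (test_links) {
        for (k in seq_len(nrow(link_idx))) {
          Akp <- A_minus[[k]]
          for (j in seq_len(ncol(A))) Akp[, j] <-
              A_minus[[k]][perm_cols[[j]], j]
          s_perm <- g_perm - .parafit_stat(B, C, Akp)
          if (s_perm >= link_stat[k]) n_ge_link[k] <- n_ge_link[k] + 1L
        }
      }
    }
  })
  link_tab <- data.frame(host = hosts[link_idx[, 1]],
                         parasite = paras[link_idx[, 2]],
                         stat = link_stat,
                         p = if (test_links)
                           (1 + n_ge_link) / (1 + n_perm)
                         else NA_real_)
  structure(list(global_stat = global,
                 global_p = (1 + n_ge_global) / (1 + n_perm),
                 links = link_tab, n_perm = n_perm, seed = seed,
                 host_pcoa = host_pc, parasite_pcoa = para_pc,
                 sqrt_dist = sqrt_dist,
                 convention = "stat = sum((B' A C)^2); B, C = PCoA axes scaled by sqrt(eigenvalue); A hosts x parasites"),
            class = "parafit_result")
}

#' @export
print.parafit_result <- function(x, ...) {
  cat("ParaFit co-speciation test (", x$n_perm, "permutations )\n")
  cat(sprintf("  ParaFitGlobal = %.6g, p = %.4g\n", x$global_stat,
              x$global_p))
  if (!all(is.na(x$links$p))) {
    cat("  per-link ParaFitLink1:\n")
    print(x$links, row.names = FALSE)
  }
  invisible(x)
}

#' @rdname parafit_test
#' @param host_pcoa,parasite_pcoa Precomputed [pcoa()] embeddings.
#' @param A Binary association matrix (hosts x parasites).
#' @return `parafit_global()`: list with `global_stat` and `global_p`.
#' @export
parafit_global <- function(host_pcoa, parasite_pcoa, A, n_perm = 999,
                           seed = NULL) {
  B <- host_pcoa$coordinates; C <- parasite_pcoa$coordinates
  if (nrow(B) != nrow(A) || nrow(C) != ncol(A))
    stop("association matrix dimensions do not match the PCoA point counts")
  global <- .parafit_stat(B, C, A)
  if (n_perm < 1)
    return(list(global_stat = global, global_p = NA_real_))
  n_ge <- with_seed(seed,
    sum(replicate(n_perm,
                  .parafit_stat(B, C, .permute_assoc(A)) >= global)))
  list(global_stat = global, global_p = (1 + n_ge) / (1 + n_perm))
}

#' @rdname parafit_test
#' @param link Length-2 vector `c(host, parasite)` naming one link of `A`.
#' @return `parafit_link1()`: list with `stat` and `p`.
#' @export
parafit_link1 <- function(host_pcoa, parasite_pcoa, A, link, n_perm = 999,
                          seed = NULL) {
  hi <- match(link[1], rownames(A)); pj <- match(link[2], colnames(A))
  if (is.na(hi) || is.na(pj) || A[hi, pj] == 0)
    stop("link not present in the association matrix: ",
         paste(link, collapse = " - "))
  B <- host_pcoa$coordinates; C <- parasite_pcoa$coordinates
  global <- .parafit_stat(B, C, A)
  Ak <- A; Ak[hi, pj] <- 0L
  stat <- global - .parafit_stat(B, C, Ak)
  n_ge <- with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      perm_cols <- lapply(seq_len(ncol(A)), function(j) sample(nrow(A)))
      Ap <- A; Akp <- Ak
      for (j in seq_len(ncol(A))) {
        Ap[, j] <- A[perm_cols[[j]], j]
        Akp[, j] <- Ak[perm_cols[[j]], j]
      }
      s_perm <- .parafit_stat(B, C, Ap) - .parafit_stat(B, C, Akp)
      if (s_perm >= stat) cnt <- cnt + 1L
    }
    cnt
  })
  list(stat = stat, p = (1 + n_ge) / (1 + n_perm))
}
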