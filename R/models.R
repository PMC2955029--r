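#' Nucleotide substitution models
#'
#' Constructs a reversible substitution model of the GTR family, optionally
#' with discrete-gamma rate variation across sites and a proportion of
#' invariant sites (the "+G+I" extensions).  The rate matrix is always
#' rescaled so that the mean substitution rate at stationarity is 1, so
#' branch lengths are in expected substitutions per site.
#'
#' Exchangeabilities are given in the order AC, AG, AT, CG, CT, GT.
#' `K80`/`HKY` take a single transition/transversion ratio `kappa`; `TrN`
#' takes two transition rates (AG and CT) and a single transversion rate;
#' `GTR` takes all six (the GT rate is used as the reference and scaled
#' to 1).
#'
#' @param family One of `"JC"`, `"K80"`, `"HKY"`, `"TrN"`, `"GTR"`.
#' @param rates Exchangeability parameters as described above; ignored for
#'   `JC`, a scalar `kappa` for `K80`/`HKY`, length-2 `c(AG, CT)` for `TrN`,
#'   length-6 for `GTR`.
#' @param base_freqs Stationary base frequencies (A, C, G, T), summing to 1,
#'   or `NULL` to use empirical frequencies of the data at fit time.
#'   `JC`/`K80` force equal frequencies.
#' @param alpha Shape of the gamma distribution of site rates, or `NULL`
#'   for rate homogeneity.
#' @param p_inv Proportion of invariant sites in `[0, 1)`, or `NULL` for
#'   none.
#' @param n_cat Number of discrete gamma categories (default 4).
#' @return An object of class `subst_model`.
#' @examples
#' subst_model("GTR", rates = c(1, 4, 1, 1, 4, 1),
#'             base_freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 0.5, p_inv = 0.2)
#' @export
subst_model <- function(family = c("JC", "K80", "HKY", "TrN", "GTR"),
                        rates = NULL, base_freqs = NULL, alpha = NULL,
                        p_inv = NULL, n_cat = 4L) {
  family <- match.arg(family)
  if (family %in% c("JC", "K80")) {
    base_freqs <- rep(0.25, 4)
  } else if (!is.null(base_freqs)) {
    stopifnot(length(base_freqs) == 4, all(base_freqs > 0))
    base_freqs <- base_freqs / sum(base_freqs)
  }
  rates <- switch(family,
    JC = 1,
    K80 = ,
    HKY = if (is.null(rates)) 2 else rates[[1L]],
    TrN = if (is.null(rates)) c(2, 2) else {
      stopifnot(length(rates) == 2); as.numeric(rates)
    },
    GTR = if (is.null(rates)) rep(1, 6) else {
      stopifnot(length(rates) == 6, rates[6] > 0)
      as.numeric(rates) / rates[6]
    })
  if (!is.null(alpha)) stopifnot(alpha > 0)
  if (!is.null(p_inv)) stopifnot(p_inv >= 0, p_inv < 1)
  structure(list(family = family, rates = rates, base_freqs = base_freqs,
                 alpha = alpha, p_inv = p_inv, n_cat = as.integer(n_cat)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  tag <- x$family
  if (!is.null(x$alpha)) tag <- paste0(tag, "+G(", signif(x$alpha, 3), ")")
  if (!is.null(x$p_inv)) tag <- paste0(tag, "+I(", signif(x$p_inv, 3), ")")
  cat("Substitution model:", tag, "\n")
  if (!is.null(x$base_freqs))
    cat("  base freqs:", paste(signif(x$base_freqs, 4), collapse = " "), "\n")
  cat("  exchangeabilities:",
      paste(signif(model_exchangeabilities(x), 4), collapse = " "), "\n")
  invisible(x)
}

# Full 6-vector of exchangeabilities (AC, AG, AT, CG, CT, GT).
model_exchangeabilities <- function(model) {
  r <- model$rates
  switch(model$family,
    JC = rep(1, 6),
    K80 = ,
    HKY = c(1, r, 1, 1, r, 1),
    TrN = c(1, r[1], 1, 1, r[2], 1),
    GTR = r)
}

# Rate matrix Q scaled to mean rate 1 at stationarity.
model_Q <- function(model, base_freqs = NULL) {
  pi <- if (is.null(model$base_freqs)) base_freqs else model$base_freqs
  stopifnot(!is.null(pi))
  s <- model_exchangeabilities(model)
  Q <- matrix(0, 4, 4, dimnames = list(c("a", "c", "g", "t"),
                                       c("a", "c", "g", "t")))
  Q[1, 2] <- s[1]; Q[1, 3] <- s[2]; Q[1, 4] <- s[3]
  Q[2, 3] <- s[4]; Q[2, 4] <- s[5]; Q[3, 4] <- s[6]
  Q <- Q + t(Q)
  Q <- sweep(Q, 2, pi, "*")
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Symmetrised eigendecomposition of Q; P(t) = U1 diag(exp(lam t)) U2.
model_eigen <- function(model, base_freqs = NULL) {
  pi <- if (is.null(model$base_freqs)) base_freqs else model$base_freqs
  Q <- model_Q(model, base_freqs = pi)
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  list(U1 = diag(1 / sp) %*% eig$vectors,
       U2 = t(eig$vectors) %*% diag(sp),
       lam = eig$values, pi = pi)
}

#' Discrete-gamma rate categories
#'
#' Rates of `n_cat` equal-probability classes of a gamma(shape, shape)
#' distribution, each class represented by its median, renormalised so the
#' category mean is exactly 1.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param n_cat Number of categories.
#' @return Numeric vector of `n_cat` relative rates with mean 1.
#' @export
gamma_rates <- function(alpha, n_cat = 4L) {
  stopifnot(alpha > 0, n_cat >= 1)
  if (n_cat == 1L) return(1)
  r <- stats::qgamma((seq_len(n_cat) - 0.5) / n_cat, shape = alpha,
                     rate = alpha)
  r / mean(r)
}

# Rate classes for the likelihood: invariant class (rate 0) plus gamma
# categories, with gamma rates inflated by 1/(1 - p_inv) so the overall
# expected rate stays 1.
rate_classes <- function(model) {
  pinv <- if (is.null(model$p_inv)) 0 else model$p_inv
  if (is.null(model$alpha)) {
    r <- 1
    w <- 1
  } else {
    r <- gamma_rates(model$alpha, model$n_cat)
    w <- rep(1 / model$n_cat, model$n_cat)
  }
  if (pinv > 0) {
    r <- c(0, r / (1 - pinv))
    w <- c(pinv, (1 - pinv) * w)
  }
  list(rates = r, weights = w)
}

# --- free-parameter packing for numerical optimisation -----------------

model_pack <- function(model) {
  p <- numeric(0)
  nm <- character(0)
  if (model$family %in% c("K80", "HKY")) {
    p <- c(p, log(model$rates)); nm <- c(nm, "kappa")
  } else if (model$family == "TrN") {
    p <- c(p, log(model$rates)); nm <- c(nm, "kappa1", "kappa2")
  } else if (model$family == "GTR") {
    p <- c(p, log(model$rates[1:5]))
    nm <- c(nm, paste0("r", 1:5))
  }
  if (!is.null(model$alpha)) { p <- c(p, log(model$alpha)); nm <- c(nm, "alpha") }
  if (!is.null(model$p_inv)) {
    p <- c(p, stats::qlogis(max(model$p_inv, 1e-6))); nm <- c(nm, "p_inv")
  }
  stats::setNames(p, nm)
}

model_unpack <- function(model, p) {
  i <- 0
  take <- function(n) { v <- p[i + seq_len(n)]; i <<- i + n; v }
  if (model$family %in% c("K80", "HKY")) {
    model$rates <- exp(take(1))
  } else if (model$family == "TrN") {
    model$rates <- exp(take(2))
  } else if (model$family == "GTR") {
    model$rates <- c(exp(take(5)), 1)
  }
  if (!is.null(model$alpha)) model$alpha <- min(exp(take(1)), 100)
  if (!is.null(model$p_inv)) model$p_inv <- stats::plogis(take(1)) * 0.999
  model
}
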