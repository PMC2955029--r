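#' Alignment container
#'
#' Alignments are stored as plain character matrices: one row per taxon
#' (rownames are the taxon ids), one column per alignment column, entries
#' upper-case IUPAC nucleotide (or amino-acid) codes with `-` for gaps.
#' `as_alignment()` normalises either such a matrix or a named character
#' vector of equal-length sequence strings into this form.
#'
#' @param x Character matrix, or named character vector of aligned
#'   sequence strings.
#' @return Character matrix with unique rownames.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    n <- nchar(x)
    if (length(unique(n)) != 1L)
      stop("sequences have unequal lengths: ",
           paste(unique(n), collapse = ", "))
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("alignment rows must carry unique taxon ids")
  if (ncol(m) < 1L) stop("alignment has no columns")
  m
}

#' @rdname as_alignment
#' @param aln An alignment matrix.
#' @export
alignment_strings <- function(aln) {
  stats::setNames(apply(aln, 1, paste, collapse = ""), rownames(aln))
}

# IUPAC nucleotide -> 4-bit state mask (A=1, C=2, G=4, T=8); anything
# unresolved (N, -, ?) is full ambiguity and contributes likelihood 1.
.iupac_mask <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L, R = 5L, Y = 10L,
                 S = 6L, W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
                 V = 7L, N = 15L, "-" = 15L, "?" = 15L, "." = 15L, X = 15L)

# regex class of everything that is NOT a valid code ('-' kept last)
.non_iupac_class <- "[^ACGTURYSWKMBDHVNX?.-]"

# Compress an alignment into unique site patterns for the pruning engine.
# Returns tip_pat (n_pat x n_tip masks, tips ordered as `tip_order`),
# weights (pattern multiplicities) and index (column -> pattern row).
encode_patterns <- function(aln, tip_order = rownames(aln)) {
  miss <- setdiff(tip_order, rownames(aln))
  if (length(miss))
    stop("taxa missing from alignment: ", paste(miss, collapse = ", "))
  m <- aln[tip_order, , drop = FALSE]
  codes <- .iupac_mask[m]
  if (anyNA(codes))
    stop("unrecognised residue codes: ",
         paste(unique(m[is.na(codes)]), collapse = ", "))
  codes <- matrix(as.integer(codes), nrow = nrow(m))
  key <- apply(codes, 2, paste, collapse = ",")
  idx <- match(key, unique(key))
  keep <- !duplicated(key)
  tip_pat <- t(codes[, keep, drop = FALSE])
  list(tip_pat = tip_pat,
       weights = as.numeric(tabulate(idx, max(idx))),
       index = idx)
}

# Empirical base frequencies from unambiguous residues.
empirical_base_freqs <- function(aln) {
  tab <- table(factor(aln, levels = c("A", "C", "G", "T")))
  f <- as.numeric(tab)
  if (sum(f) == 0) return(rep(0.25, 4))
  f <- f + 1e-3  # guard against absent states
  f / sum(f)
}
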