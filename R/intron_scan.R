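#' Map a cox1 query sequence onto an intronless reference CDS
#'
#' Globally aligns a query nucleotide sequence against an intronless
#' reference coding sequence (Needleman-Wunsch via `Biostrings`, default
#' scores match 2, mismatch -3, gap open -8, gap extend -1).  Positions are
#' numbered on the reference CDS, 1-based at the A of the reference start
#' codon, so that "inserted after position N" names the last reference
#' nucleotide preceding an insertion -- the convention used to name introns
#' 714, 723 and 870.  Insertions in the query show up as runs of gaps in
#' the aligned reference.
#'
#' @param query Named length-1 character vector (or plain string) with the
#'   query nucleotide sequence.
#' @param reference Named length-1 character vector with the reference CDS.
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @param min_identity Minimum proportion of identical residues over
#'   jointly aligned (exon) positions; below this the reference is
#'   rejected as unsuitable.
#' @return An object of class `reference_map`: aligned query/reference
#'   strings, a `map` data frame of `(query_pos, ref_pos)` pairs for all
#'   jointly aligned positions, and the exon identity.
#' @export
map_to_reference <- function(query, reference, match = 2, mismatch = -3,
                             gap_open = 8, gap_extend = 1,
                             min_identity = 0.4) {
  qid <- if (!is.null(names(query))) names(query)[1] else "query"
  rid <- if (!is.null(names(reference))) names(reference)[1] else "reference"
  q <- toupper(unname(query[[1]])); r <- toupper(unname(reference[[1]]))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(r), type = "global",
    substitutionMatrix = sm, gapOpening = gap_open,
    gapExtension = gap_extend)
  aq <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ar <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qpos <- cumsum(aq != "-")
  rpos <- cumsum(ar != "-")
  both <- aq != "-" & ar != "-"
  ident <- mean(aq[both] == ar[both])
  if (!any(both) || ident < min_identity)
    stop("reference unsuitable: exon identity ",
         sprintf("%.1f%%", 100 * ident), " below ",
         sprintf("%.0f%%", 100 * min_identity))
  structure(list(query_id = qid, reference_id = rid,
                 aligned_query = aq, aligned_reference = ar,
                 query_pos = qpos, ref_pos = rpos,
                 map = data.frame(query_pos = qpos[both],
                                  ref_pos = rpos[both]),
                 exon_identity = ident, ref_length = nchar(r)),
            class = "reference_map")
}

#' @export
print.reference_map <- function(x, ...) {
  cat("Reference map:", x$query_id, "vs", x$reference_id, "\n")
  cat(sprintf("  %d aligned columns, exon identity %.1f%%\n",
              length(x$aligned_query), 100 * x$exon_identity))
  invisible(x)
}

#' Detect insertions relative to the reference CDS
#'
#' One record is reported per run of reference gaps of at least `min_len`
#' nucleotides in the reference map; `site` is the last reference CDS
#' position preceding the run (so an intron reported at site 723 sits
#' between reference positions 723 and 724).  Records are sorted by site.
#'
#' @param map A [map_to_reference()] result.
#' @param min_len Minimum insertion length in bp (default 30, well below
#'   the smallest known cox1 group I intron).
#' @details An insertion whose boundary bases repeat the flanking exon
#'   bases can be placed at more than one site with identical alignment
#'   score (the gap can "slide").  Reported insertions are therefore
#'   left-normalised: the run is shifted to the smallest equivalent site,
#'   rotating the insertion sequence accordingly, so output does not
#'   depend on the aligner's arbitrary gap placement.
#' @return Data frame with columns `query_id`, `site`, `length`, `seq`;
#'   zero rows when the query carries no insertion.
#' @export
detect_insertions <- function(map, min_len = 30L) {
  stopifnot(inherits(map, "reference_map"))
  refseq <- paste(map$aligned_reference[map$aligned_reference != "-"],
                  collapse = "")
  gap_ref <- map$aligned_reference == "-" & map$aligned_query != "-"
  runs <- rle(gap_ref)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_len
  out <- data.frame(query_id = character(0), site = integer(0),
                    length = integer(0), seq = character(0),
                    stringsAsFactors = FALSE)
  for (i in which(keep)) {
    cols <- starts[i]:ends[i]
    site <- if (starts[i] == 1L) 0L else map$ref_pos[starts[i] - 1L]
    seq <- paste(map$aligned_query[cols], collapse = "")
    norm <- normalize_insertion(refseq, site, seq)
    out <- rbind(out, data.frame(
      query_id = map$query_id, site = norm$site, length = nchar(norm$seq),
      seq = norm$seq, stringsAsFactors = FALSE))
  }
  out[order(out$site), , drop = FALSE]
}

#' Left-normalise an equivalent-insertion placement
#'
#' Inserting `seq` after reference position `site` is indistinguishable
#' from inserting a rotated copy one position earlier whenever the
#' insertion's last base equals the reference base at `site`.  This
#' helper shifts a `(site, seq)` pair to its canonical leftmost
#' equivalent.
#'
#' @param refseq Reference CDS string.
#' @param site Reference position preceding the insertion.
#' @param seq Inserted sequence.
#' @return List with normalised `site` and `seq`.
#' @export
normalize_insertion <- function(refseq, site, seq) {
  L <- nchar(seq)
  while (site >= 1L &&
         substring(seq, L, L) == substring(refseq, site, site)) {
    seq <- paste0(substring(refseq, site, site), substring(seq, 1L, L - 1L))
    site <- site - 1L
  }
  list(site = as.integer(site), seq = seq)
}

# Count of positions (of 9) at which a 9-mer differs from LAGLIDADG.
.laglidadg_mismatches <- function(protein) {
  motif <- strsplit("LAGLIDADG", "")[[1]]
  n <- nchar(protein)
  if (n < 9L) return(integer(0))
  p <- strsplit(protein, "")[[1]]
  vapply(seq_len(n - 8L), function(i) sum(p[i:(i + 8L)] != motif),
         integer(1))
}

#' Scan an intron for open reading frames
#'
#' Finds all maximal start-to-stop ORFs of at least `min_aa` amino acids
#' on both strands and all three frames under the given genetic code
#' (default table 4, in which TGA reads as tryptophan).  Each ORF runs
#' from the first ATG after the preceding stop through its terminating
#' stop codon.  Every ORF is scanned for the LAGLIDADG homing-endonuclease
#' motif (exact or with one mismatch) and its internal TGA codons -- stops
#' under the standard nuclear code -- are counted.
#'
#' @param intron Intron nucleotide sequence string.
#' @param table NCBI translation table id (default 4).
#' @param min_aa Minimum ORF length in amino acids, stop excluded.
#' @return Data frame with columns `start`, `end` (1-based positions on
#'   the intron's forward strand coordinates of the scanned strand),
#'   `strand`, `frame`, `protein`, `has_laglidadg`, `internal_tga_count`.
#' @export
find_orfs <- function(intron, table = 4L, min_aa = 50L) {
  intron <- toupper(intron)
  stopifnot(nchar(intron) > 0)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") intron else reverse_complement(intron)
    for (frame in 0:2) {
      if (nchar(s) - frame < 3L) next
      prot <- translate_dna(s, table = table, frame = frame)
      stops <- c(0L, which(strsplit(prot, "")[[1]] == "*"))
      for (k in seq_len(length(stops) - 1L)) {
        seg <- substring(prot, stops[k] + 1L, stops[k + 1L] - 1L)
        m_rel <- regexpr("M", seg, fixed = TRUE)
        if (m_rel < 0) next
        aa_start <- stops[k] + as.integer(m_rel)    # first codon of ORF
        aa_stop <- stops[k + 1L]                    # stop codon index
        n_aa <- aa_stop - aa_start                  # stop excluded
        if (n_aa < min_aa) next
        nt_start <- frame + (aa_start - 1L) * 3L + 1L
        nt_end <- frame + aa_stop * 3L              # incl. stop codon
        orf_nt <- substring(s, nt_start, nt_end)
        codons <- substring(orf_nt, seq(1L, nchar(orf_nt) - 3L, 3L),
                            seq(3L, nchar(orf_nt) - 3L, 3L) + 0L)
        protein <- substring(prot, aa_start, aa_stop - 1L)
        mism <- .laglidadg_mismatches(protein)
        out[[length(out) + 1L]] <- data.frame(
          start = nt_start, end = nt_end, strand = strand,
          frame = frame, protein = protein,
          has_laglidadg = length(mism) > 0 && min(mism) <= 1L,
          internal_tga_count = sum(codons == "TGA"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      protein = character(0), has_laglidadg = logical(0),
                      internal_tga_count = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Percent identity between two sequences
#'
#' Global pairwise alignment identity: matching positions divided by
#' aligned positions, excluding columns where both sequences are gapped; a
#' gap aligned to a base counts as a mismatch.
#'
#' @param a,b Nucleotide sequence strings.
#' @inheritParams map_to_reference
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, match = 2, mismatch = -3, gap_open = 8,
                              gap_extend = 1) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = sm, gapOpening = gap_open,
    gapExtension = gap_extend)
  x <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  keep <- !(x == "-" & y == "-")
  100 * sum(x[keep] == y[keep]) / sum(keep)
}

#' Alignment column statistics
#'
#' Classifies every column of an alignment using its unambiguous residues
#' (A/C/G/T for nucleotides, the 20 amino acids for proteins): *constant*
#' when at most one state is present, *variable* otherwise, and
#' *parsimony-informative* when at least two states each occur in at
#' least two sequences.  A column is counted as having missing data when
#' it contains `-`, `?` or `N` (`X` for proteins).
#'
#' @param aln Alignment matrix.
#' @param alphabet `"dna"` or `"protein"`.
#' @return List with `n_cols`, `n_constant`, `n_variable`,
#'   `n_informative`, `n_with_missing`.
#' @export
column_stats <- function(aln, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (is.null(dim(aln)) || ncol(aln) < 1L || nrow(aln) < 1L)
    stop("empty alignment")
  nuc <- if (alphabet == "dna") c("A", "C", "G", "T")
         else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  miss_codes <- if (alphabet == "dna") c("-", "?", "N") else c("-", "?", "X")
  n_constant <- 0L; n_variable <- 0L; n_informative <- 0L
  n_with_missing <- 0L
  for (j in seq_len(ncol(aln))) {
    col <- aln[, j]
    if (any(col %in% miss_codes)) n_with_missing <- n_with_missing + 1L
    counts <- table(factor(col[col %in% nuc], levels = nuc))
    n_states <- sum(counts > 0)
    if (n_states >= 2L) {
      n_variable <- n_variable + 1L
      if (sum(counts >= 2L) >= 2L) n_informative <- n_informative + 1L
    } else {
      n_constant <- n_constant + 1L
    }
  }
  list(n_cols = ncol(aln), n_constant = n_constant,
       n_variable = n_variable, n_informative = n_informative,
       n_with_missing = n_with_missing)
}

#' Scan a set of cox1 sequences for introns
#'
#' Convenience wrapper running [map_to_reference()], [detect_insertions()]
#' and [find_orfs()] over every query, producing the per-intron report
#' table.
#'
#' @param queries Named character vector of cox1 query sequences.
#' @param reference Named length-1 character vector with the intronless
#'   reference CDS.
#' @param table Genetic-code table id.
#' @param min_len Minimum insertion length (bp).
#' @param min_aa Minimum ORF length (aa).
#' @return List with `table` (data frame: `query_id`, `site`, `length`,
#'   `orf_count`, `has_laglidadg`, `internal_tga_count`) and `introns`
#'   (named character vector of intron sequences, named
#'   `<query_id>_intron<site>`).
#' @export
scan_introns <- function(queries, reference, table = 4L, min_len = 30L,
                         min_aa = 50L) {
  rows <- list(); introns <- character(0)
  for (id in names(queries)) {
    m <- map_to_reference(stats::setNames(queries[id], id), reference)
    ins <- detect_insertions(m, min_len = min_len)
    if (!nrow(ins)) next
    for (i in seq_len(nrow(ins))) {
      orfs <- find_orfs(ins$seq[i], table = table, min_aa = min_aa)
      lag <- orfs[orfs$has_laglidadg, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = id, site = ins$site[i], length = ins$length[i],
        orf_count = nrow(orfs),
        has_laglidadg = any(orfs$has_laglidadg),
        internal_tga_count = if (nrow(lag)) max(lag$internal_tga_count)
                             else 0L,
        stringsAsFactors = FALSE)
      introns[paste0(id, "_intron", ins$site[i])] <- ins$seq[i]
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(0), site = integer(0),
               length = integer(0), orf_count = integer(0),
               has_laglidadg = logical(0), internal_tga_count = integer(0))
  list(table = tab, introns = introns)
}
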