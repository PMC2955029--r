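#' Read sequences from a FASTA file
#'
#' Returns a named character vector of upper-case sequences, one element per
#' record, in file order.  Record ids are the first whitespace-delimited
#' token of each header line.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`; DNA sequences are checked
#'   against IUPAC nucleotide codes plus `-`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("FASTA file contains no records: ", path)
  ids <- vapply(strsplit(names(ss), "[ \t]+"), `[[`, "", 1L)
  if (any(ids == "")) stop("empty FASTA header in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(gsub("[ \t]", "", as.character(ss)))
  if (any(nchar(seqs) == 0)) stop("empty sequence in ", path)
  if (alphabet == "dna") {
    bad <- grepl(.non_iupac_class, seqs)
    if (any(bad))
      stop("non-IUPAC characters in records: ",
           paste(ids[bad], collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read an alignment from a NEXUS file
#'
#' Reads the DATA/CHARACTERS block (simple or interleaved) of a NEXUS file
#' and checks the matrix against the declared NTAX/NCHAR dimensions.  TREES
#' blocks are ignored with a warning.
#'
#' @param path Path to a NEXUS file.
#' @return Alignment matrix (see [as_alignment()]).
#' @export
read_nexus_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path, warn = FALSE)
  if (any(grepl("begin\\s+trees", txt, ignore.case = TRUE)))
    warning("NEXUS TREES block present and ignored: ", path)
  hdr <- paste(txt, collapse = " ")
  ntax <- regmatches(hdr, regexpr("[Nn][Tt][Aa][Xx]\\s*=\\s*[0-9]+", hdr))
  nchr <- regmatches(hdr, regexpr("[Nn][Cc][Hh][Aa][Rr]\\s*=\\s*[0-9]+", hdr))
  if (!length(ntax) || !length(nchr))
    stop("NEXUS DIMENSIONS (ntax/nchar) not found in ", path)
  ntax <- as.integer(sub(".*=\\s*", "", ntax))
  nchr <- as.integer(sub(".*=\\s*", "", nchr))
  recs <- tryCatch(ape::read.nexus.data(path), error = function(e)
    stop("NEXUS matrix does not match its declared dimensions (",
         conditionMessage(e), ") in ", path))
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L)
    stop("ragged NEXUS matrix: row lengths ",
         paste(unique(lens), collapse = ", "))
  m <- as_alignment(do.call(rbind, recs))
  if (nrow(m) != ntax || ncol(m) != nchr)
    stop(sprintf("NEXUS dimensions (%d x %d) do not match matrix (%d x %d)",
                 ntax, nchr, nrow(m), ncol(m)))
  m
}

#' Write an alignment to a NEXUS file
#'
#' @param aln Alignment matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus_alignment <- function(aln, path) {
  recs <- lapply(seq_len(nrow(aln)), function(i) tolower(aln[i, ]))
  names(recs) <- rownames(aln)
  ape::write.nexus.data(recs, file = path, format = "dna",
                        interleaved = FALSE)
  invisible(path)
}

#' Read and write Newick trees
#'
#' Thin wrappers over `ape` that add an explicit syntax check: unbalanced
#' parentheses are reported with the character offset of the first
#' imbalance.
#'
#' @param path Path to a Newick file (first tree is returned).
#' @return `read_newick()`: an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- cumsum((chars <- strsplit(txt, "")[[1]]) == "(") -
    cumsum(chars == ")")
  if (any(depth < 0))
    stop("unbalanced ')' at character ", which(depth < 0)[1], " of ", path)
  if (length(depth) && depth[length(depth)] != 0)
    stop("unbalanced '(' (", depth[length(depth)],
         " unclosed) in ", path)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  tr
}

#' @rdname read_newick
#' @param tree An `ape::phylo` tree.
#' @param path Output path; if `NULL` the Newick string is returned.
#' @return `write_newick()`: the path (or the Newick string), invisibly.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Genetic-code translation
#'
#' Translates a nucleotide sequence under an NCBI translation table.  Table
#' 4 (the mold/protozoan/coelenterate mitochondrial code, used by
#' demosponge mitochondria) reads TGA as tryptophan; table 1 (standard)
#' reads it as a stop.  Stops are rendered `*`; codons containing
#' ambiguity or gap characters are rendered `X`; a trailing partial codon
#' is ignored.
#'
#' @param seq Nucleotide sequence string.
#' @param table NCBI translation table id (e.g. 1 or 4).
#' @param frame Reading-frame offset: 0, 1 or 2.
#' @return Amino-acid string.
#' @export
translate_dna <- function(seq, table = 4L, frame = 0L) {
  stopifnot(frame %in% 0:2)
  seq <- toupper(seq)
  if (grepl(.non_iupac_class, seq))
    stop("sequence contains non-nucleotide characters")
  code <- genetic_code(table)
  s <- substring(seq, frame + 1L, nchar(seq))
  n_cod <- nchar(s) %/% 3L
  if (n_cod < 1L) stop("sequence shorter than one codon after frame offset")
  starts <- (seq_len(n_cod) - 1L) * 3L + 1L
  codons <- substring(s, starts, starts + 2L)
  codons <- chartr("U", "T", codons)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' @rdname translate_dna
#' @return `genetic_code()`: named character vector mapping the 64 codons
#'   to amino acids (`*` for stop).
#' @export
genetic_code <- function(table = 4L) {
  Biostrings::getGeneticCode(as.character(table))
}

#' Reverse complement of a nucleotide sequence
#'
#' Handles all IUPAC ambiguity codes and gaps.
#'
#' @param seq Nucleotide sequence string.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGTURYSWKMBDHVN", "TGCAAYRSWMKVHDBN", toupper(seq))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Read and write host-parasite association tables
#'
#' Two-column tab-separated tables with a header line `host<TAB>parasite`,
#' one row per association link.
#'
#' @param path Path to a TSV file.
#' @return `read_links()`: data frame with columns `host`, `parasite`.
#' @export
read_links <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("host", "parasite") %in% names(df)))
    stop("association table needs 'host' and 'parasite' columns: ", path)
  df[c("host", "parasite")]
}

#' @rdname read_links
#' @param links Data frame with columns `host`, `parasite`.
#' @export
write_links <- function(links, path) {
  utils::write.table(links[c("host", "parasite")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
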