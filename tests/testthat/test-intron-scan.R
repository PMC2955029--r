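test_that("reference map is the identity for a self-alignment", {
  ref <- c(refseq = random_dna(900, seed = 1))
  m <- map_to_reference(ref, ref)
  expect_equal(m$exon_identity, 1)
  expect_equal(m$map$query_pos, m$map$ref_pos)
  expect_equal(nrow(detect_insertions(m)), 0L)
})

test_that("injected introns are detected at the right site and length", {
  ref <- c(refseq = random_dna(1200, seed = 2))
  intron <- random_dna(300, seed = 3)
  q <- c(query1 = inject_intron(ref, 100, intron))
  m <- map_to_reference(q, ref)
  ins <- detect_insertions(m)
  norm <- normalize_insertion(ref[[1]], 100L, intron)
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$site, norm$site)
  expect_equal(ins$length, 300L)
  expect_equal(ins$seq, norm$seq)

  # two introns at the study's sites come back sorted by site
  i714 <- random_dna(985, seed = 4); i870 <- random_dna(948, seed = 5)
  q2 <- inject_intron(c(q = inject_intron(ref, 870, i870)), 714, i714)
  ins2 <- detect_insertions(map_to_reference(c(q2 = q2), ref))
  expect_equal(ins2$site,
               c(normalize_insertion(ref[[1]], 714L, i714)$site,
                 normalize_insertion(ref[[1]], 870L, i870)$site))
  expect_equal(ins2$length, c(985L, 948L))

  # an unalignable reference is rejected
  expect_error(map_to_reference(c(x = strrep("A", 600)),
                                c(y = strrep("C", 600))),
               "reference unsuitable")
})

test_that("removing detected insertions restores a clean translation", {
  # reference with no internal stops under table 4
  prot <- paste0("M", strrep("ALGVSTIF", 40))
  ref <- c(ref = protein_to_dna(prot))
  intron <- laglidadg_intron()
  q <- c(q = inject_intron(ref, 723, intron))
  ins <- detect_insertions(map_to_reference(q, ref))
  expect_equal(nrow(ins), 1L)
  restored <- paste0(substring(q, 1, ins$site),
                     substring(q, ins$site + ins$length + 1, nchar(q)))
  aa <- translate_dna(restored, table = 4)
  expect_false(grepl("\\*", substring(aa, 1, nchar(aa) - 1)))
  expect_equal(restored, unname(ref))
})

test_that("ORF scan finds the LAGLIDADG frame with internal TGA codons", {
  intron <- laglidadg_intron()
  orfs <- find_orfs(intron, table = 4, min_aa = 50)
  expect_equal(nrow(orfs), 1L)
  expect_true(orfs$has_laglidadg)
  expect_gte(orfs$internal_tga_count, 1L)
  expect_false(grepl("\\*", orfs$protein))
  expect_equal((orfs$end - orfs$start + 1L) %% 3L, 0L)
  # the same ORF is found on the minus strand of the reverse complement
  orfs_rc <- find_orfs(reverse_complement(intron), table = 4, min_aa = 50)
  expect_equal(nrow(orfs_rc), 1L)
  expect_equal(orfs_rc$strand, "-")
  expect_equal(orfs_rc$protein, orfs$protein)
  # one mismatch in the motif is tolerated, two are not
  expect_true(find_orfs(protein_to_dna(
    paste0("M", strrep("S", 20), "LAGLIDSDG", strrep("T", 30), "*")),
    min_aa = 50)$has_laglidadg)
  expect_false(find_orfs(protein_to_dna(
    paste0("M", strrep("S", 20), "LAGLFDSDG", strrep("T", 30), "*")),
    min_aa = 50)$has_laglidadg)
  # no start codon, no ORF
  expect_equal(nrow(find_orfs(strrep("C", 400))), 0L)
})

test_that("pairwise identity uses aligned positions and matches known cases", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 75)
  # ~10% substitutions -> ~90% identity
  set.seed(7)
  a <- strsplit(random_dna(600, seed = 10), "")[[1]]
  b <- a
  flip <- sample(600, 60)
  for (i in flip) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  id <- pairwise_identity(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_gt(id, 86); expect_lt(id, 94)
})

test_that("column statistics classify constant/variable/informative sites", {
  # hand-counted 4 x 6 matrix: col1 constant, col2 singleton (variable,
  # not informative), col3 informative (2+2), col4 constant with gap,
  # col5 informative (2+2 with N ignored is 2+1 -> NOT informative),
  # col6 all missing -> constant by convention
  m <- as_alignment(rbind(
    a = c("A", "A", "A", "A", "C", "-"),
    b = c("A", "C", "A", "A", "C", "-"),
    c = c("A", "A", "G", "-", "G", "-"),
    d = c("A", "A", "G", "A", "N", "-")))
  rownames(m) <- letters[1:4]
  cs <- column_stats(m)
  expect_equal(cs$n_cols, 6L)
  expect_equal(cs$n_constant, 3L)
  expect_equal(cs$n_variable, 3L)
  expect_equal(cs$n_informative, 1L)
  expect_equal(cs$n_with_missing, 3L)
  expect_lte(cs$n_informative, cs$n_variable)
  expect_equal(cs$n_constant + cs$n_variable, cs$n_cols)

  ident <- as_alignment(c(x = "AAAA", y = "AAAA"))
  expect_equal(column_stats(ident)$n_constant, 4L)
  expect_error(column_stats(matrix(character(0), 0, 0)), "empty")
})

test_that("scan_introns assembles the per-intron report", {
  ref <- c(ref = protein_to_dna(paste0("M", strrep("ALGVSTIF", 40))))
  q1 <- c(sampleA = unname(inject_intron(ref, 723, laglidadg_intron())))
  q2 <- c(sampleB = unname(ref))
  res <- scan_introns(c(q1, q2), ref)
  expect_equal(nrow(res$table), 1L)
  expect_equal(res$table$query_id, "sampleA")
  expect_true(res$table$has_laglidadg)
  expect_gte(res$table$internal_tga_count, 1L)
  expect_equal(length(res$introns), 1L)
})
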