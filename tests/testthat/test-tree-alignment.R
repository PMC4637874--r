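# Tree and alignment I/O and validation.

test_that("newick parsing round-trips and validates", {
  tr <- read_tree("(A:1,B:1);")
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(sort(tr$edge.length), c(1, 1))

  tr3 <- read_tree("((A:1,B:2):0.5,C:3);")
  expect_equal(length(tr3$tip.label), 3L)
  internal_edge <- tr3$edge.length[tr3$edge[, 2] > 3]
  expect_equal(internal_edge, 0.5)

  rt <- read_tree(write_tree(tr3))
  expect_true(ape::all.equal.phylo(rt, tr3, use.edge.length = FALSE))
  expect_equal(sum(rt$edge.length), sum(tr3$edge.length), tolerance = 1e-6)

  expect_error(read_tree("((A,B),(A,C));"), "duplicate leaf")
  expect_error(read_tree("(A:1,B:1,C:1,D:1);"), "polytomies")
  tr4 <- read_tree("(A:1,B:1,C:1,D:1);", resolve_polytomies = TRUE)
  expect_true(ape::is.binary.phylo(tr4))
  expect_true(attr(tr4, "polytomies_resolved"))
})

test_that("FASTA codon alignments parse, with stop and ragged errors", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">t1", "ATGAAACCCGGG", ">t2", "ATGAAACCAGGA",
               ">t3", "ATGAAGCCCGGG"), fa)
  aln <- read_alignment(fa, alphabet = "codon")
  expect_equal(aln$L, 4L)  # 12 nt -> 4 codon columns
  expect_equal(nrow(aln$x), 3L)
  expect_false(anyNA(aln$x))

  writeLines(c(">t1", "ATGAAACCCGGG", ">t2", "ATGAAACCAGG"), fa)
  expect_error(read_alignment(fa, alphabet = "codon"), "ragged")

  writeLines(c(">t1", "ATGTAACCCGGG", ">t2", "ATGAAACCAGGA"), fa)
  expect_error(read_alignment(fa, alphabet = "codon"),
               "stop codon 'TAA' in taxon 't1' at codon 2")
})

test_that("gaps and ambiguities become missing data; codons translate", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">t1", "ATG---CCNGGG", ">t2", "ATGAAACCAGGA"), fa)
  aln <- read_alignment(fa, alphabet = "codon")
  expect_true(is.na(aln$x["t1", 2]))  # gap codon
  expect_true(is.na(aln$x["t1", 3]))  # ambiguous codon
  aa <- translate_alignment(aln)
  expect_equal(aa$alphabet, "aa")
  expect_equal(aa$L, 4L)
  expect_equal(AA_STATES[aa$x["t2", ]], c("M", "K", "P", "G"))

  writeLines(c(">t1", "MKX-W", ">t2", "MKLAW"), fa)
  aap <- read_alignment(fa, alphabet = "aa")
  expect_true(all(is.na(aap$x["t1", 3:4])))
  expect_equal(AA_STATES[aap$x["t1", c(1, 2, 5)]], c("M", "K", "W"))
})

test_that("alignment FASTA writing round-trips", {
  set.seed(3)
  aln <- random_aa_alignment(c("sp1", "sp2", "sp3"), 40)
  fa <- tempfile(fileext = ".fasta")
  write_alignment(aln, fa)
  back <- read_alignment(fa, alphabet = "aa")
  expect_identical(back$x, aln$x)
})

test_that("relaxed sequential PHYLIP is readable", {
  ph <- tempfile(fileext = ".phy")
  writeLines(c(" 3 6", "taxon_one  MKLVWA", "taxon_two  MKLVWA",
               "taxon_tri  MRLVWA"), ph)
  aln <- read_alignment(ph, alphabet = "aa", format = "phylip")
  expect_equal(nrow(aln$x), 3L)
  expect_equal(aln$L, 6L)
  expect_equal(AA_STATES[aln$x["taxon_tri", 2]], "R")
})

test_that("reference-taxon ungapped positions are tracked", {
  x <- matrix(c(1L, NA, 2L, 3L, 4L, 5L, 6L, 7L), nrow = 2, byrow = TRUE)
  rownames(x) <- c("ref", "oth")
  aln <- phyloconverge:::alignment_from_states(x, "aa")
  expect_equal(phyloconverge:::ref_positions(aln), c(1L, NA, 2L, 3L))
})
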