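test_that("self-alignment of short peptides scores the substitution diagonal", {
  # self-alignment over a distinct-scoring matrix admits no gapped improvement
  expect_equal(global_align("A", "A")$score, BL62["A", "A"])
  aln <- global_align("ACDC", "ACDC")
  expect_equal(aln$score, sum(BL62[cbind(c("A", "C", "D", "C"),
                                         c("A", "C", "D", "C"))]))
  expect_identical(aln$aligned_a, "ACDC")
  expect_identical(aln$aligned_b, "ACDC")
})

test_that("alignment result satisfies its structural invariants", {
  set.seed(41)
  for (i in 1:25) {
    a <- random_protein(sample(3:40, 1))
    b <- random_protein(sample(3:40, 1))
    aln <- global_align(a, b)
    expect_equal(nchar(aln$aligned_a), aln$column_count)
    expect_equal(nchar(aln$aligned_b), aln$column_count)
    expect_identical(gsub("-", "", aln$aligned_a), a)
    expect_identical(gsub("-", "", aln$aligned_b), b)
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
  }
})

test_that("score matches exhaustive enumeration on short sequences", {
  alphabet <- c("A", "C", "G", "W")
  # exhaustive over every ordered pair with both lengths <= 2, spot sample
  # of longer pairs up to length 5 x 5 against the enumeration oracle
  short <- unlist(lapply(1:2, enumerate_seqs, alphabet = alphabet))
  for (a in short) for (b in short)
    expect_equal(global_align(a, b)$score, oracle_align_score(a, b, BL62),
                 info = paste(a, b))
  set.seed(7)
  for (i in 1:40) {
    a <- random_protein(sample(3:5, 1), alphabet)
    b <- random_protein(sample(3:5, 1), alphabet)
    expect_equal(global_align(a, b)$score, oracle_align_score(a, b, BL62),
                 info = paste(a, b))
  }
})

test_that("score agrees with Biostrings::pairwiseAlignment on random pairs", {
  set.seed(11)
  for (i in 1:20) {
    a <- random_protein(sample(5:60, 1))
    b <- random_protein(sample(5:60, 1))
    ours <- global_align(a, b)$score
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = "BLOSUM62", gapOpening = 11,
      gapExtension = 1, type = "global"))
    expect_equal(ours, ref, info = paste(a, b))
  }
})

test_that("score is symmetric and self-alignment dominates", {
  set.seed(5)
  for (i in 1:10) {
    a <- random_protein(12)
    b <- random_protein(12)
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
    expect_gte(global_align(a, a)$score, global_align(a, b)$score)
  }
})

test_that("illegal residues are rejected with symbol and position", {
  expect_error(global_align("AC1D", "ACD"), "'1' at position 3")
  expect_error(global_align("", "ACD"), "non-empty")
})

test_that("free end-gap mode does not penalise terminal overhangs", {
  aln <- global_align("CDEF", "MMCDEF", free_end_gaps = TRUE)
  expect_equal(aln$score,
               sum(BL62[cbind(c("C", "D", "E", "F"), c("C", "D", "E", "F"))]))
  expect_identical(aln$aligned_a, "--CDEF")
})

test_that("position projection matches hand-counted cases", {
  aln <- as_alignment("AC-GT", "ACTGT")
  expect_equal(project_position(aln, 3), 4L)       # G in a -> 4 in b
  expect_equal(project_position(aln, 1:4), c(1L, 2L, 4L, 5L))
  ident <- as_alignment("ACGT", "ACGT")
  expect_equal(project_position(ident, 1:4), 1:4)
  gap <- as_alignment("AC-T", "ACGT")
  expect_equal(project_position(gap, 3, from = "b"), NA_integer_)
  expect_error(project_position(ident, 5), "out of range")
})

test_that("projection a->b->a is the identity on non-gap positions", {
  set.seed(13)
  for (i in 1:50) {
    a <- random_protein(sample(5:30, 1))
    b <- random_protein(sample(5:30, 1))
    aln <- global_align(a, b)
    fwd <- project_position(aln, seq_len(nchar(a)))
    ok <- !is.na(fwd)
    expect_identical(project_position(aln, fwd[ok], from = "b"),
                     seq_len(nchar(a))[ok])
  }
})

test_that("conserved cysteines are called only for Cys/Cys columns", {
  cc <- conserved_cysteines(list(pair_id = "p", mouse = "MCKC",
                                 human = "MCKS"))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$mouse_position, 2L)
  expect_equal(cc$human_position, 2L)

  s <- "MCADCWKLCR"                         # identical pair, 3 cysteines
  cc2 <- conserved_cysteines(list(pair_id = "q", mouse = s, human = s))
  expect_equal(cc2$mouse_position, c(2L, 5L, 9L))
  expect_identical(cc2$mouse_position, cc2$human_position)

  # count bound: never more than the rarer species' cysteine count
  set.seed(17)
  for (i in 1:20) {
    a <- random_protein(25)
    b <- random_protein(25)
    cc3 <- conserved_cysteines(list(pair_id = "r", mouse = a, human = b))
    expect_lte(nrow(cc3), min(lengths(gregexpr("C", a, fixed = TRUE)),
                              lengths(gregexpr("C", b, fixed = TRUE))))
  }
})

test_that("a mismatched alignment is rejected as inconsistent", {
  aln <- global_align("MCKC", "MCKS")
  expect_error(
    conserved_cysteines(list(pair_id = "p", mouse = "MCKC", human = "MCKC"),
                        alignment = aln),
    "does not match")
})

test_that("synthetic ortholog pairs are recovered exactly from sequence", {
  set.seed(19)
  for (s in 1:30) {
    p <- gen_ortholog_pair(80, identity = 0.85, n_conserved_cys = 4,
                           n_species_specific_cys = 1, indel_rate = 0.02,
                           seed = s, pair_id = "t")
    cc <- conserved_cysteines(list(pair_id = "t", mouse = p$mouse,
                                   human = p$human))
    expect_identical(cbind(mouse_pos = cc$mouse_position,
                           human_pos = cc$human_position),
                     p$truth$conserved_pairs, info = paste("seed", s))
  }
})

test_that("FASTA round trip pairs records by shared identifier", {
  pairs <- lapply(1:3, function(i)
    gen_ortholog_pair(40, seed = i, pair_id = sprintf("ID%d", i)))
  mp <- withr::local_tempfile(fileext = ".fasta")
  hp <- withr::local_tempfile(fileext = ".fasta")
  write_ortholog_fasta(pairs, mp, hp)
  cc <- map_conserved_cysteines(mp, hp)
  direct <- dplyr::bind_rows(lapply(pairs, function(p)
    conserved_cysteines(list(pair_id = p$truth$pair_id, mouse = p$mouse,
                             human = p$human))))
  expect_equal(cc, direct)
})
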