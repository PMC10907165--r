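test_that("self-alignment gives identity and 100% identity", {
  a <- global_align("ACDEFG", "ACDEFG")
  expect_equal(a$alignedA, a$alignedB)
  expect_equal(a$percent_identity, 100)
  expect_true(all(a$columns$class == "identical"))
})

test_that("a single deletion is aligned with one gap at the optimal score", {
  a <- global_align("ACDEFG", "ACEFG")
  expect_equal(sum(strsplit(a$alignedB, "")[[1]] == "-"), 1L)
  # removing gaps recovers the inputs
  expect_equal(gsub("-", "", a$alignedA), "ACDEFG")
  expect_equal(gsub("-", "", a$alignedB), "ACEFG")
})

test_that("alignment scores equal brute-force enumeration for short sequences", {
  sch <- scoring_scheme()
  set.seed(17)
  for (k in 1:12) {
    la <- sample(2:8, 1); lb <- sample(2:8, 1)
    sa <- paste(sample(dboxr:::AA_STANDARD, la, replace = TRUE), collapse = "")
    sb <- paste(sample(dboxr:::AA_STANDARD, lb, replace = TRUE), collapse = "")
    a <- global_align(sa, sb, sch)
    oracle <- brute_force_align_score(sa, sb, sch$matrix,
                                      sch$gap_open, sch$gap_extend)
    expect_equal(a$score, oracle, tolerance = 1e-9,
                 label = paste("score", sa, "vs", sb))
  }
})

test_that("identity handling: disjoint sequences, symmetry, denominators", {
  expect_equal(global_align("AAAA", "GGGG")$percent_identity, 0)
  a1 <- global_align("MKQPISVTMVT", "MKQPISVTMVS")
  a2 <- global_align("MKQPISVTMVS", "MKQPISVTMVT")
  expect_equal(a1$percent_identity, a2$percent_identity)
  # hand-counted example with one gap: gapless columns vs full length
  a <- global_align("ACDE", "ACXE")
  expect_equal(percent_identity(a, "gapless"), 75)
  aln <- list(columns = data.frame(resA = c("A", "C", "-", "D", "E"),
                                   resB = c("A", "C", "X", "D", "E"),
                                   stringsAsFactors = FALSE))
  expect_equal(percent_identity(aln, "gapless"), 100)
  expect_equal(percent_identity(aln, "alignment"), 80)
  expect_warning(
    pid <- percent_identity(list(columns = data.frame(resA = "-", resB = "A"))),
    "no aligned columns")
  expect_true(is.na(pid))
})

test_that("column classes follow the Clustal strong/weak groups", {
  expect_equal(dboxr:::column_class(c("I", "I", "I")), "identical")
  expect_equal(dboxr:::column_class(c("I", "V", "L")), "strong")    # MILV
  expect_equal(dboxr:::column_class(c("S", "A", "G")), "weak")      # SAG
  expect_equal(dboxr:::column_class(c("D", "K", "G")), "none")
})

test_that("star-alignment column classes project onto reference positions", {
  ref <- annotated_sequence("ref", "MIVSAG")
  alns <- list(global_align(ref, annotated_sequence("s1", "MLVSAG")),
               global_align(ref, annotated_sequence("s2", "MVVTAG")))
  cc <- column_classes(alns)
  expect_equal(cc$position, 1:6)
  expect_equal(cc$class[1], "identical")            # M M M
  expect_equal(cc$class[2], "strong")               # I L V
  expect_equal(cc$class[6], "identical")            # G G G
  # permutation invariance in the non-reference sequences
  cc2 <- column_classes(rev(alns))
  expect_equal(cc2$class, cc$class)
  # identical sequences give all-identical columns
  same <- list(global_align(ref, annotated_sequence("a", "MIVSAG")),
               global_align(ref, annotated_sequence("b", "MIVSAG")))
  expect_true(all(column_classes(same)$class == "identical"))
  # mixed references are rejected
  bad <- list(alns[[1]], global_align(annotated_sequence("other", "MMMMMM"),
                                      annotated_sequence("s", "MMMIMM")))
  expect_error(column_classes(bad), "same reference")
})

test_that("conservation maps onto structure residues and flags offsets", {
  fx <- cached_beta_pair("antiparallel", 6)   # poly-ALA chains, resno 1..6
  ref <- annotated_sequence("ref", "AAAAAA")
  alns <- list(global_align(ref, annotated_sequence("s1", "AAAAAA")),
               global_align(ref, annotated_sequence("s2", "AAASAA")))
  cc <- column_classes(alns)
  m <- map_conservation(cc, fx$model, "A")
  expect_equal(nrow(m), 6L)
  expect_false(any(m$class == "unaligned"))
  expect_equal(m$class[4], "strong")          # A/A/S falls in the STA group
  expect_false(attr(m, "flagged_mismatch"))
  # a deliberate off-by-12 numbering mismatch is flagged
  expect_warning(m2 <- map_conservation(cc, fx$model, "A",
                                        numbering_offset = 12L),
                 "numbering")
  expect_true(attr(m2, "flagged_mismatch"))
  expect_true(all(m2$class == "unaligned"))
  # single-residue sequence against a single-residue chain
  gly <- read_structure(write_lines_tmp(minimal_pdb_text(), ".pdb"))
  cc1 <- data.frame(position = 1L, ref_residue = "G", class = "identical")
  expect_equal(nrow(map_conservation(cc1, gly, "A")), 1L)
})

test_that("the shorter-sequence identity denominator is available", {
  a <- global_align("ACDEFG", "ACDE")
  expect_equal(percent_identity(a, "shorter"), 100)
  expect_lt(percent_identity(a, "alignment"), 100)
})
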