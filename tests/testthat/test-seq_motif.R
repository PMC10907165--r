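test_that("hydropathy classification is total, deterministic and strict", {
  expect_equal(classify_hydropathy("I"), "PHI")
  expect_equal(classify_hydropathy("S"), "ZETA")
  expect_equal(classify_hydropathy("P"), "P")
  expect_equal(classify_hydropathy(c("V", "T", "M", "G", "H")),
               c("PHI", "ZETA", "PHI", "ZETA", "ZETA"))
  # every standard residue maps to exactly one class
  cls <- classify_hydropathy(dboxr:::AA_STANDARD)
  expect_true(all(cls %in% c("PHI", "ZETA", "P")))
  expect_equal(sum(cls == "P"), 1L)
  expect_error(classify_hydropathy("B"), "non-standard")
})

test_that("hydropathy_string is length-preserving and matches the motif form", {
  expect_equal(hydropathy_string("ISVTMVT"), "FzFzFFz")
  expect_equal(hydropathy_string(""), "")
  expect_equal(hydropathy_string("PPP"), "PPP")
  set.seed(42)
  for (k in 1:20) {
    s <- paste(sample(dboxr:::AA_STANDARD, sample(1:40, 1), replace = TRUE),
               collapse = "")
    expect_equal(nchar(hydropathy_string(s)), nchar(s))
  }
  expect_error(hydropathy_string("AXB"), "position")
})

test_that("beta propensity profile averages the table over the window", {
  homo <- annotated_sequence("v7", "VVVVVVV")
  prof <- beta_propensity_profile(homo, window = 5)
  expect_equal(prof$score, rep(CHOU_FASMAN_BETA[["V"]], 7))
  expect_equal(prof$truncated,
               c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))

  # window 1 returns exactly the per-residue table values
  s <- annotated_sequence("x", "QPISVTMVTPAD")
  p1 <- beta_propensity_profile(s, window = 1)
  expect_equal(p1$score, unname(CHOU_FASMAN_BETA[s$residues]))
  expect_false(any(p1$truncated))

  # window larger than the sequence: every position flagged, scores are
  # means over the available context (hand value for the full window)
  short <- annotated_sequence("s", "VIV")
  pbig <- beta_propensity_profile(short, window = 7)
  expect_true(all(pbig$truncated))
  expect_equal(pbig$score[2],
               mean(CHOU_FASMAN_BETA[c("V", "I", "V")]), tolerance = 1e-12)

  expect_error(beta_propensity_profile(s, window = 4), "odd")
})

test_that("the D-box region of TonB scores as high beta propensity", {
  # residues 46-49 (Ser-Val-Thr-Met) of the peptide spanning 43-54 exceed
  # the default threshold of 1.0 with the default window; hand-computed
  # window-5 means: 1.158, 1.258, 1.278, 1.366
  pep <- annotated_sequence("TonB", "QPISVTMVTPAD", 43)
  prof <- beta_propensity_profile(pep)
  sel <- prof$position %in% 46:49
  expect_equal(prof$residue[sel], c("S", "V", "T", "M"))
  expect_equal(prof$score[sel], c(1.158, 1.258, 1.278, 1.366),
               tolerance = 1e-12)
  expect_true(all(prof$score[sel] > attr(prof, "threshold")))
})

test_that("scan_dbox finds the printed D-box peptide match exactly", {
  pep <- annotated_sequence("TonB", "QPISVTMVTPAD", 43)
  hits <- scan_dbox(pep, proline_window = 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$core_start, 45)
  expect_equal(hits$core_end, 51)
  expect_equal(hits$core_seq, "ISVTMVT")
  expect_equal(hits$proline_up, 44)
  expect_equal(hits$proline_down, 52)
  expect_true(hits$passes_propensity)
  # same result at the default proline window
  expect_equal(scan_dbox(pep)$core_start, 45)
})

test_that("scan_dbox handles negatives, short input and the proline gate", {
  expect_equal(nrow(scan_dbox(annotated_sequence("a", "AAAAAAAAAA"))), 0L)
  expect_error(scan_dbox(annotated_sequence("s", "ISVTMV")), "shorter")
  # motif present but no flanking prolines: rejected unless gate disabled
  bare <- annotated_sequence("b", "GGISVTMVTGG")
  expect_equal(nrow(scan_dbox(bare)), 0L)
  free <- scan_dbox(bare, require_prolines = FALSE)
  expect_equal(nrow(free), 1L)
  expect_true(is.na(free$proline_up))
})

test_that("every reported core re-derives to the motif pattern", {
  set.seed(7)
  for (k in 1:30) {
    res <- sample(dboxr:::AA_STANDARD, 50, replace = TRUE)
    s <- annotated_sequence("r", res)
    hits <- scan_dbox(s, require_prolines = FALSE)
    if (nrow(hits) > 0L) {
      expect_true(all(vapply(hits$core_seq, hydropathy_string,
                             character(1)) == "FzFzFFz"))
      expect_equal(hits$core_end - hits$core_start, rep(6, nrow(hits)))
      expect_false(is.unsorted(hits$core_start))
    }
  }
})

test_that("generator round-trip: embedded motifs are recovered exactly", {
  g <- gen_motif_sequences(n = 15, length = 60, n_motifs = 2, seed = 5)
  hits <- do.call(rbind, lapply(g$sequences, scan_dbox))
  expect_equal(nrow(hits), nrow(g$truth))
  expect_equal(hits$core_start, g$truth$core_start)
  expect_equal(hits$core_seq, g$truth$core_seq)
})

test_that("score_motif is monotone in propensity and anchor proximity", {
  pep <- annotated_sequence("TonB", "QPISVTMVTPAD", 43)
  prof <- beta_propensity_profile(pep)
  hit <- scan_dbox(pep)[1, ]
  s_no_anchor <- score_motif(hit, prof)
  expect_equal(s_no_anchor, hit$mean_core_propensity)
  s_near <- score_motif(hit, prof, anchor_end = hit$core_start)
  s_far <- score_motif(hit, prof, anchor_end = hit$core_start - 50)
  expect_equal(s_near, s_no_anchor)
  expect_lt(s_far, s_near)
  # mismatched sequence reference is rejected
  other <- beta_propensity_profile(annotated_sequence("other", "QPISVTMVTPAD", 43))
  expect_error(score_motif(hit, other), "different sequences")
})

test_that("FASTA round trip preserves ids, residues and numbering offsets", {
  seqs <- list(annotated_sequence("plain", "ACDEFG"),
               annotated_sequence("sliced", "QPISVTMVTPAD", 43))
  path <- tempfile(fileext = ".fasta")
  write_fasta_annotated(seqs, path)
  back <- read_fasta_annotated(path)
  expect_equal(names(back), c("plain", "sliced"))
  expect_equal(back$sliced$offset, 43L)
  expect_equal(back$plain$residues, seqs[[1]]$residues)
  expect_equal(back$sliced$residues, seqs[[2]]$residues)
  expect_error(read_fasta_annotated(tempfile()), "not found")
})
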