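test_that("a single extended strand has no hydrogen bonds", {
  m <- structure_model(dboxr:::build_backbone(8, phi = -139, psi = 135,
                                              with_amide_H = TRUE))
  hb <- detect_backbone_hbonds(m)
  expect_equal(nrow(hb), 0L)
})

test_that("ideal beta pairs produce exactly the designed bond ladders", {
  for (type in c("antiparallel", "parallel")) {
    fx <- cached_beta_pair(type, 7)
    expect_lt(fx$placement_rss, 0.05)
    hb <- detect_backbone_hbonds(fx$model)
    inter <- hb[hb$donor_chain != hb$acceptor_chain, ]
    got <- sort(paste(inter$donor_chain, inter$donor_resno,
                      inter$acceptor_chain, inter$acceptor_resno))
    want <- sort(paste(fx$expected_bonds$donor_chain,
                       fx$expected_bonds$donor_resno,
                       fx$expected_bonds$acceptor_chain,
                       fx$expected_bonds$acceptor_resno))
    expect_equal(got, want)
    expect_true(all(inter$energy < -0.5))
  }
})

test_that("strands pulled 20 A apart form no inter-strand bonds", {
  fx <- cached_beta_pair("antiparallel", 5, separation = 20)
  hb <- detect_backbone_hbonds(fx$model)
  expect_equal(sum(hb$donor_chain != hb$acceptor_chain), 0L)
})

test_that("the geometric criterion agrees with Kabsch-Sander on clean ladders", {
  fx <- cached_beta_pair("antiparallel", 7)
  ks <- detect_backbone_hbonds(fx$model)
  geo <- detect_backbone_hbonds(fx$model, criterion = "geometric")
  keyify <- function(h) sort(paste(h$donor_chain, h$donor_resno,
                                   h$acceptor_chain, h$acceptor_resno))
  expect_equal(keyify(geo), keyify(ks))
  expect_true(all(is.na(geo$energy)))
})

test_that("bridge classification is 100% correct on ideal pairs, lengths 3-10", {
  for (type in c("antiparallel", "parallel")) {
    for (n in 3:10) {
      fx <- cached_beta_pair(type, n)
      hb <- detect_backbone_hbonds(fx$model)
      br <- classify_bridges(hb, fx$model)
      inter <- br[br$chain_i != br$chain_j, ]
      expect_gt(nrow(inter), 0)
      expect_true(all(inter$type == type),
                  label = sprintf("%s n=%d pure type", type, n))
      want <- fx$expected_bridges
      got <- sort(paste(inter$resno_i, inter$resno_j))
      expect_equal(got, sort(paste(want$resno_i, want$resno_j)),
                   label = sprintf("%s n=%d bridge set", type, n))
    }
  }
})

test_that("sheet_topology counts strands and helices on ideal fixtures", {
  fx <- cached_beta_pair("antiparallel", 6)
  tA <- sheet_topology(fx$model, "A")
  tB <- sheet_topology(fx$model, "B")
  expect_equal(tA$n_strands + tB$n_strands, 2L)
  expect_equal(tA$n_helices + tB$n_helices, 0L)

  helix <- gen_helix_fixture(12)
  th <- sheet_topology(helix, "A")
  expect_equal(th$n_strands, 0L)
  expect_equal(th$n_helices, 1L)

  expect_error(sheet_topology(helix, "Z"), "fewer than 5|not in model")
})

test_that("recruitment detection: single ladder gives one partner, flag off", {
  fx <- cached_beta_pair("parallel", 6)
  rec <- detect_strand_recruitment(fx$model, "A", burial = FALSE)
  expect_equal(nrow(rec$partners), 1L)
  expect_equal(rec$partners$partner, "B")
  expect_equal(rec$partners$type, "parallel")
  expect_false(rec$recruited_to_two_sheets)
})

test_that("recruitment detection: no bridges gives an empty report", {
  fx <- cached_beta_pair("antiparallel", 5, separation = 20)
  rec <- detect_strand_recruitment(fx$model, "A", burial = FALSE)
  expect_equal(nrow(rec$partners), 0L)
  expect_false(rec$recruited_to_two_sheets)
})

test_that("a strand recruited by two sheets sets the two-sheet flag with one
           parallel and one antiparallel ladder", {
  fx <- cached_recruitment_complex(7)
  rec <- detect_strand_recruitment(fx$model, "P", burial = FALSE)
  expect_true(rec$recruited_to_two_sheets)
  expect_setequal(rec$partners$partner, c("A", "B"))
  types <- stats::setNames(rec$partners$type, rec$partners$partner)
  expect_equal(types[["A"]], "parallel")
  expect_equal(types[["B"]], "antiparallel")
})

test_that("recruitment preconditions name the available chains", {
  fx <- cached_beta_pair("parallel", 5)
  expect_error(detect_strand_recruitment(fx$model, "Q"), "available: A, B")
  solo <- structure_model(fx$model$atoms[fx$model$atoms$chain == "A", ])
  expect_error(detect_strand_recruitment(solo, "A"), "no partner")
})
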