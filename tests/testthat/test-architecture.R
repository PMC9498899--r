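bg <- function(n, ch = "A") paste(rep(ch, n), collapse = "")
finger <- function(d1, d2, d3) {
  paste0("C", bg(d1), "C", bg(d2), "C", bg(d3), "H")
}
rr30 <- paste0(bg(10, "R"), bg(20, "A"))  # 10/30 arginine

test_that("the plant RR-TZF finger pair is detected at linker 16 and only 16", {
  for (lk in 14:20) {
    seq <- c(p = paste0(rr30, finger(7, 5, 3), bg(lk), finger(5, 4, 3), bg(10)))
    motifs <- scanCcch(seq)
    pair <- detectPlantRrTzf(motifs)
    if (lk == 16) {
      expect_false(is.null(pair))
      expect_equal(pair$linker, 16L)
      expect_equal(pair$motifA$start, 31L)
      expect_equal(pair$motifB$start, 31L + 19L + 16L)
    } else {
      expect_null(pair)
    }
  }
  # d1 = 8 first finger also qualifies
  seq8 <- c(p = paste0(rr30, finger(8, 5, 3), bg(16), finger(5, 4, 3)))
  expect_false(is.null(detectPlantRrTzf(scanCcch(seq8))))
})

test_that("the animal-type pair needs two (8,5,3) fingers 18-19 residues apart", {
  for (lk in c(17, 18, 19, 20)) {
    seq <- c(p = paste0(bg(5), finger(8, 5, 3), bg(lk), finger(8, 5, 3), bg(5)))
    pair <- detectAnimalTzf(scanCcch(seq))
    if (lk %in% c(18, 19)) expect_false(is.null(pair)) else expect_null(pair)
  }
  # (7,5,3) fingers at 18 do not qualify
  seq7 <- c(p = paste0(bg(5), finger(7, 5, 3), bg(18), finger(7, 5, 3)))
  expect_null(detectAnimalTzf(scanCcch(seq7)))
})

test_that("motifs from another protein are rejected", {
  m <- scanCcch(c(a = paste0(finger(7, 5, 3), bg(16), finger(5, 4, 3))))
  m$protein_id[1] <- "b"
  expect_error(detectPlantRrTzf(m), "single protein")
})

test_that("the arginine-rich test enforces both the count and the fraction thresholds", {
  seq <- c(p = paste0(bg(22), bg(8, "R"), finger(7, 5, 3)))
  rr <- arginineRichRegion(seq, anchor = 31)
  expect_false(is.null(rr))
  expect_equal(rr$arg_fraction, 8 / 30, tolerance = 1e-12)
  expect_equal(c(rr$start, rr$end), c(1L, 30L))
  # zero arginines -> nothing
  expect_null(arginineRichRegion(c(p = paste0(bg(30), "C")), anchor = 31))
  # enough fraction but too few arginines in a short truncated window
  short <- c(p = paste0("RR", finger(7, 5, 3)))
  expect_null(arginineRichRegion(short, anchor = 3))  # 2 R < minArg
  # fraction below 0.2 fails even with >= 3 arginines
  sparse <- c(p = paste0(bg(27), "RRR", finger(7, 5, 3)))
  expect_null(arginineRichRegion(sparse, anchor = 31, window = 100))
})

test_that("classification follows the RR_TZF > TZF > NON_TZF rule order", {
  rr_tzf <- c(p = paste0(rr30, finger(7, 5, 3), bg(16), finger(5, 4, 3)))
  expect_equal(classifyArchitecture(rr_tzf)$call, "RR_TZF")
  tzf <- c(p = paste0(bg(30), finger(8, 5, 3), bg(18), finger(8, 5, 3)))
  expect_equal(classifyArchitecture(tzf)$call, "TZF")
  # plant pair without an arginine-rich upstream window: the pair spacing
  # fails the animal test, so the call collapses to NON_TZF with a note
  bare_pair <- c(p = paste0(bg(30), finger(7, 5, 3), bg(16), finger(5, 4, 3)))
  cl <- classifyArchitecture(bare_pair)
  expect_equal(cl$call, "NON_TZF")
  expect_equal(cl$note, "tandem without RR region")
  # dropping the RR requirement recovers the plant call
  expect_equal(classifyArchitecture(bare_pair, requireRr = FALSE)$call, "RR_TZF")
  # no tandem at all
  expect_equal(classifyArchitecture(c(p = paste0(bg(10), finger(7, 5, 3))))$call,
               "NON_TZF")
})

test_that("a protein holding both tandem forms is called RR_TZF", {
  both <- c(p = paste0(rr30, finger(7, 5, 3), bg(16), finger(5, 4, 3), bg(40),
                       finger(8, 5, 3), bg(18), finger(8, 5, 3)))
  expect_equal(classifyArchitecture(both)$call, "RR_TZF")
})

test_that("classification is pure and its tandem evidence comes from the scan output", {
  fam <- generateFamily(nProteins = 30, seed = 23)
  tab1 <- architectureTable(fam$sequences)
  tab2 <- architectureTable(fam$sequences)
  expect_identical(tab1, tab2)
  motifs <- scanCcch(fam$sequences)
  called <- tab1[tab1$call != "NON_TZF", ]
  for (k in seq_len(nrow(called))) {
    keys <- paste(motifs$protein_id, motifs$start, motifs$end)
    expect_true(paste(called$protein_id[k], called$pair_a_start[k],
                      called$pair_a_end[k]) %in% keys)
    expect_true(paste(called$protein_id[k], called$pair_b_start[k],
                      called$pair_b_end[k]) %in% keys)
  }
})

test_that("architecture calls on generator output match the planted truth", {
  fam <- generateFamily(nProteins = 60, seed = 29)
  tab <- architectureTable(fam$sequences)
  rr_truth <- unique(fam$truth$protein_id[fam$truth$kind == "rr_tzf_cassette"])
  tzf_truth <- setdiff(
    unique(fam$truth$protein_id[fam$truth$kind == "tzf_cassette"]), rr_truth)
  expect_setequal(tab$protein_id[tab$call == "RR_TZF"], rr_truth)
  expect_setequal(tab$protein_id[tab$call == "TZF"], tzf_truth)
})
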