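test_that("FASTA reading parses entries in order and takes the header token as id", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a some description", "MKC", ">b", "MRH"), f)
  x <- readProteinFasta(f)
  expect_equal(names(x), c("a", "b"))
  expect_equal(as.character(x), c(a = "MKC", b = "MRH"))
})

test_that("FASTA reading flags malformed input, duplicates, and empty files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MKC", ">a", "MK"), f)
  expect_error(readProteinFasta(f), "line 1")
  writeLines(c(">a", "MKC", ">a", "MRH"), f)
  expect_error(readProteinFasta(f), "duplicate")
  file.create(f2 <- withr::local_tempfile(fileext = ".fasta"))
  expect_warning(x <- readProteinFasta(f2), "empty")
  expect_length(x, 0)
})

test_that("write/read round trip reproduces sequences byte-identically", {
  set.seed(11)
  seqs <- setNames(vapply(c(10, 59, 60, 61, 185), random_protein, ""),
                   paste0("p", 1:5))
  f <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(seqs, f)
  back <- readProteinFasta(f)
  expect_equal(as.character(back), seqs)
  # and the files themselves are identical on a second write
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("translation follows the standard code, strips one terminal stop, and flags internal stops", {
  expect_equal(as.character(translateCds(c(x = "ATGGGCTGA"))), c(x = "MG"))
  expect_error(translateCds(c(x = "ATGTAGGGC")), "internal stop at codon 2")
  expect_equal(as.character(translateCds(c(x = "ATGTAGGGC"),
                                         truncateAtStop = TRUE)), c(x = "M"))
  expect_error(translateCds(c(x = "ATGGG")), "divisible by 3")
  expect_equal(as.character(translateCds(c(x = "ATGGGCC"), forceFrame = TRUE)),
               c(x = "MG"))
  # codon with N translates to X when ambiguous
  expect_equal(as.character(translateCds(c(x = "ATGANCGGC"))), c(x = "MXG"))
})

test_that("translation of a random 300-codon CDS matches an independent codon-table lookup", {
  skip_if_not_installed("seqinr")
  set.seed(21)
  # avoid stop codons by sampling codons from the non-stop set
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1, paste, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  cds <- paste(sample(setdiff(codons, stops), 300, replace = TRUE),
               collapse = "")
  got <- as.character(translateCds(c(x = cds)))[["x"]]
  oracle <- paste(seqinr::translate(seqinr::s2c(cds)), collapse = "")
  expect_equal(got, oracle)
})

test_that("pairwise identity is 1 for self, 0 for disjoint alphabets, symmetric, and DP-optimal", {
  a <- Biostrings::AAStringSet(c(a = "MKVLDEAARWQ"))
  expect_equal(pairwiseIdentity(a, a)$identity, 1.0)
  expect_equal(pairwiseIdentity(c(a = "AAAA"), c(b = "TTTT"))$identity, 0.0)
  set.seed(31)
  for (i in 1:5) {
    s1 <- random_protein(40); s2 <- random_protein(35)
    r12 <- pairwiseIdentity(c(a = s1), c(b = s2))
    r21 <- pairwiseIdentity(c(b = s2), c(a = s1))
    expect_equal(r12$identity, r21$identity)
    expect_equal(r12$aligned_columns, r21$aligned_columns)
  }
})

test_that("alignment score equals an independent Gotoh affine-gap oracle", {
  set.seed(41)
  for (i in 1:8) {
    s1 <- random_protein(sample(20:50, 1))
    s2 <- s1
    # mutate: substitutions plus an indel
    pos <- sample(nchar(s2), 3)
    for (p in pos) substr(s2, p, p) <- sample(AA_LETTERS, 1)
    if (i %% 2 == 0) s2 <- paste0(substr(s2, 1, 10), substr(s2, 14, nchar(s2)))
    mat <- diag(1, 20); dimnames(mat) <- list(AA_LETTERS, AA_LETTERS)
    aln <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 10, gapExtension = 0.5)
    expect_equal(Biostrings::score(aln), gotoh_score(s1, s2), tolerance = 1e-9)
  }
})

test_that("a single substitution in 50 residues gives identity 49/50", {
  set.seed(51)
  s1 <- random_protein(50)
  s2 <- s1
  p <- 25
  substr(s2, p, p) <- setdiff(AA_LETTERS, substr(s1, p, p))[1]
  r <- pairwiseIdentity(c(a = s1), c(b = s2))
  expect_equal(r$identity, 49 / 50)
  expect_equal(r$aligned_columns, 50)
})

test_that("mixed sequence kinds are rejected", {
  expect_error(pairwiseIdentity(Biostrings::AAStringSet(c(a = "MKV")),
                                Biostrings::DNAStringSet(c(b = "ATG"))),
               "different kinds")
})

test_that("deduplication removes identical pairs, keeps ~91%-identical pairs, and is idempotent", {
  set.seed(61)
  base <- random_protein(100)
  near <- base
  for (p in sample(100, 9)) # 9 substitutions -> 91% identity
    substr(near, p, p) <- setdiff(AA_LETTERS, substr(near, p, p))[1]
  x <- Biostrings::AAStringSet(c(s1 = base, s2 = base, s3 = near))
  dd <- deduplicateSequences(x)
  expect_equal(sort(names(dd$kept)), c("s1", "s3"))
  expect_equal(dd$removed$removed_id, "s2")
  expect_equal(dd$removed$retained_id, "s1")
  expect_gt(dd$removed$identity, 0.97)
  # both members of the ~91% pair survive the 97% filter
  expect_true(all(c("s1", "s3") %in% names(dd$kept)))
  # idempotence
  dd2 <- deduplicateSequences(dd$kept)
  expect_equal(as.character(dd2$kept), as.character(dd$kept))
  expect_equal(nrow(dd2$removed), 0L)
  expect_error(deduplicateSequences(x, threshold = 1.5), "fraction")
})

test_that("no kept pair exceeds the threshold and retention is longest-first", {
  set.seed(71)
  pool <- random_protein(80)
  seqs <- c(long = paste0(pool, random_protein(20)), full = pool,
            trunc = substr(pool, 1, 70), other = random_protein(90))
  dd <- deduplicateSequences(Biostrings::AAStringSet(seqs), threshold = 0.75)
  kept <- dd$kept
  expect_gt(nrow(dd$removed), 0)
  combs <- combn(length(kept), 2)
  for (k in seq_len(ncol(combs))) {
    r <- pairwiseIdentity(kept[combs[1, k]], kept[combs[2, k]])
    expect_lte(r$identity, 0.75)
  }
  # the longest variant of the duplicated pool is the one retained
  expect_true("long" %in% names(kept))
  expect_true(all(dd$removed$retained_id == "long"))
})
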