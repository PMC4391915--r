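test_that("longest ORF finding and translation meet the contract", {
  expect_identical(longest_orf_translate("ATGAAATAA")$sequence, "MK")
  expect_error(longest_orf_translate("CCCGGGCCC"), "no ATG")
  expect_error(longest_orf_translate("ATGAA"), ">= 6 nt")
  expect_error(longest_orf_translate("ATGANATAA"), "ambiguous base")
  expect_error(longest_orf_translate("ATGXXXTAA"), "non-ACGTN")
  # the longest of several ORFs wins, across frames
  seq <- paste0("ATGAAATAA", "C", "ATGGAAGAGTTCTGA")  # 2 aa vs 4 aa
  expect_identical(longest_orf_translate(seq)$sequence, "MEEF")
  # reverse-complement search is opt-in
  fwd <- "ATGGAAGAGTTCAAATGA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  expect_error(longest_orf_translate(rc, both_strands = FALSE), "no ATG")
  expect_identical(longest_orf_translate(rc, both_strands = TRUE)$sequence,
                   "MEEFK")
})

test_that("molecular weight equals the sum of published average residue masses", {
  # glycine: residue 57.0513 Da + one water 18.0153 Da
  expect_equal(molecular_weight("G"), (57.0513 + 18.0153) / 1000,
               tolerance = 1e-9)
  expect_equal(molecular_weight("GG"), (2 * 57.0513 + 18.0153) / 1000,
               tolerance = 1e-9)
  expect_error(molecular_weight("GXG"), "position")
})

test_that("molecular weight cross-checks against an independent implementation", {
  skip_if_not_installed("seqinr")
  set.seed(41)
  for (i in 1:5) {
    aa <- paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                       60, replace = TRUE), collapse = "")
    ours <- molecular_weight(aa) * 1000
    theirs <- seqinr::pmw(strsplit(aa, "")[[1]])
    expect_equal(ours, unname(theirs), tolerance = 1e-3)
  }
})

test_that("percent identity obeys the trivial contracts", {
  expect_equal(percent_identity("MKLVHEAT", "MKLVHEAT"), 100.0)
  expect_equal(percent_identity("AAAA", "CCCC"), 0.0)
  set.seed(43)
  aas <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:10) {
    a <- paste(sample(aas, sample(8:20, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(8:20, 1), replace = TRUE), collapse = "")
    expect_equal(percent_identity(a, b), percent_identity(b, a),
                 tolerance = 1e-10)
    expect_equal(percent_identity(a, a), 100.0)
  }
})

test_that("alignment matches brute-force enumeration on tiny sequences", {
  set.seed(47)
  aas <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:15) {
    a <- paste(sample(aas, sample(3:5, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(3:5, 1), replace = TRUE), collapse = "")
    oracle <- brute_align(a, b)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    expect_equal(Biostrings::score(aln), oracle$score, tolerance = 1e-9)
    # the implementation's identity is achieved by some optimal alignment
    pid <- percent_identity(a, b)
    expect_true(any(abs(pid - oracle$identities) < 1e-9))
  }
})

test_that("identity tables are symmetric with unit diagonal and honour domains", {
  dom <- list(DBD = c(0, 6), LBD = c(6, 14))
  r1 <- protein_record("r1", "MKLVHEATWCREDYES", species = "sp1",
                       domains = list(DBD = c(0, 6), LBD = c(6, 16)))
  r2 <- protein_record("r2", "MKLVHECTWCREDY", species = "sp2",
                       domains = dom)
  r3 <- protein_record("r3", "MKLVHEATWCREDYES", species = "sp3",
                       domains = list(DBD = c(0, 6), LBD = c(6, 16)))
  tab <- identity_table(list(r1, r2, r3))
  expect_equal(unname(diag(unclass(tab))), rep(100, 3))
  expect_equal(unclass(tab), t(unclass(tab)))
  expect_equal(tab["r1", "r3"], 100)
  # domain-restricted comparison equals identity of the sub-sequences
  expect_equal(percent_identity(r1, r2, domain = "DBD"),
               percent_identity("MKLVHE", "MKLVHE"))
  expect_error(percent_identity(r1, protein_record("x", "MKLV"),
                                domain = "DBD"), "lacks")
  # identical records give the all-100 table
  tab2 <- identity_table(list(r1, r3))
  expect_true(all(unclass(tab2) == 100))
})

test_that("protein records validate sequences and domain intervals", {
  expect_error(protein_record("p", "MKB"), "non-standard")
  expect_warning(protein_record("p", "MKX"), "unknown \\(X\\)")
  expect_error(protein_record("p", "MKLV", domains = list(D = c(0, 9))),
               "within the sequence")
  expect_error(protein_record("p", "MKLVHE",
                              domains = list(D = c(0, 4), E = c(3, 6))),
               "overlap")
})

test_that("FASTA and identity-table round trips preserve content", {
  recs <- list(protein_record("p1", "MKLVHEAT", species = "sp1"),
               protein_record("p2", "MKLVHECT", species = "sp2"))
  f <- tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_protein_fasta(f)
  expect_identical(vapply(back, function(r) r$sequence, character(1)),
                   c("MKLVHEAT", "MKLVHECT"))
  tab <- identity_table(recs)
  tf <- tempfile(fileext = ".tsv")
  write_identity_table(tab, tf)
  df <- read.delim(tf, check.names = FALSE)
  expect_equal(df$p1, unname(unclass(tab)[, "p1"]), tolerance = 1e-6)
})

test_that("ORF simulation and translation round-trip across lengths", {
  set.seed(51)
  for (len in sample(1:500, 12)) {
    nt <- simulate_orf(len, seed = len, utr5 = 10, utr3 = 10)
    expect_identical(nchar(longest_orf_translate(nt)$sequence),
                     as.integer(len))
  }
})
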