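# FASTA records, translation, reading frames, codon-aware alignment and
# numt screening.

test_that("FASTA parsing handles headers, taxa, empty files and duplicates", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q1", "ACGT", ">r1 Thunnus albacares", "TTTT"), tf)
  x <- read_fasta(tf, "query", 2)
  expect_equal(nrow(x), 2L)
  expect_equal(x$id, c("q1", "r1"))
  expect_equal(x$taxon, c(NA, "Thunnus albacares"))
  expect_equal(x$sequence, c("ACGT", "TTTT"))

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_equal(nrow(read_fasta(empty, "query")), 0L)

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_fasta(dup, "query"), "Duplicate")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">a", "ACGT"), bad)
  expect_error(read_fasta(bad, "query"), "line 1")
})

test_that("FASTA round-trips through write_fasta", {
  x <- barcode_set(c("a", "b"), c(NA, "Some species"),
                   c(strrep("ACGT", 40), strrep("TTGCA", 33)))
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(x, tf, width = 60)
  y <- read_fasta(tf, "query")
  expect_equal(y$sequence, x$sequence)
  expect_equal(y$taxon, x$taxon)
})

test_that("translation follows the vertebrate and invertebrate mito codes", {
  expect_equal(translate_dna("ATGTTTTAA", 0, 2), "MF*")
  # AGA: stop in the vertebrate code, Ser in the invertebrate code
  expect_equal(translate_dna("AGA", 0, 2), "*")
  expect_equal(translate_dna("AGA", 0, 5), "S")
  expect_equal(translate_dna("ATGNNN", 0, 2), "MX")
  expect_equal(translate_dna("ATG-TT", 0, 2), "MX")
  expect_error(translate_dna("ATG", 0, 99), "genetic code")
})

test_that("translation length equals floor((len - frame) / 3) and matches seqinr", {
  skip_if_not_installed("seqinr")
  set.seed(4)
  for (i in 1:5) {
    n <- sample(60:90, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    for (f in 0:2) {
      aa <- translate_dna(s, f, 2)
      expect_equal(nchar(aa), (n - f) %/% 3)
      ref <- paste(seqinr::translate(strsplit(s, "")[[1]], frame = f,
                                     numcode = 2), collapse = "")
      expect_equal(aa, ref)
    }
  }
})

test_that("reading-frame choice minimizes stops and flags numt suspects", {
  # coding in frame 0, stops in the shifted frames (verified by brute force)
  core <- paste0("TTCCGTTCTACGTCCCTTAGCGGAGAGCCAACAATAATATACCTAGTGA",
                 "TCCCTAAAGGATTCAAGCGAGCTCAAGAAACATATATCAAC")
  stops <- function(s) sapply(0:2, function(fr)
    sum(strsplit(translate_dna(s, fr, 2), "")[[1]] == "*"))
  expect_equal(stops(core)[1], 0)
  expect_true(all(stops(core)[2:3] > 0))
  rec <- barcode_set("a", sequence = core)
  expect_equal(as.integer(pick_reading_frame(rec[1, ])), 0L)
  # one extra leading base shifts the clean frame to 1
  rec2 <- barcode_set("b", sequence = paste0("G", core))
  expect_equal(as.integer(pick_reading_frame(rec2[1, ])), 1L)
  # stop-riddled sequence: all frames early-stop, warned, frame = argmin
  junk <- paste0("AAAACTTTCTCACTTATATTAATCAGATAAGATTATTTATCATAATCTT",
                 "TTCACAGACATATTTAACTGAATAAAGAATTTTGAGTTCTT")
  rec3 <- barcode_set("c", sequence = junk)
  expect_warning(f <- pick_reading_frame(rec3[1, ]), "numt")
  expect_equal(as.integer(f), which.min(stops(junk)) - 1L)
})

test_that("codon-aware alignment round-trips and gaps are codon-width", {
  b <- barcode_set(c("a", "b"), sequence = c("ATGTTT", "ATGAAATTT"))
  al <- codon_aware_align(b)
  expect_equal(degap(aligned_row(al, "a")), "ATGTTT")
  expect_equal(degap(aligned_row(al, "b")), "ATGAAATTT")
  # the shorter row gains exactly one codon-width gap
  expect_equal(sum(al$matrix["a", ] == "-"), 3L)
  expect_equal(al$length, 9L)

  ident <- barcode_set(c("x", "y"),
                       sequence = rep(strrep("ATGTTTGCA", 8), 2))
  al2 <- codon_aware_align(ident)
  expect_equal(al2$length, 72L)
  expect_equal(sum(al2$matrix == "-"), 0L)

  expect_error(codon_aware_align(ident[1, ]), "at least 2")
})

test_that("substitution-only differences produce a gapless alignment", {
  fx <- sim_fixture(6, 60, seed = 31)
  recs <- barcode_set(fx$am$ids, fx$am$taxa,
                      apply(fx$am$matrix, 1, paste, collapse = ""))
  al <- codon_aware_align(recs)
  expect_equal(sum(al$matrix == "-"), 0L)
  expect_equal(al$length, fx$am$length)
  # simulation round-trip: alignment equals the simulated matrix
  expect_equal(al$matrix[fx$am$ids, ], fx$am$matrix[fx$am$ids, ],
               ignore_attr = TRUE)
})

test_that("numt screen flags internal stops and frameshift gaps only", {
  s <- strrep("ATGTTTGCA", 8)
  s_stop <- paste0(substr(s, 1, 30), "TAA", substr(s, 34, nchar(s)))
  clean2 <- sub("TTT", "TTC", s)
  am <- as_aligned_matrix(barcode_set(c("ok", "bad"),
                                      sequence = c(s, s_stop)))
  rep1 <- numt_screen(am)
  expect_true(rep1$passed[rep1$record_id == "ok"])
  expect_false(rep1$passed[rep1$record_id == "bad"])
  expect_equal(rep1$stop_columns[[2]], 31L)

  # 2-column internal gap run breaks the frame
  r1 <- seq_chars(s)
  r2 <- seq_chars(clean2); r2[10:11] <- "-"
  am2 <- structure(list(matrix = rbind(a = r1, b = r2), ids = c("a", "b"),
                        taxa = c(NA, NA), genetic_code = 2,
                        frame_offset = 0L,
                        codon_pos = rep(1:3, nchar(s) / 3),
                        length = nchar(s)), class = "aligned_matrix")
  rep2 <- numt_screen(am2)
  expect_false(rep2$passed[2])
  expect_equal(unname(rep2$frameshift_gap_runs[[2]][1, ]), c(10L, 2L))

  # terminal stop codon is tolerated
  s_term <- paste0(substr(s, 1, nchar(s) - 3), "TAA")
  am3 <- as_aligned_matrix(barcode_set("t", sequence = s_term))
  expect_true(numt_screen(am3)$passed[1])

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_numt_report(rep1, tf)
  out <- read.delim(tf)
  expect_equal(out$passed, c(TRUE, FALSE))
})

test_that("simulator output always passes the numt screen", {
  for (seed in c(5, 6)) {
    fx <- sim_fixture(5, 50, seed = seed)
    expect_true(all(numt_screen(fx$am)$passed))
  }
})
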