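test_that("read_fasta parses records, strips noise and validates the alphabet", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q", "MKV"), f)
  seqs <- read_fasta(f)
  expect_length(seqs, 1)
  expect_equal(seqs[[1]]$id, "q")
  expect_equal(seqs[[1]]$residues, "MKV")
  expect_equal(seqs[[1]]$length, 3)

  # wrapped lines, lower case, whitespace and digits inside residue lines
  writeLines(c(">s1 first protein", "mkvl", "at", ">s2", "MK 12VL", "ATER"), f)
  seqs <- read_fasta(f)
  expect_length(seqs, 2)
  expect_equal(vapply(seqs, `[[`, character(1), "id"), c("s1", "s2"))
  expect_equal(seqs[[1]]$residues, "MKVLAT")
  expect_equal(seqs[[2]]$residues, "MKVLATER")
  expect_equal(seqs[[1]]$description, "first protein")

  # ambiguity letters are accepted and mapped to X
  writeLines(c(">amb", "MBZU*K"), f)
  expect_equal(read_fasta(f)[[1]]$residues, "MXXXXK")

  # empty file and invalid letters
  writeLines(character(0), f)
  expect_error(read_fasta(f), "no sequences")
  writeLines(c(">bad", "MKOQ"), f)
  expect_error(read_fasta(f), "O.*bad|bad.*O")
})

test_that("fasta round-trip preserves ids and residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- list(fragal_seq("a1", strrep("MKVLATERQWHD", 12), "desc one"),
               fragal_seq("a2", "WWHDC"))
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(lapply(back, `[[`, "id"), lapply(seqs, `[[`, "id"))
  expect_equal(lapply(back, `[[`, "residues"), lapply(seqs, `[[`, "residues"))
})

test_that("fragment_sequence follows the sliding-window rule", {
  s50 <- fragal_seq("s", rand_prot(50))
  fr <- fragment_sequence(s50, 50, 10, 25)
  expect_equal(fr$start, c(0, 10, 20))
  expect_equal(fr$length, c(50, 40, 30))
  expect_equal(fr$index, c(0, 1, 2))

  # length 103: starts 0..70 survive the 25-residue minimum
  fr <- fragment_sequence(fragal_seq("s", rand_prot(103)), 50, 10, 25)
  expect_equal(nrow(fr), 8)
  expect_equal(fr$start, seq(0, 70, 10))
  expect_equal(fr$length, c(rep(50, 6), 43, 33))

  # a 3418-residue target: the truncated tail B337 is kept with 48 residues
  long <- fragal_seq("t", rand_prot(3418))
  fr <- fragment_sequence(long, 50, 10, 25)
  i337 <- fr[fr$index == 337, ]
  expect_equal(i337$start, 3370)
  expect_equal(i337$length, 48)
  expect_equal(i337$residues, substr(long$residues, 3371, 3418))
  expect_true(all(fr$length >= 25))
  expect_equal(max(fr$index), 339)  # 3390 + 28 residues still passes min 25

  # single / no fragment when fraglen exceeds the sequence
  expect_equal(nrow(fragment_sequence(fragal_seq("s", rand_prot(30)), 50, 10, 25)), 1)
  expect_equal(nrow(fragment_sequence(fragal_seq("s", rand_prot(10)), 50, 10, 25)), 0)
  expect_error(fragment_sequence(s50, 50, 50), "step")
})

test_that("fragments cover the sequence and reconstruct the parent", {
  set.seed(421)
  for (len in c(61, 150, 333, 1024)) {
    s <- fragal_seq("p", rand_prot(len))
    fr <- fragment_sequence(s, 50, 10, 25)
    covered <- logical(len)
    for (k in seq_len(nrow(fr)))
      covered[(fr$start[k] + 1):(fr$start[k] + fr$length[k])] <- TRUE
    expect_true(all(covered[seq_len(len - 24)]))
    # overlapping fragments agree with the parent everywhere
    rebuilt <- rep(NA_character_, len)
    for (k in seq_len(nrow(fr))) {
      chars <- strsplit(fr$residues[k], "")[[1]]
      idx <- (fr$start[k] + 1):(fr$start[k] + fr$length[k])
      expect_true(all(is.na(rebuilt[idx]) | rebuilt[idx] == chars))
      rebuilt[idx] <- chars
    }
    expect_equal(paste(rebuilt[!is.na(rebuilt)], collapse = ""),
                 substr(s$residues, 1, max(fr$start + fr$length)))
    # determinism / order stability
    expect_identical(fr, fragment_sequence(s, 50, 10, 25))
  }
})

test_that("read_features parses plain and UniProt FT dialects and validates ranges", {
  s <- fragal_seq("P51587", rand_prot(3418))
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# hBRCA2 annotation",
               "REPEAT 1517 1551 BRC4",
               "MOD_RES 3387 3387 Phosphothreonine by CHK1/CHK2",
               "FT   REPEAT          1002..1036",
               "FT                   /note=\"BRC 1\"",
               "FT   VAR_SEQ         1..100"), f)
  tr <- read_features(f, s)
  expect_s3_class(tr, "fragal_features")
  expect_equal(nrow(tr), 3)                  # VAR_SEQ kind is not positional
  expect_equal(tr$start, c(1002, 1517, 3387))  # sorted by start
  expect_equal(tr$label[tr$start == 1002], "BRC 1")
  expect_equal(attr(tr, "seq_id"), "P51587")

  writeLines(character(0), f)
  expect_equal(nrow(read_features(f, s)), 0)

  writeLines("REPEAT 5000 5010 x", f)
  expect_error(read_features(f, fragal_seq("h", rand_prot(3418))), "outside")
  writeLines("REPEAT 40 20 x", f)
  expect_error(read_features(f, s), "end < start")
  writeLines("REPEAT 40", f)
  expect_error(read_features(f, s), "malformed")
})
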