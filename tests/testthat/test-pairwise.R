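test_that("global alignment handles identity and forced end-gap cases", {
  al <- global_align("MKVLAT", "MKVLAT")
  expect_equal(al$columns, 6)
  expect_equal(al$n_identity, 6)
  expect_equal(al$n_gap_columns, 0)
  diag_sum <- sum(BL62[cbind(strsplit("MKVLAT", "")[[1]],
                             strsplit("MKVLAT", "")[[1]])])
  expect_equal(al$raw_score, diag_sum)

  # free end gaps: W pairs with the terminal W at zero gap cost
  al <- global_align("AAW", "W")
  expect_equal(al$raw_score, BL62["W", "W"])
  expect_equal(al$aligned_b, "--W")
  expect_equal(al$n_gap_columns, 2)

  expect_error(global_align("", "MK"), "empty")
  expect_error(global_align("MK", ""), "empty")
})

test_that("global scores match the enumeration oracle with and without free end gaps", {
  set.seed(101)
  four <- c("A", "C", "D", "E")
  for (k in 1:60) {
    a <- rand_prot(sample(1:6, 1), four)
    b <- rand_prot(sample(1:6, 1), four)
    open <- sample(c(5, 10, 25), 1); ext <- sample(c(0.5, 1, 2), 1)
    for (fe in c(TRUE, FALSE)) {
      sch <- scoring_scheme(gap_open = open, gap_extend = ext, free_end_gaps = fe)
      expect_equal(global_align(a, b, sch)$raw_score,
                   oracle_global(a, b, BL62, open, ext, fe),
                   info = sprintf("%s vs %s open=%g ext=%g free=%s",
                                  a, b, open, ext, fe))
    }
  }
})

test_that("alignment scores are symmetric and recover the inputs", {
  set.seed(77)
  for (k in 1:20) {
    a <- rand_prot(sample(5:40, 1)); b <- rand_prot(sample(5:40, 1))
    al <- global_align(a, b)
    expect_equal(al$raw_score, global_align(b, a)$raw_score)
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
    expect_equal(nchar(al$aligned_a), al$columns)
    expect_lte(al$n_identity + al$n_similar_only + al$n_gap_columns, al$columns)
  }
})

test_that("global scores agree with an independent aligner", {
  skip_if_not_installed("Biostrings")
  set.seed(11)
  # Biostrings charges open + L*ext for a length-L gap; open' = open - ext
  # maps it onto this package's open + (L-1)*ext convention.
  open <- 12; ext <- 2
  sch <- scoring_scheme(gap_open = open, gap_extend = ext, free_end_gaps = FALSE)
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sub <- as.matrix(e$BLOSUM62)
  for (k in 1:15) {
    a <- rand_prot(sample(3:25, 1)); b <- rand_prot(sample(3:25, 1))
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = sub, gapOpening = open - ext,
      gapExtension = ext, type = "global", scoreOnly = TRUE)
    expect_equal(global_align(a, b, sch)$raw_score, ref)
    ref_loc <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = sub, gapOpening = open - ext,
      gapExtension = ext, type = "local", scoreOnly = TRUE)
    expect_equal(local_align(a, b, sch)$raw_score, ref_loc)
  }
})

test_that("column statistics follow the EMBOSS convention", {
  # synthetic counts: 50 columns, 20 identical, 10 similar-only, 5 gapped
  al <- structure(list(aligned_a = "", aligned_b = "", raw_score = 0,
                       columns = 50L, n_identity = 20L, n_similar_only = 10L,
                       n_gap_columns = 5L, type = "global"),
                  class = "fragal_alignment")
  st <- alignment_stats(al)
  expect_equal(st$pct_identity, 40)
  expect_equal(st$pct_similarity, 60)
  expect_equal(st$pct_similar_only, 20)

  st <- alignment_stats(global_align("MKVLATERQW", "MKVLATERQW"))
  expect_equal(st$pct_identity, 100)
  expect_equal(st$pct_similar_only, 0)

  al$columns <- 0L
  expect_error(alignment_stats(al), "undefined")

  # per-column classification against an independent column classifier
  set.seed(5)
  for (k in 1:10) {
    al <- global_align(rand_prot(30), rand_prot(30))
    ca <- strsplit(al$aligned_a, "")[[1]]; cb <- strsplit(al$aligned_b, "")[[1]]
    gap <- ca == "-" | cb == "-"
    ident <- !gap & ca == cb
    expect_equal(al$n_identity, sum(ident))
    expect_equal(al$n_similar_only, sum(BL62[cbind(ca[!gap & !ident],
                                                   cb[!gap & !ident])] > 0))
    expect_equal(al$n_gap_columns, sum(gap))
  }
})

test_that("FRscore algebra: bounds, cap and monotonicity", {
  mk <- function(id, sim_only, cols = 50L) {
    al <- structure(list(columns = cols, n_identity = id,
                         n_similar_only = sim_only,
                         n_gap_columns = cols - id - sim_only,
                         type = "global"),
                    class = "fragal_alignment")
    alignment_stats(al)
  }
  expect_equal(frscore(mk(50L, 0L)), 100)
  expect_equal(frscore(mk(0L, 0L)), 0)
  expect_equal(frscore(global_align("MKVLAT", "MKVLAT")), 100)
  # the exclusive reading caps a perfect alignment at 66.7
  expect_equal(frscore(mk(50L, 0L), mode = "exclusive"), 200 / 3)
  # inclusive is the only reading compatible with reported scores above 66.7
  expect_gt(frscore(mk(45L, 5L)), 66.7)

  # converting one similar-only column to identity gains (2/3)*(100/columns)
  for (id in c(0L, 10L, 30L)) {
    lo <- frscore(mk(id, 10L)); hi <- frscore(mk(id + 1L, 9L))
    expect_equal(hi - lo, (2 / 3) * (100 / 50))
    expect_gt(hi, lo)
  }

  # bounds over random alignments, both readings
  set.seed(9)
  for (k in 1:25) {
    al <- global_align(rand_prot(sample(2:30, 1)), rand_prot(sample(2:30, 1)))
    for (m in c("inclusive", "exclusive")) {
      v <- frscore(al, mode = m)
      expect_gte(v, 0); expect_lte(v, 100)
    }
  }
})
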