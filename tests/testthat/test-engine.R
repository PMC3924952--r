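test_that("run_fragal reports a perfect self-match first and evaluates all pairs", {
  set.seed(31)
  s <- fragal_seq("q", rand_prot(60))
  m <- run_fragal(s, s)
  expect_s3_class(m, "fragal_matches")
  expect_equal(m$a_index[1], 0)
  expect_equal(m$b_index[1], 0)
  expect_equal(m$frscore[1], 100)
  # completeness: every fragment pair was evaluated
  expect_equal(attr(m, "n_a_fragments"), attr(m, "n_b_fragments"))
  expect_equal(attr(m, "n_a_fragments"),
               nrow(fragment_sequence(s, 50, 10, 25)))
  # nothing below the threshold leaks through
  expect_true(all(m$pct_similarity >= 30))
  # coordinates follow the index * step convention
  expect_equal(m$a_start, m$a_index * 10 + 1)
  # byte-identical rerun
  expect_identical(m, run_fragal(s, s))
})

test_that("threshold filtering keeps the inclusive boundary", {
  rec <- random_records(3)
  rec$pct_similarity <- c(25, 30, 35)
  expect_equal(nrow(filter_by_threshold(rec, 30)), 2)
  expect_equal(nrow(filter_by_threshold(rec, 0)), 3)
  expect_equal(nrow(filter_by_threshold(rec, 100)), 0)
  expect_error(filter_by_threshold(rec, 101), "\\[0, 100\\]")
})

test_that("stitching respects the chain invariants", {
  one <- random_records(1)
  ch <- stitch_chains(one)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$cumulative_score, one$frscore)
  expect_equal(ch[[1]]$average_score, one$frscore)

  # overlapping A-intervals are never stitched
  two <- random_records(2)
  two$a_index <- c(0L, 1L); two$a_start <- c(1L, 11L); two$a_end <- c(50L, 60L)
  two$b_index <- c(0L, 10L); two$b_start <- c(1L, 101L); two$b_end <- c(50L, 150L)
  ch <- stitch_chains(two)
  expect_length(ch, 2)
  expect_true(all(vapply(ch, function(c) nrow(c$members), integer(1)) == 1))

  # known 4-record configuration: two compatible pairs, one blocker
  rec <- data.frame(
    a_index = c(0L, 10L, 20L, 11L), b_index = c(0L, 10L, 20L, 2L),
    a_start = c(1L, 101L, 201L, 111L), a_end = c(50L, 150L, 250L, 160L),
    b_start = c(1L, 101L, 201L, 21L), b_end = c(50L, 150L, 250L, 70L),
    frscore = c(40, 50, 60, 45),
    pct_identity = 0, pct_similarity = 0, pct_similar_only = 0, raw_score = 0)
  ch <- stitch_chains(rec)
  expect_equal(ch[[1]]$cumulative_score, oracle_best_chain_score(rec))
  expect_equal(ch[[1]]$cumulative_score, 40 + 50 + 60)
  # every chain is strictly increasing and non-overlapping in both sequences
  for (c in ch) {
    mb <- c$members
    if (nrow(mb) > 1) {
      expect_true(all(diff(mb$a_index) > 0) && all(diff(mb$b_index) > 0))
      expect_true(all(mb$a_start[-1] > mb$a_end[-nrow(mb)]))
      expect_true(all(mb$b_start[-1] > mb$b_end[-nrow(mb)]))
    }
  }
  # chains partition the records
  expect_equal(sum(vapply(ch, function(c) nrow(c$members), integer(1))),
               nrow(rec))
})

test_that("top chain matches exhaustive search on random record sets", {
  set.seed(202)
  for (k in 1:30) {
    rec <- random_records(sample(2:9, 1))
    ch <- stitch_chains(rec)
    expect_equal(ch[[1]]$cumulative_score, oracle_best_chain_score(rec),
                 tolerance = 1e-10)
  }
})

test_that("annotation filtering splits known from novel matches", {
  set.seed(44)
  s <- fragal_seq("q", rand_prot(80))
  t <- fragal_seq("t", rand_prot(80))
  m <- run_fragal(s, s, threshold = 0)

  f <- withr::local_tempfile()
  writeLines("DOMAIN 1 20 dom", f)
  tr <- read_features(f, s)  # seq_id "q"

  expect_identical(filter_by_annotation(m, tr, "all"), m)
  ann <- filter_by_annotation(m, tr, "annotated")
  nov <- filter_by_annotation(m, tr, "novel")
  expect_equal(nrow(ann) + nrow(nov), nrow(m))
  expect_true(all(ann$b_start <= 20))
  expect_true(all(nov$b_start > 20))

  # empty track: nothing is annotated
  writeLines(character(0), f)
  empty_tr <- read_features(f, s)
  expect_equal(nrow(filter_by_annotation(m, empty_tr, "annotated")), 0)

  # track for the wrong sequence
  writeLines("DOMAIN 1 20 dom", f)
  wrong <- read_features(f, t)
  expect_error(filter_by_annotation(m, wrong, "annotated"), "track")

  # chains inherit the annotated status of their members
  ch <- stitch_chains(m)
  ann_ch <- filter_by_annotation(ch, tr, "annotated")
  nov_ch <- filter_by_annotation(ch, tr, "novel")
  expect_equal(length(ann_ch) + length(nov_ch), length(ch))
})

test_that("a planted mutated motif is recovered as the top match", {
  set.seed(77)
  motif <- rand_prot(30)
  bench <- make_benchmark(motif, a_position = 120, b_position = 310,
                          mutation_rate = 0.1, seed = 99)
  m <- run_fragal(bench$A, bench$B)
  top <- m[1, ]
  tr <- bench$truth
  expect_true(top$a_start <= tr$end[1] && top$a_end >= tr$start[1])
  expect_true(top$b_start <= tr$end[2] && top$b_end >= tr$start[2])
})
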