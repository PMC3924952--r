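# Independent brute-force references: alignment scores by exhaustive
# enumeration of alignment paths, local scores by enumeration over substring
# pairs, and chain scores by enumeration over record subsets. These never
# share code with the package's dynamic-programming implementations.

AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
BL62 <- fragal:::BLOSUM62_VALUES

rand_prot <- function(n, alphabet = AAS) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Score one complete op path (0 diagonal, 1 consume a, 2 consume b).
# A gap run of length L costs open + (L - 1) * ext unless it is the first or
# last run of the path and free_end is TRUE.
score_ops_oracle <- function(ops, ac, bc, submat, open, ext, free_end) {
  sc <- 0; ai <- 0L; bi <- 0L
  nops <- length(ops)
  run_val <- -1L; run_len <- 0L; run_start <- 0L
  close_run <- function(at_end) {
    if (run_val > 0L && !(free_end && (run_start == 1L || at_end)))
      sc <<- sc - (open + (run_len - 1) * ext)
  }
  for (k in seq_len(nops)) {
    v <- ops[k]
    if (v != run_val) { close_run(FALSE); run_val <- v; run_len <- 0L; run_start <- k }
    run_len <- run_len + 1L
    if (v == 0L) {
      ai <- ai + 1L; bi <- bi + 1L
      sc <- sc + submat[ac[ai], bc[bi]]
    } else if (v == 1L) ai <- ai + 1L else bi <- bi + 1L
  }
  close_run(TRUE)
  sc
}

oracle_global <- function(a, b, submat = BL62, open = 25, ext = 0.5,
                          free_end = TRUE) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  na <- length(ac); nb <- length(bc)
  sa <- match(ac, rownames(submat)); sb <- match(bc, colnames(submat))
  nr <- nrow(submat)
  best <- -Inf
  # Enumerate every monotone path, scoring incrementally. Each gap run is
  # charged open + (len-1)*ext as it grows; the first run is free when it is
  # a gap run and free_end holds (free_run), and the final run's accumulated
  # charge (run_pen) is refunded at the leaf when free_end holds.
  rec <- function(i, j, sc, lastv, free_run, run_pen, at_start) {
    if (i == na && j == nb) {
      if (free_end && lastv > 0L) sc <- sc + run_pen
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i < na && j < nb)
      rec(i + 1L, j + 1L, sc + submat[sa[i + 1L] + nr * (sb[j + 1L] - 1L)],
          0L, FALSE, 0, FALSE)
    if (i < na) {
      if (lastv == 1L) { pen <- if (free_run) 0 else ext; fr <- free_run; rp <- run_pen + pen }
      else { fr <- free_end && at_start; pen <- if (fr) 0 else open; rp <- pen }
      rec(i + 1L, j, sc - pen, 1L, fr, rp, FALSE)
    }
    if (j < nb) {
      if (lastv == 2L) { pen <- if (free_run) 0 else ext; fr <- free_run; rp <- run_pen + pen }
      else { fr <- free_end && at_start; pen <- if (fr) 0 else open; rp <- pen }
      rec(i, j + 1L, sc - pen, 2L, fr, rp, FALSE)
    }
  }
  rec(0L, 0L, 0, -1L, FALSE, 0, TRUE)
  best
}

oracle_local <- function(a, b, submat = BL62, open = 25, ext = 0.5) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in 1:na) for (i2 in i1:na) for (j1 in 1:nb) for (j2 in j1:nb)
    best <- max(best, oracle_global(substr(a, i1, i2), substr(b, j1, j2),
                                    submat, open, ext, free_end = FALSE))
  best
}

# Best cumulative FRscore over every subset of records that forms a valid
# chain (strictly increasing indices, non-overlapping intervals in both
# sequences). Assumes nrow(records) <= ~15.
oracle_best_chain_score <- function(records) {
  n <- nrow(records)
  best <- 0
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    idx <- idx[order(records$a_index[idx], records$b_index[idx])]
    ok <- TRUE
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        p <- idx[k - 1]; q <- idx[k]
        if (!(records$a_index[p] < records$a_index[q] &&
              records$b_index[p] < records$b_index[q] &&
              records$a_end[p] < records$a_start[q] &&
              records$b_end[p] < records$b_start[q])) { ok <- FALSE; break }
      }
    }
    if (ok) best <- max(best, sum(records$frscore[idx]))
  }
  best
}

# Random match records on an index grid, for chaining tests.
random_records <- function(n, fraglen = 50, step = 10, max_index = 12) {
  ai <- sample.int(max_index, n, replace = TRUE) - 1L
  bi <- sample.int(max_index, n, replace = TRUE) - 1L
  data.frame(
    a_index = ai, b_index = bi,
    a_start = ai * step + 1L, a_end = ai * step + fraglen,
    b_start = bi * step + 1L, b_end = bi * step + fraglen,
    frscore = round(runif(n, 30, 100), 1),
    pct_identity = 50, pct_similarity = 60, pct_similar_only = 10,
    raw_score = 0, stringsAsFactors = FALSE)
}
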