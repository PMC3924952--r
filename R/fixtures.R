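# Synthetic benchmark generator: random host sequences with planted,
# independently point-mutated shared motifs and machine-readable truth.

#' Background amino-acid composition tables
#'
#' `"uniform"` gives every one of the 20 standard residues probability 0.05
#' (the simplest null). `"robinson"` is the Robinson-Robinson natural
#' composition estimated from a large protein census, normalized to sum
#' exactly to one.
#'
#' @param name `"uniform"` or `"robinson"`.
#' @return Named numeric vector of residue frequencies summing to 1.
#' @examples
#' aa_composition("robinson")[c("L", "W")]
#' @export
aa_composition <- function(name = c("uniform", "robinson")) {
  name <- match.arg(name)
  if (name == "uniform")
    return(stats::setNames(rep(1 / 20, 20), AA20))
  rr <- c(A = 0.0780, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0192,
          Q = 0.0426, E = 0.0631, G = 0.0738, H = 0.0219, I = 0.0514,
          L = 0.0901, K = 0.0574, M = 0.0224, F = 0.0385, P = 0.0520,
          S = 0.0711, T = 0.0584, W = 0.0132, Y = 0.0321, V = 0.0648)
  (rr / sum(rr))[AA20]
}

#' Random protein sequence
#'
#' Residues are drawn i.i.d. from `composition`; the result is
#' deterministic given `seed`.
#'
#' @param length Positive sequence length.
#' @param composition Named residue frequency vector summing to 1 (within
#'   1e-9), e.g. from [aa_composition()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param id Identifier for the resulting sequence.
#' @return A [fragal_seq()].
#' @examples
#' random_sequence(30, seed = 1)
#' @export
random_sequence <- function(length, composition = aa_composition("uniform"),
                            seed = NULL, id = "random") {
  if (!is.numeric(length) || length < 1)
    stop("length must be a positive integer", call. = FALSE)
  check_composition(composition)
  res <- with_seed(seed,
    paste(sample(names(composition), length, replace = TRUE,
                 prob = composition), collapse = ""))
  fragal_seq(id, res)
}

check_composition <- function(composition) {
  if (is.null(names(composition)) || !all(names(composition) %in% AA_ALPHABET))
    stop("composition must be named by amino-acid letters", call. = FALSE)
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition frequencies must sum to 1", call. = FALSE)
  invisible(TRUE)
}

# Independent per-site substitution: each residue is replaced, with
# probability `rate`, by a uniformly chosen *different* standard residue.
mutate_motif <- function(motif, rate) {
  if (rate == 0) return(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  for (k in which(hit))
    chars[k] <- sample(setdiff(AA20, chars[k]), 1)
  paste(chars, collapse = "")
}

#' Generate a planted-motif benchmark pair
#'
#' Two random host sequences are generated and a copy of `motif` --
#' independently point-mutated in each host at `mutation_rate` per site --
#' is substituted (not inserted) at the stated 0-based offsets. The truth
#' table records the 1-based inclusive motif intervals in both sequences,
#' which is exactly what recall experiments against [run_fragal()] consume.
#' No indels are introduced: under a gap-opening penalty chosen to suppress
#' gaps, indel-free planting is the matched test.
#'
#' @param motif Residue string to plant (e.g. a 30-mer emulating a
#'   RAD51-binding repeat).
#' @param a_position,b_position 0-based offsets of the planted copy in the
#'   query and target hosts; the motif must fit inside each host.
#' @param host_length_a,host_length_b Host sequence lengths (default 500).
#' @param mutation_rate Per-site substitution probability in `[0, 1]`
#'   applied independently to each planted copy (default 0).
#' @param composition Background composition, see [aa_composition()].
#' @param seed Integer seed; drives hosts and mutations.
#' @param motif_id Identifier used in the truth table.
#' @return A list with `A` and `B` ([fragal_seq()]) and `truth`, a data
#'   frame with columns `seq_id`, `start`, `end`, `motif_id`.
#' @examples
#' bench <- make_benchmark(strrep("WQKLHDMRCE", 3), 100, 300, seed = 1)
#' bench$truth
#' @export
make_benchmark <- function(motif, a_position, b_position,
                           host_length_a = 500, host_length_b = 500,
                           mutation_rate = 0,
                           composition = aa_composition("uniform"),
                           seed = NULL, motif_id = "motif1") {
  motif <- normalize_residues(motif, what = "motif")
  lm <- nchar(motif)
  if (lm < 1) stop("motif must be non-empty", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must lie in [0, 1]", call. = FALSE)
  if (a_position < 0 || a_position + lm > host_length_a ||
      b_position < 0 || b_position + lm > host_length_b)
    stop("motif does not fit inside the host at the stated offset",
         call. = FALSE)
  check_composition(composition)
  with_seed(seed, {
    host_a <- paste(sample(names(composition), host_length_a, replace = TRUE,
                           prob = composition), collapse = "")
    host_b <- paste(sample(names(composition), host_length_b, replace = TRUE,
                           prob = composition), collapse = "")
    copy_a <- mutate_motif(motif, mutation_rate)
    copy_b <- mutate_motif(motif, mutation_rate)
    substr(host_a, a_position + 1, a_position + lm) <- copy_a
    substr(host_b, b_position + 1, b_position + lm) <- copy_b
    list(
      A = fragal_seq("synthA", host_a),
      B = fragal_seq("synthB", host_b),
      truth = data.frame(
        seq_id = c("synthA", "synthB"),
        start = c(a_position + 1L, b_position + 1L),
        end = c(a_position + lm, b_position + lm),
        motif_id = motif_id, stringsAsFactors = FALSE))
  })
}

#' Write a benchmark pair to FASTA plus a truth TSV
#'
#' @param bench Result of [make_benchmark()].
#' @param fasta_a,fasta_b,truth_path Output paths; the truth table is a
#'   BED-like TSV (`seq_id`, `start`, `end`, `motif_id`) with 1-based
#'   inclusive coordinates, matching the report format.
#' @return `invisible(NULL)`.
#' @export
write_benchmark <- function(bench, fasta_a, fasta_b, truth_path) {
  write_fasta(bench$A, fasta_a)
  write_fasta(bench$B, fasta_b)
  utils::write.table(bench$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
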