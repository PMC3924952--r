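# Significance estimation: Smith-Waterman local alignment and
# shuffle-based z-scores / empirical p-values.

#' Local (Smith-Waterman) affine-gap alignment
#'
#' Optimal local alignment of two residue strings. When no residue pair
#' scores positively the optimum is the empty alignment (score 0). The
#' returned object additionally carries the 1-based coordinates of the
#' aligned region in each input (`a_begin`/`a_end`, `b_begin`/`b_end`; all
#' zero for an empty alignment).
#'
#' @inheritParams global_align
#' @return A `fragal_alignment` (see [global_align()]).
#' @examples
#' local_align("MKVWWLAT", "HHWWH")$raw_score
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  a <- residues_of(a); b <- residues_of(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  u <- scheme_units(scheme)
  res <- align_pair_cpp(encode_residues(a, scheme), encode_residues(b, scheme),
                        u$submat2, u$open2, u$ext2, 2L)
  build_alignment(a, b, res, scheme, "local")
}

#' Shuffle-based significance of a pairwise local alignment
#'
#' The observed Smith-Waterman score of `a` vs `b` is compared with the
#' scores of `a` against `n_shuffles` independent residue permutations of
#' `b` (composition-preserving Fisher-Yates shuffles). The z-score is
#' `(observed - mean) / sd` of the shuffled scores and the empirical
#' p-value uses the add-one estimator `(1 + #{shuffled >= observed}) /
#' (n_shuffles + 1)`, so it is never zero. Z-scores above 8 are commonly
#' treated as significant for this construction.
#'
#' Significance scoring is deliberately decoupled from fragment scoring:
#' the default scheme here is BLOSUM62 with gap open 10 / extend 1 and
#' penalized end gaps, a conventional null model, whereas the fragment
#' aligner's gap open of 25 exists to suppress gaps, not to model chance
#' similarity.
#'
#' @inheritParams global_align
#' @param n_shuffles Number of permutations, at least 30 (default 200).
#' @param seed Integer seed making the null reproducible; `NULL` uses the
#'   current RNG stream.
#' @param scheme A [scoring_scheme()] for the local aligner.
#' @return A list of class `fragal_significance` with `observed_score`,
#'   `shuffle_mean`, `shuffle_sd`, `zscore`, `empirical_p`, `n_shuffles`
#'   and `seed`.
#' @examples
#' s <- random_sequence(80, seed = 7)
#' shuffle_zscore(s, s, n_shuffles = 50, seed = 1)$zscore
#' @export
shuffle_zscore <- function(a, b, scheme = scoring_scheme(gap_open = 10,
                                                         gap_extend = 1,
                                                         free_end_gaps = FALSE),
                           n_shuffles = 200, seed = NULL) {
  if (n_shuffles < 30) stop("n_shuffles must be at least 30", call. = FALSE)
  a <- residues_of(a); b <- residues_of(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  u <- scheme_units(scheme)
  ea <- encode_residues(a, scheme)
  eb <- encode_residues(b, scheme)
  observed <- local_score_cpp(ea, eb, u$submat2, u$open2, u$ext2) / 2
  scores <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(k)
      local_score_cpp(ea, eb[sample.int(length(eb))],
                      u$submat2, u$open2, u$ext2) / 2,
      numeric(1))
  })
  mu <- mean(scores)
  sdev <- stats::sd(scores)
  if (!is.finite(sdev) || sdev == 0)
    stop("degenerate shuffle null: shuffled scores have zero variance",
         call. = FALSE)
  structure(
    list(observed_score = observed, shuffle_mean = mu, shuffle_sd = sdev,
         zscore = (observed - mu) / sdev,
         empirical_p = (1 + sum(scores >= observed)) / (n_shuffles + 1),
         n_shuffles = as.integer(n_shuffles),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "fragal_significance")
}

#' @export
print.fragal_significance <- function(x, ...) {
  cat(sprintf(paste0("<fragal_significance> observed %.1f, null %.2f +/- %.2f ",
                     "(n=%d)\n  z = %.2f, empirical p = %.4g\n"),
              x$observed_score, x$shuffle_mean, x$shuffle_sd, x$n_shuffles,
              x$zscore, x$empirical_p))
  invisible(x)
}
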