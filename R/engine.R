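# The fragmented-alignment driver: all-vs-all fragment comparison,
# threshold filtering, chain stitching and annotation filtering.

#' Run the fragmented alignment of two protein sequences
#'
#' Both sequences are cut into overlapping fragments
#' ([fragment_sequence()]), every (query fragment, target fragment) pair is
#' globally aligned under `scheme`, and each pair whose percent similarity
#' reaches `threshold` is reported with its FRscore and column statistics.
#' Records are sorted by FRscore descending with deterministic tie-breaking
#' (query index, then target index, ascending).
#'
#' @param A Query sequence ([fragal_seq()] or residue string).
#' @param B Target sequence.
#' @param fraglen,step,min_fragment_length Fragmentation parameters, see
#'   [fragment_sequence()].
#' @param threshold Minimum percent similarity for a fragment pair to be
#'   reported (default 30, the method's default mode).
#' @param scheme A [scoring_scheme()]; the default uses BLOSUM62 with gap
#'   open 25 / extend 0.5 and free end gaps.
#' @param frscore_mode FRscore reading, see [frscore()].
#' @return A data frame of class `fragal_matches` with columns `a_index`,
#'   `b_index`, `a_start`, `a_end`, `b_start`, `b_end` (1-based inclusive),
#'   `frscore`, `pct_identity`, `pct_similarity`, `pct_similar_only` and
#'   `raw_score`. Attributes `query_id`, `target_id` and `params` carry
#'   provenance.
#' @examples
#' s <- fragal_seq("q", strrep("MKVLATERQWHD", 5))
#' run_fragal(s, s)[1, ]
#' @export
run_fragal <- function(A, B, fraglen = 50, step = 10, threshold = 30,
                       scheme = scoring_scheme(),
                       min_fragment_length = floor(fraglen / 2),
                       frscore_mode = c("inclusive", "exclusive")) {
  frscore_mode <- match.arg(frscore_mode)
  A <- as_fragal_seq(A, id = "query")
  B <- as_fragal_seq(B, id = "target")
  if (A$length == 0 || B$length == 0) stop("empty sequence", call. = FALSE)
  if (threshold < 0 || threshold > 100)
    stop("threshold must lie in [0, 100]", call. = FALSE)
  fa <- fragment_sequence(A, fraglen, step, min_fragment_length)
  fb <- fragment_sequence(B, fraglen, step, min_fragment_length)
  params <- list(fraglen = fraglen, step = step, threshold = threshold,
                 min_fragment_length = min_fragment_length,
                 frscore_mode = frscore_mode,
                 matrix = scheme$matrix_name, gap_open = scheme$gap_open,
                 gap_extend = scheme$gap_extend,
                 free_end_gaps = scheme$free_end_gaps)
  if (nrow(fa) == 0 || nrow(fb) == 0) {
    warning("no fragments produced; returning empty match table")
    return(empty_matches(A$id, B$id, params))
  }
  u <- scheme_units(scheme)
  enc_a <- lapply(fa$residues, encode_residues, scheme = scheme)
  enc_b <- lapply(fb$residues, encode_residues, scheme = scheme)
  m <- fragment_stats_cpp(enc_a, enc_b, u$submat2, u$open2, u$ext2,
                          if (scheme$free_end_gaps) 1L else 0L)
  cols <- m[, 3]; n_id <- m[, 4]; n_sim <- m[, 5]
  pid <- 100 * n_id / cols
  psim <- 100 * (n_id + n_sim) / cols
  fr <- if (frscore_mode == "inclusive") psim / 3 + 2 * pid / 3
        else (psim - pid) / 3 + 2 * pid / 3
  ia <- m[, 1] + 1L; ib <- m[, 2] + 1L
  rec <- data.frame(
    a_index = fa$index[ia], b_index = fb$index[ib],
    a_start = fa$start[ia] + 1L, a_end = fa$start[ia] + fa$length[ia],
    b_start = fb$start[ib] + 1L, b_end = fb$start[ib] + fb$length[ib],
    frscore = fr, pct_identity = pid, pct_similarity = psim,
    pct_similar_only = psim - pid, raw_score = m[, 7] / 2,
    stringsAsFactors = FALSE)
  rec <- rec[rec$pct_similarity >= threshold, , drop = FALSE]
  rec <- rec[order(-rec$frscore, rec$a_index, rec$b_index), , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec, query_id = A$id, target_id = B$id, params = params,
            n_a_fragments = nrow(fa), n_b_fragments = nrow(fb),
            class = c("fragal_matches", "data.frame"))
}

empty_matches <- function(query_id, target_id, params) {
  rec <- data.frame(a_index = integer(), b_index = integer(),
                    a_start = integer(), a_end = integer(),
                    b_start = integer(), b_end = integer(),
                    frscore = numeric(), pct_identity = numeric(),
                    pct_similarity = numeric(), pct_similar_only = numeric(),
                    raw_score = numeric(), stringsAsFactors = FALSE)
  structure(rec, query_id = query_id, target_id = target_id, params = params,
            n_a_fragments = 0L, n_b_fragments = 0L,
            class = c("fragal_matches", "data.frame"))
}

#' Keep fragment matches above a similarity threshold
#'
#' @param records A `fragal_matches` data frame.
#' @param threshold Minimum percent similarity (inclusive boundary).
#' @return The filtered records, order preserved.
#' @export
filter_by_threshold <- function(records, threshold) {
  stopifnot(is.data.frame(records))
  if (threshold < 0 || threshold > 100)
    stop("threshold must lie in [0, 100]", call. = FALSE)
  keep_attrs(records[records$pct_similarity >= threshold, , drop = FALSE], records)
}

keep_attrs <- function(x, template) {
  for (a in c("query_id", "target_id", "params",
              "n_a_fragments", "n_b_fragments"))
    attr(x, a) <- attr(template, a)
  class(x) <- class(template)
  rownames(x) <- NULL
  x
}

#' Stitch fragment matches into collinear chains
#'
#' Dynamic-programming weighted chaining: a chain is an ordered run of
#' matches whose fragment indices strictly increase in both sequences and
#' whose fragment intervals do not overlap in either sequence. The chain
#' maximizing cumulative FRscore is extracted, its members are removed, and
#' the process repeats, so every record ends up in exactly one chain
#' (singletons allowed). Chains are returned in decreasing cumulative-score
#' order.
#'
#' @param records A `fragal_matches` data frame.
#' @return A list of class `fragal_chains`; each element is a
#'   `fragal_chain` list with `members` (rows of `records`),
#'   `cumulative_score` and `average_score`.
#' @export
stitch_chains <- function(records) {
  stopifnot(is.data.frame(records))
  chains <- list()
  pool <- as.data.frame(records)
  while (nrow(pool) > 0) {
    ord <- order(pool$a_index, pool$b_index)
    pool <- pool[ord, , drop = FALSE]
    n <- nrow(pool)
    dp <- pool$frscore
    prev <- rep(NA_integer_, n)
    if (n > 1) {
      for (i in 2:n) {
        for (j in 1:(i - 1)) {
          ok <- pool$a_index[j] < pool$a_index[i] &&
                pool$b_index[j] < pool$b_index[i] &&
                pool$a_end[j] < pool$a_start[i] &&
                pool$b_end[j] < pool$b_start[i]
          if (ok && dp[j] + pool$frscore[i] > dp[i]) {
            dp[i] <- dp[j] + pool$frscore[i]
            prev[i] <- j
          }
        }
      }
    }
    best <- which.max(dp)
    path <- integer()
    k <- best
    while (!is.na(k)) { path <- c(k, path); k <- prev[k] }
    members <- pool[path, , drop = FALSE]
    rownames(members) <- NULL
    chains[[length(chains) + 1L]] <- structure(
      list(members = members,
           cumulative_score = sum(members$frscore),
           average_score = mean(members$frscore)),
      class = "fragal_chain")
    pool <- pool[-path, , drop = FALSE]
  }
  if (length(chains) > 1) {
    cum <- vapply(chains, `[[`, numeric(1), "cumulative_score")
    chains <- chains[order(-cum)]
  }
  structure(chains, class = "fragal_chains",
            query_id = attr(records, "query_id"),
            target_id = attr(records, "target_id"))
}

#' @export
print.fragal_chain <- function(x, ...) {
  cat(sprintf("<fragal_chain> %d member(s), cumulative %.1f, average %.1f\n",
              nrow(x$members), x$cumulative_score, x$average_score))
  pairs <- sprintf("A%d-B%d", x$members$a_index, x$members$b_index)
  cat(" ", paste(pairs, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.fragal_chains <- function(x, ...) {
  cat(sprintf("<fragal_chains> %d chain(s)\n", length(x)))
  for (ch in x) print(ch)
  invisible(x)
}

#' Filter matches or chains by a target annotation track
#'
#' A record is "annotated" when its target-side fragment interval overlaps
#' at least one feature by at least `min_overlap` residues; a chain is
#' annotated when any member is. `mode = "annotated"` keeps annotated
#' entries, `"novel"` keeps the complement and `"all"` is the identity.
#' Order is preserved.
#'
#' @param x A `fragal_matches` data frame or `fragal_chains` list.
#' @param track A [read_features()] track for the target sequence.
#' @param mode One of `"all"`, `"annotated"`, `"novel"`.
#' @param min_overlap Minimum overlap in residues (default 1).
#' @return The filtered object.
#' @export
filter_by_annotation <- function(x, track, mode = c("all", "annotated", "novel"),
                                 min_overlap = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "fragal_features"))
  target_id <- attr(x, "target_id")
  track_id <- attr(track, "seq_id")
  if (!is.null(target_id) && !is.null(track_id) && !identical(target_id, track_id))
    stop(sprintf("annotation track is for '%s' but matches target '%s'",
                 track_id, target_id), call. = FALSE)
  if (mode == "all") return(x)
  hit_fun <- function(bs, be) {
    if (nrow(track) == 0) return(FALSE)
    any(pmin(track$end, be) - pmax(track$start, bs) + 1 >= min_overlap)
  }
  if (inherits(x, "fragal_chains")) {
    hit <- vapply(x, function(ch)
      any(mapply(hit_fun, ch$members$b_start, ch$members$b_end)), logical(1))
    out <- unclass(x)[if (mode == "annotated") hit else !hit]
    return(structure(out, class = "fragal_chains",
                     query_id = attr(x, "query_id"),
                     target_id = attr(x, "target_id")))
  }
  hit <- if (nrow(x)) mapply(hit_fun, x$b_start, x$b_end) else logical(0)
  keep_attrs(x[if (mode == "annotated") hit else !hit, , drop = FALSE], x)
}

#' Annotated-status flags for a set of matches
#'
#' @param records A `fragal_matches` data frame.
#' @param track A [read_features()] track for the target, or `NULL`.
#' @param min_overlap Minimum overlap in residues.
#' @return Logical vector, one flag per record (`FALSE` everywhere when
#'   `track` is `NULL` or empty).
#' @export
annotated_flags <- function(records, track = NULL, min_overlap = 1) {
  if (nrow(records) == 0) return(logical(0))
  if (is.null(track) || nrow(track) == 0) return(rep(FALSE, nrow(records)))
  mapply(function(bs, be)
    any(pmin(track$end, be) - pmax(track$start, bs) + 1 >= min_overlap),
    records$b_start, records$b_end)
}
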