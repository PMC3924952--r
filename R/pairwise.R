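# Pairwise alignment, column statistics and the FRscore.

build_alignment <- function(a, b, res, scheme, type) {
  ops <- res$ops
  achars <- strsplit(a, "", fixed = TRUE)[[1]]
  bchars <- strsplit(b, "", fixed = TRUE)[[1]]
  if (type == "local") {
    achars <- if (res$a_end > 0) achars[res$a_begin:res$a_end] else character(0)
    bchars <- if (res$b_end > 0) bchars[res$b_begin:res$b_end] else character(0)
  }
  ca <- cb <- character(length(ops))
  ai <- bi <- 1L
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) {
      ca[k] <- achars[ai]; cb[k] <- bchars[bi]; ai <- ai + 1L; bi <- bi + 1L
    } else if (ops[k] == 1L) {
      ca[k] <- achars[ai]; cb[k] <- "-"; ai <- ai + 1L
    } else {
      ca[k] <- "-"; cb[k] <- bchars[bi]; bi <- bi + 1L
    }
  }
  gap <- ca == "-" | cb == "-"
  ident <- !gap & ca == cb
  sim_only <- logical(length(ops))
  nong <- which(!gap & !ident)
  if (length(nong))
    sim_only[nong] <- scheme$submat[cbind(ca[nong], cb[nong])] > 0
  structure(
    list(aligned_a = paste(ca, collapse = ""),
         aligned_b = paste(cb, collapse = ""),
         raw_score = res$score2 / 2,
         columns = length(ops),
         n_identity = sum(ident),
         n_similar_only = sum(sim_only),
         n_gap_columns = sum(gap),
         type = type,
         a_begin = res$a_begin, a_end = res$a_end,
         b_begin = res$b_begin, b_end = res$b_end),
    class = "fragal_alignment")
}

#' Global affine-gap alignment of two residue strings
#'
#' Needleman-Wunsch global alignment under an affine gap model. With
#' `scheme$free_end_gaps` (the default) leading and trailing gap runs cost
#' nothing, matching the needle convention the fragment scoring relies on.
#' Traceback tie-breaking is fixed (diagonal over up over left), so the
#' output is bit-identical across runs.
#'
#' @param a,b Non-empty residue strings or [fragal_seq()] objects.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `fragal_alignment` with the gapped strings
#'   `aligned_a`/`aligned_b`, `raw_score`, and the column counts `columns`,
#'   `n_identity`, `n_similar_only` (distinct residues with positive
#'   substitution score) and `n_gap_columns`.
#' @examples
#' al <- global_align("MKVLAT", "MKVLAT")
#' al$n_identity
#' @seealso [local_align()], [alignment_stats()], [frscore()]
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  a <- residues_of(a); b <- residues_of(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  u <- scheme_units(scheme)
  res <- align_pair_cpp(encode_residues(a, scheme), encode_residues(b, scheme),
                        u$submat2, u$open2, u$ext2,
                        if (scheme$free_end_gaps) 1L else 0L)
  build_alignment(a, b, res, scheme,
                  if (scheme$free_end_gaps) "global (free end gaps)" else "global")
}

residues_of <- function(x) {
  if (inherits(x, "fragal_seq")) x$residues
  else normalize_residues(as.character(x))
}

#' @export
print.fragal_alignment <- function(x, width = 60, ...) {
  st <- if (x$columns > 0) alignment_stats(x) else NULL
  cat(sprintf("# %s alignment, length %d, score %.1f\n",
              x$type, x$columns, x$raw_score))
  if (!is.null(st))
    cat(sprintf("# identity %d/%d (%.1f%%), similarity %.1f%%, gaps %d\n",
                x$n_identity, x$columns, st$pct_identity, st$pct_similarity,
                x$n_gap_columns))
  ca <- strsplit(x$aligned_a, "")[[1]]
  cb <- strsplit(x$aligned_b, "")[[1]]
  mark <- ifelse(ca != "-" & ca == cb, "|",
                 ifelse(ca == "-" | cb == "-", " ", ":"))
  if (x$columns > 0) {
    for (off in seq.int(1, x$columns, by = width)) {
      idx <- off:min(x$columns, off + width - 1)
      cat(paste(ca[idx], collapse = ""), "\n",
          paste(mark[idx], collapse = ""), "\n",
          paste(cb[idx], collapse = ""), "\n\n", sep = "")
    }
  }
  invisible(x)
}

#' Percent identity and similarity of an alignment
#'
#' Percentages follow the EMBOSS convention: the denominator is the full
#' alignment length, gap columns included. `pct_similarity` is
#' identity-inclusive (identical columns plus distinct residue pairs with a
#' positive substitution score); `pct_similar_only` is the difference.
#'
#' @param al A `fragal_alignment`.
#' @return A list of class `fragal_stats` with `pct_identity`,
#'   `pct_similarity` and `pct_similar_only`, each in `[0, 100]`.
#' @export
alignment_stats <- function(al) {
  stopifnot(inherits(al, "fragal_alignment"))
  if (al$columns == 0)
    stop("statistics undefined for an empty alignment", call. = FALSE)
  pid <- 100 * al$n_identity / al$columns
  psim <- 100 * (al$n_identity + al$n_similar_only) / al$columns
  structure(list(pct_identity = pid, pct_similarity = psim,
                 pct_similar_only = psim - pid),
            class = "fragal_stats")
}

#' Weighted identity/similarity score of a fragment alignment
#'
#' `FRscore = 1/3 * %similarity + 2/3 * %identity`, designed to up-weight
#' identical residues relative to plain percent similarity. Two readings of
#' the similarity term are provided:
#' \describe{
#'   \item{`inclusive` (default)}{`%similarity` counts identical columns as
#'     similar (the needle "Similarity" percentage). A perfect alignment
#'     scores 100. This is the default because reported scores above the
#'     66.7 ceiling of the exclusive reading (e.g. 73.5) are only possible
#'     under it.}
#'   \item{`exclusive`}{the similarity term excludes identical columns, so a
#'     perfect alignment caps at 66.7.}
#' }
#'
#' @param stats A `fragal_stats` or `fragal_alignment` object.
#' @param mode `"inclusive"` or `"exclusive"`.
#' @return A number in `[0, 100]`; 100 iff every column is identical
#'   (inclusive mode).
#' @examples
#' frscore(global_align("MKVLAT", "MKVLAT"))
#' @export
frscore <- function(stats, mode = c("inclusive", "exclusive")) {
  mode <- match.arg(mode)
  if (inherits(stats, "fragal_alignment")) stats <- alignment_stats(stats)
  stopifnot(inherits(stats, "fragal_stats"))
  sim <- if (mode == "inclusive") stats$pct_similarity else stats$pct_similar_only
  sim / 3 + 2 * stats$pct_identity / 3
}
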