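# Substitution matrix and scoring scheme.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET <- c(AA20, "X")

# Canonical NCBI BLOSUM62 integer matrix, restricted to the 20 standard
# residues plus X (unknown). Ambiguity letters B/Z/U/* are mapped to X on
# input, so no further rows are needed.
BLOSUM62_VALUES <- matrix(c(
    4,  -1,  -2,  -2,   0,  -1,  -1,   0,  -2,  -1,  -1,  -1,  -1,  -2,  -1,   1,   0,  -3,  -2,   0,  -1,  # A
   -1,   5,   0,  -2,  -3,   1,   0,  -2,   0,  -3,  -2,   2,  -1,  -3,  -2,  -1,  -1,  -3,  -2,  -3,  -1,  # R
   -2,   0,   6,   1,  -3,   0,   0,   0,   1,  -3,  -3,   0,  -2,  -3,  -2,   1,   0,  -4,  -2,  -3,  -1,  # N
   -2,  -2,   1,   6,  -3,   0,   2,  -1,  -1,  -3,  -4,  -1,  -3,  -3,  -1,   0,  -1,  -4,  -3,  -3,  -1,  # D
    0,  -3,  -3,  -3,   9,  -3,  -4,  -3,  -3,  -1,  -1,  -3,  -1,  -2,  -3,  -1,  -1,  -2,  -2,  -1,  -1,  # C
   -1,   1,   0,   0,  -3,   5,   2,  -2,   0,  -3,  -2,   1,   0,  -3,  -1,   0,  -1,  -2,  -1,  -2,  -1,  # Q
   -1,   0,   0,   2,  -4,   2,   5,  -2,   0,  -3,  -3,   1,  -2,  -3,  -1,   0,  -1,  -3,  -2,  -2,  -1,  # E
    0,  -2,   0,  -1,  -3,  -2,  -2,   6,  -2,  -4,  -4,  -2,  -3,  -3,  -2,   0,  -2,  -2,  -3,  -3,  -1,  # G
   -2,   0,   1,  -1,  -3,   0,   0,  -2,   8,  -3,  -3,  -1,  -2,  -1,  -2,  -1,  -2,  -2,   2,  -3,  -1,  # H
   -1,  -3,  -3,  -3,  -1,  -3,  -3,  -4,  -3,   4,   2,  -3,   1,   0,  -3,  -2,  -1,  -3,  -1,   3,  -1,  # I
   -1,  -2,  -3,  -4,  -1,  -2,  -3,  -4,  -3,   2,   4,  -2,   2,   0,  -3,  -2,  -1,  -2,  -1,   1,  -1,  # L
   -1,   2,   0,  -1,  -3,   1,   1,  -2,  -1,  -3,  -2,   5,  -1,  -3,  -1,   0,  -1,  -3,  -2,  -2,  -1,  # K
   -1,  -1,  -2,  -3,  -1,   0,  -2,  -3,  -2,   1,   2,  -1,   5,   0,  -2,  -1,  -1,  -1,  -1,   1,  -1,  # M
   -2,  -3,  -3,  -3,  -2,  -3,  -3,  -3,  -1,   0,   0,  -3,   0,   6,  -4,  -2,  -2,   1,   3,  -1,  -1,  # F
   -1,  -2,  -2,  -1,  -3,  -1,  -1,  -2,  -2,  -3,  -3,  -1,  -2,  -4,   7,  -1,  -1,  -4,  -3,  -2,  -1,  # P
    1,  -1,   1,   0,  -1,   0,   0,   0,  -1,  -2,  -2,   0,  -1,  -2,  -1,   4,   1,  -3,  -2,  -2,  -1,  # S
    0,  -1,   0,  -1,  -1,  -1,  -1,  -2,  -2,  -1,  -1,  -1,  -1,  -2,  -1,   1,   5,  -2,  -2,   0,  -1,  # T
   -3,  -3,  -4,  -4,  -2,  -2,  -3,  -2,  -2,  -3,  -2,  -3,  -1,   1,  -4,  -3,  -2,  11,   2,  -3,  -1,  # W
   -2,  -2,  -2,  -3,  -2,  -1,  -2,  -3,   2,  -1,  -1,  -2,  -1,   3,  -3,  -2,  -2,   2,   7,  -1,  -1,  # Y
    0,  -3,  -3,  -3,  -1,  -2,  -2,  -3,  -3,   3,   1,  -2,   1,  -1,  -2,  -2,   0,  -3,  -1,   4,  -1,  # V
   -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1   # X
), nrow = 21, byrow = TRUE,
   dimnames = list(c(AA20, "X"), c(AA20, "X")))
storage.mode(BLOSUM62_VALUES) <- "integer"

#' Scoring scheme for pairwise alignment
#'
#' Bundles the substitution matrix and affine gap penalties used by
#' [global_align()], [local_align()] and [run_fragal()]. The defaults
#' reproduce the fragment-scoring setup of the fragmented-alignment method:
#' BLOSUM62 with a deliberately high gap-opening penalty (25 instead of the
#' usual 10) so that gaps are discouraged inside short fragment alignments,
#' and needle-style free end gaps.
#'
#' A gap of length L costs `gap_open + (L - 1) * gap_extend`. Half-integer
#' penalties are handled exactly (scoring is carried out internally in
#' doubled integer units).
#'
#' @param matrix Either the name `"BLOSUM62"` or a symmetric integer
#'   substitution matrix with residue letters as dimnames (must cover the 20
#'   standard amino acids plus `X`).
#' @param gap_open Non-negative gap opening penalty (default 25).
#' @param gap_extend Non-negative gap extension penalty, `<= gap_open`
#'   (default 0.5).
#' @param free_end_gaps If `TRUE` (default), leading and trailing gap runs in
#'   a global alignment cost nothing.
#' @return An object of class `fragal_scheme`.
#' @examples
#' scoring_scheme()
#' scoring_scheme(gap_open = 10, gap_extend = 1, free_end_gaps = FALSE)
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 25, gap_extend = 0.5,
                           free_end_gaps = TRUE) {
  if (is.character(matrix)) {
    name <- match.arg(matrix, "BLOSUM62")
    submat <- BLOSUM62_VALUES
  } else {
    if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
        !identical(rownames(matrix), colnames(matrix)))
      stop("'matrix' must be a named square substitution matrix", call. = FALSE)
    missing <- setdiff(AA_ALPHABET, rownames(matrix))
    if (length(missing))
      stop("substitution matrix lacks rows for: ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (!isTRUE(all.equal(matrix, t(matrix))))
      stop("substitution matrix must be symmetric", call. = FALSE)
    name <- "custom"
    submat <- matrix[AA_ALPHABET, AA_ALPHABET]
    storage.mode(submat) <- "integer"
  }
  if (!is.numeric(gap_open) || !is.numeric(gap_extend) ||
      gap_open < gap_extend || gap_extend < 0)
    stop("need gap_open >= gap_extend >= 0", call. = FALSE)
  structure(
    list(matrix_name = name, submat = submat,
         gap_open = as.numeric(gap_open), gap_extend = as.numeric(gap_extend),
         free_end_gaps = isTRUE(free_end_gaps)),
    class = "fragal_scheme")
}

#' @export
print.fragal_scheme <- function(x, ...) {
  cat("<fragal scoring scheme>\n",
      " matrix:        ", x$matrix_name, "\n",
      " gap open:      ", x$gap_open, "\n",
      " gap extend:    ", x$gap_extend, "\n",
      " free end gaps: ", x$free_end_gaps, "\n", sep = "")
  invisible(x)
}

# Doubled-integer pieces handed to the C++ core.
scheme_units <- function(scheme) {
  list(submat2 = scheme$submat * 2L,
       open2 = as.integer(round(2 * scheme$gap_open)),
       ext2 = as.integer(round(2 * scheme$gap_extend)))
}

# Uppercase, strip whitespace/digits, map ambiguity letters to X, and verify
# the residue alphabet. `what` names the offending record in errors.
normalize_residues <- function(x, what = "sequence") {
  x <- toupper(gsub("[[:space:][:digit:]]", "", x))
  x <- chartr("BZU", "XXX", gsub("\\*", "X", x))
  bad <- regmatches(x, regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x))
  if (length(bad) && nzchar(bad))
    stop(sprintf("invalid residue letter '%s' in %s", bad, what), call. = FALSE)
  x
}

# Residue string -> 0-based integer codes into the substitution matrix.
encode_residues <- function(x, scheme) {
  codes <- match(strsplit(x, "", fixed = TRUE)[[1]], rownames(scheme$submat)) - 1L
  if (anyNA(codes))
    stop("residue with no substitution-matrix row after X-mapping", call. = FALSE)
  codes
}
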