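# Sequence and annotation I/O, and the sliding-window fragmenter.

#' Create a protein sequence object
#'
#' @param id Non-empty identifier token.
#' @param residues Residue string; whitespace and digits are stripped,
#'   lower case is raised, and the ambiguity letters `B`, `Z`, `U` and `*`
#'   are mapped to `X` (substitution matrices carry no stable rows for them).
#' @param description Optional free-text description.
#' @return An object of class `fragal_seq` with fields `id`, `description`,
#'   `residues` and `length`.
#' @examples
#' fragal_seq("q", "MKVLAT")
#' @export
fragal_seq <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("sequence id must be a non-empty string", call. = FALSE)
  residues <- normalize_residues(residues, what = sprintf("record '%s'", id))
  structure(
    list(id = id, description = description, residues = residues,
         length = nchar(residues)),
    class = "fragal_seq")
}

#' @export
print.fragal_seq <- function(x, ...) {
  head <- if (x$length > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<fragal_seq> %s (%d aa)\n  %s\n", x$id, x$length, head))
  invisible(x)
}

as_fragal_seq <- function(x, id = "seq") {
  if (inherits(x, "fragal_seq")) x else fragal_seq(id, x)
}

#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order. Line wrapping, whitespace and digits
#' in the residue lines are tolerated; residues are upper-cased and
#' ambiguity letters are mapped to `X` (see [fragal_seq()]). Any other
#' non-amino-acid letter raises an error naming the letter and the record.
#'
#' @param path Path to a FASTA file.
#' @return A list of [fragal_seq()] objects.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       set.attributes = FALSE, whole.header = TRUE),
    error = function(e) stop("no sequences in ", path, call. = FALSE))
  if (!length(recs)) stop("no sequences in ", path, call. = FALSE)
  out <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    header <- names(recs)[k]
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    out[[k]] <- fragal_seq(id, recs[[k]], description = desc)
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A `fragal_seq` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "fragal_seq")) seqs <- list(seqs)
  seqinr::write.fasta(lapply(seqs, `[[`, "residues"),
                      names = vapply(seqs, function(s) {
                        if (nzchar(s$description)) paste(s$id, s$description) else s$id
                      }, character(1)),
                      file.out = path, as.string = TRUE, nbchar = 60)
  invisible(path)
}

#' Read a feature annotation track
#'
#' Two dialects are accepted, mixed freely within one file:
#' \itemize{
#'   \item Plain whitespace-separated lines `KIND START END LABEL...` with
#'     1-based inclusive coordinates; `#` starts a comment.
#'   \item UniProt flat-file `FT` lines (`FT  REPEAT  1517..1551`, with an
#'     optional following `/note="..."` line supplying the label), restricted
#'     to the single-chain positional kinds REPEAT, MOD_RES, DOMAIN, MOTIF.
#' }
#' All ranges are validated against the sequence length.
#'
#' @param path Path to the annotation file.
#' @param seq The annotated [fragal_seq()] (the target of a run).
#' @return A data frame of class `fragal_features` with columns `kind`,
#'   `start`, `end`, `label`, sorted by `start`, carrying the sequence id in
#'   `attr(, "seq_id")`.
#' @export
read_features <- function(path, seq) {
  seq <- as_fragal_seq(seq)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  kind <- character(); start <- integer(); end <- integer(); label <- character()
  ft_kinds <- c("REPEAT", "MOD_RES", "DOMAIN", "MOTIF")
  last_ft <- 0L
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    if (grepl("^FT\\s", raw)) {
      m <- regmatches(raw, regexec("^FT\\s+([A-Z_]+)\\s+(\\d+)\\.\\.(\\d+)", raw))[[1]]
      if (length(m) == 4L && m[2] %in% ft_kinds) {
        kind <- c(kind, m[2])
        start <- c(start, as.integer(m[3]))
        end <- c(end, as.integer(m[4]))
        label <- c(label, "")
        last_ft <- length(kind)
      } else if (last_ft > 0L && grepl("/note=", raw)) {
        note <- regmatches(raw, regexec("/note=\"([^\"]*)", raw))[[1]]
        if (length(note) == 2L) label[last_ft] <- note[2]
      }
      next
    }
    if (!nzchar(trimws(line))) next
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) < 3L)
      stop("malformed feature line: ", trimws(raw), call. = FALSE)
    s <- suppressWarnings(as.integer(parts[2]))
    e <- suppressWarnings(as.integer(parts[3]))
    if (is.na(s) || is.na(e))
      stop("malformed feature line (non-integer range): ", trimws(raw), call. = FALSE)
    kind <- c(kind, parts[1]); start <- c(start, s); end <- c(end, e)
    label <- c(label, paste(parts[-(1:3)], collapse = " "))
    last_ft <- 0L
  }
  if (length(start)) {
    if (any(end < start))
      stop("malformed feature: end < start", call. = FALSE)
    if (any(start < 1L) || any(end > seq$length))
      stop(sprintf("feature range outside sequence '%s' (1..%d)",
                   seq$id, seq$length), call. = FALSE)
  }
  feats <- data.frame(kind = kind, start = start, end = end, label = label,
                      stringsAsFactors = FALSE)
  feats <- feats[order(feats$start), , drop = FALSE]
  rownames(feats) <- NULL
  structure(feats, seq_id = seq$id, class = c("fragal_features", "data.frame"))
}

#' Cut a sequence into overlapping fragments
#'
#' Fragments of length `fraglen` are taken at starts 0, `step`, 2*`step`, ...
#' while the start lies inside the sequence; trailing fragments shorter than
#' `fraglen` are kept if and only if they reach `min_fragment_length`. The
#' fragment index is `start / step`, so index times `step` recovers the
#' 0-based start offset (index 91 of a 50/10 decomposition covers 0-based
#' positions 910-959, i.e. residues 911-960 in 1-based reporting).
#'
#' @param seq A [fragal_seq()] or residue string.
#' @param fraglen Fragment length X (default 50, matched to the ~30-aa
#'   repeats the method targets).
#' @param step Sliding-window step Y, must be `< fraglen` (default 10).
#' @param min_fragment_length Shortest trailing fragment kept
#'   (default `floor(fraglen / 2)`).
#' @return A data frame with columns `parent_id`, `index`, `start` (0-based),
#'   `length`, `residues`.
#' @examples
#' fragment_sequence(fragal_seq("q", strrep("MKVLATER", 10)), 50, 10)
#' @export
fragment_sequence <- function(seq, fraglen = 50, step = 10,
                              min_fragment_length = floor(fraglen / 2)) {
  seq <- as_fragal_seq(seq)
  if (step >= fraglen) stop("step must be smaller than fraglen", call. = FALSE)
  if (step < 1 || fraglen < 1) stop("fraglen and step must be positive", call. = FALSE)
  if (min_fragment_length > fraglen)
    stop("min_fragment_length cannot exceed fraglen", call. = FALSE)
  starts <- seq.int(0L, length.out = max(0L, ceiling(seq$length / step)), by = step)
  starts <- starts[starts < seq$length]
  len <- pmin(fraglen, seq$length - starts)
  keep <- len >= min_fragment_length
  starts <- starts[keep]; len <- len[keep]
  if (length(starts) == 0)
    return(data.frame(parent_id = character(), index = integer(),
                      start = integer(), length = integer(),
                      residues = character(), stringsAsFactors = FALSE))
  data.frame(
    parent_id = rep(seq$id, length(starts)),
    index = as.integer(starts / step),
    start = as.integer(starts),
    length = as.integer(len),
    residues = substring(seq$residues, starts + 1L, starts + len),
    stringsAsFactors = FALSE)
}
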