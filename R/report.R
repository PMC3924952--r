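# Run configuration, result tables, TSV/HTML rendering and the
# UniProt reproduction driver.

#' Build and validate a run configuration
#'
#' Collects every knob of a fragmented-alignment run. Defaults are the
#' method's default mode: 50-residue fragments sliding in steps of 10,
#' BLOSUM62 with gap open 25 / extend 0.5, 30% similarity threshold.
#'
#' @param query_path,target_path FASTA files; the first record of each is
#'   used.
#' @param fraglen,step,min_fragment_length See [fragment_sequence()].
#' @param gap_open,gap_extend,matrix See [scoring_scheme()].
#' @param min_similarity Percent-similarity threshold in `[0, 100]`.
#' @param sort_mode `"average"` ranks single fragment matches by FRscore;
#'   `"cumulative"` ranks stitched chains by cumulative FRscore.
#' @param annotation_path Optional [read_features()] file for the target.
#' @param filter_mode See [filter_by_annotation()].
#' @param frscore_mode See [frscore()].
#' @param zscore_shuffles Shuffle count for [shuffle_zscore()] runs.
#' @param seed Integer seed for any randomized step.
#' @param out_tsv,out_html Optional output paths.
#' @return A list of class `fragal_config`.
#' @export
fragal_config <- function(query_path, target_path, fraglen = 50, step = 10,
                          gap_open = 25, gap_extend = 0.5,
                          matrix = "BLOSUM62", min_similarity = 30,
                          min_fragment_length = floor(fraglen / 2),
                          sort_mode = c("average", "cumulative"),
                          annotation_path = NULL,
                          filter_mode = c("all", "annotated", "novel"),
                          frscore_mode = c("inclusive", "exclusive"),
                          zscore_shuffles = 200, seed = 1,
                          out_tsv = NULL, out_html = NULL) {
  sort_mode <- match.arg(sort_mode)
  filter_mode <- match.arg(filter_mode)
  frscore_mode <- match.arg(frscore_mode)
  if (step >= fraglen) stop("step must be smaller than fraglen", call. = FALSE)
  if (min_similarity < 0 || min_similarity > 100)
    stop("min_similarity must lie in [0, 100]", call. = FALSE)
  structure(
    list(query_path = query_path, target_path = target_path,
         fraglen = fraglen, step = step, gap_open = gap_open,
         gap_extend = gap_extend, matrix = matrix,
         min_similarity = min_similarity,
         min_fragment_length = min_fragment_length, sort_mode = sort_mode,
         annotation_path = annotation_path, filter_mode = filter_mode,
         frscore_mode = frscore_mode, zscore_shuffles = zscore_shuffles,
         seed = seed, out_tsv = out_tsv, out_html = out_html),
    class = "fragal_config")
}

#' Execute a configured run and write result files
#'
#' Reads the sequences, runs [run_fragal()], applies the annotation filter,
#' ranks according to `sort_mode` and writes the results TSV (and optional
#' HTML report). Ranks are assigned before annotation filtering, so a
#' filtered table keeps its original (possibly non-contiguous) ranks. Every
#' configuration value is logged, giving full provenance; identical inputs,
#' configuration and seed produce byte-identical outputs.
#'
#' @param config A [fragal_config()].
#' @return Invisibly, a list with `records`, `chains`, `table` and `config`.
#' @export
cli_run <- function(config) {
  stopifnot(inherits(config, "fragal_config"))
  for (nm in names(config)) {
    val <- config[[nm]]
    message(sprintf("config: %s = %s", nm,
                    if (is.null(val)) "NULL" else paste(val, collapse = ",")))
  }
  query <- read_fasta(config$query_path)[[1]]
  target <- read_fasta(config$target_path)[[1]]
  message(sprintf("query: %s (%d aa); target: %s (%d aa)",
                  query$id, query$length, target$id, target$length))
  scheme <- scoring_scheme(config$matrix, config$gap_open, config$gap_extend)
  records <- run_fragal(query, target, fraglen = config$fraglen,
                        step = config$step, threshold = config$min_similarity,
                        scheme = scheme,
                        min_fragment_length = config$min_fragment_length,
                        frscore_mode = config$frscore_mode)
  message(sprintf("fragment pairs evaluated: %d x %d; matches kept: %d",
                  attr(records, "n_a_fragments"),
                  attr(records, "n_b_fragments"), nrow(records)))
  track <- if (!is.null(config$annotation_path))
    read_features(config$annotation_path, target) else NULL
  chains <- stitch_chains(records)
  tbl <- results_table(records, chains, track,
                       sort_mode = config$sort_mode,
                       filter_mode = config$filter_mode)
  if (!is.null(config$out_tsv)) {
    write_results_tsv(tbl, config$out_tsv)
    message("results TSV: ", config$out_tsv)
  }
  if (!is.null(config$out_html)) {
    writeLines(render_html(list(records = records, chains = chains,
                                track = track), config), config$out_html)
    message("HTML report: ", config$out_html)
  }
  invisible(list(records = records, chains = chains, table = tbl,
                 config = config))
}

#' Assemble the ranked results table
#'
#' @param records A `fragal_matches` data frame.
#' @param chains Chains from [stitch_chains()] (computed when `NULL`).
#' @param track Optional annotation track for the `annotated_flag` column
#'   and `filter_mode`.
#' @param sort_mode `"average"` (FRscore order) or `"cumulative"` (chain
#'   order, members grouped).
#' @param filter_mode See [filter_by_annotation()]; ranks are assigned
#'   before filtering.
#' @return Data frame with columns `rank`, `a_index`, `a_start`, `a_end`,
#'   `b_index`, `b_start`, `b_end`, `frscore`, `pct_identity`,
#'   `pct_similarity`, `annotated_flag`, `chain_id` (1-based inclusive
#'   coordinates).
#' @export
results_table <- function(records, chains = NULL, track = NULL,
                          sort_mode = c("average", "cumulative"),
                          filter_mode = c("all", "annotated", "novel")) {
  sort_mode <- match.arg(sort_mode)
  filter_mode <- match.arg(filter_mode)
  if (is.null(chains)) chains <- stitch_chains(records)
  key <- function(d) paste(d$a_index, d$b_index)
  chain_id <- rep(NA_integer_, nrow(records))
  for (ci in seq_along(chains))
    chain_id[match(key(chains[[ci]]$members), key(records))] <- ci
  tbl <- data.frame(
    rank = seq_len(nrow(records)),
    records[, c("a_index", "a_start", "a_end", "b_index", "b_start", "b_end",
                "frscore", "pct_identity", "pct_similarity")],
    annotated_flag = annotated_flags(records, track),
    chain_id = chain_id,
    stringsAsFactors = FALSE)
  if (sort_mode == "cumulative" && nrow(tbl) > 0) {
    pos_in_chain <- stats::ave(seq_len(nrow(tbl)), tbl$chain_id,
                               FUN = seq_along)
    tbl <- tbl[order(tbl$chain_id, pos_in_chain), , drop = FALSE]
  }
  if (filter_mode != "all" && !is.null(track)) {
    keep <- if (filter_mode == "annotated") tbl$annotated_flag
            else !tbl$annotated_flag
    tbl <- tbl[keep, , drop = FALSE]
  }
  rownames(tbl) <- NULL
  tbl
}

#' Write a results table as TSV
#'
#' FRscore and percentage columns are printed with one decimal place.
#'
#' @param tbl Table from [results_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(tbl, path) {
  out <- tbl
  for (col in c("frscore", "pct_identity", "pct_similarity"))
    if (col %in% names(out)) out[[col]] <- sprintf("%.1f", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

html_table <- function(tbl) {
  if (nrow(tbl) == 0) return("<p>0 matches</p>")
  esc <- function(x) gsub(">", "&gt;", gsub("<", "&lt;", gsub("&", "&amp;", x)))
  num <- vapply(tbl, is.numeric, logical(1)) &
    names(tbl) %in% c("frscore", "pct_identity", "pct_similarity",
                      "cumulative_score", "average_score")
  cells <- tbl
  for (j in which(num)) cells[[j]] <- sprintf("%.1f", tbl[[j]])
  rows <- apply(cells, 1, function(r)
    paste0("<tr><td>", paste(esc(trimws(r)), collapse = "</td><td>"),
           "</td></tr>"))
  paste0("<table border='1'><tr><th>",
         paste(esc(names(tbl)), collapse = "</th><th>"), "</th></tr>",
         paste(rows, collapse = ""), "</table>")
}

#' Render a self-contained HTML report
#'
#' The report shows the ranked matches under both sorting criteria (best
#' average FRscore and best cumulative chain score) together with the full
#' parameter provenance. Numbers are printed with the same one-decimal
#' precision as the TSV output.
#'
#' @param results List with `records` (and optionally `chains`, `track`),
#'   e.g. the return value of [cli_run()].
#' @param config The [fragal_config()] of the run.
#' @return A single character scalar of HTML.
#' @export
render_html <- function(results, config) {
  records <- results$records
  chains <- results$chains %||% stitch_chains(records)
  track <- results$track
  avg_tbl <- results_table(records, chains, track, sort_mode = "average")
  cum_summary <- if (length(chains)) data.frame(
    chain_id = seq_along(chains),
    members = vapply(chains, function(ch)
      paste(sprintf("A%d-B%d", ch$members$a_index, ch$members$b_index),
            collapse = ","), character(1)),
    cumulative_score = vapply(chains, `[[`, numeric(1), "cumulative_score"),
    average_score = vapply(chains, `[[`, numeric(1), "average_score"),
    stringsAsFactors = FALSE) else data.frame()
  params <- vapply(names(unclass(config)), function(nm) {
    v <- config[[nm]]
    sprintf("<li>%s = %s</li>", nm,
            if (is.null(v)) "NULL" else paste(v, collapse = ","))
  }, character(1))
  paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>fragmented alignment report</title></head><body>",
    "<h1>Fragmented alignment report</h1>",
    sprintf("<p>%d matches, %d chains</p>", nrow(records), length(chains)),
    "<h2>Best average FRscore</h2>", html_table(avg_tbl),
    "<h2>Best cumulative chain score</h2>", html_table(cum_summary),
    "<h2>Parameters</h2><ul>", paste(params, collapse = ""), "</ul>",
    "</body></html>")
}

#' Map alignment columns to sequence positions
#'
#' @param al A `fragal_alignment`.
#' @param a_offset,b_offset 0-based offsets of the aligned strings inside
#'   their parent sequences (e.g. the fragment start), added to the
#'   returned positions.
#' @return Data frame with one row per alignment column: `a_pos`, `b_pos`
#'   (1-based positions in the parents, `NA` at gaps).
#' @export
alignment_position_map <- function(al, a_offset = 0, b_offset = 0) {
  ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
  local_a <- if (identical(al$type, "local")) al$a_begin - 1L else 0L
  local_b <- if (identical(al$type, "local")) al$b_begin - 1L else 0L
  a_pos <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-") + a_offset + local_a)
  b_pos <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-") + b_offset + local_b)
  data.frame(a_pos = a_pos, b_pos = b_pos)
}

#' Default cache directory for downloaded UniProt sequences
#'
#' @return The per-user cache directory used by [fragal_reproduction()] and
#'   `scripts/fetch_uniprot.R`.
#' @export
uniprot_cache_dir <- function() {
  tools::R_user_dir("fragal", which = "cache")
}

#' Recompute the published BRCA2 / HAT case studies
#'
#' Runs the full method on the four UniProt sequences of the original case
#' studies (dmBRCA2 Q9W157 vs hBRCA2 P51587; Utp6 Q02354 vs human Q9NYH9)
#' and returns the headline quantities: the FRscores of the A67-B152,
#' A75-B152 and A61-B151 fragment matches, the query position aligned with
#' the phosphorylated T3387 of hBRCA2, the query start of the newly
#' identified BRC repeat and HAT segment, and the shuffle z-score of the
#' A91-B337 match. The sequences are not shipped with the package; download
#' them once with `scripts/fetch_uniprot.R` into `cache_dir`.
#'
#' @param cache_dir Directory containing `Q9W157.fasta`, `P51587.fasta`,
#'   `Q02354.fasta`, `Q9NYH9.fasta`; defaults to [uniprot_cache_dir()].
#' @param n_shuffles,seed Passed to [shuffle_zscore()].
#' @return Named list of quantities.
#' @export
fragal_reproduction <- function(cache_dir = uniprot_cache_dir(),
                                n_shuffles = 200, seed = 1) {
  acc <- c("Q9W157", "P51587", "Q02354", "Q9NYH9")
  paths <- file.path(cache_dir, paste0(acc, ".fasta"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing cached UniProt sequences (run scripts/fetch_uniprot.R): ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  seqs <- lapply(paths, function(p) read_fasta(p)[[1]])
  names(seqs) <- acc
  dm <- seqs$Q9W157; hs <- seqs$P51587
  frag_of <- function(seq, idx, fraglen = 50, step = 10)
    substr(seq$residues, idx * step + 1, min(idx * step + fraglen, seq$length))
  matches <- run_fragal(dm, hs)
  fr_of <- function(ai, bi) {
    hit <- matches$frscore[matches$a_index == ai & matches$b_index == bi]
    if (length(hit)) hit[1] else NA_real_
  }
  # phosphorylation-site match: T3387 of hBRCA2 inside fragment B337
  a91 <- frag_of(dm, 91); b337 <- frag_of(hs, 337)
  al <- global_align(a91, b337)
  cmap <- alignment_position_map(al, a_offset = 910, b_offset = 3370)
  t_query <- cmap$a_pos[match(3387, cmap$b_pos)]
  z <- shuffle_zscore(a91, b337, n_shuffles = n_shuffles, seed = seed)
  # new BRC repeat: local alignment of fragment A61 against the BRC4 repeat
  brc4 <- substr(hs$residues, 1517, 1551)
  brc_al <- local_align(frag_of(dm, 61), brc4)
  brc_start <- 610 + brc_al$a_begin
  # new HAT segment in Utp6, against the annotated human HAT region
  utp6 <- seqs$Q02354; hsnrap <- seqs$Q9NYH9
  hat <- run_fragal(utp6, hsnrap)
  hat_feats <- data.frame(start = c(121, 156, 304, 488, 524),
                          end = c(153, 188, 335, 520, 557))
  top_hat <- hat[annotated_flags(hat, structure(
    cbind(kind = "REPEAT", hat_feats, label = "HAT"),
    seq_id = attr(hat, "target_id"),
    class = c("fragal_features", "data.frame"))), , drop = FALSE][1, ]
  hat_al <- local_align(frag_of(utp6, top_hat$a_index),
                        substr(hsnrap$residues, top_hat$b_start, top_hat$b_end))
  hat_start <- top_hat$a_start + hat_al$a_begin - 1
  list(frscore_a67_b152 = fr_of(67, 152),
       frscore_a75_b152 = fr_of(75, 152),
       frscore_a61_b151 = fr_of(61, 151),
       t3387_query_position = t_query,
       brc_repeat_query_start = brc_start,
       hat_segment_query_start = hat_start,
       zscore_a91_b337 = z$zscore)
}
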