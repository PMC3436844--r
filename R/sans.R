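#' Search parameters
#'
#' @param H number of hits to report per query.
#' @param W window half-width in suffix ranks per side; defaults to `H`
#'   so that at least `H` best-matching suffixes fall inside the window
#'   whether they are lexically smaller or greater than the query suffix.
#' @param T optional score threshold; when set, all hits with score `>= T`
#'   are reported instead of the top `H`.
#' @param memory_limit bytes of database text indexed per section; the
#'   database is searched in contiguous sections so only one section's index
#'   is in memory at a time.
#' @return An object of class `search_params`.
#' @export
search_params <- function(H = 100L, W = NULL, T = NULL,
                          memory_limit = Inf) {
  if (is.null(W)) W <- H
  stopifnot(W >= 1L, H >= 1L)
  structure(list(W = as.integer(W), H = as.integer(H), T = T,
                 memory_limit = memory_limit),
            class = "search_params")
}

#' Mask low-complexity query suffixes
#'
#' Short tandem repeats give rise to artificially high neighborhood scores. A
#' query suffix is masked iff its characters at positions (1,2,3) are
#' identical or its characters at positions (1,3,5) are identical, counting
#' 1-based from the suffix start. For suffixes shorter than a pattern, only
#' the pattern positions available within the suffix's own protein are
#' compared, so a suffix is masked when those available positions satisfy
#' the pattern; in particular suffixes of one or two residues are always
#' masked (too short to be informative), as are sentinel positions. Masked
#' suffixes contribute to neither the SANS nor the KSEARCH score.
#'
#' @param qdb query [sequence_db()].
#' @return Logical vector over 0-based text offsets (`mask[s+1]` is the flag
#'   for offset `s`); `TRUE` = masked.
#' @export
mask_query_suffixes <- function(qdb) {
  n <- nchar(qdb$txt)
  ch <- strsplit(qdb$txt, "", fixed = TRUE)[[1]]
  lens <- diff(qdb$start)                       # protein length + sentinel
  pe <- rep.int(qdb$start[-1] - 1L, lens)       # 0-based sentinel offset
  s <- 0:(n - 1L)
  at <- function(d) {                           # character at offset s + d
    i <- s + d + 1L
    i[i > n] <- NA_integer_
    ch[i]
  }
  c1 <- ch
  len <- pe - s                            # residues from the suffix start
  eq2 <- c1 == at(1L); eq3 <- c1 == at(2L); eq5 <- c1 == at(4L)
  eq2[is.na(eq2)] <- FALSE; eq3[is.na(eq3)] <- FALSE; eq5[is.na(eq5)] <- FALSE
  # pattern (1,2,3): all available positions equal (vacuous for len <= 1)
  rule123 <- (len >= 3L & eq2 & eq3) | (len == 2L & eq2) | (len == 1L)
  # pattern (1,3,5): positions 3 and 5 exist only for len >= 3 and >= 5
  rule135 <- (len >= 5L & eq3 & eq5) | (len >= 3L & len < 5L & eq3) |
    (len < 3L & len >= 1L)
  mask <- len == 0L | rule123 | rule135    # len == 0: sentinel position
  mask
}

#' SANS neighborhood scores of one query protein
#'
#' For each unmasked suffix of the query protein with insertion rank `l`
#' (from the merged suffix order), the window covers the 2W database ranks
#' `l-W+1, ..., l, l+1, ..., l+W`, clipped to the valid rank range. Every
#' window rank contributes 1 to the database protein owning that suffix
#' (binary identity function), and contributions are accumulated over all
#' suffixes of the query protein.
#'
#' @param db_index database [suffix_index()].
#' @param mapping [map_query_suffixes()] result for the query set.
#' @param qdb query [sequence_db()].
#' @param qprot query protein index (1-based).
#' @param params [search_params()].
#' @param mask optional precomputed [mask_query_suffixes()] vector.
#' @return Integer vector of scores, one per database protein (as labelled
#'   by `db_index$sap`).
#' @export
sans_scores <- function(db_index, mapping, qdb, qprot, params = search_params(),
                        mask = NULL) {
  if (qprot < 1L || qprot > qdb$n_proteins) stop("query protein out of range")
  if (is.null(mask)) mask <- mask_query_suffixes(qdb)
  n_db_prot <- max(db_index$sap)
  offs <- seq.int(qdb$start[qprot], qdb$start[qprot + 1L] - 2L)
  offs <- offs[!mask[offs + 1L]]
  if (length(offs) == 0L) return(integer(n_db_prot))
  W <- params$W
  l <- mapping$isa_mapped[offs + 1L]
  idx <- rep(l, each = 2L * W) + seq.int(-W + 1L, W)
  idx <- idx[idx >= 0L & idx < db_index$n]
  tabulate(db_index$sap[idx + 1L], nbins = n_db_prot)
}

#' Select reported hits from a score vector
#'
#' Top-`H` by score with ties broken by ascending database protein index, or
#' in threshold mode all proteins with score `>= T`. Zero-score proteins are
#' never reported.
#'
#' @param scores numeric vector of per-database-protein scores.
#' @param params [search_params()].
#' @return data.frame with columns `target` (1-based protein index),
#'   `score` and `rank`.
#' @export
select_hits <- function(scores, params = search_params()) {
  keep <- which(scores > 0)
  if (!is.null(params$T)) keep <- keep[scores[keep] >= params$T]
  ord <- keep[order(-scores[keep], keep)]
  if (is.null(params$T)) ord <- head(ord, params$H)
  data.frame(target = ord,
             score = scores[ord],
             rank = seq_along(ord))
}

# split database proteins into contiguous sections whose text (residues +
# sentinels) fits the memory limit
section_boundaries <- function(db, memory_limit) {
  sizes <- diff(db$start)
  if (any(sizes > memory_limit))
    stop("memory limit smaller than the largest single protein")
  sec <- integer(db$n_proteins)
  cur <- 1L; used <- 0
  for (i in seq_len(db$n_proteins)) {
    if (used + sizes[i] > memory_limit && used > 0) { cur <- cur + 1L; used <- 0 }
    sec[i] <- cur
    used <- used + sizes[i]
  }
  sec
}

subset_db <- function(db, idx) {
  seqs <- vapply(idx, function(i) db_sequence(db, i), character(1))
  sequence_db(seqs, db$ids[idx])
}

#' Search a database with the SANS word filter
#'
#' Runs the full pipeline: index the database (in sections if a memory limit
#' is set), merge the query suffixes into each section's suffix order,
#' accumulate windowed neighborhood scores per query protein, and report the
#' top hits. Per-protein scores from all sections are summed before hit
#' selection. Windows are computed per section, so sectioning perturbs
#' results through windows at section boundaries; because every query
#' suffix contributes 2W window hits in every section, a much smaller
#' trailing section concentrates background score on its few proteins —
#' choose `memory_limit` so sections are of comparable size.
#'
#' @param db database [sequence_db()] (or path to a FASTA file).
#' @param qdb query [sequence_db()] (or path to a FASTA file).
#' @param params [search_params()].
#' @return A `hit_table`: data.frame with columns `query_id`, `target_id`,
#'   `rank` (1-based) and `score`, hits of each query sorted by descending
#'   score. Attribute `mode` is `"sans"`.
#' @export
sans_search <- function(db, qdb, params = search_params()) {
  if (is.character(db)) db <- load_fasta(db)
  if (is.character(qdb)) qdb <- load_fasta(qdb)
  sec <- section_boundaries(db, params$memory_limit)
  q_sa <- build_suffix_array(qdb$txt)
  mask <- mask_query_suffixes(qdb)
  scores <- matrix(0L, nrow = db$n_proteins, ncol = qdb$n_proteins)
  for (s in unique(sec)) {
    rows <- which(sec == s)
    sdb <- if (length(unique(sec)) == 1L) db else subset_db(db, rows)
    idx <- suffix_index(sdb)
    mapping <- map_query_suffixes(idx, sdb, qdb, q_sa = q_sa)
    for (q in seq_len(qdb$n_proteins)) {
      sc <- sans_scores(idx, mapping, qdb, q, params, mask = mask)
      scores[rows[seq_along(sc)], q] <- scores[rows[seq_along(sc)], q] + sc
    }
  }
  hits_from_scores(scores, db, qdb, params, mode = "sans")
}

# assemble the per-query hit tables from a db x query score matrix
hits_from_scores <- function(scores, db, qdb, params, mode) {
  out <- vector("list", qdb$n_proteins)
  for (q in seq_len(qdb$n_proteins)) {
    h <- select_hits(scores[, q], params)
    if (nrow(h) > 0)
      out[[q]] <- data.frame(query_id = qdb$ids[q],
                             target_id = db$ids[h$target],
                             rank = h$rank,
                             score = h$score)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(query_id = character(0), target_id = character(0),
                      rank = integer(0), score = numeric(0))
  rownames(res) <- NULL
  attr(res, "mode") <- mode
  class(res) <- c("hit_table", "data.frame")
  res
}

#' Write / read a hit table as TSV
#'
#' Tab-separated with a header line starting with `#`; the score column is
#' named after the search mode (`sans_score`, `ksearch_score`), plus
#' `greedy_score` when the table has been rescored.
#'
#' @param hits a `hit_table`.
#' @param path output file.
#' @return `write_hits` returns `path` invisibly; `read_hits` a `hit_table`.
#' @export
write_hits <- function(hits, path) {
  mode <- attr(hits, "mode")
  if (is.null(mode)) mode <- "sans"
  df <- as.data.frame(hits)
  names(df)[names(df) == "score"] <- paste0(sub("_greedy$", "", mode), "_score")
  con <- file(path, "w")
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  df <- read.table(path, sep = "\t", skip = 1L, col.names = cols,
                   colClasses = NA, stringsAsFactors = FALSE)
  score_col <- grep("^(sans|ksearch)_score$", cols, value = TRUE)
  mode <- sub("_score$", "", score_col[1])
  names(df)[names(df) == score_col[1]] <- "score"
  attr(df, "mode") <- mode
  class(df) <- c("hit_table", "data.frame")
  df
}
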