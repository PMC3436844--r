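#' Read an NCBI-format substitution matrix
#'
#' Parses the plain-text layout used by NCBI matrix files (`#` comment lines,
#' a header row of residue letters, one labelled row per residue).
#'
#' @param path matrix file.
#' @return Integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  mat <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(header))))
  rownames(mat) <- vapply(rows, `[`, character(1), 1L)
  colnames(mat) <- header
  mat
}

blosum_cache <- new.env(parent = emptyenv())

#' The bundled BLOSUM62 substitution matrix
#'
#' @return Integer matrix in half-bit units with rows/columns for the 20
#'   standard residues plus B, Z, X and `*`.
#' @export
blosum62 <- function() {
  if (is.null(blosum_cache$b62)) {
    blosum_cache$b62 <- read_score_matrix(
      system.file("extdata", "BLOSUM62.txt", package = "sansearch"))
  }
  blosum_cache$b62
}

# residue string -> row indices into the scoring matrix (unknowns -> X)
residue_indices <- function(seq, mat) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  i <- match(ch, rownames(mat))
  i[is.na(i)] <- match("X", rownames(mat))
  i
}

#' Two-hit alignment seeds
#'
#' Finds diagonals carrying two exact, non-overlapping identical 3-mer
#' matches whose start-to-start distance is at most `max_dist` residues.
#' Coordinates are 0-based; `diag = q_start - s_start`.
#'
#' @param q,s residue strings (length >= 3).
#' @param max_dist maximum start-to-start distance between the two 3-mer
#'   hits (40 by default).
#' @return data.frame with columns `diag`, `q1`, `q2` (0-based query starts
#'   of the two 3-mer hits, `q1 < q2`), ordered by `q1`.
#' @export
find_two_hit_seeds <- function(q, s, max_dist = 40L) {
  Lq <- nchar(q); Ls <- nchar(s)
  empty <- data.frame(diag = integer(0), q1 = integer(0), q2 = integer(0))
  if (Lq < 3L || Ls < 3L) return(empty)
  qk <- substring(q, 1:(Lq - 2L), 3:Lq)
  sk <- substring(s, 1:(Ls - 2L), 3:Ls)
  spos <- split(0:(Ls - 3L), sk)
  qhit <- spos[qk]                       # per query position: matching s starts
  nh <- lengths(qhit)
  if (sum(nh) == 0L) return(empty)
  qi <- rep.int(0:(Lq - 3L), nh)
  si <- unlist(qhit, use.names = FALSE)
  d <- qi - si
  ord <- order(d, qi)
  d <- d[ord]; qi <- qi[ord]
  # pair every hit with the first later hit on the same diagonal that does
  # not overlap it (start distance >= 3); overlapping hits act as one hit
  out <- lapply(split(qi, d), function(p) {
    j <- findInterval(p + 2L, p) + 1L     # first index with p[j] >= p[i] + 3
    i <- which(j <= length(p))
    i <- i[p[j[i]] - p[i] <= max_dist]
    if (length(i) == 0L) return(NULL)
    data.frame(q1 = p[i], q2 = p[j[i]])
  })
  diags <- as.integer(names(out))
  keep <- !vapply(out, is.null, logical(1))
  if (!any(keep)) return(empty)
  out <- do.call(rbind, Map(function(df, dg) cbind(diag = dg, df),
                            out[keep], diags[keep]))
  out <- out[order(out$q1, out$diag), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ungapped x-drop extension of a seed into an HSP
#'
#' Extends left and right along the seed's diagonal; extension in each
#' direction stops once the running score falls more than `xdrop` below its
#' running maximum, and the segment is trimmed to the maximal-scoring extent.
#'
#' @param q,s residue strings.
#' @param seed one-row data.frame (or list) with `diag`, `q1`, `q2` as
#'   produced by [find_two_hit_seeds()].
#' @param matrix substitution matrix ([blosum62()] by default).
#' @param xdrop drop-off in raw score units.
#' @return An `hsp`: list with 0-based half-open `q_start`, `q_end`,
#'   `s_start`, `s_end`, `diag` and `score`.
#' @export
extend_hsp <- function(q, s, seed, matrix = blosum62(), xdrop = 20L) {
  d <- seed$diag
  qi <- residue_indices(q, matrix)
  si <- residue_indices(s, matrix)
  lo <- max(0L, d)                              # 0-based first aligned q pos
  hi <- min(nchar(q), nchar(s) + d) - 1L        # 0-based last aligned q pos
  v <- matrix[cbind(qi[(lo:hi) + 1L], si[(lo:hi) - d + 1L])]
  a <- seed$q1 - lo + 1L                        # seed span, 1-based into v
  b <- seed$q2 + 2L - lo + 1L
  scanned <- 0L
  ext <- function(w) {                          # x-drop best-prefix extension
    if (length(w) == 0L) return(0L)
    cs <- cumsum(w)
    peak <- cummax(cs)
    stop_at <- which(peak - cs > xdrop)[1]
    lim <- if (is.na(stop_at)) length(cs) else stop_at - 1L
    scanned <<- scanned + (if (is.na(stop_at)) length(cs) else stop_at)
    if (lim < 1L) return(0L)
    best <- which.max(cs[seq_len(lim)])
    if (cs[best] > 0) best else 0L
  }
  b <- b + ext(if (b < length(v)) v[(b + 1L):length(v)] else numeric(0))
  a <- a - ext(if (a > 1L) rev(v[1:(a - 1L)]) else numeric(0))
  structure(list(q_start = lo + a - 1L, q_end = lo + b,
                 s_start = lo + a - 1L - d, s_end = lo + b - d,
                 diag = d, score = sum(v[a:b]), scanned = scanned),
            class = "hsp")
}

hsp_before <- function(h, g) h$q_end <= g$q_start && h$s_end <= g$s_start

#' Chain HSPs into a sequential (colinear) alignment
#'
#' HSPs are considered in descending score order; an HSP is kept iff it is
#' strictly before or strictly after every already-selected HSP in both the
#' query and subject coordinates. No gap penalties are applied: the total is
#' the plain sum of member scores.
#'
#' @param hsps list of `hsp` objects from one sequence pair.
#' @return A `greedy_alignment`: list with `hsps` (selected, in query order)
#'   and `total_score`.
#' @export
chain_hsps <- function(hsps) {
  if (length(hsps) == 0L)
    return(structure(list(hsps = list(), total_score = 0),
                     class = "greedy_alignment"))
  sc <- vapply(hsps, `[[`, numeric(1), "score")
  qs <- vapply(hsps, `[[`, numeric(1), "q_start")
  sel <- list()
  for (i in order(-sc, qs)) {
    h <- hsps[[i]]
    ok <- all(vapply(sel, function(g) hsp_before(h, g) || hsp_before(g, h),
                     logical(1)))
    if (ok) sel[[length(sel) + 1L]] <- h
  }
  sel <- sel[order(vapply(sel, `[[`, numeric(1), "q_start"))]
  structure(list(hsps = sel,
                 total_score = sum(vapply(sel, `[[`, numeric(1), "score"))),
            class = "greedy_alignment")
}

#' Greedy approximate alignment of one sequence pair
#'
#' Scans the query from beginning to end for two-hit seeds; each accepted
#' seed is extended without gaps into an HSP, after which the scan jumps to
#' the end of that HSP (seeds already inside an HSP are not tested). HSPs
#' with non-positive score are discarded, and the survivors are chained
#' greedily into a colinear alignment.
#'
#' @inheritParams extend_hsp
#' @param max_dist two-hit distance bound (see [find_two_hit_seeds()]).
#' @return A `greedy_alignment` (see [chain_hsps()]). The number of
#'   extension steps performed is recorded in attribute `steps`.
#' @export
greedy_align_pair <- function(q, s, matrix = blosum62(), xdrop = 20L,
                              max_dist = 40L) {
  seeds <- find_two_hit_seeds(q, s, max_dist = max_dist)
  hsps <- list()
  cur_end <- 0L   # query scan position: 0-based end of the last HSP
  steps <- 0L
  if (nrow(seeds) > 0L) for (r in seq_len(nrow(seeds))) {
    seed <- seeds[r, ]
    if (seed$q1 < cur_end) next
    h <- extend_hsp(q, s, seed, matrix = matrix, xdrop = xdrop)
    steps <- steps + h$scanned + (seed$q2 - seed$q1 + 3L)
    if (h$score > 0) {
      hsps[[length(hsps) + 1L]] <- h
      cur_end <- h$q_end
    }
  }
  out <- chain_hsps(hsps)
  attr(out, "steps") <- steps
  out
}

#' Rescore a hit table by greedy alignment
#'
#' Computes the greedy alignment total score for every (query, target) pair
#' in the table, re-sorts each query's hits by alignment score (descending),
#' breaking ties by the original filter score and then by database order,
#' and keeps the top `keep` hits. Pairs with no seeds score 0.
#'
#' @param hits a `hit_table` from [sans_search()] or [ksearch_search()].
#' @param db,qdb the databases the hits refer to.
#' @param keep hits to keep per query after reranking.
#' @param matrix,xdrop,max_dist see [greedy_align_pair()].
#' @return A `hit_table` with an additional `greedy_score` column and
#'   recomputed ranks.
#' @export
rescore_hits <- function(hits, db, qdb, keep = 1000L, matrix = blosum62(),
                         xdrop = 20L, max_dist = 40L) {
  mode <- attr(hits, "mode")
  if (nrow(hits) == 0L || keep == 0L) {
    out <- hits[integer(0), ]
    out$greedy_score <- numeric(0)
  } else {
    qpos <- match(hits$query_id, qdb$ids)
    tpos <- match(hits$target_id, db$ids)
    gs <- numeric(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      gs[i] <- greedy_align_pair(db_sequence(qdb, qpos[i]),
                                 db_sequence(db, tpos[i]),
                                 matrix = matrix, xdrop = xdrop,
                                 max_dist = max_dist)$total_score
    }
    hits$greedy_score <- gs
    parts <- lapply(split(seq_len(nrow(hits)), hits$query_id), function(ii) {
      ii <- ii[order(-hits$greedy_score[ii], -hits$score[ii], tpos[ii])]
      ii <- head(ii, keep)
      part <- hits[ii, ]
      part$rank <- seq_along(ii)
      part
    })
    out <- do.call(rbind, parts[unique(hits$query_id)])
    rownames(out) <- NULL
  }
  attr(out, "mode") <- mode
  class(out) <- c("hit_table", "data.frame")
  out
}
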