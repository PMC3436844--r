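# Independent brute-force oracles used across the suite. All string ordering
# uses radix (byte / C-locale) comparisons so results do not depend on the
# session locale; the sentinel '$' (0x24) sorts below every residue letter.

all_suffixes <- function(txt) {
  n <- nchar(txt)
  substring(txt, 1:n, n)
}

# naive suffix array: sort all suffixes, return 0-based offsets
oracle_sa <- function(txt) {
  order(all_suffixes(txt), method = "radix") - 1L
}

# per-suffix mapping oracle: for each query offset, the largest 0-based
# database rank whose suffix is <= the query suffix (-1 if none).
# A stable radix sort of database suffixes followed by query suffixes puts
# every query suffix immediately after any equal database suffix.
oracle_map <- function(db_txt, q_txt) {
  dsuf <- all_suffixes(db_txt)
  qsuf <- all_suffixes(q_txt)
  nd <- length(dsuf)
  ord <- order(c(dsuf, qsuf), method = "radix")
  is_db <- ord <= nd
  n_db_before <- cumsum(is_db)
  mapped <- integer(length(qsuf))
  mapped[ord[!is_db] - nd] <- n_db_before[!is_db] - 1L
  mapped
}

# literal-pattern masking oracle for a single suffix: chars within the
# protein only, 1-based pattern positions from the suffix start; pattern
# positions beyond the suffix are vacuously satisfied
oracle_masked <- function(suffix_in_protein) {
  ch <- strsplit(suffix_in_protein, "", fixed = TRUE)[[1]]
  pat <- function(pos) {
    pos <- pos[pos <= length(ch)]
    length(unique(ch[pos])) <= 1L
  }
  pat(c(1, 2, 3)) || pat(c(1, 3, 5))
}

# brute-force SANS score oracle: sort all database suffixes, binary-search
# each unmasked query suffix, count window labels
oracle_sans_scores <- function(db, qdb, qprot, W) {
  sa0 <- oracle_sa(db$txt)
  sap <- protein_of_position(db, sa0)
  mapped <- oracle_map(db$txt, qdb$txt)
  mask <- vapply(0:(nchar(qdb$txt) - 1L), function(s) {
    p <- findInterval(s, qdb$start)
    sent <- qdb$start[p + 1L] - 1L
    if (s == sent) return(TRUE)
    oracle_masked(substr(qdb$txt, s + 1L, sent))
  }, logical(1))
  offs <- seq.int(qdb$start[qprot], qdb$start[qprot + 1L] - 2L)
  offs <- offs[!mask[offs + 1L]]
  scores <- integer(db$n_proteins)
  n <- nchar(db$txt)
  for (s in offs) {
    l <- mapped[s + 1L]
    win <- (l - W + 1L):(l + W)
    win <- win[win >= 0L & win < n]
    for (j in win) scores[sap[j + 1L]] <- scores[sap[j + 1L]] + 1L
  }
  scores
}

# dense k-mer dot product over the full 20^k space (k <= 3)
oracle_kmer_dot <- function(a, b, k) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  enc <- function(seq) {
    L <- nchar(seq)
    if (L < k) return(integer(20^k))
    km <- substring(seq, 1:(L - k + 1L), k:L)
    v <- integer(20^k)
    for (w in km) {
      d <- match(strsplit(w, "")[[1]], aa) - 1L
      i <- sum(d * 20^((k - 1):0)) + 1L
      v[i] <- v[i] + 1L
    }
    v
  }
  sum(enc(a) * enc(b))
}

# exhaustive optimal colinear chain score over a list of hsp objects
oracle_best_chain <- function(hsps) {
  m <- length(hsps)
  if (m == 0L) return(0)
  compat <- function(h, g)
    (h$q_end <= g$q_start && h$s_end <= g$s_start) ||
    (g$q_end <= h$q_start && g$s_end <= h$s_start)
  best <- 0
  for (bits in 0:(2^m - 1L)) {
    sel <- which(bitwAnd(bits, 2^(0:(m - 1L))) > 0)
    ok <- TRUE
    if (length(sel) > 1L)
      for (i in sel) for (j in sel) if (i < j && !compat(hsps[[i]], hsps[[j]])) {
        ok <- FALSE; break
      }
    if (ok)
      best <- max(best, sum(vapply(hsps[sel], `[[`, numeric(1), "score")))
  }
  best
}

# maximal-sum contiguous segment of a numeric vector (Kadane), with bounds
oracle_best_segment <- function(v) {
  best <- 0; best_i <- 0L; best_j <- -1L
  cur <- 0; cur_i <- 1L
  for (j in seq_along(v)) {
    if (cur <= 0) { cur <- 0; cur_i <- j }
    cur <- cur + v[j]
    if (cur > best) { best <- cur; best_i <- cur_i; best_j <- j }
  }
  list(score = best, from = best_i, to = best_j)
}

# direct average-precision oracle
oracle_ap <- function(ranked, truth) {
  truth <- unique(truth)
  total <- 0
  tp <- 0
  for (p in seq_along(ranked)) {
    if (ranked[p] %in% truth) {
      tp <- tp + 1
      total <- total + tp / p
    }
  }
  total / length(truth)
}

# random sequence_db over a given alphabet
random_db <- function(n_prot, max_len, alphabet = LETTERS[1:20],
                      min_len = 1L) {
  seqs <- vapply(seq_len(n_prot), function(i) {
    L <- sample(min_len:max_len, 1L)
    paste0(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
  sequence_db(seqs, sprintf("p%03d", seq_len(n_prot)))
}

write_temp_fasta <- function(records, dir = tempdir()) {
  path <- tempfile("fx", tmpdir = dir, fileext = ".fasta")
  lines <- unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]])))
  writeLines(lines, path)
  path
}
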