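#' k-mer count vector of a protein
#'
#' Counts every length-`k` substring of the sequence (overlapping, never
#' crossing sentinels since the input is a single protein's residues).
#'
#' @param seq residue string.
#' @param k word length (`k >= 1`).
#' @return Named integer vector of counts with attribute `k`; empty when the
#'   sequence is shorter than `k`.
#' @examples
#' kmer_vector("AAA", 2)  # AA: 2
#' @export
kmer_vector <- function(seq, k) {
  stopifnot(k >= 1L)
  L <- nchar(seq)
  if (L < k) {
    v <- integer(0)
  } else {
    kmers <- substring(seq, 1:(L - k + 1L), k:L)
    tab <- table(kmers)
    v <- as.integer(tab)
    names(v) <- names(tab)
  }
  structure(v, k = as.integer(k), class = "kmer_vector")
}

#' KSEARCH score: dot product of k-mer count vectors
#'
#' @param qvec,dvec [kmer_vector()]s built with the same `k`.
#' @return Sum over shared k-mers of the product of the two counts.
#' @export
ksearch_score <- function(qvec, dvec) {
  if (!identical(attr(qvec, "k"), attr(dvec, "k")))
    stop("k-mer vectors built with different k")
  shared <- intersect(names(qvec), names(dvec))
  if (length(shared) == 0L) return(0L)
  sum(unclass(qvec)[shared] * unclass(dvec)[shared])
}

# all k-mers of one protein of a sequence_db starting at unmasked offsets
masked_query_kmers <- function(qdb, qprot, k, mask) {
  st <- qdb$start[qprot]
  en <- qdb$start[qprot + 1L] - 1L        # sentinel offset
  offs <- seq.int(st, en - 1L)
  offs <- offs[offs + k <= en]            # k-mer fully inside the protein
  offs <- offs[!mask[offs + 1L]]          # masked suffix start: no k-mer
  if (length(offs) == 0L) return(character(0))
  substring(qdb$txt, offs + 1L, offs + k)
}

#' Search a database by k-mer composition (KSEARCH)
#'
#' Ranks database proteins by the dot product of k-mer count vectors with
#' each query protein, via an inverted k-mer table over the database. Query
#' k-mers starting at masked suffix offsets are suppressed (tandem-repeat
#' masking shared with the SANS engine); database k-mers are all counted.
#' Hit selection semantics (top-`H` / threshold, tie on ascending database
#' index) match the SANS engine.
#'
#' @param db database [sequence_db()] (or FASTA path).
#' @param qdb query [sequence_db()] (or FASTA path).
#' @param k word length; 6 is the recommended default for protein search.
#' @param params [search_params()].
#' @return A `hit_table` (see [sans_search()]) with attribute `mode`
#'   `"ksearch"`.
#' @export
ksearch_search <- function(db, qdb, k = 6L, params = search_params()) {
  if (is.character(db)) db <- load_fasta(db)
  if (is.character(qdb)) qdb <- load_fasta(qdb)
  mask <- mask_query_suffixes(qdb)

  # inverted table: k-mer -> (database protein, count)
  dt_list <- lapply(seq_len(db$n_proteins), function(i) {
    seq <- db_sequence(db, i)
    L <- nchar(seq)
    if (L < k) return(NULL)
    data.table::data.table(kmer = substring(seq, 1:(L - k + 1L), k:L),
                           prot = i)
  })
  inv <- data.table::rbindlist(dt_list)
  scores <- matrix(0, nrow = db$n_proteins, ncol = qdb$n_proteins)
  if (nrow(inv) > 0L) {
    kmer <- prot <- dcount <- qcount <- NULL  # NSE bindings
    inv <- inv[, list(dcount = .N), by = list(kmer, prot)]
    data.table::setkey(inv, kmer)
    for (q in seq_len(qdb$n_proteins)) {
      qk <- masked_query_kmers(qdb, q, k, mask)
      if (length(qk) == 0L) next
      qt <- data.table::data.table(kmer = qk)[, list(qcount = .N), by = kmer]
      jj <- inv[qt, nomatch = NULL]
      if (nrow(jj) == 0L) next
      sc <- jj[, list(score = sum(qcount * dcount)), by = prot]
      scores[sc$prot, q] <- sc$score
    }
  }
  hits_from_scores(scores, db, qdb, params, mode = "ksearch")
}
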