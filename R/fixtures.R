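#' Random protein sequence
#'
#' Residues drawn i.i.d. over the 20-letter standard alphabet (uniform, or a
#' supplied composition). Uses the current RNG stream, so wrap in
#' `set.seed()` for reproducibility.
#'
#' @param length sequence length (>= 1).
#' @param composition optional named probability vector over residues.
#' @return Residue string.
#' @export
random_protein <- function(length, composition = NULL) {
  stopifnot(length >= 1L)
  if (is.null(composition)) {
    letters <- AA_STANDARD
    prob <- NULL
  } else {
    letters <- names(composition)
    prob <- composition
  }
  paste0(sample(letters, length, replace = TRUE, prob = prob), collapse = "")
}

#' Mutate a sequence by random substitutions
#'
#' Each position is substituted independently with probability `rate` to a
#' uniformly chosen different residue; with `indel_rate > 0`, positions are
#' additionally deleted or followed by an inserted random residue with
#' probability `indel_rate / 2` each. Substitution-only mutation (the
#' default) preserves length and gives exact control over planted identity.
#'
#' @param seq residue string.
#' @param rate substitution probability per position, in `[0, 1]`.
#' @param indel_rate indel probability per position (default 0).
#' @return Mutated residue string.
#' @export
mutate_protein <- function(seq, rate, indel_rate = 0) {
  stopifnot(rate >= 0, rate <= 1)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(AA_STANDARD, ch[i]), 1L)
  if (indel_rate > 0) {
    u <- runif(length(ch))
    del <- u < indel_rate / 2
    ins <- u >= indel_rate / 2 & u < indel_rate
    out <- character(0)
    for (i in seq_along(ch)) {
      if (!del[i]) out <- c(out, ch[i])
      if (ins[i]) out <- c(out, sample(AA_STANDARD, 1L))
    }
    ch <- if (length(out)) out else sample(AA_STANDARD, 1L)
  }
  paste0(ch, collapse = "")
}

#' Specification of a synthetic retrieval benchmark
#'
#' Describes a database of unrelated random proteins with planted families
#' and a query set of mutated family members at controlled identity.
#' Protein lengths default to a log-normal distribution clipped to
#' `[len_min, len_max]` with mean about 330 residues, echoing the length
#' statistics of large real protein databases; `fixed_length` overrides it.
#'
#' @param n_proteins database size (includes the planted family members).
#' @param n_families number of planted families.
#' @param family_size database members per family (member 1 is the random
#'   seed protein; further members are mutated copies at rate `rate`).
#' @param queries_per_family mutated queries generated per family.
#' @param rate substitution rate for queries (and extra family members);
#'   planted identity is `100 * (1 - rate)` percent. May be a vector, cycled
#'   over families.
#' @param indel_rate optional indel rate for queries (default 0).
#' @param fixed_length if non-NULL, all proteins get this length.
#' @param len_min,len_max,len_meanlog,len_sdlog log-normal length model.
#' @param seed RNG seed; the same spec yields byte-identical outputs.
#' @return An object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_proteins = 1000L, n_families = 50L,
                           family_size = 1L, queries_per_family = 20L,
                           rate = 0.3, indel_rate = 0,
                           fixed_length = NULL,
                           len_min = 50L, len_max = 2000L,
                           len_meanlog = log(330) - 0.45^2 / 2,
                           len_sdlog = 0.45,
                           seed = 42L) {
  stopifnot(n_proteins >= 1L, n_families >= 0L, family_size >= 1L,
            all(rate >= 0 & rate <= 1))
  if (n_families * family_size > n_proteins)
    stop("families larger than the database")
  structure(as.list(environment()), class = "benchmark_spec")
}

#' The fixed benchmark of the feasible retrieval regime
#'
#' 1000 unrelated database proteins of length 300; 50 of them are planted
#' targets, each queried by 20 replicate copies carrying 30% random
#' substitutions (70% planted identity — inside the 50-100% identity range
#' where word filters are expected to retrieve the source at rank 1).
#'
#' @param seed RNG seed.
#' @return A `benchmark_spec`.
#' @export
feasible_regime_spec <- function(seed = 42L) {
  benchmark_spec(n_proteins = 1000L, n_families = 50L, family_size = 1L,
                 queries_per_family = 20L, rate = 0.3,
                 fixed_length = 300L, seed = seed)
}

sample_length <- function(spec) {
  if (!is.null(spec$fixed_length)) return(spec$fixed_length)
  L <- round(rlnorm(1, spec$len_meanlog, spec$len_sdlog))
  as.integer(min(max(L, spec$len_min), spec$len_max))
}

#' Generate a synthetic benchmark
#'
#' Builds the database, query set and truth table described by a
#' [benchmark_spec()]. Family members occupy the first
#' `n_families * family_size` database slots; queries are mutated copies of
#' each family's seed protein; the truth table lists every query's family
#' co-members with the planted percent identity. Deterministic under the
#' spec's seed.
#'
#' @param spec a [benchmark_spec()].
#' @param dir optional directory; when given, writes `db.fasta`,
#'   `query.fasta` and `truth.tsv` there.
#' @return list with `db` and `qdb` ([sequence_db()]s) and `truth`
#'   (data.frame `query_id`, `target_id`, `identity`).
#' @export
make_benchmark <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "benchmark_spec"))
  set.seed(spec$seed)
  nfam_members <- spec$n_families * spec$family_size
  rates <- rep_len(spec$rate, max(spec$n_families, 1L))

  db_seqs <- character(spec$n_proteins)
  db_ids <- sprintf("D%05d", seq_len(spec$n_proteins))
  fam_of <- rep(NA_integer_, spec$n_proteins)
  # family seeds and mutated co-members first, unrelated proteins after
  slot <- 1L
  seeds <- character(max(spec$n_families, 1L))
  for (f in seq_len(spec$n_families)) {
    seeds[f] <- random_protein(sample_length(spec))
    for (m in seq_len(spec$family_size)) {
      db_seqs[slot] <- if (m == 1L) seeds[f] else
        mutate_protein(seeds[f], rates[f])
      fam_of[slot] <- f
      slot <- slot + 1L
    }
  }
  while (slot <= spec$n_proteins) {
    db_seqs[slot] <- random_protein(sample_length(spec))
    slot <- slot + 1L
  }

  q_seqs <- character(0); q_ids <- character(0)
  truth <- list()
  for (f in seq_len(spec$n_families)) {
    members <- db_ids[which(fam_of == f)]
    for (r in seq_len(spec$queries_per_family)) {
      qid <- sprintf("Q%03d_%02d", f, r)
      q_ids <- c(q_ids, qid)
      q_seqs <- c(q_seqs, mutate_protein(seeds[f], rates[f],
                                         indel_rate = spec$indel_rate))
      truth[[length(truth) + 1L]] <-
        data.frame(query_id = qid, target_id = members,
                   identity = 100 * (1 - rates[f]))
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(query_id = character(0), target_id = character(0),
               identity = numeric(0))
  rownames(truth) <- NULL
  db <- sequence_db(db_seqs, db_ids)
  qdb <- if (length(q_seqs)) sequence_db(q_seqs, q_ids) else NULL

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(db, file.path(dir, "db.fasta"))
    if (!is.null(qdb)) write_fasta(qdb, file.path(dir, "query.fasta"))
    con <- file(file.path(dir, "truth.tsv"), "w")
    writeLines("#query_id\ttarget_id\tidentity", con)
    write.table(truth, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    close(con)
  }
  list(db = db, qdb = qdb, truth = truth)
}

#' Write a sequence database as FASTA
#'
#' One record per protein, sequence on a single line (byte-deterministic).
#'
#' @param db a [sequence_db()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  lines <- character(2L * db$n_proteins)
  lines[c(TRUE, FALSE)] <- paste0(">", db$ids)
  lines[c(FALSE, TRUE)] <- vapply(seq_len(db$n_proteins),
                                  function(i) db_sequence(db, i), character(1))
  writeLines(lines, path)
  invisible(path)
}
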