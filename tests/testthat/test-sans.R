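test_that("tandem-repeat masking follows the (1,2,3)/(1,3,5) rules", {
  qdb <- sequence_db(c("AAAB", "ABABA", "ABCDE"), c("a", "b", "c"))
  m <- mask_query_suffixes(qdb)
  by_prot <- split(m, rep(1:3, diff(qdb$start)))
  # AAAB$: AAAB masked by (1,2,3); AAB survives both patterns; the one- and
  # two-residue tails are always masked, as is the sentinel
  expect_equal(unname(by_prot[[1]]), c(TRUE, FALSE, TRUE, TRUE, TRUE))
  # ABABA$: ABABA masked by (1,3,5); BABA and ABA by the available-position
  # reading of (1,3,5); short tails masked
  expect_equal(unname(by_prot[[2]]), rep(TRUE, 6))
  # ABCDE$: all informative suffixes unmasked; short tails + sentinel masked
  expect_equal(unname(by_prot[[3]]), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("masking never reaches across protein boundaries", {
  # last residues of protein 1 and first of protein 2 would satisfy (1,2,3)
  # if the pattern crossed the sentinel
  qdb <- sequence_db(c("CBAA", "AAD"), c("x", "y"))
  m <- mask_query_suffixes(qdb)
  # suffix starting at the first A of protein 1 ("AA" within the protein):
  # short tails are masked, but never because of the next protein's residues
  expect_true(m[3])
  # suffix "AAD" of protein 2: A,A,D satisfies neither pattern
  expect_false(m[6])
})

test_that("masking agrees with the literal-pattern oracle on random suffixes", {
  set.seed(33)
  for (rep in 1:10) {
    qdb <- random_db(sample(2:6, 1), 40, alphabet = LETTERS[1:4])
    m <- mask_query_suffixes(qdb)
    ends <- qdb$start[-1] - 1L
    for (s in 0:(nchar(qdb$txt) - 1L)) {
      p <- findInterval(s, qdb$start)
      expected <- if (s == ends[p]) TRUE else
        oracle_masked(substr(qdb$txt, s + 1L, ends[p]))
      expect_identical(m[s + 1L], expected)
    }
  }
})

test_that("sans_scores reproduces hand-checkable cases", {
  db <- sequence_db(c("MKVLA", "WWWWW"), c("P0", "P1"))
  qdb <- sequence_db("MKVLA", "q")
  idx <- suffix_index(db)
  mp <- map_query_suffixes(idx, db, qdb)
  sc <- sans_scores(idx, mp, qdb, 1, search_params(H = 1, W = 1))
  expect_gt(sc[1], sc[2])
  expect_equal(sc[2], 0L)
  hits <- select_hits(sc, search_params(H = 1, W = 1))
  expect_equal(hits$target[1], 1L)

  # an all-repeat query is fully masked and scores nothing anywhere
  qrep <- sequence_db("AAAAA", "rep")
  mpr <- map_query_suffixes(idx, db, qrep)
  expect_equal(sans_scores(idx, mpr, qrep, 1, search_params(H = 5, W = 5)),
               c(0L, 0L))
})

test_that("sans_scores equals the brute-force window oracle; monotone in W", {
  set.seed(404)
  for (rep in 1:15) {
    db <- random_db(sample(3:20, 1), 30, alphabet = LETTERS[1:6])
    qdb <- random_db(sample(1:3, 1), 30, alphabet = LETTERS[1:6])
    idx <- suffix_index(db)
    mp <- map_query_suffixes(idx, db, qdb)
    mask <- mask_query_suffixes(qdb)
    prev <- NULL
    for (W in c(1L, 3L, 8L)) {
      for (q in seq_len(qdb$n_proteins)) {
        sc <- sans_scores(idx, mp, qdb, q, search_params(H = W, W = W), mask)
        expect_equal(sc, oracle_sans_scores(db, qdb, q, W))
        if (q == 1L) {
          if (!is.null(prev)) expect_true(all(sc >= prev))
          prev <- sc
        }
      }
    }
    prev <- NULL
  }
})

test_that("select_hits applies top-H, threshold and tie rules", {
  p <- function(...) search_params(...)
  expect_equal(select_hits(c(5, 3, 0), p(H = 2))$target, c(1L, 2L))
  expect_equal(select_hits(c(5, 5), p(H = 1))$target, 1L)  # lower index wins
  th <- select_hits(c(5, 3), p(H = 10, T = 4))
  expect_equal(th$target, 1L)
  expect_equal(select_hits(c(0, 0), p(H = 3))$target, integer(0))
  expect_equal(select_hits(c(1, 2, 3), p(H = 2))$rank, c(1L, 2L))
})

test_that("every database member retrieves itself at rank 1 (W = H = 1)", {
  set.seed(77)
  db <- random_db(40, 60, min_len = 12)
  hits <- sans_search(db, db, search_params(H = 1, W = 1))
  top1 <- hits[hits$rank == 1, ]
  expect_equal(nrow(top1), 40L)
  expect_equal(top1$target_id, top1$query_id)
})

test_that("sectioned search accumulates scores across sections", {
  set.seed(88)
  db <- random_db(30, 50, min_len = 40)
  qdb <- sequence_db(vapply(1:5, function(i)
    mutate_protein(db_sequence(db, i * 5), 0.1), character(1)),
    sprintf("q%d", 1:5))
  whole <- sans_search(db, qdb, search_params(H = 1, W = 1))
  # two balanced sections: window effects at the boundary leave the clear
  # top hit of each query unchanged
  bytes <- nchar(db$txt)
  split2 <- sans_search(db, qdb,
                        search_params(H = 1, W = 1,
                                      memory_limit = ceiling(bytes * 0.55)))
  expect_equal(split2[split2$rank == 1, c("query_id", "target_id")],
               whole[whole$rank == 1, c("query_id", "target_id")])
  # memory limit below the largest protein is infeasible
  expect_error(
    sans_search(db, qdb, search_params(H = 1, memory_limit = 10)),
    "largest single protein")
})

test_that("single-section search is the scores+selection composition", {
  set.seed(99)
  db <- random_db(10, 40)
  qdb <- random_db(2, 40)
  params <- search_params(H = 5, W = 2)
  idx <- suffix_index(db)
  mp <- map_query_suffixes(idx, db, qdb)
  mask <- mask_query_suffixes(qdb)
  hits <- sans_search(db, qdb, params)
  for (q in 1:2) {
    sc <- sans_scores(idx, mp, qdb, q, params, mask)
    manual <- select_hits(sc, params)
    got <- hits[hits$query_id == qdb$ids[q], ]
    expect_equal(got$target_id, db$ids[manual$target])
    expect_equal(got$score, manual$score)
  }
})

test_that("hit tables round-trip through the TSV format", {
  set.seed(12)
  db <- random_db(10, 30, min_len = 10)
  hits <- sans_search(db, db, search_params(H = 3, W = 3))
  path <- tempfile(fileext = ".tsv")
  write_hits(hits, path)
  expect_match(readLines(path, n = 1), "^#query_id\ttarget_id\trank\tsans_score$")
  back <- read_hits(path)
  expect_equal(back$query_id, hits$query_id)
  expect_equal(back$score, hits$score)
  expect_equal(attr(back, "mode"), "sans")
})
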