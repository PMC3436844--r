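test_that("the bundled BLOSUM62 matches the reference matrix", {
  b <- blosum62()
  ref <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K",
          "M","F","P","S","T","W","Y","V")
  # the 20 standard residues agree entry-for-entry with the independent copy
  expect_equal(b[aa, aa], ref[aa, aa])
  expect_true(isSymmetric(unname(b)))
  expect_equal(b["A", "A"], 4L)
  expect_equal(b["W", "W"], 11L)
})

test_that("two-hit seeds require one diagonal and spacing within [3, 40]", {
  seeds <- find_two_hit_seeds("MKVLAQR", "MKVLAQR")
  expect_true(any(seeds$diag == 0 & seeds$q1 == 0 & seeds$q2 == 3))
  # no shared 3-mers -> no seeds
  expect_equal(nrow(find_two_hit_seeds("MKVLAQ", "DEFGHI")), 0L)
  # two identical 3-mers 50 apart on one diagonal, nothing else shared on
  # it: distance bound rejects the pair
  farq <- paste0("MKV", strrep("A", 47), "MKV")
  fars <- paste0("MKV", strrep("C", 47), "MKV")
  expect_equal(nrow(find_two_hit_seeds(farq, fars)), 0L)
  # overlapping 3-mer hits do not pair (distance < 3)
  expect_equal(nrow(find_two_hit_seeds("MKVL", "MKVL")), 0L)
  # at exactly 40 apart the pair is accepted
  edgeq <- paste0("MKV", strrep("A", 37), "MKV")
  edges <- paste0("MKV", strrep("C", 37), "MKV")
  s2 <- find_two_hit_seeds(edgeq, edges)
  expect_true(any(s2$diag == 0 & s2$q1 == 0 & s2$q2 == 40))
})

test_that("x-drop extension spans identical sequences exactly", {
  seed <- data.frame(diag = 0L, q1 = 0L, q2 = 3L)
  h <- extend_hsp("AAAAAA", "AAAAAA", seed)
  expect_equal(h$q_start, 0L); expect_equal(h$q_end, 6L)
  expect_equal(h$score, 24)

  set.seed(31)
  for (rep in 1:10) {
    s <- random_protein(sample(20:60, 1))
    seeds <- find_two_hit_seeds(s, s)
    seeds <- seeds[seeds$diag == 0, ]
    if (nrow(seeds) == 0) next
    h <- extend_hsp(s, s, seeds[1, ])
    b <- blosum62()
    ch <- strsplit(s, "")[[1]]
    expect_equal(h$score, sum(b[cbind(ch, ch)]))
    expect_equal(c(h$q_start, h$q_end), c(0L, nchar(s)))
  }
})

test_that("extension stops inside a long mismatch block", {
  # identity block, then a mismatch wall longer than the x-drop allows
  left <- "MKVLAQRSTW"   # diagonal sum 52
  wall <- strrep("P", 15)
  right <- "GHIKL"       # diagonal sum 27 < 52, so the left block is optimal
  q <- paste0(left, wall, right)
  s <- paste0(left, strrep("W", 15), right)
  seeds <- find_two_hit_seeds(q, s)
  seeds <- seeds[seeds$diag == 0 & seeds$q1 < 10, ]
  h <- extend_hsp(q, s, seeds[1, ])
  # the HSP equals the best-scoring segment on that diagonal (Kadane oracle)
  b <- blosum62()
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  v <- b[cbind(qc, sc)]
  best <- oracle_best_segment(v)
  expect_equal(h$score, best$score)
  expect_equal(h$q_start, best$from - 1L)
  expect_equal(h$q_end, best$to)
})

test_that("chaining keeps colinear HSPs and drops crossing ones", {
  mk <- function(qs, ss, len, score)
    structure(list(q_start = qs, q_end = qs + len, s_start = ss,
                   s_end = ss + len, diag = qs - ss, score = score),
              class = "hsp")
  one <- mk(0, 0, 10, 30)
  expect_equal(chain_hsps(list(one))$total_score, 30)
  two <- mk(20, 20, 5, 12)
  ch <- chain_hsps(list(one, two))
  expect_equal(ch$total_score, 42)
  expect_length(ch$hsps, 2)
  # crossing HSPs: higher score wins
  cross <- chain_hsps(list(mk(0, 20, 10, 30), mk(20, 0, 10, 20)))
  expect_equal(cross$total_score, 30)
  expect_length(cross$hsps, 1)
  expect_equal(chain_hsps(list())$total_score, 0)
})

test_that("chained HSPs are strictly ordered and never beat the DP optimum", {
  set.seed(43)
  n_equal <- 0; n_tot <- 0
  for (rep in 1:60) {
    a <- random_protein(120)
    b <- mutate_protein(a, runif(1, 0.3, 0.6))
    seeds <- find_two_hit_seeds(a, b)
    if (nrow(seeds) == 0) next
    hsps <- lapply(seq_len(min(nrow(seeds), 8)), function(i)
      extend_hsp(a, b, seeds[i, ]))
    hsps <- Filter(function(h) h$score > 0, hsps)
    if (length(hsps) == 0) next
    ch <- chain_hsps(hsps)
    if (length(ch$hsps) > 1) {
      qs <- vapply(ch$hsps, `[[`, numeric(1), "q_start")
      qe <- vapply(ch$hsps, `[[`, numeric(1), "q_end")
      ss <- vapply(ch$hsps, `[[`, numeric(1), "s_start")
      se <- vapply(ch$hsps, `[[`, numeric(1), "s_end")
      expect_true(all(qe[-length(qe)] <= qs[-1]))
      expect_true(all(se[-length(se)] <= ss[-1]))
    }
    expect_equal(ch$total_score,
                 sum(vapply(ch$hsps, `[[`, numeric(1), "score")))
    opt <- oracle_best_chain(hsps)
    expect_lte(ch$total_score, opt)
    n_tot <- n_tot + 1
    if (ch$total_score == opt) n_equal <- n_equal + 1
  }
  expect_gte(n_equal / n_tot, 0.9)
})

test_that("greedy rescoring reranks by alignment score", {
  set.seed(52)
  base <- random_protein(120)
  db <- sequence_db(c(mutate_protein(base, 0.5), base),
                    c("mut50", "ident"))
  qdb <- sequence_db(base, "q")
  hits <- sans_search(db, qdb, search_params(H = 2, W = 2))
  res <- rescore_hits(hits, db, qdb, keep = 2)
  expect_equal(res$target_id[res$rank == 1], "ident")
  expect_true(all(c("greedy_score") %in% names(res)))
  # hits with no seeds score 0 and fall to the bottom
  db2 <- sequence_db(c(base, random_protein(120)), c("ident", "rand"))
  h2 <- data.frame(query_id = "q", target_id = c("rand", "ident"),
                   rank = 1:2, score = c(5, 4))
  attr(h2, "mode") <- "sans"; class(h2) <- c("hit_table", "data.frame")
  r2 <- rescore_hits(h2, db2, qdb, keep = 2)
  expect_equal(r2$target_id, c("ident", "rand"))
  expect_equal(r2$greedy_score[2], 0)
  # keep = 0 empties the list
  expect_equal(nrow(rescore_hits(hits, db, qdb, keep = 0)), 0L)
})

test_that("near-identical pairs need fewer extension steps than distant ones", {
  set.seed(61)
  steps_at <- function(rate, n = 40) {
    mean(replicate(n, {
      a <- random_protein(300)
      attr(greedy_align_pair(a, mutate_protein(a, rate)), "steps")
    }))
  }
  expect_lte(steps_at(0.02), steps_at(0.5))
})
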