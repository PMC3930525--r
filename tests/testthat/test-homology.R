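test_that("local protein alignment matches known scores and handles no-hit pairs", {
  sc <- blosum62_scoring()
  al <- local_align_protein("MKV", "MKV", sc)
  expect_equal(al$score, 14)  # BLOSUM62 diagonal 5 + 5 + 4
  expect_identical(al$aln1, "MKV")

  al0 <- local_align_protein("AAAA", "CCCC", sc)
  expect_equal(al0$score, 0)
  expect_identical(al0$aln1, "")

  # self-alignment score is the sum of diagonal matrix entries
  set.seed(5)
  for (i in 1:5) {
    p <- random_protein(8, rownames(sc$matrix)[1:20])
    expect_equal(local_align_protein(p, p, sc)$score,
                 sum(diag(sc$matrix[strsplit(p, "")[[1]],
                                    strsplit(p, "")[[1]], drop = FALSE])))
  }
})

test_that("local alignment equals an exhaustive DP oracle on short pairs", {
  sc <- blosum62_scoring()
  set.seed(21)
  for (i in 1:40) {
    p1 <- random_protein(sample(1:6, 1))
    p2 <- random_protein(sample(1:6, 1))
    expect_equal(local_align_protein(p1, p2, sc)$score,
                 oracle_align_score(p1, p2, sc$matrix, sc$gap_open,
                                    sc$gap_extend, "local"),
                 info = paste(p1, p2))
  }
})

test_that("the stop and ambiguity residues score as configured", {
  sc <- blosum62_scoring()
  # X-neutrality takes precedence in the single (*, X) cell
  expect_true(all(sc$matrix["*", setdiff(colnames(sc$matrix), "X")] == -4))
  expect_true(all(sc$matrix[setdiff(rownames(sc$matrix), "X"), "*"] == -4))
  expect_true(all(sc$matrix[, "X"] == 0))
  expect_true(all(sc$matrix["X", ] == 0))
})

test_that("translated self-search reports a full-coverage plus-frame hit", {
  # tryptophan codons make the coding frame score far above any other frame
  # (off-frame translations are low-scoring V/P repeats)
  cds <- paste0("ATG", strrep("TGG", 13), "GAA")
  hits <- translated_search(c(q = cds), c(s = cds))
  top <- hits[1, ]
  expect_identical(c(top$qframe, top$sframe), c(1L, 1L))
  expect_equal(top$pident, 100)
  expect_identical(c(top$qstart, top$qend), c(1L, 45L))
})

test_that("a reverse-complemented subject is found on a minus frame", {
  cds <- simulate_cds(40, seed = 3)
  hits <- translated_search(c(q = cds), c(s = reverse_complement(cds)))
  expect_true(hits$qframe[1] * hits$sframe[1] < 0)
  expect_equal(hits$pident[1], 100)
})

test_that("best translated score is symmetric under a symmetric matrix", {
  set <- simulate_homolog_set(3, 0.5, 0.25, seed = 9, n_codons = 40)
  fwd <- translated_search(set$seqs_a, set$seqs_b, max_evalue = NULL)
  rev <- translated_search(set$seqs_b, set$seqs_a, max_evalue = NULL)
  for (i in seq_along(set$seqs_a)) {
    a <- names(set$seqs_a)[i]; b <- names(set$seqs_b)[i]
    s_fwd <- fwd$raw_score[fwd$query_id == a & fwd$subject_id == b]
    s_rev <- rev$raw_score[rev$query_id == b & rev$subject_id == a]
    expect_equal(max(s_fwd), max(s_rev))
  }
})

test_that("unrelated random sequences rarely pass the e-value threshold", {
  set.seed(31)
  n_hit <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    q <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    hits <- translated_search(c(q = q), c(s = s), max_evalue = 1e-5)
    if (nrow(hits)) n_hit <- n_hit + 1L
  }
  expect_lte(n_hit / n_rep, 0.05)
})

test_that("reciprocal best hits form a matching and drop score ties", {
  mk <- function(q, s, score) {
    data.frame(query_id = q, subject_id = s, qframe = 1L, sframe = 1L,
               qstart = 1L, qend = 30L, sstart = 1L, send = 30L,
               raw_score = score, bitscore = score, evalue = 1e-10,
               aln_len_aa = 10L, pident = 100, stringsAsFactors = FALSE)
  }
  # mutual best -> one pair
  pairs <- reciprocal_best_hits(mk("a", "b", 100), mk("b", "a", 90))
  expect_identical(pairs$id_a, "a")
  expect_identical(pairs$id_b, "b")
  # a -> b best but b -> c best: no pair
  pairs <- reciprocal_best_hits(mk("a", "b", 100), mk("b", "c", 90))
  expect_identical(nrow(pairs), 0L)
  # exact tie between distinct subjects drops the query, with a warning
  hits_ab <- rbind(mk("a", "b", 100), mk("a", "b2", 100))
  expect_warning(pairs <- reciprocal_best_hits(hits_ab, mk("b", "a", 90)),
                 "tie")
  expect_identical(nrow(pairs), 0L)
  # matching property on a larger random pairing
  set <- simulate_homolog_set(5, 0.3, 0.2, seed = 17, n_codons = 50)
  p <- reciprocal_best_hits(translated_search(set$seqs_a, set$seqs_b),
                            translated_search(set$seqs_b, set$seqs_a))
  expect_false(anyDuplicated(p$id_a) > 0)
  expect_false(anyDuplicated(p$id_b) > 0)
})

test_that("RBH recovers simulated orthologue pairs with no false pairs", {
  n_true <- 0L
  n_found <- 0L
  n_false <- 0L
  for (seed in 1:20) {
    set <- simulate_homolog_set(4, 0.5, 0.2, seed = 100 + seed, n_codons = 60)
    pairs <- reciprocal_best_hits(
      translated_search(set$seqs_a, set$seqs_b),
      translated_search(set$seqs_b, set$seqs_a))
    truth_map <- stats::setNames(set$truth$id_b, set$truth$id_a)
    n_true <- n_true + nrow(set$truth)
    n_found <- n_found + sum(truth_map[pairs$id_a] == pairs$id_b)
    n_false <- n_false + sum(truth_map[pairs$id_a] != pairs$id_b)
  }
  expect_identical(n_false, 0L)
  expect_gte(n_found / n_true, 0.95)
})

test_that("tabular hit files parse, infer orientation, and reject bad columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t98.5\t100\t1\t0\t1\t300\t1\t300\t1e-50\t250", f)
  h <- read_tabular_hits(f)
  expect_equal(h$pident, 98.5)
  expect_equal(h$evalue, 1e-50)
  expect_identical(h$qframe, 1L)

  writeLines("q1\ts1\t98.5\t100\t1\t0\t1\t300\t300\t1\t1e-50\t250", f)
  h <- read_tabular_hits(f)
  expect_identical(h$sframe, -1L)
  expect_lte(h$sstart, h$send)

  writeLines("q1\ts1\t98.5\t100\t1\t0\t1\t300\t1\t300\t1e-50", f)
  expect_error(read_tabular_hits(f), "12 or 14.*found 11")
})
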