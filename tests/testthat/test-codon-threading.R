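test_that("trimming snaps to codon boundaries of the hit frame", {
  set.seed(1)
  seq400 <- simulate_cds(133, 1)  # 399 nt, extend to 400
  seq400 <- paste0(seq400, "A")
  p <- list(pair_id = "p", qframe = 1L, sframe = 1L,
            qstart = 1L, qend = 300L, sstart = 1L, send = 300L)
  tr <- trim_to_overlap(p, seq400, seq400)
  expect_identical(nchar(tr$cds_a), 300L)
  expect_identical(tr$cds_a, substring(seq400, 1, 300))

  # frame +2 hit covering nt 2-301: starts at 2, length 300
  p2 <- list(pair_id = "p", qframe = 2L, sframe = 1L,
             qstart = 2L, qend = 301L, sstart = 1L, send = 300L)
  tr2 <- trim_to_overlap(p2, seq400, seq400)
  expect_identical(tr2$cds_a, substring(seq400, 2, 301))

  # off-frame region is advanced to the next codon start of the frame
  p3 <- list(pair_id = "p", qframe = 1L, sframe = 1L,
             qstart = 3L, qend = 300L, sstart = 1L, send = 300L)
  tr3 <- trim_to_overlap(p3, seq400, seq400)
  expect_identical(tr3$cds_a, substring(seq400, 4, 300))

  # shorter than one codon after snapping: discarded with a reason
  p4 <- list(pair_id = "p", qframe = 1L, sframe = 1L,
             qstart = 3L, qend = 4L, sstart = 1L, send = 300L)
  tr4 <- trim_to_overlap(p4, seq400, seq400)
  expect_s3_class(tr4, "pair_discard")
  expect_identical(attr(tr4, "reason"), "short_after_snap")
  # out-of-bounds coordinates are an error
  p5 <- list(pair_id = "p", qframe = 1L, sframe = 1L,
             qstart = 1L, qend = 500L, sstart = 1L, send = 300L)
  expect_error(trim_to_overlap(p5, seq400, seq400), "out of bounds")
})

test_that("minus-frame trimming reproduces the hit-frame translation", {
  # cross-check: the trimmed fragment, translated in frame +1, must equal the
  # subject-frame translation of the hit region of the original sequence
  for (seed in 1:25) {
    cds <- simulate_cds(60, 400 + seed)
    rc <- reverse_complement(cds)
    hits <- translated_search(c(q = cds), c(s = rc))
    p <- hits[1, ]
    p$pair_id <- "m"
    tr <- trim_to_overlap(p, cds, rc)
    expect_identical(nchar(tr$cds_b) %% 3L, 0L)
    expect_true(grepl(translate_cds(tr$cds_b), translate_frame(rc, p$sframe),
                      fixed = TRUE))
    expect_true(grepl(translate_cds(tr$cds_a), translate_frame(cds, p$qframe),
                      fixed = TRUE))
  }
})

test_that("global protein alignment matches examples and the DP oracle", {
  sc <- blosum62_scoring()
  al <- protein_align_global("MAV", "MV", sc)
  expect_identical(al$aln1, "MAV")
  expect_identical(al$aln2, "M-V")

  al2 <- protein_align_global("MKV", "MKV", sc)
  expect_identical(al2$aln1, al2$aln2)

  set.seed(13)
  for (i in 1:40) {
    p1 <- random_protein(sample(1:6, 1))
    p2 <- random_protein(sample(1:6, 1))
    expect_equal(protein_align_global(p1, p2, sc)$score,
                 oracle_align_score(p1, p2, sc$matrix, sc$gap_open,
                                    sc$gap_extend, "global"),
                 info = paste(p1, p2))
  }
})

test_that("codon threading replaces residues by source codons", {
  aln <- thread_codons("MAV", "M-V", "ATGGCCGTT", "ATGGTT")
  expect_identical(aln$codons_a, c("ATG", "GCC", "GTT"))
  expect_identical(aln$codons_b, c("ATG", "---", "GTT"))
  # gap-free identical pair: columns equal the two CDSs
  aln2 <- thread_codons("MA", "MA", "ATGGCC", "ATGGCC")
  expect_identical(aln2$codons_a, aln2$codons_b)
  # translation mismatch is a consistency error
  expect_error(thread_codons("M", "M", "GCC", "ATG"), "does not match")
})

test_that("ungapped row content always reproduces the source CDS", {
  sc <- blosum62_scoring()
  for (seed in 1:10) {
    ev <- evolve_pair(simulate_cds(40, 600 + seed), 0.8, 0.4, 700 + seed)
    al <- protein_align_global(translate_cds(ev$desc1), translate_cds(ev$desc2), sc)
    aln <- thread_codons(al$aln1, al$aln2, ev$desc1, ev$desc2)
    expect_identical(paste(aln$codons_a[aln$codons_a != "---"], collapse = ""),
                     ev$desc1)
    expect_identical(paste(aln$codons_b[aln$codons_b != "---"], collapse = ""),
                     ev$desc2)
  }
})

test_that("stop and nonsense columns are deleted, idempotently", {
  aln <- new_codon_alignment(c("ATG", "TAA", "ATN", "GGG"),
                             c("ATG", "CAA", "ATG", "GGA"))
  clean <- remove_stop_and_nonsense(aln)
  expect_identical(clean$codons_a, c("ATG", "GGG"))
  expect_identical(attr(clean, "n_removed"), 2L)
  again <- remove_stop_and_nonsense(clean)
  expect_identical(again$codons_a, clean$codons_a)
  expect_identical(attr(again, "n_removed"), 0L)
  # no stops or N: unchanged
  ok <- new_codon_alignment(c("ATG", "GGG"), c("ATG", "GGA"))
  expect_identical(remove_stop_and_nonsense(ok)$codons_b, ok$codons_b)
})

test_that("the minimum-length filter counts ungapped codons times three", {
  mk <- function(n) new_codon_alignment(rep("GGG", n), rep("GGA", n))
  expect_false(filter_min_length(mk(49)))  # 147 bp
  expect_identical(attr(filter_min_length(mk(49)), "reason"), "below_min_length")
  expect_true(filter_min_length(mk(50)))   # 150 bp
  expect_false(filter_min_length(new_codon_alignment(character(0), character(0))))
  # gap columns do not count towards the comparable length
  gappy <- new_codon_alignment(c(rep("GGG", 50), "---"),
                               c(rep("GGA", 50), "ATG"))
  expect_identical(aln_len_bp(gappy), 150L)
})

test_that("the full chain on identical sequences is gap-free and full length", {
  cds <- simulate_cds(60, 12)
  aln <- codon_align_pair(cds, cds)
  expect_identical(n_ungapped(aln), 60L)
  expect_identical(aln_len_bp(aln), nchar(cds))
  expect_identical(aln$codons_a, aln$codons_b)
})
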