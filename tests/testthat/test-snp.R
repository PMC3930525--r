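# A contig with controlled structure: no mononucleotide run longer than 2
# except where placed deliberately.
snp_test_contig <- function(len = 300L) {
  paste(rep(c("A", "C", "G", "T"), length.out = len), collapse = "")
}

pileup_row <- function(contig, pos, counts) {
  data.frame(contig = contig, pos = pos, countA = counts[["A"]],
             countC = counts[["C"]], countG = counts[["G"]],
             countT = counts[["T"]], stringsAsFactors = FALSE)
}

test_that("substitutions are classified as transitions or transversions", {
  expect_identical(classify_substitution("A", "G"), "transition")
  expect_identical(classify_substitution("C", "T"), "transition")
  expect_identical(classify_substitution("A", "C"), "transversion")
  expect_identical(classify_substitution("G", "T"), "transversion")
  expect_error(classify_substitution("A", "A"), "identical")
})

test_that("depth and MAF thresholds are strict and tiers nest", {
  contigs <- c(ct = snp_test_contig())
  # maf exactly 0.20 at depth 20: passes low (> 0.15) but not medium (> 0.20)
  pu <- pileup_row("ct", 100L, c(A = 16, C = 4, G = 0, T = 0))
  calls <- call_snps(pu, contigs)
  expect_identical(nrow(calls), 1L)
  expect_true(calls$tier_low)
  expect_false(calls$tier_medium)
  expect_false(calls$tier_high)
  expect_identical(calls$tiers, "low")
  # depth 40, maf 0.30: all three tiers
  pu <- pileup_row("ct", 100L, c(A = 28, C = 12, G = 0, T = 0))
  calls <- call_snps(pu, contigs)
  expect_true(all(calls$tier_low, calls$tier_medium, calls$tier_high))
  # depth exactly at a bound does not pass that tier (strict inequality)
  pu <- pileup_row("ct", 100L, c(A = 5, C = 3, G = 0, T = 0))  # depth 8
  expect_identical(nrow(call_snps(pu, contigs)), 0L)
})

test_that("flanking and homopolymer rules exclude calls", {
  contigs <- c(ct = snp_test_contig())
  strong <- c(A = 28, C = 0, G = 12, T = 0)
  # left flank 29 bp < 50
  expect_identical(nrow(call_snps(pileup_row("ct", 30L, strong), contigs)), 0L)
  # right flank < 50
  expect_identical(nrow(call_snps(pileup_row("ct", 260L, strong), contigs)), 0L)
  # position 51 has exactly 50 bp on the left: kept
  expect_identical(nrow(call_snps(pileup_row("ct", 51L, strong), contigs)), 1L)
  # a run of three reference As swallows the call
  with_run <- c(ct2 = paste0(substring(snp_test_contig(), 1, 99), "AAA",
                             substring(snp_test_contig(), 103, 300)))
  expect_identical(nrow(call_snps(pileup_row("ct2", 101L, strong), with_run)), 0L)
  # run of two is tolerated
  with_run2 <- c(ct3 = paste0(substring(snp_test_contig(), 1, 99), "AAC",
                              substring(snp_test_contig(), 103, 300)))
  expect_identical(nrow(call_snps(pileup_row("ct3", 100L, strong), with_run2)), 1L)
})

test_that("multi-allelic columns are rejected by the third-allele ceiling", {
  contigs <- c(ct = snp_test_contig())
  # third allele count 2 > max(1, 0.4) at depth 40
  pu <- pileup_row("ct", 100L, c(A = 26, C = 12, G = 2, T = 0))
  expect_identical(nrow(call_snps(pu, contigs)), 0L)
  # third allele count 1 is within the ceiling
  pu <- pileup_row("ct", 100L, c(A = 27, C = 12, G = 1, T = 0))
  expect_identical(nrow(call_snps(pu, contigs)), 1L)
  # unknown contig is an input error
  expect_error(call_snps(pileup_row("nope", 100L, c(A = 28, C = 12, G = 0, T = 0)),
                         contigs), "unknown contig")
})

test_that("raising any threshold never increases the call count", {
  set.seed(77)
  contig <- c(sim = paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                          collapse = ""))
  planted <- data.frame(pos = seq(60, 340, by = 20),
                        minor_base = NA_character_, target_maf = NA_real_)
  ref <- strsplit(contig[[1]], "")[[1]]
  for (i in seq_len(nrow(planted))) {
    planted$minor_base[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                            ref[planted$pos[i]]), 1)
    planted$target_maf[i] <- sample(c(0.1, 0.18, 0.22, 0.3, 0.45), 1)
  }
  sim <- simulate_pileup(contig[[1]], planted, depth = 20, seed = 5)
  names(contig) <- "sim_contig"
  n_calls <- function(d, f) {
    nrow(call_snps(sim$pileup, contig,
                   snp_tiers(min_depth = c(low = d, medium = d, high = d),
                             min_maf = c(low = f, medium = f, high = f))))
  }
  for (f in c(0.1, 0.2, 0.3)) {
    counts <- vapply(c(5, 10, 15, 19, 25), n_calls, numeric(1), f = f)
    expect_true(all(diff(counts) <= 0))
  }
  for (d in c(5, 15)) {
    counts <- vapply(c(0.05, 0.15, 0.25, 0.45), n_calls, numeric(1), d = d)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("deterministic planted pileups are recovered exactly per tier", {
  contig <- paste0(snp_test_contig(140), "GGGG", snp_test_contig(156))
  planted <- data.frame(
    pos = c(80L, 120L, 142L, 200L, 230L),
    minor_base = c("C", "G", "A", "C", "A"),
    target_maf = c(0.30, 0.22, 0.40, 0.18, 0.10))
  # pos 142 sits inside the GGGG run; ensure minor differs from reference
  ref <- strsplit(contig, "")[[1]]
  stopifnot(all(planted$minor_base != ref[planted$pos]))
  sim <- simulate_pileup(contig, planted, depth = 40, error_rate = 0, seed = 3)
  contigs <- c(sim_contig = contig)
  calls <- call_snps(sim$pileup, contigs)
  expect_true(sim$truth$in_homopolymer[sim$truth$pos == 142])
  for (tier in c("low", "medium", "high")) {
    expect_setequal(calls$pos[calls[[paste0("tier_", tier)]]],
                    sim$truth$pos[sim$truth[[paste0("expect_", tier)]]])
  }
  # tier nesting on every call
  expect_true(all(calls$tier_low[calls$tier_medium]))
  expect_true(all(calls$tier_medium[calls$tier_high]))
  # summary identities
  smry <- summarize_snps(calls)
  expect_identical(smry$n_transitions + smry$n_transversions, smry$n_snps)
  expect_identical(smry$tier, c("low", "medium", "high"))
  expect_true(all(diff(smry$n_snps) <= 0))
})

test_that("summaries count SNPs, contigs and substitution classes", {
  expect_identical(summarize_snps(call_snps(
    pileup_row("ct", 100L, c(A = 20, C = 0, G = 0, T = 0)),
    c(ct = snp_test_contig())))$n_snps, c(0L, 0L, 0L))
  # three passing SNPs on two contigs
  contigs <- c(c1 = snp_test_contig(), c2 = snp_test_contig())
  pu <- rbind(pileup_row("c1", 100L, c(A = 28, C = 12, G = 0, T = 0)),
              pileup_row("c1", 150L, c(A = 28, C = 0, G = 12, T = 0)),
              pileup_row("c2", 100L, c(A = 0, C = 28, G = 0, T = 12)))
  smry <- summarize_snps(call_snps(pu, contigs))
  expect_identical(smry$n_snps[smry$tier == "low"], 3L)
  expect_identical(smry$n_contigs[smry$tier == "low"], 2L)
  expect_identical(smry$n_transversions + smry$n_transitions, smry$n_snps)
})

test_that("the VCF writer emits valid minimal records", {
  contigs <- c(ct = snp_test_contig())
  calls <- call_snps(pileup_row("ct", 100L, c(A = 28, C = 12, G = 0, T = 0)),
                     contigs)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(calls, contigs, f)
  lines <- readLines(f)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 1L)
  fields <- strsplit(body, "\t")[[1]]
  expect_identical(fields[c(1, 2, 4, 5)], c("ct", "100", "A", "C"))
  expect_match(fields[8], "DP=40;AF=0.3")
})
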