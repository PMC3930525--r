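# Seeded generators with the statistical structure the analysis assumes:
# coding-sequence pairs diverged under a known dN/dS ratio (omega),
# expression tables in which log(Ka/Ks) depends linearly on log bias
# covariates with known coefficients, and base-count pileups with planted
# SNPs of known depth and minor-allele frequency. Every generator is
# bit-reproducible for a fixed seed and returns its generating truth.

#' The 61 sense codons of a genetic code
#'
#' @param code Genetic code.
#' @return Character vector of codons that do not encode a stop.
#' @export
sense_codons <- function(code = standard_genetic_code()) {
  names(code)[code != "*"]
}

#' Simulate a stop-free coding sequence
#'
#' Starts with ATG; remaining codons are uniform random sense codons.
#'
#' @param n_codons Number of codons (at least 2).
#' @param seed Integer seed (deterministic output per seed).
#' @return A single DNA string of length `3 * n_codons`.
#' @export
simulate_cds <- function(n_codons, seed) {
  if (n_codons < 2) stop("n_codons must be at least 2", call. = FALSE)
  with_local_seed(seed, {
    codons <- c("ATG", sample(sense_codons(), n_codons - 1L, replace = TRUE))
    paste(codons, collapse = "")
  })
}

# One lineage: `n_prop` proposed point mutations at uniform random
# sites/alternative bases; proposals creating a stop codon are rejected;
# synonymous/nonsynonymous proposals accepted per the selection scheme.
mutate_lineage <- function(seq, omega, n_prop, code) {
  codons <- split_codons(seq)
  n_syn <- 0L
  n_nonsyn <- 0L
  if (n_prop > 0) {
    L <- nchar(seq)
    sites <- sample.int(L, n_prop, replace = TRUE)
    alt_idx <- sample.int(3L, n_prop, replace = TRUE)
    acc <- stats::runif(n_prop)
    for (j in seq_len(n_prop)) {
      site <- sites[[j]]
      ci <- (site - 1L) %/% 3L + 1L
      pos <- (site - 1L) %% 3L + 1L
      old_codon <- codons[[ci]]
      old_base <- substring(old_codon, pos, pos)
      new_base <- setdiff(BASES, old_base)[[alt_idx[[j]]]]
      new_codon <- old_codon
      substring(new_codon, pos, pos) <- new_base
      if (code[[new_codon]] == "*") next  # stop-creating proposal rejected
      syn <- code[[new_codon]] == code[[old_codon]]
      accept <- if (omega <= 1) {
        syn || acc[[j]] < omega
      } else {
        !syn || acc[[j]] < 1 / omega
      }
      if (!accept) next
      codons[[ci]] <- new_codon
      if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
    }
  }
  list(seq = paste(codons, collapse = ""), n_syn = n_syn, n_nonsyn = n_nonsyn,
       n_proposed = n_prop)
}

#' Evolve a pair of descendants from a common ancestor
#'
#' Each lineage receives `Poisson(divergence * length / 2)` proposed point
#' mutations at uniform random sites and alternative bases. Proposals that
#' would create a stop codon are rejected. For `omega <= 1`, synonymous
#' proposals are always accepted and nonsynonymous proposals with
#' probability `omega`; for `omega > 1`, nonsynonymous proposals are always
#' accepted and synonymous proposals with probability `1 / omega`.
#'
#' @param ancestor Stop-free in-frame DNA string (as from [simulate_cds()]).
#' @param omega Target dN/dS ratio, `>= 0`.
#' @param divergence Expected proposed substitutions per site (both lineages
#'   combined).
#' @param seed Integer seed.
#' @param code Genetic code.
#' @return List with `desc1`, `desc2` and `truth` (per-lineage realized
#'   synonymous/nonsynonymous substitution and proposal counts, `omega`,
#'   `divergence`, `seed`).
#' @export
evolve_pair <- function(ancestor, omega, divergence, seed,
                        code = standard_genetic_code()) {
  stopifnot(omega >= 0, divergence >= 0)
  if (grepl("\\*", translate_cds(ancestor, code))) {
    stop("ancestor must be stop-free in frame +1", call. = FALSE)
  }
  with_local_seed(seed, {
    lambda <- divergence * nchar(ancestor) / 2
    l1 <- mutate_lineage(ancestor, omega, stats::rpois(1, lambda), code)
    l2 <- mutate_lineage(ancestor, omega, stats::rpois(1, lambda), code)
    list(desc1 = l1$seq, desc2 = l2$seq,
         truth = list(omega = omega, divergence = divergence, seed = seed,
                      n_syn = c(l1$n_syn, l2$n_syn),
                      n_nonsyn = c(l1$n_nonsyn, l2$n_nonsyn),
                      n_proposed = c(l1$n_proposed, l2$n_proposed)))
  })
}

#' Simulate a set of homologous sequence pairs across two "species"
#'
#' Independent ancestors per pair; descendant 1 of each pair goes to set A,
#' descendant 2 to set B, under distinct identifier namespaces. Optionally
#' writes the two FASTA files and the truth table.
#'
#' @param n_pairs Number of pairs.
#' @param omega A single dN/dS ratio or one per pair.
#' @param divergence Expected proposed substitutions per site.
#' @param seed Integer seed.
#' @param n_codons Codons per ancestor (default 200).
#' @param dir Optional output directory; when given, writes `set_a.fasta`,
#'   `set_b.fasta` and `truth.tsv` there.
#' @return List with named sequence vectors `seqs_a`, `seqs_b` and a `truth`
#'   data frame (intended pairing, omega, realized substitution counts).
#' @export
simulate_homolog_set <- function(n_pairs, omega, divergence, seed,
                                 n_codons = 200L, dir = NULL) {
  stopifnot(n_pairs >= 1)
  omega <- rep_len(omega, n_pairs)
  seqs_a <- character(n_pairs)
  seqs_b <- character(n_pairs)
  truth <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    anc <- simulate_cds(n_codons, seed + 1000L * i)
    ev <- evolve_pair(anc, omega[[i]], divergence, seed + 1000L * i + 1L)
    seqs_a[[i]] <- ev$desc1
    seqs_b[[i]] <- ev$desc2
    truth[[i]] <- data.frame(
      id_a = sprintf("spA_%04d", i), id_b = sprintf("spB_%04d", i),
      omega = omega[[i]],
      n_syn = sum(ev$truth$n_syn), n_nonsyn = sum(ev$truth$n_nonsyn),
      n_proposed = sum(ev$truth$n_proposed), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  names(seqs_a) <- truth$id_a
  names(seqs_b) <- truth$id_b
  out <- list(seqs_a = seqs_a, seqs_b = seqs_b, truth = truth, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(seqs_a, file.path(dir, "set_a.fasta"))
    write_fasta(seqs_b, file.path(dir, "set_b.fasta"))
    write_tsv(truth, file.path(dir, "truth.tsv"))
    out$dir <- dir
  }
  out
}

#' Printed-model coefficient presets for the decoupling generator
#'
#' Effect sizes on the scale of the default (`"methods"`) transform profile:
#' response `log(Ka/Ks)`; log-transformed overall expression and bias
#' covariates; raw lengths and tissue counts. `"congeneric"` carries the
#' effect sizes of the close-species comparison (n = 761 scale, adjusted
#' r-squared 0.105); `"distant"` those of the 100-Myr comparison (n = 249
#' scale, adjusted r-squared 0.150). The intercept is set so the typical
#' ratio is deep in the purifying range.
#'
#' @param comparison `"congeneric"` or `"distant"`.
#' @return List with `coefficients` (named, in [fit_decoupling_glm()] term
#'   order plus `intercept`), `n` and `target_adj_r2`.
#' @export
decoupling_sim_defaults <- function(comparison = c("congeneric", "distant")) {
  comparison <- match.arg(comparison)
  if (comparison == "congeneric") {
    list(coefficients = c(intercept = -2.7, overall_expression = -0.013,
                          aln_length = -0.0008, sequence_length = -0.0002,
                          n_tissues = 0.0192, sex_biased_expression = 0.201,
                          morph_biased_expression = 0.230,
                          morph_x_sex = 0.0917),
         n = 761L, target_adj_r2 = 0.105)
  } else {
    list(coefficients = c(intercept = -2.7, overall_expression = 0.0263,
                          aln_length = -0.0007, sequence_length = 0.0001,
                          n_tissues = 0.0434, sex_biased_expression = 0.315,
                          morph_biased_expression = 0.384,
                          morph_x_sex = 0.144),
         n = 249L, target_adj_r2 = 0.150)
  }
}

#' Simulate an expression table with a known decoupling signal
#'
#' Covariates: log-normal overall expression and sex/morph biases
#' (`log ~ N(3, 1)` and `N(0, 1)` respectively), uniform-integer tissue
#' counts 1-11, uniform sequence lengths 150-3000 bp with alignment lengths
#' uniform between 150 and the sequence length. The true `log(Ka/Ks)` is the
#' linear predictor under the given coefficients plus Gaussian noise; the
#' observed `ratio` column is its exponential. When `noise_sd` is `NULL` it
#' is calibrated from the realized linear predictor so that the model's
#' expected adjusted r-squared is `target_adj_r2`.
#'
#' @param n_genes Number of genes (well above the model's term count).
#' @param coefficients Named coefficient vector as in
#'   [decoupling_sim_defaults()] (its `"congeneric"` set is the default).
#' @param noise_sd Gaussian noise standard deviation, or `NULL` to calibrate.
#' @param seed Integer seed.
#' @param target_adj_r2 Calibration target used when `noise_sd` is `NULL`.
#' @param horn_biased_frac Fraction of genes flagged horn-biased (flags are
#'   assigned at random and carry no effect on the simulated ratio).
#' @return List with `table` (columns `gene_id`, `overall_expression`,
#'   `sex_bias`, `morph_bias`, `n_tissues`, `sequence_length`, `aln_length`,
#'   `horn_biased`, `ratio`) and `truth` (`coefficients`, `noise_sd`,
#'   `true_log_ratio`, `seed`).
#' @export
simulate_expression_table <- function(n_genes,
                                      coefficients = decoupling_sim_defaults("congeneric")$coefficients,
                                      noise_sd = NULL, seed = 1L,
                                      target_adj_r2 = 0.105,
                                      horn_biased_frac = 0) {
  stopifnot(n_genes > length(coefficients) + 10L)
  with_local_seed(seed, {
    log_overall <- stats::rnorm(n_genes, 3, 1)
    log_sex <- stats::rnorm(n_genes, 0, 1)
    log_morph <- stats::rnorm(n_genes, 0, 1)
    n_tissues <- sample(1:11, n_genes, replace = TRUE)
    sequence_length <- round(stats::runif(n_genes, 150, 3000))
    aln_length <- round(stats::runif(n_genes, 150, sequence_length))
    b <- coefficients
    lp <- b[["intercept"]] +
      b[["overall_expression"]] * log_overall +
      b[["aln_length"]] * aln_length +
      b[["sequence_length"]] * sequence_length +
      b[["n_tissues"]] * n_tissues +
      b[["sex_biased_expression"]] * log_sex +
      b[["morph_biased_expression"]] * log_morph +
      b[["morph_x_sex"]] * log_morph * log_sex
    if (is.null(noise_sd)) {
      noise_sd <- stats::sd(lp) * sqrt((1 - target_adj_r2) / target_adj_r2)
    }
    true_log_ratio <- lp + stats::rnorm(n_genes, 0, noise_sd)
    tab <- data.frame(
      gene_id = sprintf("gene_%05d", seq_len(n_genes)),
      overall_expression = exp(log_overall),
      sex_bias = exp(log_sex), morph_bias = exp(log_morph),
      n_tissues = n_tissues, sequence_length = sequence_length,
      aln_length = aln_length,
      horn_biased = stats::runif(n_genes) < horn_biased_frac,
      ratio = exp(true_log_ratio), stringsAsFactors = FALSE)
    list(table = tab,
         truth = list(coefficients = coefficients, noise_sd = noise_sd,
                      true_log_ratio = true_log_ratio, seed = seed))
  })
}

#' Simulate a base-count pileup with planted SNPs
#'
#' Every contig position receives `depth` base observations. A planted
#' position gets `round(depth * target_maf)` minor-base counts — exactly,
#' when `error_rate` is 0. With `error_rate > 0`, every other read miscalls
#' independently with that probability, uniformly over the three other
#' bases. The truth records, per planted SNP, the realized minor count and
#' whether it is expected to pass each tier given the supplied contig's
#' flanks and homopolymer runs.
#'
#' @param contig A single DNA string (reference).
#' @param planted Data frame with columns `pos`, `minor_base`, `target_maf`
#'   (positions distinct and within the contig; planting inside a
#'   homopolymer is allowed, to exercise the exclusion rule, and flagged).
#' @param depth Reads per position.
#' @param error_rate Per-read miscall probability (default 0).
#' @param seed Integer seed.
#' @param tiers,min_flank,max_homopolymer Thresholds used to annotate the
#'   truth (must match the later [call_snps()] settings for truth to apply).
#' @return List with `pileup` (a [read_pileup()]-layout data frame) and
#'   `truth` (planted table plus `minor_count`, `in_homopolymer`,
#'   `flank_ok`, and one `expect_<tier>` column per tier).
#' @export
simulate_pileup <- function(contig, planted, depth, error_rate = 0, seed = 1L,
                            tiers = snp_tiers(), min_flank = 50L,
                            max_homopolymer = 2L) {
  L <- nchar(contig)
  depth <- as.integer(depth)
  stopifnot(all(planted$pos >= 1), all(planted$pos <= L),
            !anyDuplicated(planted$pos), depth >= 1)
  ref <- strsplit(contig, "")[[1]]
  with_local_seed(seed, {
    counts <- matrix(0L, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
    for (p in seq_len(L)) counts[p, ref[[p]]] <- depth
    minor_count <- integer(nrow(planted))
    if (nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        p <- planted$pos[[i]]
        mb <- planted$minor_base[[i]]
        if (mb == ref[[p]]) stop("minor base equals reference at position ", p,
                                 call. = FALSE)
        mc <- as.integer(round(depth * planted$target_maf[[i]]))
        counts[p, ref[[p]]] <- depth - mc
        counts[p, mb] <- mc
        minor_count[[i]] <- mc
      }
    }
    if (error_rate > 0) {
      for (p in seq_len(L)) {
        if (p %in% planted$pos) next
        n_err <- stats::rbinom(1, depth, error_rate)
        if (n_err > 0) {
          errs <- table(sample(setdiff(BASES, ref[[p]]), n_err, replace = TRUE))
          counts[p, ref[[p]]] <- depth - n_err
          counts[p, names(errs)] <- counts[p, names(errs)] + as.integer(errs)
        }
      }
    }
    pileup <- data.frame(contig = "sim_contig", pos = seq_len(L),
                         countA = counts[, "A"], countC = counts[, "C"],
                         countG = counts[, "G"], countT = counts[, "T"],
                         stringsAsFactors = FALSE)
    truth <- planted
    if (nrow(truth)) {
      truth$minor_count <- minor_count
      truth$maf <- minor_count / depth
      truth$in_homopolymer <- vapply(truth$pos, function(p) {
        homopolymer_run_at(contig, p) > max_homopolymer
      }, logical(1))
      truth$flank_ok <- truth$pos - 1L >= min_flank & L - truth$pos >= min_flank
      for (t in seq_len(nrow(tiers))) {
        truth[[paste0("expect_", tiers$tier[t])]] <-
          depth > tiers$min_depth[t] & truth$maf > tiers$min_maf[t] &
          truth$flank_ok & !truth$in_homopolymer
      }
    }
    list(pileup = pileup, truth = truth, seed = seed)
  })
}
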