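# Tiered SNP discovery from per-position base-count pileups over assembly
# contigs: depth and minor-allele-frequency thresholds at three nested
# stringencies, a flanking-distance rule, a homopolymer exclusion targeting
# pyrosequencing error, and transition/transversion classification.

#' SNP stringency tiers
#'
#' Default thresholds: low (depth > 8, MAF > 15%), medium (depth > 12,
#' MAF > 20%), high (depth > 15, MAF > 25%). All inequalities are strict.
#'
#' @param min_depth,min_maf Numeric vectors of per-tier thresholds, named
#'   `low`/`medium`/`high` in increasing stringency.
#' @return Data frame with columns `tier`, `min_depth`, `min_maf`.
#' @export
snp_tiers <- function(min_depth = c(low = 8, medium = 12, high = 15),
                      min_maf = c(low = 0.15, medium = 0.20, high = 0.25)) {
  stopifnot(length(min_depth) == length(min_maf),
            !is.unsorted(min_depth), !is.unsorted(min_maf),
            all(min_depth > 0), all(min_maf > 0))
  data.frame(tier = names(min_depth), min_depth = unname(min_depth),
             min_maf = unname(min_maf), stringsAsFactors = FALSE)
}

#' Read a base-count pileup table
#'
#' Tab-separated with header: `contig`, `pos` (1-based), `countA`, `countC`,
#' `countG`, `countT`.
#'
#' @param path Path to the pileup TSV.
#' @return Data frame of pileup columns.
#' @export
read_pileup <- function(path) {
  df <- read_tsv_strict(path, required = c("contig", "pos", "countA",
                                           "countC", "countG", "countT"))
  df$pos <- as.integer(df$pos)
  for (cl in c("countA", "countC", "countG", "countT")) {
    df[[cl]] <- as.integer(df[[cl]])
    if (any(df[[cl]] < 0)) stop("negative base count in ", path, call. = FALSE)
  }
  df
}

#' Transition or transversion?
#'
#' A <-> G and C <-> T substitutions are transitions; every other base pair
#' is a transversion.
#'
#' @param major,minor Distinct bases.
#' @return `"transition"` or `"transversion"` (vectorised).
#' @export
classify_substitution <- function(major, minor) {
  if (any(major == minor)) stop("identical bases", call. = FALSE)
  purine <- function(b) b %in% c("A", "G")
  ifelse(purine(major) == purine(minor), "transition", "transversion")
}

# Length of the maximal mononucleotide run containing `pos` in `seq`.
homopolymer_run_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  i <- which(ends >= pos)[1]
  r$lengths[i]
}

#' Call SNPs from pileup columns at tiered stringency
#'
#' A pileup column yields a call iff: exactly one minor allele is considered
#' (the second-most-frequent base; columns whose third-most-frequent base
#' exceeds the noise ceiling are rejected as multi-allelic); depth and minor
#' allele frequency strictly exceed at least the lowest tier's thresholds;
#' the position has at least `min_flank` bp of contig sequence on each side;
#' and the maximal mononucleotide run of the contig reference containing the
#' position is no longer than `max_homopolymer`. Each call carries every
#' tier whose thresholds it passes; tiers are nested by construction when
#' thresholds are ordered.
#'
#' @param pileup Data frame from [read_pileup()] (columns `contig`, `pos`,
#'   `countA`, `countC`, `countG`, `countT`).
#' @param contigs Named character vector of contig sequences.
#' @param tiers Tier thresholds from [snp_tiers()].
#' @param min_flank Minimum flanking sequence on each side (default 50 bp).
#' @param max_homopolymer Longest tolerated mononucleotide run containing
#'   the site (default 2).
#' @param third_allele_ceiling Function of depth giving the maximum count
#'   tolerated for a third allele (default `max(1, 1% of depth)`).
#' @return Data frame of calls: `contig`, `pos`, `major_base`, `minor_base`,
#'   `depth`, `maf`, one logical column per tier (`tier_low`, ...), `tiers`
#'   (comma-separated labels) and `substitution_class`.
#' @export
call_snps <- function(pileup, contigs, tiers = snp_tiers(), min_flank = 50L,
                      max_homopolymer = 2L,
                      third_allele_ceiling = function(depth) pmax(1, 0.01 * depth)) {
  unknown <- setdiff(unique(pileup$contig), names(contigs))
  if (length(unknown)) {
    stop("pileup references unknown contig(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(pileup))) {
    counts <- c(A = pileup$countA[i], C = pileup$countC[i],
                G = pileup$countG[i], T = pileup$countT[i])
    depth <- sum(counts)
    contig <- pileup$contig[i]
    pos <- pileup$pos[i]
    clen <- nchar(contigs[[contig]])
    if (pos < 1L || pos > clen) {
      stop("pileup position ", pos, " outside contig ", contig, call. = FALSE)
    }
    ord <- order(counts, decreasing = TRUE)
    major <- names(counts)[ord[1]]
    minor <- names(counts)[ord[2]]
    minor_count <- counts[[ord[2]]]
    third_count <- counts[[ord[3]]]
    if (minor_count == 0L) next
    if (third_count > third_allele_ceiling(depth)) next
    maf <- minor_count / depth
    pass <- depth > tiers$min_depth & maf > tiers$min_maf
    if (!any(pass)) next
    if (pos - 1L < min_flank || clen - pos < min_flank) next
    if (homopolymer_run_at(contigs[[contig]], pos) > max_homopolymer) next
    row <- data.frame(contig = contig, pos = pos, major_base = major,
                      minor_base = minor, depth = depth, maf = maf,
                      stringsAsFactors = FALSE)
    for (t in seq_len(nrow(tiers))) {
      row[[paste0("tier_", tiers$tier[t])]] <- pass[t]
    }
    row$tiers <- paste(tiers$tier[pass], collapse = ",")
    row$substitution_class <- classify_substitution(major, minor)
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    out <- data.frame(contig = character(0), pos = integer(0),
                      major_base = character(0), minor_base = character(0),
                      depth = integer(0), maf = numeric(0),
                      stringsAsFactors = FALSE)
    for (t in tiers$tier) out[[paste0("tier_", t)]] <- logical(0)
    out$tiers <- character(0)
    out$substitution_class <- character(0)
    return(out)
  }
  do.call(rbind, rows)
}

#' Per-tier SNP summary
#'
#' Counts, per tier: SNPs, contigs with at least one SNP, transversions and
#' transitions. Transitions + transversions equal the SNP count within each
#' tier by construction.
#'
#' @param calls Call table from [call_snps()].
#' @param tiers Tier thresholds (for tier names/order).
#' @return Data frame with columns `tier`, `n_snps`, `n_contigs`,
#'   `n_transversions`, `n_transitions`.
#' @export
summarize_snps <- function(calls, tiers = snp_tiers()) {
  rows <- lapply(tiers$tier, function(t) {
    col <- paste0("tier_", t)
    sel <- if (nrow(calls)) calls[calls[[col]], , drop = FALSE] else calls
    data.frame(tier = t, n_snps = nrow(sel),
               n_contigs = length(unique(sel$contig)),
               n_transversions = sum(sel$substitution_class == "transversion"),
               n_transitions = sum(sel$substitution_class == "transition"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write SNP calls as minimal VCF v4.2
#'
#' REF is the major allele, ALT the minor; INFO carries `DP` and `AF`
#' (minor-allele frequency); FILTER lists the passed tier labels.
#'
#' @param calls Call table from [call_snps()].
#' @param contigs Named character vector of contig sequences (for header
#'   contig lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(calls, contigs, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
               sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       nchar(contigs)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;AF=%.6g",
                       calls$contig, calls$pos, calls$major_base,
                       calls$minor_base, gsub(",", ";", calls$tiers),
                       calls$depth, calls$maf), con)
  }
  invisible(path)
}
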