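# Nei-Gojobori (1986) Ka/Ks estimation on a codon alignment: fractional
# synonymous/nonsynonymous site counting per codon, pathway-averaged
# substitution counting between codon pairs, Jukes-Cantor correction of the
# proportions, and selection classification of the ratio.
#
# Conventions (standard NG86): a single-nucleotide change that produces a
# stop codon counts as nonsynonymous in site counting; mutational pathways
# that pass through a stop codon are excluded from difference counting (if
# every ordering is excluded, all orderings are used); site totals are
# averaged between the two rows.

.ng_env <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

codon_neighbours <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(BASES, ch[pos])) {
      nb <- ch
      nb[pos] <- b
      out <- c(out, paste(nb, collapse = ""))
    }
  }
  out
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each of the three positions, the synonymous contribution is the
#' fraction of the three possible single-nucleotide changes that preserve
#' the amino acid; changes producing a stop codon count as nonsynonymous.
#' `s + n = 3` exactly for every sense codon.
#'
#' @param codon A sense codon (stop codons are an error).
#' @param code Genetic code.
#' @return Named numeric vector `c(s = , n = )`.
#' @export
#' @examples
#' synonymous_sites("TTT") # s = 1/3
#' synonymous_sites("GGG") # s = 1
synonymous_sites <- function(codon, code = standard_genetic_code()) {
  aa <- code[[codon]]
  if (is.na(aa) || aa == "*") stop("not a sense codon: ", codon, call. = FALSE)
  nb <- codon_neighbours(codon)
  syn <- sum(code[nb] == aa)   # stop neighbours never equal a sense aa
  c(s = syn / 3, n = 3 - syn / 3)
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Pathway-averaged substitution counts between two codons
#'
#' When the codons differ at `k` positions, classifies the `k` single-base
#' steps as synonymous or nonsynonymous along each of the `k!` orderings and
#' averages; orderings passing through a stop codon are excluded (with a
#' fallback to all orderings when every one is excluded). `sd + nd = k`
#' exactly.
#'
#' @param codon1,codon2 Sense codons.
#' @param code Genetic code.
#' @return Named numeric vector `c(sd = , nd = )`.
#' @export
#' @examples
#' pathway_diffs("TTT", "TTC") # one synonymous step
#' pathway_diffs("TTT", "GTA") # two pathways, one through a stop-free route
pathway_diffs <- function(codon1, codon2, code = standard_genetic_code()) {
  for (cd in c(codon1, codon2)) {
    aa <- code[[cd]]
    if (is.na(aa) || aa == "*") stop("not a sense codon: ", cd, call. = FALSE)
  }
  c1 <- strsplit(codon1, "")[[1]]
  c2 <- strsplit(codon2, "")[[1]]
  diff_pos <- which(c1 != c2)
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  syn_counts <- numeric(0)
  through_stop <- logical(0)
  for (ord in permutations_of(diff_pos)) {
    cur <- c1
    syn <- 0
    stopped <- FALSE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- c2[pos]
      cur_codon <- paste(cur, collapse = "")
      nxt_codon <- paste(nxt, collapse = "")
      if (code[[nxt_codon]] == "*") stopped <- TRUE
      if (code[[nxt_codon]] == code[[cur_codon]]) syn <- syn + 1
      cur <- nxt
    }
    syn_counts <- c(syn_counts, syn)
    through_stop <- c(through_stop, stopped)
  }
  use <- if (all(through_stop)) rep(TRUE, length(syn_counts)) else !through_stop
  sd <- mean(syn_counts[use])
  c(sd = sd, nd = k - sd)
}

# Cached per-codon site counts and 64x64 pathway tables for the standard
# code; built once per session.
ng_tables <- function(code = standard_genetic_code()) {
  if (!is.null(.ng_env$tables)) return(.ng_env$tables)
  codons <- names(code)
  sense <- codons[code != "*"]
  s_sites <- stats::setNames(rep(NA_real_, 64), codons)
  for (cd in sense) s_sites[[cd]] <- synonymous_sites(cd, code)[["s"]]
  sd_mat <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  k_mat <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  for (a in sense) {
    for (b in sense) {
      pd <- pathway_diffs(a, b, code)
      sd_mat[a, b] <- pd[["sd"]]
      k_mat[a, b] <- pd[["sd"]] + pd[["nd"]]
    }
  }
  .ng_env$tables <- list(s_sites = s_sites, sd = sd_mat, k = k_mat)
  .ng_env$tables
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) ln(1 - (4/3) p)`; undefined (returned as `NA`, the saturation
#' signal) for `p >= 0.75`.
#'
#' @param p Proportion of observed differences per site, `p >= 0`.
#' @return Corrected substitutions per site, or `NA_real_` when saturated.
#' @export
jukes_cantor <- function(p) {
  stopifnot(all(p >= 0))
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori Ka/Ks estimate for a codon alignment
#'
#' Computes fractional site totals (`S`, `N`, averaged over the two rows),
#' pathway-averaged difference totals (`Sd`, `Nd`), proportions
#' (`pS = Sd/S`, `pN = Nd/N`), Jukes-Cantor distances (`Ks`, `Ka`) and the
#' `Ka/Ks` ratio, over the ungapped columns of a cleaned codon alignment.
#'
#' Status values: `"ok"`; `"ks_zero"` when `Ks = 0` (ratio reported `NA`,
#' mirroring how such homologue pairs are tabulated); `"saturated_s"` /
#' `"saturated_n"` when a proportion reaches the Jukes-Cantor domain
#' boundary 0.75; `"empty"` when there are no ungapped columns. The ratio is
#' 0 when `Ka = 0` with `Ks > 0`.
#'
#' @param aln A cleaned `codon_alignment` (no stop or nonsense codons).
#' @param code Genetic code.
#' @return Object of class `kaks_estimate`: list with `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `Ks`, `Ka`, `ratio`, `status`, `n_ungapped`, `aln_len_bp`.
#' @export
kaks <- function(aln, code = standard_genetic_code()) {
  tabs <- ng_tables(code)
  keep <- aln$codons_a != "---" & aln$codons_b != "---"
  ca <- aln$codons_a[keep]
  cb <- aln$codons_b[keep]
  est <- list(S = 0, N = 0, Sd = 0, Nd = 0, pS = NA_real_, pN = NA_real_,
              Ks = NA_real_, Ka = NA_real_, ratio = NA_real_,
              status = "empty", n_ungapped = length(ca),
              aln_len_bp = 3L * length(ca))
  class(est) <- "kaks_estimate"
  if (!length(ca)) return(est)
  sa <- tabs$s_sites[ca]
  sb <- tabs$s_sites[cb]
  if (anyNA(sa) || anyNA(sb)) {
    stop("alignment contains stop or nonsense codons; run ",
         "remove_stop_and_nonsense() first", call. = FALSE)
  }
  est$S <- (sum(sa) + sum(sb)) / 2
  est$N <- 3 * length(ca) - est$S
  sd_col <- tabs$sd[cbind(ca, cb)]
  k_col <- tabs$k[cbind(ca, cb)]
  est$Sd <- sum(sd_col)
  est$Nd <- sum(k_col - sd_col)
  est$pS <- if (est$S > 0) est$Sd / est$S else 0
  est$pN <- if (est$N > 0) est$Nd / est$N else 0
  if (est$pS >= 0.75) {
    est$status <- "saturated_s"
    return(est)
  }
  if (est$pN >= 0.75) {
    est$status <- "saturated_n"
    return(est)
  }
  est$Ks <- jukes_cantor(est$pS)
  est$Ka <- jukes_cantor(est$pN)
  if (est$Ks == 0) {
    est$status <- "ks_zero"   # ratio undefined, reported NA (Ka may be 0 too)
  } else {
    est$status <- "ok"
    est$ratio <- est$Ka / est$Ks
  }
  est
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf("Ka/Ks estimate [%s]: Ka=%.4g Ks=%.4g ratio=%s (S=%.2f N=%.2f Sd=%.2f Nd=%.2f, %d codons)\n",
              x$status, x$Ka, x$Ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.4g", x$ratio),
              x$S, x$N, x$Sd, x$Nd, x$n_ungapped))
  invisible(x)
}

#' Selection class of a Ka/Ks estimate
#'
#' `positive` iff the estimate is usable and `Ka/Ks > 1`; `purifying` for
#' ratios below 1 (including 0); `neutral` at exactly 1; `undetermined` for
#' saturated, empty or `Ks = 0` estimates.
#'
#' @param est A `kaks_estimate`.
#' @return One of `"positive"`, `"purifying"`, `"neutral"`, `"undetermined"`.
#' @export
classify_selection <- function(est) {
  if (is.na(est$ratio)) return("undetermined")
  if (est$ratio > 1) "positive" else if (est$ratio < 1) "purifying" else "neutral"
}

#' Tabulate Ka/Ks estimates for many pairs
#'
#' @param alns Named list of cleaned `codon_alignment` objects (names become
#'   `pair_id`).
#' @param ids Optional data frame with columns `pair_id`, `id_a`, `id_b`.
#' @param code Genetic code.
#' @return Data frame with one row per pair: identifiers, `aln_len_bp`, the
#'   NG86 quantities, `status` and `selection_class`.
#' @export
kaks_table <- function(alns, ids = NULL, code = standard_genetic_code()) {
  rows <- lapply(names(alns), function(pid) {
    est <- kaks(alns[[pid]], code)
    data.frame(pair_id = pid, aln_len_bp = est$aln_len_bp,
               S = est$S, N = est$N, Sd = est$Sd, Nd = est$Nd,
               pS = est$pS, pN = est$pN, Ka = est$Ka, Ks = est$Ks,
               ratio = est$ratio, status = est$status,
               selection_class = classify_selection(est),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(ids)) out <- merge(ids, out, by = "pair_id", sort = FALSE)
  out
}
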