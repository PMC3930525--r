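# Six-frame translated search and reciprocal-best-hit pairing: a desk-scale
# stand-in for a translated BLAST (tBLASTx-style) screen between two
# transcript sets. Scores use BLOSUM62 with affine gaps 11/1; E-values use the
# Karlin-Altschul form with fixed gapped-BLOSUM62 constants and are an
# approximation (a raw-score threshold may be used instead).

KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Protein scoring scheme for translated searches
#'
#' BLOSUM62 with affine gap penalties, adjusted for translated-search use:
#' `*` (stop) scores -4 against everything and `X` (untranslatable codon)
#' scores 0 against everything.
#'
#' @param gap_open,gap_extend Affine gap penalties (positive costs); a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @return A list with elements `matrix`, `gap_open`, `gap_extend`.
#' @export
blosum62_scoring <- function(gap_open = 11, gap_extend = 1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  m["*", ] <- -4
  m[, "*"] <- -4
  m["X", ] <- 0
  m[, "X"] <- 0
  list(matrix = m, gap_open = gap_open, gap_extend = gap_extend)
}

check_scoring_covers <- function(scoring, ...) {
  letters_seen <- unique(strsplit(paste0(..., collapse = ""), "")[[1]])
  missing <- setdiff(letters_seen, rownames(scoring$matrix))
  if (length(missing)) {
    stop("scoring matrix lacks residue(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Optimal local protein alignment
#'
#' Smith-Waterman optimum under affine gap penalties (via
#' `Biostrings::pairwiseAlignment`). The score is never negative; an empty
#' alignment with score 0 is possible when no residue pair scores positively.
#'
#' @param p1,p2 Protein strings (may contain `*` and `X`).
#' @param scoring Scoring scheme from [blosum62_scoring()].
#' @return List with `score`, aligned strings `aln1`/`aln2`, and 1-based
#'   residue coordinates `start1`, `end1`, `start2`, `end2` (0s when empty).
#' @export
local_align_protein <- function(p1, p2, scoring = blosum62_scoring()) {
  stopifnot(nzchar(p1), nzchar(p2))
  check_scoring_covers(scoring, p1, p2)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = scoring$matrix, gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend, type = "local")
  sc <- BiocGenerics::score(al)
  a1 <- as.character(Biostrings::pattern(al))
  a2 <- as.character(Biostrings::subject(al))
  if (sc <= 0 || !nzchar(a1)) {
    return(list(score = max(sc, 0), aln1 = "", aln2 = "",
                start1 = 0L, end1 = 0L, start2 = 0L, end2 = 0L,
                n_match = 0L))
  }
  list(score = sc, aln1 = a1, aln2 = a2,
       start1 = BiocGenerics::start(Biostrings::pattern(al)),
       end1 = BiocGenerics::end(Biostrings::pattern(al)),
       start2 = BiocGenerics::start(Biostrings::subject(al)),
       end2 = BiocGenerics::end(Biostrings::subject(al)),
       n_match = Biostrings::nmatch(al))
}

# All six frame translations of a DNA string, dropping empty frames.
six_frames <- function(seq, code) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  prots <- vapply(frames, function(f) translate_frame(seq, f, code), character(1))
  keep <- nzchar(prots)
  list(frames = frames[keep], proteins = prots[keep])
}

# Map aligned residue coordinates in frame `f` back to 1-based nucleotide
# coordinates on the original (unreversed) strand.
residue_to_nt <- function(rstart, rend, frame, nt_len) {
  off <- abs(frame)
  o_start <- off + 3L * (rstart - 1L)
  o_end <- off + 3L * rend - 1L
  if (frame > 0) c(o_start, o_end) else c(nt_len - o_end + 1L, nt_len - o_start + 1L)
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             qframe = integer(0), sframe = integer(0),
             qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0),
             raw_score = numeric(0), bitscore = numeric(0), evalue = numeric(0),
             aln_len_aa = integer(0), pident = numeric(0),
             stringsAsFactors = FALSE)
}

#' Six-frame translated search between transcript sets
#'
#' For every query/subject pair, all 36 query-frame x subject-frame
#' combinations are scored by local protein alignment and the single best
#' combination (one HSP per pair) is retained if it passes the reporting
#' threshold. Residue coordinates are mapped back to 1-based nucleotide
#' coordinates on the original strands.
#'
#' E-values use `E = K * m * n * exp(-lambda * S)` with fixed gapped-BLOSUM62
#' constants (`K = 0.041`, `lambda = 0.267`), `m` and `n` being the summed
#' protein frame lengths of query and subject; bit scores are
#' `(lambda * S - ln K) / ln 2`.
#'
#' @param queries,subjects Named character vectors of DNA sequences.
#' @param scoring Scoring scheme from [blosum62_scoring()].
#' @param max_evalue Report a hit only if its E-value is below this (default
#'   `1e-5`, the study-style threshold). Set `NULL` to disable.
#' @param min_score Alternative raw-score threshold (`NULL` to disable).
#' @param code Genetic code.
#' @return Data frame of hits sorted by descending raw score, ties broken by
#'   `(subject_id, qframe, sframe)`.
#' @export
translated_search <- function(queries, subjects, scoring = blosum62_scoring(),
                              max_evalue = 1e-5, min_score = NULL,
                              code = standard_genetic_code()) {
  stopifnot(is.character(queries), is.character(subjects))
  if (!length(subjects)) return(empty_hits())
  if (is.null(names(queries)) || is.null(names(subjects))) {
    stop("queries and subjects must be named", call. = FALSE)
  }
  sub_frames <- lapply(subjects, six_frames, code = code)
  sub_mn <- vapply(sub_frames, function(fr) sum(nchar(fr$proteins)), numeric(1))
  rows <- vector("list", 0L)
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi]
    qfr <- six_frames(queries[[qi]], code)
    if (!length(qfr$frames)) next
    q_aa <- Biostrings::AAStringSet(qfr$proteins)
    m <- sum(nchar(qfr$proteins))
    for (si in seq_along(subjects)) {
      sid <- names(subjects)[si]
      sfr <- sub_frames[[si]]
      if (!length(sfr$frames)) next
      best <- NULL
      for (sfi in seq_along(sfr$frames)) {
        scores <- Biostrings::pairwiseAlignment(
          q_aa, Biostrings::AAString(sfr$proteins[[sfi]]),
          substitutionMatrix = scoring$matrix, gapOpening = scoring$gap_open,
          gapExtension = scoring$gap_extend, type = "local", scoreOnly = TRUE)
        qbest <- which.max(scores)
        if (is.null(best) || scores[qbest] > best$score) {
          best <- list(score = scores[qbest], qfi = qbest, sfi = sfi)
        }
      }
      if (is.null(best) || best$score <= 0) next
      evalue <- KA_K * m * sub_mn[[si]] * exp(-KA_LAMBDA * best$score)
      if (!is.null(max_evalue) && evalue > max_evalue) next
      if (!is.null(min_score) && best$score < min_score) next
      al <- local_align_protein(qfr$proteins[[best$qfi]],
                                sfr$proteins[[best$sfi]], scoring)
      if (al$score <= 0) next
      qf <- qfr$frames[[best$qfi]]
      sf <- sfr$frames[[best$sfi]]
      qnt <- residue_to_nt(al$start1, al$end1, qf, nchar(queries[[qi]]))
      snt <- residue_to_nt(al$start2, al$end2, sf, nchar(subjects[[si]]))
      aln_len <- nchar(al$aln1)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qid, subject_id = sid, qframe = qf, sframe = sf,
        qstart = qnt[1], qend = qnt[2], sstart = snt[1], send = snt[2],
        raw_score = al$score,
        bitscore = (KA_LAMBDA * al$score - log(KA_K)) / log(2),
        evalue = evalue, aln_len_aa = aln_len,
        pident = 100 * al$n_match / aln_len,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits[order(-hits$raw_score, hits$subject_id, hits$qframe, hits$sframe), ,
       drop = FALSE]
}

# Best subject per query; ties between distinct subjects drop the query.
best_by_query <- function(hits) {
  dropped <- character(0)
  best <- list()
  for (qid in unique(hits$query_id)) {
    h <- hits[hits$query_id == qid, , drop = FALSE]
    top <- max(h$raw_score)
    at_top <- unique(h$subject_id[h$raw_score == top])
    if (length(at_top) > 1L) {
      dropped <- c(dropped, qid)
      next
    }
    hh <- h[h$raw_score == top & h$subject_id == at_top, , drop = FALSE]
    best[[qid]] <- hh[1L, , drop = FALSE]
  }
  list(best = best, dropped = dropped)
}

#' Reciprocal-best-hit homologue pairing
#'
#' Emits a pair `(a, b)` iff `b` is `a`'s single best subject in `hits_ab`
#' and `a` is `b`'s single best subject in `hits_ba`. An exact raw-score tie
#' between distinct best subjects drops the sequence from pairing (with a
#' warning). The result is a matching: no identifier occurs twice.
#'
#' @param hits_ab,hits_ba Hit tables from [translated_search()] (or
#'   [read_tabular_hits()]), computed with the same scoring.
#' @param max_evalue,min_score Optional additional thresholds applied to both
#'   tables before pairing.
#' @return Data frame of pairs with columns `pair_id`, `id_a`, `id_b`,
#'   `score_ab`, `score_ba` and the `hit_ab` coordinates/frames used by
#'   downstream trimming (`qframe`, `sframe`, `qstart`, `qend`, `sstart`,
#'   `send`). Attribute `dropped_ties` lists identifiers dropped for ties.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, max_evalue = NULL,
                                 min_score = NULL) {
  filt <- function(h) {
    if (!is.null(max_evalue)) h <- h[h$evalue <= max_evalue, , drop = FALSE]
    if (!is.null(min_score)) h <- h[h$raw_score >= min_score, , drop = FALSE]
    h
  }
  hits_ab <- filt(hits_ab)
  hits_ba <- filt(hits_ba)
  out <- data.frame(pair_id = character(0), id_a = character(0),
                    id_b = character(0), score_ab = numeric(0),
                    score_ba = numeric(0), qframe = integer(0),
                    sframe = integer(0), qstart = integer(0), qend = integer(0),
                    sstart = integer(0), send = integer(0),
                    stringsAsFactors = FALSE)
  if (!nrow(hits_ab) || !nrow(hits_ba)) return(out)
  ab <- best_by_query(hits_ab)
  ba <- best_by_query(hits_ba)
  if (length(c(ab$dropped, ba$dropped))) {
    warning("dropped for exact best-hit score ties: ",
            paste(unique(c(ab$dropped, ba$dropped)), collapse = ", "),
            call. = FALSE)
  }
  rows <- list()
  for (qid in names(ab$best)) {
    hab <- ab$best[[qid]]
    sid <- hab$subject_id
    hba <- ba$best[[sid]]
    if (is.null(hba) || hba$subject_id != qid) next
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = paste0(qid, "|", sid), id_a = qid, id_b = sid,
      score_ab = hab$raw_score, score_ba = hba$raw_score,
      qframe = hab$qframe, sframe = hab$sframe,
      qstart = hab$qstart, qend = hab$qend,
      sstart = hab$sstart, send = hab$send,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(out)
  res <- do.call(rbind, rows)
  attr(res, "dropped_ties") <- unique(c(ab$dropped, ba$dropped))
  res[order(res$id_a), , drop = FALSE]
}

#' Read a BLAST-style tabular hit file
#'
#' Reads 12-column tab-separated hits (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), plus two optional
#' trailing columns giving query and subject frames. When frame columns are
#' absent, minus orientation is inferred from `start > end` coordinate pairs
#' (coordinates are normalised so start <= end and the frame recorded as -1,
#' the exact frame index being unknown; plus orientation records +1). Raw
#' scores are back-computed from the bit score.
#'
#' @param path Path to a tab-separated hit file without a header row.
#' @return Hit data frame in the layout of [translated_search()].
#' @export
read_tabular_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_hits())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (!length(f) %in% c(12L, 14L)) {
      stop_with_line(sprintf("expected 12 or 14 tab-separated columns, found %d",
                             length(f)), i)
    }
    qstart <- as.integer(f[7]); qend <- as.integer(f[8])
    sstart <- as.integer(f[9]); send <- as.integer(f[10])
    if (length(f) == 14L) {
      qframe <- as.integer(f[13]); sframe <- as.integer(f[14])
    } else {
      qframe <- if (qstart > qend) -1L else 1L
      sframe <- if (sstart > send) -1L else 1L
    }
    bits <- as.numeric(f[12])
    data.frame(query_id = f[1], subject_id = f[2],
               qframe = qframe, sframe = sframe,
               qstart = min(qstart, qend), qend = max(qstart, qend),
               sstart = min(sstart, send), send = max(sstart, send),
               raw_score = (bits * log(2) + log(KA_K)) / KA_LAMBDA,
               bitscore = bits, evalue = as.numeric(f[11]),
               aln_len_aa = as.integer(f[4]), pident = as.numeric(f[3]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
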