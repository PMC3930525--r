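# From a reciprocally-paired hit to a clean in-frame codon alignment:
# trim both sequences to the overlapping hit region (snapped to codon
# boundaries of the hit frame), translate, align the proteins globally,
# thread the source codons back through the protein alignment, delete
# stop/nonsense columns, and apply the minimum-length filter.

#' Trim a homologue pair to its overlapping hit region
#'
#' Cuts each sequence to the hit coordinates of the A->B hit, re-orients it
#' to the hit frame's strand, then advances the start and recedes the end to
#' the nearest codon boundary of that frame (never extending beyond the hit).
#'
#' @param pair One row of a [reciprocal_best_hits()] table (or any list with
#'   `pair_id`, `qframe`, `sframe`, `qstart`, `qend`, `sstart`, `send`).
#' @param seq_a,seq_b The DNA sequences referenced by the pair.
#' @return List with in-frame fragments `cds_a`, `cds_b` (lengths divisible
#'   by 3), `pair_id` and an `origin` record; or an empty object of class
#'   `pair_discard` with attribute `reason = "short_after_snap"` when a
#'   region is shorter than one codon.
#' @export
trim_to_overlap <- function(pair, seq_a, seq_b) {
  cut_one <- function(seq, start, end, frame) {
    L <- nchar(seq)
    if (start < 1L || end > L || start > end) {
      stop("hit coordinates out of bounds for sequence of length ", L,
           call. = FALSE)
    }
    if (frame > 0) {
      oriented <- seq; os <- start; oe <- end
    } else {
      oriented <- reverse_complement(seq)
      os <- L - end + 1L; oe <- L - start + 1L
    }
    off <- abs(frame)
    p <- os + ((off - os) %% 3L)
    len <- ((oe - p + 1L) %/% 3L) * 3L
    if (len < 3L) return(NULL)
    substring(oriented, p, p + len - 1L)
  }
  cds_a <- cut_one(seq_a, pair$qstart, pair$qend, pair$qframe)
  cds_b <- cut_one(seq_b, pair$sstart, pair$send, pair$sframe)
  if (is.null(cds_a) || is.null(cds_b)) {
    return(structure(list(), class = "pair_discard", reason = "short_after_snap"))
  }
  list(cds_a = cds_a, cds_b = cds_b, pair_id = pair$pair_id,
       origin = list(qframe = pair$qframe, sframe = pair$sframe,
                     qstart = pair$qstart, qend = pair$qend,
                     sstart = pair$sstart, send = pair$send))
}

#' Optimal global protein alignment
#'
#' Needleman-Wunsch optimum under affine gap penalties (via
#' `Biostrings::pairwiseAlignment`, type `"global"`: end gaps are penalised).
#'
#' @param p1,p2 Non-empty protein strings.
#' @param scoring Scoring scheme from [blosum62_scoring()].
#' @return List with equal-length gapped strings `aln1`, `aln2` and `score`.
#' @export
protein_align_global <- function(p1, p2, scoring = blosum62_scoring()) {
  stopifnot(nzchar(p1), nzchar(p2))
  check_scoring_covers(scoring, p1, p2)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = scoring$matrix, gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend, type = "global")
  list(aln1 = as.character(Biostrings::alignedPattern(al)),
       aln2 = as.character(Biostrings::alignedSubject(al)),
       score = BiocGenerics::score(al))
}

#' Construct a codon alignment from two codon-column vectors
#'
#' Each element is a codon (`"NNN"`) or the gap column `"---"`; a column may
#' not be gap in both rows.
#'
#' @param codons_a,codons_b Equal-length character vectors of codon columns.
#' @return A `codon_alignment` object.
#' @export
new_codon_alignment <- function(codons_a, codons_b) {
  stopifnot(length(codons_a) == length(codons_b))
  if (any(codons_a == "---" & codons_b == "---")) {
    stop("codon alignment column is gap in both rows", call. = FALSE)
  }
  structure(list(codons_a = codons_a, codons_b = codons_b),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", length(x$codons_a), "columns,",
      n_ungapped(x), "ungapped (", aln_len_bp(x), "bp )\n")
  invisible(x)
}

#' Codon-alignment column accessors
#'
#' `n_ungapped()` counts columns where neither row is a gap; `aln_len_bp()`
#' is three times that count (the comparable length entering the Ka/Ks
#' minimum-length filter).
#'
#' @param aln A codon alignment from [thread_codons()].
#' @return An integer.
#' @export
n_ungapped <- function(aln) {
  sum(aln$codons_a != "---" & aln$codons_b != "---")
}

#' @rdname n_ungapped
#' @export
aln_len_bp <- function(aln) 3L * n_ungapped(aln)

#' Thread codons through a protein alignment
#'
#' Replaces each residue column of a gapped protein alignment by the source
#' codon of the corresponding coding fragment (PAL2NAL-style back-threading);
#' gap residues become `---`. The ungapped content of each protein row must
#' equal the frame +1 translation of its fragment.
#'
#' @param aln1,aln2 Equal-length gapped protein strings.
#' @param cds_a,cds_b In-frame nucleotide fragments (lengths divisible by 3).
#' @param code Genetic code.
#' @return A `codon_alignment` object.
#' @export
thread_codons <- function(aln1, aln2, cds_a, cds_b,
                          code = standard_genetic_code()) {
  stopifnot(nchar(aln1) == nchar(aln2),
            nchar(cds_a) %% 3L == 0L, nchar(cds_b) %% 3L == 0L)
  thread_row <- function(aln, cds, label) {
    if (gsub("-", "", aln, fixed = TRUE) != translate_cds(cds, code)) {
      stop("protein row ", label, " does not match the translation of its ",
           "coding fragment", call. = FALSE)
    }
    res <- strsplit(aln, "")[[1]]
    codons <- split_codons(cds)
    out <- rep("---", length(res))
    out[res != "-"] <- codons
    out
  }
  new_codon_alignment(thread_row(aln1, cds_a, "A"), thread_row(aln2, cds_b, "B"))
}

#' Delete stop and nonsense codon columns
#'
#' Removes every column in which either row holds a stop codon (TAA, TAG,
#' TGA) or a nonsense codon — any codon containing a character outside
#' `{A,C,G,T}` and therefore untranslatable. Idempotent; may return an empty
#' alignment.
#'
#' @param aln A `codon_alignment`.
#' @return The cleaned `codon_alignment`, with attribute `n_removed`.
#' @export
remove_stop_and_nonsense <- function(aln) {
  bad_codon <- function(codons) {
    codons != "---" & (codons %in% STOP_CODONS | grepl("[^ACGT]", codons))
  }
  bad <- bad_codon(aln$codons_a) | bad_codon(aln$codons_b)
  out <- new_codon_alignment(aln$codons_a[!bad], aln$codons_b[!bad])
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Minimum-alignment-length filter
#'
#' Keeps an alignment only if its comparable length (ungapped columns x 3)
#' reaches `min_bp`; short alignments give unreliable distance estimates
#' (the default asks for 50 or more comparable codons).
#'
#' @param aln A cleaned `codon_alignment`.
#' @param min_bp Minimum comparable length in bp (default 150).
#' @return Logical scalar; when `FALSE` it carries attribute
#'   `reason = "below_min_length"`.
#' @export
filter_min_length <- function(aln, min_bp = 150L) {
  if (aln_len_bp(aln) >= min_bp) TRUE
  else structure(FALSE, reason = "below_min_length")
}

#' Build a clean codon alignment for a coding-fragment pair
#'
#' Convenience chain: translate both in-frame fragments, align the proteins
#' globally (or accept an externally produced protein alignment), thread
#' codons, and delete stop/nonsense columns.
#'
#' @param cds_a,cds_b In-frame nucleotide fragments.
#' @param scoring Protein scoring scheme.
#' @param code Genetic code.
#' @param aligned_proteins Optional list with gapped strings `aln1`, `aln2`
#'   from an external aligner; when given, the internal global alignment is
#'   skipped.
#' @return A cleaned `codon_alignment`.
#' @export
codon_align_pair <- function(cds_a, cds_b, scoring = blosum62_scoring(),
                             code = standard_genetic_code(),
                             aligned_proteins = NULL) {
  if (is.null(aligned_proteins)) {
    aligned_proteins <- protein_align_global(translate_cds(cds_a, code),
                                             translate_cds(cds_b, code),
                                             scoring)
  }
  aln <- thread_codons(aligned_proteins$aln1, aligned_proteins$aln2,
                       cds_a, cds_b, code)
  remove_stop_and_nonsense(aln)
}

#' Write a codon alignment as gapped aligned FASTA
#'
#' @param aln A `codon_alignment`.
#' @param ids Character vector of two identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, ids, path) {
  stopifnot(length(ids) == 2L)
  write_fasta(stats::setNames(c(paste(aln$codons_a, collapse = ""),
                                paste(aln$codons_b, collapse = "")), ids),
              path)
}
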