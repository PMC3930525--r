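#' kakspipe: comparative molecular evolution for transcriptome assemblies
#'
#' Tools to pair transcripts between two de novo transcriptome assemblies by
#' reciprocal translated best hits, build clean in-frame codon alignments,
#' estimate Ka/Ks with the Nei-Gojobori (1986) counting method, discover SNPs
#' from base-count pileups at tiered stringency, and test whether sex- and
#' morph-biased gene expression predicts relaxed or positive selection.
#'
#' @keywords internal
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Standard nuclear genetic code
#'
#' Returns the standard genetic code as a named character vector mapping all
#' 64 codons (DNA alphabet) to one-letter amino acids, with `"*"` for the
#' three stop codons (TAA, TAG, TGA).
#'
#' @return Named character vector of length 64.
#' @export
#' @examples
#' code <- standard_genetic_code()
#' code[["ATG"]]
standard_genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code) <- chartr("U", "T", names(code))
  stopifnot(length(code) == 64, sum(code == "*") == 3)
  code
}

stop_with_line <- function(msg, line) {
  stop(sprintf("%s (line %d)", msg, line), call. = FALSE)
}

#' Read a DNA FASTA file
#'
#' Strict FASTA reader for assembly contigs: sequence characters are
#' uppercased and must be in `{A,C,G,T,N}` after case folding; `U` and any
#' other character raise a parse error naming the offending line. Record
#' order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase DNA sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  cur_line <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    s <- paste0(seqs[[length(seqs)]], collapse = "")
    if (!nzchar(s)) stop_with_line(sprintf("empty record '%s'", cur), cur_line)
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      flush()
      id <- strsplit(trimws(substring(line, 2)), "[ \t]")[[1]][1]
      if (is.na(id) || !nzchar(id)) stop_with_line("malformed FASTA header", i)
      if (id %in% ids) stop_with_line(sprintf("duplicate identifier '%s'", id), i)
      ids <- c(ids, id)
      seqs <- c(seqs, "")
      cur <- id
      cur_line <- i
    } else {
      if (is.null(cur)) stop_with_line("sequence data before first header", i)
      chunk <- toupper(gsub("[ \t]", "", line))
      bad <- regmatches(chunk, regexpr(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), chunk))
      if (length(bad) && nzchar(bad)) {
        stop_with_line(sprintf("illegal character '%s' in sequence '%s'", bad, cur), i)
      }
      seqs[[length(seqs)]] <- paste0(seqs[[length(seqs)]], chunk)
    }
  }
  flush()
  if (!length(ids)) stop("no FASTA records found in ", path, call. = FALSE)
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences (DNA or protein).
#' @param path Output path.
#' @param width Line width for wrapped sequence lines (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  stopifnot(is.character(x), !is.null(names(x)), all(nzchar(names(x))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' Watson-Crick reverse complement of DNA strings; `N` maps to `N`.
#'
#' @param x Character vector of uppercase DNA sequences.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), character(1))
}

split_codons <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate one reading frame
#'
#' Translates a DNA sequence in one of the six reading frames. Minus frames
#' translate the reverse complement; `|frame| - 1` leading bases are skipped
#' and any trailing partial codon is dropped. Codons containing `N` translate
#' to `X`; stop codons are rendered `*`.
#'
#' @param seq A single uppercase DNA string.
#' @param frame Integer in `{1, 2, 3, -1, -2, -3}`.
#' @param code Genetic code, as from [standard_genetic_code()].
#' @return A single protein string (possibly empty).
#' @export
#' @examples
#' translate_frame("ATGGCC", 1)
#' translate_frame("TTTATG", -3)
translate_frame <- function(seq, frame, code = standard_genetic_code()) {
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L)) {
    stop("frame must be one of +1, +2, +3, -1, -2, -3", call. = FALSE)
  }
  s <- if (frame < 0) reverse_complement(seq) else seq
  offset <- abs(frame) - 1L
  if (offset >= nchar(s)) return("")
  s <- substring(s, offset + 1L)
  codons <- split_codons(s)
  if (!length(codons)) return("")
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' @rdname translate_frame
#' @details `translate_cds()` is shorthand for frame +1 translation.
#' @export
translate_cds <- function(seq, code = standard_genetic_code()) {
  translate_frame(seq, 1L, code)
}

read_tsv_strict <- function(path, required = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop("missing required column(s) in ", path, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Run body with a temporarily seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}
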