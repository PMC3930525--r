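# Independent oracles used across the suite. Each reimplements the checked
# computation from first principles (literal dynamic programming, literal
# permutation enumeration, literal subset enumeration, refitting), sharing no
# code path with the package.

# Gotoh affine-gap alignment score by exhaustive dynamic programming.
# Gap of length L costs open + L * ext. type "global" penalises end gaps.
oracle_align_score <- function(p1, p2, mat, open, ext,
                               type = c("global", "local")) {
  type <- match.arg(type)
  a <- strsplit(p1, "")[[1]]
  b <- strsplit(p2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in p2 (consumes p1)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in p1 (consumes p2)
  M[1, 1] <- 0
  if (type == "global") {
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      diag_best <- max(M[i, j], X[i, j], Y[i, j])
      sc <- mat[a[i], b[j]] + diag_best
      M[i + 1, j + 1] <- if (type == "local") max(0, sc) else sc
    }
  }
  if (type == "global") {
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  } else {
    max(0, max(M))
  }
}

# Genetic code lookup independent of the package (via seqinr).
oracle_aa <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

oracle_sense_codons <- function() {
  all_codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                  c("T", "C", "A", "G")), 1, paste, collapse = "")
  all_codons[vapply(all_codons, oracle_aa, character(1)) != "*"]
}

# Per-codon synonymous site count by literal neighbour enumeration.
oracle_syn_sites <- function(codon) {
  aa <- oracle_aa(codon)
  syn <- 0
  for (pos in 1:3) {
    for (base in c("A", "C", "G", "T")) {
      if (base == substring(codon, pos, pos)) next
      nb <- codon
      substring(nb, pos, pos) <- base
      if (oracle_aa(nb) == aa) syn <- syn + 1
    }
  }
  syn / 3
}

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(oracle_permutations(v[-i]), function(rest) c(v[i], rest))
  }), recursive = FALSE)
}

# Pathway-averaged synonymous difference count by literal enumeration of the
# k! orderings; orderings through a stop are excluded, with all-excluded
# fallback.
oracle_pathway_sd <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(0)
  syn <- numeric(0)
  stopped <- logical(0)
  for (ord in oracle_permutations(pos)) {
    cur <- c1
    ns <- 0
    hit_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      substring(nxt, p, p) <- substring(c2, p, p)
      if (oracle_aa(nxt) == "*") hit_stop <- TRUE
      if (oracle_aa(nxt) == oracle_aa(cur)) ns <- ns + 1
      cur <- nxt
    }
    syn <- c(syn, ns)
    stopped <- c(stopped, hit_stop)
  }
  if (all(stopped)) mean(syn) else mean(syn[!stopped])
}

# Exact two-sided Mann-Whitney p by literal enumeration of all
# choose(n1 + n2, n1) assignments of the observed values to the first group.
oracle_mw_exact <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  N <- length(v)
  u_of <- function(idx) {
    xs <- v[idx]; ys <- v[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  us <- apply(utils::combn(N, n1), 2, u_of)
  u_obs <- u_of(seq_len(n1))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Partial r-squared by refitting without the term (drop-one SSE comparison).
oracle_partial_r2 <- function(X, term) {
  full <- stats::lm(y ~ ., data = X)
  reduced <- stats::lm(y ~ ., data = X[, setdiff(names(X), term)])
  sse_f <- sum(stats::resid(full)^2)
  sse_r <- sum(stats::resid(reduced)^2)
  (sse_r - sse_f) / sse_r
}

# Random protein string over a reduced alphabet.
random_protein <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
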