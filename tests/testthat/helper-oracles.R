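# Independent oracles and small generators used across the suite.
# These deliberately avoid the package's own code paths: expansion by
# recursion, alignment by exhaustive enumeration, primer matching by
# string scanning of expansions, rarefaction by closed form.

IUPAC_SETS_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# recursive degenerate expansion
oracle_expand <- function(seq) {
  if (nchar(seq) == 0L) return("")
  first <- IUPAC_SETS_ORACLE[[substr(seq, 1L, 1L)]]
  rest <- oracle_expand(substr(seq, 2L, nchar(seq)))
  sort(as.vector(outer(first, rest, paste0)))
}

# exhaustive affine-gap global alignment score by enumerating every
# alignment (ops: M = both, X = gap in b, Y = gap in a); gap runs of
# length L cost gap_open + L * gap_extend
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = -4, gap_extend = -1) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  score_ops <- function(ops) {
    i <- 0L; j <- 0L; s <- 0; prev <- "M"
    for (op in ops) {
      if (op == "M") {
        i <- i + 1L; j <- j + 1L
        s <- s + if (ac[i] == bc[j]) match else mismatch
      } else {
        if (op != prev) s <- s + gap_open
        s <- s + gap_extend
        if (op == "X") i <- i + 1L else j <- j + 1L
      }
      prev <- op
    }
    s
  }
  best <- -Inf
  recurse <- function(i, j, ops) {
    if (i == length(ac) && j == length(bc)) {
      best <<- max(best, score_ops(ops)); return(invisible())
    }
    if (i < length(ac) && j < length(bc)) recurse(i + 1L, j + 1L, c(ops, "M"))
    if (i < length(ac)) recurse(i + 1L, j, c(ops, "X"))
    if (j < length(bc)) recurse(i, j + 1L, c(ops, "Y"))
  }
  recurse(0L, 0L, character(0))
  best
}

# zero-mismatch primer matching by scanning every concrete expansion
# (overlap-safe); returns sorted unique 0-based plus-strand starts for the
# motif and, separately, for its reverse complement
oracle_match_starts <- function(primer, template) {
  m <- nchar(primer); n <- nchar(template)
  scan_exact <- function(expansions) {
    if (m > n) return(integer(0))
    subs <- substring(template, seq_len(n - m + 1L), m:n)
    which(subs %in% expansions) - 1L
  }
  plus <- scan_exact(oracle_expand(primer))
  rc <- degeprimer::reverse_complement(primer)
  minus <- scan_exact(oracle_expand(rc))
  list(plus = as.integer(plus), minus = as.integer(minus))
}

# expected number of OTUs observed in a without-replacement subsample of
# size d from counts n_i (hypergeometric closed form)
oracle_rarefaction <- function(counts, d) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

random_iupac_str <- function(n, letters = names(IUPAC_SETS_ORACLE)) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# small ready-made clade used by several files (kept modest for speed)
small_clade <- function(seed = 11L, n_targets = 10L, insert_length = 150L,
                        ...) {
  generate_clade(clade_spec(n_targets = n_targets, n_nontargets = 3L,
                            insert_length = insert_length, seed = seed, ...))
}

L5_FWD <- "GCTCAGGAYGAACGCYGG"
L5_REV <- "CACCGCTACACATGRADTTC"
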