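# IUPAC nucleotide algebra.
#
# Every letter is backed by a 4-bit mask over {A=1, C=2, G=4, T=8}; two
# letters are compatible iff their masks intersect. All higher-level
# matching (consensus calling, in-silico PCR) reduces to this bit algebra.

IUPAC_BASES <- c(A = 1L, C = 2L, G = 4L, T = 8L)

IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

# mask -> letter (index = mask value)
IUPAC_LETTER <- character(15L)
IUPAC_LETTER[IUPAC_MASK] <- names(IUPAC_MASK)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' IUPAC code lookup table
#'
#' Returns the standard IUPAC nucleotide ambiguity table: for each of the 15
#' one-letter codes, the set of concrete bases it denotes. A code is
#' *degenerate* iff it denotes more than one base.
#'
#' @return A named list mapping each IUPAC letter to a character vector of
#'   concrete bases, e.g. `Y -> c("C","T")`.
#' @examples
#' iupac_table()[["D"]]  # "A" "G" "T"
#' @export
iupac_table <- function() {
  lapply(IUPAC_MASK, function(m) names(IUPAC_BASES)[bitwAnd(m, IUPAC_BASES) > 0L])
}

# Split a sequence string into single letters.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# Encode an IUPAC string (no gaps) as an integer mask vector.
# Invalid letters are reported with their 1-based positions.
encode_iupac <- function(seq, what = "sequence") {
  ch <- seq_chars(toupper(seq))
  m <- IUPAC_MASK[ch]
  if (anyNA(m)) {
    bad <- which(is.na(m))
    stop(sprintf("invalid IUPAC letter(s) %s in %s at position(s) %s",
                 paste(unique(ch[bad]), collapse = ","), what,
                 paste(utils::head(bad, 5L), collapse = ",")), call. = FALSE)
  }
  unname(m)
}

#' Do two IUPAC letters match?
#'
#' Two letters match iff their base sets intersect, i.e. some concrete
#' nucleotide is consistent with both. The relation is symmetric and
#' reflexive; on concrete bases it is plain equality.
#'
#' @param a,b Single IUPAC letters (gaps not allowed).
#' @return Logical scalar.
#' @examples
#' iupac_match("Y", "C")  # TRUE: C is in {C,T}
#' iupac_match("R", "Y")  # FALSE: {A,G} and {C,T} are disjoint
#' @export
iupac_match <- function(a, b) {
  ma <- encode_iupac(a, "letter a")
  mb <- encode_iupac(b, "letter b")
  if (length(ma) != 1L || length(mb) != 1L)
    stop("iupac_match() compares single letters; see match_sites() for strings")
  bitwAnd(ma, mb) > 0L
}

#' Expand a degenerate sequence into its concrete variants
#'
#' Enumerates every plain A/C/G/T sequence consistent with an IUPAC string.
#' The number of expansions is the fold degeneracy (product of per-position
#' base-set sizes); a cap guards against combinatorial blow-up.
#'
#' @param seq IUPAC string without gaps.
#' @param cap Maximum number of expansions allowed (default 1024).
#' @return Character vector of all concrete expansions, each the same length
#'   as `seq`, in lexicographic position order.
#' @examples
#' expand_degenerate("GCTCAGGAYGAACGCYGG")  # 4 sequences (two Y positions)
#' @export
expand_degenerate <- function(seq, cap = 1024L) {
  masks <- encode_iupac(seq)
  sets <- lapply(masks, function(m) names(IUPAC_BASES)[bitwAnd(m, IUPAC_BASES) > 0L])
  fold <- prod(lengths(sets))
  if (fold > cap)
    stop(sprintf("degenerate expansion of %d sequences exceeds cap %d", fold, cap))
  if (length(sets) == 0L) return(character(0))
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out)
}

#' Count degenerate positions and fold degeneracy
#'
#' @param seq IUPAC string without gaps.
#' @return List with `n_degenerate` (number of positions whose code denotes
#'   more than one base) and `fold` (product of base-set sizes over all
#'   positions, i.e. the number of concrete expansions).
#' @examples
#' count_degeneracy("CACCGCTACACATGRADTTC")  # 2 degenerate positions, 6-fold
#' @export
count_degeneracy <- function(seq) {
  masks <- encode_iupac(seq)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, IUPAC_BASES) > 0L), integer(1))
  list(n_degenerate = sum(sizes > 1L), fold = prod(sizes))
}

#' Reverse complement of an IUPAC string
#'
#' Complements honour the full ambiguity table (comp(R)=Y, comp(D)=H,
#' comp(N)=N, ...); applying the function twice returns the input.
#'
#' @param seq IUPAC string without gaps.
#' @return The reverse complement, same length.
#' @examples
#' reverse_complement("AAACCC")  # "GGGTTT"
#' @export
reverse_complement <- function(seq) {
  encode_iupac(seq)  # validates
  ch <- seq_chars(toupper(seq))
  paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
}
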