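# Multiple alignment and per-column profiles.
#
# The aligner is a classic progressive scheme at desk scale: a k-mer
# (k = 6) distance matrix feeds a UPGMA guide tree, and groups are merged
# by affine-gap global profile-profile alignment (compiled DP core in
# src/profile_align.cpp). For large inputs a pre-computed alignment can be
# supplied instead via as_alignment(read_fasta(...)).

#' Construct an alignment object from gapped sequences
#'
#' @param seqs Named character vector of equal-length gapped residue strings.
#' @return An object of class `degealn`: list with `seqs` and `n_columns`.
#' @export
as_alignment <- function(seqs) {
  seqs <- as_seq_set(seqs, attr(seqs, "descriptions"))
  widths <- nchar(seqs)
  if (length(seqs) > 0L && length(unique(widths)) != 1L)
    stop("aligned sequences must all have the same length")
  structure(list(seqs = seqs,
                 n_columns = if (length(seqs)) widths[[1]] else 0L),
            class = "degealn")
}

#' @export
print.degealn <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns\n",
              length(x$seqs), x$n_columns))
  invisible(x)
}

# per-letter profile weights: degenerate letters spread 1/|bases| over
# their bases; '-' goes to the gap row
profile_weights <- function() {
  w <- matrix(0, nrow = 5L, ncol = 16L,
              dimnames = list(c("A", "C", "G", "T", "gap"),
                              c(names(IUPAC_MASK), "-")))
  for (letter in names(IUPAC_MASK)) {
    bases <- names(IUPAC_BASES)[bitwAnd(IUPAC_MASK[[letter]], IUPAC_BASES) > 0L]
    w[bases, letter] <- 1 / length(bases)
  }
  w["gap", "-"] <- 1
  w
}

# 5 x L frequency profile of a character matrix of gapped rows
rows_to_profile <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  prof <- matrix(0, nrow = 5L, ncol = ncol(mat),
                 dimnames = list(rownames(profile_weights()), NULL))
  for (i in seq_len(nrow(mat))) prof <- prof + profile_weights()[, mat[i, ]]
  prof / nrow(mat)
}

kmer_counts <- function(seq, k = 6L) {
  n <- nchar(seq)
  if (n < k) return(table(character(0)))
  table(substring(seq, 1:(n - k + 1L), k:n))
}

kmer_distance_matrix <- function(seqs, k = 6L) {
  counts <- lapply(seqs, kmer_counts, k = k)
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared_keys <- intersect(names(counts[[i]]), names(counts[[j]]))
    shared <- sum(pmin(counts[[i]][shared_keys], counts[[j]][shared_keys]))
    denom <- max(1L, min(nchar(seqs[[i]]), nchar(seqs[[j]])) - k + 1L)
    d[i, j] <- d[j, i] <- 1 - shared / denom
  }
  d
}

# merge two groups of gapped rows along a traceback path
merge_groups <- function(rows_x, rows_y, path) {
  cx <- strsplit(rows_x, "", fixed = TRUE)
  cy <- strsplit(rows_y, "", fixed = TRUE)
  take_x <- path != 3L  # consume an X column on 1 or 2
  take_y <- path != 2L
  ix <- cumsum(take_x)
  iy <- cumsum(take_y)
  out_x <- lapply(cx, function(ch) {
    v <- rep("-", length(path)); v[take_x] <- ch[ix[take_x]]
    paste(v, collapse = "")
  })
  out_y <- lapply(cy, function(ch) {
    v <- rep("-", length(path)); v[take_y] <- ch[iy[take_y]]
    paste(v, collapse = "")
  })
  c(unlist(out_x), unlist(out_y))
}

#' Progressive multiple sequence alignment
#'
#' Aligns ungapped sequences progressively: a k-mer (k = 6) distance matrix
#' drives a UPGMA guide tree, and groups are merged by affine-gap global
#' profile-profile alignment. Deterministic for fixed inputs and
#' parameters; ties in the DP break in a fixed order (diagonal first).
#' A gap run of length L scores `gap_open + L * gap_extend`.
#'
#' Intended for desk-scale jobs (up to a few hundred sequences of a few
#' kb); larger studies should supply an external alignment through
#' [as_alignment()].
#'
#' @param records Named character vector of ungapped sequences (>= 1).
#' @param match,mismatch,gap_open,gap_extend Alignment scores; defaults
#'   +1/-1/-4/-1.
#' @return A `degealn` alignment (row order = input order).
#' @export
align_progressive <- function(records, match = 1, mismatch = -1,
                              gap_open = -4, gap_extend = -1) {
  records <- as_seq_set(records)
  if (any(grepl("-", records, fixed = TRUE)))
    stop("align_progressive() expects ungapped input; use as_alignment() for pre-aligned data")
  n <- length(records)
  if (n == 0L) stop("no sequences to align")
  if (n == 1L) {
    warning("single sequence: returned unchanged as a 1-row alignment")
    return(as_alignment(records))
  }
  groups <- lapply(records, function(s) unname(s))
  ids <- lapply(seq_len(n), function(i) names(records)[i])

  if (n == 2L) {
    merge_order <- matrix(c(-1L, -2L), nrow = 1L)
  } else {
    d <- kmer_distance_matrix(records)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    merge_order <- hc$merge
  }

  cluster_rows <- vector("list", nrow(merge_order))
  cluster_ids <- vector("list", nrow(merge_order))
  fetch <- function(idx) {
    if (idx < 0L) list(rows = groups[[-idx]], ids = ids[[-idx]])
    else list(rows = cluster_rows[[idx]], ids = cluster_ids[[idx]])
  }
  for (s in seq_len(nrow(merge_order))) {
    a <- fetch(merge_order[s, 1L])
    b <- fetch(merge_order[s, 2L])
    res <- .cpp_align_profiles(rows_to_profile(a$rows), rows_to_profile(b$rows),
                               match, mismatch, gap_open, gap_extend)
    cluster_rows[[s]] <- merge_groups(a$rows, b$rows, res$path)
    cluster_ids[[s]] <- c(a$ids, b$ids)
  }
  final_rows <- cluster_rows[[nrow(merge_order)]]
  final_ids <- cluster_ids[[nrow(merge_order)]]
  ord <- match(names(records), final_ids)
  as_alignment(stats::setNames(final_rows[ord], names(records)))
}

#' Global pairwise alignment score
#'
#' Affine-gap Needleman-Wunsch score between two ungapped sequences, under
#' the same scoring convention as [align_progressive()] (a gap run of
#' length L scores `gap_open + L * gap_extend`).
#'
#' @inheritParams align_progressive
#' @param a,b Ungapped sequences.
#' @return Numeric score of the optimal global alignment.
#' @export
pairwise_score <- function(a, b, match = 1, mismatch = -1,
                           gap_open = -4, gap_extend = -1) {
  pa <- rows_to_profile(a)
  pb <- rows_to_profile(b)
  .cpp_align_profiles(pa, pb, match, mismatch, gap_open, gap_extend)$score
}

#' Per-column base profiles of an alignment
#'
#' For every column, the observation counts over A, C, G, T and gap.
#' Degenerate input letters contribute fractionally (1/|bases| to each of
#' their bases), so A+C+G+T+gap always sums to the number of rows; the
#' `other` column additionally records how many observations in the column
#' came from degenerate letters.
#'
#' @param aln A `degealn` alignment.
#' @return data.frame with columns `column` (1-based), `A`, `C`, `G`, `T`,
#'   `gap`, `other`; one row per alignment column.
#' @export
column_profiles <- function(aln) {
  stopifnot(inherits(aln, "degealn"))
  n <- length(aln$seqs)
  mat <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  prof <- matrix(0, nrow = 5L, ncol = aln$n_columns,
                 dimnames = list(rownames(profile_weights()), NULL))
  other <- numeric(aln$n_columns)
  degenerate_letters <- names(IUPAC_MASK)[
    vapply(IUPAC_MASK, function(m) sum(bitwAnd(m, IUPAC_BASES) > 0L), 0L) > 1L]
  for (i in seq_len(n)) {
    prof <- prof + profile_weights()[, mat[i, ]]
    other <- other + (mat[i, ] %in% degenerate_letters)
  }
  data.frame(column = seq_len(aln$n_columns),
             A = prof["A", ], C = prof["C", ], G = prof["G", ],
             T = prof["T", ], gap = prof["gap", ], other = other)
}

#' Minimal degenerate consensus letter of one column profile
#'
#' Returns the smallest IUPAC code whose base set covers every concrete
#' base whose frequency among non-gap observations is at least
#' `min_fraction` (default 0: every observed base must be covered, the
#' strictest setting). Columns containing any gap observation are
#' disqualified for primer design and return `NA`.
#'
#' If `min_fraction` excludes every base (possible up to 0.5 when three or
#' four bases tie), the most frequent base(s) are still included so the
#' consensus is never empty.
#'
#' @param counts Named numeric vector with entries `A`, `C`, `G`, `T`,
#'   `gap` (as one row of [column_profiles()]).
#' @param min_fraction Minimum per-base frequency (0 to 0.5) for inclusion.
#' @return Single IUPAC letter, or `NA_character_` for gap-containing
#'   columns.
#' @export
minimal_degenerate_consensus <- function(counts, min_fraction = 0) {
  stopifnot(min_fraction >= 0, min_fraction <= 0.5)
  counts <- counts[c("A", "C", "G", "T", "gap")]
  if (anyNA(counts)) stop("profile must supply A, C, G, T and gap counts")
  if (sum(counts) == 0) stop("empty column profile")
  if (counts[["gap"]] > 0) return(NA_character_)
  base_counts <- counts[c("A", "C", "G", "T")]
  freqs <- base_counts / sum(base_counts)
  keep <- base_counts > 0 & freqs >= min_fraction
  if (!any(keep)) keep <- freqs == max(freqs)
  mask <- sum(IUPAC_BASES[names(base_counts)[keep]])
  IUPAC_LETTER[mask]
}

#' Consensus letters for every alignment column
#'
#' Vectorized [minimal_degenerate_consensus()] over [column_profiles()];
#' gap-containing columns yield `NA`.
#'
#' @inheritParams column_profiles
#' @inheritParams minimal_degenerate_consensus
#' @return Character vector of length `n_columns` (IUPAC letters or `NA`).
#' @export
consensus_letters <- function(aln, min_fraction = 0) {
  prof <- column_profiles(aln)
  vapply(seq_len(nrow(prof)), function(i) {
    minimal_degenerate_consensus(
      c(A = prof$A[i], C = prof$C[i], G = prof$G[i], T = prof$T[i],
        gap = prof$gap[i]),
      min_fraction = min_fraction)
  }, character(1))
}

#' Export column profiles as TSV
#'
#' @param profiles Result of [column_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
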