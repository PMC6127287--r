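# Degenerate primer design from conserved alignment windows.
#
# Constraint system: primers 17-24 nt with at most two degenerate
# positions, pairs with predicted products > 400 bp, and (by default)
# 100% coverage of the target set at the primer locus with zero
# mismatches. Window enumeration considers every length in
# [min_len, max_len], not only maximal conserved blocks, because primers
# of different lengths at one site are legitimate design alternatives.

#' Primer design constraints
#'
#' @param min_len,max_len Primer length bounds in nt (defaults 17 and 24).
#' @param max_degenerate Maximum number of degenerate positions (default 2).
#' @param min_product Minimum predicted product size in bp; pairs must be
#'   strictly longer (default 400).
#' @param min_target_coverage Minimum fraction of target sequences a
#'   candidate must match full-length with zero mismatches (default 1).
#' @param min_fraction Per-base inclusion threshold for the consensus, see
#'   [minimal_degenerate_consensus()] (default 0: cover all observed bases).
#' @return List of class `design_constraints`.
#' @export
design_constraints <- function(min_len = 17L, max_len = 24L,
                               max_degenerate = 2L, min_product = 400L,
                               min_target_coverage = 1.0, min_fraction = 0) {
  stopifnot(min_len <= max_len, min_len >= 1L, max_degenerate >= 0L,
            min_target_coverage >= 0, min_target_coverage <= 1)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 max_degenerate = as.integer(max_degenerate),
                 min_product = as.integer(min_product),
                 min_target_coverage = min_target_coverage,
                 min_fraction = min_fraction),
            class = "design_constraints")
}

is_degenerate_letter <- function(letters) {
  sizes <- vapply(IUPAC_MASK, function(m) sum(bitwAnd(m, IUPAC_BASES) > 0L), 0L)
  degset <- names(sizes)[sizes > 1L]
  letters %in% degset
}

#' Find conserved primer-design windows in an alignment
#'
#' Enumerates every alignment window whose length lies in
#' `[min_len, max_len]` and whose per-column minimal degenerate consensus
#' (i) contains no gap-disqualified column and (ii) has at most
#' `max_degenerate` degenerate columns. Overlapping windows are allowed and
#' reported in ascending start order (then ascending length).
#'
#' @param aln A `degealn` alignment of the target set.
#' @param constraints A [design_constraints()] object.
#' @return data.frame with `start`, `end` (0-based half-open alignment
#'   columns), `consensus` (IUPAC string) and `n_degenerate`.
#' @export
find_conserved_windows <- function(aln, constraints = design_constraints()) {
  stopifnot(inherits(aln, "degealn"))
  nc <- aln$n_columns
  if (nc < constraints$min_len) {
    warning("alignment shorter than min_len: no windows")
    return(data.frame(start = integer(0), end = integer(0),
                      consensus = character(0), n_degenerate = integer(0)))
  }
  cons <- consensus_letters(aln, min_fraction = constraints$min_fraction)
  bad <- as.integer(is.na(cons))
  deg <- as.integer(!is.na(cons) & is_degenerate_letter(cons))
  cum_bad <- c(0L, cumsum(bad))
  cum_deg <- c(0L, cumsum(deg))
  out <- list()
  for (len in constraints$min_len:min(constraints$max_len, nc)) {
    starts <- 0:(nc - len)                     # 0-based
    n_bad <- cum_bad[starts + len + 1L] - cum_bad[starts + 1L]
    n_deg <- cum_deg[starts + len + 1L] - cum_deg[starts + 1L]
    ok <- n_bad == 0L & n_deg <= constraints$max_degenerate
    if (any(ok)) {
      s <- starts[ok]
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = s + len,
        consensus = vapply(s, function(x)
          paste(cons[(x + 1L):(x + len)], collapse = ""), character(1)),
        n_degenerate = n_deg[ok])
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      consensus = character(0), n_degenerate = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end - res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# zero-mismatch IUPAC comparison of a candidate against each aligned row
# over the window columns; rows are gap-free there by construction
window_coverage <- function(aln, start, end, consensus) {
  cand <- encode_iupac(consensus)
  hits <- vapply(aln$seqs, function(row) {
    sub <- substr(row, start + 1L, end)
    if (grepl("-", sub, fixed = TRUE)) return(FALSE)
    all(bitwAnd(encode_iupac(sub), cand) > 0L)
  }, logical(1))
  mean(hits)
}

# map 0-based alignment column boundaries to ungapped positions on a
# reference row: refpos[c+1] = number of non-gap chars in columns 1..c
reference_map <- function(ref_row) {
  chars <- seq_chars(ref_row)
  c(0L, cumsum(chars != "-"))
}

#' Build primer candidates from conserved windows
#'
#' Each window yields a forward candidate (the consensus 5'->3') and a
#' reverse candidate (its reverse complement, i.e. the primer as ordered
#' for the opposite strand). Target coverage is the fraction of aligned
#' target rows matched full-length with zero mismatches at the window
#' locus; candidates below `min_target_coverage` are dropped. Identical
#' (sequence, orientation) candidates arising from overlapping windows are
#' merged, keeping the widest window.
#'
#' Position labels such as `"15f"` / `"687r"` give the 1-based start of the
#' binding site on the designated reference sequence (by default the first
#' alignment row), following the field's primer naming convention.
#'
#' @param windows Result of [find_conserved_windows()].
#' @param aln The alignment the windows were found in.
#' @param constraints A [design_constraints()] object.
#' @param reference Id of the alignment row used for position labels and
#'   product sizes (default: first row).
#' @return data.frame of candidates: `name`, `position`, `sequence`,
#'   `orientation`, `start`, `end`, `length`, `n_degenerate`, `fold`,
#'   `coverage`, `tm`.
#' @export
make_candidates <- function(windows, aln, constraints = design_constraints(),
                            reference = NULL) {
  stopifnot(inherits(aln, "degealn"))
  if (is.null(reference)) reference <- names(aln$seqs)[1L]
  refmap <- reference_map(aln$seqs[[reference]])
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    cov <- window_coverage(aln, w$start, w$end, w$consensus)
    if (cov < constraints$min_target_coverage) return(NULL)
    deg <- count_degeneracy(w$consensus)
    ref_start <- refmap[w$start + 1L] + 1L     # 1-based on reference
    fwd_pos <- sprintf("%df", ref_start)
    rev_pos <- sprintf("%dr", ref_start)
    data.frame(
      name = c(sprintf("p%s", fwd_pos), sprintf("p%s", rev_pos)),
      position = c(fwd_pos, rev_pos),
      sequence = c(w$consensus, reverse_complement(w$consensus)),
      orientation = c("forward", "reverse"),
      start = w$start, end = w$end,
      length = w$end - w$start,
      n_degenerate = deg$n_degenerate, fold = deg$fold,
      coverage = cov,
      tm = c(estimate_tm(w$consensus),
             estimate_tm(reverse_complement(w$consensus))))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(name = character(0), position = character(0),
                      sequence = character(0), orientation = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), n_degenerate = integer(0),
                      fold = integer(0), coverage = numeric(0),
                      tm = numeric(0)))
  cand <- do.call(rbind, rows)
  # dedupe identical (sequence, orientation): keep the widest window
  key <- paste(cand$sequence, cand$orientation)
  cand <- cand[order(key, -(cand$end - cand$start)), , drop = FALSE]
  cand <- cand[!duplicated(paste(cand$sequence, cand$orientation)), , drop = FALSE]
  cand <- cand[order(cand$start, cand$end, cand$orientation), , drop = FALSE]
  # disambiguate names from distinct windows sharing a reference start
  dup <- duplicated(cand$name) | duplicated(cand$name, fromLast = TRUE)
  cand$name[dup] <- sprintf("%s_%d", cand$name[dup], cand$length[dup])
  rownames(cand) <- NULL
  cand
}

#' Assemble primer pairs passing the product-size filter
#'
#' Considers every forward x reverse combination whose forward window lies
#' entirely upstream of the reverse window, and keeps pairs whose predicted
#' product (measured on the designated ungapped reference between the
#' forward window start and the reverse window end) is strictly longer
#' than `min_product`. Output order is deterministic:
#' (forward start, reverse start).
#'
#' @param candidates Result of [make_candidates()].
#' @param aln The alignment (for reference coordinates).
#' @inheritParams make_candidates
#' @return data.frame of pairs: `name`, `forward`, `reverse`,
#'   `forward_seq`, `reverse_seq`, `product_size`.
#' @export
assemble_pairs <- function(candidates, aln,
                           constraints = design_constraints(),
                           reference = NULL) {
  stopifnot(inherits(aln, "degealn"))
  if (is.null(reference)) reference <- names(aln$seqs)[1L]
  refmap <- reference_map(aln$seqs[[reference]])
  fwd <- candidates[candidates$orientation == "forward", , drop = FALSE]
  rev <- candidates[candidates$orientation == "reverse", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev))) {
    if (rev$start[j] < fwd$end[i]) next
    product <- refmap[rev$end[j] + 1L] - refmap[fwd$start[i] + 1L]
    if (product <= constraints$min_product) next
    out[[length(out) + 1L]] <- data.frame(
      name = sprintf("%s_%s", fwd$name[i], rev$name[j]),
      forward = fwd$name[i], reverse = rev$name[j],
      forward_seq = fwd$sequence[i], reverse_seq = rev$sequence[j],
      forward_start = fwd$start[i], reverse_start = rev$start[j],
      product_size = product)
  }
  if (!length(out)) {
    warning("no primer pairs pass the product-size filter")
    return(data.frame(name = character(0), forward = character(0),
                      reverse = character(0), forward_seq = character(0),
                      reverse_seq = character(0),
                      forward_start = integer(0), reverse_start = integer(0),
                      product_size = integer(0)))
  }
  pairs <- do.call(rbind, out)
  pairs <- pairs[order(pairs$forward_start, pairs$reverse_start), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Screening estimate of primer melting temperature
#'
#' Wallace rule (2(A+T) + 4(G+C)) for oligos shorter than 14 nt, otherwise
#' the GC formula 64.9 + 41 x (GC - 16.4) / N. Degenerate positions are
#' averaged over their expansions (both formulas are linear in GC count,
#' so the expectation is computed in closed form). A screening estimator
#' for ranking only; annealing temperatures are determined empirically.
#'
#' @param seq IUPAC oligo, no gaps.
#' @return Estimated Tm in degrees C, rounded to 0.1.
#' @export
estimate_tm <- function(seq) {
  masks <- encode_iupac(seq)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, IUPAC_BASES) > 0L), 0L)
  # expected number of G/C draws at each position
  exp_gc <- vapply(seq_along(masks), function(i) {
    hits <- sum(bitwAnd(masks[i], c(IUPAC_BASES[["G"]], IUPAC_BASES[["C"]])) > 0L)
    hits / sizes[i]
  }, numeric(1))
  n <- length(masks)
  gc <- sum(exp_gc)
  tm <- if (n < 14L) 2 * (n - gc) + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
  round(tm, 1)
}

#' One-call primer design pipeline
#'
#' Align (unless given a `degealn`), scan conserved windows, build
#' candidates and assemble pairs under one constraint set.
#'
#' @param targets Named character vector of ungapped target sequences, or
#'   a pre-built `degealn` alignment.
#' @inheritParams make_candidates
#' @return List with `alignment`, `windows`, `candidates`, `pairs`.
#' @export
design_primers <- function(targets, constraints = design_constraints(),
                           reference = NULL) {
  aln <- if (inherits(targets, "degealn")) targets else align_progressive(targets)
  windows <- find_conserved_windows(aln, constraints)
  candidates <- make_candidates(windows, aln, constraints, reference)
  pairs <- if (nrow(candidates)) {
    assemble_pairs(candidates, aln, constraints, reference)
  } else {
    data.frame(name = character(0), forward = character(0),
               reverse = character(0), forward_seq = character(0),
               reverse_seq = character(0), forward_start = integer(0),
               reverse_start = integer(0), product_size = integer(0))
  }
  list(alignment = aln, windows = windows, candidates = candidates,
       pairs = pairs)
}
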