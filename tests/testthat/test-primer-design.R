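test_that("identical sequences yield conserved windows at every admissible
           start", {
  seqs <- setNames(rep(random_dna_str(30), 3), c("a", "b", "c"))
  set.seed(1)
  aln <- as_alignment(seqs)
  win <- find_conserved_windows(aln)
  w17 <- win[win$end - win$start == 17L, ]
  expect_identical(w17$start, 0:13)
  expect_true(all(win$n_degenerate == 0L))
})

test_that("windows whose consensus needs too many degenerate columns are
           excluded", {
  # three variable columns in the middle of a 20-column alignment
  base <- "AAAAAAAAAAAAAAAAAAAA"
  v1 <- base; substr(v1, 8, 8) <- "C"; substr(v1, 10, 10) <- "G"
  v2 <- base; substr(v2, 12, 12) <- "T"
  aln <- as_alignment(c(a = base, b = v1, c = v2))
  win <- find_conserved_windows(aln, design_constraints(min_len = 17,
                                                        max_len = 20))
  # any 17+ window covers columns 8..12, i.e. 3 degenerate columns
  expect_identical(nrow(win), 0L)
  # relaxing the budget admits them
  win3 <- find_conserved_windows(
    aln, design_constraints(min_len = 17, max_len = 20, max_degenerate = 3))
  expect_gt(nrow(win3), 0L)
})

test_that("an alignment shorter than min_len warns and returns nothing", {
  aln <- as_alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_warning(win <- find_conserved_windows(aln), "shorter")
  expect_identical(nrow(win), 0L)
})

test_that("candidates carry full coverage, reverse complements, and the
           constraint invariants", {
  cl <- small_clade(seed = 31)
  aln <- align_progressive(cl$targets)
  cons <- design_constraints(min_product = 100L)
  win <- find_conserved_windows(aln, cons)
  cand <- make_candidates(win, aln, cons)
  expect_gt(nrow(cand), 0L)
  # invariants mirroring the design constraints, asserted on all outputs
  expect_true(all(cand$length >= cons$min_len & cand$length <= cons$max_len))
  expect_true(all(cand$n_degenerate <= cons$max_degenerate))
  expect_true(all(cand$coverage == 1.0))
  # forward/reverse of one window are reverse complements
  fwd <- cand[cand$orientation == "forward", ]
  rev_ <- cand[cand$orientation == "reverse", ]
  shared <- intersect(paste(fwd$start, fwd$end), paste(rev_$start, rev_$end))
  expect_gt(length(shared), 0L)
  key <- shared[1]
  f <- fwd$sequence[paste(fwd$start, fwd$end) == key]
  r <- rev_$sequence[paste(rev_$start, rev_$end) == key]
  expect_identical(reverse_complement(f), r)
})

test_that("a single uncovered mismatch drops a candidate at full required
           coverage", {
  seqs <- setNames(rep("ACGTACGTACGTACGTACGTACGT", 5), paste0("s", 1:5))
  broken <- seqs
  substr(broken[["s5"]], 10, 10) <- "G"  # A -> G at one locus
  names(broken) <- names(seqs)
  aln_ok <- as_alignment(seqs)
  aln_bad <- as_alignment(broken)
  cons <- design_constraints(min_len = 17, max_len = 17, max_degenerate = 0)
  win_ok <- find_conserved_windows(aln_ok, cons)
  cand_ok <- make_candidates(win_ok, aln_ok, cons)
  expect_true(all(cand_ok$coverage == 1))
  # with the mutated row, windows over the locus now need a degenerate
  # column; forcing a zero-degeneracy consensus there is impossible, so
  # coverage-based dropping is exercised via a manual window instead
  cov <- degeprimer:::window_coverage(aln_bad, 0L, 17L,
                                      substr(seqs[[1]], 1, 17))
  expect_equal(cov, 4 / 5)
})

test_that("pair assembly respects the product-size filter and the
           combinatorial bound, deterministically", {
  # synthetic candidate table: 11 forward, 5 reverse (as in a real panel
  # screen), windows spaced so some pairs fail the size filter
  aln <- as_alignment(setNames(rep(paste(rep("A", 900), collapse = ""), 2),
                               c("r1", "r2")))
  fwd_starts <- seq(0, 200, by = 20)          # 11 forwards
  rev_starts <- seq(300, 860, by = 140)       # 5 reverses
  cand <- rbind(
    data.frame(name = sprintf("f%02d", seq_along(fwd_starts)),
               sequence = strrep("A", 18), orientation = "forward",
               start = fwd_starts, end = fwd_starts + 18L),
    data.frame(name = sprintf("r%02d", seq_along(rev_starts)),
               sequence = strrep("T", 18), orientation = "reverse",
               start = rev_starts, end = rev_starts + 18L))
  cons <- design_constraints(min_product = 400L)
  pairs <- assemble_pairs(cand, aln, cons)
  expect_lte(nrow(pairs), 11L * 5L)
  expect_true(all(pairs$product_size > 400L))
  # every admissible combination is present: recompute the bound directly
  expected_n <- sum(outer(fwd_starts, rev_starts + 18L,
                          function(f, r) r - f > 400L & TRUE))
  expect_identical(nrow(pairs), as.integer(expected_n))
  # explicit include/exclude cases
  expect_false(any(pairs$forward_start == 200 & pairs$reverse_start == 300))
  expect_true(any(pairs$forward_start == 0 & pairs$reverse_start == 860))
  # re-running is byte-identical
  pairs2 <- assemble_pairs(cand, aln, cons)
  expect_identical(pairs, pairs2)
})

test_that("Tm screening estimates follow the Wallace and GC rules, with
           degenerate positions averaged over expansions", {
  expect_equal(estimate_tm("AAAA"), 8.0)
  expect_equal(estimate_tm("GGGG"), 16.0)
  expect_equal(estimate_tm("AY"),
               mean(c(estimate_tm("AC"), estimate_tm("AT"))))
  # >= 14 nt switches to the GC formula
  s <- strrep("AG", 8)  # 16 nt, 8 GC
  expect_equal(estimate_tm(s), round(64.9 + 41 * (8 - 16.4) / 16, 1))
  d <- "RGGGGGGGGGGGGG"  # R averages G (GC) and A (AT) at position 1
  expect_equal(estimate_tm(d),
               round(64.9 + 41 * (13.5 - 16.4) / 14, 1))
})

test_that("the full designer recovers the planted pair on a synthetic
           clade", {
  cl <- small_clade(seed = 8, n_targets = 12, insert_length = 300)
  res <- design_primers(align_progressive(cl$targets),
                        design_constraints(min_product = 250L))
  fwd_ok <- L5_FWD %in% res$candidates$sequence[
    res$candidates$orientation == "forward"]
  rev_ok <- L5_REV %in% res$candidates$sequence[
    res$candidates$orientation == "reverse"]
  expect_true(fwd_ok)
  expect_true(rev_ok)
  planted <- res$pairs[res$pairs$forward_seq == L5_FWD &
                       res$pairs$reverse_seq == L5_REV, ]
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$product_size,
                   nchar(L5_FWD) + 300L + nchar(L5_REV))
})
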