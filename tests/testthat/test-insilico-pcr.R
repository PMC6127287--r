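test_that("exact placements are found with correct coordinates", {
  hits <- match_sites("ACGT", "TTACGTTT", match_policy(0, 0))
  plus <- hits[hits$strand == "+", ]
  expect_identical(nrow(plus), 1L)
  expect_identical(plus$start, 2L)
  expect_identical(plus$end, 6L)
  expect_identical(plus$mismatches, 0L)
})

test_that("a 3'-terminal mismatch abolishes the hit even within the
           mismatch budget", {
  pol <- match_policy(max_mismatches = 1, three_prime_anchor = 1,
                      search_both_strands = FALSE)
  hits <- match_sites("ACGT", "TTACGATT", pol)
  expect_identical(nrow(hits), 0L)
  # without the anchor the same placement is accepted
  hits2 <- match_sites("ACGT", "TTACGATT",
                       match_policy(max_mismatches = 1, three_prime_anchor = 0,
                                    search_both_strands = FALSE))
  expect_true(any(hits2$start == 2L & hits2$mismatches == 1L))
})

test_that("degenerate positions match their variants at zero cost", {
  tpl <- paste0(random_dna_str(30), "GCTCAGGACGAACGCTGG", random_dna_str(30))
  set.seed(2)
  hits <- match_sites(L5_FWD, tpl, match_policy(0, 3))
  expect_identical(nrow(hits[hits$strand == "+", ]), 1L)
  expect_identical(hits$mismatches[hits$strand == "+"], 0L)
})

test_that("a primer longer than the template yields no hits", {
  expect_identical(nrow(match_sites("ACGTACGTACGT", "ACGT",
                                    match_policy(0, 0))), 0L)
})

test_that("zero-mismatch matching equals the expansion-scan oracle on
           random templates", {
  set.seed(17)
  policy <- match_policy(max_mismatches = 0, three_prime_anchor = 0)
  for (i in 1:60) {
    primer <- random_iupac_str(sample(6:10, 1),
                               letters = c("A", "C", "G", "T", "R", "Y",
                                           "S", "W", "K", "M", "N"))
    if (count_degeneracy(primer)$fold > 64) next
    tpl <- random_dna_str(120)
    # plant one expansion half the time so positives occur
    if (i %% 2 == 0) {
      exp1 <- sample(expand_degenerate(primer), 1)
      at <- sample(1:(120 - nchar(exp1)), 1)
      substr(tpl, at, at + nchar(exp1) - 1) <- exp1
    }
    got <- match_sites(primer, tpl, policy)
    want <- oracle_match_starts(primer, tpl)
    expect_identical(got$start[got$strand == "+"], want$plus)
    expect_identical(got$start[got$strand == "-"], want$minus)
  }
})

test_that("amplification of a planted clade is complete, position-consistent
           and yields the planted insert", {
  cl <- small_clade(seed = 19)
  pair <- list(forward = L5_FWD, reverse = L5_REV)
  hits <- amplify(pair, cl$targets, match_policy(0, 3))
  prim <- hits[hits$primary, ]
  expect_identical(sort(prim$template_id), sort(names(cl$targets)))
  expect_true(all(prim$product_length == cl$truth$product_length))
  for (k in seq_len(nrow(prim))) {
    tpl <- cl$targets[[prim$template_id[k]]]
    expect_identical(prim$insert[k],
                     cl$truth$inserts[[prim$template_id[k]]])
    # position consistency: the spanned region is footprints + insert
    span <- substr(tpl, prim$start[k] + 1L, prim$end[k])
    expect_identical(nchar(span), prim$product_length[k])
    expect_identical(substr(tpl, prim$fwd_end[k] + 1L, prim$rev_start[k]),
                     prim$insert[k])
  }
  # non-targets are structurally unamplifiable
  expect_identical(nrow(amplify(pair, cl$nontargets, match_policy(0, 3))), 0L)
})

test_that("the product-size window excludes short amplicons", {
  tpl <- c(x = paste0("AACCGGTTAACC", "TTGTGGCG", strrep("A", 150),
                      reverse_complement("CAGTCAGT"), "GGTTCCAAGGTT"))
  pair <- list(forward = "TTGTGGCG", reverse = "CAGTCAGT")
  hits <- amplify(pair, tpl, match_policy(0, 0), product_range = c(50, 3000))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$product_length, 8L + 150L + 8L)
  expect_identical(nrow(amplify(pair, tpl, match_policy(0, 0),
                                product_range = c(400, 3000))), 0L)
})

test_that("minus-strand products are found and reported in forward
           orientation", {
  set.seed(23)
  insert <- random_dna_str(100)
  plus_template <- paste0("GGAATTCCGG", "TTGTGGCG", insert,
                          reverse_complement("CAGTCAGT"), "AATTGGCCAA")
  tpl <- c(flipped = reverse_complement(plus_template))
  pair <- list(forward = "TTGTGGCG", reverse = "CAGTCAGT")
  hits <- amplify(pair, tpl, match_policy(0, 3), product_range = c(50, 500))
  expect_identical(hits$strand, "-")
  expect_identical(hits$insert, insert)
})

test_that("coverage reports count targets and non-targets correctly", {
  cl <- small_clade(seed = 29)
  pair <- list(forward = L5_FWD, reverse = L5_REV)
  rep1 <- coverage_report(pair, cl$targets, cl$nontargets, match_policy(0, 3))
  expect_equal(rep1$target_coverage, 1.0)
  expect_identical(rep1$nontarget_hits, 0L)
  expect_identical(nrow(rep1$table),
                   length(cl$targets) + length(cl$nontargets))

  # a primer matching nothing
  rep2 <- coverage_report(list(forward = strrep("ACGT", 5),
                               reverse = strrep("GTCA", 5)),
                          cl$nontargets, character(0), match_policy(0, 3))
  expect_equal(rep2$target_coverage, 0.0)

  # one target carrying a 3'-anchor mismatch in its forward site
  targets <- cl$targets
  s <- cl$truth$sites
  row1 <- s[s$template_id == names(targets)[1], ]
  pos <- row1$fwd_end  # last base of the forward footprint (1-based = end)
  ch <- substr(targets[[1]], pos, pos)
  substr(targets[[1]], pos, pos) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  rep3 <- coverage_report(pair, targets, cl$nontargets, match_policy(0, 3))
  expect_equal(rep3$target_coverage, (length(targets) - 1) / length(targets))

  expect_error(coverage_report(pair, character(0)), "empty")
})
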