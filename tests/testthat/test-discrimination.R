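test_that("pairwise identity handles equality, substitutions, overhangs and
           symmetry", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  # terminal overhangs are excluded from the denominator
  expect_equal(pairwise_identity("ACGTACGT", "GTAC"), 1.0)
  expect_error(pairwise_identity("", "ACGT"), "empty")
  set.seed(41)
  for (i in 1:10) {
    a <- random_dna_str(sample(20:60, 1))
    b <- random_dna_str(sample(20:60, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("distance models agree with closed forms and with an independent
           distance implementation", {
  base <- random_dna_str(100)
  set.seed(43)
  seqs <- c(s1 = base, s2 = base, s3 = base)
  expect_true(all(distance_matrix(seqs, "p")[upper.tri(diag(3))] == 0))
  expect_true(all(distance_matrix(seqs, "JC69")[upper.tri(diag(3))] == 0))

  # plant exactly 10 substitutions in 100 nt: p = 0.1
  mut <- base
  pos <- sample(100, 10)
  for (p in pos) {
    old <- substr(mut, p, p)
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  seqs2 <- c(a = base, b = mut, c = random_dna_str(100))
  dm_p <- distance_matrix(seqs2, "p")
  expect_equal(dm_p["a", "b"], 0.1)
  dm_jc <- distance_matrix(seqs2, "JC69")
  expect_equal(dm_jc["a", "b"], -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)

  # cross-check JC69 and K2P against ape::dist.dna on the aligned pair
  mat <- rbind(strsplit(tolower(base), "")[[1]],
               strsplit(tolower(mut), "")[[1]])
  rownames(mat) <- c("a", "b")
  bin <- ape::as.DNAbin(mat)
  expect_equal(dm_jc["a", "b"], ape::dist.dna(bin, model = "JC69")[1],
               tolerance = 1e-9)
  dm_k2p <- distance_matrix(seqs2, "K2P")
  expect_equal(dm_k2p["a", "b"], ape::dist.dna(bin, model = "K80")[1],
               tolerance = 1e-9)
})

test_that("saturated distances fall back to the configured maximum with a
           warning", {
  # p > 0.75 forces the JC69 logarithm argument non-positive
  seqs <- c(a = strrep("A", 40), b = strrep("C", 40), c = strrep("G", 40))
  expect_warning(dm <- distance_matrix(seqs, "JC69", max_distance = 7),
                 "saturated")
  expect_true(all(dm[upper.tri(dm)] == 7))
})

test_that("the indistinguishable fraction counts threshold exceedances over
           all pairs and is monotone in the threshold", {
  ids <- matrix(c(1, 1, 0.9,
                  1, 1, 0.9,
                  0.9, 0.9, 1), 3, 3,
                dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_equal(indistinguishable_fraction(ids, 0.98), 1 / 3)
  expect_equal(indistinguishable_fraction(ids, 0.95), 1 / 3)
  expect_equal(indistinguishable_fraction(ids, 0.85), 1)
  expect_equal(indistinguishable_fraction(ids + diag(0, 3), 1), 1 / 3)
  low <- ids; low[1, 2] <- low[2, 1] <- 0.9
  expect_equal(indistinguishable_fraction(low, 0.98), 0)
  set.seed(47)
  m <- matrix(runif(100), 10, 10); m <- (m + t(m)) / 2; diag(m) <- 1
  dimnames(m) <- list(letters[1:10], letters[1:10])
  ths <- seq(0.1, 1, by = 0.1)
  fr <- vapply(ths, function(t) indistinguishable_fraction(m, t), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("a same-species denominator can exclude within-species pairs", {
  ids <- matrix(c(1, 0.99, 0.5,
                  0.99, 1, 0.5,
                  0.5, 0.5, 1), 3, 3,
                dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  sp <- c(x = "Lactobacillus casei", y = "Lactobacillus casei",
          z = "Weissella confusa")
  expect_equal(indistinguishable_fraction(ids, 0.98), 1 / 3)
  expect_equal(indistinguishable_fraction(ids, 0.98, species = sp), 0)
})

test_that("three-taxon neighbor joining solves the closed form", {
  dm <- matrix(c(0, 5, 9,
                 5, 0, 10,
                 9, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(dm)
  expect_s3_class(tree, "phylo")
  # closed form: vA = (dAB + dAC - dBC)/2 = 2, vB = 3, vC = 7
  el <- setNames(tree$edge.length,
                 tree$tip.label[tree$edge[, 2]])
  expect_equal(unname(el["A"]), 2)
  expect_equal(unname(el["B"]), 3)
  expect_equal(unname(el["C"]), 7)
})

test_that("NJ reconstructs additive matrices exactly: topology, path
           lengths, and invariance to label order", {
  set.seed(53)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    true_tree <- ape::rtree(n, rooted = FALSE)
    true_tree$edge.length <- true_tree$edge.length + 0.1
    dm <- cophenetic(true_tree)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    nj_tree <- neighbor_joining(dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true_tree), nj_tree)), 0)
    # additive distances are reproduced by tree path lengths
    back <- cophenetic(nj_tree)[rownames(dm), colnames(dm)]
    expect_equal(back, dm, tolerance = 1e-8)
    # permuting the matrix leaves the topology unchanged
    perm <- sample(n)
    nj_perm <- neighbor_joining(dm[perm, perm])
    expect_equal(as.numeric(ape::dist.topo(nj_tree, nj_perm)), 0)
    # and the in-package NJ agrees with ape's on the same input
    expect_equal(as.numeric(ape::dist.topo(nj_tree, ape::nj(dm))), 0)
  }
})

test_that("degenerate matrices are rejected and negative branches clamp", {
  bad <- matrix(runif(9), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(bad), "symmetric")
  neg <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  neg[1, 2] <- neg[2, 1] <- -1
  expect_error(neighbor_joining(neg), "negative")
  # a strong triangle violation yields a negative terminal estimate
  dm <- matrix(c(0, 10, 2,
                 10, 0, 2,
                 2, 2, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(tree <- neighbor_joining(dm), "clamped")
  expect_true(all(tree$edge.length >= 0))
})

test_that("newick serialization round trips topology and branch lengths", {
  set.seed(59)
  dm <- cophenetic(ape::rtree(8, rooted = FALSE))
  tree <- neighbor_joining(dm)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tree, f)
  back <- ape::read.tree(f)
  expect_equal(as.numeric(ape::dist.topo(tree, back)), 0)
  expect_equal(sort(back$edge.length), sort(tree$edge.length),
               tolerance = 1e-9)
})

test_that("resolution comparison matches identical inputs and flags
           conserved-flank inflation", {
  set.seed(61)
  inserts <- setNames(vapply(1:6, function(i) random_dna_str(80),
                             character(1)), paste0("s", 1:6))
  same <- compare_resolution(inserts, inserts, threshold = 0.98)
  expect_equal(same$fraction_full, same$fraction_insert)
  expect_identical(nrow(same$detail), 0L)

  # conserved flanks push full-length identity above the threshold while
  # the variable insert stays distinguishable
  flank <- strrep("ACGT", 250)
  full <- setNames(paste0(flank, inserts, flank), names(inserts))
  res <- compare_resolution(full, inserts, threshold = 0.9)
  expect_lte(res$fraction_insert, res$fraction_full)
  expect_gt(res$fraction_full, 0)

  expect_error(compare_resolution(inserts[1:3], inserts[4:6]), "labels")
})
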