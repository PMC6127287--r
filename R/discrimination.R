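# Species discriminability of amplicon regions.
#
# Pairwise identities come from global affine-gap alignment with terminal
# gap columns excluded (partial inserts are not penalized for length).
# The headline statistic is the indistinguishable-pair fraction: the share
# of all unordered sequence pairs whose identity meets a threshold
# (98% by default), i.e. pairs a marker region cannot tell apart.
# Trees are Saitou-Nei neighbor joining with deterministic tie-breaking.

align_pair_chars <- function(a, b, match = 1, mismatch = -1,
                             gap_open = 4, gap_extend = 1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  pa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  pb <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  both <- which(pa != "-" & pb != "-")
  # drop terminal-gap columns (overhangs), keep internal gaps
  keep <- seq(min(both), max(both))
  list(a = pa[keep], b = pb[keep])
}

#' Pairwise identity of two sequences
#'
#' Global affine-gap alignment; identity = identical columns / aligned
#' columns, with terminal-gap (overhang) columns excluded from the
#' denominator. Internal gap columns count as differences. Scoring matches
#' the package aligner defaults (+1/-1, gap open -4, extend -1).
#'
#' @param a,b Non-empty ungapped sequences.
#' @return Identity in [0, 1].
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  al <- align_pair_chars(a, b)
  mean(al$a == al$b)
}

#' All-vs-all identity matrix
#'
#' @param records Named character vector of ungapped sequences (>= 2).
#' @return Symmetric numeric matrix of pairwise identities with unit
#'   diagonal, dimnames = record ids.
#' @export
identity_matrix <- function(records) {
  records <- as_seq_set(records)
  n <- length(records)
  if (n < 2L) stop("need at least 2 sequences")
  m <- diag(1, n)
  dimnames(m) <- list(names(records), names(records))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- pairwise_identity(records[[i]], records[[j]])
  }
  m
}

pair_subst_stats <- function(a, b) {
  al <- align_pair_chars(a, b)
  cols <- length(al$a)
  comparable <- al$a != "-" & al$b != "-"
  ts_pairs <- c("AG", "GA", "CT", "TC")
  pairkey <- paste0(al$a, al$b)
  diff <- comparable & al$a != al$b
  list(cols = cols,
       p = mean(al$a != al$b),
       P = sum(diff & pairkey %in% ts_pairs) / cols,
       Q = sum(diff & !(pairkey %in% ts_pairs)) / cols)
}

#' Pairwise distance matrix under a substitution model
#'
#' p-distance is 1 minus [pairwise_identity()]; JC69 applies the
#' Jukes-Cantor correction -(3/4) ln(1 - 4p/3); K2P (Kimura
#' two-parameter) separates transition and transversion proportions on
#' the pairwise alignment. Saturated pairs (logarithm argument <= 0) are
#' set to `max_distance` with a warning.
#'
#' @param inserts Named character vector of ungapped sequences (>= 2; a
#'   tree additionally needs >= 3).
#' @param model One of `"p"`, `"JC69"`, `"K2P"`.
#' @param max_distance Value assigned to saturated pairs (default 5).
#' @return Symmetric matrix of distances, zero diagonal.
#' @export
distance_matrix <- function(inserts, model = c("p", "JC69", "K2P"),
                            max_distance = 5) {
  model <- match.arg(model)
  inserts <- as_seq_set(inserts)
  n <- length(inserts)
  if (n < 2L) stop("need at least 2 sequences")
  d <- matrix(0, n, n, dimnames = list(names(inserts), names(inserts)))
  saturated <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    st <- pair_subst_stats(inserts[[i]], inserts[[j]])
    val <- switch(model,
      p = st$p,
      JC69 = {
        arg <- 1 - 4 * st$p / 3
        if (arg <= 0) { saturated <- TRUE; max_distance }
        else -0.75 * log(arg)
      },
      K2P = {
        a1 <- 1 - 2 * st$P - st$Q
        a2 <- 1 - 2 * st$Q
        if (a1 <= 0 || a2 <= 0) { saturated <- TRUE; max_distance }
        else -0.5 * log(a1) - 0.25 * log(a2)
      })
    d[i, j] <- d[j, i] <- val
  }
  if (saturated)
    warning(sprintf("saturated distance(s) set to max_distance = %g", max_distance))
  d
}

#' Fraction of sequence pairs indistinguishable at an identity threshold
#'
#' Share of unordered pairs with pairwise identity >= `threshold`, over
#' all n(n-1)/2 pairs. When a `species` mapping is supplied the
#' denominator is restricted to pairs of *distinct* species (same-species
#' pairs are then distinguishable by definition and excluded).
#'
#' @param identities Symmetric identity matrix from [identity_matrix()].
#' @param threshold Identity threshold in (0, 1]; default 0.98.
#' @param species Optional named character vector mapping sequence label
#'   to species; restricts the denominator to between-species pairs.
#' @return Proportion in [0, 1].
#' @export
indistinguishable_fraction <- function(identities, threshold = 0.98,
                                       species = NULL) {
  stopifnot(is.matrix(identities), threshold > 0, threshold <= 1)
  n <- nrow(identities)
  if (n < 2L) stop("need at least 2 sequences")
  up <- upper.tri(identities)
  if (!is.null(species)) {
    sp <- species[rownames(identities)]
    diff_sp <- outer(sp, sp, `!=`)
    up <- up & diff_sp
    if (!any(up)) stop("no between-species pairs under the given mapping")
  }
  sum(identities[up] >= threshold) / sum(up)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with a deterministic tie-break: among
#' minimal-Q pairs the lexicographically lowest label pair is joined
#' (internal nodes inherit their lowest leaf label for this purpose).
#' Additive distances are reproduced exactly by tree path lengths.
#' Negative branch lengths are clamped to zero with a warning.
#'
#' @param dm Symmetric distance matrix with >= 3 unique labels, zero
#'   diagonal, no negative entries.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (!is.matrix(dm) || is.null(rownames(dm)))
    stop("dm must be a labeled matrix")
  if (nrow(dm) < 3L) stop("need at least 3 labels for a tree")
  if (any(dm < 0)) stop("negative distances are not allowed")
  if (max(abs(dm - t(dm))) > 1e-9) stop("distance matrix must be symmetric")
  if (anyDuplicated(rownames(dm))) stop("duplicate labels")

  D <- dm
  labels <- rownames(dm)              # current node sort keys
  newick <- rownames(dm)              # current node newick fragments
  clamped <- FALSE
  fmt <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.12g", x)
  }
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      p <- sort(c(labels[ij[1]], labels[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    nw <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(vi), newick[j], fmt(vj))
    lab <- min(labels[i], labels[j])
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    labels <- c(labels[keep], lab)
    newick <- c(newick[keep], nw)
  }
  va <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  vb <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  vc <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  tree_str <- sprintf("(%s:%s,%s:%s,%s:%s);",
                      newick[1], fmt(va), newick[2], fmt(vb),
                      newick[3], fmt(vc))
  if (clamped) warning("negative branch length(s) clamped to 0")
  ape::read.tree(text = tree_str)
}

#' Compare species resolution of full-length markers vs amplicon inserts
#'
#' Computes the indistinguishable-pair fraction at the same threshold on
#' matched full-length sequences and insert regions, with per-pair detail
#' of pairs resolved by one region but not the other.
#'
#' @param full_length,inserts Named character vectors with identical label
#'   sets.
#' @inheritParams indistinguishable_fraction
#' @return List with `fraction_full`, `fraction_insert` and `detail`
#'   (data.frame of pairs, identities and which region resolves them).
#' @export
compare_resolution <- function(full_length, inserts, threshold = 0.98,
                               species = NULL) {
  if (!setequal(names(full_length), names(inserts)))
    stop("full_length and inserts must carry the same labels")
  inserts <- inserts[names(full_length)]
  id_full <- identity_matrix(full_length)
  id_ins <- identity_matrix(inserts)
  up <- which(upper.tri(id_full), arr.ind = TRUE)
  detail <- data.frame(
    a = rownames(id_full)[up[, 1]], b = colnames(id_full)[up[, 2]],
    identity_full = id_full[up], identity_insert = id_ins[up])
  detail$indistinct_full <- detail$identity_full >= threshold
  detail$indistinct_insert <- detail$identity_insert >= threshold
  list(fraction_full = indistinguishable_fraction(id_full, threshold, species),
       fraction_insert = indistinguishable_fraction(id_ins, threshold, species),
       detail = detail[detail$indistinct_full != detail$indistinct_insert, ,
                       drop = FALSE])
}

#' Write a distance matrix in square PHYLIP format
#' @param dm Labeled symmetric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(c(sprintf("%-10s", rownames(dm)[i]),
                       sprintf("%.6f", dm[i, ])), collapse = " "), con)
  }
  invisible(path)
}
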