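# Synthetic clade and read-set generators.
#
# The generators build data with the structure the pipeline assumes, so
# every stage is testable without downloads: a target clade carrying
# planted degenerate primer sites flanking a variable insert region,
# non-target outgroups guaranteed to lack the sites, and labeled read
# mixtures of known composition. Everything is seeded and byte-stable.
#
# Default geometry mirrors the packaged LAB primer panel's best pair
# (L5): an 18 nt forward site, a 20 nt reverse site, and a 712 nt insert,
# for a ~750 bp product.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# substitute each position independently with probability p (to one of
# the three other bases)
mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  ch <- seq_chars(seq)
  hit <- stats::runif(length(ch)) < p
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  }
  paste(ch, collapse = "")
}

# realize a degenerate site: each ambiguous position is drawn uniformly
# from its allowed bases
realize_site <- function(site) {
  masks <- encode_iupac(site)
  paste(vapply(masks, function(m) {
    bases <- names(IUPAC_BASES)[bitwAnd(m, IUPAC_BASES) > 0L]
    if (length(bases) == 1L) bases else sample(bases, 1L)
  }, character(1)), collapse = "")
}

#' Specification of a synthetic target clade
#'
#' @param n_targets Number of target sequences (default 20).
#' @param n_nontargets Number of non-target outgroup sequences (default 5).
#' @param site_fwd,site_rev Planted degenerate primer sites, 5'->3' in
#'   primer orientation; defaults are the packaged panel's best pair
#'   (18 nt forward, 20 nt reverse).
#' @param insert_length Length of the variable inter-primer region
#'   (default 712 nt, for a ~750 bp product).
#' @param flank_length Variable flank on each side of the amplicon
#'   (default 40 nt).
#' @param divergence Per-target, per-position substitution probability of
#'   insert and flank positions relative to the clade root (default 0.10,
#'   i.e. typical pairwise differences near 19%).
#' @param n_close_pairs Number of engineered near-identical target pairs
#'   (default 0); members of such a pair differ only by `close_divergence`.
#' @param close_divergence Substitution probability within a close pair
#'   (default 0.005).
#' @param seed Integer RNG seed.
#' @return List of class `clade_spec`.
#' @export
clade_spec <- function(n_targets = 20L, n_nontargets = 5L,
                       site_fwd = "GCTCAGGAYGAACGCYGG",
                       site_rev = "CACCGCTACACATGRADTTC",
                       insert_length = 712L, flank_length = 40L,
                       divergence = 0.10, n_close_pairs = 0L,
                       close_divergence = 0.005, seed = 1L) {
  if (insert_length < 1L) stop("insert_length must be at least 1")
  stopifnot(n_targets >= 2L, n_nontargets >= 0L,
            2L * n_close_pairs <= n_targets)
  structure(list(n_targets = as.integer(n_targets),
                 n_nontargets = as.integer(n_nontargets),
                 site_fwd = toupper(site_fwd), site_rev = toupper(site_rev),
                 insert_length = as.integer(insert_length),
                 flank_length = as.integer(flank_length),
                 divergence = divergence,
                 n_close_pairs = as.integer(n_close_pairs),
                 close_divergence = close_divergence,
                 seed = as.integer(seed)),
            class = "clade_spec")
}

# does `seq` (either strand) share a 17-mer with any window of the
# degenerate site, or harbor a near-match of the full site?
shares_site_kmers <- function(seq, site, k = 17L) {
  enc <- encode_iupac(seq)
  for (motif in list(site, reverse_complement(site))) {
    masks <- encode_iupac(motif)
    m <- length(masks)
    for (s in 0:(m - k)) {
      if (nrow(scan_motif(masks[(s + 1L):(s + k)], enc, 0L, integer(0))))
        return(TRUE)
    }
    if (nrow(scan_motif(masks, enc, 2L, integer(0)))) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic target clade with planted primer sites
#'
#' Target sequences are `flank + forward site + insert + reverse-site
#' complement + flank`. Degenerate positions of the planted sites are
#' realized independently per target (uniform over their allowed bases),
#' so a consensus over the clade must re-derive the degeneracies; flank
#' and insert positions diverge from a common root by per-position
#' substitution. Optionally, `n_close_pairs` target pairs are made nearly
#' identical in the insert to engineer a known indistinguishable-pair
#' count. Non-targets are random sequences rejected until they share no
#' 17-mer with either site (on either strand) and carry no near-match of
#' the full sites, so zero-amplification assertions are structural, not
#' probabilistic.
#'
#' @param spec A [clade_spec()].
#' @return List: `targets`, `nontargets` (named character vectors),
#'   `truth` (list with per-target site coordinates, realized sites,
#'   inserts, the pairwise insert-identity ground truth matrix computed by
#'   construction, and `n_indistinguishable_98`, the number of insert
#'   pairs with identity >= 0.98).
#' @export
generate_clade <- function(spec = clade_spec()) {
  stopifnot(inherits(spec, "clade_spec"))
  with_seed(spec$seed, {
    fl <- spec$flank_length
    site_rev_rc <- reverse_complement(spec$site_rev)
    root_insert <- random_dna(spec$insert_length)
    root_flank1 <- random_dna(fl)
    root_flank2 <- random_dna(fl)

    ids <- sprintf("t%02d", seq_len(spec$n_targets))
    inserts <- character(spec$n_targets)
    close_partner <- rep(NA_integer_, spec$n_targets)
    for (i in seq_len(spec$n_targets)) {
      if (spec$n_close_pairs > 0L && i %% 2L == 0L &&
          i <= 2L * spec$n_close_pairs) {
        inserts[i] <- mutate_seq(inserts[i - 1L], spec$close_divergence)
        close_partner[i] <- i - 1L
      } else {
        inserts[i] <- mutate_seq(root_insert, spec$divergence)
      }
    }
    fwd_sites <- vapply(ids, function(x) realize_site(spec$site_fwd), character(1))
    rev_sites <- vapply(ids, function(x) realize_site(spec$site_rev), character(1))
    flank1 <- vapply(ids, function(x) mutate_seq(root_flank1, spec$divergence),
                     character(1))
    flank2 <- vapply(ids, function(x) mutate_seq(root_flank2, spec$divergence),
                     character(1))
    targets <- stats::setNames(paste0(
      flank1, fwd_sites, inserts,
      vapply(rev_sites, reverse_complement, character(1)), flank2), ids)

    total_len <- nchar(targets[[1L]])
    nt_ids <- if (spec$n_nontargets) sprintf("nt%02d", seq_len(spec$n_nontargets))
              else character(0)
    nontargets <- stats::setNames(vapply(nt_ids, function(id) {
      repeat {
        cand <- random_dna(total_len)
        if (!shares_site_kmers(cand, spec$site_fwd) &&
            !shares_site_kmers(cand, spec$site_rev)) return(cand)
      }
    }, character(1)), nt_ids)

    # construction ground truth: inserts are equal-length and
    # substitution-only, so identity is the Hamming identity
    id_truth <- diag(1, spec$n_targets)
    dimnames(id_truth) <- list(ids, ids)
    ch <- strsplit(inserts, "", fixed = TRUE)
    for (i in seq_len(spec$n_targets - 1L)) for (j in (i + 1L):spec$n_targets) {
      id_truth[i, j] <- id_truth[j, i] <- mean(ch[[i]] == ch[[j]])
    }
    fwd_start <- fl                      # 0-based
    rev_rc_start <- fl + nchar(spec$site_fwd) + spec$insert_length
    truth <- list(
      sites = data.frame(
        template_id = ids,
        fwd_start = fwd_start, fwd_end = fwd_start + nchar(spec$site_fwd),
        rev_start = rev_rc_start,
        rev_end = rev_rc_start + nchar(spec$site_rev),
        fwd_site = unname(fwd_sites), rev_site = unname(rev_sites),
        close_partner = ifelse(is.na(close_partner), "",
                               ids[pmax(close_partner, 1L)])),
      inserts = stats::setNames(inserts, ids),
      product_length = nchar(spec$site_fwd) + spec$insert_length +
        nchar(spec$site_rev),
      insert_identity = id_truth,
      n_indistinguishable_98 = sum(id_truth[upper.tri(id_truth)] >= 0.98))
    list(targets = targets, nontargets = nontargets, truth = truth,
         spec = spec)
  })
}

#' Specification of a synthetic amplicon read set
#'
#' @param composition Named numeric vector of relative abundances summing
#'   to 1; names are clade target ids and optionally `"offtarget"` for a
#'   decoy pool.
#' @param depth Number of reads (default 2551, the depth-standardization
#'   size used throughout the worked examples).
#' @param error_rate Per-base substitution probability applied to each
#'   read (default 0).
#' @param source Draw reads from amplicon `"insert"` regions (default) or
#'   from `"full"`-length sequences (universal-primer emulation).
#' @param n_decoys Number of distinct random decoy sequences backing the
#'   `"offtarget"` pool (default 10).
#' @param seed Integer RNG seed.
#' @return List of class `read_set_spec`.
#' @export
read_set_spec <- function(composition, depth = 2551L, error_rate = 0,
                          source = c("insert", "full"), n_decoys = 10L,
                          seed = 1L) {
  source <- match.arg(source)
  stopifnot(depth >= 1L, abs(sum(composition) - 1) < 1e-8,
            !is.null(names(composition)))
  structure(list(composition = composition, depth = as.integer(depth),
                 error_rate = error_rate, source = source,
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed)),
            class = "read_set_spec")
}

#' Generate a labeled read set from a synthetic clade
#'
#' Reads are drawn taxon-by-taxon according to the composition (from the
#' insert region or full-length sequence), with independent per-base
#' substitution errors; the `"offtarget"` fraction is served by a small
#' pool of random decoy sequences of matching length. True source labels
#' are kept as a sidecar.
#'
#' @param spec A [read_set_spec()].
#' @param clade Result of [generate_clade()].
#' @return List: `reads` (character vector, length `depth`) and `truth`
#'   (data.frame `read_id`, `taxon`).
#' @export
generate_reads <- function(spec, clade) {
  stopifnot(inherits(spec, "read_set_spec"))
  taxa <- names(spec$composition)
  known <- c(names(clade$targets), "offtarget")
  if (!all(taxa %in% known))
    stop(sprintf("unknown taxon/taxa in composition: %s",
                 paste(setdiff(taxa, known), collapse = ", ")))
  with_seed(spec$seed, {
    source_seqs <- if (spec$source == "insert") clade$truth$inserts
                   else clade$targets
    decoys <- vapply(seq_len(spec$n_decoys), function(i)
      random_dna(nchar(source_seqs[[1L]])), character(1))
    draws <- sample(taxa, spec$depth, replace = TRUE,
                    prob = spec$composition)
    reads <- vapply(draws, function(tx) {
      base <- if (tx == "offtarget") decoys[sample.int(length(decoys), 1L)]
              else source_seqs[[tx]]
      mutate_seq(base, spec$error_rate)
    }, character(1), USE.NAMES = FALSE)
    list(reads = reads,
         truth = data.frame(read_id = sprintf("r%06d", seq_len(spec$depth)),
                            taxon = draws))
  })
}

#' Write the full synthetic fixture set to a directory
#'
#' Writes `targets.fasta`, `nontargets.fasta`, a `truth.tsv` of planted
#' site coordinates and one `reads_<sample>.fasta` per requested read set.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [clade_spec()].
#' @param read_specs Optional named list of [read_set_spec()] objects.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dir, spec = clade_spec(), read_specs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clade <- generate_clade(spec)
  write_fasta(clade$targets, file.path(dir, "targets.fasta"))
  if (length(clade$nontargets))
    write_fasta(clade$nontargets, file.path(dir, "nontargets.fasta"))
  utils::write.table(clade$truth$sites, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(read_specs)) {
    rs <- generate_reads(read_specs[[nm]], clade)
    write_fasta(stats::setNames(rs$reads, rs$truth$read_id),
                file.path(dir, sprintf("reads_%s.fasta", nm)))
    utils::write.table(rs$truth, file.path(dir, sprintf("reads_%s_truth.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
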