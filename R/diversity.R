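# Amplicon-survey diversity summaries.
#
# Depth standardization by seeded subsampling to the smallest sample,
# exact dereplication to OTUs (100% identity over the full read), best-hit
# taxonomy against a labeled reference, target-read proportions,
# presence/absence and relative-abundance tables, Shannon diversity and
# rarefaction.

# run expr with a local RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Subsample read sets to a common depth
#'
#' Uniform sampling without replacement, seeded and reproducible. With
#' `depth = "auto"` every sample is drawn down to the size of the smallest
#' sample — the standard depth-standardization step before comparing
#' samples.
#'
#' @param samples Named list of character vectors of reads.
#' @param depth Integer target depth, or `"auto"` (minimum sample size).
#' @param seed Integer RNG seed.
#' @return Named list of subsampled read vectors, each of length `depth`.
#' @export
subsample_reads <- function(samples, depth = "auto", seed = 1L) {
  stopifnot(is.list(samples), length(samples) > 0L)
  sizes <- lengths(samples)
  if (identical(depth, "auto")) depth <- min(sizes)
  depth <- as.integer(depth)
  if (any(sizes < depth)) {
    short <- names(samples)[sizes < depth][1L]
    stop(sprintf("sample '%s' has %d reads, fewer than depth %d",
                 short, sizes[[short]], depth))
  }
  with_seed(seed, lapply(samples, function(reads) reads[sample.int(length(reads), depth)]))
}

#' Dereplicate reads into exact-identity OTUs
#'
#' Clusters reads at 100% pairwise identity over the full length, i.e.
#' exact string dereplication. The representative of each OTU is its first
#' occurrence in the input.
#'
#' @param reads Character vector of ungapped reads.
#' @return List of class `degeotu`: `otus` (data.frame `otu_id`,
#'   `representative`, `count`, in order of first occurrence) and
#'   `total_reads`.
#' @export
dereplicate <- function(reads) {
  reads <- normalize_residues(as.character(reads))
  if (length(reads) == 0L) {
    return(structure(list(otus = data.frame(otu_id = character(0),
                                            representative = character(0),
                                            count = integer(0)),
                          total_reads = 0L), class = "degeotu"))
  }
  reps <- unique(reads)
  counts <- as.integer(table(factor(reads, levels = reps)))
  structure(list(otus = data.frame(otu_id = sprintf("OTU%d", seq_along(reps)),
                                   representative = reps, count = counts),
                 total_reads = length(reads)),
            class = "degeotu")
}

#' @export
print.degeotu <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs from %d reads\n",
              nrow(x$otus), x$total_reads))
  invisible(x)
}

#' Best-match taxonomic assignment of OTU representatives
#'
#' Each representative receives the label of its highest-identity
#' reference sequence if that identity reaches `min_identity`, otherwise
#' `"unassigned"`. Exact matches short-circuit the alignment. Ties at the
#' best identity go to the first reference in file order and are flagged.
#'
#' @param otus A `degeotu` table.
#' @param reference Named character vector of reference sequences; names
#'   are taxon labels (binomials such as `"Lactobacillus delbrueckii"`;
#'   several references may share a label).
#' @param min_identity Assignment threshold (default 0.97, a conventional
#'   species-level proxy).
#' @return data.frame `otu_id`, `taxon`, `identity`, `tie`, `count`.
#' @export
assign_taxonomy <- function(otus, reference, min_identity = 0.97) {
  stopifnot(inherits(otus, "degeotu"))
  if (length(reference) == 0L) stop("empty reference set")
  ref_seqs <- normalize_residues(as.character(reference))
  ref_labels <- names(reference)
  rows <- lapply(seq_len(nrow(otus$otus)), function(i) {
    rep_seq <- otus$otus$representative[i]
    exact <- which(ref_seqs == rep_seq)
    if (length(exact)) {
      ids <- rep(1, length(exact))
      best <- exact
    } else {
      ids <- vapply(ref_seqs, function(r) pairwise_identity(rep_seq, r),
                    numeric(1))
      best <- which(ids == max(ids))
      ids <- ids[best]
    }
    top <- ids[1L]
    tie <- length(best) > 1L && length(unique(ref_labels[best])) > 1L
    taxon <- if (top >= min_identity) ref_labels[best[1L]] else "unassigned"
    data.frame(otu_id = otus$otus$otu_id[i], taxon = taxon,
               identity = top, tie = tie, count = otus$otus$count[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Target-read proportion
#'
#' Percentage of reads assigned to a set of target taxa. Two call forms:
#' a data.frame of assignments (from [assign_taxonomy()]) plus the target
#' label set, or raw counts `target_proportion(target_reads, total_reads)`.
#' Display rounding follows survey-table convention: percentages of at
#' least 1 round to the nearest integer, smaller ones to one decimal.
#'
#' @param x Assignment data.frame with `taxon` and `count` columns, or a
#'   single integer count of target reads.
#' @param target_taxa Character vector of target labels (data.frame form),
#'   or the integer total read count (count form).
#' @return List: `target_reads`, `total_reads`, `percent` (raw),
#'   `percent_display` (rounded for display).
#' @examples
#' target_proportion(356, 2551)$percent_display  # 14
#' @export
target_proportion <- function(x, target_taxa) {
  if (is.numeric(x)) {
    target <- as.numeric(x)
    total <- as.numeric(target_taxa)
  } else {
    stopifnot(is.data.frame(x), all(c("taxon", "count") %in% names(x)))
    target <- sum(x$count[x$taxon %in% target_taxa])
    total <- sum(x$count)
  }
  pct <- if (total > 0) 100 * target / total else 0
  disp <- if (pct >= 1) round(pct) else round(pct, 1)
  list(target_reads = target, total_reads = total,
       percent = pct, percent_display = disp)
}

#' Relative abundance, presence/absence and richness per condition
#'
#' Accepts either a named list of per-condition assignment data.frames
#' (with `taxon` and `count`; relative abundance is then
#' 100 x reads/total within each condition) or a ready-made numeric
#' matrix of relative abundances (taxa x conditions, in percent).
#' Presence means abundance > 0; richness counts present target taxa per
#' condition.
#'
#' @param conditions Named list of assignment data.frames, or a numeric
#'   matrix with taxon rownames.
#' @param target_taxa Optional label set; richness is restricted to these
#'   taxa (default: all rows).
#' @return List: `abundance` (percent matrix), `presence` (logical
#'   matrix), `richness` (named integer vector).
#' @export
abundance_and_presence <- function(conditions, target_taxa = NULL) {
  if (is.matrix(conditions) || is.data.frame(conditions)) {
    ab <- as.matrix(conditions)
    storage.mode(ab) <- "double"
  } else {
    stopifnot(is.list(conditions), length(conditions) >= 1L)
    taxa <- sort(unique(unlist(lapply(conditions, function(d) d$taxon))))
    ab <- sapply(conditions, function(d) {
      tot <- sum(d$count)
      v <- stats::setNames(numeric(length(taxa)), taxa)
      agg <- tapply(d$count, d$taxon, sum)
      v[names(agg)] <- 100 * agg / max(tot, 1L)
      v
    })
    ab <- matrix(ab, nrow = length(taxa),
                 dimnames = list(taxa, names(conditions)))
  }
  if (any(ab < 0)) stop("negative abundances")
  presence <- ab > 0
  rows <- if (is.null(target_taxa)) rownames(ab)
          else intersect(rownames(ab), target_taxa)
  richness <- colSums(presence[rows, , drop = FALSE])
  list(abundance = ab, presence = presence,
       richness = stats::setNames(as.integer(richness), colnames(ab)))
}

#' Observed OTUs, Shannon diversity and rarefaction
#'
#' Shannon entropy is computed on OTU relative frequencies with natural
#' logarithms (`base = 2` optional). Rarefaction points are means over
#' seeded without-replacement subsamples of the read pool; depths
#' exceeding the total read count are skipped with a warning.
#'
#' @param otus A `degeotu` table.
#' @param rarefaction_depths Integer vector of subsampling depths
#'   (default: 10 evenly spaced depths up to the total).
#' @param replicates Subsamples per depth (default 10).
#' @param seed RNG seed.
#' @param base Logarithm base for Shannon (default `exp(1)`).
#' @return List of class `degediv`: `observed_otus`, `shannon`,
#'   `rarefaction` (data.frame `depth`, `mean`, `sd`).
#' @export
alpha_diversity <- function(otus, rarefaction_depths = NULL,
                            replicates = 10L, seed = 1L, base = exp(1)) {
  stopifnot(inherits(otus, "degeotu"), replicates >= 1L)
  counts <- otus$otus$count
  total <- otus$total_reads
  shannon <- if (length(counts)) {
    unname(vegan::diversity(counts, index = "shannon", base = base))
  } else 0
  if (is.null(rarefaction_depths))
    rarefaction_depths <- unique(pmax(1L, round(seq(0, total, length.out = 11L))[-1L]))
  rarefaction_depths <- as.integer(rarefaction_depths)
  if (any(rarefaction_depths > total)) {
    warning("rarefaction depth(s) beyond total reads skipped")
    rarefaction_depths <- rarefaction_depths[rarefaction_depths <= total]
  }
  pool <- rep(seq_along(counts), counts)
  curve <- with_seed(seed, {
    do.call(rbind, lapply(rarefaction_depths, function(d) {
      obs <- vapply(seq_len(replicates), function(r) {
        length(unique(pool[sample.int(length(pool), d)]))
      }, numeric(1))
      data.frame(depth = d, mean = mean(obs), sd = stats::sd(obs))
    }))
  })
  if (is.null(curve))
    curve <- data.frame(depth = integer(0), mean = numeric(0), sd = numeric(0))
  structure(list(observed_otus = length(counts), shannon = shannon,
                 rarefaction = curve),
            class = "degediv")
}

#' @export
print.degediv <- function(x, ...) {
  cat(sprintf("observed OTUs: %d, Shannon: %.4f\n", x$observed_otus, x$shannon))
  invisible(x)
}

#' Write rarefaction curve as TSV
#' @param div A `degediv` result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rarefaction <- function(div, path) {
  utils::write.table(div$rarefaction, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
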