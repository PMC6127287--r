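# IUPAC-aware in-silico PCR.
#
# Ungapped primer placement with a mismatch budget and a 3'-anchor rule:
# hits with any mismatch in the terminal anchor positions are discarded,
# because 3'-terminal mismatches abolish polymerase extension. Matching is
# pure bit algebra on IUPAC masks (a primer letter matches a template
# letter iff their base sets intersect), so degenerate positions match all
# their variants at zero mismatch cost.

#' In-silico PCR match policy
#'
#' @param max_mismatches Total mismatches tolerated per primer site
#'   (default 2). The strict discriminability workflow uses 0.
#' @param three_prime_anchor Number of 3'-terminal primer positions where
#'   no mismatch is tolerated (default 3, the common in-silico PCR
#'   convention).
#' @param search_both_strands Also search the reverse complement of the
#'   primer on the given strand (default TRUE).
#' @return List of class `match_policy`.
#' @export
match_policy <- function(max_mismatches = 2L, three_prime_anchor = 3L,
                         search_both_strands = TRUE) {
  stopifnot(max_mismatches >= 0L, three_prime_anchor >= 0L)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 three_prime_anchor = as.integer(three_prime_anchor),
                 search_both_strands = isTRUE(search_both_strands)),
            class = "match_policy")
}

# scan an encoded motif along an encoded template; anchor_idx are motif
# positions (1-based) where zero mismatches are allowed
scan_motif <- function(motif, template, max_mm, anchor_idx) {
  m <- length(motif)
  n <- length(template)
  if (m > n) return(data.frame(start = integer(0), mismatches = integer(0)))
  S <- n - m + 1L
  mm <- integer(S)
  anchor_mm <- integer(S)
  for (j in seq_len(m)) {
    bad <- bitwAnd(motif[j], template[j:(j + S - 1L)]) == 0L
    mm <- mm + bad
    if (j %in% anchor_idx) anchor_mm <- anchor_mm + bad
  }
  keep <- mm <= max_mm & anchor_mm == 0L
  data.frame(start = which(keep) - 1L, mismatches = mm[keep])
}

#' Find primer binding sites on a template
#'
#' Reports every ungapped placement of the primer (and, when the policy
#' searches both strands, of its reverse complement) with at most
#' `max_mismatches` total mismatches and zero mismatches within the
#' 3'-terminal anchor. A mismatch is a position where the IUPAC base sets
#' of primer and template are disjoint. No indels are considered.
#'
#' @param primer IUPAC string, ungapped, 5'->3'.
#' @param template Single named or unnamed ungapped sequence string.
#' @param policy A [match_policy()].
#' @return data.frame with `start`, `end` (0-based half-open template
#'   coordinates), `mismatches`, `strand` (`"+"`: primer anneals to the
#'   minus strand and extends rightwards along the given sequence; `"-"`:
#'   the reverse).
#' @export
match_sites <- function(primer, template, policy = match_policy()) {
  if (policy$three_prime_anchor > nchar(primer))
    stop("three_prime_anchor longer than the primer")
  p <- encode_iupac(primer, "primer")
  t_enc <- encode_iupac(template, "template")
  m <- length(p)
  anchor_plus <- if (policy$three_prime_anchor)
    (m - policy$three_prime_anchor + 1L):m else integer(0)
  plus <- scan_motif(p, t_enc, policy$max_mismatches, anchor_plus)
  plus$strand <- rep("+", nrow(plus))
  out <- plus
  if (policy$search_both_strands) {
    rc <- encode_iupac(reverse_complement(primer))
    # primer 3' end maps to the left end of the plus-strand footprint
    anchor_minus <- if (policy$three_prime_anchor)
      seq_len(policy$three_prime_anchor) else integer(0)
    minus <- scan_motif(rc, t_enc, policy$max_mismatches, anchor_minus)
    minus$strand <- rep("-", nrow(minus))
    out <- rbind(plus, minus)
  }
  out$end <- out$start + m
  out <- out[order(out$start, out$strand), c("start", "end", "mismatches", "strand")]
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(template_id = character(0), strand = character(0),
             start = integer(0), end = integer(0),
             fwd_start = integer(0), fwd_end = integer(0),
             rev_start = integer(0), rev_end = integer(0),
             product_length = integer(0),
             mismatches_fwd = integer(0), mismatches_rev = integer(0),
             insert = character(0), primary = logical(0))
}

#' Amplify templates with a primer pair
#'
#' Enumerates, per template, every productive (forward site, reverse site)
#' combination whose product length falls in `product_range`. On the plus
#' strand the forward primer anneals left and the reverse primer's
#' reverse complement is found downstream; the symmetric minus-strand
#' orientation is also searched. Footprints must not overlap. The insert
#' is the template region strictly between the two primer footprints,
#' reported 5'->3' in forward-primer orientation (minus-strand products
#' are reverse-complemented).
#'
#' One hit per template is flagged `primary`: fewest total mismatches,
#' then shortest product, then leftmost start.
#'
#' @param pair List or one-row data.frame with `forward_seq` and
#'   `reverse_seq` (or `forward`/`reverse`) IUPAC primer strings.
#' @param templates Named character vector of ungapped templates.
#' @param policy A [match_policy()].
#' @param product_range Length-2 numeric: admissible product sizes in nt
#'   (default c(100, 3000)).
#' @return data.frame of amplicon hits (possibly 0 rows): template id,
#'   strand, overall and per-primer footprint coordinates (0-based
#'   half-open), product length, per-primer mismatch counts, insert
#'   sequence, and the `primary` flag.
#' @export
amplify <- function(pair, templates, policy = match_policy(),
                    product_range = c(100L, 3000L)) {
  fwd <- if (!is.null(pair$forward_seq)) pair$forward_seq else pair$forward
  rev <- if (!is.null(pair$reverse_seq)) pair$reverse_seq else pair$reverse
  if (is.null(fwd) || is.null(rev))
    stop("pair must provide forward and reverse primer sequences")
  fwd <- as.character(fwd)[1L]
  rev <- as.character(rev)[1L]
  stopifnot(product_range[1] >= nchar(fwd) + nchar(rev))
  templates <- as_seq_set(templates)
  res <- lapply(names(templates), function(id) {
    tpl <- templates[[id]]
    fhits <- match_sites(fwd, tpl, policy)
    rhits <- match_sites(rev, tpl, policy)
    rows <- list()
    add <- function(left, right, strand, mm_f, mm_r, f_span, r_span) {
      product <- right[2] - left[1]
      if (product < product_range[1] || product > product_range[2]) return()
      if (left[2] > right[1]) return()   # overlapping footprints
      insert <- substr(tpl, left[2] + 1L, right[1])
      if (strand == "-") insert <- reverse_complement(insert)
      rows[[length(rows) + 1L]] <<- data.frame(
        template_id = id, strand = strand,
        start = left[1], end = right[2],
        fwd_start = f_span[1], fwd_end = f_span[2],
        rev_start = r_span[1], rev_end = r_span[2],
        product_length = product,
        mismatches_fwd = mm_f, mismatches_rev = mm_r,
        insert = insert, primary = FALSE)
    }
    fp <- fhits[fhits$strand == "+", , drop = FALSE]
    fm <- fhits[fhits$strand == "-", , drop = FALSE]
    rp <- rhits[rhits$strand == "+", , drop = FALSE]
    rm <- rhits[rhits$strand == "-", , drop = FALSE]
    # plus-strand product: forward on +, reverse complement of rev downstream
    for (i in seq_len(nrow(fp))) for (j in seq_len(nrow(rm))) {
      if (rm$start[j] >= fp$end[i])
        add(c(fp$start[i], fp$end[i]), c(rm$start[j], rm$end[j]), "+",
            fp$mismatches[i], rm$mismatches[j],
            c(fp$start[i], fp$end[i]), c(rm$start[j], rm$end[j]))
    }
    # minus-strand product: reverse primer on +, forward's revcomp downstream
    for (i in seq_len(nrow(rp))) for (j in seq_len(nrow(fm))) {
      if (fm$start[j] >= rp$end[i])
        add(c(rp$start[i], rp$end[i]), c(fm$start[j], fm$end[j]), "-",
            fm$mismatches[j], rp$mismatches[i],
            c(fm$start[j], fm$end[j]), c(rp$start[i], rp$end[i]))
    }
    if (!length(rows)) return(NULL)
    hits <- do.call(rbind, rows)
    total_mm <- hits$mismatches_fwd + hits$mismatches_rev
    best <- order(total_mm, hits$product_length, hits$start)[1L]
    hits$primary[best] <- TRUE
    hits
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty_hits())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Target/non-target coverage report for a primer pair
#'
#' In-silico specificity screen: fraction of target templates amplified
#' and number of non-target templates amplified, with a per-template
#' detail table.
#'
#' @inheritParams amplify
#' @param targets Named character vector of target templates (non-empty).
#' @param nontargets Optional named character vector of non-target
#'   templates (specificity panel).
#' @return List with `target_coverage` (proportion), `nontarget_hits`
#'   (count of amplified non-target templates) and `table` (per-template
#'   amplified flag, product length and mismatches of the primary hit).
#' @export
coverage_report <- function(pair, targets, nontargets = character(0),
                            policy = match_policy(),
                            product_range = c(100L, 3000L)) {
  if (length(targets) == 0L) stop("empty target set")
  score_set <- function(templates, role) {
    if (length(templates) == 0L)
      return(data.frame(template_id = character(0), role = character(0),
                        amplified = logical(0), product_length = integer(0),
                        mismatches = integer(0)))
    hits <- amplify(pair, templates, policy, product_range)
    prim <- hits[hits$primary, , drop = FALSE]
    idx <- match(names(templates), prim$template_id)
    data.frame(template_id = names(templates), role = role,
               amplified = !is.na(idx),
               product_length = prim$product_length[idx],
               mismatches = prim$mismatches_fwd[idx] + prim$mismatches_rev[idx])
  }
  ttab <- score_set(targets, "target")
  ntab <- score_set(nontargets, "nontarget")
  list(target_coverage = mean(ttab$amplified),
       nontarget_hits = sum(ntab$amplified),
       table = rbind(ttab, ntab))
}

#' Export amplicon hits as TSV
#' @param hits Result of [amplify()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export amplicon hits as BED (0-based, half-open)
#' @inheritParams write_hits_tsv
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$template_id, start = hits$start,
                    end = hits$end,
                    name = sprintf("%s|%d-%d|%s", hits$template_id,
                                   hits$start, hits$end, hits$strand),
                    score = hits$mismatches_fwd + hits$mismatches_rev,
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export extracted inserts as FASTA
#'
#' Headers follow `template_id|start-end|strand`; only primary hits are
#' written unless `primary_only = FALSE`.
#'
#' @inheritParams write_hits_tsv
#' @param primary_only Write only the designated primary hit per template.
#' @export
write_inserts_fasta <- function(hits, path, primary_only = TRUE) {
  if (primary_only) hits <- hits[hits$primary, , drop = FALSE]
  ids <- sprintf("%s|%d-%d|%s", hits$template_id, hits$start, hits$end,
                 hits$strand)
  write_fasta(stats::setNames(hits$insert, ids), path)
}

#' Extract primary-hit inserts keyed by template id
#'
#' @param hits Result of [amplify()].
#' @return Named character vector: template id -> insert sequence of that
#'   template's primary hit.
#' @export
primary_inserts <- function(hits) {
  prim <- hits[hits$primary, , drop = FALSE]
  stats::setNames(prim$insert, prim$template_id)
}
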