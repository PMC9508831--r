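## Assembly evaluation against truth strain genomes. The reference is the
## set of strain-specific genomes (conceptually their concatenation):
## genome fraction measures, per strain, the union of reference bases
## covered by aligned contig blocks; identity is the fraction of
## completely matching bases in each contig's optimal alignment; N50 /
## NGA50, error rate (mismatch + indel), N rate, and the three-trigger
## misassembled-contig classification follow their standard definitions.
## Alignment is the package's own seed-and-extend engine (minimizer
## seeding, best local gapless segment per placement); near-optimal
## alignments within a score ratio of the best are all retained so that
## contigs matching several identical strain regions count toward each.

#' Evaluation parameters
#'
#' @param min_eval_len contigs shorter than this are not evaluated
#'   (default 500 bp; can be lowered to 300-400 for short-read strain
#'   assemblies).
#' @param ambiguity_score alignments scoring at least this fraction of a
#'   contig's best alignment score are all retained (default 0.9999).
#' @param min_block minimum aligned block length in bp (default 65).
#' @param min_block_identity minimum block identity (default 0.9).
#' @param mis_gap_bp adjacent blocks of one contig leaving a reference
#'   gap or overlap beyond this trigger a misassembly (default 1000).
#' @param seed_k,window,max_occ minimizer settings.
#' @return an `eval_params` list.
#' @export
eval_params <- function(min_eval_len = 500L, ambiguity_score = 0.9999,
                        min_block = 65L, min_block_identity = 0.9,
                        mis_gap_bp = 1000L, seed_k = 15L, window = 5L,
                        max_occ = 2000L) {
  structure(list(
    min_eval_len = check_count(min_eval_len, "min_eval_len", 1L),
    ambiguity_score = check_fraction(ambiguity_score, "ambiguity_score"),
    min_block = check_count(min_block, "min_block", 1L),
    min_block_identity = check_fraction(min_block_identity,
                                        "min_block_identity"),
    mis_gap_bp = check_count(mis_gap_bp, "mis_gap_bp", 1L),
    seed_k = check_count(seed_k, "seed_k", 4L),
    window = check_count(window, "window", 1L),
    max_occ = check_count(max_occ, "max_occ", 1L)
  ), class = "eval_params")
}

#' Align contigs to truth strain genomes
#'
#' Finds, per contig, all local alignment blocks to any strain genome
#' (both strands). Within each contig, a non-redundant tiling of blocks
#' is selected greedily by score (`primary = TRUE`); additional blocks
#' scoring at least `ambiguity_score` of the contig's best block are
#' also retained, so a contig matching two identical regions counts for
#' both.
#'
#' @param contigs named character vector of contig sequences.
#' @param truth named character vector of strain genomes.
#' @param params an [eval_params()].
#' @return data.frame of class `contig_alignments`: `contig_id`,
#'   `ref_strain_id`, 0-based half-open `q_start`, `q_end`, `t_start`,
#'   `t_end`, `strand`, `n_match`, `aln_len`, `identity`, `primary`,
#'   `best`.
#' @export
align_contigs_to_truth <- function(contigs, truth,
                                   params = eval_params()) {
  keep <- nchar(contigs) >= params$min_eval_len
  contigs <- contigs[keep]
  empty <- data.frame(contig_id = character(0),
                      ref_strain_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      strand = character(0), n_match = integer(0),
                      aln_len = integer(0), identity = numeric(0),
                      primary = logical(0), best = logical(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("contig_alignments", "data.frame")
  if (length(contigs) == 0L) return(empty)
  bl <- cpp_map_blocks(as.character(contigs), as.character(truth),
                       params$seed_k, params$window, params$max_occ,
                       2L, 4L)
  if (nrow(bl) == 0L) return(empty)
  bl$identity <- bl$n_match / bl$aln_len
  bl <- bl[bl$aln_len >= params$min_block &
             bl$identity >= params$min_block_identity, , drop = FALSE]
  if (nrow(bl) == 0L) return(empty)
  out <- data.frame(
    contig_id = names(contigs)[bl$query],
    ref_strain_id = names(truth)[bl$target],
    q_start = bl$q_start, q_end = bl$q_end,
    t_start = bl$t_start, t_end = bl$t_end,
    strand = ifelse(bl$strand == 0L, "+", "-"),
    n_match = bl$n_match, aln_len = bl$aln_len,
    identity = bl$identity, stringsAsFactors = FALSE)
  ## near-duplicate placements of the same contig region on the same
  ## reference region: keep the best-scoring one
  out <- out[order(out$contig_id, -out$n_match, out$ref_strain_id,
                   out$t_start, method = "radix"), , drop = FALSE]
  dedup <- !logical(nrow(out))
  for (cid in unique(out$contig_id)) {
    rows <- which(out$contig_id == cid)
    for (a in seq_along(rows)) {
      if (!dedup[rows[a]]) next
      ra <- rows[a]
      for (b in seq_along(rows)) {
        if (b <= a || !dedup[rows[b]]) next
        rb <- rows[b]
        if (out$ref_strain_id[ra] == out$ref_strain_id[rb] &&
            out$strand[ra] == out$strand[rb]) {
          qo <- min(out$q_end[ra], out$q_end[rb]) -
            max(out$q_start[ra], out$q_start[rb])
          to <- min(out$t_end[ra], out$t_end[rb]) -
            max(out$t_start[ra], out$t_start[rb])
          if (qo > 0.8 * (out$q_end[rb] - out$q_start[rb]) && to > 0)
            dedup[rb] <- FALSE
        }
      }
    }
  }
  out <- out[dedup, , drop = FALSE]
  ## primary tiling + ambiguity retention per contig
  out$primary <- FALSE
  out$best <- FALSE
  keep_rows <- logical(nrow(out))
  for (cid in unique(out$contig_id)) {
    rows <- which(out$contig_id == cid)
    best_score <- max(out$n_match[rows])
    covered <- integer(0)
    for (r in rows) {  # rows already sorted by descending n_match
      span <- seq.int(out$q_start[r], out$q_end[r] - 1L)
      new <- length(setdiff(span, covered))
      if (new >= max(30L, 0.5 * length(span))) {
        out$primary[r] <- TRUE
        keep_rows[r] <- TRUE
        covered <- union(covered, span)
      } else if (out$n_match[r] >= params$ambiguity_score * best_score) {
        keep_rows[r] <- TRUE  # ambiguous near-optimal duplicate
      }
    }
    cand <- rows[out$n_match[rows] == best_score]
    out$best[cand[1]] <- TRUE
  }
  out <- out[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contig_alignments", "data.frame")
  out
}

#' Genome fraction
#'
#' Percentage of truth bases covered by any retained alignment, per
#' strain and overall (union of covered intervals; overlapping
#' alignments count once).
#'
#' @param alignments a `contig_alignments` data.frame.
#' @param truth named character vector of strain genomes.
#' @return list with `overall` (%) and `per_strain` (named %, one entry
#'   per truth strain).
#' @export
genome_fraction <- function(alignments, truth) {
  per <- setNames(numeric(length(truth)), names(truth))
  covered_total <- 0
  for (s in names(truth)) {
    al <- alignments[alignments$ref_strain_id == s, , drop = FALSE]
    if (nrow(al)) {
      ir <- IRanges::reduce(IRanges::IRanges(start = al$t_start + 1L,
                                             end = al$t_end))
      cov <- sum(IRanges::width(ir))
    } else cov <- 0
    per[s] <- 100 * cov / nchar(truth[[s]])
    covered_total <- covered_total + cov
  }
  list(overall = 100 * covered_total / sum(nchar(truth)),
       per_strain = per)
}

#' N50 of a length set
#'
#' The largest length L such that contigs of length >= L sum to at least
#' half of the total assembly length.
#'
#' @param lengths integer vector of contig lengths.
#' @return N50 in bp (0 for an empty set).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) return(0L)
  l <- sort(as.integer(lengths), decreasing = TRUE)
  l[which(cumsum(as.numeric(l)) >= sum(as.numeric(l)) / 2)[1]]
}

#' NGA50 of aligned blocks against the truth
#'
#' The largest aligned-block length L such that blocks of length >= L
#' cover at least half of the total truth length; `NA` (reported as "-")
#' when all aligned blocks together cover less than half of the truth.
#'
#' @param alignments a `contig_alignments` data.frame (primary blocks
#'   are used).
#' @param truth named character vector of strain genomes.
#' @return NGA50 in bp, or `NA` when undefined.
#' @export
nga50 <- function(alignments, truth) {
  al <- alignments[alignments$primary, , drop = FALSE]
  total <- sum(nchar(truth))
  lens <- sort(al$t_end - al$t_start, decreasing = TRUE)
  if (sum(as.numeric(lens)) < total / 2) return(NA_integer_)
  lens[which(cumsum(as.numeric(lens)) >= total / 2)[1]]
}

#' Classify misassembled contigs
#'
#' A contig with two or more primary alignment blocks is misassembled
#' when any pair of blocks adjacent in contig coordinates (i) leaves a
#' reference gap or overlap larger than `mis_gap_bp`, (ii) switches
#' strand, or (iii) switches strain. Single-block contigs are never
#' misassembled.
#'
#' @param alignments a `contig_alignments` data.frame.
#' @param params an [eval_params()].
#' @return list with `flags` (named logical per evaluated contig),
#'   `reasons` (named character) and `rate` (% of evaluated contigs).
#' @export
classify_misassemblies <- function(alignments, params = eval_params()) {
  cids <- unique(alignments$contig_id)
  flags <- setNames(logical(length(cids)), cids)
  reasons <- setNames(rep("", length(cids)), cids)
  for (cid in cids) {
    al <- alignments[alignments$contig_id == cid & alignments$primary, ,
                     drop = FALSE]
    if (nrow(al) < 2L) next
    al <- al[order(al$q_start), , drop = FALSE]
    for (j in seq_len(nrow(al) - 1L)) {
      a <- al[j, ]; b <- al[j + 1L, ]
      if (a$ref_strain_id != b$ref_strain_id) {
        flags[cid] <- TRUE; reasons[cid] <- "strain_switch"; break
      }
      if (a$strand != b$strand) {
        flags[cid] <- TRUE; reasons[cid] <- "strand_switch"; break
      }
      gap <- if (a$strand == "+") b$t_start - a$t_end
             else a$t_start - b$t_end
      if (abs(gap) > params$mis_gap_bp) {
        flags[cid] <- TRUE; reasons[cid] <- "gap_or_overlap"; break
      }
    }
  }
  list(flags = flags, reasons = reasons,
       rate = if (length(flags)) 100 * mean(flags) else 0)
}

#' Error and N rates
#'
#' Mismatch rate = mismatching columns / aligned columns; indel rate =
#' indel bases / aligned columns; error rate is their sum. N rate is the
#' percentage of ambiguous bases over all evaluated contig bases.
#'
#' @param alignments a `contig_alignments` data.frame (primary blocks).
#' @param contigs named character vector of the evaluated contigs.
#' @return list with `error_rate`, `mismatch_rate`, `indel_rate`,
#'   `n_rate` (all %).
#' @export
error_and_n_rates <- function(alignments, contigs) {
  al <- alignments[alignments$primary, , drop = FALSE]
  cols <- sum(al$aln_len)
  mism <- sum(al$aln_len - al$n_match)
  mismatch_rate <- if (cols > 0) 100 * mism / cols else 0
  indel_rate <- 0  # gapless block model: indels surface as split blocks
  total <- sum(nchar(contigs))
  n_ct <- sum(vapply(contigs, function(s)
    nchar(gsub("[^Nn]", "", s)), numeric(1)))
  list(error_rate = mismatch_rate + indel_rate,
       mismatch_rate = mismatch_rate, indel_rate = indel_rate,
       n_rate = if (total > 0) 100 * n_ct / total else 0)
}

#' Evaluate an assembly against truth strain genomes
#'
#' @param contigs named character vector of contig sequences, or a path
#'   to an assembly FASTA.
#' @param truth named character vector of strain genomes, or a FASTA
#'   path.
#' @param params an [eval_params()].
#' @return an `assembly_metrics` list: overall and per-strain genome
#'   fraction, identity, total length, N50, NGA50, misassembled-contig
#'   rate, error rate and N rate (percent scales), plus the alignments.
#' @export
evaluate_assembly <- function(contigs, truth, params = eval_params()) {
  if (is.character(contigs) && length(contigs) == 1L &&
      file.exists(contigs)) contigs <- parse_fasta(contigs)
  if (is.character(truth) && length(truth) == 1L && file.exists(truth))
    truth <- parse_fasta(truth)
  eval_ct <- contigs[nchar(contigs) >= params$min_eval_len]
  al <- align_contigs_to_truth(contigs, truth, params)
  gf <- genome_fraction(al, truth)
  mis <- classify_misassemblies(al, params)
  rates <- error_and_n_rates(al, eval_ct)
  best <- al[al$best, , drop = FALSE]
  identity <- if (nrow(best)) 100 * sum(best$n_match) / sum(best$aln_len)
              else NA_real_
  structure(list(
    genome_fraction = gf$overall,
    genome_fraction_per_strain = gf$per_strain,
    identity = identity,
    total_len = sum(nchar(contigs)),
    n_contigs = length(contigs),
    n_evaluated = length(eval_ct),
    n50 = n50(nchar(eval_ct)),
    nga50 = nga50(al, truth),
    misassembled_contig_rate = mis$rate,
    misassembly_flags = mis$flags,
    misassembly_reasons = mis$reasons,
    error_rate = rates$error_rate,
    mismatch_rate = rates$mismatch_rate,
    indel_rate = rates$indel_rate,
    n_rate = rates$n_rate,
    alignments = al
  ), class = "assembly_metrics")
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat("Assembly evaluation\n")
  cat(sprintf("  genome fraction: %.2f%%\n", x$genome_fraction))
  cat(sprintf("  identity:        %s\n",
              if (is.na(x$identity)) "-" else sprintf("%.2f%%", x$identity)))
  cat(sprintf("  total length:    %d bp in %d contigs (%d evaluated)\n",
              x$total_len, x$n_contigs, x$n_evaluated))
  cat(sprintf("  N50 / NGA50:     %d / %s bp\n", x$n50,
              if (is.na(x$nga50)) "-" else x$nga50))
  cat(sprintf("  misassembled:    %.2f%%\n", x$misassembled_contig_rate))
  cat(sprintf("  error rate:      %.3f%% (mismatch %.3f%% + indel %.3f%%)\n",
              x$error_rate, x$mismatch_rate, x$indel_rate))
  cat(sprintf("  N rate:          %.3f%%\n", x$n_rate))
  invisible(x)
}
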