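## Quality control preceding assembly: terminal quality trimming, adapter
## clipping, length filtering, and paired-end self-overlap base correction.
## Only the rules relevant to strain-aware assembly are implemented:
## terminal bases below a Phred cutoff are trimmed in a single pass from
## each end, reads are kept only if strictly longer than a minimum length,
## and within the self-overlap of a mate pair a low-quality base is
## replaced by its high-quality partner.

#' Quality-control parameters
#'
#' @param end_trim_phred terminal bases with Phred below this are trimmed
#'   from the 5' and 3' ends (default 20).
#' @param min_len_keep reads are kept only if strictly longer than this
#'   many bp after trimming (default 70).
#' @param min_len_strainaware optional additional minimum read length
#'   (inclusive) for strain-aware assembly of pre-trimmed datasets; off by
#'   default.
#' @param adapters optional character vector of adapter sequences to clip
#'   from read 3' ends.
#' @param mate_margin Phred margin for paired-end base correction: in a
#'   mate self-overlap a disagreeing base is replaced when its partner's
#'   quality exceeds it by at least this much (default 20).
#' @return a `qc_params` list.
#' @export
qc_params <- function(end_trim_phred = 20L, min_len_keep = 70L,
                      min_len_strainaware = NULL, adapters = NULL,
                      mate_margin = 20L) {
  structure(list(
    end_trim_phred = check_count(end_trim_phred, "end_trim_phred"),
    min_len_keep = check_count(min_len_keep, "min_len_keep", min = 1L),
    min_len_strainaware = if (!is.null(min_len_strainaware))
      check_count(min_len_strainaware, "min_len_strainaware", min = 1L),
    adapters = if (!is.null(adapters)) toupper(as.character(adapters)),
    mate_margin = check_count(mate_margin, "mate_margin")
  ), class = "qc_params")
}

## longest 3' clip: full adapter occurrence anywhere, else an exact match
## of an adapter prefix (>= 3 bp) with the read suffix
adapter_clip_pos <- function(seq, adapters) {
  n <- nchar(seq)
  cut <- n
  for (ad in adapters) {
    hit <- regexpr(ad, seq, fixed = TRUE)[1]
    if (hit > 0L) cut <- min(cut, hit - 1L)
    la <- nchar(ad)
    if (min(la, n) < 3L) next
    for (l in seq(min(la, n), 3L)) {
      if (l > cut) next
      if (substr(seq, cut - l + 1L, cut) == substr(ad, 1L, l)) {
        cut <- cut - l
        break
      }
    }
  }
  cut
}

#' Trim reads by terminal quality and adapters, and filter by length
#'
#' Terminal bases with Phred below `end_trim_phred` are removed in a single
#' pass from each end (trimming stops at the first base meeting the
#' threshold); adapters, when given, are clipped from the 3' end. Reads are
#' kept only if the trimmed length is strictly greater than `min_len_keep`
#' (and at least `min_len_strainaware` when that filter is enabled).
#'
#' @param reads a [read_set()] with qualities.
#' @param params a [qc_params()] record.
#' @return a [read_set()] of the kept, trimmed reads, with attribute
#'   `"report"` (a `qc_report`): counts of input/kept/dropped reads and
#'   trimmed bases, reconciling exactly with per-read outcomes.
#' @export
quality_trim <- function(reads, params = qc_params()) {
  n <- nrow(reads)
  if (n == 0L) {
    out <- reads
    attr(out, "report") <- qc_report(0L, 0L, 0L, 0L, 0L)
    return(out)
  }
  if (anyNA(reads$qual)) stopf("quality_trim requires per-base qualities")
  b <- cpp_trim_bounds(reads$qual, params$end_trim_phred)
  s <- b[, 1L]
  e <- b[, 2L]
  seq <- substr(reads$seq, s + 1L, e)
  qual <- substr(reads$qual, s + 1L, e)
  if (!is.null(params$adapters) && length(params$adapters)) {
    cut <- vapply(seq, adapter_clip_pos, integer(1),
                  adapters = params$adapters, USE.NAMES = FALSE)
    seq <- substr(seq, 1L, cut)
    qual <- substr(qual, 1L, cut)
  }
  len <- nchar(seq)
  keep <- len > params$min_len_keep
  if (!is.null(params$min_len_strainaware))
    keep <- keep & len >= params$min_len_strainaware
  out <- read_set(reads$id[keep], seq[keep], qual[keep],
                  reads$mate_id[keep])
  ## mate links to dropped reads are severed
  out$mate_id[!(out$mate_id %in% out$id)] <- NA_character_
  attr(out, "report") <- qc_report(
    n_input = n, n_kept = sum(keep), n_dropped_short = sum(!keep),
    n_bases_trimmed = sum(nchar(reads$seq)) - sum(len),
    n_bases_corrected = 0L)
  out
}

qc_report <- function(n_input, n_kept, n_dropped_short, n_bases_trimmed,
                      n_bases_corrected) {
  stopifnot(n_kept + n_dropped_short == n_input)
  structure(list(n_input = as.integer(n_input), n_kept = as.integer(n_kept),
                 n_dropped_short = as.integer(n_dropped_short),
                 n_bases_trimmed = as.integer(n_bases_trimmed),
                 n_bases_corrected = as.integer(n_bases_corrected)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("QC report: %d reads in, %d kept, %d dropped short; ",
                     "%d bases trimmed, %d bases corrected\n"),
              x$n_input, x$n_kept, x$n_dropped_short, x$n_bases_trimmed,
              x$n_bases_corrected))
  invisible(x)
}

#' Correct mismatched bases in the self-overlap of a mate pair
#'
#' The self-overlap is detected by gapless alignment of the reverse
#' complement of `r2` against `r1` over all offsets (overlap of at least
#' `min_ov` bp at identity >= `min_identity`). Within the overlap, at
#' columns where the mates disagree and one Phred value exceeds the other
#' by at least `params$mate_margin`, the low-quality base and its quality
#' are replaced by the high-quality ones. Without a detectable overlap the
#' reads are returned unchanged.
#'
#' @param r1,r2 single-row [read_set()]s (or lists with `seq`/`qual`).
#' @param params a [qc_params()].
#' @param min_ov minimum overlap length (default 30 bp).
#' @param min_identity minimum overlap identity (default 0.9).
#' @return list with corrected `r1`, `r2` and `n_corrected`.
#' @export
pair_overlap_correct <- function(r1, r2, params = qc_params(),
                                 min_ov = 30L, min_identity = 0.9) {
  res <- cpp_mate_correct(r1$seq, r1$qual, r2$seq, r2$qual,
                          as.integer(min_ov), min_identity,
                          params$mate_margin)
  r1$seq <- res$seq1; r1$qual <- res$qual1
  r2$seq <- res$seq2; r2$qual <- res$qual2
  list(r1 = r1, r2 = r2, n_corrected = res$n_corrected)
}

#' Run the full quality-control stage on a read set
#'
#' Applies paired-end self-overlap correction (for paired reads), then
#' terminal quality trimming, adapter clipping and length filtering.
#'
#' @param reads a [read_set()].
#' @param params a [qc_params()].
#' @param correct_mates logical; run [pair_overlap_correct()] on mate
#'   pairs first (default TRUE).
#' @return kept reads as a [read_set()] with attribute `"report"`.
#' @export
qc_reads <- function(reads, params = qc_params(), correct_mates = TRUE) {
  n_corrected <- 0L
  if (correct_mates && any(!is.na(reads$mate_id))) {
    idx <- match(reads$mate_id, reads$id)
    first <- which(!is.na(idx) & seq_len(nrow(reads)) < idx)
    for (i in first) {
      j <- idx[i]
      res <- cpp_mate_correct(reads$seq[i], reads$qual[i],
                              reads$seq[j], reads$qual[j],
                              30L, 0.9, params$mate_margin)
      if (res$n_corrected > 0L) {
        reads$seq[i] <- res$seq1; reads$qual[i] <- res$qual1
        reads$seq[j] <- res$seq2; reads$qual[j] <- res$qual2
        n_corrected <- n_corrected + res$n_corrected
      }
    }
  }
  out <- quality_trim(reads, params)
  rep <- attr(out, "report")
  rep$n_bases_corrected <- n_corrected
  attr(out, "report") <- rep
  out
}
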