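## All-vs-all suffix-prefix (dovetail) overlap detection and scoring.
##
## Detection uses minimizer seeding (canonical k-mers, sliding-window
## minimum) followed by gapless verification along the seed diagonal; the
## alignment model is substitution-aware, which matches Illumina-type
## short reads where indel errors are rare. Each overlap is scored as
##
##   D = w_identity * i + w_length * o / ((r1 + r2) / 2)
##
## with i the overlap identity (matches / alignment columns), o the
## overlap length and r1, r2 the two sequence lengths; with the default
## weights (0.9 / 0.1) D lies in [0, 1] and trades overlap quality
## against overlap length.

#' Overlap-detection and scoring parameters
#'
#' @param min_ovlen minimum overlap length in bp; overlaps shorter than
#'   this are discarded (default 30, i.e. length < 30 is dropped).
#' @param min_identity minimum overlap identity; overlaps below this are
#'   discarded (default 0.9; the boundary value passes).
#' @param w_identity,w_length score weights for identity and relative
#'   overlap length; must sum to 1 (defaults 0.9 and 0.1).
#' @param overhang_tol tolerance in bp for classifying an alignment as
#'   dovetail/containment when its ends do not exactly reach the sequence
#'   ends (default 5; relevant for imported alignments with overhangs).
#' @param seed_k minimizer k-mer size (default 15).
#' @param window minimizer window length (default 5).
#' @param max_occ seeds occurring in more than this many sequences are
#'   skipped as repetitive (default 150).
#' @return an `overlap_params` list.
#' @export
overlap_params <- function(min_ovlen = 30L, min_identity = 0.9,
                           w_identity = 0.9, w_length = 0.1,
                           overhang_tol = 5L, seed_k = 15L, window = 5L,
                           max_occ = 150L) {
  if (abs(w_identity + w_length - 1) > 1e-9)
    stopf("w_identity + w_length must equal 1")
  structure(list(
    min_ovlen = check_count(min_ovlen, "min_ovlen", min = 1L),
    min_identity = check_fraction(min_identity, "min_identity"),
    w_identity = check_fraction(w_identity, "w_identity"),
    w_length = check_fraction(w_length, "w_length"),
    overhang_tol = check_count(overhang_tol, "overhang_tol"),
    seed_k = check_count(seed_k, "seed_k", min = 4L),
    window = check_count(window, "window", min = 1L),
    max_occ = check_count(max_occ, "max_occ", min = 1L)
  ), class = "overlap_params")
}

## Pick the layout interpretation whose unexplained overhang (aligned-end
## distance from the sequence ends it is supposed to reach) is smallest;
## ties prefer containment. Hits where no interpretation fits within the
## tolerance are internal matches.
classify_hits <- function(a_start, a_end, len_a, ob_start, ob_end, len_b,
                          tol) {
  if (length(a_start) == 0L) return(character(0))
  ov <- cbind(
    b_in_a = ob_start + (len_b - ob_end),
    a_in_b = a_start + (len_a - a_end),
    ab = (len_a - a_end) + ob_start,
    ba = a_start + (len_b - ob_end))
  best <- apply(ov, 1L, which.min)
  type <- colnames(ov)[best]
  type[ov[cbind(seq_along(best), best)] > tol] <- "internal"
  type
}

#' Detect suffix-prefix overlaps among sequences
#'
#' All-vs-all detection of dovetail overlaps (and containments) between
#' the given sequences, in both relative orientations. Pairs are reported
#' once, with the lexicographically smaller id as `id_a`; hits are sorted
#' by `(id_a, id_b, a_start)`. Coordinates are 0-based half-open on the
#' forward orientation of each sequence.
#'
#' @param seqs named character vector of sequences (unique names).
#' @param params an [overlap_params()].
#' @param keep_cigar keep the per-hit CIGAR (`=`/`X` runs) column; turn
#'   off to save memory on large runs.
#' @return data.frame of class `overlap_hits`: `id_a`, `id_b`, `strand`
#'   (`"same"`/`"opposite"`), forward-orientation coordinates, overlap
#'   length `o`, `n_match`, `aln_len`, layout `offset` (start of the
#'   oriented second sequence relative to the first), `type`
#'   (`"ab"`/`"ba"` dovetails, `"b_in_a"`/`"a_in_b"` containments) and
#'   sequence lengths.
#' @export
find_overlaps <- function(seqs, params = overlap_params(),
                          keep_cigar = TRUE) {
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stopf("`seqs` must have unique names")
  if (length(seqs) < 2L)
    return(empty_hits(keep_cigar))
  ord <- order(ids, method = "radix")
  seqs <- as.character(seqs)[ord]
  ids <- ids[ord]
  raw <- cpp_find_overlaps(seqs, params$seed_k, params$window,
                           params$min_ovlen, params$min_identity,
                           params$max_occ, keep_cigar)
  if (nrow(raw) == 0L) return(empty_hits(keep_cigar))
  len <- nchar(seqs)
  la <- len[raw$a]
  lb <- len[raw$b]
  a_start <- pmax(0L, raw$offset)
  a_end <- pmin(la, raw$offset + lb)
  ob_start <- a_start - raw$offset
  ob_end <- a_end - raw$offset
  b_start <- ifelse(raw$strand == 0L, ob_start, lb - ob_end)
  b_end <- ifelse(raw$strand == 0L, ob_end, lb - ob_start)
  out <- data.frame(
    id_a = ids[raw$a], id_b = ids[raw$b],
    strand = ifelse(raw$strand == 0L, "same", "opposite"),
    a_start = a_start, a_end = a_end,
    b_start = b_start, b_end = b_end,
    o = raw$o, n_match = raw$n_match, aln_len = raw$o,
    offset = raw$offset,
    type = classify_hits(a_start, a_end, la, ob_start, ob_end, lb,
                         params$overhang_tol),
    len_a = la, len_b = lb,
    stringsAsFactors = FALSE)
  if (keep_cigar) out$cigar <- raw$cigar
  out <- out[order(out$id_a, out$id_b, out$a_start, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("overlap_hits", "data.frame")
  out
}

empty_hits <- function(keep_cigar = TRUE) {
  out <- data.frame(id_a = character(0), id_b = character(0),
                    strand = character(0), a_start = integer(0),
                    a_end = integer(0), b_start = integer(0),
                    b_end = integer(0), o = integer(0),
                    n_match = integer(0), aln_len = integer(0),
                    offset = integer(0), type = character(0),
                    len_a = integer(0), len_b = integer(0),
                    stringsAsFactors = FALSE)
  if (keep_cigar) out$cigar <- character(0)
  class(out) <- c("overlap_hits", "data.frame")
  out
}

#' Score overlaps
#'
#' Computes, per hit, the identity `i = n_match / aln_len`, the overlap
#' length `o` (the longer of the two overlap spans), and the overlap score
#' `D = w_identity * i + w_length * o / ((r1 + r2) / 2)`.
#'
#' @param hits an `overlap_hits` data.frame from [find_overlaps()] or
#'   [read_paf()].
#' @param params an [overlap_params()] (supplies the weights).
#' @return data.frame of class `scored_overlaps` with appended columns
#'   `i`, `o`, `r1`, `r2`, `D`.
#' @export
score_overlaps <- function(hits, params = overlap_params()) {
  if (any(hits$aln_len == 0L))
    stopf("zero-length alignment cannot be scored")
  out <- as.data.frame(hits)
  out$i <- out$n_match / out$aln_len
  out$o <- pmax(out$a_end - out$a_start, out$b_end - out$b_start)
  out$r1 <- out$len_a
  out$r2 <- out$len_b
  out$D <- params$w_identity * out$i +
    params$w_length * out$o / ((out$r1 + out$r2) / 2)
  class(out) <- c("scored_overlaps", "data.frame")
  out
}

#' Filter scored overlaps by length and identity
#'
#' Retains exactly the overlaps with `o >= min_ovlen` and
#' `i >= min_identity`; both boundary values pass.
#'
#' @param scored a `scored_overlaps` data.frame.
#' @param params an [overlap_params()].
#' @return the retained rows, same class.
#' @export
filter_overlaps <- function(scored, params = overlap_params()) {
  keep <- scored$o >= params$min_ovlen & scored$i >= params$min_identity
  out <- scored[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## PAF interoperability -----------------------------------------------------

#' Write overlap hits to PAF
#'
#' Standard 12-column PAF with a `cg:Z:` CIGAR tag; `id_a` is the query
#' and `id_b` the target, both coordinate sets on forward orientation.
#'
#' @param hits an `overlap_hits` data.frame (with `cigar` column).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(hits, path) {
  cig <- if ("cigar" %in% names(hits)) hits$cigar else NA_character_
  lines <- paste(hits$id_a, hits$len_a, hits$a_start, hits$a_end,
                 ifelse(hits$strand == "same", "+", "-"),
                 hits$id_b, hits$len_b, hits$b_start, hits$b_end,
                 hits$n_match, hits$aln_len, 255L,
                 ifelse(is.na(cig), "", paste0("cg:Z:", cig)),
                 sep = "\t")
  lines <- sub("\t$", "", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read overlap hits from PAF
#'
#' Parses PAF records (at least the 12 mandatory columns) into an
#' `overlap_hits` data.frame; the `cg:Z:` tag supplies the CIGAR.
#'
#' @param path PAF file.
#' @param overhang_tol tolerance used to classify dovetails/containments.
#' @param require_cigar error when a record lacks a `cg:Z:` tag
#'   (identity computation needs it); default TRUE.
#' @return an `overlap_hits` data.frame.
#' @export
read_paf <- function(path, overhang_tol = 5L, require_cigar = TRUE) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stopf("PAF record %d has %d columns; 12 are mandatory",
          which(nf < 12L)[1], nf[which(nf < 12L)[1]])
  get <- function(k) vapply(fields, `[[`, character(1), k)
  cig <- vapply(fields, function(f) {
    tag <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    if (length(tag)) sub("^cg:Z:", "", tag[1]) else NA_character_
  }, character(1))
  if (require_cigar && anyNA(cig))
    stopf("PAF record %d lacks the cg:Z: CIGAR tag required for identity",
          which(is.na(cig))[1])
  strand_chr <- get(5)
  len_a <- as.integer(get(2)); len_b <- as.integer(get(7))
  a_start <- as.integer(get(3)); a_end <- as.integer(get(4))
  b_start <- as.integer(get(8)); b_end <- as.integer(get(9))
  ob_start <- ifelse(strand_chr == "+", b_start, len_b - b_end)
  ob_end <- ifelse(strand_chr == "+", b_end, len_b - b_start)
  out <- data.frame(
    id_a = get(1), id_b = get(6),
    strand = ifelse(strand_chr == "+", "same", "opposite"),
    a_start = a_start, a_end = a_end, b_start = b_start, b_end = b_end,
    o = pmax(a_end - a_start, b_end - b_start),
    n_match = as.integer(get(10)), aln_len = as.integer(get(11)),
    offset = a_start - ob_start,
    type = classify_hits(a_start, a_end, len_a, ob_start, ob_end, len_b,
                         as.integer(overhang_tol)),
    len_a = len_a, len_b = len_b,
    cigar = cig,
    stringsAsFactors = FALSE)
  class(out) <- c("overlap_hits", "data.frame")
  out
}
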