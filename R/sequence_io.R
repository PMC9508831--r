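## FASTQ/FASTA input and output, and the read-set container shared by all
## pipeline stages. A read set is a plain data.frame (class "read_set") with
## columns id, seq, qual (Phred+33 string or NA), mate_id (NA for unpaired).
## Coordinates are 0-based half-open throughout the package.

#' Construct a read set
#'
#' @param id character vector of unique read identifiers.
#' @param seq character vector of DNA sequences.
#' @param qual character vector of Phred+33 quality strings (or `NA` for
#'   FASTA-derived reads); must match `seq` in length base-per-base.
#' @param mate_id optional character vector naming each read's mate
#'   (`NA` for unpaired reads).
#' @return a `read_set` data.frame.
#' @export
read_set <- function(id, seq, qual = NA_character_, mate_id = NA_character_) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  qual <- as.character(qual)
  if (length(qual) == 1L) qual <- rep(qual, length(id))
  if (length(mate_id) == 1L) mate_id <- rep(as.character(mate_id), length(id))
  if (anyDuplicated(id))
    stopf("duplicate read id: %s", id[duplicated(id)][1])
  bad <- which(!is.na(qual) & nchar(qual) != nchar(seq))
  if (length(bad))
    stopf("record '%s': quality length (%d) != sequence length (%d)",
          id[bad[1]], nchar(qual[bad[1]]), nchar(seq[bad[1]]))
  out <- data.frame(id = id, seq = seq, qual = qual, mate_id = mate_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set with %d reads (%d paired), lengths %d-%d bp\n",
              nrow(x), sum(!is.na(x$mate_id)),
              if (nrow(x)) min(nchar(x$seq)) else 0L,
              if (nrow(x)) max(nchar(x$seq)) else 0L))
  invisible(x)
}

#' Parse FASTQ file(s) into a read set
#'
#' Reads one FASTQ file, or a pair of mate files. Gzip input is handled
#' transparently. For paired input the two files must contain the same
#' number of records with matching identifier stems (trailing `/1`, `/2`
#' or ` 1:...`, ` 2:...` tags are stripped); mate linkage is recorded in
#' the `mate_id` column and R2 identifiers are suffixed to stay unique.
#'
#' @param path FASTQ file (R1 for paired data).
#' @param paired_with optional mate (R2) FASTQ file.
#' @return a [read_set()] in file order (R1 block then R2 block for paired
#'   input).
#' @export
parse_fastq <- function(path, paired_with = NULL) {
  r1 <- parse_fastq_one(path)
  if (is.null(paired_with)) {
    return(read_set(r1$id, r1$seq, r1$qual))
  }
  r2 <- parse_fastq_one(paired_with)
  if (length(r1$id) != length(r2$id))
    stopf("mate files differ in record count: %d vs %d",
          length(r1$id), length(r2$id))
  stem1 <- sub("[/ ][12].*$", "", r1$id)
  stem2 <- sub("[/ ][12].*$", "", r2$id)
  if (!all(stem1 == stem2))
    stopf("mate id mismatch at record %d: '%s' vs '%s'",
          which(stem1 != stem2)[1], r1$id[which(stem1 != stem2)[1]],
          r2$id[which(stem1 != stem2)[1]])
  id1 <- paste0(stem1, "/1")
  id2 <- paste0(stem2, "/2")
  read_set(c(id1, id2), c(r1$seq, r2$seq), c(r1$qual, r2$qual),
           mate_id = c(id2, id1))
}

parse_fastq_one <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stopf("malformed FASTQ '%s': %d lines (not a multiple of 4)",
          path, length(lines))
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seq <- lines[seq(2L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  if (length(hdr) && any(substr(hdr, 1L, 1L) != "@"))
    stopf("malformed FASTQ '%s': record %d does not start with '@'",
          path, which(substr(hdr, 1L, 1L) != "@")[1])
  id <- sub("^@", "", hdr)
  id <- sub("\\s.*$", "", id)
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stopf("malformed FASTQ record '%s': %d bases but %d quality values",
          id[bad[1]], nchar(seq[bad[1]]), nchar(qual[bad[1]]))
  list(id = id, seq = toupper(seq), qual = qual)
}

#' Parse a FASTA file
#'
#' @param path FASTA file (gzip handled transparently).
#' @return named character vector of sequences.
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' Writes 80-column wrapped FASTA. Whitespace in identifiers is replaced
#' by `_` (with a message), so records round-trip through [parse_fasta()].
#'
#' @param seqs named character vector of sequences (names are record ids),
#'   or an unnamed vector together with `ids`.
#' @param path output file.
#' @param ids optional character vector of record ids.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, ids = names(seqs)) {
  if (length(seqs) && is.null(ids))
    stopf("record ids are required (names of `seqs` or `ids=`)")
  if (length(ids) && any(grepl("\\s", ids))) {
    message("write_fasta: replacing whitespace in ", sum(grepl("\\s", ids)),
            " record id(s) with '_'")
    ids <- gsub("\\s+", "_", ids)
  }
  dss <- Biostrings::DNAStringSet(setNames(as.character(seqs), ids))
  Biostrings::writeXStringSet(dss, filepath = path, width = 80L)
  invisible(path)
}

#' Write a read set to FASTQ
#'
#' @param reads a [read_set()].
#' @param path output file (one file; mates are interleaved by input order).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  qual[is.na(qual)] <- vapply(nchar(reads$seq[is.na(qual)]),
                              function(n) strrep("I", n), character(1))
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), 4L)] <- reads$seq
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- qual
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
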