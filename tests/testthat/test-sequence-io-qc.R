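test_that("FASTQ parsing yields reads in file order and handles gzip", {
  tmp <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII",
               "@r2 comment", "TTTTGGGG", "+", "!!!!IIII"), tmp)
  rs <- parse_fastq(tmp)
  expect_s3_class(rs, "read_set")
  expect_equal(rs$id, c("r1", "r2"))
  expect_equal(rs$seq, c("ACGTACGT", "TTTTGGGG"))

  gz <- withr::local_tempfile(fileext = ".fastq.gz")
  con <- gzfile(gz, "wt")
  writeLines(readLines(tmp), con)
  close(con)
  rs_gz <- parse_fastq(gz)
  expect_identical(rs_gz, rs)
})

test_that("malformed and mismatched FASTQ input is a hard error", {
  tmp <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@bad", "ACGTACGT", "+", "III"), tmp)
  expect_error(parse_fastq(tmp), "bad")

  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@a/1", "ACGT", "+", "IIII",
               "@b/1", "ACGT", "+", "IIII",
               "@c/1", "ACGT", "+", "IIII"), r1)
  writeLines(c("@a/2", "ACGT", "+", "IIII",
               "@b/2", "ACGT", "+", "IIII"), r2)
  expect_error(parse_fastq(r1, r2), "record count")
})

test_that("paired parsing links mates by id stem", {
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@a/1", "ACGTAA", "+", "IIIIII"), r1)
  writeLines(c("@a/2", "TTACGT", "+", "IIIIII"), r2)
  rs <- parse_fastq(r1, r2)
  expect_equal(nrow(rs), 2L)
  expect_equal(rs$mate_id, c("a/2", "a/1"))
})

test_that("terminal quality trimming applies the stated keep rule", {
  params <- qc_params()  # Phred < 20 trimmed, length > 70 kept
  ## all high quality: unchanged
  set.seed(1)
  rs <- make_read_set(rand_dna(100), q = 30L)
  out <- quality_trim(rs, params)
  expect_equal(out$seq, rs$seq)

  ## 80 bp read whose last 15 bases are Phred 15: trimmed to 65, dropped
  seq80 <- rand_dna(80)
  qual <- paste0(const_qual(65, 30L), const_qual(15, 15L))
  out <- quality_trim(read_set("x", seq80, qual), params)
  expect_equal(nrow(out), 0L)
  rep <- attr(out, "report")
  expect_equal(rep$n_dropped_short, 1L)

  ## exactly 71 bp after trimming: strictly greater than 70, so kept
  seq <- rand_dna(81)
  qual <- paste0(const_qual(71, 30L), const_qual(10, 10L))
  out <- quality_trim(read_set("y", seq, qual), params)
  expect_equal(nchar(out$seq), 71L)

  ## exactly 70 bp: dropped (">70 bp" is strict)
  qual <- paste0(const_qual(70, 30L), const_qual(11, 10L))
  out <- quality_trim(read_set("z", seq, qual), params)
  expect_equal(nrow(out), 0L)
})

test_that("QC is idempotent and kept reads satisfy the invariants", {
  set.seed(42)
  params <- qc_params()
  n <- 50L
  seqs <- vapply(sample(60:120, n, replace = TRUE), rand_dna, character(1))
  quals <- vapply(nchar(seqs), function(k)
    rawToChar(as.raw(sample(c(5L, 15L, 25L, 35L), k, replace = TRUE) + 33L)),
    character(1))
  rs <- read_set(sprintf("p%02d", 1:n), seqs, quals)
  once <- quality_trim(rs, params)
  twice <- quality_trim(once, params)
  expect_equal(twice$seq, once$seq)
  expect_equal(twice$qual, once$qual)
  rep <- attr(once, "report")
  expect_equal(rep$n_kept + rep$n_dropped_short, rep$n_input)
  if (nrow(once)) {
    expect_true(all(nchar(once$seq) > params$min_len_keep))
    first_q <- vapply(once$qual, function(q)
      as.integer(charToRaw(substr(q, 1, 1))) - 33L, integer(1))
    last_q <- vapply(once$qual, function(q)
      as.integer(charToRaw(substr(q, nchar(q), nchar(q)))) - 33L,
      integer(1))
    expect_true(all(first_q >= params$end_trim_phred))
    expect_true(all(last_q >= params$end_trim_phred))
  }
})

test_that("adapter suffixes are clipped before length filtering", {
  ad <- "AGATCGGAAGAGC"
  core <- rand_dna(90)
  rs <- read_set("a", paste0(core, ad), const_qual(90 + nchar(ad), 30L))
  out <- quality_trim(rs, qc_params(adapters = ad))
  expect_equal(out$seq, core)
})

test_that("mate self-overlap correction replaces low-quality bases", {
  set.seed(9)
  frag <- rand_dna(300)
  r1 <- list(seq = substr(frag, 1, 200), qual = const_qual(200, 40L))
  r2_fwd <- substr(frag, 101, 300)  # overlap [101,200] of length 100
  ## plant a disagreement inside the overlap at fragment position 150
  bad <- r2_fwd
  substr(bad, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                 substr(bad, 50, 50))[1]
  ## position 50 on forward r2 = position 151 in the stored (reverse
  ## complement) orientation; give it Phred 5 so r1's Q40 base wins
  r2 <- list(seq = revcomp(bad),
             qual = paste0(const_qual(150, 40L), "&", const_qual(49, 40L)))
  res <- pair_overlap_correct(r1, r2)
  expect_equal(res$n_corrected, 1L)
  expect_equal(revcomp(res$r2$seq), r2_fwd)

  ## identical overlap: nothing corrected
  r2b <- list(seq = revcomp(r2_fwd), qual = const_qual(200, 40L))
  res2 <- pair_overlap_correct(r1, r2b)
  expect_equal(res2$n_corrected, 0L)
  expect_equal(res2$r1$seq, r1$seq)

  ## unrelated mates: no overlap detected, unchanged
  r3 <- list(seq = rand_dna(200), qual = const_qual(200, 40L))
  res3 <- pair_overlap_correct(r1, r3)
  expect_equal(res3$n_corrected, 0L)
})

test_that("FASTA writing round-trips and sanitizes ids", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  seqs <- setNames(c(rand_dna(170), rand_dna(35), rand_dna(90)),
                   c("c1", "c2", "c3"))
  write_fasta(seqs, tmp)
  back <- parse_fasta(tmp)
  expect_equal(back, seqs)

  ## empty input still produces a valid (empty) file
  write_fasta(character(0), tmp)
  expect_equal(length(parse_fasta(tmp)), 0L)

  ## whitespace in ids replaced by underscores
  expect_message(write_fasta(setNames("ACGT", "id with space"), tmp),
                 "whitespace")
  expect_equal(names(parse_fasta(tmp)), "id_with_space")
})

test_that("FASTQ writing round-trips through the parser", {
  tmp <- withr::local_tempfile(fileext = ".fastq")
  rs <- make_read_set(c(rand_dna(80), rand_dna(100)))
  write_fastq(rs, tmp)
  back <- parse_fastq(tmp)
  expect_equal(back$seq, rs$seq)
  expect_equal(back$qual, rs$qual)
})
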