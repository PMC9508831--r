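test_that("suffix-prefix overlaps are found with correct coordinates", {
  set.seed(21)
  a <- paste0(rand_dna(50), rand_dna(50))
  b <- paste0(substr(a, 51, 100), rand_dna(50))
  h <- find_overlaps(c(x = a, y = b))
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "same")
  expect_equal(h$o, 50L)
  expect_equal(h$n_match, 50L)
  expect_equal(h$a_start, 50L)
  expect_equal(h$a_end, 100L)
  expect_equal(h$b_start, 0L)
  expect_equal(h$b_end, 50L)
  expect_equal(h$type, "ab")
  expect_equal(h$cigar, "50=")

  ## reverse-complement partner: strand opposite, forward coordinates
  h2 <- find_overlaps(c(x = a, y = revcomp(b)))
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "opposite")
  expect_equal(h2$o, 50L)
  expect_equal(h2$b_start, 50L)
  expect_equal(h2$b_end, 100L)

  ## two unrelated reads share no seed: no hit
  h3 <- find_overlaps(c(x = rand_dna(100), y = rand_dna(100)))
  expect_equal(nrow(h3), 0L)
})

test_that("engine agrees with the brute-force all-pairs oracle", {
  set.seed(33)
  params <- overlap_params()
  for (rep in 1:3) {
    genome <- rand_dna(600)
    starts <- sort(sample(1:400, 12))
    seqs <- substring(genome, starts, starts + sample(120:200, 12,
                                                      replace = TRUE))
    flip <- runif(12) < 0.4
    seqs[flip] <- revcomp(seqs[flip])
    names(seqs) <- sprintf("s%02d", 1:12)
    hits <- find_overlaps(seqs, params)
    hits <- hits[hits$type %in% c("ab", "ba"), ]
    oracle <- brute_overlaps(seqs, params$min_ovlen, params$min_identity)
    ## dovetail pairs only (exclude containments from the oracle too)
    lens <- nchar(seqs)
    ## classify oracle hits with the same minimal-overhang rule: a pair
    ## counts as dovetail when the dovetail interpretation leaves the
    ## smallest unexplained overhang
    la <- lens[oracle$id_a]; lb <- lens[oracle$id_b]
    a0 <- pmax(0L, oracle$offset); a1 <- pmin(la, oracle$offset + lb)
    ob0 <- a0 - oracle$offset; ob1 <- a1 - oracle$offset
    ov_cont <- pmin(ob0 + (lb - ob1), a0 + (la - a1))
    ov_dove <- pmin((la - a1) + ob0, a0 + (lb - ob1))
    oracle <- oracle[ov_dove < ov_cont & ov_dove <= params$overhang_tol, ]
    key <- function(d) sort(paste(d$id_a, d$id_b, d$strand))
    expect_equal(key(hits), key(oracle), info = sprintf("rep %d", rep))
    ## matches agree on the shared pairs
    m <- merge(hits, oracle, by = c("id_a", "id_b", "strand"))
    expect_equal(m$n_match.x, m$n_match.y)
  }
})

test_that("the overlap score matches hand-evaluated values exactly", {
  mk <- function(n_match, aln_len, o, r1, r2) {
    data.frame(id_a = "a", id_b = "b", strand = "same",
               a_start = 0L, a_end = o, b_start = 0L, b_end = o,
               o = o, n_match = n_match, aln_len = aln_len,
               offset = 0L, type = "ab", len_a = r1, len_b = r2)
  }
  p <- overlap_params()
  ## i = 1, o = 250, r1 = r2 = 250: both terms maximal
  expect_equal(score_overlaps(mk(250, 250, 250, 250, 250), p)$D, 1.0,
               tolerance = 1e-12)
  ## i = 0.95, o = 100, r1 = 250, r2 = 150: 0.9*0.95 + 0.1*100/200
  expect_equal(score_overlaps(mk(95, 100, 100, 250, 150), p)$D, 0.905,
               tolerance = 1e-12)
  ## i = 0.9, o = 30, r1 = r2 = 250: 0.81 + 0.1*30/250
  expect_equal(score_overlaps(mk(27, 30, 30, 250, 250), p)$D, 0.822,
               tolerance = 1e-12)
  ## zero-length alignment is a hard error
  expect_error(score_overlaps(mk(0, 0, 0, 10, 10), p), "zero-length")
})

test_that("the score is bounded and monotone in identity and length", {
  set.seed(5)
  n <- 10000L
  r1 <- sample(100:300, n, replace = TRUE)
  r2 <- sample(100:300, n, replace = TRUE)
  o <- pmin(r1, r2) - sample(0:50, n, replace = TRUE)
  i <- runif(n, 0.5, 1)
  p <- overlap_params()
  D <- p$w_identity * i + p$w_length * o / ((r1 + r2) / 2)
  expect_true(all(D >= 0 & D <= 1))
  ## monotone in i at fixed o, r1, r2
  eps <- 1e-6
  D_up <- p$w_identity * pmin(i + eps, 1) + p$w_length * o / ((r1 + r2) / 2)
  expect_true(all(D_up >= D))
  ## monotone in o at fixed i, r1, r2
  D_o <- p$w_identity * i + p$w_length * (o + 1) / ((r1 + r2) / 2)
  expect_true(all(D_o >= D))
})

test_that("scoring is symmetric under swapping the two sequences", {
  set.seed(77)
  a <- paste0(rand_dna(60), rand_dna(60))
  b <- paste0(substr(a, 61, 120), rand_dna(60))
  h_ab <- score_overlaps(find_overlaps(c(a = a, b = b)))
  h_ba <- score_overlaps(find_overlaps(c(b = a, a = b)))
  expect_equal(h_ab$D, h_ba$D)
  expect_equal(h_ab$i, h_ba$i)
  expect_equal(h_ab$o, h_ba$o)
})

test_that("filtering keeps exactly the stated boundary semantics", {
  p <- overlap_params()
  mk <- function(o, i) {
    data.frame(o = o, i = i, D = 0.9 * i + 0.1 * o / 250)
  }
  sc <- rbind(mk(29, 1.0),   # too short: "<30 bp" discarded
              mk(30, 0.9),   # both boundaries pass
              mk(100, 0.899),# identity below 0.9 discarded
              mk(100, 0.9))
  out <- filter_overlaps(sc, p)
  expect_equal(nrow(out), 2L)
  expect_true(all(out$o >= 30 & out$i >= 0.9))
  ## empty stream passes through
  expect_equal(nrow(filter_overlaps(sc[0, ], p)), 0L)
})

test_that("PAF round-trips losslessly including strand conversion", {
  set.seed(13)
  a <- paste0(rand_dna(80), rand_dna(70))
  b <- paste0(substr(a, 81, 150), rand_dna(80))
  hits <- find_overlaps(c(a = a, b = revcomp(b)))
  expect_equal(hits$strand, "opposite")
  tmp <- withr::local_tempfile(fileext = ".paf")
  write_paf(hits, tmp)
  back <- read_paf(tmp)
  for (col in c("id_a", "id_b", "strand", "a_start", "a_end", "b_start",
                "b_end", "o", "n_match", "aln_len", "offset", "type"))
    expect_equal(back[[col]], hits[[col]], info = col)

  ## '-' strand PAF coordinates are forward-orientation by construction:
  ## the reported target interval must contain the overlap on forward b
  expect_equal(strsplit(readLines(tmp)[1], "\t")[[1]][5], "-")
})

test_that("PAF parsing validates mandatory columns and CIGAR presence", {
  tmp <- withr::local_tempfile(fileext = ".paf")
  writeLines(paste(c("q", 100, 50, 100, "+", "t", 100, 0, 50, 50, 50),
                   collapse = "\t"), tmp)
  expect_error(read_paf(tmp), "12")
  writeLines(paste(c("q", 100, 50, 100, "+", "t", 100, 0, 50, 50, 50, 255),
                   collapse = "\t"), tmp)
  expect_error(read_paf(tmp), "cg:Z:")
  expect_equal(nrow(read_paf(tmp, require_cigar = FALSE)), 1L)
})
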