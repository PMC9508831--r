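test_that("a tiled cluster builds a path graph", {
  set.seed(61)
  g <- rand_dna(340)
  ## 5 reads of 100 bp stepped by 60: only consecutive reads overlap
  starts <- seq(1, by = 60, length.out = 5)
  seqs <- setNames(substring(g, starts, starts + 99),
                   sprintf("v%d", 1:5))
  gg <- build_cluster_graph(seqs, local_params(merge_min_ovlen = 30L))
  ## 4 undirected overlaps = 8 oriented edges (each with its mirror)
  expect_equal(nrow(gg$edges), 8L)
  pairs <- unique(t(apply(cbind(gg$edges$from %/% 2, gg$edges$to %/% 2),
                          1, sort)))
  expect_equal(nrow(pairs), 4L)

  ## two sequences that do not overlap: edgeless graph
  gg2 <- build_cluster_graph(setNames(c(rand_dna(100), rand_dna(100),
                                        rand_dna(100)), c("x", "y", "z")),
                             local_params())
  expect_equal(nrow(gg2$edges), 0L)
})

test_that("haplotype-crossing overlaps fail the strict identity cut", {
  ## one mismatch inside a 99 bp overlap: 98/99 = 0.9899 < 0.99
  set.seed(8)
  h1 <- rand_dna(199)
  h2 <- h1
  substr(h2, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                  substr(h2, 100, 100))[1]
  ## reads of 100 bp: r1 = h1[1..100], r2 = h2[51..150], r3 = h1[100..199]
  seqs <- c(r1 = substr(h1, 1, 100), r2 = substr(h2, 51, 150),
            r3 = substr(h1, 100, 199))
  gg <- build_cluster_graph(seqs, local_params())
  ## r1-r2 and r2-r3 overlaps each span the SNP: excluded at 0.99
  v_r2 <- which(gg$ids == "r2") - 1L
  expect_false(any(gg$edges$from %/% 2 == v_r2 |
                     gg$edges$to %/% 2 == v_r2))
})

test_that("unambiguous paths merge and branches terminate them", {
  set.seed(62)
  g <- rand_dna(400)
  seqs <- setNames(c(substr(g, 1, 200), substr(g, 101, 300),
                     substr(g, 201, 400)), c("a", "b", "c"))
  gg <- build_cluster_graph(seqs, local_params(merge_min_ovlen = 50L))
  res <- merge_unambiguous_paths(gg)
  expect_equal(res$n_merged, 3L)
  expect_equal(nrow(res$vertices), 1L)
  expect_equal(res$vertices$seq, g)

  ## out-branch: a overlaps both b and c at its end; no merge across it
  base <- rand_dna(200)
  tail1 <- paste0(substr(base, 101, 200), rand_dna(100))
  tail2 <- paste0(substr(base, 101, 200), rand_dna(100))
  gg2 <- build_cluster_graph(setNames(c(base, tail1, tail2),
                                      c("a", "b", "c")),
                             local_params(merge_min_ovlen = 50L))
  res2 <- merge_unambiguous_paths(gg2)
  expect_equal(res2$n_merged, 0L)
  expect_equal(nrow(res2$vertices), 3L)

  ## empty graph: empty output
  gg3 <- build_cluster_graph(setNames(c(rand_dna(80), rand_dna(80),
                                        rand_dna(80)), c("x", "y", "z")),
                             local_params())
  res3 <- merge_unambiguous_paths(gg3)
  expect_equal(res3$n_merged, 0L)
})

test_that("consensus votes by quality and keeps single reads intact", {
  r <- rand_dna(60)
  reads <- data.frame(id = c("x", "y", "z"), seq = r,
                      qual = const_qual(60, 40L),
                      stringsAsFactors = FALSE)
  sup <- data.frame(read_id = c("x", "y", "z"), offset = 0L, orient = 0L,
                    len = 60L)
  cons <- consensus_super_read(sup, reads)
  expect_equal(cons$seq, r)
  expect_equal(cons$depth, rep(3L, 60))

  ## weighted majority: {A(Q40), A(Q40), G(Q10)} -> A
  reads2 <- data.frame(
    id = c("x", "y", "z"),
    seq = c(paste0("A", substr(r, 2, 60)), paste0("A", substr(r, 2, 60)),
            paste0("G", substr(r, 2, 60))),
    qual = c(const_qual(60, 40L), const_qual(60, 40L),
             const_qual(60, 10L)),
    stringsAsFactors = FALSE)
  cons2 <- consensus_super_read(sup, reads2)
  expect_equal(substr(cons2$seq, 1, 1), "A")

  ## a single read is its own consensus
  cons3 <- consensus_super_read(sup[1, ], reads)
  expect_equal(cons3$seq, r)

  ## inconsistent offsets (garbage placement) reject the path
  reads4 <- data.frame(id = c("x", "y"),
                       seq = c(rand_dna(60), rand_dna(60)),
                       qual = const_qual(60, 40L),
                       stringsAsFactors = FALSE)
  sup4 <- data.frame(read_id = c("x", "y"), offset = c(0L, 5L),
                     orient = 0L, len = 60L)
  expect_null(consensus_super_read(sup4, reads4))
})

test_that("a single-haplotype cluster assembles into its source sequence", {
  set.seed(63)
  g <- rand_dna(2000)
  reads <- sim_cluster_reads(g, 20, label = "h1")
  res <- assemble_cluster(reads)
  expect_equal(nrow(res$contigs), 1L)
  best <- res$contigs$seq[1]
  expect_true(grepl(best, g, fixed = TRUE) ||
                grepl(revcomp(best), g, fixed = TRUE))
  expect_gte(nchar(best), 1900L)
  ## read conservation: every read is placed or reported unplaced
  expect_setequal(c(res$support$read_id, res$unplaced), reads$id)

  ## degenerate input: fewer than 3 reads emits nothing
  expect_equal(nrow(assemble_cluster(reads[1:2, ])$contigs), 0L)

  ## mutually non-overlapping short reads: nothing above min_contig_out
  rs <- make_read_set(c(rand_dna(200), rand_dna(200), rand_dna(200)))
  expect_equal(nrow(assemble_cluster(rs)$contigs), 0L)
})

test_that("two-haplotype clusters separate into pure contigs", {
  set.seed(64)
  h1 <- rand_dna(3000)
  ## SNP gaps 50-100 bp: every >=100 bp overlap window is discriminating
  h2 <- mutate_genome(h1, 1 - 1 / 75, 50, 100)$genome
  reads <- rbind(sim_cluster_reads(h1, 18, label = "x1"),
                 sim_cluster_reads(h2, 18, label = "x2"))
  class(reads) <- c("read_set", "data.frame")
  res <- assemble_cluster(reads)
  expect_gte(nrow(res$contigs), 2L)
  purity <- support_purity(res)
  expect_true(all(purity == 1))
  ## each haplotype is recovered nearly full length
  al <- align_contigs_to_truth(setNames(res$contigs$seq, res$contigs$id),
                               c(x1 = h1, x2 = h2),
                               eval_params(min_eval_len = 300L))
  gf <- genome_fraction(al, c(x1 = h1, x2 = h2))
  expect_gte(gf$overall, 95)
})

test_that("consensus corrects sequencing errors at depth", {
  set.seed(65)
  g <- rand_dna(2500)
  reads <- sim_cluster_reads(g, 20, label = "e", err = 0.005)
  res <- assemble_cluster(reads)
  al <- align_contigs_to_truth(setNames(res$contigs$seq, res$contigs$id),
                               c(g = g), eval_params(min_eval_len = 300L))
  best <- al[al$best, ]
  expect_gte(100 * sum(best$n_match) / sum(best$aln_len), 99.9)
})
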