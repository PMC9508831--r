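## helper: contigs tiled along a source with chosen overlap lengths
tile_contigs <- function(genome, cuts, overlaps) {
  n <- length(cuts) - 1L
  starts <- integer(n); ends <- integer(n)
  for (j in seq_len(n)) {
    starts[j] <- if (j == 1L) 1L else cuts[j] - overlaps[j - 1L] + 1L
    ends[j] <- cuts[j + 1L]
  }
  setNames(substring(genome, starts, ends), sprintf("c%d", seq_len(n)))
}

test_that("master-graph edges respect the >100 bp and >=0.99 thresholds", {
  set.seed(71)
  g <- rand_dna(1200)
  ## 150 bp exact overlap: edge present
  ct <- data.frame(id = c("a", "b"),
                   seq = c(substr(g, 1, 650), substr(g, 501, 1200)))
  expect_equal(nrow(build_master_graph(ct)$edges), 2L)  # edge + mirror

  ## exactly 100 bp: ">100 bp" is strict, no edge
  ct2 <- data.frame(id = c("a", "b"),
                    seq = c(substr(g, 1, 600), substr(g, 501, 1100)))
  expect_equal(nrow(build_master_graph(ct2)$edges), 0L)

  ## 150 bp at identity ~0.987 (2 mismatches in 150): no edge
  right <- substr(g, 501, 1200)
  substr(right, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                   substr(right, 50, 50))[1]
  substr(right, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                     substr(right, 100, 100))[1]
  ct3 <- data.frame(id = c("a", "b"), seq = c(substr(g, 1, 650), right))
  expect_equal(nrow(build_master_graph(ct3)$edges), 0L)
})

test_that("transitive reduction removes exactly the implied edges", {
  set.seed(72)
  g <- rand_dna(1500)
  ## triangle: a->b, b->c and the implied a->c (a-c overlap 150 bp)
  ct <- data.frame(id = c("a", "b", "c"),
                   seq = c(substr(g, 1, 800), substr(g, 501, 1200),
                           substr(g, 651, 1500)))
  mg <- build_master_graph(ct)
  expect_equal(nrow(mg$edges), 6L)  # 3 undirected edges, both directions
  red <- transitive_reduce(mg)
  expect_equal(nrow(red$edges), 4L)
  ## the removed pair is a->c (and mirror): remaining edges touch b
  expect_true(all(red$edges$from %/% 2 == 1 | red$edges$to %/% 2 == 1))

  ## plain path: nothing to remove
  ct2 <- data.frame(id = c("a", "b", "c"),
                    seq = c(substr(g, 1, 700), substr(g, 551, 1100),
                            substr(g, 951, 1500)))
  mg2 <- build_master_graph(ct2)
  expect_equal(nrow(transitive_reduce(mg2)$edges), nrow(mg2$edges))
})

test_that("transitive reduction agrees with a brute-force oracle", {
  set.seed(73)
  for (rep in 1:100) {
    nv <- sample(5:30, 1)
    ## random linear layout with occasional skip edges
    pos <- sort(sample(0:2000, nv))
    edges <- list()
    for (u in seq_len(nv - 1)) {
      for (w in (u + 1):min(nv, u + 3)) {
        if (runif(1) < 0.7) {
          edges[[length(edges) + 1L]] <-
            data.frame(from = 2L * (u - 1L), to = 2L * (w - 1L),
                       shift = pos[w] - pos[u],
                       o = 200L, i = 1.0, D = 0.95)
        }
      }
    }
    if (length(edges) == 0L) next
    e <- do.call(rbind, edges)
    g <- list(ids = sprintf("v%d", seq_len(nv)), edges = e)
    red <- transitive_reduce(g, global_params())
    oracle_removed <- brute_transitive_edges(e)
    expect_equal(nrow(red$edges), sum(!oracle_removed),
                 info = sprintf("rep %d", rep))
  }
})

test_that("inconsistent layouts are not treated as transitive", {
  ## a->c offset disagrees with a->b->c by 50 bp: edge kept
  e <- data.frame(from = c(0L, 2L, 0L), to = c(2L, 4L, 4L),
                  shift = c(500L, 500L, 1050L),
                  o = 200L, i = 1.0, D = 0.95)
  g <- list(ids = c("a", "b", "c"), edges = e)
  red <- transitive_reduce(g, global_params())
  expect_equal(nrow(red$edges), 3L)
})

test_that("read support prunes unsupported branches", {
  set.seed(74)
  g1 <- rand_dna(1600)
  u <- substr(g1, 1, 800)
  v <- substr(g1, 601, 1600)            # true continuation (200 bp ovl)
  w <- paste0(substr(g1, 601, 800), rand_dna(800))  # fake continuation
  ct <- data.frame(id = c("u", "v", "w"), seq = c(u, v, w),
                   mean_depth = 10)
  ## reads tile the true junction only; 300 bp reads at 20x give several
  ## alignments spanning the 200 bp overlap with margin to spare
  reads <- sim_cluster_reads(g1, 20, read_len = 300L, label = "t")
  mg <- build_master_graph(ct)
  expect_equal(nrow(mg$edges), 4L)  # u-v and u-w, both directions
  mg2 <- detect_branches(mg, reads, global_params())
  ## only the supported u->v (and mirror) edges survive; u is clean
  expect_equal(nrow(mg2$edges), 2L)
  expect_true(all((mg2$edges$from %/% 2 != 2) & (mg2$edges$to %/% 2 != 2)))
  expect_equal(unname(mg2$branch_flags["u"]), "clean")

  ## with reads tiling both junctions, u becomes branched
  g2 <- paste0(substr(g1, 1, 800), substr(w, 201, 1000))
  reads2 <- rbind(reads, sim_cluster_reads(g2, 20, read_len = 300L,
                                           label = "f"))
  mg3 <- detect_branches(mg, reads2, global_params())
  expect_equal(unname(mg3$branch_flags["u"]), "branched")
})

test_that("unique paths extend into master contigs and stop at branches", {
  set.seed(75)
  g <- rand_dna(2000)
  ## clean path of 3 contigs with overlaps 150 and 200 bp
  ct <- tile_contigs(g, c(0, 700, 1300, 2000), c(150, 200))
  df <- data.frame(id = names(ct), seq = unname(ct), mean_depth = 10)
  reads <- sim_cluster_reads(g, 20, read_len = 300L, label = "s")
  res <- extend_unique_paths(build_master_graph(df), reads)
  expect_equal(nrow(res$contigs), 1L)
  expect_equal(res$contigs$length, sum(nchar(ct)) - 350L)
  expect_equal(res$contigs$n_sources, 3L)
  expect_equal(res$contigs$seq, g)

  ## single contig with no edges passes through unchanged
  res1 <- extend_unique_paths(
    build_master_graph(data.frame(id = "solo", seq = rand_dna(900),
                                  mean_depth = 5)), reads = NULL)
  expect_equal(nrow(res1$contigs), 1L)
  expect_equal(res1$contigs$n_sources, 1L)
})

test_that("a branched middle vertex yields two masters and no chimera", {
  set.seed(76)
  shared <- rand_dna(600)
  gA <- paste0(rand_dna(700), shared, rand_dna(700))
  gB <- paste0(rand_dna(700), shared, rand_dna(700))
  ## contigs: A-left+shared, shared+A-right, shared+B-right
  ct <- data.frame(
    id = c("al", "ar", "br"),
    seq = c(substr(gA, 1, 1300 + 150),
            substr(gA, 701, 2000), substr(gB, 701, 2000)),
    mean_depth = 10)
  reads <- rbind(sim_cluster_reads(gA, 20, read_len = 300L, label = "A"),
                 sim_cluster_reads(gB, 20, read_len = 300L, label = "B"))
  res <- extend_unique_paths(build_master_graph(ct), reads)
  ## 'al' must not be merged through the ambiguous shared junction
  expect_equal(nrow(res$contigs), 3L)
  expect_true(all(res$contigs$n_sources == 1L))
})

test_that("assemblies round-trip through write_assembly", {
  set.seed(77)
  g <- rand_dna(1500)
  ct <- tile_contigs(g, c(0, 700, 1500), 200)
  df <- data.frame(id = names(ct), seq = unname(ct), mean_depth = 8)
  res <- extend_unique_paths(build_master_graph(df),
                             sim_cluster_reads(g, 20, read_len = 300L, label = "s"))
  dir <- withr::local_tempdir()
  fa <- write_assembly(res, dir)
  back <- parse_fasta(fa)
  expect_equal(unname(back), res$contigs$seq)
  expect_true(file.exists(file.path(dir, "report.tsv")))
  prov <- read.delim(file.path(dir, "provenance.tsv"))
  expect_setequal(prov$source_id, names(ct))

  ## empty assembly writes empty but valid outputs
  dir2 <- withr::local_tempdir()
  write_assembly(data.frame(id = character(0), seq = character(0)), dir2)
  expect_equal(length(parse_fasta(file.path(dir2, "assembly.fasta"))), 0L)
})
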