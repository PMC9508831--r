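mk_scored <- function(id_a, id_b, D, i = 1.0, o = 100L) {
  data.frame(id_a = id_a, id_b = id_b, D = D, i = i, o = o,
             stringsAsFactors = FALSE)
}

test_that("overlaps sort descending by score with deterministic ties", {
  sc <- mk_scored(c("a", "b", "c"), c("x", "y", "z"), c(0.8, 0.95, 0.9))
  expect_equal(sort_by_score(sc)$D, c(0.95, 0.9, 0.8))

  ## equal D: the higher-identity overlap ranks first
  sc2 <- mk_scored(c("a", "b"), c("x", "y"), c(0.9, 0.9),
                   i = c(0.98, 1.0))
  expect_equal(sort_by_score(sc2)$i, c(1.0, 0.98))

  ## empty input passes through
  expect_equal(nrow(sort_by_score(sc[0, ])), 0L)
})

test_that("single linkage merges in one best-first pass with a size cap", {
  ## transitive chain: one cluster when uncapped
  sc <- mk_scored(c("a", "b"), c("b", "c"), c(0.95, 0.9))
  cs <- single_linkage_cluster(sc, c("a", "b", "c"), max_size = Inf)
  expect_equal(length(cs$clusters), 1L)
  expect_setequal(cs$clusters[[1]], c("a", "b", "c"))

  ## no overlaps: all singletons
  cs2 <- single_linkage_cluster(sc[0, ], letters[1:5], max_size = Inf)
  expect_equal(length(cs2$clusters), 5L)
  expect_equal(cs2$n_singletons, 5L)

  ## cap refuses the b-c merge once both pairs exist:
  ## a-b (0.99), c-d (0.98), b-c (0.97) with cap 2
  sc3 <- mk_scored(c("a", "c", "b"), c("b", "d", "c"),
                   c(0.99, 0.98, 0.97))
  cs3 <- single_linkage_cluster(sc3, c("a", "b", "c", "d"), max_size = 2L)
  expect_equal(sort(unname(vapply(cs3$clusters, paste, character(1),
                                  collapse = "+"))),
               sort(c("a+b", "c+d")))

  ## unsorted input (score increases) is a hard error
  expect_error(single_linkage_cluster(mk_scored(c("a", "b"), c("b", "c"),
                                                c(0.8, 0.9)),
                                      c("a", "b", "c")),
               "sorted")
})

test_that("uncapped clustering equals brute-force connected components", {
  set.seed(19)
  ids <- sprintf("r%03d", 1:200)
  n_edges <- 150L
  ea <- sample(ids, n_edges, replace = TRUE)
  eb <- sample(ids, n_edges, replace = TRUE)
  keep <- ea != eb
  ea <- ea[keep]; eb <- eb[keep]
  sc <- mk_scored(ea, eb, D = round(runif(length(ea), 0.9, 1), 6))
  sc <- sort_by_score(sc)
  cs <- single_linkage_cluster(sc, ids, max_size = Inf)
  oracle <- brute_components(ids, ea, eb)
  ## identical partitions: co-membership must agree
  part_key <- function(assign) {
    split(names(assign), assign) |>
      vapply(function(v) paste(sort(v), collapse = "+"), character(1)) |>
      sort() |> unname()
  }
  expect_equal(part_key(cs$assignments), part_key(oracle))

  ## injecting duplicate records never changes the partition
  dup <- sort_by_score(rbind(sc, sc[seq(1, nrow(sc), 2), ]))
  cs_dup <- single_linkage_cluster(dup, ids, max_size = Inf)
  expect_equal(part_key(cs_dup$assignments), part_key(cs$assignments))

  ## finite caps are always respected
  for (cap in c(5L, 20L)) {
    cs_cap <- single_linkage_cluster(sc, ids, max_size = cap)
    expect_true(all(lengths(cs_cap$clusters) <= cap))
  }
})

test_that("cluster FASTA emission writes a reconciled manifest", {
  set.seed(4)
  ids <- sprintf("r%02d", 1:9)
  reads <- make_read_set(vapply(rep(80, 9), rand_dna, character(1)))
  reads$id <- ids
  ## clusters: {r01..r04}, {r05..r07}, {r08,r09} (below min size 3)
  sc <- mk_scored(c("r01", "r02", "r03", "r05", "r06", "r08"),
                  c("r02", "r03", "r04", "r06", "r07", "r09"),
                  c(0.99, 0.98, 0.97, 0.96, 0.95, 0.94))
  cs <- single_linkage_cluster(sc, ids, max_size = Inf)
  outdir <- withr::local_tempdir()
  man <- emit_cluster_reads(cs, reads, outdir, min_cluster_size = 3L)
  expect_equal(nrow(man), 2L)
  expect_equal(sort(man$n_reads), c(3L, 4L))
  fa <- list.files(outdir, pattern = "^cluster_.*\\.fasta$")
  expect_equal(length(fa), 2L)
  ## the 2-read cluster lands in the unclustered pool
  pool <- parse_fasta(file.path(outdir, "unclustered.fasta"))
  expect_setequal(names(pool), c("r08", "r09"))

  ## byte-identical manifest on rerun (determinism)
  outdir2 <- withr::local_tempdir()
  emit_cluster_reads(cs, reads, outdir2, min_cluster_size = 3L)
  expect_identical(readLines(file.path(outdir, "manifest.tsv")),
                   readLines(file.path(outdir2, "manifest.tsv")))

  ## empty cluster set: manifest with zero rows
  cs0 <- single_linkage_cluster(sc[0, ], character(0), max_size = Inf)
  outdir3 <- withr::local_tempdir()
  man0 <- emit_cluster_reads(cs0, reads, outdir3)
  expect_equal(nrow(man0), 0L)

  ## a missing read is a hard error naming the id
  cs_bad <- single_linkage_cluster(sc[0, ], c(ids, "ghost"),
                                   max_size = Inf)
  expect_error(emit_cluster_reads(cs_bad, reads, withr::local_tempdir()),
               "ghost")
})

test_that("clusters of species-specific reads never mix species", {
  set.seed(55)
  gA <- rand_dna(2000)
  gB <- rand_dna(2000)
  rA <- sim_cluster_reads(gA, 8, label = "A")
  rB <- sim_cluster_reads(gB, 8, label = "B")
  reads <- rbind(rA, rB)
  hits <- find_overlaps(setNames(reads$seq, reads$id),
                        overlap_params(), keep_cigar = FALSE)
  sc <- filter_overlaps(score_overlaps(hits))
  sc <- sc[sc$type %in% c("ab", "ba"), ]
  cs <- single_linkage_cluster(sort_by_score(sc), reads$id,
                               max_size = Inf)
  for (cl in cs$clusters) {
    species <- unique(substr(cl, 1, 1))
    expect_length(species, 1L)
  }
})
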