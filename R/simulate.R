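## Synthetic strain communities with full ground truth. Communities have
## several species; within a species, sibling strains are derived from a
## common ancestor genome by placing substitutions at controlled spacing
## until the requested average nucleotide identity (ANI) is reached.
## Strain abundances follow a log-normal distribution (natural log, mean
## 0; only sigma is exposed since the scale cancels under normalization).
## Paired-end reads are drawn uniformly with FR orientation and i.i.d.
## substitution errors; every read carries a truth record.

#' Community specification
#'
#' Defaults describe a desk-scale benchmark community: 4 species with 2
#' strains each at 99% ANI on 100 kb genomes, 20x mean coverage per
#' strain with log-normal abundance spread, 2x250 bp pairs at 0.3%
#' substitution error.
#'
#' @param n_species number of species.
#' @param strains_per_species strains per species.
#' @param genome_len ancestor genome length in bp.
#' @param target_ani average nucleotide identity between sibling strains
#'   and their ancestor.
#' @param min_snp_gap,max_snp_gap spacing bounds (bp) between consecutive
#'   strain-distinguishing substitutions.
#' @param mean_coverage mean per-strain coverage (x).
#' @param lognormal_sigma sigma of the log-normal abundance draw (0 for
#'   perfectly even strains).
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd fragment (insert) length distribution in
#'   bp; overlapping mates are allowed.
#' @param subst_error per-base substitution sequencing error rate.
#' @param seed integer seed fixing every downstream draw.
#' @return a `community_spec` list.
#' @export
community_spec <- function(n_species = 4L, strains_per_species = 2L,
                           genome_len = 100000L, target_ani = 0.99,
                           min_snp_gap = 50L, max_snp_gap = 400L,
                           mean_coverage = 20, lognormal_sigma = 1,
                           read_len = 250L, insert_mean = 600,
                           insert_sd = 60, subst_error = 0.003,
                           seed = 1L) {
  check_fraction(target_ani, "target_ani")
  check_fraction(subst_error, "subst_error")
  if (lognormal_sigma < 0) stopf("lognormal_sigma must be >= 0")
  structure(list(
    n_species = check_count(n_species, "n_species", 1L),
    strains_per_species = check_count(strains_per_species,
                                      "strains_per_species", 1L),
    genome_len = check_count(genome_len, "genome_len", 100L),
    target_ani = target_ani,
    min_snp_gap = check_count(min_snp_gap, "min_snp_gap", 1L),
    max_snp_gap = check_count(max_snp_gap, "max_snp_gap", 1L),
    mean_coverage = mean_coverage,
    lognormal_sigma = lognormal_sigma,
    read_len = check_count(read_len, "read_len", 20L),
    insert_mean = insert_mean, insert_sd = insert_sd,
    subst_error = subst_error,
    seed = check_count(seed, "seed")
  ), class = "community_spec")
}

#' Random ancestor genome
#'
#' i.i.d. uniform bases; uses the current RNG state.
#'
#' @param len genome length in bp.
#' @return a single DNA string.
#' @export
random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Derive a strain genome by controlled substitution
#'
#' Places `round((1 - target_ani) * len)` substitutions along the
#' ancestor at gaps drawn uniformly from `[min_snp_gap, max_snp_gap]`.
#' When the drawn spacing cannot fit the substitution budget into the
#' genome, gaps are rescaled linearly toward `min_snp_gap` (preserving
#' the lower bound) so the budget is met exactly; if even minimal spacing
#' cannot fit, this is a hard error.
#'
#' @param ancestor ancestor genome (DNA string).
#' @param target_ani requested ANI to the ancestor.
#' @param min_snp_gap,max_snp_gap gap bounds in bp.
#' @return list with `genome`, sorted 0-based `snp_positions`, and
#'   `realized_ani`.
#' @export
mutate_genome <- function(ancestor, target_ani, min_snp_gap = 50L,
                          max_snp_gap = 400L) {
  len <- nchar(ancestor)
  n_mut <- round((1 - target_ani) * len)
  if (n_mut == 0L)
    return(list(genome = ancestor, snp_positions = integer(0),
                realized_ani = 1))
  if ((n_mut - 1L) * min_snp_gap + 1L > len)
    stopf(paste0("infeasible SNP spacing: %d substitutions at minimum gap ",
                 "%d bp need %d bp but the genome has %d"),
          n_mut, min_snp_gap, (n_mut - 1L) * min_snp_gap + 1L, len)
  gaps <- runif(n_mut, min_snp_gap, max_snp_gap)
  span <- sum(gaps)
  if (span > len - 1L) {
    scale <- (len - 1L - n_mut * min_snp_gap) /
      max(span - n_mut * min_snp_gap, 1)
    gaps <- min_snp_gap + (gaps - min_snp_gap) * scale
  }
  pos <- cumsum(round(gaps))
  pos <- pos[pos <= len] - 1L  # 0-based
  pos <- unique(pos[pos >= 0L])
  bases <- strsplit(ancestor, "", fixed = TRUE)[[1]]
  alt <- c(A = "C", C = "G", G = "T", T = "A")
  shift <- sample(1:3, length(pos), replace = TRUE)
  for (j in seq_along(pos)) {
    b <- bases[pos[j] + 1L]
    ord <- c("A", "C", "G", "T")
    k <- match(b, ord)
    if (is.na(k)) next
    bases[pos[j] + 1L] <- ord[(k - 1L + shift[j]) %% 4L + 1L]
  }
  genome <- paste(bases, collapse = "")
  list(genome = genome, snp_positions = pos,
       realized_ani = 1 - length(pos) / len)
}

#' Sample relative strain abundances
#'
#' Weights proportional to LogNormal(0, sigma), normalized to sum 1.
#'
#' @param n number of strains.
#' @param sigma log-normal sigma (0 gives perfectly even weights).
#' @return numeric vector of weights summing to 1.
#' @export
sample_abundances <- function(n, sigma) {
  if (n < 1L) stopf("n must be >= 1")
  if (sigma < 0) stopf("sigma must be >= 0")
  w <- exp(rnorm(n, 0, sigma))
  w / sum(w)
}

#' Simulate a strain community with reads and ground truth
#'
#' Generates ancestor genomes per species, derives sibling strains at the
#' requested ANI, samples abundances, and simulates FR-oriented
#' paired-end reads with uniform fragment placement and i.i.d.
#' substitution errors. Per-strain pair counts are deterministic:
#' `round(coverage * genome_len / (2 * read_len))`. Reads never span
#' genome ends (genomes are linear). All randomness is fixed by the
#' spec's seed.
#'
#' @param spec a [community_spec()].
#' @return list with `strains` (data.frame: `species_id`, `strain_id`,
#'   `genome`, `abundance`, `coverage`, `n_snps`, `realized_ani`),
#'   `snp_positions` (list), `reads` (a [read_set()]; R1 block then R2
#'   block, ids `<strain>_p<k>/1|2`), and `truth` (data.frame:
#'   `read_id`, `strain_id`, `pos` 0-based on the forward genome,
#'   `strand`).
#' @export
simulate_community <- function(spec = community_spec()) {
  set.seed(spec$seed)
  n_strains <- spec$n_species * spec$strains_per_species
  species <- rep(sprintf("sp%d", seq_len(spec$n_species)),
                 each = spec$strains_per_species)
  strain_ids <- sprintf("%s_st%d", species,
                        rep(seq_len(spec$strains_per_species),
                            spec$n_species))
  genomes <- character(n_strains)
  snp_positions <- vector("list", n_strains)
  realized <- numeric(n_strains)
  idx <- 1L
  for (s in seq_len(spec$n_species)) {
    ancestor <- random_genome(spec$genome_len)
    for (k in seq_len(spec$strains_per_species)) {
      if (k == 1L) {
        genomes[idx] <- ancestor
        snp_positions[[idx]] <- integer(0)
        realized[idx] <- 1
      } else {
        mut <- mutate_genome(ancestor, spec$target_ani,
                             spec$min_snp_gap, spec$max_snp_gap)
        genomes[idx] <- mut$genome
        snp_positions[[idx]] <- mut$snp_positions
        realized[idx] <- mut$realized_ani
      }
      idx <- idx + 1L
    }
  }
  ab <- sample_abundances(n_strains, spec$lognormal_sigma)
  coverage <- spec$mean_coverage * n_strains * ab

  all_id <- all_seq <- all_truth_strain <- character(0)
  all_pos <- integer(0)
  all_strand <- character(0)
  r1_seq <- r2_seq <- character(0)
  r1_id <- r2_id <- character(0)
  t_strain <- character(0); t_pos <- integer(0); t_strand <- character(0)
  L <- spec$read_len
  for (j in seq_len(n_strains)) {
    glen <- nchar(genomes[j])
    n_pairs <- round(coverage[j] * glen / (2 * L))
    if (n_pairs == 0L) next
    ins <- pmin(pmax(round(rnorm(n_pairs, spec$insert_mean,
                                 spec$insert_sd)), L), glen)
    start <- floor(runif(n_pairs, 0, glen - ins + 1))  # 0-based
    flip <- runif(n_pairs) < 0.5
    left <- substr(rep(genomes[j], n_pairs), start + 1L, start + L)
    right <- revcomp(substr(rep(genomes[j], n_pairs),
                            start + ins - L + 1L, start + ins))
    ids <- sprintf("%s_p%06d", strain_ids[j], seq_len(n_pairs))
    ## FR orientation; with probability 1/2 the fragment is sequenced
    ## from the other genome strand, swapping which mate is forward
    s1 <- ifelse(flip, right, left)
    s2 <- ifelse(flip, left, right)
    p1 <- ifelse(flip, start + ins - L, start)
    p2 <- ifelse(flip, start, start + ins - L)
    st1 <- ifelse(flip, "-", "+")
    st2 <- ifelse(flip, "+", "-")
    r1_id <- c(r1_id, paste0(ids, "/1"))
    r2_id <- c(r2_id, paste0(ids, "/2"))
    r1_seq <- c(r1_seq, s1)
    r2_seq <- c(r2_seq, s2)
    t_strain <- c(t_strain, rep(strain_ids[j], 2L * n_pairs))
    t_pos <- c(t_pos, p1, p2)
    t_strand <- c(t_strand, st1, st2)
  }
  n1 <- length(r1_id)
  seqs <- c(r1_seq, r2_seq)
  ids <- c(r1_id, r2_id)
  ## truth vectors were appended strain-wise as (p1..., p2...); rebuild in
  ## the same (R1 block, R2 block) order as the read vectors
  t_pos_r1 <- t_pos_r2 <- integer(0)
  t_str_r1 <- t_str_r2 <- character(0)
  t_sn_r1 <- t_sn_r2 <- character(0)
  off <- 0L
  for (j in seq_len(n_strains)) {
    np <- sum(startsWith(r1_id, paste0(strain_ids[j], "_p")))
    if (np == 0L) next
    blk <- seq.int(off + 1L, off + 2L * np)
    t_pos_r1 <- c(t_pos_r1, t_pos[blk[seq_len(np)]])
    t_pos_r2 <- c(t_pos_r2, t_pos[blk[np + seq_len(np)]])
    t_str_r1 <- c(t_str_r1, t_strand[blk[seq_len(np)]])
    t_str_r2 <- c(t_str_r2, t_strand[blk[np + seq_len(np)]])
    t_sn_r1 <- c(t_sn_r1, t_strain[blk[seq_len(np)]])
    t_sn_r2 <- c(t_sn_r2, t_strain[blk[np + seq_len(np)]])
    off <- off + 2L * np
  }
  truth <- data.frame(read_id = ids,
                      strain_id = c(t_sn_r1, t_sn_r2),
                      pos = c(t_pos_r1, t_pos_r2),
                      strand = c(t_str_r1, t_str_r2),
                      stringsAsFactors = FALSE)

  if (spec$subst_error > 0) {
    err <- cpp_add_subst_errors(seqs, spec$subst_error)
    seqs <- as.character(err$seqs)
  }
  q <- if (spec$subst_error > 0)
    min(93L, max(2L, round(-10 * log10(spec$subst_error)))) else 40L
  qual <- vapply(nchar(seqs), function(n)
    strrep(rawToChar(as.raw(q + 33L)), n), character(1))
  reads <- read_set(ids, seqs, qual,
                    mate_id = c(r2_id, r1_id))

  strains <- data.frame(species_id = species, strain_id = strain_ids,
                        genome = genomes, abundance = ab,
                        coverage = coverage,
                        n_snps = lengths(snp_positions),
                        realized_ani = realized,
                        stringsAsFactors = FALSE)
  structure(list(strains = strains, snp_positions = snp_positions,
                 reads = reads, truth = truth, spec = spec),
            class = "strain_community")
}

#' @export
print.strain_community <- function(x, ...) {
  cat(sprintf(paste0("strain_community: %d species x %d strains, %d bp ",
                     "genomes, %d reads (%d pairs)\n"),
              x$spec$n_species, x$spec$strains_per_species,
              x$spec$genome_len, nrow(x$reads), nrow(x$reads) %/% 2L))
  invisible(x)
}

#' Write community reads and truth to disk
#'
#' @param community a `strain_community` from [simulate_community()].
#' @param dir output directory; writes `reads_1.fastq`, `reads_2.fastq`,
#'   `truth_genomes.fasta` and `truth_reads.tsv`.
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads <- community$reads
  is_r1 <- endsWith(reads$id, "/1")
  write_fastq(reads[is_r1, ], file.path(dir, "reads_1.fastq"))
  write_fastq(reads[!is_r1, ], file.path(dir, "reads_2.fastq"))
  write_fasta(setNames(community$strains$genome,
                       community$strains$strain_id),
              file.path(dir, "truth_genomes.fasta"))
  write.table(community$truth, file.path(dir, "truth_reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
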